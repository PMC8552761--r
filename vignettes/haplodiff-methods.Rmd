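---
title: "haplodiff: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haplodiff: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

haplodiff compares the two haploid genomes of a dikaryotic organism — the
setting where both nuclei of a heterokaryotic fungus have been assembled
separately — and carries the comparison through to allele-specific
expression of a tandem-duplicated gene family. This vignette records the
models behind each stage, the parameters that matter, and the design
decisions taken where the problem was genuinely open. It states no result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## Variant classification and gene conservation

A variant between the haplotypes is described by its *affected base size*,
`len(ALT) − len(REF)`: zero for a SNP (both alleles length 1), positive for
insertions, negative for deletions. Length variants are split at the 50-bp
boundary: shorter than 50 bp is an indel, longer an SV. The boundary value
itself (exactly 50) is unassigned by that phrasing; haplodiff assigns
|size| = 50 to the **SV** class, matching the common structural-variant
convention. Equal-length multi-base substitutions have affected size 0 but
are not SNPs; they are rejected as unsupported records rather than silently
mislabelled.

A variant's reference footprint is `[pos, pos + len(REF) − 1]`. An
insertion's footprint is its single anchor base — inserted sequence has no
reference coordinates to occupy. Location labels use the priority
**exon > intron > intergenic**: a footprint touching any exon is exonic even
if it also spans intronic or intergenic bases, consistent with treating
coding contact as the consequential case.

Gene conservation is the fraction of a gene's span covered by variant
footprints: ≤ 0.2 % is *conserved*, ≥ 2 % *variable*, anything between
*intermediate*. Two readings were open:

* **Merging.** Whether overlapping variant footprints should be merged
  before counting is unstated in the rule; haplodiff merges them
  (`IRanges::reduce`) so that a base covered by two variants counts once.
* **Gene length.** "Total length of a gene" is read as the genomic span,
  not the spliced length, since the rule makes no reference to splicing.

Window densities tile each contig with nonoverlapping windows (default
50 kb, the last window short); a variant belongs to the window containing
its `pos`, so window totals always equal the record count.

## The allelome: pairs, duplications, clusters

All relationship calls run off deterministic global protein alignments
(Needleman–Wunsch with BLOSUM62, gap open 10, gap extend 0.5, via
Biostrings). Two statistics are derived per alignment:

* **identity** — matching columns over all alignment columns, gap columns
  included (the stricter of the common conventions);
* **coverage** — aligned residue columns over the length of the *longer*
  sequence, so a short protein perfectly contained in a longer one has
  coverage shorter/longer.

The duplication rule ("similarity ≥ 90 %, shorter covering ≥ 50 % of the
longer") is implemented with similarity read as alignment **identity**, not
substitution-matrix positives; this is a dialect choice and is stated here
because the two differ for diverged pairs.

Allelic pairing combines an identity floor (≥ 85 %) with one-to-one
semantics. The original analysis reconciled this threshold with a
phylogenetic tree; tree building is out of scope here, so the stand-in is
**greedy best-first matching**: candidate pairs above the floor are sorted
by descending identity, then descending alignment score, then
lexicographic gene id, and accepted unless either partner is taken. This is
deterministic, order-independent, and reduces to the tree-based result
whenever alleles are closer to each other than to any paralog — the regime
the generator plants and the tests verify.

Haplotype-specific genes are those with "no comparison result" in the
opposite proteome. The original screen was a BLAST E-value cutoff; an
alignment-threshold surrogate is used instead: a gene is specific when no
opposite-proteome gene reaches identity ≥ 0.5 **and** coverage ≥ 0.5. Both
thresholds are exposed as arguments.

Tandem clusters are maximal runs of duplication-group members in gene-rank
order on one contig, tolerating at most `max_intervening` non-member genes
between consecutive members. The default is 1: the motivating cluster is
essentially contiguous, and 0 would make the call fragile to a single
annotation insertion.

## Differential expression and intersection schemes

DEG status is a fixed-threshold rule — |log2FC| ≥ 1 and p ≤ 1×10⁻³ — on
top of a test statistic. The analysis this package generalises used an
external negative-binomial package; reimplementing it is out of scope, so
`call_degs()` provides a stand-in and, alternatively, ingests any external
per-gene (log2FC, p) table and applies only the thresholds.

The stand-in: counts are normalized by **median-of-ratios size factors**
(DESeq2's estimator), fold changes are
`log2((mean norm + 1) / (mean norm + 1))` with a pseudocount of 1 to keep
zero counts finite, and p-values come from a **moderated t statistic with
empirical-Bayes variance shrinkage** on `log2(norm + 1)` (limma-trend). A
plain per-gene Welch t test is available via `test = "welch"`, but it is
not the default for a calibration reason: with three replicates a Welch
test has 2–4 degrees of freedom, and p ≤ 1×10⁻³ is then nearly unreachable
even at an 8-fold shift (observed sensitivity ≈ 0.5 at NB dispersion 0.05,
mean 200). Sharing variance information across genes restores the power the
fixed threshold assumes — the moderated test reaches sensitivity ≈ 1 with a
null DEG rate below 0.01 under the same conditions, which the acceptance
script measures on every run. No multiple-testing correction is added
beyond the fixed p rule, since none is part of the rule being modelled.

The condition designs are combinatorial rules over DEG sets:

* **Carbon scheme.** All carbon-source pairs are compared at each of the
  two temperatures; for each pair the two temperatures' DEG sets are
  intersected, and the carbon-responsive set is the union of the per-pair
  intersections. The source wording ("the intersection of any pairwise
  comparison at 25 °C and 35 °C, 15 groups in total") admits a second parse
  — intersecting across all 15 groups — so `carbon_scheme()` returns the
  per-pair sets alongside the union and either reading is recoverable.
* **Temperature scheme.** One 25-vs-35 comparison per carbon source, then
  k-of-n membership (`intersect_k_of_n()`): k = n = 6 for the strict
  intersection and k = 5 for the relaxed one. k-of-n is anti-monotone in k
  by construction, which the tests property-check against an exhaustive
  membership-count oracle.

## Allele-specific expression

The expression of the two alleles of a pair is measured only at SNP loci
that distinguish them: per allele, the mean depth over loci and the
condition's replicates, divided by the summed library size of those
replicates, × 10⁶. Whether the original normalization divided by the sum or
the mean of the three replicate library sizes is not stated; the two differ
by a factor of 3 that is identical for both alleles, so every fold ratio —
the quantity dominance calls use — is unaffected. Library size is the
column sum of the full count matrix, the only definition of "total read
count" available to the pipeline.

A pair with zero distinguishing loci is *ASE-unquantifiable*: it is
reported as such, never an error, because it is an expected outcome at low
allelic divergence. Dominance requires the same allele to be strictly
higher in **every** quantified condition; conditions where both alleles are
zero are excluded (logged), and a direction flip yields `none`. The
reported `min_fold` is the weakest fold across conditions, matching the "at
least x-fold" phrasing such analyses use.

## In-silico PCR and clone assignment

Primer matching is exact at non-degenerate positions; IUPAC codes match
their expansion (via Biostrings' ambiguity-aware matcher). No mismatch
tolerance is the strictest reading of an undocumented protocol and is the
default. Both orientations are searched (forward primer on plus strand with
the reverse primer downstream on minus, and the mirror case), products are
capped at `max_product`, and **all** products are reported — the package
does not enforce a single-band assumption, and closely spaced same-strand
copies of a family legitimately yield longer cross-copy products. Product
length counts both primer footprints (standard convention; the 563-bp
figure the generator plants includes the 19-nt and 21-nt primers).

Clones are assigned to the reference amplicon with the highest global DNA
alignment identity (match 2, mismatch −3, gap open 5, extend 2); a tie of
the top two identities within 1×10⁻⁶ is reported `ambiguous` rather than
broken arbitrarily, because reference copies two substitutions apart are
exactly the situation the assay is meant to resolve.

## The synthetic diploid generator

`simulate_diploid()` builds haplotype A from scratch and derives haplotype
B by applying every planted variant, so truth-consistency (A + variants =
B) holds by construction and is still asserted at run time. Design choices,
and what they do and do not emulate:

* **Sequence model.** Ancestral sequence is i.i.d. with configured GC
  content; there is no repeat structure, codon-usage bias or isochore
  structure. Consequences for real data: the simulator cannot exercise
  repeat-mediated misalignment or paralog collapse, so passing tests
  demonstrate correctness of the *rules*, not robustness to assembly
  artefacts.
* **Deterministic event counts.** Each variant class plants exactly
  `round(genome_length × rate)` events; the configured densities are exact
  and sampling noise enters only through placement. Defaults (8×10⁻³ SNPs,
  7.7×10⁻⁴ indels, 3.7×10⁻⁵ SVs per bp) reproduce the magnitude of an
  intrastrain fungal haplotype comparison; they are configuration, not
  claims.
* **Placement constraints.** Variant footprints never overlap (2-bp guard
  band); indels and SVs sit wholly inside one intergenic or intronic
  interval; exonic SNPs avoid first/last codons and never create stop
  codons; the family block, including its primer sites, is off limits to
  background variants. These constraints keep every planted label exactly
  recoverable and are the reason the truth tables can serve as test oracles.
* **Family construction.** Copies diverge at the *protein* level with
  disjoint mutated-site sets (⌊L·d/2⌋ sites per copy from a common
  ancestor), making pairwise paralog identity exactly 1 − 2⌊L·d/2⌋/L —
  at the default d = 0.10 that is ≥ 0.90, the duplication threshold, with
  no sampling risk. Allelic divergence between haplotypes is planted as
  synonymous substitutions at 4-fold-degenerate third codon positions (plus
  substitutions in the non-coding amplicon tail), so the two alleles of a
  copy encode identical proteins while carrying the SNP loci that ASE
  needs. A nonsynonymous allelic model would erode the B-haplotype
  duplication group below its own threshold; the synonymous choice keeps
  the planted structure self-consistent. SVs are planted only as insertions
  and deletions — no inversions or translocations, matching the classes the
  classifier distinguishes.
* **Haplotype-specific genes** are planted as whole-gene deletion (A) or
  insertion (B) SVs with 10-bp flanks, so "specific gene" and "SV" tallies
  are coupled exactly as they are in a real presence/absence comparison.
* **Expression.** Counts are negative binomial around planted means
  (`variance = μ + φμ²`; φ = 0 gives Poisson), with the family induced
  `induction_factor`-fold (default 8) at the induced temperature and
  per-copy allelic bias (defaults 1/1.5, 1, 1, 1.34 as the A:B ratio,
  emulating one copy dominated by each haplotype and two balanced copies).
  Allelic depths at a pair's loci are NB draws whose expectations sum to
  the pair's mean apportioned by the bias. Library size is the column sum
  of the count matrix. The generator does not simulate reads, mapping
  bias, or positional coverage structure — so ASE tests validate the
  estimator, not robustness to alignment artefacts.

## Numerical conventions and problem sizes

Coordinates are 1-based inclusive at every interface (GFF3/VCF convention)
and internally, so file round-trips are lossless and are tested as such.
All randomness flows through a single seed per generator call (an
expression draw may override it to rerun expression over a fixed world);
identical config + seed gives byte-identical output files, which the suite
checks by checksum. Tie-breaks are always deterministic: descending
identity, then score, then lexicographic id in pairing; first-seen root in
duplication components; input order in tallies.

The test and acceptance runs use worlds of 120–150 kb with 16–20 genes for
structure recovery, a 1-Mb world at 10⁻³ SNPs/bp for variant-class
recovery, a 254-gene world for DEG calibration (50 genes at 8-fold, NB
dispersion 0.05, 3 replicates), 100 expression draws for ASE direction
recovery, and 50 for the acceptance fold estimates — sizes chosen so the
full suite exercises every planted structure in about a minute while the
recovered quantities (SNP counts within 3√n, folds within 10 %) sit well
inside their sampling envelopes.

## Known limitations

* The allelic-pairing stand-in assumes alleles are closer than paralogs; a
  family whose duplication postdates the haplotype split can violate this
  and would need the phylogenetic treatment that is out of scope here.
* The DEG stand-in is not the external NB test it replaces; per-gene
  p-values differ even where calls agree. The external-table entry point
  exists precisely so published statistics can be substituted.
* Identity from a single optimal alignment is reported even when co-optimal
  alignments with different identity exist (scores are unique; identities
  need not be). Thresholded decisions are insensitive to this in the
  planted regime but may wobble for borderline real pairs.
* The generator's i.i.d. sequence and constraint-driven placement make
  truth exactly recoverable by design; real data adds mapping error,
  repeat collapse and annotation noise that these tests deliberately do
  not model.
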