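## Variant classification and gene-overlap analysis.
##
## The affected-base size of a variant is len(ALT) - len(REF): 0 for a SNP,
## positive for insertions, negative for deletions. Length variants shorter
## than 50 bp are indels; 50 bp and longer are structural variants. The
## published rule leaves exactly 50 unassigned ("shorter than 50 bp" vs
## "longer than 50 bp"); this package assigns |size| = 50 to the SV class,
## the common convention.

SV_BOUNDARY <- 50L

#' Classify a variant from its REF and ALT alleles
#'
#' @param ref_allele,alt_allele non-empty nucleotide strings (VCF-style,
#'   explicit alleles; no symbolic alleles).
#' @return one of `"SNP"`, `"INS_INDEL"`, `"DEL_INDEL"`, `"INS_SV"`,
#'   `"DEL_SV"`. Vectorized over both arguments.
#' @export
#' @examples
#' classify_variant("A", "T")                         # SNP
#' classify_variant("A", paste0("A", strrep("T", 10)))  # INS_INDEL
classify_variant <- function(ref_allele, alt_allele) {
  if (length(ref_allele) != length(alt_allele)) {
    stop("ref_allele and alt_allele must have the same length")
  }
  if (any(!nzchar(ref_allele)) || any(!nzchar(alt_allele))) {
    stop("empty allele string: REF and ALT must be non-empty")
  }
  bad <- grepl("[^ACGTNacgtn]", ref_allele) | grepl("[^ACGTNacgtn]", alt_allele)
  if (any(bad)) {
    stop("non-nucleotide characters in alleles at record(s) ",
         paste(which(bad), collapse = ", "))
  }
  size <- nchar(alt_allele) - nchar(ref_allele)
  mnp <- size == 0 & nchar(ref_allele) > 1
  if (any(mnp)) {
    stop("equal-length multi-base substitution (record(s) ",
         paste(which(mnp), collapse = ", "),
         ") is not a SNP, insertion or deletion; unsupported")
  }
  out <- character(length(size))
  out[size == 0] <- "SNP"
  out[size > 0 & size < SV_BOUNDARY] <- "INS_INDEL"
  out[size >= SV_BOUNDARY] <- "INS_SV"
  out[size < 0 & size > -SV_BOUNDARY] <- "DEL_INDEL"
  out[size <= -SV_BOUNDARY] <- "DEL_SV"
  out
}

#' Tally variant records into SNP / indel / SV counts
#'
#' @param variants data.frame with `ref` and `alt` columns (a `var_class`
#'   column, if present, is recomputed from the alleles).
#' @return named integer vector `c(SNP=, indel=, SV=)`, where indel sums both
#'   insertion and deletion indels, and SV both SV orientations.
#' @export
summarize_variant_classes <- function(variants) {
  if (nrow(variants) == 0) return(c(SNP = 0L, indel = 0L, SV = 0L))
  cls <- classify_variant(variants$ref, variants$alt)
  c(SNP = sum(cls == "SNP"),
    indel = sum(cls %in% c("INS_INDEL", "DEL_INDEL")),
    SV = sum(cls %in% c("INS_SV", "DEL_SV")))
}

## reference footprint of a variant: [pos, pos + max(len(ref), 1) - 1];
## an insertion occupies only its anchor base
variant_footprint <- function(variants) {
  IRanges::IRanges(variants$pos,
                   variants$pos + pmax(nchar(variants$ref), 1L) - 1L)
}

#' Locate variants relative to gene models
#'
#' A variant's reference footprint is `[pos, pos + len(REF) - 1]` (a single
#' anchor base for insertions). The label is `exon` if the footprint touches
#' any exon, else `intron` if it touches a gene span, else `intergenic` —
#' exon contact dominates when a footprint straddles a boundary.
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt`.
#' @param genes data.frame of gene spans (`gene_id`, `contig`, `start`,
#'   `end`).
#' @param exons data.frame of exon intervals (`gene_id`, `contig`, `start`,
#'   `end`).
#' @return character vector of labels, one per variant.
#' @export
annotate_variant_location <- function(variants, genes, exons) {
  if (nrow(variants) == 0) return(character(0))
  missing_ctg <- setdiff(unique(variants$contig), unique(genes$contig))
  ## contigs may legitimately carry no genes only if the annotation knows them
  if (length(missing_ctg) > 0 && !all(missing_ctg %in% exons$contig)) {
    stop("contig(s) absent from the gene annotation: ",
         paste(missing_ctg, collapse = ", "))
  }
  out <- rep("intergenic", nrow(variants))
  for (ctg in unique(variants$contig)) {
    vi <- which(variants$contig == ctg)
    fp <- variant_footprint(variants[vi, ])
    gs <- genes[genes$contig == ctg, ]
    es <- exons[exons$contig == ctg, ]
    in_gene <- IRanges::countOverlaps(fp, IRanges::IRanges(gs$start, gs$end)) > 0
    in_exon <- IRanges::countOverlaps(fp, IRanges::IRanges(es$start, es$end)) > 0
    out[vi[in_gene]] <- "intron"
    out[vi[in_exon]] <- "exon"
  }
  out
}

#' Call gene conservation from variant overlap
#'
#' Variant footprints on the gene's contig are merged (so shared bases are
#' not double-counted) and intersected with the gene's genomic span. Genes
#' whose overlapped fraction is at most 0.2% of the span are `conserved`,
#' at least 2% `variable`, otherwise `intermediate`.
#'
#' @param genes data.frame of gene spans (`gene_id`, `contig`, `start`, `end`).
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt`.
#' @param conserved_max,variable_min the two published fraction thresholds.
#' @return data.frame with `gene_id`, `overlap_bases`, `fraction`, `label`.
#' @export
classify_gene_conservation <- function(genes, variants,
                                       conserved_max = 0.002,
                                       variable_min = 0.02) {
  if (conserved_max >= variable_min) {
    stop("conserved_max must be below variable_min")
  }
  span_len <- genes$end - genes$start + 1L
  if (any(span_len <= 0)) {
    stop("zero- or negative-length gene span: ",
         paste(genes$gene_id[span_len <= 0], collapse = ", "))
  }
  overlap <- integer(nrow(genes))
  for (ctg in unique(genes$contig)) {
    gi <- which(genes$contig == ctg)
    v <- variants[variants$contig == ctg, , drop = FALSE]
    if (nrow(v) == 0) next
    fp <- IRanges::reduce(variant_footprint(v))
    span <- IRanges::IRanges(genes$start[gi], genes$end[gi])
    hits <- IRanges::findOverlaps(span, fp)
    if (length(hits) == 0) next
    ov_w <- IRanges::width(IRanges::pintersect(
      span[S4Vectors::queryHits(hits)], fp[S4Vectors::subjectHits(hits)]))
    overlap[gi] <- overlap[gi] +
      as.integer(tapply(ov_w, factor(S4Vectors::queryHits(hits),
                                     levels = seq_along(gi)), sum,
                        default = 0L))
  }
  fraction <- overlap / span_len
  label <- ifelse(fraction <= conserved_max, "conserved",
                  ifelse(fraction >= variable_min, "variable", "intermediate"))
  data.frame(gene_id = genes$gene_id, overlap_bases = overlap,
             fraction = fraction, label = label, stringsAsFactors = FALSE)
}

#' Variant counts over nonoverlapping genomic windows
#'
#' Windows tile each contig as `[1, window]`, `[window + 1, 2 * window]`, …;
#' the last window of a contig may be short. A variant is counted in the
#' window containing its `pos`.
#'
#' @param variants data.frame with `contig` and `pos`.
#' @param contig_lengths named numeric vector of contig lengths.
#' @param window window size in bases (default the published 50 kb).
#' @return data.frame with `contig`, `window_start`, `window_end`, `count`.
#' @export
variant_density_windows <- function(variants, contig_lengths, window = 50000) {
  stopifnot(window > 0)
  out <- list()
  for (ctg in names(contig_lengths)) {
    L <- contig_lengths[[ctg]]
    starts <- seq(1, L, by = window)
    ends <- pmin(starts + window - 1, L)
    pos <- variants$pos[variants$contig == ctg]
    idx <- findInterval(pos, starts)
    cnt <- tabulate(idx, nbins = length(starts))
    out[[length(out) + 1]] <- data.frame(
      contig = ctg, window_start = starts, window_end = ends, count = cnt,
      stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(variants$contig), names(contig_lengths))
  if (length(unknown) > 0) {
    stop("variants on contig(s) missing from contig_lengths: ",
         paste(unknown, collapse = ", "))
  }
  do.call(rbind, out)
}
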