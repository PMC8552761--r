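## Cross-haplotype gene relationship structure: haplotype-specific genes,
## one-to-one allelic pairs, duplication groups, tandem clusters.
##
## All decisions run off deterministic global (Needleman-Wunsch) protein
## alignments with BLOSUM62 and affine gaps. "Identity" is matching columns
## over all alignment columns (gap columns included); "coverage" is the
## number of aligned residue pairs over the length of the longer sequence,
## so a short sequence perfectly contained in a longer one has
## coverage = shorter/longer.

ALIGN_GAP_OPEN <- 10
ALIGN_GAP_EXTEND <- 0.5

#' Global pairwise protein alignment statistics
#'
#' @param a,b amino-acid strings (20-letter alphabet plus X).
#' @return list with `identity` (matches / alignment columns), `coverage`
#'   (aligned residue columns / longer length) and `score` (BLOSUM62,
#'   gap open 10, gap extend 0.5). Symmetric in `a` and `b`.
#' @export
#' @examples
#' align_proteins("HEAGAWGHEE", "HEAGAWGHEE")$identity  # 1
align_proteins <- function(a, b) {
  check_protein(a, "a")
  check_protein(b, "b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND)
  alignment_stats(aln, nchar(a), nchar(b))
}

alignment_stats <- function(aln, len_a, len_b) {
  n_match <- Biostrings::nmatch(aln)
  n_mismatch <- Biostrings::nmismatch(aln)
  n_cols <- nchar(aln)   # alignment length including gap columns
  list(identity = n_match / n_cols,
       coverage = (n_match + n_mismatch) / max(len_a, len_b),
       score = Biostrings::score(aln))
}

check_protein <- function(x, arg) {
  if (!nzchar(x)) stop("empty protein sequence in argument '", arg, "'")
  bad <- regexpr(paste0("[^", paste(c(AA_ALPHABET20, "X"), collapse = ""), "]"), x)
  if (bad > 0) {
    stop("illegal residue '", substr(x, bad, bad), "' at position ", bad,
         " of argument '", arg, "'")
  }
  invisible(TRUE)
}

## all-vs-all alignment stats between two protein sets; one vectorized
## pairwiseAlignment call per query keeps this fast enough for proteomes
align_all <- function(prots_a, prots_b) {
  ids_a <- names(prots_a); ids_b <- names(prots_b)
  subj <- Biostrings::AAStringSet(prots_b)
  res <- vector("list", length(prots_a))
  for (i in seq_along(prots_a)) {
    aln <- Biostrings::pairwiseAlignment(
      subj, Biostrings::AAString(prots_a[[i]]), type = "global",
      substitutionMatrix = "BLOSUM62",
      gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND)
    n_match <- Biostrings::nmatch(aln)
    n_mm <- Biostrings::nmismatch(aln)
    n_cols <- nchar(aln)
    res[[i]] <- data.frame(
      gene_a = ids_a[i], gene_b = ids_b,
      identity = n_match / n_cols,
      coverage = (n_match + n_mm) /
        pmax(nchar(prots_a[[i]]), nchar(prots_b)),
      score = Biostrings::score(aln),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

as_protein_vector <- function(x) {
  if (is(x, "AAStringSet")) setNames(as.character(x), names(x)) else x
}

#' Find haplotype-specific genes
#'
#' A gene is haplotype-specific when no gene in the opposite proteome
#' reaches the hit thresholds; the definition is applied symmetrically in
#' both directions.
#'
#' @param proteome_a,proteome_b named character vectors or
#'   [Biostrings::AAStringSet] of protein sequences.
#' @param min_hit_identity,min_hit_coverage alignment thresholds below which
#'   a comparison does not count as a hit (defaults 0.5 / 0.5, an alignment
#'   surrogate for "no comparison result" under a BLAST E-value screen).
#' @return list with `A_specific` and `B_specific` gene-id vectors.
#' @export
find_haplotype_specific <- function(proteome_a, proteome_b,
                                    min_hit_identity = 0.5,
                                    min_hit_coverage = 0.5) {
  pa <- as_protein_vector(proteome_a); pb <- as_protein_vector(proteome_b)
  stopifnot(length(pa) > 0, length(pb) > 0)
  st <- align_all(pa, pb)
  hit <- st$identity >= min_hit_identity & st$coverage >= min_hit_coverage
  list(A_specific = setdiff(names(pa), unique(st$gene_a[hit])),
       B_specific = setdiff(names(pb), unique(st$gene_b[hit])))
}

#' Resolve one-to-one allelic pairs between two proteomes
#'
#' Candidate pairs at protein identity >= `min_identity` are matched
#' greedily in descending (identity, score) order, with a lexicographic
#' gene-id tie-break, so that no gene appears in two pairs.
#'
#' @inheritParams find_haplotype_specific
#' @param min_identity allelic identity threshold (published value 0.85).
#' @return list with `pairs` (data.frame `gene_a`, `gene_b`, `identity`,
#'   `score`) and `unmatched_a` / `unmatched_b` id vectors.
#' @export
resolve_allelic_pairs <- function(proteome_a, proteome_b, min_identity = 0.85) {
  pa <- as_protein_vector(proteome_a); pb <- as_protein_vector(proteome_b)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(pa) == 0 || length(pb) == 0) {
    return(list(pairs = empty, unmatched_a = names(pa), unmatched_b = names(pb)))
  }
  st <- align_all(pa, pb)
  st <- st[st$identity >= min_identity, , drop = FALSE]
  st <- st[order(-st$identity, -st$score, st$gene_a, st$gene_b), , drop = FALSE]
  used_a <- character(0); used_b <- character(0); keep <- integer(0)
  for (r in seq_len(nrow(st))) {
    if (st$gene_a[r] %in% used_a || st$gene_b[r] %in% used_b) next
    keep <- c(keep, r)
    used_a <- c(used_a, st$gene_a[r]); used_b <- c(used_b, st$gene_b[r])
  }
  pairs <- st[keep, c("gene_a", "gene_b", "identity", "score"), drop = FALSE]
  rownames(pairs) <- NULL
  stopifnot(!anyDuplicated(pairs$gene_a), !anyDuplicated(pairs$gene_b))
  list(pairs = pairs,
       unmatched_a = setdiff(names(pa), pairs$gene_a),
       unmatched_b = setdiff(names(pb), pairs$gene_b))
}

#' Detect within-haplotype duplication groups
#'
#' Two genes are duplicates when the shorter protein covers at least
#' `min_coverage` of the longer and the alignment identity is at least
#' `min_identity`; groups are connected components (>= 2 members) of the
#' resulting graph.
#'
#' @param proteome named character vector or [Biostrings::AAStringSet].
#' @param min_coverage,min_identity published duplication thresholds
#'   (0.5 and 0.9).
#' @return list of character vectors of member gene ids, sorted by size
#'   then lexicographically.
#' @export
detect_duplications <- function(proteome, min_coverage = 0.5,
                                min_identity = 0.9) {
  p <- as_protein_vector(proteome)
  n <- length(p)
  if (n < 2) return(list())
  ids <- names(p)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  st <- align_all(p, p)
  st <- st[match(st$gene_a, ids) < match(st$gene_b, ids), , drop = FALSE]
  edge <- st$coverage >= min_coverage & st$identity >= min_identity
  for (r in which(edge)) {
    ra <- find(match(st$gene_a[r], ids)); rb <- find(match(st$gene_b[r], ids))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(ids, roots)
  comps <- comps[vapply(comps, length, integer(1)) >= 2]
  comps <- lapply(unname(comps), sort)
  comps[order(-vapply(comps, length, integer(1)),
              vapply(comps, `[`, character(1), 1))]
}

#' Detect tandem clusters of duplicated genes
#'
#' Within each duplication group and contig, members are scanned in gene
#' order (by start coordinate); maximal runs whose consecutive members are
#' separated by at most `max_intervening` non-member genes form clusters.
#'
#' @param groups list of duplication groups ([detect_duplications()] output).
#' @param genes data.frame of gene models (`gene_id`, `contig`, `start`,
#'   `strand`) providing the gene order.
#' @param max_intervening maximum non-member genes tolerated between
#'   consecutive cluster members (default 1).
#' @return list of data.frames (`gene_id`, `contig`, `strand`, `rank`) in
#'   genomic order, clusters of size >= 2 only.
#' @export
detect_tandem_clusters <- function(groups, genes, max_intervening = 1) {
  missing <- setdiff(unlist(groups), genes$gene_id)
  if (length(missing) > 0) {
    stop("gene(s) missing coordinates in the annotation: ",
         paste(missing, collapse = ", "))
  }
  genes <- genes[order(genes$contig, genes$start), ]
  genes$rank <- stats::ave(genes$start, genes$contig, FUN = seq_along)
  out <- list()
  for (grp in groups) {
    sub <- genes[genes$gene_id %in% grp, ]
    for (ctg in unique(sub$contig)) {
      m <- sub[sub$contig == ctg, ]
      m <- m[order(m$rank), ]
      if (nrow(m) < 2) next
      run_id <- cumsum(c(1, diff(m$rank) > max_intervening + 1))
      for (rid in unique(run_id)) {
        run <- m[run_id == rid, ]
        if (nrow(run) < 2) next
        out[[length(out) + 1]] <- data.frame(
          gene_id = run$gene_id, contig = run$contig, strand = run$strand,
          rank = run$rank, stringsAsFactors = FALSE)
      }
    }
  }
  out
}
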