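## Expression normalization, threshold-based DEG calling, and the
## carbon-source / temperature intersection schemes.

#' TPM-normalize a count matrix
#'
#' Per sample, counts are divided by gene length in kb, and the resulting
#' rates scaled to sum to one million (transcripts per million).
#'
#' @param counts integer matrix (genes x samples) or a `CountMatrix` from
#'   [simulate_expression()].
#' @param gene_lengths named vector of gene lengths in bases (taken from the
#'   `CountMatrix` if omitted).
#' @return numeric matrix of TPM values; an all-zero sample stays all-zero
#'   with a warning.
#' @export
#' @examples
#' tpm_normalize(matrix(c(10, 20, 30), 3, 1,
#'                      dimnames = list(c("a", "b", "c"), "s1")),
#'               c(a = 1000, b = 1000, c = 2000))
tpm_normalize <- function(counts, gene_lengths = NULL) {
  if (is(counts, "CountMatrix")) {
    gene_lengths <- gene_lengths %||% counts$gene_lengths
    counts <- counts$counts
  }
  stopifnot(!is.null(gene_lengths))
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(is.na(gene_lengths)) || any(gene_lengths <= 0)) {
    stop("every gene needs a positive length")
  }
  rate <- counts / (gene_lengths / 1000)
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    warning("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "))
    totals[zero] <- 1
  }
  sweep(rate, 2, totals, "/") * 1e6
}

## median-of-ratios size factors with a column-sum fallback for degenerate
## matrices (every gene containing a zero)
size_factors <- function(counts) {
  sf <- tryCatch(DESeq2::estimateSizeFactorsForMatrix(counts),
                 error = function(e) NULL)
  if (is.null(sf) || any(!is.finite(sf))) {
    warning("median-of-ratios undefined (every gene has a zero count); ",
            "falling back to library-size factors")
    ls <- colSums(counts)
    sf <- ls / exp(mean(log(ls[ls > 0])))
    sf[sf == 0] <- 1
  }
  sf
}

#' Call differentially expressed genes between two conditions
#'
#' The test statistic is a stand-in for the external package the published
#' thresholds were used with: counts are normalized with median-of-ratios
#' size factors and tested on the log2(normalized count + 1) scale. The
#' default test is a moderated t with empirical-Bayes variance shrinkage
#' across genes (limma-trend), which keeps the fixed p <= 1e-3 rule usable
#' at three replicates; `test = "welch"` gives a plain per-gene two-sided
#' Welch t test instead. The log2 fold change is always
#' log2((mean normalized count + 1) / (mean normalized count + 1)). A gene
#' is flagged DEG when |log2FC| >= `lfc_min` and p <= `p_max`
#' (published rule: 1 and 1e-3).
#'
#' Alternatively pass `stats_table` (data.frame with `gene_id`, `log2fc`,
#' `pvalue` from an external DE tool) to apply only the thresholds.
#'
#' @param counts integer matrix (genes x samples) or `CountMatrix`.
#' @param samples data.frame with `sample` and `condition` (taken from the
#'   `CountMatrix` if omitted).
#' @param condition_pair character(2): the two condition labels to compare
#'   (fold change is condition_pair[2] over condition_pair[1]).
#' @param lfc_min,p_max DEG thresholds.
#' @param test `"moderated"` (default) or `"welch"`.
#' @param stats_table optional external per-gene statistics; bypasses the
#'   built-in test.
#' @return data.frame `gene_id`, `log2fc`, `pvalue`, `deg`.
#' @export
call_degs <- function(counts, samples = NULL, condition_pair = NULL,
                      lfc_min = 1, p_max = 1e-3,
                      test = c("moderated", "welch"), stats_table = NULL) {
  test <- match.arg(test)
  if (!is.null(stats_table)) {
    stopifnot(all(c("gene_id", "log2fc", "pvalue") %in% names(stats_table)))
    out <- stats_table[, c("gene_id", "log2fc", "pvalue")]
    out$deg <- abs(out$log2fc) >= lfc_min & out$pvalue <= p_max
    return(out)
  }
  if (is(counts, "CountMatrix")) {
    samples <- samples %||% counts$samples
    counts <- counts$counts
  }
  stopifnot(!is.null(samples), length(condition_pair) == 2)
  sel1 <- samples$sample[samples$condition == condition_pair[1]]
  sel2 <- samples$sample[samples$condition == condition_pair[2]]
  if (length(sel1) < 2 || length(sel2) < 2) {
    stop("need >= 2 replicates per condition (variance undefined)")
  }
  sub <- counts[, c(sel1, sel2), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  x1 <- norm[, sel1, drop = FALSE]; x2 <- norm[, sel2, drop = FALSE]
  log2fc <- log2((rowMeans(x2) + 1) / (rowMeans(x1) + 1))
  l1 <- log2(x1 + 1); l2 <- log2(x2 + 1)
  pvalue <- if (test == "moderated") {
    design <- cbind(intercept = 1,
                    group = c(rep(0, length(sel1)), rep(1, length(sel2))))
    fit <- limma::lmFit(cbind(l1, l2), design)
    ## the mean-variance trend needs a reasonable number of genes
    fit <- tryCatch(limma::eBayes(fit, trend = nrow(norm) >= 20),
                    error = function(e) limma::eBayes(fit, trend = FALSE))
    fit$p.value[, "group"]
  } else {
    vapply(seq_len(nrow(norm)), function(g) {
      a <- l1[g, ]; b <- l2[g, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      }
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    }, numeric(1))
  }
  pvalue[is.na(pvalue)] <- 1
  data.frame(gene_id = rownames(counts), log2fc = log2fc, pvalue = pvalue,
             deg = abs(log2fc) >= lfc_min & pvalue <= p_max,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genes present in at least k of n sets
#'
#' @param sets list of character vectors (gene-id sets).
#' @param k membership threshold; `k = length(sets)` is the plain
#'   intersection, `k = 1` the union.
#' @return character vector of gene ids (sorted).
#' @export
#' @examples
#' intersect_k_of_n(list(c("a", "b"), c("b", "c"), c("b", "d")), 3)  # "b"
intersect_k_of_n <- function(sets, k) {
  n <- length(sets)
  if (k < 1 || k > n) stop("k must be between 1 and the number of sets (", n, ")")
  tab <- table(unlist(lapply(sets, unique)))
  sort(names(tab)[tab >= k])
}

#' Carbon-source responsive DEGs from the 15-pair cross-temperature scheme
#'
#' For every carbon-source pair, the DEG sets from the two temperatures are
#' intersected; the carbon-responsive set is the union of the per-pair
#' intersections. Per-pair sets are returned as well, so either reading of
#' "the intersection of any pairwise comparison" is recoverable.
#'
#' @param degs_t1,degs_t2 named lists of DEG gene-id sets, one entry per
#'   carbon-source pair, with identical names at both temperatures.
#' @return list with `responsive` (union) and `per_pair` (named list of the
#'   per-pair intersections).
#' @export
carbon_scheme <- function(degs_t1, degs_t2) {
  if (!setequal(names(degs_t1), names(degs_t2)) ||
      is.null(names(degs_t1)) || anyDuplicated(names(degs_t1))) {
    stop("the two temperatures must provide the same named carbon pairs")
  }
  per_pair <- lapply(setNames(names(degs_t1), names(degs_t1)), function(p) {
    sort(intersect(degs_t1[[p]], degs_t2[[p]]))
  })
  list(responsive = sort(unique(unlist(per_pair))), per_pair = per_pair)
}

#' Temperature-responsive DEGs across carbon sources
#'
#' One temperature comparison per carbon source; genes differentially
#' expressed in at least `k` of them are temperature-responsive (the
#' published analysis uses k = n = 6 and k = 5).
#'
#' @param deg_sets named list of DEG gene-id sets, one per carbon source.
#' @param k membership threshold (defaults to all sets).
#' @return character vector of gene ids.
#' @export
temperature_scheme <- function(deg_sets, k = length(deg_sets)) {
  intersect_k_of_n(deg_sets, k)
}
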