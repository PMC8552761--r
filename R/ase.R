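## Allele-specific expression from read depth at allele-distinguishing SNP
## loci, and allele-dominance calls across conditions.

#' Quantify allele-specific expression for one condition
#'
#' Per allele, the mean read depth over a pair's SNP loci and the
#' condition's replicates is divided by the summed library size of those
#' replicates and scaled to per-million units. Dividing by the sum rather
#' than the mean of the replicate library sizes only rescales both alleles
#' by the same constant, so fold ratios are unaffected.
#'
#' @param depth_table an `AllelicDepthTable` (from [simulate_expression()]
#'   or [read_allelic_depth()]): long-format `depths` plus `lib_sizes`.
#' @param condition condition label to quantify.
#' @return data.frame with `pair_id`, `condition`, `n_loci`, `norm_a`,
#'   `norm_b`. Pairs without loci are absent (ASE-unquantifiable).
#' @export
ase_quantify <- function(depth_table, condition) {
  d <- depth_table$depths
  libs <- depth_table$lib_sizes
  d <- d[d$condition == condition, , drop = FALSE]
  lib <- libs[libs$condition == condition, , drop = FALSE]
  if (nrow(lib) == 0) stop("unknown condition: ", condition)
  if (any(lib$lib_size <= 0)) stop("library sizes must be > 0")
  denom <- sum(lib$lib_size)
  if (nrow(d) == 0) {
    return(data.frame(pair_id = character(0), condition = character(0),
                      n_loci = integer(0), norm_a = numeric(0),
                      norm_b = numeric(0), stringsAsFactors = FALSE))
  }
  agg <- do.call(rbind, lapply(split(d, d$pair_id), function(x) {
    data.frame(pair_id = x$pair_id[1], condition = condition,
               n_loci = length(unique(x$locus)),
               norm_a = mean(x$depth_a) / denom * 1e6,
               norm_b = mean(x$depth_b) / denom * 1e6,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

#' Quantify allele-specific expression across all conditions
#'
#' @inheritParams ase_quantify
#' @return row-bound [ase_quantify()] results over every condition in the
#'   table.
#' @export
ase_quantify_all <- function(depth_table) {
  conds <- unique(depth_table$lib_sizes$condition)
  do.call(rbind, lapply(conds, function(cc) ase_quantify(depth_table, cc)))
}

#' Call allele dominance from per-condition quantifications
#'
#' An allele is dominant for a pair when its normalized expression is
#' higher in every quantified condition; the reported fold per condition is
#' dominant over other, and `min_fold` the minimum across conditions. If
#' the direction flips between conditions the call is `none`. Conditions
#' where both alleles are zero are excluded (with a message).
#'
#' @param quantifications data.frame as returned by [ase_quantify_all()].
#' @return data.frame with `pair_id`, `dominant` (`"A"`, `"B"` or
#'   `"none"`), `min_fold`, `n_conditions`.
#' @export
call_dominance <- function(quantifications) {
  stopifnot(all(c("pair_id", "condition", "norm_a", "norm_b") %in%
                  names(quantifications)))
  out <- lapply(split(quantifications, quantifications$pair_id), function(q) {
    both_zero <- q$norm_a == 0 & q$norm_b == 0
    if (any(both_zero)) {
      message("pair ", q$pair_id[1], ": excluding ", sum(both_zero),
              " condition(s) with zero expression on both alleles")
      q <- q[!both_zero, , drop = FALSE]
    }
    if (nrow(q) == 0) {
      return(data.frame(pair_id = q$pair_id[1] %||% NA_character_,
                        dominant = "none", min_fold = NA_real_,
                        n_conditions = 0L, stringsAsFactors = FALSE))
    }
    if (all(q$norm_a > q$norm_b)) {
      data.frame(pair_id = q$pair_id[1], dominant = "A",
                 min_fold = min(q$norm_a / q$norm_b), n_conditions = nrow(q),
                 stringsAsFactors = FALSE)
    } else if (all(q$norm_b > q$norm_a)) {
      data.frame(pair_id = q$pair_id[1], dominant = "B",
                 min_fold = min(q$norm_b / q$norm_a), n_conditions = nrow(q),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pair_id = q$pair_id[1], dominant = "none",
                 min_fold = NA_real_, n_conditions = nrow(q),
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
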