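#' Simulate expression counts and allelic SNP depths for a simulated world
#'
#' Draws a gene-by-sample read-count matrix around the planted expression
#' means (negative binomial with the configured dispersion; Poisson when the
#' dispersion is 0) and, for every allelic pair that carries at least one
#' allele-distinguishing SNP locus, per-locus per-replicate read depths for
#' the two alleles. Depths at a pair's loci sum in expectation to the pair's
#' total expression, apportioned by the planted allelic bias
#' (haplotype A fraction `bias / (1 + bias)`).
#'
#' Pairs with zero distinguishing loci are recorded in the returned
#' `unquantifiable` vector rather than raising an error. Library sizes are
#' the column sums of the full count matrix.
#'
#' @param config the [sim_config()] used to build the world.
#' @param truth the `SimulationTruth` from [simulate_diploid()].
#' @param seed optional seed overriding `config$seed` (so repeated expression
#'   draws over one fixed world are possible).
#' @return a list with `counts` (a `CountMatrix`: integer matrix plus
#'   `samples` metadata and `gene_lengths`) and `allelic_depth` (an
#'   `AllelicDepthTable`: long-format per-locus depths plus `lib_sizes`),
#'   and `unquantifiable` (pair ids without ASE loci).
#' @export
#' @examples
#' world <- simulate_diploid(sim_config(genome_length = 60000, n_genes = 10,
#'                                      n_hap_specific_genes = 1, seed = 7))
#' ex <- simulate_expression(world$truth$config, world$truth)
#' dim(ex$counts$counts)
simulate_expression <- function(config, truth, seed = NULL) {
  validate_sim_config(config)
  stopifnot(is(truth, "SimulationTruth"))
  with_local_seed(seed %||% (config$seed + 1L),
                  build_expression(config, truth))
}

build_expression <- function(cfg, truth) {
  cond <- cfg$conditions
  samples <- do.call(rbind, lapply(seq_len(nrow(cond)), function(j) {
    data.frame(sample = paste0(cond$label[j], "_r", seq_len(cond$n_replicates[j])),
               condition = cond$label[j],
               temperature = cond$temperature[j], carbon = cond$carbon[j],
               replicate = seq_len(cond$n_replicates[j]),
               stringsAsFactors = FALSE)
  }))
  means <- truth$expression_means
  units <- truth$units

  draw <- function(mu, n) {
    if (cfg$nb_dispersion <= 0) rpois(n, mu)
    else rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
  }

  counts <- matrix(0L, nrow = nrow(means), ncol = nrow(samples),
                   dimnames = list(rownames(means), samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- means[, samples$condition[j]]
    counts[, j] <- as.integer(draw(mu, length(mu)))
  }
  lib_sizes <- colSums(counts)

  count_obj <- structure(list(
    counts = counts, samples = samples,
    gene_lengths = setNames(units$length, units$unit)
  ), class = "CountMatrix")

  ## per-locus allelic depths for quantifiable pairs
  loci <- truth$ase_loci
  pairs <- truth$allelic_map
  quant <- pairs$unit[pairs$n_ase_loci > 0]
  unquant <- pairs$unit[pairs$n_ase_loci == 0]
  depth_rows <- list()
  for (u in quant) {
    copy <- pairs$copy[pairs$unit == u]
    bias <- if (!is.na(copy)) cfg$bias_factors[copy] else 1
    p_a <- bias / (1 + bias)
    lpos <- loci$pos[loci$pair_id == u]
    for (j in seq_len(nrow(samples))) {
      mu <- means[u, samples$condition[j]]
      da <- draw(mu * p_a, length(lpos))
      db <- draw(mu * (1 - p_a), length(lpos))
      depth_rows[[length(depth_rows) + 1]] <- data.frame(
        pair_id = u, locus = lpos, sample = samples$sample[j],
        condition = samples$condition[j], replicate = samples$replicate[j],
        depth_a = as.integer(da), depth_b = as.integer(db),
        stringsAsFactors = FALSE)
    }
  }
  depth <- if (length(depth_rows) > 0) do.call(rbind, depth_rows) else
    data.frame(pair_id = character(0), locus = integer(0),
               sample = character(0), condition = character(0),
               replicate = integer(0), depth_a = integer(0),
               depth_b = integer(0), stringsAsFactors = FALSE)
  depth_obj <- structure(list(
    depths = depth,
    lib_sizes = data.frame(sample = samples$sample,
                           condition = samples$condition,
                           replicate = samples$replicate,
                           lib_size = as.numeric(lib_sizes),
                           stringsAsFactors = FALSE)
  ), class = "AllelicDepthTable")

  list(counts = count_obj, allelic_depth = depth_obj,
       unquantifiable = unquant)
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      length(unique(x$samples$condition)), "conditions )\n")
  invisible(x)
}

#' @export
print.AllelicDepthTable <- function(x, ...) {
  cat("AllelicDepthTable:", length(unique(x$depths$pair_id)), "pairs,",
      nrow(x$depths), "locus-sample depth rows\n")
  invisible(x)
}
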