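#' Configuration for the synthetic diploid generator
#'
#' Bundles every knob of the simulated two-haplotype world: genome size and
#' composition, planted variant densities, the tandem gene family with its
#' allelic and paralog divergence, haplotype-specific genes, and the
#' expression design (conditions, induction, allelic bias, dispersion).
#'
#' Defaults emulate the study system this package models: two ~Mb-scale
#' fungal haplotypes diverged at roughly 8 SNPs/kb, a 4-copy tandem family of
#' small heat-shock genes whose copies are induced ~8-fold at the elevated
#' temperature, and allelic bias of 1.5-fold toward haplotype B for copy 1
#' and 1.34-fold toward haplotype A for copy 4.
#'
#' @param genome_length total bases of haplotype A (summed over contigs).
#' @param n_contigs number of contigs.
#' @param gc_content fraction of G+C in generated sequence.
#' @param snp_rate,indel_rate,sv_rate planted events per base. The number of
#'   planted events of each class is `round(genome_length * rate)` — the
#'   configured densities are exact by construction.
#' @param indel_len_range integer bounds for indel lengths; the maximum must
#'   stay below the 50-bp structural-variant boundary.
#' @param sv_len_range integer bounds for SV lengths; the minimum must exceed
#'   the 50-bp boundary.
#' @param n_genes number of genes annotated on haplotype A (including the
#'   family copies and the A-specific genes).
#' @param family_copies tandem copies of the planted gene family.
#' @param family_allelic_divergence substitutions per CDS site between the
#'   two alleles of one family copy (planted synonymously, so the alleles
#'   encode identical proteins but carry distinguishing SNP loci).
#' @param family_paralog_divergence target pairwise protein divergence
#'   between family copies.
#' @param n_hap_specific_genes genes private to each haplotype (planted as
#'   whole-gene insertion/deletion SVs relative to haplotype A).
#' @param conditions data.frame with columns `label`, `temperature`,
#'   `carbon`, `n_replicates` describing the expression design.
#' @param induced_temperature the `temperature` level at which the family
#'   (and temperature-responsive genes) are induced.
#' @param induction_factor fold-change applied to family copies at the
#'   induced temperature.
#' @param bias_factors per-copy allelic expression ratio (haplotype A over
#'   haplotype B); length `family_copies`.
#' @param n_temp_responsive,temp_effect non-family genes induced
#'   `temp_effect`-fold at the induced temperature on every carbon source.
#' @param n_carbon_responsive,carbon_effect genes raised `carbon_effect`-fold
#'   on one carbon source (consistently at both temperatures).
#' @param baseline_mean,baseline_log_sd log-normal baseline expression means:
#'   `exp(log(baseline_mean) + rnorm(., 0, baseline_log_sd))`.
#' @param family_baseline_means baseline means for the family copies
#'   (recycled to `family_copies`); the defaults make copies 1 and 4 the
#'   highly expressed members of the cluster.
#' @param nb_dispersion negative-binomial dispersion of simulated counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   simulated worlds.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 60000, n_genes = 10, seed = 1)
#' cfg$family_copies
sim_config <- function(genome_length = 5e5,
                       n_contigs = 2,
                       gc_content = 0.5,
                       snp_rate = 8e-3,
                       indel_rate = 7.7e-4,
                       sv_rate = 3.7e-5,
                       indel_len_range = c(1L, 49L),
                       sv_len_range = c(51L, 2000L),
                       n_genes = 40,
                       family_copies = 4,
                       family_allelic_divergence = 0.02,
                       family_paralog_divergence = 0.10,
                       n_hap_specific_genes = 3,
                       conditions = default_conditions(),
                       induced_temperature = "35",
                       induction_factor = 8,
                       bias_factors = NULL,
                       n_temp_responsive = 0,
                       temp_effect = 8,
                       n_carbon_responsive = 0,
                       carbon_effect = 8,
                       baseline_mean = 100,
                       baseline_log_sd = 1,
                       family_baseline_means = c(500, 50, 50, 500),
                       nb_dispersion = 0.05,
                       seed = 42L) {
  if (is.null(bias_factors)) {
    bias_factors <- rep(1, family_copies)
    if (family_copies >= 1) bias_factors[1] <- 1 / 1.5
    if (family_copies >= 4) bias_factors[4] <- 1.34
  }
  cfg <- structure(list(
    genome_length = as.integer(genome_length), n_contigs = as.integer(n_contigs),
    gc_content = gc_content,
    snp_rate = snp_rate, indel_rate = indel_rate, sv_rate = sv_rate,
    indel_len_range = as.integer(indel_len_range),
    sv_len_range = as.integer(sv_len_range),
    n_genes = as.integer(n_genes), family_copies = as.integer(family_copies),
    family_allelic_divergence = family_allelic_divergence,
    family_paralog_divergence = family_paralog_divergence,
    n_hap_specific_genes = as.integer(n_hap_specific_genes),
    conditions = conditions,
    induced_temperature = as.character(induced_temperature),
    induction_factor = induction_factor,
    bias_factors = bias_factors,
    n_temp_responsive = as.integer(n_temp_responsive), temp_effect = temp_effect,
    n_carbon_responsive = as.integer(n_carbon_responsive), carbon_effect = carbon_effect,
    baseline_mean = baseline_mean, baseline_log_sd = baseline_log_sd,
    family_baseline_means = rep_len(family_baseline_means, max(family_copies, 1L)),
    nb_dispersion = nb_dispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default two-temperature expression design
#'
#' Mycelium on one medium at the control and elevated temperature, three
#' replicates each.
#'
#' @return a data.frame with columns label, temperature, carbon, n_replicates.
#' @export
default_conditions <- function() {
  data.frame(
    label = c("PDA_25", "PDA_35"),
    temperature = c("25", "35"),
    carbon = c("PDA", "PDA"),
    n_replicates = c(3L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Full carbon-source by temperature design
#'
#' Six carbon sources crossed with two temperatures, the design behind the
#' 15-pair carbon scheme and the 6-comparison temperature scheme.
#'
#' @param carbons carbon-source labels.
#' @param temperatures temperature levels.
#' @param n_replicates replicates per condition.
#' @return a data.frame usable as `conditions` in [sim_config()].
#' @export
carbon_temperature_conditions <- function(carbons = c("MM", "SM", "LM", "CM", "XM", "PDA"),
                                          temperatures = c("25", "35"),
                                          n_replicates = 3L) {
  grid <- expand.grid(carbon = carbons, temperature = temperatures,
                      stringsAsFactors = FALSE)
  data.frame(
    label = paste(grid$carbon, grid$temperature, sep = "_"),
    temperature = grid$temperature,
    carbon = grid$carbon,
    n_replicates = as.integer(n_replicates),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$genome_length < 1000) stop("genome_length must be at least 1000 bases")
  if (cfg$n_contigs < 1) stop("n_contigs must be >= 1")
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1) stop("gc_content must be in (0, 1)")
  for (r in c("snp_rate", "indel_rate", "sv_rate")) {
    if (cfg[[r]] < 0) stop(r, " must be >= 0")
  }
  if (length(cfg$indel_len_range) != 2 || cfg$indel_len_range[1] < 1 ||
      cfg$indel_len_range[2] > 50 || diff(cfg$indel_len_range) < 0) {
    stop("indel_len_range must be an increasing interval within [1, 50]")
  }
  if (length(cfg$sv_len_range) != 2 || cfg$sv_len_range[1] <= 50 ||
      diff(cfg$sv_len_range) < 0) {
    stop("sv_len_range minimum must exceed 50 bp (the indel/SV boundary)")
  }
  if (cfg$family_copies < 1) stop("family_copies must be >= 1")
  if (length(cfg$bias_factors) != cfg$family_copies) {
    stop("bias_factors must have exactly family_copies entries")
  }
  if (any(cfg$bias_factors <= 0)) stop("bias_factors must all be > 0")
  if (cfg$n_genes < cfg$family_copies + cfg$n_hap_specific_genes) {
    stop("n_genes must cover family_copies + n_hap_specific_genes")
  }
  cond <- cfg$conditions
  need <- c("label", "temperature", "carbon", "n_replicates")
  if (!is.data.frame(cond) || !all(need %in% names(cond))) {
    stop("conditions must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(cond$label)) stop("condition labels must be unique")
  if (any(cond$n_replicates < 1)) stop("every condition needs >= 1 replicate")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$n_temp_responsive + cfg$n_carbon_responsive >
      cfg$n_genes - cfg$family_copies - cfg$n_hap_specific_genes) {
    stop("not enough shared non-family genes for the requested responsive genes")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$genome_length, "bp in", x$n_contigs, "contig(s);",
      x$n_genes, "genes;", x$family_copies, "family copies;",
      "rates snp/indel/sv =", x$snp_rate, x$indel_rate, x$sv_rate,
      "; seed", x$seed, "\n")
  invisible(x)
}
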