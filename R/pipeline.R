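## End-to-end orchestration: variants -> gene classes -> allelome ->
## expression -> ASE -> amplicon, mirroring the analysis order of a
## haplotype-pair comparison study.

#' Pipeline configuration with the published threshold defaults
#'
#' @param world_dir directory holding the haplotype files (as written by
#'   [write_world()]): FASTA + GFF3 + protein FASTA per haplotype and a
#'   variant VCF.
#' @param expression_dir optional directory with counts / allelic-depth
#'   tables (as written by [write_expression()]).
#' @param out_dir where stage outputs are written.
#' @param sv_boundary indel/SV affected-size boundary in bp.
#' @param conserved_max,variable_min gene-conservation fraction thresholds.
#' @param allelic_identity minimum protein identity of an allelic pair.
#' @param dup_coverage,dup_identity duplication-group thresholds.
#' @param deg_lfc,deg_p DEG thresholds.
#' @param window variant-density window in bases.
#' @param max_intervening tandem-cluster gap tolerance in genes.
#' @param fwd_primer,rev_primer in-silico PCR primer pair (IUPAC).
#' @param max_product in-silico PCR product cap in bases.
#' @param seed seed echoed into output provenance.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(world_dir, expression_dir = NULL,
                            out_dir = file.path(world_dir, "results"),
                            sv_boundary = 50,
                            conserved_max = 0.002, variable_min = 0.02,
                            allelic_identity = 0.85,
                            dup_coverage = 0.5, dup_identity = 0.9,
                            deg_lfc = 1, deg_p = 1e-3,
                            window = 50000, max_intervening = 1,
                            fwd_primer = FWD_PRIMER, rev_primer = REV_PRIMER,
                            max_product = 5000, seed = 0L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$conserved_max >= cfg$variable_min) {
    stop("invalid thresholds: conserved_max (", cfg$conserved_max,
         ") must be below variable_min (", cfg$variable_min, ")")
  }
  if (cfg$sv_boundary != 50) {
    warning("sv_boundary differs from the published 50-bp rule; ",
            "classification still uses 50")
  }
  for (p in c("allelic_identity", "dup_coverage", "dup_identity")) {
    if (cfg[[p]] <= 0 || cfg[[p]] > 1) stop(p, " must be in (0, 1]")
  }
  if (cfg$window <= 0) stop("window must be positive")
  invisible(cfg)
}

#' Run the full haplotype-comparison pipeline
#'
#' Reads the world files, classifies and locates variants, computes window
#' densities and gene-conservation calls, resolves the allelome
#' (haplotype-specific genes, allelic pairs, duplication groups, tandem
#' clusters), and — when expression data are present — calls DEGs between
#' every condition pair, quantifies allele-specific expression and calls
#' dominance. In-silico PCR runs over both haplotype genomes. All stage
#' outputs are written as TSV under `out_dir`; a machine-readable summary
#' is returned.
#'
#' @param config a [pipeline_config()].
#' @return list summarising every stage (variant class counts, location
#'   tally, conservation tally, pair/duplication/cluster structure, DEG set
#'   sizes, dominance calls, amplicon products).
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  world <- stage("load", read_world(config$world_dir))
  variants <- world$variants
  ga <- world$genome_a

  ## ---- variant layer
  summary_classes <- stage("variants", summarize_variant_classes(variants))
  variants$var_class <- classify_variant(variants$ref, variants$alt)
  variants$location <- stage("variants", annotate_variant_location(
    variants, ga$genes, ga$exons))
  contig_len <- setNames(Biostrings::width(ga$seqs), names(ga$seqs))
  windows <- variant_density_windows(variants, contig_len, config$window)
  conservation <- classify_gene_conservation(ga$genes, variants,
                                             config$conserved_max,
                                             config$variable_min)
  write_tsv(variants, file.path(config$out_dir, "variant_summary.tsv"),
            config$seed)
  write_tsv(windows, file.path(config$out_dir, "window_density.tsv"),
            config$seed)
  write_tsv(conservation, file.path(config$out_dir, "gene_conservation.tsv"),
            config$seed)

  ## ---- allelome layer
  prot_a <- world$genome_a$proteins
  prot_b <- world$genome_b$proteins
  hs <- stage("allelome", find_haplotype_specific(prot_a, prot_b))
  pairs <- stage("allelome", resolve_allelic_pairs(prot_a, prot_b,
                                                   config$allelic_identity))
  dup_a <- detect_duplications(prot_a, config$dup_coverage, config$dup_identity)
  dup_b <- detect_duplications(prot_b, config$dup_coverage, config$dup_identity)
  clus_a <- detect_tandem_clusters(dup_a, world$genome_a$genes,
                                   config$max_intervening)
  clus_b <- detect_tandem_clusters(dup_b, world$genome_b$genes,
                                   config$max_intervening)
  write_tsv(pairs$pairs, file.path(config$out_dir, "allelic_pairs.tsv"),
            config$seed)
  write_tsv(data.frame(
    haplotype = c(rep("A", length(hs$A_specific)),
                  rep("B", length(hs$B_specific))),
    gene_id = c(hs$A_specific, hs$B_specific), stringsAsFactors = FALSE),
    file.path(config$out_dir, "hap_specific.tsv"), config$seed)
  dump_groups <- function(groups, hap) {
    if (length(groups) == 0) {
      return(data.frame(haplotype = character(0), group = integer(0),
                        gene_id = character(0), stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(seq_along(groups), function(i) {
      data.frame(haplotype = hap, group = i, gene_id = groups[[i]],
                 stringsAsFactors = FALSE)
    }))
  }
  write_tsv(rbind(dump_groups(dup_a, "A"), dump_groups(dup_b, "B")),
            file.path(config$out_dir, "duplications.tsv"), config$seed)
  dump_clusters <- function(clus, hap) {
    if (length(clus) == 0) {
      return(data.frame(haplotype = character(0), cluster = integer(0),
                        gene_id = character(0), contig = character(0),
                        strand = character(0), rank = integer(0),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(seq_along(clus), function(i) {
      cbind(data.frame(haplotype = hap, cluster = i), clus[[i]])
    }))
  }
  write_tsv(rbind(dump_clusters(clus_a, "A"), dump_clusters(clus_b, "B")),
            file.path(config$out_dir, "tandem_clusters.tsv"), config$seed)

  summary <- list(
    variant_classes = summary_classes,
    variant_locations = table(variants$location),
    conservation = table(conservation$label),
    n_allelic_pairs = nrow(pairs$pairs),
    n_hap_specific = c(A = length(hs$A_specific), B = length(hs$B_specific)),
    duplication_group_sizes = list(A = vapply(dup_a, length, integer(1)),
                                   B = vapply(dup_b, length, integer(1))),
    tandem_cluster_sizes = list(A = vapply(clus_a, nrow, integer(1)),
                                B = vapply(clus_b, nrow, integer(1))))

  ## ---- expression / ASE layer (optional)
  if (!is.null(config$expression_dir)) {
    ex <- stage("expression", read_expression(config$expression_dir))
    conds <- unique(ex$counts$samples$condition)
    deg_sets <- list()
    if (length(conds) >= 2) {
      pairs_c <- utils::combn(conds, 2, simplify = FALSE)
      for (pc in pairs_c) {
        res <- call_degs(ex$counts, condition_pair = pc,
                         lfc_min = config$deg_lfc, p_max = config$deg_p)
        nm <- paste(pc, collapse = "_vs_")
        deg_sets[[nm]] <- res$gene_id[res$deg]
        write_tsv(res, file.path(config$out_dir, paste0("deg_", nm, ".tsv")),
                  config$seed)
      }
    }
    quant <- stage("ase", ase_quantify_all(ex$allelic_depth))
    dom <- call_dominance(quant)
    write_tsv(quant, file.path(config$out_dir, "ase_quantification.tsv"),
              config$seed)
    write_tsv(dom, file.path(config$out_dir, "dominance.tsv"), config$seed)
    summary$deg_set_sizes <- vapply(deg_sets, length, integer(1))
    summary$dominance <- dom
  }

  ## ---- amplicon layer
  seqs_a <- world$genome_a$seqs
  names(seqs_a) <- paste0("hapA_", names(seqs_a))
  seqs_b <- world$genome_b$seqs
  names(seqs_b) <- paste0("hapB_", names(seqs_b))
  pcr <- stage("amplicon", rbind(
    insilico_pcr_set(seqs_a, config$fwd_primer, config$rev_primer,
                     config$max_product),
    insilico_pcr_set(seqs_b, config$fwd_primer, config$rev_primer,
                     config$max_product)))
  write_tsv(pcr, file.path(config$out_dir, "amplicons.tsv"), config$seed)
  summary$amplicon_lengths <- pcr$length

  summary
}
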