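test_that("zero planted divergence gives identical haplotypes and no variants", {
  cfg <- sim_config(genome_length = 40000, n_contigs = 1, n_genes = 6,
                    snp_rate = 0, indel_rate = 0, sv_rate = 0,
                    n_hap_specific_genes = 0, family_allelic_divergence = 0,
                    seed = 1)
  w <- simulate_diploid(cfg)
  expect_identical(as.character(w$genome_a$seqs), as.character(w$genome_b$seqs))
  expect_equal(nrow(w$truth$variants), 0)
  expect_equal(w$truth$allelic_map$n_ase_loci, rep(0L, 6))
})

test_that("identical config and seed give byte-identical written worlds", {
  cfg <- sim_config(genome_length = 50000, n_contigs = 1, n_genes = 8,
                    n_hap_specific_genes = 1, sv_len_range = c(60, 200),
                    seed = 33)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_world(simulate_diploid(cfg), d1)
  write_world(simulate_diploid(cfg), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("planted variants reconstruct haplotype B exactly", {
  tw <- test_world("small")
  w <- tw$world
  for (ctg in names(w$genome_a$seqs)) {
    v <- w$truth$variants[w$truth$variants$contig == ctg, ]
    at <- IRanges::IRanges(v$pos, v$pos + nchar(v$ref) - 1L)
    rebuilt <- Biostrings::replaceAt(w$genome_a$seqs[[ctg]], at, v$alt)
    expect_identical(as.character(rebuilt), as.character(w$genome_b$seqs[[ctg]]))
  }
})

test_that("gene models are non-overlapping and the family is tandem", {
  tw <- test_world("small")
  for (g in list(tw$world$genome_a, tw$world$genome_b)) {
    for (ctg in unique(g$genes$contig)) {
      gs <- g$genes[g$genes$contig == ctg, ]
      expect_true(IRanges::isDisjoint(IRanges::IRanges(gs$start, gs$end)))
    }
  }
  ## the family copies occupy consecutive gene positions on one contig
  ga <- tw$world$genome_a$genes
  fam <- ga[grepl("hsp20", ga$gene_id), ]
  expect_equal(length(unique(fam$contig)), 1)
  on_ctg <- ga[ga$contig == fam$contig[1], ]
  on_ctg <- on_ctg[order(on_ctg$start), ]
  ranks <- which(grepl("hsp20", on_ctg$gene_id))
  expect_equal(diff(ranks), rep(1L, nrow(fam) - 1))
})

test_that("every allelic-map id exists in exactly one haplotype annotation", {
  tw <- test_world("small")
  w <- tw$world
  am <- w$truth$allelic_map
  expect_true(all(am$gene_a %in% w$genome_a$genes$gene_id))
  expect_true(all(am$gene_b %in% w$genome_b$genes$gene_id))
  expect_false(any(am$gene_a %in% w$genome_b$genes$gene_id))
  expect_false(any(am$gene_b %in% w$genome_a$genes$gene_id))
})

test_that("truth location labels match a brute-force per-base oracle", {
  tw <- test_world("small")
  w <- tw$world
  v <- w$truth$variants
  v <- v[v$origin == "background", ]
  idx <- seq(1, nrow(v), length.out = min(nrow(v), 80))
  for (r in unique(round(idx))) {
    expect_equal(
      location_oracle(v$pos[r], nchar(v$ref[r]), w$genome_a$genes,
                      w$genome_a$exons, v$contig[r]),
      v$location[r],
      label = paste("variant at", v$contig[r], v$pos[r]))
  }
})

test_that("undersized genomes are rejected with the binding constraint", {
  expect_error(
    simulate_diploid(sim_config(genome_length = 20000, n_contigs = 1,
                                n_genes = 18, n_hap_specific_genes = 2,
                                seed = 1)),
    "genome too short")
})

test_that("expression counts follow the planted induction and design shape", {
  cfg <- sim_config(genome_length = 60000, n_contigs = 1, n_genes = 8,
                    snp_rate = 1e-3, indel_rate = 0, sv_rate = 0,
                    n_hap_specific_genes = 0, induction_factor = 8,
                    nb_dispersion = 0.01, seed = 12)
  w <- simulate_diploid(cfg)
  ex <- simulate_expression(cfg, w$truth)
  expect_equal(ncol(ex$counts$counts), 6)      # 2 conditions x 3 replicates
  expect_equal(nrow(ex$counts$samples), 6)
  ## family copies: induced/control count ratio near the analytic NB mean ratio
  fam <- w$truth$allelic_map$unit[!is.na(w$truth$allelic_map$copy)]
  s25 <- ex$counts$samples$sample[ex$counts$samples$condition == "PDA_25"]
  s35 <- ex$counts$samples$sample[ex$counts$samples$condition == "PDA_35"]
  ratio <- sum(ex$counts$counts[fam, s35]) / sum(ex$counts$counts[fam, s25])
  expect_gt(ratio, 8 * 0.85)
  expect_lt(ratio, 8 * 1.15)
  ## depth table shape: one row per locus x sample, both alleles present
  d <- ex$allelic_depth$depths
  expect_true(all(c("depth_a", "depth_b") %in% names(d)))
  expect_equal(nrow(ex$allelic_depth$lib_sizes), 6)
  n_loci <- w$truth$allelic_map$n_ase_loci
  expect_equal(nrow(d), sum(n_loci) * 6)
})

test_that("allelic depths split by the planted bias in the unbiased limit", {
  cfg <- sim_config(genome_length = 60000, n_contigs = 1, n_genes = 8,
                    snp_rate = 2e-3, indel_rate = 0, sv_rate = 0,
                    n_hap_specific_genes = 0, bias_factors = rep(1, 4),
                    nb_dispersion = 0, family_baseline_means = 2000,
                    seed = 13)
  w <- simulate_diploid(cfg)
  ex <- simulate_expression(cfg, w$truth)
  d <- ex$allelic_depth$depths
  fam <- d[grepl("hsp20", d$pair_id), ]
  expect_equal(mean(fam$depth_a) / mean(fam$depth_b), 1, tolerance = 0.05)
})
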