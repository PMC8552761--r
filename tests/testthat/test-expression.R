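test_that("TPM follows the hand-computed formula and sums to one million", {
  m <- matrix(c(10, 20, 30), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  tpm <- tpm_normalize(m, c(a = 1000, b = 1000, c = 2000))
  expect_equal(unname(tpm[, 1]),
               c(2e6 / 9, 4e6 / 9, 3e6 / 9))   # 222222.2, 444444.4, 333333.3
  expect_equal(sum(tpm[, 1]), 1e6)
  ## equal counts, equal lengths
  m2 <- matrix(c(5, 5), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(unname(tpm_normalize(m2, c(a = 700, b = 700))[, 1]), c(5e5, 5e5))
  ## zero count stays zero; all-zero sample warns and stays zero
  m3 <- matrix(c(0, 10), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  m3[, 2] <- 0
  expect_warning(t3 <- tpm_normalize(m3, c(a = 500, b = 500)), "all-zero")
  expect_equal(unname(t3[1, 1]), 0)
  expect_equal(unname(t3[, 2]), c(0, 0))
})

test_that("TPM columns of simulated counts sum to one million", {
  tw <- test_world("small")
  ex <- simulate_expression(tw$cfg, tw$world$truth)
  tpm <- tpm_normalize(ex$counts)
  expect_equal(unname(colSums(tpm)), rep(1e6, ncol(tpm)), tolerance = 1e-9)
})

test_that("DEG calling applies the fold-change and p thresholds", {
  samples <- data.frame(sample = paste0("s", 1:6),
                        condition = rep(c("c1", "c2"), each = 3),
                        stringsAsFactors = FALSE)
  ## identical replicate columns: log2FC 0, nothing flagged
  m <- matrix(rep(c(50, 200, 7), 6), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), samples$sample))
  res <- call_degs(m, samples, c("c1", "c2"))
  expect_equal(res$log2fc, rep(0, 3))
  expect_false(any(res$deg))
  ## external statistics: thresholds only
  ext <- data.frame(gene_id = c("g1", "g2"), log2fc = c(3, 0.5),
                    pvalue = c(1e-6, 1e-9), stringsAsFactors = FALSE)
  res2 <- call_degs(stats_table = ext)
  expect_equal(res2$deg, c(TRUE, FALSE))
  expect_error(call_degs(m, samples[c(1, 4), ], c("c1", "c2")),
               "2 replicates")
})

test_that("the moderated stand-in recovers a strong planted induction", {
  set.seed(15)
  n <- 60
  mu <- rep(200, n)
  up <- 1:10
  m1 <- matrix(rnbinom(n * 3, mu = mu, size = 20), n, 3)
  mu2 <- mu; mu2[up] <- mu2[up] * 8
  m2 <- matrix(rnbinom(n * 3, mu = mu2, size = 20), n, 3)
  counts <- cbind(m1, m2)
  dimnames(counts) <- list(paste0("g", 1:n), paste0("s", 1:6))
  samples <- data.frame(sample = paste0("s", 1:6),
                        condition = rep(c("c1", "c2"), each = 3),
                        stringsAsFactors = FALSE)
  res <- call_degs(counts, samples, c("c1", "c2"))
  expect_true(all(res$deg[up]))
  expect_true(mean(res$deg[-up]) <= 0.05)
  ## fold-change direction and magnitude
  expect_equal(mean(res$log2fc[up]), 3, tolerance = 0.2)
})

test_that("k-of-n intersection matches the membership-count oracle", {
  sets <- list(c("a", "b"), c("b", "c"), c("b", "d"))
  expect_equal(intersect_k_of_n(sets, 3), "b")
  expect_equal(intersect_k_of_n(sets, 2), k_of_n_oracle(sets, 2))
  expect_equal(intersect_k_of_n(sets, 1), sort(c("a", "b", "c", "d")))
  expect_error(intersect_k_of_n(sets, 0), "between 1")
  expect_error(intersect_k_of_n(sets, 4), "between 1")
  set.seed(9)
  for (i in 1:50) {
    fam <- lapply(seq_len(sample(2:8, 1)), function(j)
      sample(letters, sample(0:15, 1)))
    for (k in seq_along(fam)) {
      expect_equal(intersect_k_of_n(fam, k), k_of_n_oracle(fam, k))
    }
    ## anti-monotone in k
    sizes <- vapply(seq_along(fam), function(k)
      length(intersect_k_of_n(fam, k)), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("carbon and temperature schemes implement the published designs", {
  pairs <- c("glu_lig", "glu_cel", "lig_cel")
  t25 <- list(glu_lig = c("g1", "g2"), glu_cel = c("g3"), lig_cel = c("g4"))
  t35 <- list(glu_lig = c("g1"), glu_cel = c("g3", "g9"), lig_cel = c("g5"))
  cs <- carbon_scheme(t25, t35)
  expect_equal(cs$per_pair$glu_lig, "g1")   # DE at both temperatures
  expect_equal(cs$per_pair$lig_cel, character(0))  # only one temperature
  expect_setequal(cs$responsive, c("g1", "g3"))
  expect_error(carbon_scheme(t25, t35[1:2]), "same named")

  sets <- list(MM = c("x", "y"), SM = c("x", "y"), LM = c("x", "y"),
               CM = c("x", "y"), XM = c("x", "y"), PDA = c("x"))
  expect_equal(temperature_scheme(sets), "x")              # k = 6
  expect_setequal(temperature_scheme(sets, 5), c("x", "y"))  # k = 5
  expect_true(all(temperature_scheme(sets, 6) %in% temperature_scheme(sets, 5)))
})

test_that("planted carbon and temperature responses separate cleanly", {
  cfg <- sim_config(genome_length = 3e5, n_contigs = 1, n_genes = 80,
                    snp_rate = 0, indel_rate = 0, sv_rate = 0,
                    n_hap_specific_genes = 0,
                    conditions = carbon_temperature_conditions(n_replicates = 3),
                    n_temp_responsive = 15, n_carbon_responsive = 15,
                    temp_effect = 8, carbon_effect = 8,
                    baseline_log_sd = 0.3, seed = 31)
  w <- simulate_diploid(cfg)
  ex <- simulate_expression(cfg, w$truth)
  cond <- cfg$conditions
  carbons <- unique(cond$carbon)
  cpairs <- utils::combn(carbons, 2, simplify = FALSE)
  deg_at <- function(temp) {
    sets <- list()
    for (cp in cpairs) {
      l1 <- cond$label[cond$carbon == cp[1] & cond$temperature == temp]
      l2 <- cond$label[cond$carbon == cp[2] & cond$temperature == temp]
      r <- call_degs(ex$counts, condition_pair = c(l1, l2))
      sets[[paste(cp, collapse = "_")]] <- r$gene_id[r$deg]
    }
    sets
  }
  cs <- carbon_scheme(deg_at("25"), deg_at("35"))
  tr <- w$truth$units
  planted_carbon <- tr$unit[tr$carbon_responsive]
  planted_temp <- tr$unit[tr$temp_responsive]
  expect_true(all(planted_carbon %in% cs$responsive))
  expect_equal(intersect(planted_temp, cs$responsive), character(0))

  temp_sets <- lapply(setNames(carbons, carbons), function(cb) {
    l1 <- cond$label[cond$carbon == cb & cond$temperature == "25"]
    l2 <- cond$label[cond$carbon == cb & cond$temperature == "35"]
    r <- call_degs(ex$counts, condition_pair = c(l1, l2))
    r$gene_id[r$deg]
  })
  k6 <- temperature_scheme(temp_sets, 6)
  k5 <- temperature_scheme(temp_sets, 5)
  expect_true(all(planted_temp %in% k6))
  expect_true(all(k6 %in% k5))
  expect_false(any(planted_carbon %in% k6))
})
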