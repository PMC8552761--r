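test_that("alignment statistics match definitions and the DP oracle", {
  p <- random_protein(100)
  self <- align_proteins(p, p)
  expect_equal(self$identity, 1.0)
  expect_equal(self$coverage, 1.0)
  ## 40-residue prefix contained in a 100-residue protein: coverage 0.4
  pre <- align_proteins(substr(p, 1, 40), p)
  expect_equal(pre$coverage, 0.4)
  ## textbook pair: identity equals the exhaustive DP oracle's
  o <- nw_oracle("HEAGAWGHEE", "PAWHEAE")
  st <- align_proteins("HEAGAWGHEE", "PAWHEAE")
  expect_equal(st$score, o$score)
  expect_equal(st$identity, o$identity)
  ## scores equal the oracle on random pairs; symmetry of identity/coverage
  set.seed(7)
  for (i in 1:6) {
    a <- random_protein(sample(15:60, 1)); b <- random_protein(sample(15:60, 1))
    expect_equal(align_proteins(a, b)$score, nw_oracle(a, b)$score)
    ab <- align_proteins(a, b); ba <- align_proteins(b, a)
    expect_equal(ab$identity, ba$identity)
    expect_equal(ab$coverage, ba$coverage)
  }
  expect_error(align_proteins("MKV#L", "MKVL"), "position 4")
  expect_error(align_proteins("", "MKVL"), "empty")
})

test_that("haplotype-specific calling is symmetric and exact", {
  set.seed(11)
  shared <- setNames(vapply(1:4, function(i) random_protein(80), ""),
                     paste0("s", 1:4))
  expect_equal(find_haplotype_specific(shared, shared),
               list(A_specific = character(0), B_specific = character(0)))
  extra <- c(shared, x9 = random_protein(90))
  hs <- find_haplotype_specific(extra, shared)
  expect_equal(hs$A_specific, "x9")
  expect_equal(hs$B_specific, character(0))
})

test_that("planted haplotype-specific genes are recovered exactly", {
  tw <- test_world("small")
  w <- tw$world
  hs <- find_haplotype_specific(w$genome_a$proteins, w$genome_b$proteins)
  expect_setequal(hs$A_specific, w$truth$hap_specific_ids$A)
  expect_setequal(hs$B_specific, w$truth$hap_specific_ids$B)
})

test_that("allelic pairing is one-to-one and recovers the planted map", {
  p <- random_protein(120)
  one <- resolve_allelic_pairs(c(a1 = p), c(b1 = p))
  expect_equal(nrow(one$pairs), 1)
  expect_equal(one$pairs$identity, 1.0)
  ## 50% identity is below the 85% rule: nothing pairs
  set.seed(3)
  far <- resolve_allelic_pairs(c(a1 = random_protein(100)),
                               c(b1 = random_protein(100)))
  expect_equal(nrow(far$pairs), 0)
  expect_equal(far$unmatched_a, "a1")
  expect_equal(far$unmatched_b, "b1")

  tw <- test_world("small")
  w <- tw$world
  pr <- resolve_allelic_pairs(w$genome_a$proteins, w$genome_b$proteins)
  expect_false(anyDuplicated(pr$pairs$gene_a) > 0)
  expect_false(anyDuplicated(pr$pairs$gene_b) > 0)
  m <- merge(pr$pairs, w$truth$allelic_map, by = "gene_a")
  expect_equal(nrow(m), nrow(w$truth$allelic_map))
  expect_equal(m$gene_b.x, m$gene_b.y)
  ## swapping haplotypes mirrors the pair set
  rev <- resolve_allelic_pairs(w$genome_b$proteins, w$genome_a$proteins)
  expect_setequal(paste(rev$pairs$gene_b, rev$pairs$gene_a),
                  paste(pr$pairs$gene_a, pr$pairs$gene_b))
})

test_that("duplication groups follow the coverage and identity rules", {
  p <- random_protein(100)
  expect_equal(detect_duplications(c(d1 = p, d2 = p)), list(c("d1", "d2")))
  ## perfect containment at 100/250 residues: coverage 0.4 < 0.5, no group
  set.seed(5)
  long <- random_protein(250)
  expect_equal(length(detect_duplications(
    c(short = substr(long, 1, 100), long = long))), 0)

  tw <- test_world("small")
  w <- tw$world
  fam_a <- w$truth$family_members$gene_id[w$truth$family_members$haplotype == "A"]
  grp <- detect_duplications(w$genome_a$proteins)
  expect_equal(length(grp), 1)
  expect_setequal(grp[[1]], fam_a)
})

test_that("tandem clustering respects gene order and the gap tolerance", {
  genes <- data.frame(
    gene_id = paste0("g", 1:10), contig = "c1",
    start = seq(1000, by = 5000, length.out = 10),
    strand = rep(c("+", "-"), 5), stringsAsFactors = FALSE)
  ## members at ranks 1, 2, 10 with one intervening gene tolerated
  cl <- detect_tandem_clusters(list(c("g1", "g2", "g10")), genes,
                               max_intervening = 1)
  expect_equal(length(cl), 1)
  expect_equal(cl[[1]]$gene_id, c("g1", "g2"))
  ## members on different contigs never cluster
  genes2 <- genes; genes2$contig[10] <- "c2"
  cl2 <- detect_tandem_clusters(list(c("g1", "g10")), genes2, 1)
  expect_equal(length(cl2), 0)
  expect_error(detect_tandem_clusters(list(c("g1", "gX")), genes, 1), "gX")

  tw <- test_world("small")
  w <- tw$world
  for (hap in c("A", "B")) {
    g <- if (hap == "A") w$genome_a else w$genome_b
    fam <- w$truth$family_members$gene_id[w$truth$family_members$haplotype == hap]
    cl <- detect_tandem_clusters(list(fam), g$genes, max_intervening = 1)
    expect_equal(length(cl), 1)
    expect_setequal(cl[[1]]$gene_id, fam)
    ## reported in genomic order
    expect_equal(cl[[1]]$rank, sort(cl[[1]]$rank))
  }
})

test_that("pair counts are monotone in the identity threshold", {
  tw <- test_world("small")
  w <- tw$world
  fam_a <- w$truth$family_members$gene_id[w$truth$family_members$haplotype == "A"]
  fam_b <- w$truth$family_members$gene_id[w$truth$family_members$haplotype == "B"]
  pa <- w$genome_a$proteins[fam_a]
  pb <- w$genome_b$proteins[fam_b]
  set.seed(42)
  thr <- sort(runif(12, 0.5, 1.0))
  n_pairs <- vapply(thr, function(t)
    nrow(resolve_allelic_pairs(pa, pb, min_identity = t)$pairs), integer(1))
  expect_true(all(diff(n_pairs) <= 0))
})

test_that("cluster sizes are monotone in the gap tolerance", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    genes <- data.frame(gene_id = paste0("g", 1:n), contig = "c1",
                        start = sort(sample(1e6, n)), strand = "+",
                        stringsAsFactors = FALSE)
    members <- sample(genes$gene_id, sample(2:min(6, n), 1))
    sizes <- vapply(0:4, function(k) {
      cl <- detect_tandem_clusters(list(members), genes, max_intervening = k)
      if (length(cl) == 0) 0L else max(vapply(cl, nrow, integer(1)))
    }, integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})
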