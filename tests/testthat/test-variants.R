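test_that("variant classification follows the affected-base-size rule", {
  expect_equal(classify_variant("A", "T"), "SNP")
  expect_equal(classify_variant("A", paste0("A", strrep("T", 10))), "INS_INDEL")
  ref61 <- random_dna_str(61)
  expect_equal(classify_variant(ref61, substr(ref61, 1, 1)), "DEL_SV")
  ## the 50-bp boundary: 49 is an indel, 50 and 51 are SVs
  expect_equal(classify_variant("A", paste0("A", strrep("G", 49))), "INS_INDEL")
  expect_equal(classify_variant("A", paste0("A", strrep("G", 50))), "INS_SV")
  expect_equal(classify_variant("A", paste0("G", strrep("A", 51))), "INS_SV")
  expect_equal(classify_variant(paste0("A", strrep("G", 49)), "A"), "DEL_INDEL")
  expect_equal(classify_variant(paste0("A", strrep("G", 50)), "A"), "DEL_SV")
  ## vectorized and order-independent
  refs <- c("A", "A", ref61); alts <- c("T", "ATTTTTTTTTT", "C")
  expect_equal(classify_variant(refs, alts), c("SNP", "INS_INDEL", "DEL_SV"))
  perm <- c(3, 1, 2)
  expect_equal(classify_variant(refs[perm], alts[perm]),
               c("SNP", "INS_INDEL", "DEL_SV")[perm])
})

test_that("malformed allele records are rejected", {
  expect_error(classify_variant("AT", "GC"), "multi-base substitution")
  expect_error(classify_variant("", "A"), "empty allele")
  expect_error(classify_variant("A", ""), "empty allele")
  expect_error(classify_variant("A", "<DEL>"), "non-nucleotide")
})

test_that("class summaries add up", {
  empty <- data.frame(ref = character(0), alt = character(0))
  expect_equal(summarize_variant_classes(empty), c(SNP = 0L, indel = 0L, SV = 0L))
  v <- data.frame(ref = c("A", "A", random_dna_str(61)),
                  alt = c("T", "ATTTTTTTTTT", "C"), stringsAsFactors = FALSE)
  expect_equal(summarize_variant_classes(v), c(SNP = 1L, indel = 1L, SV = 1L))
})

test_that("variant location honours footprint rules and exon priority", {
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "c",
                      start = c(1000, 3000), end = c(2000, 4000),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("g1", "g1", "g2"), contig = "c",
                      start = c(1000, 1600, 3000), end = c(1400, 2000, 4000),
                      stringsAsFactors = FALSE)
  v <- data.frame(
    contig = "c",
    pos = c(1200,   # inside exon
            2500,   # strictly between the gene spans
            1450,   # intron SNP
            1350,   # 100-bp deletion straddling the exon/intron boundary
            999),   # insertion anchored just before the gene
    ref = c("A", "A", "A", random_dna_str(101), "A"),
    alt = c("T", "T", "T", "A", paste0("A", random_dna_str(10))),
    stringsAsFactors = FALSE)
  got <- annotate_variant_location(v, genes, exons)
  expect_equal(got, c("exon", "intergenic", "intron", "exon", "intergenic"))
  ## brute-force per-base oracle agrees on every case
  oracle <- vapply(seq_len(nrow(v)), function(r)
    location_oracle(v$pos[r], nchar(v$ref[r]), genes, exons, "c"), character(1))
  expect_equal(got, oracle)
  expect_error(
    annotate_variant_location(data.frame(contig = "nope", pos = 1, ref = "A",
                                         alt = "T"), genes, exons),
    "nope")
})

test_that("conservation labels follow the 0.2% / 2% thresholds", {
  gene <- data.frame(gene_id = "g", contig = "c", start = 1, end = 1000,
                     stringsAsFactors = FALSE)
  snp_at <- function(p) data.frame(contig = "c", pos = p, ref = "A", alt = "T",
                                   stringsAsFactors = FALSE)
  one <- classify_gene_conservation(gene, snp_at(500))
  expect_equal(one$fraction, 0.001)
  expect_equal(one$label, "conserved")
  del30 <- data.frame(contig = "c", pos = 100, ref = random_dna_str(30),
                      alt = "A", stringsAsFactors = FALSE)
  expect_equal(classify_gene_conservation(gene, del30)$label, "variable")
  del10 <- data.frame(contig = "c", pos = 100, ref = random_dna_str(10),
                      alt = "A", stringsAsFactors = FALSE)
  mid <- classify_gene_conservation(gene, del10)
  expect_equal(mid$fraction, 0.01)
  expect_equal(mid$label, "intermediate")
  ## overlapping footprints are merged before counting
  dup <- rbind(snp_at(500), snp_at(500))
  expect_equal(classify_gene_conservation(gene, dup)$overlap_bases, 1)
  ## footprints clipped to the span
  hang <- data.frame(contig = "c", pos = 995, ref = random_dna_str(20),
                     alt = "A", stringsAsFactors = FALSE)
  expect_equal(classify_gene_conservation(gene, hang)$overlap_bases, 6)
  expect_error(
    classify_gene_conservation(data.frame(gene_id = "z", contig = "c",
                                          start = 5, end = 4), snp_at(1)),
    "zero")
  expect_error(classify_gene_conservation(gene, snp_at(1),
                                          conserved_max = 0.5,
                                          variable_min = 0.1),
               "below")
})

test_that("window densities tile contigs and conserve totals", {
  cl <- c(c1 = 100000)
  v <- data.frame(contig = "c1", pos = c(1, 50001), stringsAsFactors = FALSE)
  w <- variant_density_windows(v, cl)
  expect_equal(w$count, c(1, 1))
  expect_equal(w$window_start, c(1, 50001))
  empty <- variant_density_windows(v[0, ], c(c1 = 125000))
  expect_equal(nrow(empty), 3)      # last window short
  expect_equal(empty$window_end[3], 125000)
  expect_equal(sum(empty$count), 0)
  expect_error(variant_density_windows(
    data.frame(contig = "cX", pos = 5), cl), "cX")
})

test_that("window totals, class totals and record count agree on a world", {
  tw <- test_world("small")
  w <- tw$world
  v <- w$truth$variants
  dens <- variant_density_windows(v, w$truth$contig_len_a)
  expect_equal(sum(dens$count), nrow(v))
  expect_equal(sum(summarize_variant_classes(v)), nrow(v))
})
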