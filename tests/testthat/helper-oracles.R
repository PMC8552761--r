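## Independent oracles, deliberately naive: an exhaustive affine-gap global
## aligner (Gotoh three-state DP with traceback), brute-force per-base
## interval labelling, and membership counting for k-of-n intersections.

nw_oracle <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  S <- BLOSUM62
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(gap_open + gap_ext * (i - 1))
  for (j in 2:(m + 1)) Iy[1, j] <- -(gap_open + gap_ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[x[i - 1], y[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
    }
  }
  score <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  i <- n + 1; j <- m + 1; nm <- 0L; cols <- 0L
  state <- c("M", "Ix", "Iy")[which.max(c(M[i, j], Ix[i, j], Iy[i, j]))]
  while (i > 1 || j > 1) {
    cols <- cols + 1L
    if (state == "M") {
      if (x[i - 1] == y[j - 1]) nm <- nm + 1L
      state <- c("M", "Ix", "Iy")[
        which.max(c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]))]
      i <- i - 1; j <- j - 1
    } else if (state == "Ix") {
      state <- if (Ix[i, j] == M[i - 1, j] - gap_open - gap_ext) "M" else "Ix"
      i <- i - 1
    } else {
      state <- if (Iy[i, j] == M[i, j - 1] - gap_open - gap_ext) "M" else "Iy"
      j <- j - 1
    }
  }
  list(score = score, identity = nm / cols, n_cols = cols)
}

## label a variant footprint by checking every one of its bases
location_oracle <- function(pos, ref_len, genes, exons, contig) {
  bases <- pos:(pos + max(ref_len, 1) - 1)
  es <- exons[exons$contig == contig, ]
  gs <- genes[genes$contig == contig, ]
  in_exon <- any(vapply(bases, function(b)
    any(b >= es$start & b <= es$end), logical(1)))
  if (in_exon) return("exon")
  in_gene <- any(vapply(bases, function(b)
    any(b >= gs$start & b <= gs$end), logical(1)))
  if (in_gene) "intron" else "intergenic"
}

k_of_n_oracle <- function(sets, k) {
  ids <- unique(unlist(sets))
  hits <- vapply(ids, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
  sort(ids[hits >= k])
}

random_protein <- function(n) {
  paste(sample(haplodiff:::AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
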