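## Synthetic diploid world generator.
##
## Haplotype A is assembled from scratch (spacers + gene payloads); haplotype
## B is obtained by applying every planted variant to A, so truth-consistency
## (A + variants == B) holds by construction and is still asserted.

FWD_PRIMER <- "CCCCCTTTCTCCCTCACTA"
REV_PRIMER <- "AACMACAACCATCTCCWCCRT"
AMPLICON_LEN <- 563L

#' Simulate a diploid genome pair with planted ground truth
#'
#' Generates two haplotype genomes that differ by planted SNPs, indels and
#' structural variants at configured densities, carry a tandem-duplicated
#' gene family with allelic counterparts and a plantable PCR amplicon in
#' every copy, and have haplotype-specific genes (emitted as whole-gene
#' SVs). Haplotype A is the reference coordinate system of the variant set.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `genome_a`, `genome_b` (each of class
#'   `HaplotypeGenome`: `seqs` ([Biostrings::DNAStringSet]), `genes`,
#'   `exons` data.frames, `proteins` ([Biostrings::AAStringSet])) and
#'   `truth` (class `SimulationTruth`) holding the planted variants (with
#'   class and location labels), the family structure, the allelic map,
#'   haplotype-specific ids, expression means, planted bias/induction
#'   factors, allele-distinguishing SNP loci, and per-copy amplicon
#'   sequences.
#' @export
#' @examples
#' world <- simulate_diploid(sim_config(genome_length = 60000, n_genes = 10,
#'                                      n_hap_specific_genes = 1, seed = 7))
#' world$truth$class_counts
simulate_diploid <- function(config) {
  validate_sim_config(config)
  with_local_seed(config$seed, build_world(config))
}

## ---------------------------------------------------------------- payloads

make_family_payloads <- function(cfg) {
  n_codons <- 180L
  l_aa <- n_codons - 1L            # residues incl. the initial Met
  anc_cds <- random_orf(n_codons)
  anc_codons <- codons_of(anc_cds)
  anc_prot <- strsplit(translate_cds(anc_cds), "")[[1]]

  k_par <- floor(l_aa * cfg$family_paralog_divergence / 2)
  eligible <- 2:(l_aa)             # keep Met and the stop codon intact
  if (k_par * cfg$family_copies > length(eligible)) {
    stop("family CDS too short for the requested paralog divergence")
  }
  site_pool <- sample(eligible, k_par * cfg$family_copies)
  aa_by_codon <- Biostrings::GENETIC_CODE

  rev_resolved <- resolve_iupac(REV_PRIMER)
  interior_len <- AMPLICON_LEN - nchar(FWD_PRIMER) - nchar(REV_PRIMER)
  anc_interior <- random_dna(interior_len, cfg$gc_content)
  k_marker <- max(2L, round(interior_len * cfg$family_paralog_divergence / 2))
  k_amp_allelic <- round(interior_len * cfg$family_allelic_divergence)
  need <- cfg$family_copies * (k_marker + k_amp_allelic)
  if (need > interior_len) stop("amplicon interior too short for divergence settings")
  amp_pool <- sample(seq_len(interior_len), need)

  strands <- rep_len(c("+", "+", "-", "+"), cfg$family_copies)
  payloads <- vector("list", cfg$family_copies)
  pool_i <- 0L; amp_i <- 0L
  for (i in seq_len(cfg$family_copies)) {
    sites <- if (k_par > 0) site_pool[pool_i + seq_len(k_par)] else integer(0)
    pool_i <- pool_i + k_par
    codons <- anc_codons
    prot <- anc_prot
    for (s in sites) {
      new_aa <- sample(setdiff(AA_ALPHABET20, prot[s]), 1)
      prot[s] <- new_aa
      codons[s] <- sample(names(aa_by_codon)[aa_by_codon == new_aa], 1)
    }
    cds <- paste(codons, collapse = "")

    ## synonymous allelic substitutions at 4-fold degenerate third positions
    fourfold <- which(substr(codons, 1, 2) %in% FOURFOLD_PREFIXES)
    fourfold <- setdiff(fourfold, c(1L, n_codons))
    k_syn <- round(nchar(cds) * cfg$family_allelic_divergence)
    k_syn <- min(k_syn, length(fourfold))
    syn_codon_idx <- if (k_syn > 0) sort(sample(fourfold, k_syn)) else integer(0)
    syn_new <- vapply(syn_codon_idx, function(ci) {
      sample(setdiff(DNA_BASES, substr(codons[ci], 3, 3)), 1)
    }, character(1))

    ## copy-specific amplicon interior plus its allelic sites
    marker_pos <- amp_pool[amp_i + seq_len(k_marker)]; amp_i <- amp_i + k_marker
    allelic_pos <- if (k_amp_allelic > 0) {
      p <- amp_pool[amp_i + seq_len(k_amp_allelic)]; amp_i <- amp_i + k_amp_allelic
      sort(p)
    } else integer(0)
    interior <- anc_interior
    for (p in marker_pos) {
      interior <- substr_replace(interior, p,
        sample(setdiff(DNA_BASES, substr(interior, p, p)), 1))
    }
    amp_allelic_new <- vapply(allelic_pos, function(p) {
      sample(setdiff(DNA_BASES, substr(interior, p, p)), 1)
    }, character(1))
    amp_seq <- paste0(FWD_PRIMER, interior, revcomp(rev_resolved))

    payloads[[i]] <- build_gene_payload(
      cds = cds, intron_len = sample(120:250, 1), strand = strands[i],
      tail_seq = amp_seq, copy = i,
      syn_codon_idx = syn_codon_idx, syn_new = syn_new,
      amp_allelic_pos = allelic_pos, amp_allelic_new = amp_allelic_new)
  }
  payloads
}

## assemble the sense-coordinate structure of one gene
build_gene_payload <- function(cds, intron_len, strand, tail_seq = "",
                               copy = NA_integer_,
                               syn_codon_idx = integer(0), syn_new = character(0),
                               amp_allelic_pos = integer(0),
                               amp_allelic_new = character(0)) {
  cds_len <- nchar(cds)
  n_codons <- cds_len / 3
  b <- if (intron_len > 0) 3L * floor(n_codons / 2) else cds_len
  exon1 <- substr(cds, 1, b)
  exon2 <- paste0(substr(cds, b + 1, cds_len), tail_seq)
  intron <- if (intron_len > 0) random_dna(intron_len) else ""
  sense_len <- nchar(exon1) + nchar(intron) + nchar(exon2)
  list(
    cds = cds, cds_len = cds_len, b = b,
    exon1 = exon1, intron = intron, exon2 = exon2,
    sense_len = sense_len, strand = strand,
    protein = translate_cds(cds),
    tail_len = nchar(tail_seq), copy = copy,
    syn_codon_idx = syn_codon_idx, syn_new = syn_new,
    amp_allelic_pos = amp_allelic_pos, amp_allelic_new = amp_allelic_new
  )
}

make_shared_payload <- function() {
  build_gene_payload(cds = random_orf(sample(150:300, 1)),
                     intron_len = sample(80:250, 1),
                     strand = sample(c("+", "-"), 1))
}

make_specific_payload <- function() {
  build_gene_payload(cds = random_orf(sample(120:200, 1)),
                     intron_len = 0L,
                     strand = sample(c("+", "-"), 1))
}

## sense coordinate of CDS index (1-based), given the intron split after b
cds_to_sense <- function(idx, payload) {
  ifelse(idx <= payload$b, idx, idx + nchar(payload$intron))
}

## genomic interval of a sense interval for a gene starting at `start`
sense_to_genomic <- function(a, b, start, sense_len, strand) {
  if (strand == "+") c(start + a - 1L, start + b - 1L)
  else c(start + sense_len - b, start + sense_len - a)
}

genomic_gene_seq <- function(payload) {
  s <- paste0(payload$exon1, payload$intron, payload$exon2)
  if (payload$strand == "-") revcomp(s) else s
}

resolve_iupac <- function(primer) {
  chars <- strsplit(primer, "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

## ------------------------------------------------------------------ layout

build_world <- function(cfg) {
  n_family <- cfg$family_copies
  n_spec <- cfg$n_hap_specific_genes
  n_shared <- cfg$n_genes - n_family - n_spec

  fam_payloads <- make_family_payloads(cfg)
  shared_payloads <- replicate(n_shared, make_shared_payload(), simplify = FALSE)
  a_spec_payloads <- replicate(n_spec, make_specific_payload(), simplify = FALSE)
  b_spec_payloads <- replicate(n_spec, make_specific_payload(), simplify = FALSE)

  contig_len <- rep(cfg$genome_length %/% cfg$n_contigs, cfg$n_contigs)
  contig_len[1] <- contig_len[1] + cfg$genome_length %% cfg$n_contigs
  contig_ids <- sprintf("contig_%02d", seq_len(cfg$n_contigs))

  ## contig assignment: family first on contig 1, everything else round-robin
  others <- c(shared_payloads, a_spec_payloads)
  other_type <- c(rep("shared", n_shared), rep("a_specific", n_spec))
  ord <- sample(length(others))
  others <- others[ord]; other_type <- other_type[ord]
  other_contig <- rep_len(seq_len(cfg$n_contigs), length(others))

  genes <- list(); seqs <- character(cfg$n_contigs)
  min_spacer <- 400L
  for (ci in seq_len(cfg$n_contigs)) {
    pl <- if (ci == 1) c(fam_payloads, others[other_contig == ci]) else
      others[other_contig == ci]
    ty <- if (ci == 1) c(rep("family", n_family), other_type[other_contig == ci]) else
      other_type[other_contig == ci]
    gene_bp <- sum(vapply(pl, function(p) p$sense_len, numeric(1)))
    n_sp <- length(pl) + 1L
    slack <- contig_len[ci] - gene_bp - min_spacer * n_sp
    if (slack < 0) {
      stop("genome too short: contig ", contig_ids[ci], " needs at least ",
           gene_bp + min_spacer * n_sp, " bases to host ", length(pl),
           " genes with ", min_spacer, "-bp spacers but has ", contig_len[ci])
    }
    u <- runif(n_sp)
    extra <- floor(slack * u / sum(u))
    extra[n_sp] <- slack - sum(extra[-n_sp])
    spacer_len <- min_spacer + extra

    pieces <- character(0); pos <- 1L
    contig_genes <- vector("list", length(pl))
    for (k in seq_along(pl)) {
      pieces <- c(pieces, random_dna(spacer_len[k], cfg$gc_content))
      pos <- pos + spacer_len[k]
      g <- pl[[k]]
      contig_genes[[k]] <- list(payload = g, type = ty[k], contig = contig_ids[ci],
                                start = pos, end = pos + g$sense_len - 1L)
      pieces <- c(pieces, genomic_gene_seq(g))
      pos <- pos + g$sense_len
    }
    pieces <- c(pieces, random_dna(spacer_len[n_sp], cfg$gc_content))
    seqs[ci] <- paste(pieces, collapse = "")
    stopifnot(nchar(seqs[ci]) == contig_len[ci])
    genes <- c(genes, contig_genes)
  }

  ## stable ids in genomic order; family copies keep their copy index
  genes <- genes[order(vapply(genes, function(g) match(g$contig, contig_ids), numeric(1)),
                       vapply(genes, function(g) g$start, numeric(1)))]
  n_plain <- 0L
  for (k in seq_along(genes)) {
    if (genes[[k]]$type == "family") {
      genes[[k]]$id <- sprintf("hsp20_%d", genes[[k]]$payload$copy)
    } else {
      n_plain <- n_plain + 1L
      genes[[k]]$id <- sprintf("g%03d", n_plain)
    }
  }

  anno <- build_annotation(genes, contig_ids, contig_len)
  world <- plant_variants(cfg, genes, anno, seqs, contig_ids, contig_len,
                          b_spec_payloads)
  finalize_world(cfg, genes, anno, seqs, contig_ids, contig_len, world,
                 b_spec_payloads)
}

## genomic gene/exon/cds tables for haplotype A
build_annotation <- function(genes, contig_ids, contig_len) {
  gene_tab <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$id, contig = g$contig, start = g$start, end = g$end,
               strand = g$payload$strand, type = g$type,
               copy = if (g$type == "family") g$payload$copy else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  exon_rows <- list(); cds_rows <- list()
  for (g in genes) {
    p <- g$payload
    l1 <- nchar(p$exon1); li <- nchar(p$intron); l2 <- nchar(p$exon2)
    sense_ex <- if (li > 0) {
      list(c(1L, l1), c(l1 + li + 1L, p$sense_len))
    } else list(c(1L, p$sense_len))
    ## CDS sense segments exclude any non-coding tail on exon 2
    sense_cds <- if (li > 0) {
      list(c(1L, p$b), c(l1 + li + 1L, l1 + li + (p$cds_len - p$b)))
    } else list(c(1L, p$cds_len))
    for (iv in sense_ex) {
      gi <- sense_to_genomic(iv[1], iv[2], g$start, p$sense_len, p$strand)
      exon_rows[[length(exon_rows) + 1]] <-
        data.frame(gene_id = g$id, contig = g$contig, start = gi[1], end = gi[2],
                   stringsAsFactors = FALSE)
    }
    for (iv in sense_cds) {
      gi <- sense_to_genomic(iv[1], iv[2], g$start, p$sense_len, p$strand)
      cds_rows[[length(cds_rows) + 1]] <-
        data.frame(gene_id = g$id, contig = g$contig, start = gi[1], end = gi[2],
                   stringsAsFactors = FALSE)
    }
  }
  exons <- do.call(rbind, exon_rows)
  cds <- do.call(rbind, cds_rows)
  exons <- exons[order(match(exons$contig, contig_ids), exons$start), ]
  cds <- cds[order(match(cds$contig, contig_ids), cds$start), ]
  rownames(gene_tab) <- rownames(exons) <- rownames(cds) <- NULL
  list(genes = gene_tab, exons = exons, cds = cds)
}
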