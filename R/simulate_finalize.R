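## Haplotype B construction, annotation liftover, and truth assembly.

finalize_world <- function(cfg, genes, anno, seqs, contig_ids, contig_len,
                           planted, b_spec_payloads) {
  variants <- planted$variants

  ## ---- haplotype B sequences by applying every variant to A
  seqs_b <- character(length(contig_ids))
  lift <- vector("list", length(contig_ids))
  for (ci in seq_along(contig_ids)) {
    v <- variants[variants$contig == contig_ids[ci], ]
    ## assert REF strings really are the A sequence (truth consistency)
    if (nrow(v) > 0) {
      got <- substring(seqs[ci], v$pos, v$pos + nchar(v$ref) - 1L)
      stopifnot(identical(got, v$ref))
      at <- IRanges::IRanges(v$pos, v$pos + nchar(v$ref) - 1L)
      stopifnot(IRanges::isDisjoint(at))  # footprints must not overlap
      seqs_b[ci] <- as.character(Biostrings::replaceAt(
        Biostrings::DNAString(seqs[ci]), at, v$alt))
      thr <- v$pos + nchar(v$ref) - 1L
      del <- v$affected_size
      lift[[ci]] <- local({
        thr <- thr; del <- del
        function(x) x + vapply(x, function(xx) sum(del[thr < xx]), numeric(1))
      })
    } else {
      seqs_b[ci] <- seqs[ci]
      lift[[ci]] <- identity
    }
  }
  lift_pos <- function(contig, x) lift[[match(contig, contig_ids)]](x)
  contig_len_b <- nchar(seqs_b)

  ## ---- annotation tables for both haplotypes
  ga <- anno$genes
  ga$gene_id_a <- paste0("hapA_", ga$gene_id)
  keep_b <- ga$type != "a_specific"

  lift_tab <- function(tab) {
    out <- tab
    for (r in seq_len(nrow(out))) {
      out$start[r] <- lift_pos(out$contig[r], out$start[r])
      out$end[r] <- lift_pos(out$contig[r], out$end[r])
    }
    out
  }
  gb <- lift_tab(ga[keep_b, c("gene_id", "contig", "start", "end", "strand",
                              "type", "copy")])
  exons_a <- anno$exons
  exons_b <- lift_tab(exons_a[exons_a$gene_id %in% ga$gene_id[keep_b], ])
  cds_a <- anno$cds
  cds_b <- lift_tab(cds_a[cds_a$gene_id %in% ga$gene_id[keep_b], ])

  ## haplotype-B-specific genes: inserted after their anchors
  if (nrow(planted$b_anchors) > 0) {
    for (r in seq_len(nrow(planted$b_anchors))) {
      an <- planted$b_anchors[r, ]
      p <- b_spec_payloads[[an$idx]]
      s_b <- lift_pos(an$contig, an$pos) + 1L
      id <- sprintf("u%03d", an$idx)
      gb <- rbind(gb, data.frame(gene_id = id, contig = an$contig, start = s_b,
                                 end = s_b + p$sense_len - 1L,
                                 strand = p$strand, type = "b_specific",
                                 copy = NA_integer_, stringsAsFactors = FALSE))
      exons_b <- rbind(exons_b, data.frame(gene_id = id, contig = an$contig,
                                           start = s_b,
                                           end = s_b + p$sense_len - 1L,
                                           stringsAsFactors = FALSE))
      cds_segment <- sense_to_genomic(1L, p$cds_len, s_b, p$sense_len, p$strand)
      cds_b <- rbind(cds_b, data.frame(gene_id = id, contig = an$contig,
                                       start = cds_segment[1],
                                       end = cds_segment[2],
                                       stringsAsFactors = FALSE))
    }
  }
  ord_b <- order(match(gb$contig, contig_ids), gb$start)
  gb <- gb[ord_b, ]; rownames(gb) <- NULL
  exons_b <- exons_b[order(match(exons_b$contig, contig_ids), exons_b$start), ]
  cds_b <- cds_b[order(match(cds_b$contig, contig_ids), cds_b$start), ]

  ## ---- proteins, extracted from the actual sequences
  payload_of <- setNames(lapply(genes, function(g) g$payload),
                         vapply(genes, function(g) g$id, character(1)))
  for (j in seq_along(b_spec_payloads)) {
    payload_of[[sprintf("u%03d", j)]] <- b_spec_payloads[[j]]
  }
  strand_of_a <- setNames(ga$strand, ga$gene_id)
  strand_of_b <- setNames(gb$strand, gb$gene_id)

  prot_a <- extract_proteins(seqs, contig_ids, cds_a, strand_of_a)
  prot_b <- extract_proteins(seqs_b, contig_ids, cds_b, strand_of_b)
  ## haplotype A proteins must equal the generating payloads exactly
  for (id in names(prot_a)) {
    stopifnot(identical(prot_a[[id]], payload_of[[id]]$protein))
  }

  genome_a <- new_haplotype_genome("A", seqs, contig_ids, ga, exons_a, prot_a,
                                   prefix = "hapA_")
  genome_b <- new_haplotype_genome("B", seqs_b, contig_ids, gb, exons_b, prot_b,
                                   prefix = "hapB_")

  ## ---- truth assembly
  fam_a <- ga[ga$type == "family", ]
  fam_a <- fam_a[order(fam_a$copy), ]
  family_members <- rbind(
    data.frame(haplotype = "A", gene_id = paste0("hapA_", fam_a$gene_id),
               copy = fam_a$copy, stringsAsFactors = FALSE),
    data.frame(haplotype = "B", gene_id = paste0("hapB_", fam_a$gene_id),
               copy = fam_a$copy, stringsAsFactors = FALSE))

  pair_units <- ga$gene_id[ga$type %in% c("shared", "family")]
  ase <- planted$ase
  n_loci <- table(ase$pair_id)
  allelic_map <- data.frame(
    gene_a = paste0("hapA_", pair_units),
    gene_b = paste0("hapB_", pair_units),
    unit = pair_units,
    copy = ga$copy[match(pair_units, ga$gene_id)],
    n_ase_loci = as.integer(ifelse(pair_units %in% names(n_loci),
                                   n_loci[pair_units], 0L)),
    stringsAsFactors = FALSE)

  hap_specific_ids <- list(
    A = paste0("hapA_", ga$gene_id[ga$type == "a_specific"]),
    B = paste0("hapB_", gb$gene_id[gb$type == "b_specific"]))

  units <- build_units(cfg, ga, gb, exons_a, exons_b, allelic_map)
  expr <- build_expression_means(cfg, units)

  if (nrow(ase) > 0) {
    ase$pos_b <- vapply(seq_len(nrow(ase)),
                        function(r) lift_pos(ase$contig[r], ase$pos[r]),
                        numeric(1))
  } else ase$pos_b <- integer(0)

  amplicons <- family_amplicons(genes, ga, gb, seqs, seqs_b, contig_ids)

  cls <- variants$var_class
  class_counts <- c(
    SNP = sum(cls == "SNP"),
    INS_INDEL = sum(cls == "INS_INDEL"), DEL_INDEL = sum(cls == "DEL_INDEL"),
    INS_SV = sum(cls == "INS_SV"), DEL_SV = sum(cls == "DEL_SV"))

  truth <- structure(list(
    variants = variants,
    family_members = family_members,
    allelic_map = allelic_map,
    hap_specific_ids = hap_specific_ids,
    units = units$tab,
    expression_means = expr,
    planted_bias = cfg$bias_factors,
    planted_induction = rep(cfg$induction_factor, cfg$family_copies),
    ase_loci = ase,
    amplicons = amplicons,
    class_counts = class_counts,
    contig_len_a = setNames(contig_len, contig_ids),
    contig_len_b = setNames(contig_len_b, contig_ids),
    config = cfg
  ), class = "SimulationTruth")

  list(genome_a = genome_a, genome_b = genome_b, truth = truth)
}

new_haplotype_genome <- function(haplotype, seqs, contig_ids, gene_tab,
                                 exon_tab, proteins, prefix) {
  dss <- Biostrings::DNAStringSet(setNames(seqs, contig_ids))
  gt <- data.frame(gene_id = paste0(prefix, gene_tab$gene_id),
                   contig = gene_tab$contig, start = gene_tab$start,
                   end = gene_tab$end, strand = gene_tab$strand,
                   stringsAsFactors = FALSE)
  et <- data.frame(gene_id = paste0(prefix, exon_tab$gene_id),
                   contig = exon_tab$contig, start = exon_tab$start,
                   end = exon_tab$end, stringsAsFactors = FALSE)
  rownames(gt) <- rownames(et) <- NULL
  aas <- Biostrings::AAStringSet(setNames(unlist(proteins),
                                          paste0(prefix, names(proteins))))
  structure(list(haplotype = haplotype, seqs = dss, genes = gt, exons = et,
                 proteins = aas), class = "HaplotypeGenome")
}

#' @export
print.HaplotypeGenome <- function(x, ...) {
  cat("HaplotypeGenome", x$haplotype, ":", length(x$seqs), "contig(s),",
      sum(Biostrings::width(x$seqs)), "bp,", nrow(x$genes), "genes\n")
  invisible(x)
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat("SimulationTruth:", nrow(x$variants), "planted variants (",
      paste(names(x$class_counts), x$class_counts, collapse = ", "), ");",
      nrow(x$allelic_map), "allelic pairs;",
      length(x$hap_specific_ids$A), "+", length(x$hap_specific_ids$B),
      "haplotype-specific genes\n")
  invisible(x)
}

## splice CDS segments (genomic order; reverse-complemented for '-' genes)
extract_proteins <- function(seqs, contig_ids, cds_tab, strand_of) {
  ids <- unique(cds_tab$gene_id)
  out <- setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    seg <- cds_tab[cds_tab$gene_id == id, ]
    seg <- seg[order(seg$start), ]
    ci <- match(seg$contig[1], contig_ids)
    cds <- paste(substring(seqs[ci], seg$start, seg$end), collapse = "")
    if (strand_of[[id]] == "-") cds <- revcomp(cds)
    prot <- translate_cds(cds)
    if (grepl("\\*", prot)) {
      stop("internal error: premature stop codon in simulated gene ", id)
    }
    out[[id]] <- prot
  }
  out
}

build_units <- function(cfg, ga, gb, exons_a, exons_b, allelic_map) {
  exlen_a <- tapply(exons_a$end - exons_a$start + 1L, exons_a$gene_id, sum)
  exlen_b <- tapply(exons_b$end - exons_b$start + 1L, exons_b$gene_id, sum)
  pair <- data.frame(
    unit = allelic_map$unit,
    gene_a = allelic_map$gene_a, gene_b = allelic_map$gene_b,
    type = ifelse(is.na(allelic_map$copy), "pair", "family_pair"),
    copy = allelic_map$copy,
    length = as.integer(exlen_a[allelic_map$unit]),
    stringsAsFactors = FALSE)
  spec_a <- ga$gene_id[ga$type == "a_specific"]
  spec_b <- gb$gene_id[gb$type == "b_specific"]
  spec <- rbind(
    if (length(spec_a) > 0) data.frame(
      unit = paste0("hapA_", spec_a), gene_a = paste0("hapA_", spec_a),
      gene_b = NA_character_, type = "A_specific", copy = NA_integer_,
      length = as.integer(exlen_a[spec_a]), stringsAsFactors = FALSE),
    if (length(spec_b) > 0) data.frame(
      unit = paste0("hapB_", spec_b), gene_a = NA_character_,
      gene_b = paste0("hapB_", spec_b), type = "B_specific", copy = NA_integer_,
      length = as.integer(exlen_b[spec_b]), stringsAsFactors = FALSE))
  tab <- rbind(pair, spec)
  rownames(tab) <- NULL

  ## planted condition-responsive genes among the shared (non-family) pairs
  shared_units <- tab$unit[tab$type == "pair"]
  n_resp <- cfg$n_temp_responsive + cfg$n_carbon_responsive
  resp <- if (n_resp > 0) sample(shared_units, n_resp) else character(0)
  temp_ids <- head(resp, cfg$n_temp_responsive)
  carbon_ids <- tail(resp, cfg$n_carbon_responsive)
  carbons <- unique(cfg$conditions$carbon)
  tab$temp_responsive <- tab$unit %in% temp_ids
  tab$carbon_responsive <- tab$unit %in% carbon_ids
  tab$carbon <- NA_character_
  if (length(carbon_ids) > 0) {
    tab$carbon[match(carbon_ids, tab$unit)] <-
      rep_len(carbons, length(carbon_ids))
  }
  list(tab = tab)
}

build_expression_means <- function(cfg, units) {
  tab <- units$tab
  cond <- cfg$conditions
  base <- numeric(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    base[r] <- if (!is.na(tab$copy[r])) {
      cfg$family_baseline_means[tab$copy[r]]
    } else {
      rlnorm(1, meanlog = log(cfg$baseline_mean), sdlog = cfg$baseline_log_sd)
    }
  }
  m <- matrix(base, nrow = nrow(tab), ncol = nrow(cond),
              dimnames = list(tab$unit, cond$label))
  for (j in seq_len(nrow(cond))) {
    induced <- cond$temperature[j] == cfg$induced_temperature
    if (induced) {
      m[!is.na(tab$copy), j] <- m[!is.na(tab$copy), j] * cfg$induction_factor
      m[tab$temp_responsive, j] <- m[tab$temp_responsive, j] * cfg$temp_effect
    }
    hit <- tab$carbon_responsive & !is.na(tab$carbon) &
      tab$carbon == cond$carbon[j]
    m[hit, j] <- m[hit, j] * cfg$carbon_effect
  }
  m
}

family_amplicons <- function(genes, ga, gb, seqs, seqs_b, contig_ids) {
  fam <- Filter(function(g) g$type == "family", genes)
  if (length(fam) == 0) {
    return(data.frame(haplotype = character(0), gene_id = character(0),
                      copy = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (g in fam) {
    p <- g$payload
    l1 <- nchar(p$exon1); li <- nchar(p$intron)
    amp_sense <- c(l1 + li + (p$cds_len - p$b) + 1L, p$sense_len)
    for (hap in c("A", "B")) {
      gt <- if (hap == "A") ga else gb
      s <- if (hap == "A") seqs else seqs_b
      row <- gt[gt$gene_id == g$id, ]
      giv <- sense_to_genomic(amp_sense[1], amp_sense[2], row$start,
                              p$sense_len, p$strand)
      ci <- match(row$contig, contig_ids)
      seq <- substr(s[ci], giv[1], giv[2])
      if (p$strand == "-") seq <- revcomp(seq)
      stopifnot(startsWith(seq, FWD_PRIMER))
      rows[[length(rows) + 1]] <- data.frame(
        haplotype = hap, gene_id = paste0("hap", hap, "_", g$id),
        copy = p$copy, sequence = seq, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$copy, out$haplotype), ]
}
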