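## Variant planting onto haplotype A and construction of haplotype B.
##
## Placement constraints keep the planted truth exactly recoverable:
##  - footprints never overlap (2-bp guard band);
##  - the family block (copies + flanks) is off limits to background variants,
##    so primer sites are never split;
##  - indels/SVs live wholly inside one intergenic or intronic interval;
##  - exonic SNPs avoid first/last codons and never create a stop codon.

plant_variants <- function(cfg, genes, anno, seqs, contig_ids, contig_len,
                           b_spec_payloads) {
  n_contig <- length(contig_ids)
  L_tot <- sum(contig_len)

  ## per-base region code (0 intergenic, 1 exon, 2 intron) and gene index
  region <- lapply(contig_len, function(L) integer(L))
  gene_at <- lapply(contig_len, function(L) integer(L))
  blocked <- lapply(contig_len, function(L) logical(L))
  gene_index <- seq_along(genes)
  for (k in gene_index) {
    g <- genes[[k]]
    ci <- match(g$contig, contig_ids)
    region[[ci]][g$start:g$end] <- 2L
    gene_at[[ci]][g$start:g$end] <- k
  }
  for (r in seq_len(nrow(anno$exons))) {
    ci <- match(anno$exons$contig[r], contig_ids)
    region[[ci]][anno$exons$start[r]:anno$exons$end[r]] <- 1L
  }

  block <- function(ci, p1, p2, margin = 2L) {
    a <- max(1L, p1 - margin); b <- min(contig_len[ci], p2 + margin)
    blocked[[ci]][a:b] <<- TRUE
  }
  is_free <- function(ci, p1, p2) !any(blocked[[ci]][p1:p2])

  ## contig edges
  for (ci in seq_len(n_contig)) {
    block(ci, 1L, 50L, 0L); block(ci, contig_len[ci] - 49L, contig_len[ci], 0L)
  }
  ## family block (tandem cluster + flanks)
  fam <- Filter(function(g) g$type == "family", genes)
  if (length(fam) > 0) {
    fs <- min(vapply(fam, function(g) g$start, numeric(1)))
    fe <- max(vapply(fam, function(g) g$end, numeric(1)))
    block(1L, fs, fe, 100L)
  }
  ## haplotype-A-specific genes become deletion footprints later
  for (g in Filter(function(g) g$type == "a_specific", genes)) {
    block(match(g$contig, contig_ids), g$start, g$end, 30L)
  }

  ## anchors for haplotype-B-specific gene insertions
  b_anchors <- data.frame(contig = character(0), pos = integer(0), idx = integer(0))
  if (length(b_spec_payloads) > 0) {
    for (j in seq_along(b_spec_payloads)) {
      ci <- ((j - 1L) %% n_contig) + 1L
      placed <- FALSE
      for (try in 1:2000) {
        p <- sample(contig_len[ci], 1)
        if (region[[ci]][p] == 0L && is_free(ci, max(1L, p - 30L),
                                             min(contig_len[ci], p + 30L))) {
          b_anchors <- rbind(b_anchors, data.frame(
            contig = contig_ids[ci], pos = p, idx = j, stringsAsFactors = FALSE))
          block(ci, p, p, 30L)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("genome too short: no intergenic room for a ",
                        "haplotype-B-specific gene insertion anchor")
    }
  }

  rows <- list()
  add_row <- function(contig, pos, ref, alt, var_class, location, origin,
                      gene_id = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
      affected_size = nchar(alt) - nchar(ref), var_class = var_class,
      location = location, origin = origin, gene_id = gene_id,
      stringsAsFactors = FALSE)
  }

  ase_rows <- list()
  add_ase <- function(unit, contig, pos) {
    ase_rows[[length(ase_rows) + 1]] <<- data.frame(
      pair_id = unit, contig = contig, pos = as.integer(pos),
      stringsAsFactors = FALSE)
  }

  ## -------- family allelic substitutions (synonymous CDS + amplicon sites)
  for (g in fam) {
    p <- g$payload
    ci <- match(g$contig, contig_ids)
    for (k in seq_along(p$syn_codon_idx)) {
      cds_idx <- 3L * p$syn_codon_idx[k]
      sp <- cds_to_sense(cds_idx, p)
      gp <- sense_to_genomic(sp, sp, g$start, p$sense_len, p$strand)[1]
      ref <- substr(seqs[ci], gp, gp)
      alt <- if (p$strand == "+") p$syn_new[k] else comp_base(p$syn_new[k])
      stopifnot(ref != alt)
      add_row(g$contig, gp, ref, alt, "SNP", "exon", "family_allelic", g$id)
      add_ase(g$id, g$contig, gp)
    }
    l1 <- nchar(p$exon1); li <- nchar(p$intron)
    amp_start_sense <- l1 + li + (p$cds_len - p$b) + 1L
    for (k in seq_along(p$amp_allelic_pos)) {
      sp <- amp_start_sense + nchar(FWD_PRIMER) + p$amp_allelic_pos[k] - 1L
      gp <- sense_to_genomic(sp, sp, g$start, p$sense_len, p$strand)[1]
      ref <- substr(seqs[ci], gp, gp)
      alt <- if (p$strand == "+") p$amp_allelic_new[k] else
        comp_base(p$amp_allelic_new[k])
      stopifnot(ref != alt)
      add_row(g$contig, gp, ref, alt, "SNP", "exon", "family_allelic", g$id)
      add_ase(g$id, g$contig, gp)
    }
  }

  ## -------- haplotype-specific genes as whole-gene SVs
  for (g in Filter(function(g) g$type == "a_specific", genes)) {
    ci <- match(g$contig, contig_ids)
    anchor <- g$start - 11L
    ref <- substr(seqs[ci], anchor, g$end + 10L)
    add_row(g$contig, anchor, ref, substr(ref, 1, 1), "DEL_SV", "exon",
            "hap_specific_A", g$id)
  }
  if (nrow(b_anchors) > 0) {
    for (r in seq_len(nrow(b_anchors))) {
      ci <- match(b_anchors$contig[r], contig_ids)
      p <- b_anchors$pos[r]
      anchor_base <- substr(seqs[ci], p, p)
      gseq <- genomic_gene_seq(b_spec_payloads[[b_anchors$idx[r]]])
      add_row(b_anchors$contig[r], p, anchor_base, paste0(anchor_base, gseq),
              "INS_SV", "intergenic", "hap_specific_B",
              sprintf("u%03d", b_anchors$idx[r]))
    }
  }

  ## -------- CDS position maps for shared genes (for exonic SNPs)
  shared_idx <- which(vapply(genes, function(g) g$type == "shared", logical(1)))
  cds_map <- new.env(parent = emptyenv())
  for (k in shared_idx) {
    g <- genes[[k]]; p <- g$payload
    sp <- cds_to_sense(seq_len(p$cds_len), p)
    gp <- if (p$strand == "+") g$start + sp - 1L else g$start + p$sense_len - sp
    assign(as.character(k), gp, envir = cds_map)
  }

  ## -------- background SNPs, uniformly over unblocked space
  n_snp <- round(L_tot * cfg$snp_rate)
  placed <- 0L; attempts <- 0L
  max_attempts <- 60L * n_snp + 20000L
  while (placed < n_snp) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("genome too short to place ", n_snp, " SNPs (placed ", placed,
           "): unblocked space exhausted")
    }
    ci <- sample.int(n_contig, 1, prob = contig_len)
    p <- sample.int(contig_len[ci], 1)
    if (blocked[[ci]][p]) next
    reg <- region[[ci]][p]
    ref <- substr(seqs[ci], p, p)
    if (reg == 1L) {                     # exon of a shared gene
      k <- gene_at[[ci]][p]
      g <- genes[[k]]; pl <- g$payload
      gp <- get(as.character(k), envir = cds_map)
      cds_idx <- match(p, gp)
      if (is.na(cds_idx)) next           # defensive; exon == CDS for shared
      codon_i <- ceiling(cds_idx / 3)
      n_codons <- pl$cds_len / 3
      if (codon_i <= 1 || codon_i >= n_codons) next
      within <- cds_idx - 3L * (codon_i - 1L)
      codon <- substr(pl$cds, 3L * codon_i - 2L, 3L * codon_i)
      sense_ref <- if (pl$strand == "+") ref else comp_base(ref)
      stopifnot(substr(codon, within, within) == sense_ref)
      cand <- sample(setdiff(DNA_BASES, sense_ref))
      alt_sense <- NA_character_
      for (b in cand) {
        nc <- codon; substr(nc, within, within) <- b
        if (!(nc %in% STOP_CODONS)) { alt_sense <- b; break }
      }
      if (is.na(alt_sense)) next
      alt <- if (pl$strand == "+") alt_sense else comp_base(alt_sense)
      add_row(contig_ids[ci], p, ref, alt, "SNP", "exon", "background", g$id)
      add_ase(g$id, contig_ids[ci], p)
      ## the 2-bp guard band around placed SNPs forbids a second SNP in the
      ## same codon, so the stop-codon check above needs no B-state tracking
    } else {
      alt <- sample(setdiff(DNA_BASES, ref), 1)
      loc <- if (reg == 2L) "intron" else "intergenic"
      add_row(contig_ids[ci], p, ref, alt, "SNP", loc, "background",
              if (reg == 2L) genes[[gene_at[[ci]][p]]]$id else NA_character_)
    }
    block(ci, p, p)
    placed <- placed + 1L
  }

  ## -------- allowed intervals for length variants
  allowed <- allowed_length_variant_intervals(genes, anno, contig_ids, contig_len)

  place_length_variants <- function(n, len_range, class_prefix) {
    placed <- 0L; attempts <- 0L
    max_attempts <- 60L * n + 20000L
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("genome too short to place ", n, " ", class_prefix,
             " length variants of ", len_range[1], "-", len_range[2],
             " bp (placed ", placed, ")")
      }
      len <- sample(len_range[1]:len_range[2], 1)
      is_del <- runif(1) < 0.5
      fl <- if (is_del) len + 1L else 2L
      ok <- allowed$width >= fl
      if (!any(ok)) next
      w <- (allowed$width - fl + 1) * ok
      iv <- sample.int(nrow(allowed), 1, prob = w)
      p <- allowed$start[iv] + sample.int(allowed$width[iv] - fl + 1L, 1) - 1L
      ci <- match(allowed$contig[iv], contig_ids)
      if (!is_free(ci, p, p + fl - 1L)) next
      if (is_del) {
        ref <- substr(seqs[ci], p, p + len)
        alt <- substr(ref, 1, 1)
        cls <- paste0("DEL_", class_prefix)
        foot <- c(p, p + len)
      } else {
        ref <- substr(seqs[ci], p, p)
        alt <- paste0(ref, random_dna(len, cfg$gc_content))
        cls <- paste0("INS_", class_prefix)
        foot <- c(p, p)
      }
      add_row(allowed$contig[iv], p, ref, alt, cls, allowed$label[iv],
              "background", allowed$gene_id[iv])
      block(ci, foot[1], foot[2])
      placed <- placed + 1L
    }
  }

  place_length_variants(round(L_tot * cfg$indel_rate), cfg$indel_len_range, "INDEL")
  place_length_variants(round(L_tot * cfg$sv_rate), cfg$sv_len_range, "SV")

  variants <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), affected_size = integer(0),
               var_class = character(0), location = character(0),
               origin = character(0), gene_id = character(0),
               stringsAsFactors = FALSE)
  variants <- variants[order(match(variants$contig, contig_ids), variants$pos), ]
  rownames(variants) <- NULL
  ase <- if (length(ase_rows) > 0) do.call(rbind, ase_rows) else
    data.frame(pair_id = character(0), contig = character(0), pos = integer(0),
               stringsAsFactors = FALSE)
  list(variants = variants, ase = ase, b_anchors = b_anchors)
}

## disjoint intervals where an indel/SV may sit in its entirety:
## shrunken intergenic intervals and shrunken introns of shared genes
allowed_length_variant_intervals <- function(genes, anno, contig_ids, contig_len) {
  out <- list()
  for (ci in seq_along(contig_ids)) {
    gi <- anno$genes[anno$genes$contig == contig_ids[ci], ]
    span_ir <- IRanges::IRanges(gi$start, gi$end)
    inter <- IRanges::gaps(IRanges::reduce(span_ir), start = 1L,
                           end = contig_len[ci])
    inter <- IRanges::narrow(inter[IRanges::width(inter) > 120], 60, -61)
    if (length(inter) > 0) {
      out[[length(out) + 1]] <- data.frame(
        contig = contig_ids[ci], start = IRanges::start(inter),
        end = IRanges::end(inter), label = "intergenic",
        gene_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  for (g in Filter(function(g) g$type == "shared", genes)) {
    p <- g$payload
    if (nchar(p$intron) < 30) next
    l1 <- nchar(p$exon1); li <- nchar(p$intron)
    giv <- sense_to_genomic(l1 + 1L, l1 + li, g$start, p$sense_len, p$strand)
    out[[length(out) + 1]] <- data.frame(
      contig = g$contig, start = giv[1] + 8L, end = giv[2] - 8L,
      label = "intron", gene_id = g$id, stringsAsFactors = FALSE)
  }
  allowed <- do.call(rbind, out)
  allowed$width <- allowed$end - allowed$start + 1L
  allowed
}
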