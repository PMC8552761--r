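## Readers and writers for the standard formats at the pipeline boundary.
## Coordinates are 1-based inclusive in every file (GFF3/VCF convention) and
## internally, so conversion is the identity and round-trips are lossless.

provenance_lines <- function(seed = NULL) {
  l <- paste0("# haplodiff ", as.character(utils::packageVersion("haplodiff")))
  if (!is.null(seed)) l <- c(l, paste0("# seed: ", seed))
  l
}

#' Read / write FASTA
#'
#' Thin wrappers over [Biostrings] with 60-column wrapping on output.
#'
#' @param path file path.
#' @param x a [Biostrings::DNAStringSet] / [Biostrings::AAStringSet] or a
#'   named character vector.
#' @param type `"DNA"` or `"AA"`.
#' @return `read_fasta` returns a `DNAStringSet` or `AAStringSet`.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  if (type == "DNA") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (is.character(x)) {
    x <- if (type == "DNA") Biostrings::DNAStringSet(x) else
      Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

## ------------------------------------------------------------------- GFF3

## structural pre-scan with line numbers; rtracklayer does the parsing after
validate_gff3_text <- function(path) {
  lines <- readLines(path)
  spans <- list()
  parent_of <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      stop(path, ", line ", i, ": expected 9 tab-separated fields, found ",
           length(f))
    }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 1 || end < start) {
      stop(path, ", line ", i, ": invalid coordinates '", f[4], "-", f[5], "'")
    }
    attrs <- f[9]
    id <- sub(".*ID=([^;]*).*", "\\1", attrs)
    has_id <- grepl("ID=", attrs, fixed = TRUE)
    par <- sub(".*Parent=([^;]*).*", "\\1", attrs)
    has_par <- grepl("Parent=", attrs, fixed = TRUE)
    if (has_id) spans[[id]] <- c(start, end)
    if (has_id && has_par) parent_of[id] <- par
    if (has_par) {
      root <- par
      while (root %in% names(parent_of)) root <- parent_of[[root]]
      if (!is.null(spans[[par]])) {
        ps <- spans[[par]]
        if (start < ps[1] || end > ps[2]) {
          stop(path, ", line ", i, ": ", f[3], " [", start, ",", end,
               "] extends outside its parent feature '", par, "' [",
               ps[1], ",", ps[2], "]")
        }
      }
    }
  }
  invisible(TRUE)
}

#' Read gene models from a GFF3 file
#'
#' The file is structurally validated first (9 fields, sane coordinates,
#' children inside their parents — violations are reported with the line
#' number), then parsed with [rtracklayer::import].
#'
#' @param path GFF3 file.
#' @return list with `genes` (`gene_id`, `contig`, `start`, `end`, `strand`)
#'   and `exons` (`gene_id`, `contig`, `start`, `end`).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_gff3_text(path)
  gr <- rtracklayer::import(path, format = "GFF3")
  ty <- as.character(gr$type)
  gn <- gr[ty == "gene"]
  genes <- data.frame(
    gene_id = as.character(gn$ID),
    contig = as.character(GenomicRanges::seqnames(gn)),
    start = IRanges::start(gn), end = IRanges::end(gn),
    strand = as.character(GenomicRanges::strand(gn)),
    stringsAsFactors = FALSE)
  ex <- gr[ty == "exon"]
  parent <- vapply(ex$Parent, function(p) p[1], character(1))
  exons <- data.frame(
    gene_id = sub("\\.t1$", "", parent),
    contig = as.character(GenomicRanges::seqnames(ex)),
    start = IRanges::start(ex), end = IRanges::end(ex),
    stringsAsFactors = FALSE)
  ord <- order(genes$contig, genes$start)
  genes <- genes[ord, ]; rownames(genes) <- NULL
  exons <- exons[order(exons$contig, exons$start), ]; rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Write gene models to GFF3
#'
#' Emits gene / mRNA / exon features (one transcript per gene, exons as
#' annotated).
#'
#' @param genes,exons data.frames as returned by [read_gff3()].
#' @param path output file.
#' @export
write_gff3 <- function(genes, exons, path) {
  mk <- function(df, type, id, parent) {
    gr <- GenomicRanges::GRanges(
      df$contig, IRanges::IRanges(df$start, df$end),
      strand = if ("strand" %in% names(df)) df$strand else "*")
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id
    S4Vectors::mcols(gr)$Parent <- parent
    gr
  }
  strand_of <- setNames(genes$strand, genes$gene_id)
  exons$strand <- strand_of[exons$gene_id]
  gr <- c(
    mk(genes, "gene", genes$gene_id, NA_character_),
    mk(genes, "mRNA", paste0(genes$gene_id, ".t1"), genes$gene_id),
    mk(exons, "exon", NA_character_, paste0(exons$gene_id, ".t1")))
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 IRanges::start(gr),
                 match(as.character(gr$type), c("gene", "mRNA", "exon")))]
  rtracklayer::export(gr, path, format = "GFF3")
  ## drop the volatile date directive so identical inputs give identical files
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "##date")], path)
  invisible(path)
}

## -------------------------------------------------------------------- VCF

#' Read a VCF of explicit REF/ALT variants
#'
#' Parsed with [vcfR::read.vcfR]; symbolic or multi-allelic ALT records are
#' rejected (this pipeline's variant sets are explicit single-allele
#' records).
#'
#' @param path VCF file.
#' @return data.frame with `contig`, `pos`, `ref`, `alt`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  }
  bad <- is.na(fix$ALT) | grepl("<", fix$ALT, fixed = TRUE) |
    grepl("[", fix$ALT, fixed = TRUE) | grepl(",", fix$ALT, fixed = TRUE)
  if (any(bad)) {
    stop(path, ": symbolic/breakend or multi-allelic ALT in record(s) ",
         paste(head(which(bad), 5), collapse = ", "),
         "; only explicit single-allele records are supported")
  }
  data.frame(contig = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT, stringsAsFactors = FALSE)
}

#' Write variants as VCF 4.2
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt`.
#' @param contig_lengths named vector for the `##contig` header lines.
#' @param path output file.
#' @param seed optional seed echoed into the header as provenance.
#' @export
write_vcf <- function(variants, contig_lengths, path, seed = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=haplodiff_",
                  as.character(utils::packageVersion("haplodiff"))),
           if (!is.null(seed)) paste0("##haplodiffSeed=", seed),
           sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                   as.integer(contig_lengths)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants) > 0) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", variants$contig,
            as.integer(variants$pos), variants$ref, variants$alt)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

## -------------------------------------------------------------------- TSV

#' Read / write tab-separated tables with provenance comments
#'
#' Writes a header row plus leading `#` provenance lines; reading skips
#' comments.
#'
#' @param x data.frame.
#' @param path file path.
#' @param seed optional seed echoed as provenance.
#' @return `read_tsv` returns a data.frame.
#' @export
write_tsv <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

## ------------------------------------------------------------ world files

#' Write a simulated world to a directory
#'
#' Emits, per haplotype, the genome FASTA, gene models (GFF3) and protein
#' FASTA; the truth variant set as VCF (haplotype A as reference) and TSV
#' (with class/location labels); and the remaining truth tables as TSV.
#'
#' @param world the list returned by [simulate_diploid()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- world$truth
  seed <- tr$config$seed
  for (hap in c("a", "b")) {
    g <- world[[paste0("genome_", hap)]]
    write_fasta(g$seqs, file.path(dir, paste0("hap", toupper(hap), ".fasta")))
    write_gff3(g$genes, g$exons,
               file.path(dir, paste0("hap", toupper(hap), ".gff3")))
    write_fasta(g$proteins,
                file.path(dir, paste0("hap", toupper(hap), "_proteins.fasta")),
                type = "AA")
  }
  write_vcf(tr$variants[, c("contig", "pos", "ref", "alt")],
            tr$contig_len_a, file.path(dir, "variants.vcf"), seed = seed)
  write_tsv(tr$variants, file.path(dir, "truth_variants.tsv"), seed)
  write_tsv(tr$allelic_map, file.path(dir, "truth_allelic_map.tsv"), seed)
  write_tsv(tr$family_members, file.path(dir, "truth_family_members.tsv"), seed)
  hs <- rbind(
    data.frame(haplotype = "A", gene_id = tr$hap_specific_ids$A,
               stringsAsFactors = FALSE),
    data.frame(haplotype = "B", gene_id = tr$hap_specific_ids$B,
               stringsAsFactors = FALSE))
  write_tsv(hs, file.path(dir, "truth_hap_specific.tsv"), seed)
  write_tsv(tr$units, file.path(dir, "truth_units.tsv"), seed)
  em <- data.frame(unit = rownames(tr$expression_means), tr$expression_means,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(em, file.path(dir, "truth_expression_means.tsv"), seed)
  write_tsv(tr$ase_loci, file.path(dir, "truth_ase_loci.tsv"), seed)
  write_tsv(tr$amplicons, file.path(dir, "truth_amplicons.tsv"), seed)
  invisible(dir)
}

#' Read a simulated world back from a directory
#'
#' @param dir directory written by [write_world()].
#' @return list with `genome_a`, `genome_b` (`HaplotypeGenome`-shaped),
#'   `variants`, and the truth tables.
#' @export
read_world <- function(dir) {
  read_genome <- function(hap) {
    seqs <- read_fasta(file.path(dir, paste0("hap", hap, ".fasta")))
    ann <- read_gff3(file.path(dir, paste0("hap", hap, ".gff3")))
    prot <- read_fasta(file.path(dir, paste0("hap", hap, "_proteins.fasta")),
                       type = "AA")
    structure(list(haplotype = hap, seqs = seqs, genes = ann$genes,
                   exons = ann$exons, proteins = prot),
              class = "HaplotypeGenome")
  }
  list(genome_a = read_genome("A"), genome_b = read_genome("B"),
       variants = read_vcf(file.path(dir, "variants.vcf")),
       truth_variants = read_tsv(file.path(dir, "truth_variants.tsv")),
       allelic_map = read_tsv(file.path(dir, "truth_allelic_map.tsv")),
       family_members = read_tsv(file.path(dir, "truth_family_members.tsv")),
       hap_specific = read_tsv(file.path(dir, "truth_hap_specific.tsv")),
       units = read_tsv(file.path(dir, "truth_units.tsv")),
       ase_loci = read_tsv(file.path(dir, "truth_ase_loci.tsv")),
       amplicons = read_tsv(file.path(dir, "truth_amplicons.tsv")))
}

#' Write / read expression counts and allelic depths
#'
#' Counts go out as a genes-by-samples TSV plus a sample-metadata sidecar;
#' allelic depths as a long-format table (pair, locus, allele, sample,
#' depth) plus per-replicate library sizes.
#'
#' @param ex the list returned by [simulate_expression()].
#' @param dir output directory.
#' @export
write_expression <- function(ex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- data.frame(gene_id = rownames(ex$counts$counts), ex$counts$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(cm, file.path(dir, "counts.tsv"))
  meta <- ex$counts$samples
  meta$gene_length <- NULL
  write_tsv(meta, file.path(dir, "samples.tsv"))
  write_tsv(data.frame(gene_id = names(ex$counts$gene_lengths),
                       length = as.integer(ex$counts$gene_lengths),
                       stringsAsFactors = FALSE),
            file.path(dir, "gene_lengths.tsv"))
  d <- ex$allelic_depth$depths
  long <- rbind(
    data.frame(pair_id = d$pair_id, locus = d$locus, allele = "A",
               sample = d$sample, condition = d$condition,
               replicate = d$replicate, depth = d$depth_a,
               stringsAsFactors = FALSE),
    data.frame(pair_id = d$pair_id, locus = d$locus, allele = "B",
               sample = d$sample, condition = d$condition,
               replicate = d$replicate, depth = d$depth_b,
               stringsAsFactors = FALSE))
  write_tsv(long, file.path(dir, "allelic_depth.tsv"))
  write_tsv(ex$allelic_depth$lib_sizes, file.path(dir, "lib_sizes.tsv"))
  invisible(dir)
}

#' @rdname write_expression
#' @export
read_expression <- function(dir) {
  cm <- read_tsv(file.path(dir, "counts.tsv"))
  counts <- as.matrix(cm[, -1, drop = FALSE])
  rownames(counts) <- cm$gene_id
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  gl <- read_tsv(file.path(dir, "gene_lengths.tsv"))
  counts_obj <- structure(list(counts = counts, samples = samples,
                               gene_lengths = setNames(gl$length, gl$gene_id)),
                          class = "CountMatrix")
  long <- read_tsv(file.path(dir, "allelic_depth.tsv"))
  a <- long[long$allele == "A", ]
  b <- long[long$allele == "B", ]
  key <- function(x) paste(x$pair_id, x$locus, x$sample)
  b <- b[match(key(a), key(b)), ]
  depths <- data.frame(pair_id = a$pair_id, locus = a$locus,
                       sample = a$sample, condition = a$condition,
                       replicate = a$replicate, depth_a = a$depth,
                       depth_b = b$depth, stringsAsFactors = FALSE)
  depth_obj <- structure(list(depths = depths,
                              lib_sizes = read_tsv(file.path(dir, "lib_sizes.tsv"))),
                         class = "AllelicDepthTable")
  list(counts = counts_obj, allelic_depth = depth_obj)
}

#' @rdname write_expression
#' @export
read_allelic_depth <- function(dir) read_expression(dir)$allelic_depth
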