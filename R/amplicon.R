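## Degenerate-primer in-silico PCR and clone-to-copy assignment.

#' Does an IUPAC code match a concrete base?
#'
#' @param code single IUPAC nucleotide character (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @param base one of A, C, G, T.
#' @return logical. Vectorized over both arguments.
#' @export
#' @examples
#' iupac_match("M", "A")  # TRUE:  M = A or C
#' iupac_match("M", "G")  # FALSE
iupac_match <- function(code, base) {
  code <- toupper(code); base <- toupper(base)
  if (any(!code %in% names(Biostrings::IUPAC_CODE_MAP))) {
    stop("invalid IUPAC code(s): ",
         paste(unique(code[!code %in% names(Biostrings::IUPAC_CODE_MAP)]),
               collapse = ", "))
  }
  if (any(!base %in% DNA_BASES)) {
    stop("base must be one of A, C, G, T")
  }
  mapply(function(cd, bs) {
    grepl(bs, Biostrings::IUPAC_CODE_MAP[[cd]], fixed = TRUE)
  }, code, base, USE.NAMES = FALSE)
}

check_primer <- function(x, arg) {
  if (!nzchar(x)) stop("empty primer sequence in '", arg, "'")
  ch <- strsplit(toupper(x), "")[[1]]
  bad <- !ch %in% names(Biostrings::IUPAC_CODE_MAP)
  if (any(bad)) {
    stop("invalid IUPAC code '", ch[which(bad)[1]], "' at position ",
         which(bad)[1], " of primer '", arg, "'")
  }
  toupper(x)
}

## all start positions where a degenerate primer matches the template exactly
## (ambiguity only on the primer side)
primer_sites <- function(primer, template) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(primer), template,
                                fixed = "subject")
  IRanges::start(m)
}

#' In-silico PCR with degenerate primers
#'
#' Finds every product where the forward primer matches the plus strand and
#' the reverse primer matches the minus strand downstream within
#' `max_product` bases, plus the symmetric orientation (reverse primer on
#' the plus strand). Matching is exact at non-degenerate positions;
#' degenerate positions match their IUPAC expansion. Product length counts
#' both primer footprints.
#'
#' @param template nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @param fwd,rev primer sequences over the IUPAC alphabet.
#' @param max_product maximum product length in bases.
#' @param template_id identifier echoed into the result.
#' @return data.frame with `template`, `start`, `end`, `length`,
#'   `orientation` (`"forward"` if the forward primer is on the plus
#'   strand), and `sequence` (plus-strand product), sorted by `start`.
#'   No binding site gives zero rows.
#' @export
insilico_pcr <- function(template, fwd, rev, max_product = 5000,
                         template_id = "template") {
  fwd <- check_primer(fwd, "fwd"); rev <- check_primer(rev, "rev")
  if (max_product <= nchar(fwd) + nchar(rev)) {
    stop("max_product must exceed the combined primer length")
  }
  tmpl <- if (is(template, "DNAString")) template else
    Biostrings::DNAString(toupper(as.character(template)))

  find_products <- function(p5, p3, orientation) {
    s5 <- primer_sites(p5, tmpl)
    s3 <- primer_sites(Biostrings::reverseComplement(Biostrings::DNAString(p3)),
                       tmpl)
    rows <- list()
    for (a in s5) {
      for (b in s3) {
        start <- a; end <- b + nchar(p3) - 1L
        if (b <= a + nchar(p5) - 1L) next      # primers must not overlap
        len <- end - start + 1L
        if (len > max_product) next
        rows[[length(rows) + 1]] <- data.frame(
          template = template_id, start = start, end = end, length = len,
          orientation = orientation,
          sequence = as.character(Biostrings::subseq(tmpl, start, end)),
          stringsAsFactors = FALSE)
      }
    }
    rows
  }

  rows <- c(find_products(fwd, rev, "forward"),
            find_products(rev, fwd, "reverse"))
  if (length(rows) == 0) {
    return(data.frame(template = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      orientation = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- unique(out[order(out$start, out$end, out$orientation), ])
  rownames(out) <- NULL
  out
}

#' Run in-silico PCR over a set of templates
#'
#' @param templates [Biostrings::DNAStringSet] or named character vector.
#' @inheritParams insilico_pcr
#' @return row-bound [insilico_pcr()] results with the template names.
#' @export
insilico_pcr_set <- function(templates, fwd, rev, max_product = 5000) {
  if (!is(templates, "DNAStringSet")) {
    templates <- Biostrings::DNAStringSet(templates)
  }
  do.call(rbind, lapply(seq_along(templates), function(i) {
    insilico_pcr(templates[[i]], fwd, rev, max_product,
                 template_id = names(templates)[i] %||% as.character(i))
  }))
}

## global DNA alignment identity (matches over alignment columns)
dna_identity <- function(a, refs) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(refs), Biostrings::DNAString(a), type = "global",
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(aln) / nchar(aln)
}

#' Assign clone sequences to reference amplicon copies
#'
#' Each clone is assigned to the reference with the highest global-alignment
#' identity; when the top two identities tie within `tie_tol` the clone is
#' `ambiguous` and contributes to no tally entry.
#'
#' @param clones named character vector or [Biostrings::DNAStringSet] of
#'   clone sequences.
#' @param references named character vector or [Biostrings::DNAStringSet] of
#'   per-copy reference amplicons (both haplotypes).
#' @param tie_tol identity tie tolerance (default 1e-6).
#' @return list with `assignments` (data.frame `clone`, `reference`,
#'   `identity`, `status`) and `tally` (integer vector over the references,
#'   in input order).
#' @export
assign_clones <- function(clones, references, tie_tol = 1e-6) {
  cl <- if (is(clones, "DNAStringSet")) setNames(as.character(clones),
                                                 names(clones)) else clones
  rf <- if (is(references, "DNAStringSet")) setNames(as.character(references),
                                                     names(references)) else references
  stopifnot(length(rf) >= 1)
  if (any(!nzchar(cl))) stop("empty clone sequence")
  if (is.null(names(cl))) names(cl) <- paste0("clone_", seq_along(cl))
  rows <- lapply(seq_along(cl), function(i) {
    ident <- dna_identity(cl[[i]], rf)
    ord <- order(-ident)
    tie <- length(ident) > 1 && ident[ord[1]] - ident[ord[2]] <= tie_tol
    data.frame(clone = names(cl)[i],
               reference = if (tie) NA_character_ else names(rf)[ord[1]],
               identity = ident[ord[1]],
               status = if (tie) "ambiguous" else "assigned",
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  tally <- setNames(integer(length(rf)), names(rf))
  hit <- table(assignments$reference[assignments$status == "assigned"])
  tally[names(hit)] <- as.integer(hit)
  list(assignments = assignments, tally = tally)
}
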