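## Internal sequence helpers. All sequences are plain character scalars
## internally; Biostrings objects are built at module boundaries.

DNA_BASES <- c("A", "C", "G", "T")

SENSE_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
STOP_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

## codons whose third position is 4-fold degenerate (any base keeps the aa)
FOURFOLD_PREFIXES <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")

AA_ALPHABET20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' @noRd
random_dna <- function(n, gc_content = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2, (1 - gc_content) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

## random open reading frame: ATG + (n_codons - 2) sense codons + stop
#' @noRd
random_orf <- function(n_codons) {
  stopifnot(n_codons >= 3)
  body <- sample(SENSE_CODONS, n_codons - 2, replace = TRUE)
  paste(c("ATG", body, sample(STOP_CODONS, 1)), collapse = "")
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
comp_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

## translate a CDS (character), dropping the trailing stop
#' @noRd
translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  sub("\\*$", "", aa)
}

#' @noRd
codons_of <- function(cds) {
  substring(cds, seq(1, nchar(cds) - 2, by = 3), seq(3, nchar(cds), by = 3))
}

## run expr with a private RNG stream, restoring the caller's afterwards
#' @noRd
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' @noRd
substr_replace <- function(x, at, value) {
  paste0(substr(x, 1, at - 1), value, substr(x, at + nchar(value), nchar(x)))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
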