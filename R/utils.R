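#' @keywords internal
"_PACKAGE"

# IUPAC nucleotide alphabet; strict mode restricts to the unambiguous set + N
.IUPAC <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.STRICT <- c("A", "C", "G", "T", "N")

#' Reverse-complement nucleotide strings
#'
#' Vectorised over `x`; ambiguity codes are complemented per IUPAC.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Draw random nucleotide sequences
#'
#' i.i.d. uniform over A/C/G/T; uses the current RNG stream.
#'
#' @param n number of sequences.
#' @param len length (scalar or vector recycled to `n`).
#' @return character vector of length `n`.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# split a sequence into single characters
.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# log to stderr with a consistent prefix; suppressible via option
.log <- function(fmt, ...) {
  if (isTRUE(getOption("phagenet.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(paste0("[phagenet] ", fmt), ...))
}

# deterministic seed scoped to a block, restoring RNG state afterwards
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
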