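## Internal helpers shared across modules.

PAD <- "-"
NUCS <- c("A", "C", "G", "U")
SAMPLE_LEN <- 25L

## Fixed alphabetical order of the six canonical pair types (microRNA base
## first). All feature layouts and lookup tables index pair types in this
## order.
PAIR_TYPES <- c("AU", "CG", "GC", "GU", "UA", "UG")

#' Split a sequence string into single characters
#' @noRd
seqChars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1]]
}

#' Check a padded 25-mer over {A,C,G,U,-}; returns position (1-based) of the
#' first bad symbol or 0 when clean.
#' @noRd
firstBadSymbol <- function(x) {
  ch <- seqChars(x)
  bad <- which(!(ch %in% c(NUCS, PAD)))
  if (length(bad)) bad[1] else 0L
}

#' Stop with a helpful message when a sequence is malformed
#' @noRd
checkSeq25 <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(x) != SAMPLE_LEN)
    stop(what, " must have exactly ", SAMPLE_LEN, " symbols, got ", nchar(x),
         call. = FALSE)
  bad <- firstBadSymbol(x)
  if (bad > 0L)
    stop(what, " has invalid symbol '", substr(x, bad, bad),
         "' at position ", bad - 1L, " (0-based)", call. = FALSE)
  invisible(x)
}

#' Right-pad a sequence to 25 symbols with the pad character
#' @noRd
padTo25 <- function(x) {
  n <- nchar(x)
  if (n > SAMPLE_LEN)
    stop("sequence longer than ", SAMPLE_LEN, " nt: ", n, call. = FALSE)
  paste0(x, strrep(PAD, SAMPLE_LEN - n))
}

#' Length of a padded sequence before its pad suffix
#' @noRd
unpaddedLength <- function(x) {
  ch <- seqChars(x)
  pads <- ch == PAD
  if (!any(pads)) return(length(ch))
  min(which(pads)) - 1L
}

#' Pads only allowed as a suffix
#' @noRd
padIsSuffix <- function(x) {
  ch <- seqChars(x)
  pads <- which(ch == PAD)
  length(pads) == 0L || all(pads == seq(min(pads), length(ch)))
}

#' Normalize raw RNA/DNA text to the internal alphabet (uppercase, T -> U)
#' @noRd
normalizeSeq <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

#' Derive a stream-specific 32-bit seed from a base seed
#' @noRd
deriveSeed <- function(seed, stream) {
  (as.integer(seed) %% 1009L) * 2017L + as.integer(stream)
}
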