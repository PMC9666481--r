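#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the alphabet `A,C,G,T,N`
#' (case-insensitive, case preserved as upper case).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- toupper(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a DNA string into a character vector of single bases
seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

# strip digit-grouping commas and stray internal spaces from printed numbers
# (feature tables as printed contain artifacts like "1, 141")
clean_int <- function(x) {
  out <- suppressWarnings(as.integer(gsub("[, ]", "", as.character(x))))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))

# random DNA with a given A+T fraction; A/T and G/C equiprobable within class
random_dna <- function(n, at = 0.5) {
  if (n <= 0) return("")
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
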