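# Internal helpers shared across modules.

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string over {A,C,G,T,N}.
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Round half away from zero
#'
#' The print convention of the reference tables (base \code{round()} is
#' banker's rounding).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# split a string into a character vector of single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# all k-mer start positions (0-based) and strings of a sequence
kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# 0-based half-open interval length
iv_len <- function(iv) iv[2L] - iv[1L]

# translate one or more DNA codons with the standard code; codons with N
# translate to NA
translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[codon])
  out[is.na(out) & !is.na(codon)] <- NA_character_
  out
}

# stop codons under the standard code
STOP_CODONS <- c("TAA", "TAG", "TGA")

# hydropathy classes: the minimal two-class table consistent with every
# stated transition in the coconut editing summary (Y hydrophobic,
# S/T/G/H hydrophilic)
HYDROPHOBIC <- c("A", "V", "L", "I", "P", "F", "M", "W", "Y", "C")
HYDROPHILIC <- c("R", "N", "D", "E", "Q", "H", "K", "S", "T", "G")

`%||%` <- function(a, b) if (is.null(a)) b else a
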