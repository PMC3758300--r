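#' Construct a plastome sequence object
#'
#' A light container for a plastid genome: an identifier, an uppercase DNA
#' string over \{A,C,G,T,N\}, and a circular/linear topology flag.  Circular
#' genomes index positions modulo their length.
#'
#' @param sequence single DNA string; lowercase accepted, U mapped to T.
#' @param id sequence label.
#' @param circular logical topology flag (plastomes are circular molecules).
#' @return an object of class \code{plastome}.
#' @export
plastome <- function(sequence, id = "plastome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  s <- chartr("U", "T", s)
  if (nchar(s) == 0L) stop("empty sequence")
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d (alphabet is A,C,G,T,N)",
                 substr(s, bad, bad), bad))
  }
  structure(list(id = as.character(id), seq = s, circular = isTRUE(circular)),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s bp, %s\n", x$id,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
length.plastome <- function(x) nchar(x$seq)

#' Read a genome from a FASTA file
#'
#' Returns the first record, uppercased, with U mapped to T.
#'
#' @param path FASTA file with at least one record.
#' @param circular topology flag for the returned object.
#' @return a \code{\link{plastome}}.
#' @export
read_genome <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  plastome(as.character(set[[1L]]), id = names(set)[1L], circular = circular)
}

#' Write a plastome to FASTA
#' @param x a \code{plastome}.
#' @param path output file.
#' @export
write_genome <- function(x, path) {
  stopifnot(inherits(x, "plastome"))
  set <- Biostrings::DNAStringSet(x$seq)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Extract a subsequence by 0-based half-open window
#'
#' Circular genomes allow the window to wrap the origin.
#'
#' @param x a \code{plastome}.
#' @param start,end 0-based half-open bounds; \code{end} may exceed the
#'   genome length on circular genomes (wraps).
#' @return character scalar.
#' @export
plastome_subseq <- function(x, start, end) {
  n <- nchar(x$seq)
  stopifnot(start >= 0L, end >= start)
  if (end <= n) return(substr(x$seq, start + 1L, end))
  if (!x$circular) stop("window [", start, ",", end, ") exceeds linear genome length ", n)
  if (end - start > n) stop("window longer than genome")
  paste0(substr(x$seq, start + 1L, n), substr(x$seq, 1L, end - n))
}

#' GC content of a genome or window
#'
#' Fraction (G+C)/(A+C+G+T); N is excluded from the denominator.
#'
#' @param x a \code{plastome}.
#' @param window optional 0-based half-open \code{c(start, end)}.
#' @return fraction in [0, 1].
#' @export
gc_content <- function(x, window = NULL) {
  s <- if (is.null(window)) x$seq else plastome_subseq(x, window[1L], window[2L])
  if (nchar(s) == 0L) stop("GC content undefined on a zero-length window")
  f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0L) stop("GC content undefined: window contains no unambiguous bases")
  unname((f[["C"]] + f[["G"]]) / tot)
}

#' AT content of a genome or window
#' @inheritParams gc_content
#' @return fraction in [0, 1].
#' @export
at_content <- function(x, window = NULL) 1 - gc_content(x, window)

#' Flag a gene copy as truncated relative to a reference length
#'
#' Helper for pseudogene assessment at IR junctions: a duplicated gene copy
#' shortened by inverted-repeat contraction (e.g. a 174-bp rps19-like
#' fragment against the regular 279-bp gene) is flagged.  This is a helper,
#' not an automatic reclassifier: annotations marked pseudogene are taken as
#' given elsewhere.
#'
#' @param candidate_length total exon length of the candidate copy (bp), or
#'   a one-gene annotation table from which it is computed.
#' @param reference_length length of the intact gene (bp), > 0.
#' @param threshold flag when candidate < threshold * reference
#'   (default 1, i.e. any truncation flags).
#' @return logical.
#' @export
flag_truncated_copy <- function(candidate_length, reference_length, threshold = 1) {
  if (inherits(candidate_length, "gene_annotation")) {
    candidate_length <- sum(candidate_length$end - candidate_length$start)
  }
  stopifnot(reference_length > 0)
  candidate_length < threshold * reference_length
}
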