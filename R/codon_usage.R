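# Codon counting and relative synonymous codon usage (RSCU).
#
# RSCU follows the standard definition: count(codon) * family_size /
# family_total, with family sizes 1/2/3/4/6 under the standard genetic
# code.  Stop codons are excluded from the table.

# synonymous family per codon under the standard code (stops removed)
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  fam_size <- table(gc)
  list(aa = gc, n_syn = setNames(as.integer(fam_size), names(fam_size)))
}

#' Extract codons per protein-coding gene
#'
#' Splices exons in transcription order (reverse-complementing minus-strand
#' genes), splits into codons, and skips pseudogenes and RNA genes.  A
#' concatenated CDS whose length is not a multiple of 3 warns and drops the
#' trailing remainder; codons containing N are dropped with a warning.
#'
#' @param x a \code{\link{plastome}}.
#' @param ann a \code{gene_annotation}.
#' @return named list (gene key) of character vectors of codons.
#' @export
extract_cds_codons <- function(x, ann) {
  gs <- gene_spans(ann)
  keep <- gs$key[gs$kind == "protein_coding"]
  out <- list()
  for (k in keep) {
    idx <- which(paste0(ann$gene, ifelse(is.na(ann$copy_tag), "",
                                         paste0("|", ann$copy_tag))) == k)
    ex <- ann[idx, , drop = FALSE]
    ex <- ex[order(ex$exon_rank), , drop = FALSE]
    pieces <- vapply(seq_len(nrow(ex)), function(i)
      plastome_subseq(x, ex$start[i], ex$end[i]), character(1L))
    if (ex$strand[1L] == "-") pieces <- vapply(pieces, revcomp, character(1L))
    cds <- paste(pieces, collapse = "")
    nc <- nchar(cds)
    if (nc %% 3L != 0L) {
      warning(sprintf("CDS of %s has length %d, not a multiple of 3; trailing %d nt dropped",
                      k, nc, nc %% 3L))
      cds <- substr(cds, 1L, nc - nc %% 3L)
    }
    codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
    has_n <- grepl("N", codons, fixed = TRUE)
    if (any(has_n)) {
      warning(sprintf("%d codon(s) of %s contain N and were dropped", sum(has_n), k))
      codons <- codons[!has_n]
    }
    out[[k]] <- codons
  }
  out
}

#' Count codons into a codon usage table
#'
#' Aggregates over all genes; stop codons are excluded from the table but
#' internal stops only trigger a warning (annotation-level irregularities
#' such as ACG/GTG start codons are tolerated at the counting stage).
#'
#' @param codons list of per-gene codon vectors (or a single character
#'   vector), uppercase DNA triplets.
#' @return a \code{codon_usage} data.frame with columns codon, aa, count
#'   over the 61 sense codons; attributes \code{aa_totals} and
#'   \code{source_gene_count}.
#' @export
count_codons <- function(codons) {
  if (is.character(codons)) codons <- list(codons)
  all_codons <- unlist(codons, use.names = FALSE)
  if (length(all_codons) && any(nchar(all_codons) != 3L)) {
    stop("input error: non-triplet codon token(s): ",
         paste(head(unique(all_codons[nchar(all_codons) != 3L]), 3L), collapse = ", "))
  }
  n_stop_internal <- sum(all_codons %in% STOP_CODONS &
                           !seq_along(all_codons) %in% cumsum(lengths(codons)))
  if (n_stop_internal > 0L) {
    warning(n_stop_internal, " internal stop codon(s) encountered; counting continues")
  }
  fam <- codon_families()
  sense <- sort(names(fam$aa))
  counts <- table(factor(all_codons[!all_codons %in% STOP_CODONS], levels = sense))
  tab <- data.frame(codon = sense, aa = unname(fam$aa[sense]),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  aa_tot <- tapply(tab$count, tab$aa, sum)
  attr(tab, "aa_totals") <- setNames(as.integer(aa_tot), names(aa_tot))
  attr(tab, "source_gene_count") <- length(codons)
  class(tab) <- c("codon_usage", "data.frame")
  tab
}

#' Fill in RSCU values
#'
#' RSCU(codon) = count * family_size / family_total.  Families with a zero
#' total get NA (undefined, not 0); single-codon families (Met, Trp) get 1
#' when counted.  Values are kept at full precision; the printed convention
#' is 2 decimals, round half away from zero (see \code{\link{round_half_up}}).
#'
#' @param tab a \code{codon_usage} table from \code{\link{count_codons}}.
#' @return the table with an \code{rscu} column added.
#' @export
rscu <- function(tab) {
  stopifnot(inherits(tab, "codon_usage"))
  fam <- codon_families()
  tot <- as.vector(tapply(tab$count, tab$aa, sum)[tab$aa])
  nsyn <- as.vector(fam$n_syn[tab$aa])
  tab$rscu <- ifelse(tot > 0, tab$count * nsyn / tot, NA_real_)
  tab
}

#' A/T share at synonymous third positions
#'
#' Ratio of counts of codons ending in A or T to all counts, over
#' degenerate families only (single-codon families Met and Trp excluded).
#'
#' @param tab a \code{codon_usage} table.
#' @return fraction in [0, 1].
#' @export
third_position_at_bias <- function(tab) {
  stopifnot(inherits(tab, "codon_usage"))
  fam <- codon_families()
  deg <- tab[fam$n_syn[tab$aa] > 1L, , drop = FALSE]
  tot <- sum(deg$count)
  if (tot == 0L) return(NA_real_)
  sum(deg$count[substr(deg$codon, 3L, 3L) %in% c("A", "T")]) / tot
}
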