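# C-to-U RNA editing: conservation-based prediction from homolog protein
# panels and summary statistics of observed editing tables.
#
# A candidate site is a genomic C in a coding-strand codon; its edited
# codon substitutes T at that position.  The support score is the fraction
# of homolog references whose residue at that codon equals the edited
# translation, among references matching either the edited or the unedited
# translation; sites scoring at least the cutoff (default 0.8, inclusive)
# are predicted.  Silent candidates score 0.

#' Construct a homolog panel
#'
#' Per-codon aligned residues from a set of reference proteins for one
#' target gene.  Gaps are "-"; column index maps to target codon index.
#'
#' @param target_gene gene name.
#' @param residues character matrix, rows = references, columns = codons.
#' @return an object of class \code{homolog_panel}.
#' @export
homolog_panel <- function(target_gene, residues) {
  stopifnot(is.matrix(residues), is.character(residues))
  structure(list(target_gene = target_gene, residues = residues,
                 n_refs = nrow(residues)),
            class = "homolog_panel")
}

#' @export
print.homolog_panel <- function(x, ...) {
  cat(sprintf("<homolog_panel> %s: %d references x %d codons\n",
              x$target_gene, x$n_refs, ncol(x$residues)))
  invisible(x)
}

#' Read a homolog panel from aligned FASTA
#'
#' The first record is the target CDS translation (or target gene, used
#' only for the label); remaining records are the reference proteins.
#'
#' @param path aligned protein FASTA (equal lengths).
#' @param target_gene label; defaults to the first record name.
#' @return a \code{homolog_panel} of the reference rows.
#' @export
read_homolog_panel <- function(path, target_gene = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 2L) stop("panel FASTA needs a target plus >= 1 reference")
  if (length(unique(Biostrings::width(set))) != 1L) {
    stop("alignment error: panel sequences have unequal lengths")
  }
  m <- do.call(rbind, strsplit(as.character(set[-1L]), ""))
  rownames(m) <- names(set)[-1L]
  homolog_panel(target_gene %||% names(set)[1L], m)
}

#' Support score of one candidate editing site
#'
#' @param codon genomic codon (DNA triplet) containing the candidate C.
#' @param codon_pos position of the C within the codon (1, 2 or 3).
#' @param column character vector of reference residues at this codon
#'   (one per reference; gaps "-" never match).
#' @return score in [0, 1]: matches(edited) / matches(edited or unedited);
#'   0 when no reference matches either, and 0 for silent candidates.
#' @export
editing_score <- function(codon, codon_pos, column) {
  stopifnot(nchar(codon) == 3L, codon_pos %in% 1:3)
  if (substr(codon, codon_pos, codon_pos) != "C") {
    stop("not a candidate: position ", codon_pos, " of codon ", codon, " is not C")
  }
  edited <- codon
  substr(edited, codon_pos, codon_pos) <- "T"
  aa_from <- translate_codon(codon)
  aa_to <- translate_codon(edited)
  if (is.na(aa_to) || aa_to == "*" || identical(aa_from, aa_to)) return(0)
  n_to <- sum(column == aa_to, na.rm = TRUE)
  n_from <- sum(column == aa_from, na.rm = TRUE)
  if (n_to + n_from == 0L) return(0)
  n_to / (n_to + n_from)
}

#' Predict C-to-U editing sites in a CDS
#'
#' Evaluates every C on the coding strand against the homolog panel and
#' returns sites with support at or above the cutoff (inclusive), in CDS
#' position order.
#'
#' @param cds character vector of codons, or a single DNA string whose
#'   length is a multiple of 3.
#' @param panel a \code{\link{homolog_panel}} with one column per codon.
#' @param cutoff support threshold in (0, 1]; default 0.8.
#' @param gene gene label for the output (defaults to the panel's).
#' @return data.frame with columns gene, cds_position (1-based nucleotide),
#'   codon_index, codon_position, codon_genomic, codon_edited, aa_from,
#'   aa_to, score, predicted.
#' @export
predict_editing_sites <- function(cds, panel, cutoff = 0.8, gene = NULL) {
  stopifnot(inherits(panel, "homolog_panel"), cutoff > 0, cutoff <= 1)
  if (length(cds) == 1L && nchar(cds[1L]) > 3L) {
    s <- toupper(cds)
    if (nchar(s) %% 3L != 0L) stop("CDS length not a multiple of 3")
    cds <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  }
  if (length(cds) != ncol(panel$residues)) {
    stop(sprintf("alignment error: CDS has %d codons but panel has %d columns",
                 length(cds), ncol(panel$residues)))
  }
  rows <- list()
  for (ci in seq_along(cds)) {
    codon <- cds[ci]
    for (cp in which(chars(codon) == "C")) {
      sc <- editing_score(codon, cp, panel$residues[, ci])
      if (sc >= cutoff) {
        edited <- codon
        substr(edited, cp, cp) <- "T"
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene %||% panel$target_gene,
          cds_position = (ci - 1L) * 3L + cp, codon_index = ci,
          codon_position = cp, codon_genomic = codon, codon_edited = edited,
          aa_from = translate_codon(codon), aa_to = translate_codon(edited),
          score = sc, predicted = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), cds_position = integer(0),
                      codon_index = integer(0), codon_position = integer(0),
                      codon_genomic = character(0), codon_edited = character(0),
                      aa_from = character(0), aa_to = character(0),
                      score = numeric(0), predicted = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$cds_position), , drop = FALSE]
}

#' Classify an amino-acid change by hydropathy
#'
#' Two-class table: hydrophobic = \{A,V,L,I,P,F,M,W,Y,C\}, hydrophilic =
#' \{R,N,D,E,Q,H,K,S,T,G\} (the minimal assignment consistent with the
#' reference editing summaries, e.g. Y hydrophobic, S/T/H hydrophilic).
#'
#' @param from,to single-letter residues (vectorized).
#' @return character vector with values like "hydrophilic->hydrophobic".
#' @export
classify_property_change <- function(from, to) {
  cls <- function(a) {
    out <- ifelse(a %in% HYDROPHOBIC, "hydrophobic",
                  ifelse(a %in% HYDROPHILIC, "hydrophilic", NA_character_))
    if (anyNA(out)) {
      stop("unknown residue(s): ", paste(unique(a[is.na(out)]), collapse = ", "))
    }
    out
  }
  paste0(cls(from), "->", cls(to))
}

#' Summarize an RNA editing site table
#'
#' Computes the standard editing summary over sites whose RT-PCR state is
#' in \code{confirmed_states} (partial editing counts as confirmed by
#' default; only then do published per-position tallies reproduce).
#' Codon-position and amino-acid-change fields are taken as recorded in the
#' table, not re-derived from the codon strings (published rows can be
#' internally inconsistent; see \code{\link{validate_editing_rows}}).
#'
#' @param sites data.frame with columns gene, cds_position, codon_genomic,
#'   codon_edited, codon_position, aa_from, aa_to, predicted (logical),
#'   rtpcr (one of "edited", "partial", "unedited", "untested").
#' @param confirmed_states rtpcr states treated as confirmed.
#' @return a list of class \code{editing_summary}: total, by_codon_position
#'   (counts and percentages to 2 dp), c_to_u_fraction, silent_count,
#'   predicted_and_confirmed, unpredicted_confirmed, property_transitions.
#' @export
summarize_editing <- function(sites, confirmed_states = c("edited", "partial")) {
  conf <- sites[sites$rtpcr %in% confirmed_states, , drop = FALSE]
  total <- nrow(conf)
  pos_counts <- vapply(1:3, function(p) sum(conf$codon_position == p), 0L)
  names(pos_counts) <- c("pos1", "pos2", "pos3")
  pos_pct <- if (total > 0) round_half_up(100 * pos_counts / total, 2L) else pos_counts * 0
  is_c_to_u <- function(gcodon, ecodon, cpos) {
    mapply(function(g, e, p) {
      substr(g, p, p) == "C" && substr(e, p, p) == "T" &&
        sum(chars(g) != chars(e)) == 1L
    }, gcodon, ecodon, cpos, USE.NAMES = FALSE)
  }
  ctu <- if (total > 0)
    sum(is_c_to_u(conf$codon_genomic, conf$codon_edited, conf$codon_position)) / total
  else 0
  silent <- sum(conf$aa_from == conf$aa_to)
  nonsilent <- conf[conf$aa_from != conf$aa_to, , drop = FALSE]
  trans <- if (nrow(nonsilent)) {
    table(classify_property_change(nonsilent$aa_from, nonsilent$aa_to))
  } else {
    table(character(0))
  }
  all_trans <- c("hydrophilic->hydrophobic", "hydrophobic->hydrophobic",
                 "hydrophilic->hydrophilic", "hydrophobic->hydrophilic")
  transitions <- setNames(integer(length(all_trans)), all_trans)
  transitions[names(trans)] <- as.integer(trans)
  structure(list(
    total = total,
    by_codon_position = list(counts = pos_counts, percent = pos_pct),
    c_to_u_fraction = ctu,
    silent_count = silent,
    predicted_and_confirmed = sum(conf$predicted),
    unpredicted_confirmed = sum(!conf$predicted),
    property_transitions = transitions
  ), class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("<editing_summary> %d confirmed sites; codon position 1/2/3 = %d/%d/%d (%.2f%%/%.2f%%/%.2f%%)\n",
              x$total, x$by_codon_position$counts[1L], x$by_codon_position$counts[2L],
              x$by_codon_position$counts[3L], x$by_codon_position$percent[1L],
              x$by_codon_position$percent[2L], x$by_codon_position$percent[3L]))
  cat(sprintf("  C-to-U %.0f%%, silent %d, predicted-and-confirmed %d, confirmed-unpredicted %d\n",
              100 * x$c_to_u_fraction, x$silent_count, x$predicted_and_confirmed,
              x$unpredicted_confirmed))
  tt <- x$property_transitions
  cat(sprintf("  transitions: %s\n",
              paste(sprintf("%s %d", names(tt), tt), collapse = ", ")))
  invisible(x)
}

#' Flag internally inconsistent editing rows
#'
#' Recomputes the codon position and amino-acid change from the codon
#' strings and flags rows whose recorded fields disagree; counts elsewhere
#' always follow the recorded fields, so this is a report, not a filter.
#'
#' @param sites an editing site table (see \code{\link{summarize_editing}}).
#' @return the table with logical columns \code{position_consistent} and
#'   \code{aa_consistent}.
#' @export
validate_editing_rows <- function(sites) {
  derived_pos <- mapply(function(g, e) {
    d <- which(chars(g) != chars(e))
    if (length(d) == 1L) d else NA_integer_
  }, sites$codon_genomic, sites$codon_edited, USE.NAMES = FALSE)
  sites$position_consistent <- !is.na(derived_pos) &
    derived_pos == sites$codon_position
  sites$aa_consistent <- translate_codon(sites$codon_genomic) == sites$aa_from &
    translate_codon(sites$codon_edited) == sites$aa_to
  sites
}
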