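# Exact-identity repeat discovery and classification.
#
# Criteria follow what plastome repeat tables actually reflect: unit length
# greater than 10 bp (default min_period 11), 100% identity between copies,
# period at most 500 bp, at least two same-strand copies or an inverted
# partner.  Same-strand maximal repeated pairs are found by k-mer anchored
# diagonal runs; a pair whose shift is at most its match length is a tandem
# array (period = shift), otherwise a direct pair.  Families group all
# occurrences of one identical unit.  Reported coordinates are 1-based.

# same-strand maximal repeated pairs of s: data.frame(i, j, len), 0-based,
# i < j, s[i..i+len-1] == s[j..j+len-1], not extendable
same_strand_maximal_pairs <- function(s, k) {
  runs <- diagonal_runs(kmer_match_pairs(s, s, k), k)
  runs <- runs[runs$i < runs$j, , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

new_family <- function(unit, positions, type = NA_character_) {
  list(unit = unit, period = nchar(unit), positions = sort(unique(positions)),
       type = type)
}

# G.unit an exact k-fold concatenation of F.unit?
is_unit_power <- function(g_unit, f_unit) {
  lg <- nchar(g_unit); lf <- nchar(f_unit)
  lg > lf && lg %% lf == 0L && g_unit == strrep(f_unit, lg %/% lf)
}

# classify a same-strand family: tandem if any adjacent copies sit exactly
# one period apart, else direct
type_from_positions <- function(positions, period) {
  if (length(positions) < 2L) return(NA_character_)
  if (any(diff(sort(positions)) == period)) "T" else "D"
}

#' Find exact repeats in a genome
#'
#' Reports maximal repeat families: tandem (T, adjacent copies), direct
#' (D, separated same-strand copies) and inverted (I, a reverse-complement
#' partner, reported as its own single-copy record carrying the plus-strand
#' unit, mirroring published repeat tables).  A family whose unit is a
#' substring of a longer reported family and whose occurrences all lie
#' inside that family's copies is suppressed as a trivial internal repeat;
#' conversely a family whose unit is an exact concatenation power of a
#' shorter reported unit over the same positions is suppressed in favour of
#' the primitive period.
#'
#' @param x a \code{\link{plastome}} (or plain DNA string).
#' @param min_period minimum unit length in bp (default 11: repeats longer
#'   than 10 bp; also suppresses homopolymer/dinucleotide microsatellites).
#' @param max_period maximum unit length in bp (default 500; clamped to the
#'   genome length with a warning).
#' @param min_copies minimum same-strand copy number (default 2; inverted
#'   partner records are exempt and carry copies = 1).
#' @param ann optional \code{gene_annotation} used to fill a
#'   \code{region_note} column (containing gene or "intergenic").
#' @return data.frame with columns unit, period, copies, positions
#'   (comma-separated 1-based starts), type; ordered by first position then
#'   period descending.
#' @export
find_exact_repeats <- function(x, min_period = 11L, max_period = 500L,
                               min_copies = 2L, ann = NULL) {
  if (inherits(x, "plastome")) s <- x$seq else s <- toupper(x)
  n <- nchar(s)
  stopifnot(min_period >= 2L, max_period >= min_period)
  if (max_period > n) {
    warning("max_period ", max_period, " exceeds genome length ", n, "; clamped")
    max_period <- n
  }
  k <- as.integer(min_period)

  # --- same-strand emissions -------------------------------------------
  pairs <- same_strand_maximal_pairs(s, k)
  emissions <- list()
  emit <- function(unit, positions) {
    emissions[[length(emissions) + 1L]] <<- list(unit = unit, positions = positions)
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]; L <- pairs$len[r]
    p <- j - i
    if (p < min_period) next          # microsatellite shift, suppressed
    if (p <= L) {                     # tandem array: period = shift
      copies <- L %/% p + 1L
      emit(substr(s, i + 1L, i + p), i + p * (0:(copies - 1L)))
    } else if (L >= min_period) {     # direct pair: unit = full match
      emit(substr(s, i + 1L, i + L), c(i, j))
    }
  }
  fam_pos <- list()
  for (e in emissions) {
    fam_pos[[e$unit]] <- c(fam_pos[[e$unit]], e$positions)
  }
  fams <- lapply(names(fam_pos), function(u) new_family(u, fam_pos[[u]]))
  fams <- Filter(function(f) f$period >= min_period && f$period <= max_period &&
                   length(f$positions) >= min_copies, fams)

  # --- primitive-period suppression (drop unit powers) ------------------
  if (length(fams) > 1L) {
    units <- vapply(fams, `[[`, "", "unit")
    drop <- logical(length(fams))
    for (a in seq_along(fams)) {
      for (b in seq_along(fams)) {
        if (a == b || drop[b]) next
        if (is_unit_power(units[a], units[b]) &&
            all(fams[[a]]$positions %in% fams[[b]]$positions)) {
          drop[a] <- TRUE
          break
        }
      }
    }
    fams <- fams[!drop]
  }

  # --- containment suppression (drop trivial internal fragments) --------
  if (length(fams) > 1L) {
    ord <- order(-vapply(fams, `[[`, 0L, "period"),
                 vapply(fams, function(f) f$positions[1L], 0L))
    fams <- fams[ord]
    kept <- list()
    for (f in fams) {
      suppressed <- FALSE
      for (g in kept) {
        if (g$period <= f$period) next
        if (!grepl(f$unit, g$unit, fixed = TRUE)) next
        if (is_unit_power(g$unit, f$unit)) next
        gs <- g$positions; ge <- g$positions + g$period  # half-open copy spans
        contained <- vapply(f$positions, function(fp)
          any(gs <= fp & fp + f$period <= ge), logical(1L))
        if (all(contained)) {
          suppressed <- TRUE
          break
        }
      }
      if (!suppressed) kept[[length(kept) + 1L]] <- f
    }
    fams <- kept
  }
  for (a in seq_along(fams)) {
    fams[[a]]$type <- type_from_positions(fams[[a]]$positions, fams[[a]]$period)
  }

  # --- inverted repeats -------------------------------------------------
  inv <- inverted_maximal_pairs(s, k)
  inv <- inv[inv$len >= min_period & inv$len <= max_period &
               inv$b >= inv$a + inv$len, , drop = FALSE]
  partners <- list()
  units <- vapply(fams, `[[`, "", "unit")
  for (r in seq_len(nrow(inv))) {
    a <- inv$a[r]; b <- inv$b[r]; L <- inv$len[r]
    unit_a <- substr(s, a + 1L, a + L)
    hit <- which(units == unit_a)
    if (length(hit)) {                 # family sits at locus a; partner is b
      key <- units[hit[1L]]
      partners[[key]] <- c(partners[[key]], b)
    } else {
      hit <- which(units == revcomp(unit_a))
      if (length(hit)) {               # family unit sits at locus b
        key <- units[hit[1L]]
        partners[[key]] <- c(partners[[key]], a)
      } else {                         # standalone inverted pair
        fams[[length(fams) + 1L]] <- new_family(unit_a, a, type = "I")
        partners[[unit_a]] <- c(partners[[unit_a]], b)
        units <- c(units, unit_a)
      }
    }
  }
  for (key in names(partners)) {
    fam <- fams[[which(vapply(fams, `[[`, "", "unit") == key)[1L]]]
    for (pp in sort(unique(partners[[key]]))) {
      if (pp %in% fam$positions) next
      fams[[length(fams) + 1L]] <- new_family(fam$unit, pp, type = "I")
    }
  }

  # --- assemble ---------------------------------------------------------
  fams <- Filter(function(f) !is.na(f$type), fams)
  if (!length(fams)) {
    return(data.frame(unit = character(0), period = integer(0),
                      copies = integer(0), positions = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(fams, function(f) data.frame(
    unit = f$unit, period = f$period, copies = length(f$positions),
    positions = paste(f$positions + 1L, collapse = ", "),
    first = f$positions[1L], type = f$type, stringsAsFactors = FALSE)))
  out <- out[order(out$first, -out$period), , drop = FALSE]
  out$first <- NULL
  rownames(out) <- NULL
  if (!is.null(ann)) out$region_note <- annotate_positions(out, ann)
  out
}

annotate_positions <- function(records, ann) {
  gs <- gene_spans(ann)
  vapply(seq_len(nrow(records)), function(r) {
    p1 <- as.integer(strsplit(records$positions[r], ",\\s*")[[1L]][1L]) - 1L
    hit <- gs$key[gs$start <= p1 & p1 < gs$end]
    if (length(hit)) paste(hit, collapse = ",") else "intergenic"
  }, character(1L))
}

#' Classify repeat records as tandem, direct or inverted
#'
#' Applies the classification rules to records with known units and
#' occurrence positions: tandem when any adjacent copies are exactly one
#' period apart; direct when at least two same-strand copies are separated
#' by more than the period; a single-occurrence record is an inverted
#' partner when another record in the set carries the same unit or its
#' reverse complement, otherwise it is dropped with a warning.
#'
#' @param records data.frame with columns unit and positions
#'   (comma-separated 1-based starts); a copies column is recomputed.
#' @return the records with a \code{type} column filled (records that
#'   cannot be classified are removed).
#' @export
classify_repeats <- function(records) {
  stopifnot(all(c("unit", "positions") %in% names(records)))
  pos_list <- lapply(strsplit(as.character(records$positions), ",\\s*"), as.integer)
  records$copies <- lengths(pos_list)
  records$period <- nchar(records$unit)
  type <- character(nrow(records))
  keep <- rep(TRUE, nrow(records))
  for (r in seq_len(nrow(records))) {
    pos <- pos_list[[r]]
    if (length(pos) >= 2L) {
      type[r] <- type_from_positions(pos - 1L, records$period[r])
    } else {
      others <- setdiff(seq_len(nrow(records)), r)
      partner <- any(records$unit[others] == records$unit[r] |
                       records$unit[others] == revcomp(records$unit[r]))
      if (partner) {
        type[r] <- "I"
      } else {
        warning("single occurrence of '", records$unit[r],
                "' has no reverse-complement partner; dropped")
        keep[r] <- FALSE
      }
    }
  }
  records$type <- type
  records[keep, , drop = FALSE]
}
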