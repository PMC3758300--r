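# Independent oracles used across the suite.
#
# Repeat oracles find maximal repeated pairs by scanning every diagonal
# with vectorized character comparison and run-length encoding -- an
# O(n^2) method sharing no code with the k-mer-anchored implementation.
# The parsimony oracle enumerates every internal labeling exhaustively.

oracle_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# maximal same-strand repeated pairs (i, j, len), 0-based, i < j
oracle_pairs_same <- function(s, min_len) {
  sv <- oracle_chars(s)
  n <- length(sv)
  out <- list()
  for (d in seq_len(n - 1L)) {
    m <- sv[seq_len(n - d)] == sv[seq_len(n - d) + d]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_len)
    for (h in hit) {
      out[[length(out) + 1L]] <- c(i = starts[h] - 1L, j = starts[h] - 1L + d,
                                   len = r$lengths[h])
    }
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0), len = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# maximal inverted pairs (a, b, len) in forward coordinates, a < b,
# non-overlapping loci
oracle_pairs_inverted <- function(s, min_len) {
  sv <- oracle_chars(s)
  rv <- oracle_chars(plastkit::revcomp(s))
  n <- length(sv)
  out <- list()
  for (d in (-(n - 1L)):(n - 1L)) {
    idx <- seq_len(n)
    ii <- idx[idx + d >= 1L & idx + d <= n]
    if (length(ii) < min_len) next
    m <- sv[ii] == rv[ii + d]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_len)
    for (h in hit) {
      i0 <- ii[starts[h]] - 1L            # 0-based start in s
      len <- r$lengths[h]
      j0 <- i0 + d                        # 0-based start in revcomp(s)
      b0 <- n - j0 - len                  # forward start of the partner
      a <- min(i0, b0); b <- max(i0, b0)
      if (b >= a + len) {
        out[[length(out) + 1L]] <- c(a = a, b = b, len = len)
      }
    }
  }
  if (!length(out)) return(data.frame(a = integer(0), b = integer(0), len = integer(0)))
  unique(as.data.frame(do.call(rbind, out)))
}

# longest non-overlapping inverted pair, ties by smaller first start
oracle_longest_inverted <- function(s, min_len) {
  cand <- oracle_pairs_inverted(s, min_len)
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(-cand$len, cand$a, cand$b), , drop = FALSE]
  cand[1L, ]
}

# independently-written family assembly over oracle pairs, following the
# documented rules (tandem period = shift; primitive periods win over unit
# powers; trivial internal fragments contained in a longer family's copies
# are suppressed)
oracle_repeat_families <- function(s, min_period = 11L, max_period = 500L,
                                   min_copies = 2L) {
  pairs <- oracle_pairs_same(s, min_period)
  fams <- list()
  note <- function(unit, pos) {
    key <- unit
    fams[[key]] <<- sort(unique(c(fams[[key]], pos)))
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]; L <- pairs$len[r]
    p <- j - i
    if (p < min_period) next
    if (p <= L) {
      copies <- L %/% p + 1L
      note(substr(s, i + 1L, i + p), i + p * (0:(copies - 1L)))
    } else if (L >= min_period) {
      note(substr(s, i + 1L, i + L), c(i, j))
    }
  }
  units <- names(fams)
  keep <- vapply(units, function(u) {
    nchar(u) >= min_period && nchar(u) <= max_period &&
      length(fams[[u]]) >= min_copies
  }, logical(1L))
  units <- units[keep]
  # primitive periods beat their concatenation powers
  is_pow <- function(g, f) nchar(g) > nchar(f) && nchar(g) %% nchar(f) == 0L &&
    g == strrep(f, nchar(g) %/% nchar(f))
  drop <- rep(FALSE, length(units))
  for (a in seq_along(units)) {
    for (b in seq_along(units)) {
      if (a == b || drop[b]) next
      if (is_pow(units[a], units[b]) && all(fams[[units[a]]] %in% fams[[units[b]]])) {
        drop[a] <- TRUE; break
      }
    }
  }
  units <- units[!drop]
  # containment suppression, longest units first
  units <- units[order(-nchar(units))]
  kept <- character(0)
  for (u in units) {
    contained <- FALSE
    for (g in kept) {
      if (nchar(g) <= nchar(u) || !grepl(u, g, fixed = TRUE) || is_pow(g, u)) next
      gpos <- fams[[g]]
      if (all(vapply(fams[[u]], function(fp)
        any(gpos <= fp & fp + nchar(u) <= gpos + nchar(g)), logical(1L)))) {
        contained <- TRUE; break
      }
    }
    if (!contained) kept <- c(kept, u)
  }
  res <- lapply(kept, function(u) {
    pos <- fams[[u]]
    list(unit = u, positions = pos,
         type = if (any(diff(pos) == nchar(u))) "T" else "D")
  })
  # inverted families
  inv <- oracle_pairs_inverted(s, min_period)
  inv <- inv[inv$len <= max_period, , drop = FALSE]
  for (r in seq_len(nrow(inv))) {
    a <- inv$a[r]; b <- inv$b[r]; L <- inv$len[r]
    ua <- substr(s, a + 1L, a + L)
    hit <- which(vapply(res, function(f) f$unit == ua, logical(1L)))
    if (length(hit)) {
      res[[length(res) + 1L]] <- list(unit = ua, positions = b, type = "I")
    } else {
      hit <- which(vapply(res, function(f) f$unit == plastkit::revcomp(ua), logical(1L)))
      if (length(hit)) {
        res[[length(res) + 1L]] <- list(unit = res[[hit[1L]]]$unit, positions = a, type = "I")
      } else {
        res[[length(res) + 1L]] <- list(unit = ua, positions = a, type = "I")
        res[[length(res) + 1L]] <- list(unit = ua, positions = b, type = "I")
      }
    }
  }
  if (!length(res)) {
    return(data.frame(unit = character(0), copies = integer(0),
                      positions = character(0), type = character(0)))
  }
  out <- do.call(rbind, lapply(res, function(f) data.frame(
    unit = f$unit, copies = length(f$positions),
    positions = paste(f$positions + 1L, collapse = ", "),
    first = f$positions[1L], type = f$type, stringsAsFactors = FALSE)))
  out <- out[order(out$first, -nchar(out$unit)), , drop = FALSE]
  out$first <- NULL
  rownames(out) <- NULL
  out
}

# exhaustive small-parsimony oracle: minimum changes over every internal
# labeling; optionally the minimum number of edges entering derived_state
# among minimum-change labelings
oracle_parsimony <- function(tree, states, fixed_root_state = NULL,
                             derived_state = NULL) {
  tips <- tree$tip.label
  ntip <- length(tips)
  nnode <- tree$Nnode
  alphabet <- sort(unique(c(states[!is.na(states)], fixed_root_state, derived_state)))
  st <- as.character(states[tips])
  edge <- tree$edge
  root <- ntip + 1L
  grids <- rep(list(alphabet), nnode)
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  best <- Inf
  best_orig <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- c(st, as.character(combos[r, ]))
    if (!is.null(fixed_root_state) && lab[root] != fixed_root_state) next
    diffs <- lab[edge[, 1L]] != lab[edge[, 2L]]
    diffs[is.na(diffs)] <- FALSE         # unknown leaves are free
    # unknown leaf: choose its parent's state (zero cost, no origin)
    changes <- sum(diffs, na.rm = TRUE)
    if (changes > best) next
    orig <- if (!is.null(derived_state)) {
      sum(lab[edge[, 2L]] == derived_state & lab[edge[, 1L]] != derived_state,
          na.rm = TRUE) + as.integer(lab[root] == derived_state)
    } else 0L
    if (changes < best) {
      best <- changes
      best_orig <- orig
    } else {
      best_orig <- min(best_orig, orig)
    }
  }
  list(length = best, origins = best_orig)
}

random_states <- function(tips, alphabet = c("0", "1")) {
  setNames(sample(alphabet, length(tips), replace = TRUE), tips)
}

write_temp_fasta <- function(seqs, names = paste0("seq", seq_along(seqs))) {
  f <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", names), seqs)), f)
  f
}
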