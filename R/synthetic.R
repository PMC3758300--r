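# Seeded generators producing inputs with the structure each pipeline
# stage assumes: quadripartite genomes with repeat-free single-copy
# regions, repeat fixtures embedding known units, and homolog panels with
# planted C-to-U edits.  All generators are deterministic functions of
# their arguments plus the seed.
#
# Background base composition defaults to the AT-rich plastid regime
# (GC ~ 0.374, the coconut genome-wide value); configurable.

random_dna <- function(n, gc = 0.374) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic quadripartite plastome
#'
#' Builds genome = LSC + IRb + SSC + reverse_complement(IRb) from random
#' AT-rich sequence, with single-copy regions verified free of chance
#' repeats at the detection scale: generation is rejected and retried
#' unless the only duplications at k = 31 are the two IR copies, and the
#' region boundary bases are resampled so the planted IR pair is not
#' extendable by even one base.
#'
#' @param lsc,ssc single-copy region lengths in bp.
#' @param ir_total combined length of both IR copies (must be even).
#'   Defaults are the coconut plastome dimensions (genome 154,731 bp).
#' @param seed integer seed; identical arguments and seed give a
#'   byte-identical genome.
#' @param gc background GC fraction.
#' @param max_tries rejection-sampling cap.
#' @return list with \code{genome} (a \code{\link{plastome}}) and
#'   \code{truth} (the generating \code{region_partition}).
#' @export
make_quadripartite_genome <- function(lsc = 84230L, ssc = 17391L,
                                      ir_total = 53110L, seed = 1L,
                                      gc = 0.374, max_tries = 20L) {
  stopifnot(lsc > 0L, ssc > 0L, ir_total > 0L)
  if (ir_total %% 2L != 0L) stop("spec error: ir_total must split evenly into two copies")
  irh <- ir_total %/% 2L
  n <- lsc + ssc + ir_total
  if (ir_total >= n) stop("spec error: IR longer than genome")
  set.seed(as.integer(seed))
  k <- 31L
  for (try in seq_len(max_tries)) {
    lsc_seq <- random_dna(lsc, gc)
    ssc_seq <- random_dna(ssc, gc)
    irb_seq <- random_dna(irh, gc)
    # boundary guards: the IR pair must not extend into the single-copy
    # regions (1-base extensions would shift the recovered partition)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    while (substr(ssc_seq, ssc, ssc) == comp[substr(ssc_seq, 1L, 1L)]) {
      substr(ssc_seq, ssc, ssc) <- sample(c("A", "C", "G", "T"), 1L)
    }
    while (substr(lsc_seq, lsc, lsc) == comp[substr(lsc_seq, 1L, 1L)]) {
      substr(lsc_seq, lsc, lsc) <- sample(c("A", "C", "G", "T"), 1L)
    }
    g <- paste0(lsc_seq, irb_seq, ssc_seq, revcomp(irb_seq))
    if (irh >= k) {
      km <- c(kmers(g, k), kmers(revcomp(g), k))
      dup <- duplicated(km)
      expected <- 2L * (irh - k + 1L)
      if (sum(dup) != expected || anyDuplicated(km[dup])) next
    }
    genome <- plastome(g, id = sprintf("synthetic_quadripartite_seed%d", seed))
    truth <- structure(list(
      lsc = c(0L, lsc), irb = c(lsc, lsc + irh),
      ssc = c(lsc + irh, lsc + irh + ssc),
      ira = c(lsc + irh + ssc, n),
      genome_length = n, offset = 0L), class = "region_partition")
    return(list(genome = genome, truth = truth))
  }
  stop("generation error: could not produce a repeat-free quadripartite genome in ",
       max_tries, " tries")
}

#' Generate a repeat fixture sequence
#'
#' Embeds the requested repeat records left to right, separated by random
#' spacers verified repeat-free above the detection floor.  Records with
#' two or more copies are laid out with the stated inter-copy gaps (0 for
#' adjacent tandem copies); a record with \code{copies = 1} and type "I" is
#' an inverted partner: the reverse complement of its unit is embedded, and
#' \code{group} links it to its plus-strand primary for the repeat-freeness
#' whitelist.
#'
#' @param records data.frame with columns unit, copies, type and optionally
#'   gaps (comma-separated bp between consecutive copies), gap_seq
#'   (explicit gap sequences, comma-separated) and group (integer linking
#'   inverted partners to their primary record; defaults to row number).
#' @param seed integer seed.
#' @param flank random flank length on each side.
#' @param spacer random spacer length between records.
#' @param gc background GC fraction.
#' @param min_period repeat-freeness floor for the background (bp).
#' @param max_tries rejection-sampling cap.
#' @return list with \code{genome} (a linear \code{\link{plastome}}) and
#'   \code{truth} (data.frame unit, period, copies, positions, type with
#'   1-based comma-separated positions, as detected coordinates).
#' @export
make_repeat_fixture <- function(records, seed = 1L, flank = 60L, spacer = 40L,
                                gc = 0.374, min_period = 11L, max_tries = 50L) {
  stopifnot(all(c("unit", "copies", "type") %in% names(records)))
  nr <- nrow(records)
  if (is.null(records$gaps)) records$gaps <- ""
  if (is.null(records$gap_seq)) records$gap_seq <- ""
  if (is.null(records$group)) records$group <- seq_len(nr)
  set.seed(as.integer(seed))
  for (try in seq_len(max_tries)) {
    fix <- try_repeat_layout(records, flank, spacer, gc, min_period)
    if (!is.null(fix)) {
      fix$genome <- plastome(fix$sequence, id = sprintf("repeat_fixture_seed%d", seed),
                             circular = FALSE)
      fix$sequence <- NULL
      return(fix)
    }
  }
  stop("generation error: spacers failed repeat-freeness after ", max_tries, " tries")
}

# one layout attempt; NULL on verification failure
try_repeat_layout <- function(records, flank, spacer, gc, min_period) {
  nr <- nrow(records)
  pieces <- character(0)
  spans <- list()       # per record: c(start0, end0) half-open, 0-based
  positions <- vector("list", nr)
  cur <- 0L
  add <- function(x) { pieces <<- c(pieces, x); cur <<- cur + nchar(x); invisible(NULL) }
  add(random_dna(flank, gc))
  for (r in seq_len(nr)) {
    u <- toupper(records$unit[r])
    m <- nchar(u)
    copies <- records$copies[r]
    emb <- if (copies == 1L && records$type[r] == "I") revcomp(u) else u
    gaps <- if (nzchar(records$gaps[r]))
      as.integer(strsplit(records$gaps[r], ",\\s*")[[1L]]) else rep(0L, max(copies - 1L, 0L))
    gseq <- if (nzchar(records$gap_seq[r]))
      strsplit(records$gap_seq[r], ",\\s*")[[1L]] else NULL
    if (length(gaps) != max(copies - 1L, 0L)) {
      stop("record ", r, ": need ", copies - 1L, " gap value(s)")
    }
    start0 <- cur
    pos <- integer(copies)
    for (cc in seq_len(copies)) {
      pos[cc] <- cur
      add(emb)
      if (cc < copies && gaps[cc] > 0L) {
        g <- if (!is.null(gseq) && cc <= length(gseq) && nzchar(gseq[cc]))
          toupper(gseq[cc]) else random_dna(gaps[cc], gc)
        if (nchar(g) != gaps[cc]) stop("record ", r, ": gap_seq length mismatch")
        add(g)
      }
    }
    positions[[r]] <- pos
    spans[[r]] <- c(start0, cur)
    if (r < nr) add(random_dna(spacer, gc))
  }
  add(random_dna(flank, gc))
  s <- paste(pieces, collapse = "")
  s <- polish_background(s, records, positions, spans, min_period)
  if (is.null(s)) return(NULL)
  truth <- data.frame(
    unit = toupper(records$unit), period = nchar(records$unit),
    copies = records$copies,
    positions = vapply(positions, function(p) paste(p + 1L, collapse = ", "), ""),
    type = records$type, stringsAsFactors = FALSE)
  list(sequence = s, truth = truth)
}

# Break accidental extensions of planted matches.  For every planted copy
# pair the match may continue structurally through fixed (copy / explicit
# gap) characters, but the first position where a random background
# character continues the match is a frontier: that character is resampled
# so the detected family boundaries equal the planted ones.  Inverted
# partners are guarded the same way under complementarity.
fix_pair_frontiers <- function(s, records, positions, spans) {
  sv <- chars(s)
  n <- length(sv)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  fixed <- logical(n)
  for (r in seq_len(nrow(records))) {
    m <- nchar(records$unit[r])
    for (p in positions[[r]]) fixed[seq.int(p + 1L, p + m)] <- TRUE
    if (nzchar(records$gap_seq[r])) {
      fixed[seq.int(spans[[r]][1L] + 1L, spans[[r]][2L])] <- TRUE
    }
  }
  resample_differ <- function(q, other_char) {
    sv[q] <<- sample(setdiff(c("A", "C", "G", "T"), other_char), 1L)
  }
  group_of <- records$group
  for (iter in 1:10) {
    changed <- FALSE
    bad <- FALSE
    # same-strand pairs within a record group (unit occurrences share one
    # string; cross-copy matches are the planted structure)
    for (g in unique(group_of)) {
      ridx <- which(group_of == g)
      fwd <- integer(0); rev <- integer(0); m <- 0L
      for (r in ridx) {
        m <- nchar(records$unit[r])
        if (records$copies[r] == 1L && records$type[r] == "I") {
          rev <- c(rev, positions[[r]])
        } else {
          fwd <- c(fwd, positions[[r]])
        }
      }
      walk <- function(a, b, dir) {
        # dir +1: rightward from match end; dir -1: leftward from start
        t <- if (dir > 0L) m else -1L
        repeat {
          pa <- a + t + 1L; pb <- b + t + 1L
          if (pa < 1L || pb < 1L || pa > n || pb > n) return(FALSE)
          if (sv[pa] != sv[pb]) return(FALSE)
          if (fixed[pa] && fixed[pb]) { t <- t + dir; next }
          resample_differ(if (fixed[pa]) pb else pa, sv[if (fixed[pa]) pa else pb])
          return(TRUE)
        }
      }
      if (length(fwd) > 1L) {
        for (ii in seq_along(fwd)) for (jj in seq_len(ii - 1L)) {
          a <- fwd[jj]; b <- fwd[ii]
          if (walk(a, b, +1L)) changed <- TRUE
          if (walk(a, b, -1L)) changed <- TRUE
        }
      }
      # inverted partners: the partner's outside neighbours must not
      # complement the characters flanking any primary copy (a 1-base
      # extension would enlarge the planted inverted match).  Handled
      # position-centric: the partner-side character avoids the whole
      # banned set; when the banned set leaves at most one base free, a
      # modifiable primary-side flanking character is nudged as well so
      # the joint constraints stay satisfiable.
      for (b in rev) {
        guard_side <- function(pp, counterparts) {
          counterparts <- counterparts[counterparts >= 1L & counterparts <= n]
          if (pp < 1L || pp > n || !length(counterparts)) return(invisible(NULL))
          banned <- unique(comp[sv[counterparts]])
          surv <- setdiff(c("A", "C", "G", "T"), banned)
          if (!sv[pp] %in% banned) return(invisible(NULL))
          changed <<- TRUE
          nudge <- function() {
            mod <- counterparts[!fixed[counterparts]]
            if (!length(mod)) { bad <<- TRUE; return(FALSE) }
            qq <- mod[sample.int(length(mod), 1L)]
            sv[qq] <<- sample(setdiff(c("A", "C", "G", "T"), sv[qq]), 1L)
            TRUE
          }
          if (fixed[pp]) {
            nudge()
          } else if (length(surv) >= 2L) {
            sv[pp] <<- sample(surv, 1L)
          } else {
            # forced (or impossible): open space on the primary side too,
            # the next pass re-evaluates the loosened constraints
            if (nudge() && length(surv) == 1L) sv[pp] <<- surv
          }
          invisible(NULL)
        }
        guard_side(b, a_right <- fwd + m + 1L)          # char before partner
        guard_side(b + m + 1L, fwd)                     # char after partner
      }
    }
    if (bad) return(NULL)
    if (!changed) return(paste(sv, collapse = ""))
  }
  NULL
}

fixed_background_mask <- function(n, records, positions, spans) {
  fixed <- logical(n)
  for (r in seq_len(nrow(records))) {
    m <- nchar(records$unit[r])
    for (p in positions[[r]]) fixed[seq.int(p + 1L, p + m)] <- TRUE
    if (nzchar(records$gap_seq[r])) {
      fixed[seq.int(spans[[r]][1L] + 1L, spans[[r]][2L])] <- TRUE
    }
  }
  fixed
}

# first duplicated k-mer (forward or between strands) not fully explained
# by the spans of one linked record group; NULL when clean
find_unexplained_kmer <- function(s, records, spans, k) {
  n <- nchar(s)
  km_f <- kmers(s, k)
  km_r <- kmers(revcomp(s), k)
  rc_start <- (n - k):0       # forward coords of reverse-strand k-mer starts
  occ <- data.frame(kmer = c(km_f, km_r),
                    start = c(seq_along(km_f) - 1L, rc_start),
                    stringsAsFactors = FALSE)
  group_of <- records$group
  span_grp <- lapply(sort(unique(group_of)), function(g) {
    do.call(rbind, spans[group_of == g])
  })
  dup_kmers <- unique(occ$kmer[duplicated(occ$kmer)])
  for (kmer in dup_kmers) {
    st <- unique(occ$start[occ$kmer == kmer])
    explained <- FALSE
    for (sg in span_grp) {
      if (all(vapply(st, function(p)
        any(sg[, 1L] <= p & p + k <= sg[, 2L]), logical(1L)))) {
        explained <- TRUE
        break
      }
    }
    if (!explained) return(list(kmer = kmer, starts = st))
  }
  NULL
}

# Alternate frontier guarding with duplicate repair: an unexplained
# duplicated k-mer necessarily touches random background (internally
# periodic planted units plus AT-rich background make such coincidences
# common), so one of its random characters is resampled and the sequence
# re-checked until clean.
polish_background <- function(s, records, positions, spans, min_period) {
  fixed <- fixed_background_mask(nchar(s), records, positions, spans)
  for (iter in 1:400) {
    s <- fix_pair_frontiers(s, records, positions, spans)
    if (is.null(s)) return(NULL)
    bad <- find_unexplained_kmer(s, records, spans, min_period)
    if (is.null(bad)) return(s)
    cand <- unlist(lapply(bad$starts, function(p) seq.int(p + 1L, p + min_period)))
    cand <- cand[!fixed[cand]]
    if (!length(cand)) return(NULL)   # conflict between fixed characters
    q <- cand[sample.int(length(cand), 1L)]
    sv <- chars(s)
    sv[q] <- sample(setdiff(c("A", "C", "G", "T"), sv[q]), 1L)
    s <- paste(sv, collapse = "")
  }
  NULL
}

#' Generate a CDS and homolog panel with planted C-to-U edits
#'
#' Builds a random CDS whose planted codons carry exactly one C, and a
#' reference panel supporting the edited residue at the stated fraction in
#' planted columns.  Elsewhere references carry the unedited residue,
#' except that a \code{background_support} fraction supports the edit at
#' the first C of every unplanted C-containing codon (modelling diffuse
#' disagreement below the calling cutoff).
#'
#' @param cds_length_codons CDS length in codons.
#' @param planted_edits data.frame with columns codon_index and support
#'   (fraction of references supporting the edit), or an integer vector of
#'   codon indices (support 1).  The achieved support is
#'   floor(support * panel_size) / panel_size, so a fraction below the
#'   calling cutoff can never round up across it.
#' @param panel_size number of reference proteins.
#' @param background_support support fraction at unplanted candidate sites
#'   (must be below the intended calling cutoff).
#' @param seed integer seed.
#' @return list with \code{cds} (codon vector), \code{panel} (a
#'   \code{\link{homolog_panel}}) and \code{truth} (data.frame of planted
#'   sites with cds_position, codon_index, codon_position, codon_genomic,
#'   codon_edited, support).
#' @export
make_homolog_panel <- function(cds_length_codons, planted_edits,
                               panel_size = 10L, background_support = 0,
                               seed = 1L) {
  if (is.numeric(planted_edits) && is.null(dim(planted_edits))) {
    planted_edits <- data.frame(codon_index = as.integer(planted_edits), support = 1)
  }
  stopifnot(all(c("codon_index", "support") %in% names(planted_edits)),
            all(planted_edits$support >= 0 & planted_edits$support <= 1),
            all(planted_edits$codon_index >= 2L),
            all(planted_edits$codon_index <= cds_length_codons))
  set.seed(as.integer(seed))
  # editable codons with a single C and a non-silent C->T change
  pool <- c("TCA", "TCG", "TCT", "ACA", "ACG", "ACT", "CAT", "CGG", "CGT")
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  cds <- c("ATG", sample(sense, cds_length_codons - 1L, replace = TRUE))
  cds[planted_edits$codon_index] <- sample(pool, nrow(planted_edits), replace = TRUE)
  residues <- matrix("", nrow = panel_size, ncol = cds_length_codons)
  truth <- list()
  planted_at <- planted_edits$codon_index
  for (ci in seq_len(cds_length_codons)) {
    codon <- cds[ci]
    aa <- unname(gc_tab[codon])
    p <- match(ci, planted_at)
    if (!is.na(p)) {
      cp <- which(chars(codon) == "C")[1L]
      edited <- codon
      substr(edited, cp, cp) <- "T"
      aa_to <- unname(gc_tab[edited])
      n_sup <- floor(planted_edits$support[p] * panel_size)
      residues[, ci] <- c(rep(aa_to, n_sup), rep(aa, panel_size - n_sup))
      truth[[length(truth) + 1L]] <- data.frame(
        cds_position = (ci - 1L) * 3L + cp, codon_index = ci, codon_position = cp,
        codon_genomic = codon, codon_edited = edited,
        support = n_sup / panel_size, stringsAsFactors = FALSE)
    } else {
      col <- rep(aa, panel_size)
      cpos <- which(chars(codon) == "C")
      if (length(cpos) && background_support > 0) {
        edited <- codon
        substr(edited, cpos[1L], cpos[1L]) <- "T"
        aa_to <- unname(gc_tab[edited])
        if (!is.na(aa_to) && aa_to != "*" && aa_to != aa) {
          nb <- floor(background_support * panel_size)
          if (nb > 0L) col[seq_len(nb)] <- aa_to
        }
      }
      residues[, ci] <- col
    }
  }
  list(cds = cds,
       panel = homolog_panel("synthetic_gene", residues),
       truth = do.call(rbind, truth))
}
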