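# Inverted-repeat detection and the quadripartite LSC/IRb/SSC/IRa partition.
#
# Detection is exact-identity (the genome-as-assembled semantics): the IR
# pair is the longest pair of non-overlapping intervals (X, Y) such that
# seq(Y) == reverse_complement(seq(X)).  Implementation is k-mer anchored:
# matching k-mers between the genome and its reverse complement fall on
# diagonals; maximal runs along a diagonal are maximal common substrings.

# all matching k-mer start positions between two strings, as 0-based (i, j)
kmer_match_pairs <- function(s1, s2, k) {
  k1 <- kmers(s1, k)
  k2 <- kmers(s2, k)
  if (!length(k1) || !length(k2)) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  d1 <- data.frame(kmer = k1, i = seq_along(k1) - 1L, stringsAsFactors = FALSE)
  d2 <- data.frame(kmer = k2, j = seq_along(k2) - 1L, stringsAsFactors = FALSE)
  m <- merge(d1, d2, by = "kmer")
  data.frame(i = m$i, j = m$j)
}

# merge diagonal runs of k-mer matches into maximal common substrings;
# returns data.frame(i, j, len), 0-based
diagonal_runs <- function(pairs, k) {
  if (!nrow(pairs)) return(data.frame(i = integer(0), j = integer(0), len = integer(0)))
  d <- pairs$i - pairs$j
  o <- order(d, pairs$i)
  i <- pairs$i[o]; d <- d[o]
  new_run <- c(TRUE, d[-1L] != d[-length(d)] | i[-1L] != i[-length(i)] + 1L)
  run_id <- cumsum(new_run)
  i0 <- tapply(i, run_id, min)
  im <- tapply(i, run_id, max)
  dd <- tapply(d, run_id, `[`, 1L)
  data.frame(i = as.integer(i0), j = as.integer(i0 - dd),
             len = as.integer(im - i0 + k))
}

# inverted maximal pairs of one sequence: data.frame(a, b, len) with a < b,
# 0-based starts of the two loci in s; s[b..] == revcomp(s[a..])
inverted_maximal_pairs <- function(s, k) {
  n <- nchar(s)
  runs <- diagonal_runs(kmer_match_pairs(s, revcomp(s), k), k)
  if (!nrow(runs)) return(data.frame(a = integer(0), b = integer(0), len = integer(0)))
  a <- runs$i
  b <- n - runs$j - runs$len
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- unique(data.frame(a = lo, b = hi, len = runs$len))
  out[order(-out$len, out$a, out$b), , drop = FALSE]
}

#' Detect the plastid inverted-repeat pair
#'
#' Finds the longest pair of non-overlapping intervals (X, Y) with
#' seq(Y) equal to the reverse complement of seq(X); ties are broken by the
#' smaller start of X.  On circular genomes a half-rotation is also
#' searched so that a pair spanning the origin is found.  Exact identity is
#' required between the copies (N does not match N).
#'
#' @param x a \code{\link{plastome}}.
#' @param min_length minimum IR copy length in bp (default 1000: plastid
#'   IRs are tens of kb, a high floor avoids spurious short matches).
#' @return a list with 0-based half-open intervals \code{x} and \code{y}
#'   (x before y), \code{length} (one copy, bp) and \code{rotation} (offset
#'   applied to the input frame; 0 unless the pair spanned the origin), or
#'   \code{NULL} when no pair of at least \code{min_length} exists (the
#'   no-IR signal, distinct from an empty interval).
#' @export
detect_inverted_repeat_pair <- function(x, min_length = 1000L) {
  stopifnot(inherits(x, "plastome"), min_length >= 1L)
  n <- nchar(x$seq)
  k <- min(25L, as.integer(min_length))
  best_of <- function(s) {
    cand <- inverted_maximal_pairs(s, k)
    if (!nrow(cand)) return(NULL)
    # exclude self-overlapping loci (fold-back palindromes)
    ok <- cand$b >= cand$a + cand$len
    cand <- cand[ok & cand$len >= min_length, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand[1L, ]
  }
  hit <- best_of(x$seq)
  rotation <- 0L
  if (x$circular) {
    shift <- n %/% 2L
    s2 <- paste0(substr(x$seq, shift + 1L, n), substr(x$seq, 1L, shift))
    hit2 <- best_of(s2)
    if (!is.null(hit2) && (is.null(hit) || hit2$len > hit$len)) {
      hit <- hit2
      rotation <- shift
    }
  }
  if (is.null(hit)) return(NULL)
  list(x = c(hit$a, hit$a + hit$len), y = c(hit$b, hit$b + hit$len),
       length = hit$len, rotation = rotation)
}

#' Derive the quadripartite partition from an IR pair
#'
#' The two single-copy segments between the IR copies are labeled LSC
#' (longer) and SSC (shorter); on a tie the segment following the first IR
#' copy is declared SSC.  The partition is reported in a canonical rotation
#' that places the LSC start at position 0, giving the region order LSC,
#' IRb, SSC, IRa around the circle.
#'
#' @param x a \code{\link{plastome}}.
#' @param ir_pair result of \code{\link{detect_inverted_repeat_pair}} (the
#'   copies must be exact reverse complements and non-overlapping).
#' @return an object of class \code{region_partition}: 0-based half-open
#'   intervals \code{lsc}, \code{irb}, \code{ssc}, \code{ira} in the
#'   canonical frame, \code{genome_length}, and \code{offset} such that
#'   canonical coordinate = (input coordinate - offset) mod genome_length.
#' @export
partition_quadripartite <- function(x, ir_pair) {
  if (is.null(ir_pair)) stop("no IR pair supplied (no-IR signal)")
  n <- nchar(x$seq)
  rot <- ir_pair$rotation %||% 0L
  s <- if (rot == 0L) x$seq else
    paste0(substr(x$seq, rot + 1L, n), substr(x$seq, 1L, rot))
  X <- ir_pair$x; Y <- ir_pair$y
  stopifnot(X[1L] < Y[1L], X[2L] <= Y[1L])
  sx <- substr(s, X[1L] + 1L, X[2L])
  sy <- substr(s, Y[1L] + 1L, Y[2L])
  if (!identical(sy, revcomp(sx))) {
    stop("IR pair copies are not exact reverse complements")
  }
  midA <- c(X[2L], Y[1L])          # between the copies
  lenA <- iv_len(midA)
  lenB <- (n - Y[2L]) + X[1L]      # wraps the origin
  if (lenA == 0L || lenB == 0L) {
    stop("degenerate partition: IR copies are adjacent (zero-length single-copy segment)")
  }
  if (lenB >= lenA) {
    # LSC wraps the origin; IRb is the first copy
    lsc_start <- Y[2L]             # in current frame, mod n
    l <- lenB; i <- iv_len(X); ssc <- lenA
  } else {
    lsc_start <- X[2L]
    l <- lenA; i <- iv_len(Y); ssc <- lenB
  }
  offset <- (lsc_start + rot) %% n  # input -> canonical shift
  part <- structure(list(
    lsc = c(0L, l),
    irb = c(l, l + i),
    ssc = c(l + i, l + i + ssc),
    ira = c(l + i + ssc, n),
    genome_length = n,
    offset = as.integer(offset)
  ), class = "region_partition")
  stopifnot(iv_len(part$lsc) + iv_len(part$irb) + iv_len(part$ssc) +
              iv_len(part$ira) == n)
  part
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> genome %s bp | LSC %s, IRb %s, SSC %s, IRa %s (IR total %s)\n",
              format(x$genome_length, big.mark = ","),
              format(iv_len(x$lsc), big.mark = ","),
              format(iv_len(x$irb), big.mark = ","),
              format(iv_len(x$ssc), big.mark = ","),
              format(iv_len(x$ira), big.mark = ","),
              format(iv_len(x$irb) + iv_len(x$ira), big.mark = ",")))
  invisible(x)
}

#' Region lengths of a partition
#' @param part a \code{region_partition}.
#' @return named integer vector: lsc, irb, ssc, ira, ir_total, genome.
#' @export
region_lengths <- function(part) {
  c(lsc = iv_len(part$lsc), irb = iv_len(part$irb), ssc = iv_len(part$ssc),
    ira = iv_len(part$ira), ir_total = iv_len(part$irb) + iv_len(part$ira),
    genome = part$genome_length)
}

#' Gene-to-junction distance profile
#'
#' For each requested gene, the signed distance (bp) from the gene end
#' nearest to its nearest LSC/IR/SSC junction.  A gene lying clear of the
#' junction reports the non-negative gap; a gene straddling a junction
#' reports the overhang across it as a negative value (the smaller of the
#' two overhangs).
#'
#' @param part a \code{region_partition}.
#' @param ann a \code{gene_annotation} in the same input frame as the
#'   genome that produced \code{part}.
#' @param genes character vector of gene names (a \code{copy_tag} may be
#'   appended as \code{"gene|tag"}).
#' @return data.frame with columns gene, junction, distance.
#' @export
junction_profile <- function(part, ann, genes) {
  n <- part$genome_length
  gs <- gene_spans(ann)
  junctions <- c("LSC/IRb" = part$lsc[2L], "IRb/SSC" = part$irb[2L],
                 "SSC/IRa" = part$ssc[2L], "IRa/LSC" = 0L)
  rows <- lapply(genes, function(g) {
    hit <- which(gs$key == g | gs$gene == g)
    if (!length(hit)) {
      stop("unknown gene '", g, "'; annotated genes: ",
           paste(sort(unique(gs$key)), collapse = ", "))
    }
    hit <- hit[1L]
    g1 <- (gs$start[hit] - part$offset) %% n
    g2 <- g1 + (gs$end[hit] - gs$start[hit])   # may exceed n (wraps)
    per_junction <- vapply(junctions, function(J) {
      Js <- c(J, J + n)                         # junction images on the circle
      d <- Inf
      for (jj in Js) {
        if (g1 < jj && jj < g2) {
          d_str <- -min(g2 - jj, jj - g1)
          if (abs(d_str) < abs(d)) d <- d_str
        } else {
          gap <- min(circ_dist(g1 %% n, jj %% n, n), circ_dist(g2 %% n, jj %% n, n))
          if (gap < abs(d)) d <- gap
        }
      }
      d
    }, numeric(1L))
    best <- which.min(abs(per_junction))
    data.frame(gene = g, junction = names(junctions)[best],
               distance = as.integer(per_junction[best]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

circ_dist <- function(a, b, n) {
  d <- abs(a - b)
  min(d, n - d)
}
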