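FEATURE_KINDS <- c("protein_coding", "tRNA", "rRNA", "pseudogene")

#' Build a gene annotation table
#'
#' One row per exon, 0-based half-open coordinates, exons in transcription
#' order (\code{exon_rank}).  Duplicate gene names (IR duplicates) are
#' distinguished by \code{copy_tag}.
#'
#' @param df data.frame with columns gene, kind, strand, exon_rank, start,
#'   end and optionally copy_tag.
#' @param genome_length optional; if given, exon coordinates are checked
#'   against it.
#' @return a \code{gene_annotation} data.frame.
#' @export
gene_annotation <- function(df, genome_length = NULL) {
  need <- c("gene", "kind", "strand", "exon_rank", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$copy_tag)) df$copy_tag <- NA_character_
  bad <- setdiff(unique(df$kind), FEATURE_KINDS)
  if (length(bad)) {
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(FEATURE_KINDS, collapse = "/"), ")")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$end <= df$start)) {
    i <- which(df$end <= df$start)[1L]
    stop(sprintf("coordinate error: exon end <= start for gene '%s' (%d..%d)",
                 df$gene[i], df$start[i], df$end[i]))
  }
  if (any(df$start < 0)) stop("coordinate error: negative exon start")
  if (!is.null(genome_length) && any(df$end > genome_length)) {
    i <- which(df$end > genome_length)[1L]
    stop(sprintf("coordinate error: exon of gene '%s' ends at %d, beyond genome length %d",
                 df$gene[i], df$end[i], genome_length))
  }
  key <- paste(df$gene, ifelse(is.na(df$copy_tag), "", df$copy_tag))
  for (k in unique(key)) {
    ex <- df[key == k, , drop = FALSE]
    ir <- IRanges::IRanges(ex$start + 1L, ex$end)
    if (sum(IRanges::width(IRanges::reduce(ir))) != sum(IRanges::width(ir))) {
      stop("overlapping exons within gene '", ex$gene[1L], "'")
    }
  }
  df <- df[order(df$gene, df$copy_tag, df$exon_rank), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read gene annotations from a TSV table or GenBank flat file
#'
#' The TSV format has columns \code{gene}, \code{kind}, \code{exons}
#' (comma-separated \code{start..end}, 1-based inclusive, transcription
#' order), \code{strand}, and optional \code{copy_tag}.  GenBank flat files
#' are parsed for CDS/tRNA/rRNA features (a \code{/pseudo} qualifier maps to
#' kind \code{pseudogene}); duplicate gene names are disambiguated with
#' copy tags "a", "b", ...
#'
#' @param path input file.
#' @param format "auto" (by extension/content), "tsv" or "genbank".
#' @param genome_length optional coordinate bound check.
#' @return a \code{gene_annotation} data.frame (0-based half-open).
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "genbank"),
                            genome_length = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^LOCUS", first)) "genbank" else "tsv"
  }
  if (format == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      ex <- parse_exon_spec(tab$exons[i], tab$gene[i])
      data.frame(gene = tab$gene[i], kind = tab$kind[i], strand = tab$strand[i],
                 copy_tag = if ("copy_tag" %in% names(tab) && nzchar(tab$copy_tag[i]) &&
                               !is.na(tab$copy_tag[i])) tab$copy_tag[i] else NA_character_,
                 exon_rank = seq_len(nrow(ex)), start = ex$start, end = ex$end,
                 stringsAsFactors = FALSE)
    })
    return(gene_annotation(do.call(rbind, rows), genome_length))
  }
  read_annotation_genbank(path, genome_length)
}

# "10..288,300..400" (1-based inclusive) -> 0-based half-open data.frame
parse_exon_spec <- function(spec, gene = "?") {
  parts <- strsplit(trimws(spec), ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^\\s*(\\d+)\\.\\.(\\d+)\\s*$", parts))
  if (any(lengths(m) != 3L)) stop("cannot parse exon spec '", spec, "' of gene ", gene)
  start1 <- as.integer(vapply(m, `[`, "", 2L))
  end1 <- as.integer(vapply(m, `[`, "", 3L))
  if (any(end1 < start1)) {
    stop(sprintf("coordinate error: exon end < start (%s) in gene %s", spec, gene))
  }
  data.frame(start = start1 - 1L, end = end1)
}

# minimal GenBank feature-table reader: CDS, tRNA, rRNA features with
# join()/complement() locations and /gene, /pseudo qualifiers
read_annotation_genbank <- function(path, genome_length = NULL) {
  lines <- readLines(path)
  feat0 <- grep("^FEATURES", lines)
  if (!length(feat0)) stop("GenBank format error: no FEATURES block in ", path)
  end0 <- grep("^(ORIGIN|CONTIG|//)", lines)
  end0 <- if (length(end0)) min(end0[end0 > feat0[1L]]) else length(lines) + 1L
  block <- lines[(feat0[1L] + 1L):(end0 - 1L)]
  starts <- grep("^ {5}\\S", block)
  if (!length(starts)) stop("GenBank format error: empty FEATURES block")
  bounds <- c(starts, length(block) + 1L)
  keep <- c(CDS = "protein_coding", tRNA = "tRNA", rRNA = "rRNA")
  out <- list()
  for (i in seq_along(starts)) {
    chunk <- block[bounds[i]:(bounds[i + 1L] - 1L)]
    key <- sub("^ {5}(\\S+).*", "\\1", chunk[1L])
    if (!key %in% names(keep)) next
    txt <- paste(gsub("^ +", "", chunk), collapse = "")
    loc <- sub(paste0("^", key), "", sub("/.*$", "", txt))
    loc <- gsub(" ", "", loc)
    minus <- grepl("complement\\(", loc)
    loc <- gsub("complement\\(|join\\(|order\\(|\\)|<|>", "", loc)
    iv <- parse_exon_spec(loc, key)
    if (minus) iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
    gene <- if (grepl("/gene=\"", txt)) sub(".*/gene=\"([^\"]+)\".*", "\\1", txt) else key
    kind <- if (grepl("/pseudo", txt, fixed = TRUE)) "pseudogene" else unname(keep[key])
    out[[length(out) + 1L]] <- data.frame(
      gene = gene, kind = kind, strand = if (minus) "-" else "+",
      copy_tag = NA_character_, exon_rank = seq_len(nrow(iv)),
      start = iv$start, end = iv$end, stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("GenBank format error: no CDS/tRNA/rRNA features found")
  df <- do.call(rbind, out)
  # disambiguate IR duplicates
  per_gene <- split(seq_len(nrow(df)), df$gene)
  for (idx in per_gene) {
    firsts <- idx[df$exon_rank[idx] == 1L]
    if (length(firsts) > 1L) {
      grp <- cumsum(df$exon_rank[idx] == 1L)
      df$copy_tag[idx] <- letters[grp]
    }
  }
  gene_annotation(df, genome_length)
}

#' Write a gene annotation table to TSV
#'
#' Inverse of \code{\link{read_annotation}} for the TSV format; writing then
#' re-reading reproduces identical records.
#'
#' @param ann a \code{gene_annotation}.
#' @param path output file.
#' @export
write_annotation <- function(ann, path) {
  sp <- split(seq_len(nrow(ann)), paste(ann$gene, ifelse(is.na(ann$copy_tag), "", ann$copy_tag)))
  rows <- lapply(sp, function(idx) {
    ex <- ann[idx, , drop = FALSE]
    ex <- ex[order(ex$exon_rank), , drop = FALSE]
    data.frame(gene = ex$gene[1L], kind = ex$kind[1L],
               exons = paste(sprintf("%d..%d", ex$start + 1L, ex$end), collapse = ","),
               strand = ex$strand[1L],
               copy_tag = ifelse(is.na(ex$copy_tag[1L]), "", ex$copy_tag[1L]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$gene, tab$copy_tag), , drop = FALSE]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# per-gene overall span and metadata; key distinguishes IR copies
gene_spans <- function(ann) {
  key <- paste0(ann$gene, ifelse(is.na(ann$copy_tag), "", paste0("|", ann$copy_tag)))
  sp <- split(seq_len(nrow(ann)), key)
  do.call(rbind, lapply(names(sp), function(k) {
    idx <- sp[[k]]
    data.frame(key = k, gene = ann$gene[idx[1L]], kind = ann$kind[idx[1L]],
               strand = ann$strand[idx[1L]],
               start = min(ann$start[idx]), end = max(ann$end[idx]),
               n_exons = length(idx), stringsAsFactors = FALSE)
  }))
}

#' Intron count per gene
#' @param ann a \code{gene_annotation}.
#' @return named integer vector (gene key -> number of exon gaps).
#' @export
intron_count <- function(ann) {
  gs <- gene_spans(ann)
  setNames(gs$n_exons - 1L, gs$key)
}

#' Report overlapping gene pairs
#'
#' Every unordered pair of distinct genes whose exon intervals intersect is
#' reported with the total overlapping bp, sorted by overlap length
#' descending (then by gene names for determinism).
#'
#' @param ann a \code{gene_annotation} (one shared coordinate system).
#' @return data.frame with columns gene1, gene2, overlap_bp.
#' @export
gene_overlaps <- function(ann) {
  empty <- data.frame(gene1 = character(0), gene2 = character(0),
                      overlap_bp = integer(0))
  if (is.null(ann) || nrow(ann) == 0L) return(empty)
  key <- paste0(ann$gene, ifelse(is.na(ann$copy_tag), "", paste0("|", ann$copy_tag)))
  sp <- split(seq_len(nrow(ann)), key)
  ks <- sort(names(sp))
  ranges <- lapply(sp, function(idx)
    IRanges::reduce(IRanges::IRanges(ann$start[idx] + 1L, ann$end[idx])))
  out <- list()
  for (i in seq_along(ks)) {
    for (j in seq_len(i - 1L)) {
      ov <- IRanges::intersect(ranges[[ks[i]]], ranges[[ks[j]]])
      w <- sum(IRanges::width(ov))
      if (w > 0L) {
        pair <- sort(c(ks[i], ks[j]))
        out[[length(out) + 1L]] <- data.frame(
          gene1 = pair[1L], gene2 = pair[2L], overlap_bp = w,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$overlap_bp, res$gene1, res$gene2), , drop = FALSE]
  rownames(res) <- NULL
  res
}
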