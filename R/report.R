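# Cross-species comparison reports and the staged pipeline driver.

#' Compare per-species genome summaries
#'
#' Tabulates per-species rows side by side and flags the minimum and
#' maximum species for every numeric metric; on ties no flag is set.
#'
#' @param inputs data.frame with a \code{species} column and one numeric
#'   column per metric (e.g. genome_length, lsc, ssc, ir, gc), or a named
#'   list of such one-row frames.
#' @return a \code{comparison_report}: the input table with an attribute
#'   \code{flags} (data.frame metric, min_species, max_species; NA on
#'   ties).
#' @export
compare_genomes <- function(inputs) {
  if (is.list(inputs) && !is.data.frame(inputs)) {
    inputs <- do.call(rbind, lapply(names(inputs), function(sp) {
      row <- as.data.frame(as.list(inputs[[sp]]), stringsAsFactors = FALSE)
      cbind(data.frame(species = sp, stringsAsFactors = FALSE), row)
    }))
  }
  if (!"species" %in% names(inputs)) stop("schema error: 'species' column required")
  if (nrow(inputs) < 2L) stop("need at least two species to compare")
  if (anyDuplicated(inputs$species)) stop("schema error: duplicate species")
  metrics <- names(inputs)[vapply(inputs, is.numeric, logical(1L))]
  if (!length(metrics)) stop("schema error: no numeric metrics to compare")
  flags <- do.call(rbind, lapply(metrics, function(m) {
    v <- inputs[[m]]
    mn <- which(v == min(v)); mx <- which(v == max(v))
    data.frame(metric = m,
               min_species = if (length(mn) == 1L) inputs$species[mn] else NA_character_,
               max_species = if (length(mx) == 1L) inputs$species[mx] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  structure(inputs, flags = flags, class = c("comparison_report", "data.frame"))
}

#' @export
print.comparison_report <- function(x, ...) {
  print.data.frame(x, ...)
  fl <- attr(x, "flags")
  fl <- fl[!is.na(fl$min_species) | !is.na(fl$max_species), , drop = FALSE]
  if (nrow(fl)) {
    cat("\nExtremes:\n")
    for (r in seq_len(nrow(fl))) {
      cat(sprintf("  %s: min %s, max %s\n", fl$metric[r],
                  fl$min_species[r], fl$max_species[r]))
    }
  }
  invisible(x)
}

#' Run analysis stages over one genome
#'
#' Executes the requested stages in dependency order and writes their
#' outputs (JSON/TSV) under \code{out_dir}.  Outputs contain no timestamps,
#' so a rerun with the same configuration and seed is byte-identical.
#'
#' @param config list with elements \code{genome} (FASTA path or a
#'   \code{\link{plastome}}), optional \code{annotation} (TSV path or a
#'   \code{gene_annotation}), \code{stages} (subset of "partition",
#'   "codon_usage", "repeats"), \code{out_dir}, and optional parameters
#'   \code{min_ir}, \code{min_period}, \code{max_period}, \code{min_copies}.
#' @return named list of per-stage results (also written to files); the
#'   configuration used is logged to \code{config.json}.
#' @export
run_pipeline <- function(config) {
  stages_avail <- c("partition", "codon_usage", "repeats")
  stages <- config$stages %||% stages_avail
  bad <- setdiff(stages, stages_avail)
  if (length(bad)) {
    stop("config error: unknown stage(s) ", paste(bad, collapse = ", "),
         " (available: ", paste(stages_avail, collapse = ", "), ")")
  }
  if (is.null(config$genome)) stop("config error: no genome given")
  genome <- if (inherits(config$genome, "plastome")) config$genome
            else read_genome(config$genome)
  ann <- NULL
  if (!is.null(config$annotation)) {
    ann <- if (inherits(config$annotation, "gene_annotation")) config$annotation
           else read_annotation(config$annotation, genome_length = nchar(genome$seq))
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  log_cfg <- list(genome = genome$id, genome_length = nchar(genome$seq),
                  stages = stages,
                  params = config[intersect(names(config),
                    c("min_ir", "min_period", "max_period", "min_copies", "seed"))])
  jsonlite::write_json(log_cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if ("partition" %in% stages) {
    ir <- detect_inverted_repeat_pair(genome, min_length = config$min_ir %||% 1000L)
    if (is.null(ir)) stop("no inverted repeat pair found at the requested floor")
    part <- partition_quadripartite(genome, ir)
    results$partition <- part
    jsonlite::write_json(
      c(as.list(region_lengths(part)), list(offset = part$offset)),
      file.path(out_dir, "partition.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  if ("codon_usage" %in% stages) {
    if (is.null(ann)) {
      stop("staged error: stage 'codon_usage' requires the missing artifact 'annotation'")
    }
    cu <- rscu(count_codons(extract_cds_codons(genome, ann)))
    results$codon_usage <- cu
    out <- cu
    out$rscu <- round_half_up(out$rscu, 2L)
    write.table(out, file.path(out_dir, "codon_usage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if ("repeats" %in% stages) {
    reps <- find_exact_repeats(genome,
                               min_period = config$min_period %||% 11L,
                               max_period = config$max_period %||% 500L,
                               min_copies = config$min_copies %||% 2L,
                               ann = ann)
    results$repeats <- reps
    write.table(reps, file.path(out_dir, "repeats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(results)
}
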