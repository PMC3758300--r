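# Packaged reference fixtures: plain-text transcriptions of published
# values for the coconut chloroplast genome and the monocot phylogeny used
# for character mapping.  Loaders validate the schema and internal
# consistency of each table before returning it.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "plastkit")
  if (!nzchar(p)) stop("fixture not found: ", file)
  p
}

#' Load a packaged reference fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{codon_usage}{61 sense codons with printed counts, the published
#'     RSCU column and recognizing tRNAs; adds a \code{codon} column with
#'     the DNA form of the printed codon.}
#'   \item{repeats}{the 13 published repeat families (unit, 1-based
#'     positions, copies, type).}
#'   \item{palm_comparison}{genome metrics of six palm chloroplast
#'     genomes, species in columns.}
#'   \item{editing_sites}{110 investigated editing sites with prediction
#'     flag and RT-PCR outcome.}
#'   \item{tree}{the 25-taxon monocot phylogeny (rooted, \code{phylo}).}
#'   \item{tree_characters}{taxon-by-character states for gene
#'     duplication/pseudogenization/loss mapping.}
#' }
#'
#' @param name fixture id (see above).
#' @return the parsed, schema-validated fixture.
#' @export
load_fixture <- function(name = c("codon_usage", "repeats", "palm_comparison",
                                  "editing_sites", "tree", "tree_characters")) {
  name <- match.arg(name)
  switch(name,
    codon_usage = load_codon_usage_fixture(),
    repeats = load_repeats_fixture(),
    palm_comparison = load_palm_comparison_fixture(),
    editing_sites = load_editing_sites_fixture(),
    tree = load_tree_fixture(),
    tree_characters = load_tree_characters_fixture())
}

integrity_fail <- function(what, detail) {
  stop("fixture integrity error in ", what, ": ", detail)
}

load_codon_usage_fixture <- function() {
  tab <- read.delim(fixture_path("cocos_codon_usage.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  tab$codon_printed <- tab$codon
  tab$codon <- chartr("U", "T", toupper(tab$codon))
  if (nrow(tab) != 61L) integrity_fail("codon_usage", paste(nrow(tab), "rows, expected 61"))
  if (anyDuplicated(tab$codon)) integrity_fail("codon_usage", "duplicate codons")
  if (any(tab$codon %in% STOP_CODONS)) integrity_fail("codon_usage", "stop codon present")
  fam <- codon_families()
  if (!setequal(tab$codon, names(fam$aa))) {
    integrity_fail("codon_usage", "codon set is not the 61 sense codons")
  }
  if (any(tab$count < 0) || any(tab$count != as.integer(tab$count))) {
    integrity_fail("codon_usage", "counts must be non-negative integers")
  }
  tab
}

load_repeats_fixture <- function() {
  tab <- read.delim(fixture_path("cocos_repeats.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  if (nrow(tab) != 13L) integrity_fail("repeats", paste(nrow(tab), "rows, expected 13"))
  pos <- strsplit(tab$positions, ",\\s*")
  if (!all(lengths(pos) == tab$copies)) {
    integrity_fail("repeats", "copy count does not match number of positions")
  }
  if (!all(nchar(tab$unit) == tab$size_bp)) {
    integrity_fail("repeats", "unit length does not match size_bp")
  }
  if (!all(tab$size_bp > 10L & tab$size_bp <= 500L)) {
    integrity_fail("repeats", "period outside (10, 500]")
  }
  if (!all(tab$type %in% c("T", "D", "I"))) integrity_fail("repeats", "bad type")
  tab
}

load_palm_comparison_fixture <- function() {
  tab <- read.delim(fixture_path("palm_genome_comparison.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  species <- setdiff(names(tab), "characteristic")
  if (length(species) != 6L) integrity_fail("palm_comparison", "expected six species")
  if (!"Cocos" %in% species) integrity_fail("palm_comparison", "Cocos column missing")
  size <- tab[tab$characteristic == "size_bp", species]
  lsc <- tab[tab$characteristic == "lsc_bp", species]
  ssc <- tab[tab$characteristic == "ssc_bp", species]
  ir <- tab[tab$characteristic == "ir_bp", species]
  if (!all(size == lsc + ssc + ir)) {
    integrity_fail("palm_comparison", "regions do not sum to genome size")
  }
  tab
}

load_editing_sites_fixture <- function() {
  tab <- read.delim(fixture_path("cocos_editing_sites.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  if (!all(tab$codon_position %in% 1:3)) integrity_fail("editing_sites", "bad codon position")
  if (!all(tab$rtpcr %in% c("edited", "partial", "unedited", "untested"))) {
    integrity_fail("editing_sites", "bad rtpcr state")
  }
  if (!all(nchar(tab$codon_genomic) == 3L & nchar(tab$codon_edited) == 3L)) {
    integrity_fail("editing_sites", "codons must be triplets")
  }
  tab$predicted <- tab$predicted == 1L
  tab$shared_oil_palm <- tab$shared_oil_palm == 1L
  if (nrow(tab) != 110L) integrity_fail("editing_sites", paste(nrow(tab), "rows, expected 110"))
  tab
}

load_tree_fixture <- function() {
  tr <- read_newick(fixture_path("monocot_tree.nwk"))
  if (length(tr$tip.label) != 25L) {
    integrity_fail("tree", paste(length(tr$tip.label), "leaves, expected 25"))
  }
  tr
}

load_tree_characters_fixture <- function() {
  chars <- read_character_matrix(fixture_path("monocot_characters.tsv"))
  tr <- load_tree_fixture()
  if (!setequal(rownames(chars), tr$tip.label)) {
    integrity_fail("tree_characters", "taxa do not match the tree leaves")
  }
  chars
}

#' Build repeat-fixture generator records from the packaged repeat table
#'
#' Converts the published repeat rows into \code{\link{make_repeat_fixture}}
#' records: inter-copy gaps are derived from the printed start positions,
#' inverted partner rows are linked to their primaries, and the 3-bp gap
#' between the two copies of the 30-bp direct repeat is fixed to "TAC" --
#' the unique spacer consistent with the printed coordinates of the nested
#' 19-bp tandem at that locus (which detection then recovers as its own
#' family without it being planted).
#'
#' @param rows which fixture rows to include (default: all except the
#'   nested 19-bp tandem, which emerges from the 30-bp repeat's locus).
#' @return a records data.frame for \code{\link{make_repeat_fixture}}.
#' @export
repeat_records_from_reference <- function(rows = c(1:6, 8:13)) {
  tab <- load_repeats_fixture()
  tab <- tab[tab$no %in% rows, , drop = FALSE]
  gaps <- vapply(seq_len(nrow(tab)), function(i) {
    p <- as.integer(strsplit(tab$positions[i], ",\\s*")[[1L]])
    if (length(p) < 2L) return("")
    paste(diff(p) - tab$size_bp[i], collapse = ",")
  }, character(1L))
  gap_seq <- ifelse(tab$no == 1L, "TAC", "")
  # inverted partners share their primary's unit (or its reverse
  # complement); link them for the repeat-freeness whitelist
  group <- tab$no
  for (i in which(tab$type == "I" & tab$copies == 1L)) {
    prim <- which(tab$unit == tab$unit[i] & tab$copies > 1L)
    if (length(prim)) group[i] <- group[prim[1L]]
  }
  data.frame(unit = tab$unit, copies = tab$copies, type = tab$type,
             gaps = gaps, gap_seq = gap_seq, group = group,
             no = tab$no, stringsAsFactors = FALSE)
}
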