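# Codon extraction, counting and RSCU.

toy_genome_ann <- function() {
  # plus-strand gene, minus-strand gene, and a two-exon gene split
  # mid-codon; pseudogene and tRNA must be skipped
  plus <- "ATGAAATAA"
  minus_cds <- "ATGTTCGGA"              # appears reverse-complemented
  split_cds <- "ATGCCTGACTTT"           # split after 5 nt (mid-codon)
  seqs <- paste0(plus, "GGGG", revcomp(minus_cds), "GGGG",
                 substr(split_cds, 1, 5), "AACC", substr(split_cds, 6, 12),
                 "GGGG", "ATGCAT")
  g <- plastome(seqs, circular = FALSE)
  ann <- gene_annotation(data.frame(
    gene = c("plus", "minus", "split", "split", "pseudo", "trn"),
    kind = c("protein_coding", "protein_coding", "protein_coding",
             "protein_coding", "pseudogene", "tRNA"),
    strand = c("+", "-", "+", "+", "+", "+"),
    exon_rank = c(1L, 1L, 1L, 2L, 1L, 1L),
    start = c(0L, 13L, 26L, 35L, 46L, 46L),
    end = c(9L, 22L, 31L, 42L, 52L, 52L)))
  list(g = g, ann = ann)
}

test_that("CDS codons splice exons, honor strand, and skip non-coding", {
  fx <- toy_genome_ann()
  cds <- extract_cds_codons(fx$g, fx$ann)
  expect_setequal(names(cds), c("plus", "minus", "split"))
  expect_equal(cds$plus, c("ATG", "AAA", "TAA"))
  expect_equal(cds$minus, c("ATG", "TTC", "GGA"))
  expect_equal(cds$split, c("ATG", "CCT", "GAC", "TTT"))
})

test_that("length remainders and N codons are dropped with warnings", {
  g <- plastome("ATGAAAT", circular = FALSE)
  ann <- gene_annotation(data.frame(gene = "x", kind = "protein_coding",
                                    strand = "+", exon_rank = 1L,
                                    start = 0L, end = 7L))
  expect_warning(cds <- extract_cds_codons(g, ann), "not a multiple of 3")
  expect_equal(cds$x, c("ATG", "AAA"))

  gn <- plastome("ATGANAAAA", circular = FALSE)
  annn <- gene_annotation(data.frame(gene = "x", kind = "protein_coding",
                                     strand = "+", exon_rank = 1L,
                                     start = 0L, end = 9L))
  expect_warning(cdsn <- extract_cds_codons(gn, annn), "contain N")
  expect_equal(cdsn$x, c("ATG", "AAA"))
})

test_that("count_codons excludes stops, aggregates and validates input", {
  tab <- count_codons(list(a = c("ATG", "AAA", "TAA"), b = c("AAA", "TGA")))
  expect_equal(tab$count[tab$codon == "AAA"], 2L)
  expect_false(any(c("TAA", "TAG", "TGA") %in% tab$codon))
  expect_equal(sum(tab$count), 3L)
  expect_equal(nrow(tab), 61L)
  expect_error(count_codons(c("AT", "AAA")), "non-triplet")
  empty <- count_codons(list())
  expect_equal(sum(empty$count), 0L)
})

test_that("count_codons is invariant under gene order permutation", {
  genes <- list(a = c("ATG", "AAA"), b = c("TTT", "AAA"), c = c("GGG", "CCC"))
  t1 <- count_codons(genes)
  t2 <- count_codons(genes[c(3, 1, 2)])
  expect_equal(t1$count, t2$count)
})

test_that("RSCU follows the standard definition", {
  # uniform counts across a 4-fold family -> all RSCU 1
  tab <- count_codons(rep(c("GGA", "GGC", "GGG", "GGT"), 5))
  r <- rscu(tab)
  expect_equal(r$rscu[r$aa == "G"], rep(1, 4))
  # single-codon families get 1 when counted, NA totals stay NA
  tabm <- count_codons(c("ATG", "TGG"))
  rm_ <- rscu(tabm)
  expect_equal(rm_$rscu[rm_$codon == "ATG"], 1)
  expect_true(is.na(rm_$rscu[rm_$codon == "GGG"]))
})

test_that("RSCU on the reference counts matches printed two-fold values and the standard 6-fold value", {
  fix <- load_fixture("codon_usage")
  counts <- rep(fix$codon, fix$count)
  r <- rscu(count_codons(counts))
  # Phe, printed two decimals
  expect_equal(round_half_up(r$rscu[r$codon == "TTT"], 2), 1.23)
  expect_equal(round_half_up(r$rscu[r$codon == "TTC"], 2), 0.77)
  # Leu UUA under the standard formula: 785 * 6 / 2624
  expect_equal(round_half_up(r$rscu[r$codon == "TTA"], 2),
               round_half_up(785 * 6 / 2624, 2))
  expect_equal(round_half_up(785 * 6 / 2624, 2), 1.79)
})

test_that("family mean RSCU equals 1 for every counted family", {
  fix <- load_fixture("codon_usage")
  r <- rscu(count_codons(rep(fix$codon, fix$count)))
  for (aa in unique(r$aa)) {
    fam <- r$rscu[r$aa == aa]
    if (all(!is.na(fam))) expect_equal(mean(fam), 1, tolerance = 1e-12)
  }
  # random counts, several seeds
  for (seed in 1:5) {
    set.seed(seed)
    codons <- sample(r$codon, 500, replace = TRUE)
    rr <- rscu(count_codons(codons))
    for (aa in unique(rr$aa[rr$count > 0])) {
      fam <- rr$rscu[rr$aa == aa]
      tot <- sum(rr$count[rr$aa == aa])
      if (tot > 0) expect_equal(mean(fam), 1, tolerance = 1e-12)
    }
  }
})

test_that("aa totals conserve the counted triplets", {
  fix <- load_fixture("codon_usage")
  tab <- count_codons(rep(fix$codon, fix$count))
  expect_equal(sum(attr(tab, "aa_totals")), sum(tab$count))
  expect_equal(sum(tab$count), sum(fix$count))
})

test_that("third-position A/T share behaves on degenerate families", {
  only_at <- count_codons(c("GGA", "GGT", "GGA"))
  expect_equal(third_position_at_bias(only_at), 1)
  uniform <- count_codons(rep(c("GGA", "GGC", "GGG", "GGT"), 3))
  expect_equal(third_position_at_bias(uniform), 0.5)
  fix <- load_fixture("codon_usage")
  bias <- third_position_at_bias(count_codons(rep(fix$codon, fix$count)))
  expect_gt(bias, 0.5)   # AT bias direction at synonymous third positions
})
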