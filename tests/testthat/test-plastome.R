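# Core sequence model, FASTA/annotation I/O, composition and overlaps.

test_that("read_genome normalizes case and RNA and rejects bad input", {
  f <- write_temp_fasta("acgt")
  g <- read_genome(f)
  expect_equal(g$seq, "ACGT")
  expect_equal(length(g), 4L)

  f2 <- write_temp_fasta("ACGU")
  expect_equal(read_genome(f2)$seq, "ACGT")

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_genome(empty), "format error")

  expect_error(plastome("ACGXT"), "position 4")
  expect_error(plastome(""), "empty")
})

test_that("gc_content matches a per-base tally and complements at_content", {
  expect_equal(gc_content(plastome("GGCC")), 1.0)
  expect_equal(gc_content(plastome("ATAT")), 0.0)
  set.seed(71)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE,
                    prob = c(0.32, 0.18, 0.19, 0.31)), collapse = "")
  g <- plastome(s)
  sv <- oracle_chars(s)
  expect_equal(gc_content(g), sum(sv %in% c("G", "C")) / length(sv))
  expect_equal(gc_content(g), 1 - at_content(g))
  w <- c(100L, 1100L)
  svw <- sv[101:1100]
  expect_equal(gc_content(g, w), sum(svw %in% c("G", "C")) / 1000)
  # N excluded from the denominator
  gn <- plastome("GGNNAA")
  expect_equal(gc_content(gn), 0.5)
  expect_error(gc_content(g, c(5L, 5L)), "zero-length")
})

test_that("plastome_subseq wraps the origin on circular genomes only", {
  g <- plastome("ACGTTGCA")
  expect_equal(plastome_subseq(g, 6L, 10L), "CAAC")
  lin <- plastome("ACGTTGCA", circular = FALSE)
  expect_error(plastome_subseq(lin, 6L, 10L), "linear")
})

test_that("annotation TSV round-trips and validates coordinates", {
  df <- data.frame(
    gene = c("rps19", "ycf3", "ycf3", "ndhB", "ndhB"),
    kind = c("protein_coding", "protein_coding", "protein_coding", "protein_coding", "protein_coding"),
    strand = c("+", "+", "+", "-", "-"),
    copy_tag = c(NA, NA, NA, "a", "a"),
    exon_rank = c(1L, 1L, 2L, 1L, 2L),
    start = c(9L, 100L, 200L, 400L, 300L),
    end = c(288L, 150L, 260L, 450L, 350L),
    stringsAsFactors = FALSE)
  ann <- gene_annotation(df, genome_length = 1000L)
  f <- tempfile(fileext = ".tsv")
  write_annotation(ann, f)
  ann2 <- read_annotation(f)
  o1 <- as.data.frame(ann)[order(ann$gene, ann$exon_rank), ]
  o2 <- as.data.frame(ann2)[order(ann2$gene, ann2$exon_rank), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
  expect_equal(unname(intron_count(ann)[c("ndhB|a", "rps19", "ycf3")]), c(1L, 0L, 1L))
})

test_that("read_annotation reports coordinate and schema errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tkind\texons\tstrand", "rps19\tprotein_coding\t10..288\t+"), f)
  a <- read_annotation(f)
  expect_equal(nrow(a), 1L)
  expect_equal(a$start, 9L)
  expect_equal(a$end, 288L)

  writeLines(c("gene\tkind\texons\tstrand", "bad\tprotein_coding\t50..10\t+"), f)
  expect_error(read_annotation(f), "coordinate error")

  writeLines(c("gene\tkind\texons\tstrand", "x\tmystery\t1..9\t+"), f)
  expect_error(read_annotation(f), "unknown feature kind")

  writeLines(c("gene\tkind\texons\tstrand", "x\tprotein_coding\t1..999\t+"), f)
  expect_error(read_annotation(f, genome_length = 100L), "beyond genome length")
})

test_that("GenBank features parse with joins, strands and pseudo flags", {
  gb <- c("LOCUS test 100 bp DNA",
          "FEATURES             Location/Qualifiers",
          "     source          1..100",
          "     CDS             join(10..30,41..60)",
          "                     /gene=\"ycf3\"",
          "     tRNA            complement(70..90)",
          "                     /gene=\"trnH\"",
          "     CDS             5..25",
          "                     /gene=\"rps19\"",
          "                     /pseudo",
          "ORIGIN", "//")
  f <- tempfile(fileext = ".gb")
  writeLines(gb, f)
  a <- read_annotation(f, genome_length = 100L)
  expect_equal(sort(unique(a$gene)), c("rps19", "trnH", "ycf3"))
  expect_equal(a$kind[a$gene == "rps19"], "pseudogene")
  expect_equal(a$strand[a$gene == "trnH"], "-")
  expect_equal(unname(intron_count(a)["ycf3"]), 1L)
})

test_that("gene_overlaps reports intersecting pairs sorted and symmetric", {
  ann <- gene_annotation(data.frame(
    gene = c("atpE", "atpB", "ndhF", "ycf1_pseudo", "far"),
    kind = c(rep("protein_coding", 3L), "pseudogene", "protein_coding"),
    strand = "+", exon_rank = 1L,
    start = c(0L, 96L, 300L, 443L, 900L),
    end = c(100L, 200L, 500L, 700L, 950L)))
  ov <- gene_overlaps(ann)
  expect_equal(ov$overlap_bp, c(57L, 4L))
  expect_equal(ov$gene1[2L], "atpB")
  expect_equal(ov$gene2[2L], "atpE")
  expect_equal(ov$gene1[1L], "ndhF")
  # invariant under permutation of the annotation rows
  set.seed(5)
  for (i in 1:5) {
    sh <- ann[sample(nrow(ann)), ]
    class(sh) <- class(ann)
    expect_equal(gene_overlaps(sh), ov)
  }
  expect_equal(nrow(gene_overlaps(ann[ann$gene == "far", ])), 0L)
})

test_that("flag_truncated_copy flags shortened IR-junction copies", {
  expect_true(flag_truncated_copy(174, 279))
  expect_false(flag_truncated_copy(279, 279))
  expect_false(flag_truncated_copy(280, 279))
  expect_true(flag_truncated_copy(250, 279, threshold = 0.95))
  expect_false(flag_truncated_copy(270, 279, threshold = 0.95))
})
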