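# Exact repeat discovery and classification.

test_that("an embedded three-copy tandem is recovered with its period", {
  rec <- repeat_records_from_reference(rows = 2)
  fx <- make_repeat_fixture(rec, seed = 7)
  det <- suppressWarnings(find_exact_repeats(fx$genome))
  expect_equal(nrow(det), 1L)
  expect_equal(det$period, 24L)
  expect_equal(det$copies, 3L)
  expect_equal(det$type, "T")
  expect_equal(det$positions, fx$truth$positions)
  expect_equal(det$unit, fx$truth$unit)
})

test_that("a repeat-free sequence yields an empty result", {
  set.seed(19)
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
    if (!nrow(oracle_pairs_same(s, 11L)) && !nrow(oracle_pairs_inverted(s, 11L))) break
  }
  det <- suppressWarnings(find_exact_repeats(plastome(s, circular = FALSE)))
  expect_equal(nrow(det), 0L)
})

test_that("detection equals the O(n^2) diagonal-scan oracle on random sequences", {
  set.seed(500)
  n_checked <- 0L
  for (seed in 1:50) {
    set.seed(seed + 3000L)
    n <- sample(200:500, 1L)
    # low-complexity alphabet mixture raises chance repeat density
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    det <- suppressWarnings(find_exact_repeats(plastome(s, circular = FALSE)))
    orc <- oracle_repeat_families(s)
    expect_equal(det[, c("unit", "copies", "positions", "type")],
                 orc[, c("unit", "copies", "positions", "type")],
                 info = paste("seed", seed))
    n_checked <- n_checked + nrow(orc)
  }
  expect_gt(n_checked, 0L)   # the sweep must have exercised nonempty cases
})

test_that("maximal pair finding matches the oracle pair set", {
  for (seed in 1:10) {
    set.seed(seed + 900L)
    s <- paste(sample(c("A", "T", "G"), 300, replace = TRUE), collapse = "")
    imp <- plastkit:::same_strand_maximal_pairs(s, 11L)
    orc <- oracle_pairs_same(s, 11L)
    imp <- imp[order(imp$i, imp$j), ]; rownames(imp) <- NULL
    orc <- orc[order(orc$i, orc$j), ]; rownames(orc) <- NULL
    expect_equal(imp, orc)
  }
})

test_that("families are strand symmetric", {
  rec <- repeat_records_from_reference(rows = c(5, 6, 9, 10))
  fx <- make_repeat_fixture(rec, seed = 23)
  det_f <- suppressWarnings(find_exact_repeats(fx$genome))
  det_r <- suppressWarnings(find_exact_repeats(
    plastome(revcomp(fx$genome$seq), circular = FALSE)))
  expect_equal(nrow(det_f), nrow(det_r))
  expect_equal(sort(table(det_f$type)), sort(table(det_r$type)))
  # every unit reappears as itself or its reverse complement
  for (u in det_f$unit) {
    expect_true(u %in% det_r$unit || revcomp(u) %in% det_r$unit)
  }
})

test_that("tandem copies reconstruct the genome substring exactly", {
  rec <- repeat_records_from_reference(rows = c(4, 12, 13))
  fx <- make_repeat_fixture(rec, seed = 3)
  det <- suppressWarnings(find_exact_repeats(fx$genome))
  tand <- det[det$type == "T", , drop = FALSE]
  expect_gt(nrow(tand), 0L)
  for (r in seq_len(nrow(tand))) {
    pos <- as.integer(strsplit(tand$positions[r], ",\\s*")[[1L]])
    adj <- pos[c(diff(pos) == tand$period[r], FALSE) | c(FALSE, diff(pos) == tand$period[r])]
    arr <- paste(rep(tand$unit[r], length(adj)), collapse = "")
    expect_equal(substr(fx$genome$seq, adj[1L], adj[1L] + nchar(arr) - 1L), arr)
  }
})

test_that("the published record set classifies as 8 tandem / 3 direct / 2 inverted", {
  tab <- load_fixture("repeats")
  cl <- classify_repeats(tab)
  counts <- table(cl$type)
  expect_equal(unname(counts[["T"]]), 8L)
  expect_equal(unname(counts[["D"]]), 3L)
  expect_equal(unname(counts[["I"]]), 2L)
  # re-derived types agree with the published column
  expect_equal(cl$type, tab$type)
})

test_that("classification rules cover adjacency, separation and partners", {
  rec <- data.frame(unit = c("ACGTACGTACGT", "ACGTACGTACGT", "TTTTAAAACCCCG"),
                    positions = c("1, 13", "100, 150", "400"),
                    stringsAsFactors = FALSE)
  cl <- classify_repeats(rec[1:2, ])
  expect_equal(cl$type, c("T", "D"))
  # single occurrence with a reverse-complement partner present
  rec2 <- data.frame(unit = c("TTTTAAAACCCCG", "CGGGGTTTTAAAA"),
                     positions = c("10, 60", "400"))
  cl2 <- classify_repeats(rec2)
  expect_equal(cl2$type, c("D", "I"))
  # single occurrence without partner is dropped with a warning
  expect_warning(cl3 <- classify_repeats(rec[3, , drop = FALSE]), "no reverse-complement partner")
  expect_equal(nrow(cl3), 0L)
})

test_that("round trips recover planted families and the emergent nested tandem", {
  recA <- repeat_records_from_reference(rows = c(1, 5, 6, 8, 9, 10, 11))
  fxA <- make_repeat_fixture(recA, seed = 1)
  detA <- suppressWarnings(find_exact_repeats(fxA$genome))
  # all planted rows are recovered verbatim
  for (r in seq_len(nrow(fxA$truth))) {
    hit <- detA[detA$unit == fxA$truth$unit[r] & detA$positions == fxA$truth$positions[r], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$type, fxA$truth$type[r])
  }
  # the 19-bp nested tandem emerges at offset 14 of the 30-bp repeat locus,
  # sharing its second start with the outer repeat's second copy
  nested <- detA[detA$period == 19L, ]
  expect_equal(nrow(nested), 1L)
  expect_equal(nested$type, "T")
  outer_start <- as.integer(strsplit(
    fxA$truth$positions[fxA$truth$period == 30L], ",\\s*")[[1L]])
  nested_pos <- as.integer(strsplit(nested$positions, ",\\s*")[[1L]])
  expect_equal(nested_pos, c(outer_start[1L] + 14L, outer_start[2L]))
  expect_equal(nrow(detA), nrow(fxA$truth) + 1L)
})

test_that("max_period filters the plastome-scale IR out of repeat reports", {
  out <- make_quadripartite_genome(lsc = 3000L, ssc = 800L, ir_total = 2400L,
                                  seed = 2L)
  det <- find_exact_repeats(out$genome, min_period = 11L, max_period = 500L)
  expect_false(any(det$period > 500L))
})
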