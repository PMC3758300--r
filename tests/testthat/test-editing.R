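# C-to-U editing prediction and summary statistics.

test_that("editing_score is the edited-residue support fraction", {
  # TCA (S) -> TTA (L)
  expect_equal(editing_score("TCA", 2, rep("L", 10)), 1.0)
  expect_equal(editing_score("TCA", 2, rep("S", 10)), 0.0)
  expect_equal(editing_score("TCA", 2, c(rep("L", 8), rep("S", 2))), 0.8)
  # references matching neither residue are excluded from the denominator
  expect_equal(editing_score("TCA", 2, c("L", "L", "G", "-")), 1.0)
  expect_equal(editing_score("TCA", 2, c("G", "A", "-")), 0)
  # silent candidate (CTG -> TTG, both Leu) scores 0 regardless of support
  expect_equal(editing_score("CTG", 1, rep("L", 10)), 0)
  expect_error(editing_score("TAA", 2, "L"), "not a candidate")
})

test_that("prediction is inclusive at the cutoff and ordered by position", {
  panel10 <- homolog_panel("g", do.call(rbind, replicate(10, c("M", "L", "S"), simplify = FALSE)))
  cds <- c("ATG", "TCA", "TCT")   # TCA -> TTA (L) supported; TCT columns S
  pred <- predict_editing_sites(cds, panel10, cutoff = 0.8)
  expect_equal(pred$cds_position, 5L)
  expect_equal(pred$codon_edited, "TTA")
  # boundary: 8/10 support is predicted at 0.8, 7/10 is not
  p8 <- homolog_panel("g", do.call(rbind, replicate(10, c("M", "L", "S"), simplify = FALSE)))
  p8$residues[9:10, 2] <- "S"
  expect_equal(nrow(predict_editing_sites(cds, p8, 0.8)), 1L)
  p7 <- p8; p7$residues[8, 2] <- "S"
  expect_equal(nrow(predict_editing_sites(cds, p7, 0.8)), 0L)
})

test_that("an ACG start codon edits to ATG under full reference support", {
  cds <- c("ACG", "GAT")
  panel <- homolog_panel("ndhD-like",
                         do.call(rbind, replicate(10, c("M", "D"), simplify = FALSE)))
  pred <- predict_editing_sites(cds, panel, 0.8)
  expect_equal(pred$cds_position, 2L)
  expect_equal(pred$codon_genomic, "ACG")
  expect_equal(pred$codon_edited, "ATG")
  expect_equal(pred$aa_to, "M")
})

test_that("a panel identical to the target predicts nothing", {
  mk <- make_homolog_panel(60, data.frame(codon_index = integer(0), support = numeric(0)),
                           seed = 4)
  expect_equal(nrow(predict_editing_sites(mk$cds, mk$panel, 0.8)), 0L)
})

test_that("planted edits are recovered perfectly at support above cutoff", {
  set.seed(12)
  idx <- sort(sample(2:199, 20))
  mk <- make_homolog_panel(200, data.frame(codon_index = idx, support = 0.9),
                           background_support = 0.5, seed = 13)
  pred <- predict_editing_sites(mk$cds, mk$panel, 0.8)
  expect_equal(pred$cds_position, mk$truth$cds_position)   # sensitivity 1
  expect_equal(nrow(pred), 20L)                            # specificity 1
  # support below the cutoff is never called
  mk2 <- make_homolog_panel(100, data.frame(codon_index = c(10, 40), support = 0.79),
                            seed = 14)
  expect_equal(nrow(predict_editing_sites(mk2$cds, mk2$panel, 0.8)), 0L)
})

test_that("raising the cutoff never adds predicted sites", {
  mk <- make_homolog_panel(150, data.frame(codon_index = c(5, 30, 70, 110),
                                           support = c(0.6, 0.8, 0.9, 1.0)),
                           background_support = 0.3, seed = 15)
  cuts <- c(0.2, 0.5, 0.8, 0.9, 1.0)
  sets <- lapply(cuts, function(ct)
    predict_editing_sites(mk$cds, mk$panel, ct)$cds_position)
  for (i in seq_along(cuts)[-1L]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1L]]))
  }
})

test_that("hydropathy transitions classify as published", {
  expect_equal(classify_property_change("S", "L"), "hydrophilic->hydrophobic")
  expect_equal(classify_property_change("P", "L"), "hydrophobic->hydrophobic")
  expect_equal(classify_property_change("P", "S"), "hydrophobic->hydrophilic")
  expect_equal(classify_property_change("D", "F"), "hydrophilic->hydrophobic")
  expect_equal(classify_property_change("H", "Y"), "hydrophilic->hydrophobic")
  expect_error(classify_property_change("S", "B"), "unknown residue")
})

test_that("summary respects confirmed_states and conserves counts", {
  sites <- load_fixture("editing_sites")
  s <- summarize_editing(sites)
  expect_equal(sum(s$by_codon_position$counts), s$total)
  expect_equal(sum(s$property_transitions), s$total - s$silent_count)
  expect_equal(s$predicted_and_confirmed + s$unpredicted_confirmed, s$total)
  # strict confirmation drops partial sites
  strict <- summarize_editing(sites, confirmed_states = "edited")
  expect_lt(strict$total, s$total)
  expect_equal(strict$total, sum(sites$rtpcr == "edited"))
  # empty input is an all-zero summary, not an error
  z <- summarize_editing(sites[0, ])
  expect_equal(z$total, 0L)
  expect_equal(sum(z$property_transitions), 0L)
})

test_that("the validator flags rows inconsistent with their codon strings", {
  sites <- load_fixture("editing_sites")
  v <- validate_editing_rows(sites)
  # published rows whose printed amino acids disagree with the codons
  bad_aa <- v[!v$aa_consistent, ]
  expect_true(all(c("ndhH", "rps3") %in% bad_aa$gene))
  # a consistent row stays consistent
  row_ok <- v[v$gene == "atpA" & v$cds_position == 914, ]
  expect_true(row_ok$aa_consistent && row_ok$position_consistent)
  # counts are driven by printed fields, so the summary is unchanged
  expect_equal(summarize_editing(v)$total, summarize_editing(sites)$total)
})
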