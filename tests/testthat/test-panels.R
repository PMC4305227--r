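test_that("min_fold takes the minimum only under a consistent direction", {
  fos <- min_fold(c(27.4, 28.6, 33.5, 34.9, 13.2, 13.7), rep("up", 6))
  expect_equal(fos$fold, 13.2)
  expect_equal(fos$direction, "up")
  expect_equal(min_fold(c(5, 5, 5, 5), rep("up", 4))$fold, 5)
  conflict <- min_fold(c(5, 5, 5, 5), c("up", "up", "down", "up"))
  expect_equal(conflict$direction, "disqualified")
  expect_true(is.na(conflict$fold))
  flat <- min_fold(c(1, 2), c("flat", "flat"))
  expect_equal(flat$direction, "disqualified")
})

test_that("panel selection matches an exhaustive per-gene oracle on random tables", {
  spec <- panel_spec("aecopd_specific", up_threshold = 3, down_threshold = 2)
  rec <- random_records(paste0("g", 1:100), spec$comparisons, seed = 21)
  panel <- select_panel(rec, spec)
  expect_equal(sort(panel$up$gene_id),
               sort(panel_oracle(rec, spec$comparisons, "up", 3)))
  expect_equal(sort(panel$down$gene_id),
               sort(panel_oracle(rec, spec$comparisons, "down", 2)))
  # ordered by min fold descending
  expect_true(all(diff(panel$up$min_fold) <= 0))
  expect_true(all(diff(panel$down$min_fold) <= 0))
})

test_that("panels are nested in the threshold and empty at infinite threshold", {
  spec4 <- panel_spec("copd_specific", 4, 4)
  rec <- random_records(paste0("g", 1:80), spec4$comparisons, seed = 3)
  loose <- select_panel(rec, spec4)
  tight <- select_panel(rec, panel_spec("copd_specific", 8, 8))
  expect_true(all(tight$up$gene_id %in% loose$up$gene_id))
  expect_true(all(tight$down$gene_id %in% loose$down$gene_id))
  inf <- select_panel(rec, panel_spec("copd_specific", Inf, 4))
  expect_equal(nrow(inf$up), 0)
})

test_that("genes missing a panel comparison are an error", {
  spec <- panel_spec("copd_specific", 2, 2)
  rec <- random_records("g1", spec$comparisons[-1], seed = 1)
  expect_error(select_panel(rec, spec), "missing one or more")
})

test_that("the published COPD-specific example yields 14 up and 2 down tenfold survivors", {
  w <- example_copd_panel_folds()
  rec <- as_fold_records(w, panel_spec("copd_specific")$comparisons)
  panel <- select_panel(rec, panel_spec("copd_specific", 10, 10),
                        symbols = stats::setNames(w$symbol, w$seq_id))
  expect_equal(nrow(panel$up), 14)
  expect_equal(nrow(panel$down), 2)
  expect_setequal(
    w$symbol[match(panel$down$gene_id, w$seq_id)], c("TFCP2L1", "SCP2"))
})

test_that("the published AECOPD-specific example yields 8 up and 8 down survivors with symbol dedup", {
  w <- example_aecopd_panel_folds()
  rec <- as_fold_records(w, panel_spec("aecopd_specific")$comparisons)
  panel <- select_panel(rec, panel_spec("aecopd_specific", 10, 3),
                        symbols = stats::setNames(w$symbol, w$seq_id))
  expect_equal(panel$counts$rows, c(8L, 8L))
  # two sequences each for SH2D1B and CD8B: six distinct down symbols
  expect_equal(panel$counts$symbols, c(8L, 6L))
  expect_equal(panel$up$min_fold[panel$up$gene_id == "BC004490"], 13.2)
  expect_output(print(panel), "up:   8 row")
})

test_that("parameter recovery: planted exacerbation genes are found with high sensitivity and precision", {
  cfg <- simulation_config(
    n_subjects_per_arm = 6, n_genes = 1000, noise_sd = 0.25,
    planted_aecopd = list(list(n = 50, fold = 12, direction = "up")),
    seed = 2024)
  study <- generate_study(cfg)
  # simulated intensities share one scale by construction, so recovery is
  # measured on the summarized log2 data without cross-sample renormalization
  genes <- summarize_probes(log2_transform(study$probes), study$annotation)
  rec <- fold_change_all(genes, study$design,
                         panel_spec("aecopd_specific")$comparisons)
  panel <- select_panel(rec, panel_spec("aecopd_specific", 10, 10))
  truth <- study$truth$gene_id[study$truth$label == "aecopd_specific_up"]
  tp <- length(intersect(panel$up$gene_id, truth))
  sensitivity <- tp / length(truth)
  precision <- tp / max(nrow(panel$up), 1)
  expect_gte(sensitivity, 0.85)
  expect_gte(precision, 0.85)
})
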