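test_that("configuration invariants are enforced", {
  expect_error(simulation_config(), "seed is required")
  expect_error(simulation_config(n_genes = 0, seed = 1), "positive")
  expect_error(simulation_config(seed = 1, planted_copd = list(
    list(n = 5, fold = 1, direction = "up"))), "> 1")
  expect_error(simulation_config(n_genes = 10, seed = 1, planted_aecopd = list(
    list(n = 11, fold = 2, direction = "up"))), "exceed n_genes")
})

test_that("generation is deterministic given the seed and has the designed shape", {
  cfg <- tiny_config(noise_sd = 0.3)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$probes, s2$probes)
  expect_identical(s1$design, s2$design)
  expect_equal(dim(s1$probes), c(40 * 2, 3 * 5))
  expect_true(all(s1$probes > 0))
  # the three AE groups share subjects, one sample per day
  ae <- s1$design[s1$design$group %in% c("AE1", "AE3", "AE10"), ]
  expect_equal(as.integer(table(ae$subject_id)), rep(3L, 3))
  expect_equal(sort(unique(s1$design$group)), sort(study_groups()))
})

test_that("with no planted signal and zero noise every pairwise fold is 1", {
  study <- generate_study(tiny_config())
  genes <- summarize_probes(log2_transform(study$probes), study$annotation)
  rec <- fold_change_all(genes, study$design)
  expect_equal(rec$ratio, rep(1, nrow(rec)), tolerance = 1e-9)
  expect_true(all(study$truth$label == "null"))
})

test_that("planted genes carry their fold exactly in the designated comparisons and nowhere else", {
  cfg <- tiny_config(
    planted_copd = list(list(n = 3, fold = 6, direction = "down")),
    planted_aecopd = list(list(n = 3, fold = 8, direction = "up")),
    planted_trajectories = list(list(pattern = "down-up", n = 2,
                                     step_fold = 3)))
  study <- generate_study(cfg)
  genes <- summarize_probes(log2_transform(study$probes), study$annotation)
  rec <- fold_change_all(genes, study$design)
  truth <- study$truth

  copd <- truth$gene_id[truth$label == "copd_specific_down"]
  for (p in c("STABLE_vs_CON", "AE1_vs_CON", "AE3_vs_CON", "AE10_vs_CON")) {
    sub <- rec[rec$pair == p & rec$gene_id %in% copd, ]
    expect_equal(sub$ratio, rep(6, 3), tolerance = 1e-9)
    expect_equal(sub$direction, rep("down", 3))
  }
  # COPD-planted genes are flat between exacerbation days
  sub <- rec[rec$pair == "AE10_vs_AE3" & rec$gene_id %in% copd, ]
  expect_equal(sub$ratio, rep(1, 3), tolerance = 1e-9)

  aec <- truth$gene_id[truth$label == "aecopd_specific_up"]
  for (p in panel_spec("aecopd_specific")$comparisons) {
    sub <- rec[rec$pair == p & rec$gene_id %in% aec, ]
    expect_equal(sub$ratio, rep(8, 3), tolerance = 1e-9)
    expect_equal(sub$direction, rep("up", 3))
  }
  sub <- rec[rec$pair == "STABLE_vs_CON" & rec$gene_id %in% aec, ]
  expect_equal(sub$ratio, rep(1, 3), tolerance = 1e-9)

  traj <- truth$gene_id[truth$label == "traj_du"]
  s1 <- rec[rec$pair == "AE3_vs_AE1" & rec$gene_id %in% traj, ]
  s2 <- rec[rec$pair == "AE10_vs_AE3" & rec$gene_id %in% traj, ]
  calls <- classify_trajectory(s1, s2)
  expect_equal(calls$pattern, rep("down-up", 2))
  expect_equal(calls$qualifying_fold, rep(3, 2), tolerance = 1e-9)
})

test_that("under realistic noise the realized minimum fold stays near the planted value", {
  cfg <- simulation_config(
    n_subjects_per_arm = 6, n_genes = 200, probes_per_gene = 1,
    noise_sd = 0.25,
    planted_aecopd = list(list(n = 50, fold = 12, direction = "up")),
    seed = 77)
  study <- generate_study(cfg)
  rownames(study$probes) <- study$annotation$gene_id
  rec <- fold_change_all(log2_transform(study$probes), study$design,
                         panel_spec("aecopd_specific")$comparisons)
  planted <- study$truth$gene_id[study$truth$label == "aecopd_specific_up"]
  realized_min <- tapply(rec$ratio[rec$gene_id %in% planted],
                         rec$gene_id[rec$gene_id %in% planted], min)
  expect_gte(mean(realized_min >= 8 & realized_min <= 18), 0.95)
})

test_that("simulated DESS records are valid, hit their targets, and saturate cleanly", {
  design <- generate_study(tiny_config())$design
  zero <- generate_dess_records(design,
                                c(CON = 0, STABLE = 0, AE1 = 0, AE3 = 0,
                                  AE10 = 0), dispersion = 0, seed = 4)
  expect_true(all(zero$level == 0))
  full <- generate_dess_records(design,
                                c(CON = 256, STABLE = 256, AE1 = 256,
                                  AE3 = 256, AE10 = 256),
                                dispersion = 0, seed = 4)
  expect_true(all(full$level == 4))
  expect_equal(unique(score_dess(full)$total), 256)

  targets <- c(CON = 3.2, STABLE = 38.7, AE1 = 85.7, AE3 = 70.5,
               AE10 = 36.7)
  big <- generate_study(simulation_config(n_subjects_per_arm = 6,
                                          n_genes = 2, seed = 8))
  recs <- generate_dess_records(big$design, targets, dispersion = 10,
                                seed = 99)
  scores <- score_dess(recs)
  groups <- big$design$group[match(scores$sample_id, big$design$sample_id)]
  s <- summarize_dess(scores, groups)
  expect_true(all(abs(s$mean - targets[s$group]) <= 5))
  expect_error(generate_dess_records(big$design, c(CON = 300), seed = 1),
               "\\[0, 256\\]")
  expect_error(generate_dess_records(big$design, targets["CON"], seed = 1),
               "no target for group")
})
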