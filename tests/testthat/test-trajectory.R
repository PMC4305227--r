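steps_from_example <- function() {
  tr <- example_trajectory_steps()
  list(step1 = data.frame(gene_id = tr$seq_id, ratio = tr$step1_fold,
                          direction = sub("-.*", "", tr$pattern),
                          stringsAsFactors = FALSE),
       step2 = data.frame(gene_id = tr$seq_id, ratio = tr$step2_fold,
                          direction = sub(".*-", "", tr$pattern),
                          stringsAsFactors = FALSE),
       expected = tr$pattern)
}

test_that("patterns are the product of the step directions and the qualifying fold the smaller ratio", {
  s <- steps_from_example()
  calls <- classify_trajectory(s$step1, s$step2)
  expect_equal(calls$pattern, s$expected)
  expect_equal(calls$qualifying_fold, pmin(s$step1$ratio, s$step2$ratio))
  # named checks: consistently falling and late-rising genes
  expect_equal(calls$pattern[calls$gene_id == "NM_000032"], "down-down")
  expect_equal(calls$qualifying_fold[calls$gene_id == "NM_000032"], 6.4)
  expect_equal(calls$pattern[calls$gene_id == "NM_016730"], "up-up")
  expect_equal(calls$qualifying_fold[calls$gene_id == "NM_016730"], 3.0)
})

test_that("a flat step leaves the gene unclassified and every call gets exactly one label", {
  s1 <- data.frame(gene_id = c("a", "b"), ratio = c(1, 2),
                   direction = c("flat", "up"))
  s2 <- data.frame(gene_id = c("a", "b"), ratio = c(3, 1),
                   direction = c("up", "flat"))
  calls <- classify_trajectory(s1, s2)
  expect_equal(calls$pattern, c("unclassified", "unclassified"))
  s <- steps_from_example()
  calls2 <- classify_trajectory(s$step1, s$step2)
  expect_true(all(calls2$pattern %in% c(trajectory_patterns(),
                                        "unclassified")))
  expect_error(classify_trajectory(s1, s2[1, ]), "not step2")
})

test_that("the pattern depends only on the step signs, not magnitudes", {
  set.seed(9)
  for (i in 1:5) {
    dirs <- sample(c("up", "down"), 2, replace = TRUE)
    r1 <- exp(runif(2, 0.1, 3))
    c1 <- classify_trajectory(
      data.frame(gene_id = "g", ratio = r1[1], direction = dirs[1]),
      data.frame(gene_id = "g", ratio = r1[2], direction = dirs[2]))
    c2 <- classify_trajectory(
      data.frame(gene_id = "g", ratio = 100 * r1[1], direction = dirs[1]),
      data.frame(gene_id = "g", ratio = r1[2] / 7, direction = dirs[2]))
    expect_equal(c1$pattern, c2$pattern)
    expect_equal(c1$pattern, paste(dirs, collapse = "-"))
  }
})

test_that("the pattern census reproduces the published fold-tier counts and is monotone", {
  s <- steps_from_example()
  calls <- classify_trajectory(s$step1, s$step2)
  expect_equal(unname(pattern_census(calls, 2)), c(3L, 3L, 7L, 8L))
  expect_equal(unname(pattern_census(calls, 4)), c(3L, 3L, 7L, 0L))
  expect_equal(unname(pattern_census(calls, 5)), c(2L, 0L, 0L, 0L))
  expect_equal(unname(pattern_census(calls, Inf)), rep(0L, 4))
  for (th in c(2, 3, 4, 5, 8)) {
    expect_true(all(pattern_census(calls, th + 1) <= pattern_census(calls, th)))
  }
})

test_that("severity concordance compares sign patterns and reports a 3-point correlation", {
  dess <- c(85.7, 70.5, 36.7)
  sr <- example_stable_relative()
  alas2 <- unlist(sr[which(sr$symbol == "ALAS2"), c("AE1", "AE3", "AE10")],
                  use.names = FALSE)
  cc <- dess_concordance(alas2, dess)
  expect_equal(cc$pattern, "down-down")
  expect_true(cc$pattern_match)
  expect_gt(cc$r, 0)
  # perfectly aligned / anti-aligned trajectories
  expect_equal(dess_concordance(dess, dess)$r, 1)
  anti <- dess_concordance(-dess, dess)
  expect_equal(anti$r, -1)
  expect_false(anti$pattern_match)
  expect_warning(flat <- dess_concordance(c(2, 2, 2), dess),
                 "zero-variance")
  expect_true(is.na(flat$r))
  # log-signed variant keeps the pattern decision
  expect_true(dess_concordance(alas2, dess, log_signed = TRUE)$pattern_match)
})
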