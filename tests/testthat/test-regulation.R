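models <- default_kinase_models()

test_that("log2 transform and median centering behave as documented", {
  tab <- data.frame(intensity_a = c(8, 0, 2), intensity_b = c(4, 16, 64))
  t1 <- log2_transform_normalize(tab, "none")
  expect_equal(t1$intensity_a, c(3, NA, 1))
  expect_equal(t1$intensity_b, c(2, 4, 6))
  t2 <- log2_transform_normalize(tab, "median_center")
  expect_equal(stats::median(t2$intensity_b, na.rm = TRUE), 0)
  expect_equal(t2$intensity_b, c(-2, 0, 2))
})

test_that("ratio_test matches the reference t-test and handles degenerate input", {
  g1 <- c(1.0, 1.1, 0.9, 1.0)
  g2 <- c(0.0, 0.1, -0.1, 0.0)
  r <- ratio_test(g1, g2)
  ref <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  expect_equal(r$ratio, mean(g1) - mean(g2))
  # identical groups: exact null
  r0 <- ratio_test(c(2, 3, 4), c(2, 3, 4))
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  # zero variance in both groups, equal means: no division error
  rz <- ratio_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(rz$t, 0); expect_equal(rz$p, 1)
  # zero variance, different means: overwhelming evidence
  rs <- ratio_test(c(2, 2), c(1, 1))
  expect_identical(rs$t, Inf); expect_equal(rs$p, 0)
  # under two observations: undefined, not an error
  ru <- ratio_test(1, c(1, 2))
  expect_true(ru$undefined); expect_true(is.na(ru$p))
  # Welch variant agrees with the reference implementation
  rw <- ratio_test(g1, c(g2, 2), var_equal = FALSE)
  refw <- stats::t.test(g1, c(g2, 2), var.equal = FALSE)
  expect_equal(rw$p, refw$p.value)
})

test_that("classification implements the group A/B rules", {
  res <- data.frame(
    protein_id = c("a", "b", "c", "d"), position = 1:4, residue = "S",
    log2_ratio_treatment = c(-1.2, 0.3, -0.8, 1.4),
    p_treatment = c(0.01, 0.5, 0.02, 0.001),
    log2_ratio_motif = c(2.0, 1.0, 2.0, 1.0),
    p_motif = c(0.003, 0.001, 0.2, 0.01))
  res$q_treatment <- res$p_treatment; res$q_motif <- res$p_motif
  out <- classify_sites(res, alpha = 0.05)
  expect_identical(out$direction, c("down", "unchanged", "down", "up"))
  expect_identical(out$group, c("B", "none", "A", "none"))
  # partition property: up/down/unchanged exhaustive, A and B partition down
  withr::with_seed(11, {
    rnd <- data.frame(
      protein_id = sprintf("p%d", 1:500), position = 1L, residue = "S",
      log2_ratio_treatment = stats::rnorm(500),
      p_treatment = stats::runif(500),
      log2_ratio_motif = stats::rnorm(500),
      p_motif = stats::runif(500))
  })
  cl <- classify_sites(rnd)
  expect_true(all(cl$direction %in% c("up", "down", "unchanged")))
  expect_true(all(cl$group[cl$direction != "down"] == "none"))
  expect_true(all(cl$group[cl$direction == "down"] %in% c("A", "B")))
})

test_that("stoichiometry is the endogenous/boost ratio with clipping and flags", {
  d <- ck2_design()
  tab <- data.frame(protein_id = c("P1", "P2", "P3"), position = 1:3,
                    residue = "S",
                    intensity_126 = c(50, 120, 10), intensity_127 = 1,
                    intensity_128 = c(100, 100, 0),
                    intensity_129 = c(50, 120, 10), intensity_130 = 1,
                    intensity_131 = c(100, 100, 0))
  st <- estimate_stoichiometry(tab, d, "DMSO")
  expect_equal(st$stoichiometry[1], 0.5)
  expect_false(st$clipped[1])
  # ratios above 1 are clipped, flagged
  expect_equal(st$stoichiometry[2], 1)
  expect_true(st$clipped[2])
  # no boost signal: undefined
  expect_true(st$undefined[3])
  expect_true(is.na(st$stoichiometry[3]))
  expect_identical(st$n_replicates, c(2L, 2L, 0L))
})

test_that("oracle-mode simulation recovers ground-truth stoichiometry exactly", {
  d <- ck2_design()
  sites <- synthetic_site_table(300, models, planted = c(CK2 = 100), seed = 7)
  truth <- assign_ground_truth(sites, models, conditions = c("DMSO", "CKi"),
                               seed = 8)
  acq <- acquisition_params(ms1_detection_threshold = 0, oracle = TRUE, seed = 9)
  tab <- simulate_tmt_experiment(truth, d, equal_amounts(d), acq,
                                 boost_model = models$CK2, efficiency = 1,
                                 boost_source_condition = "CKi",
                                 force_match_probability = 1)
  st <- estimate_stoichiometry(tab, d, "CKi")
  expect_equal(st$stoichiometry, truth$stoich_CKi, tolerance = 1e-12)
})

test_that("cumulative curve sorts ascending with ties on the higher rank", {
  cv <- cumulative_stoichiometry_curve(c(0.5, 0.1, 0.9))
  expect_equal(cv$stoichiometry, c(0.1, 0.5, 0.9))
  expect_equal(cv$cumulative_fraction, c(1, 2, 3) / 3 * 100)
  # all-equal values collapse to a single step at 100%
  cv2 <- cumulative_stoichiometry_curve(c(0.3, 0.3, 0.3))
  expect_identical(nrow(cv2), 1L)
  expect_equal(cv2$cumulative_fraction, 100)
  # non-decreasing in both coordinates
  withr::with_seed(3, v <- stats::runif(200))
  cv3 <- cumulative_stoichiometry_curve(v)
  expect_true(all(diff(cv3$stoichiometry) >= 0))
  expect_true(all(diff(cv3$cumulative_fraction) >= 0))
  expect_identical(nrow(cumulative_stoichiometry_curve(numeric(0))), 0L)
})

test_that("overlap counts match brute-force set enumeration", {
  s <- list(a = c("x", "y"), b = c("z", "w"))
  o <- overlap_analysis(s)
  expect_equal(o$pairwise["a", "b"], 0L)
  expect_equal(o$union, 4L)
  oid <- overlap_analysis(list(a = c("x", "y"), b = c("y", "x")))
  expect_equal(oid$pairwise["a", "b"], 2L)
  expect_equal(oid$union, 2L)
  withr::with_seed(13, {
    sets <- lapply(1:4, function(i) sample(sprintf("s%02d", 1:40), 20))
    names(sets) <- letters[1:4]
  })
  o3 <- overlap_analysis(sets)
  for (i in 1:4) for (j in 1:4)
    expect_equal(o3$pairwise[i, j], length(intersect(sets[[i]], sets[[j]])))
})

test_that("dual-ratio tests pool duplicate channels across replicate injections", {
  d <- ck2_design()
  sites <- synthetic_site_table(400, models, planted = c(CK2 = 80), seed = 21)
  truth <- assign_ground_truth(sites, models, conditions = c("DMSO", "CKi"),
                               inhibited_kinase = "CK2", inhibitor_effect = 0.5,
                               treated_condition = "CKi", seed = 22)
  tabs <- lapply(c(23, 24), function(s)
    simulate_tmt_experiment(truth, d, equal_amounts(d), quiet_acq(s, cv = 0.05),
                            boost_model = models$CK2,
                            boost_source_condition = "CKi"))
  res <- regulation_test(tabs, d, control = "DMSO", treated = "CKi")
  expect_identical(nrow(res), nrow(truth))
  expect_true(all(res$n_treatment_obs == 8))  # 2+2 channels x 2 injections
  res <- classify_sites(res)
  hit <- site_key(res) %in% site_key(truth)[grepl("CK2", truth$direct_substrate_of)]
  # substrates are called down; their motif ratio is positive and significant
  expect_gt(mean(res$group[hit] == "B"), 0.9)
  expect_lt(stats::median(res$log2_ratio_treatment[hit]), 0)
  expect_gt(stats::median(res$log2_ratio_motif[hit]), 0)
})
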