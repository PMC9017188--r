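models <- default_kinase_models()

test_that("generate_proteome is seeded and respects its composition", {
  p1 <- generate_proteome(5, seed = 7)
  p2 <- generate_proteome(5, seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1, generate_proteome(5, seed = 8)))

  # composition without K or R leaves nothing to cleave
  comp <- stats::setNames(rep(0, 20), c("A","C","D","E","F","G","H","I","K","L",
                                        "M","N","P","Q","R","S","T","V","W","Y"))
  comp[c("A", "S", "G", "L")] <- 0.25
  pno <- generate_proteome(5, length_mean = 100, composition = comp, seed = 3)
  digs <- digest_proteome(pno, max_missed = 2)
  expect_identical(nrow(digs), 5L)
  expect_identical(digs$sequence, pno$sequence)

  # uniform composition: observed residue frequencies within 3 binomial SEs
  unif <- stats::setNames(rep(0.05, 20), names(comp))
  pu <- generate_proteome(1000, length_mean = 100, composition = unif, seed = 11)
  chars <- unlist(strsplit(pu$sequence, ""))
  n <- length(chars)
  se <- sqrt(0.05 * 0.95 / n)
  obs <- table(factor(chars, levels = names(comp))) / n
  expect_true(all(abs(obs - 0.05) < 3 * se + 1e-12))

  bad <- unif; bad["A"] <- 0.10
  expect_error(generate_proteome(5, composition = bad, seed = 1), "sum to 1")
})

test_that("digest applies the tryptic rule with KP suppression and missed cleavages", {
  # hand application of cleavage after K/R
  d0 <- digest("MKTAYIAKQR", max_missed = 0)
  expect_identical(d0$sequence, c("MK", "TAYIAK", "QR"))
  expect_identical(d0$start, c(1L, 3L, 9L))
  expect_identical(d0$end, c(2L, 8L, 10L))
  # no cleavage sites at all
  expect_identical(digest("AAAA", max_missed = 2)$sequence, "AAAA")
  # KP suppression keeps the bond intact...
  expect_identical(digest("AKPA", max_missed = 0)$sequence, "AKPA")
  # ...unless switched off
  expect_identical(digest("AKPA", max_missed = 0, kp_suppression = FALSE)$sequence,
                   c("AK", "PA"))
  # missed-cleavage products join adjacent fragments
  d2 <- digest("MKTAYIAKQR", max_missed = 2)
  expect_setequal(d2$sequence[d2$missed_cleavages == 1], c("MKTAYIAK", "TAYIAKQR"))
  expect_identical(d2$sequence[d2$missed_cleavages == 2], "MKTAYIAKQR")
  expect_error(digest(""), "empty")
})

test_that("peptide coordinates are 1-based inclusive substrings of the protein", {
  prot <- generate_proteome(10, length_mean = 120, seed = 21)
  digs <- digest_proteome(prot, max_missed = 2)
  seqs <- stats::setNames(prot$sequence, prot$id)
  expect_identical(digs$sequence,
                   unname(substring(seqs[digs$protein_id], digs$start, digs$end)))
  expect_true(all(digs$missed_cleavages <= 2))
})

test_that("phosphosite_universe truncates peptide windows at tryptic boundaries", {
  prot <- data.frame(id = "P1", sequence = "MARKAASPKDDDSDDE")
  uni <- phosphosite_universe(prot, w = 7)
  expect_true(all(uni$residue %in% c("S", "T", "Y")))
  s7 <- uni[uni$position == 7, ]
  expect_identical(s7$window, extract_window(prot$sequence, 7, 7))
  # peptide AASPK spans 5..9; everything outside is padding
  expect_identical(s7$peptide_window, "_____AASPK_____")
})

test_that("ground truth classes, priors, and inhibitor perturbation behave as specified", {
  sites <- synthetic_site_table(3000, models,
                                planted = c(CK2 = 400, SRC = 400, ERK2 = 300),
                                seed = 31)
  truth <- assign_ground_truth(sites, models, conditions = c("control", "treated"),
                               inhibited_kinase = "CK2", inhibitor_effect = 0.5,
                               seed = 32)
  expect_true(all(truth$stoich_control >= 0 & truth$stoich_control <= 1))
  # class-mean ordering: acidophilic > pro-directed > tyrosine
  mu <- tapply(truth$stoich_control, truth$kinase_class, mean)
  expect_gt(mu[["acidophilic"]], mu[["pro_directed"]])
  expect_gt(mu[["pro_directed"]], mu[["tyrosine"]])
  # substrates of the inhibited kinase are scaled in the treated condition only
  hit <- grepl("CK2", truth$direct_substrate_of)
  expect_gt(sum(hit), 300)
  expect_equal(truth$stoich_treated[hit], 0.5 * truth$stoich_control[hit])
  expect_equal(truth$stoich_treated[!hit], truth$stoich_control[!hit])
  # substrate flags only for kinases that accept the residue
  src_sub <- grepl("SRC", truth$direct_substrate_of)
  expect_true(all(truth$residue[src_sub] == "Y"))

  # null perturbation leaves conditions identical
  t0 <- assign_ground_truth(sites[1:200, ], models, inhibited_kinase = "CK2",
                            inhibitor_effect = 1.0, seed = 33)
  expect_identical(t0$stoich_treated, t0$stoich_control)

  expect_error(assign_ground_truth(sites[1:10, ], models,
                                   conditions = c("a", "b"),
                                   inhibited_kinase = "CK2",
                                   treated_condition = "treated", seed = 1),
               "unknown condition")
})

test_that("a Beta(2,2) prior recovers its analytic mean", {
  sites <- synthetic_site_table(5000, seed = 41)
  pri <- list(acidophilic = c(2, 2), basophilic = c(2, 2),
              pro_directed = c(2, 2), tyrosine = c(2, 2), none = c(2, 2))
  truth <- assign_ground_truth(sites, models, priors = pri, seed = 42)
  se <- sqrt(1 / 20 / 5000)  # Beta(2,2) variance 1/20
  expect_lt(abs(mean(truth$stoich_control) - 0.5), 3 * se)
})

test_that("back-phosphorylation follows efficiency x match x availability", {
  ck2 <- models$CK2
  win <- "AAAALGHSDEDAAAA"  # strong CK2 consensus, score 5
  truth <- data.frame(window = win, peptide_window = win)
  p <- match_probability(motif_score(win, ck2), ck2)
  # stated formula at efficiency 0.5, stoichiometry 0.2
  expect_equal(simulate_kinase_reaction(truth, ck2, efficiency = 0.5,
                                        stoichiometry = 0.2),
               0.5 * p * 0.8)
  # full conversion: efficiency 1, saturating match, empty site
  hot <- kinase_motif_model("hot", "acidophilic", "S", ck2$logodds,
                            match_midpoint = -50, match_slope = 3)
  expect_equal(simulate_kinase_reaction(truth, hot, efficiency = 1,
                                        stoichiometry = 0), 1, tolerance = 1e-12)
  # wrong acceptor residue returns 0, not an error
  ywin <- flat_window("Y")
  expect_identical(
    simulate_kinase_reaction(data.frame(window = ywin, peptide_window = ywin),
                             ck2, efficiency = 1), 0)
  # peptide-level reaction sees the truncated window
  pka <- models$PKA
  full <- sample_motif_windows(pka, 20, seed = 51)
  tr <- data.frame(window = full,
                   peptide_window = paste0(strrep("_", 7), substr(full, 8, 15)))
  expect_lt(max(simulate_kinase_reaction(tr, pka, level = "peptide")), 0.01)
  expect_gt(mean(simulate_kinase_reaction(tr, pka, level = "protein")), 0.9)
  expect_error(simulate_kinase_reaction(truth, ck2, efficiency = 1.5), "efficiency")
})

test_that("oracle-mode reporter intensities are exactly proportional to abundance", {
  design <- ck2_design()
  sites <- synthetic_site_table(200, models, planted = c(CK2 = 50), seed = 61)
  truth <- assign_ground_truth(sites, models, conditions = c("DMSO", "CKi"),
                               inhibited_kinase = "CK2",
                               treated_condition = "CKi", seed = 62)
  acq <- acquisition_params(ms1_detection_threshold = 0, oracle = TRUE, seed = 63)
  tab <- simulate_tmt_experiment(truth, design, equal_amounts(design), acq,
                                 boost_model = models$CK2,
                                 boost_source_condition = "CKi")
  expect_identical(nrow(tab), nrow(truth))
  # sample-channel intensity / (scale x amount) recovers the true stoichiometry
  got <- tab$intensity_126 / (acq$intensity_scale * 25)
  expect_equal(got, truth$stoich_DMSO, tolerance = 1e-12)
  # boost channel carries treated stoichiometry + back fraction, capped at 1
  frac131 <- tab$intensity_131 / (acq$intensity_scale * 25)
  expect_true(all(frac131 <= 1 + 1e-12))
  expect_true(all(frac131 >= truth$stoich_CKi - 1e-12))
})

test_that("the simulated table is deterministic for a fixed seed", {
  design <- ck2_design()
  sites <- synthetic_site_table(150, models, planted = c(CK2 = 30), seed = 71)
  truth <- assign_ground_truth(sites, models, conditions = c("DMSO", "CKi"),
                               seed = 72)
  acq <- acquisition_params(seed = 73)
  run <- function() simulate_tmt_experiment(truth, design, equal_amounts(design),
                                            acq, boost_model = models$CK2,
                                            boost_source_condition = "CKi")
  expect_identical(run(), run())
  expect_error(simulate_tmt_experiment(truth, design,
                                       equal_amounts(design, -1), acq,
                                       boost_model = models$CK2),
               "non-negative")
})

test_that("boosting pulls sub-threshold sites over the MS1 detection limit", {
  design <- titration_design()
  # low-stoichiometry pY sites matched by the boost kinase
  sites <- synthetic_site_table(300, models, planted = c(EGFR = 300), seed = 81)
  truth <- assign_ground_truth(sites, models, conditions = "HeLa", seed = 82)
  acq <- acquisition_params(oracle = TRUE, seed = 83)
  run_boost <- function(b) {
    amts <- equal_amounts(design, 25); amts["131"] <- b
    simulate_tmt_experiment(truth, design, amts, acq, boost_model = models$EGFR,
                            boost_source_condition = "HeLa", keep_all = TRUE)
  }
  t0 <- run_boost(0); t25 <- run_boost(25)
  expect_gt(sum(t25$detected), sum(t0$detected))
  # the boosting mechanism: every site detected without boost stays detected
  expect_true(all(which(t0$detected) %in% which(t25$detected)))
  # some site is detected only because the boost channel lifts the MS1 sum
  gained <- t25$detected & !t0$detected
  expect_gt(sum(gained), 0)
})

test_that("endogenous phosphosite residue composition hits the 90:10:0.05 target", {
  sites <- synthetic_site_table(20000, seed = 91)
  w <- c(S = 90, T = 10, Y = 0.05) / 100.05
  obs <- table(factor(sites$residue, levels = c("S", "T", "Y")))
  for (r in c("S", "T", "Y")) {
    se <- sqrt(20000 * w[r] * (1 - w[r]))
    expect_lt(abs(obs[[r]] - 20000 * w[r]), 4 * se + 3)
  }
})
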