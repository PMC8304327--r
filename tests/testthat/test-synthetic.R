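test_that("noise-free PRM forward model inverts exactly for every peptide pair", {
  sim <- simulate_prm_experiment(
    prm_truth(p_light = c(S226 = 0.95, S255 = 0.95), q_heavy = 0,
              rho = 1, sigma = 0),
    seed = 5)
  est <- occupancy_pipeline(sim)
  expect_equal(est$occ_light, rep(0.95, nrow(est)), tolerance = 1e-9)
  expect_equal(est$occ_heavy, rep(0, nrow(est)), tolerance = 1e-9)
})

test_that("PRM simulator is deterministic under a fixed seed", {
  s1 <- simulate_prm_experiment(seed = 7)
  s2 <- simulate_prm_experiment(seed = 7)
  expect_identical(s1$transitions, s2$transitions)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_prm_experiment(seed = 8)
  expect_false(identical(s1$transitions$area, s3$transitions$area))
})

test_that("H/L ratios are independent of ionization factors at sigma = 0", {
  # different seeds draw different ionization factors; with sigma = 0 the
  # per-peptide ratios must nevertheless be identical (channel-shared factors)
  tr <- prm_truth(p_light = c(S226 = 0.9, S255 = 0.7), q_heavy = 0.01,
                  rho = 1.3, sigma = 0)
  q1 <- peptide_areas_from_transitions(simulate_prm_experiment(tr, seed = 1)$transitions)
  q2 <- peptide_areas_from_transitions(simulate_prm_experiment(tr, seed = 2)$transitions)
  expect_false(isTRUE(all.equal(q1$area_light, q2$area_light)))
  expect_equal(q1$hl_ratio, q2$hl_ratio, tolerance = 1e-12)
})

test_that("mean recovered occupancy over 100 pairs is within 0.01 of truth at sigma 0.05", {
  n <- 100
  panel <- synthetic_pair_panel(n)
  p <- stats::setNames(rep(0.80, n), panel$site_id)
  sim <- simulate_prm_experiment(
    prm_truth(p_light = p, q_heavy = 0.01, sigma = 0.05),
    panel = panel, n_replicates = 1, seed = 19)
  est <- occupancy_pipeline(sim, panel = panel)
  expect_gt(nrow(est), 90)
  expect_lt(abs(mean(est$occ_light) - 0.80), 0.01)
})

test_that("PRM simulator refuses a panel without normalization peptides", {
  expect_error(simulate_prm_experiment(norm_peptides = character(0)),
               "normalization")
})

test_that("co-IP simulator enforces control missingness and injects QC failures", {
  sim <- simulate_coip_tables(
    coip_truth(n_background = 40, n_true = 10, control_missingness = 1),
    mode = "labelfree", seed = 21)
  ctrl_cols <- paste0("ibaq_", sim$design$sample[sim$design$is_control])
  true_rows <- sim$truth$is_true_interactor
  for (col in ctrl_cols) {
    expect_true(all(is.na(sim$groups[[col]][true_rows])))
  }
  expect_true(any(sim$groups$reverse))
  expect_true(any(sim$groups$contaminant))
  # decoys and contaminants never survive the QC filter
  kept <- filter_protein_groups(sim$groups, sim$design, mode = "labelfree")
  expect_false(any(kept$reverse | kept$contaminant))
})

test_that("co-IP simulator is deterministic and validates the design", {
  s1 <- simulate_coip_tables(seed = 4)
  s2 <- simulate_coip_tables(seed = 4)
  expect_identical(s1$groups, s2$groups)
  expect_error(simulate_coip_tables(mode = "silac", n_replicates = 0),
               "replicates")
})

test_that("proteolysis simulator recovers configured full-length fractions at sigma 0", {
  sim <- simulate_proteolysis_bands(sigma = 0, seed = 2)
  ffl <- fraction_full_length(sim$bands)
  wt7 <- ffl$ratio[ffl$genotype == "WT" & ffl$dose == 7]
  expect_equal(wt7, rep(0.35, length(wt7)), tolerance = 1e-12)
  # dose 0: all peptides only in band A
  d0 <- sim$bands[sim$bands$dose == 0, ]
  expect_true(all(d0$band == "A"))
  expect_true(all(ffl$ratio[ffl$dose == 0] == 1))
})

test_that("after-site peptides lose lane share relative to before-site peptides", {
  sim <- simulate_proteolysis_bands(sigma = 0.02, seed = 9)
  bvl <- band_vs_lane_ratio(sim$bands)
  bvl <- assign_cleavage_side(bvl, site = 607)
  for (d in c(7, 14)) {
    before <- bvl$ratio[bvl$dose == d & bvl$side == "before"]
    after <- bvl$ratio[bvl$dose == d & bvl$side == "after"]
    expect_lt(median(after), median(before))
  }
})

test_that("proteolysis simulator rejects spans outside the protein", {
  bad <- tibble::tibble(peptide = "P1", start = 700, end = 730)
  expect_error(simulate_proteolysis_bands(panel = bad), "span outside")
})

test_that("CWB simulator inverts exactly at sigma 0 and validates fractions", {
  sim <- simulate_cwb_signals(secreted = c(WT = 0.016, AA = 0.045),
                              baseline = 0.03, sigma = 0, seed = 3)
  ratios <- cwb_absolute_ratios(sim$measurements)
  est <- secreted_fraction(ratios)$estimates
  expect_equal(est$mean_secreted[est$construct == "WT"], 0.016,
               tolerance = 1e-12)
  expect_equal(est$mean_secreted[est$construct == "AA"], 0.045,
               tolerance = 1e-12)
  expect_error(simulate_cwb_signals(fraction_analyzed = c(CM = 0, lysate = 0.5)),
               "fraction_analyzed")
})

test_that("CWB t-test distinguishes WT-like from mutant-like secretion at low noise", {
  # power over repeated small experiments at truths 0.016 vs 0.045
  hits <- vapply(1:40, function(s) {
    sim <- simulate_cwb_signals(secreted = c(WT = 0.016, AA = 0.045),
                                sigma = 0.05, n_replicates = 3, seed = s)
    res <- secreted_fraction(cwb_absolute_ratios(sim$measurements))
    res$comparisons$p[1] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})
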