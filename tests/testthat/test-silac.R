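make_transitions <- function(areas_light, areas_heavy,
                             seq = "PEPTIDEK", sample = "s1", rep = 1L) {
  dplyr::bind_rows(
    tibble::tibble(modified_sequence = seq, precursor_charge = 2L,
                   fragment_ion = paste0("y", seq_along(areas_light)),
                   label_channel = "light", sample_id = sample,
                   replicate = rep, area = areas_light),
    tibble::tibble(modified_sequence = seq, precursor_charge = 2L,
                   fragment_ion = paste0("y", seq_along(areas_heavy)),
                   label_channel = "heavy", sample_id = sample,
                   replicate = rep, area = areas_heavy)
  )
}

test_that("peptide area is the plain sum of fragment areas per channel", {
  rec <- make_transitions(c(100, 250, 150), c(50, 100, 100))
  q <- peptide_areas_from_transitions(rec)
  expect_equal(q$area_light, 500)
  expect_equal(q$area_heavy, 250)
  expect_equal(q$hl_ratio, 0.5)

  single <- make_transitions(100, 70)
  qs <- peptide_areas_from_transitions(single)
  expect_equal(qs$area_light, 100)
  expect_equal(qs$hl_ratio, 0.7)
})

test_that("a channel with all fragments missing yields a flagged missing ratio", {
  rec <- make_transitions(c(100, 200), c(NA_real_, NA_real_))
  q <- peptide_areas_from_transitions(rec)
  expect_true(is.na(q$area_heavy))
  expect_true(is.na(q$hl_ratio))
  expect_equal(q$flag, "heavy_missing")
})

test_that("protein reference ratio is the median of normalization peptides", {
  q <- tibble::tibble(
    modified_sequence = c("N1", "N2", "N3"), sample_id = "s1", replicate = 1L,
    area_light = 1, area_heavy = 1, hl_ratio = c(0.9, 1.0, 1.4), flag = "ok")
  z <- protein_reference_ratio(q)
  expect_equal(z$z, 1.0)
  expect_equal(z$n_peptides, 3L)

  # even count: midpoint of the two central ratios
  q2 <- q[1:2, ]; q2$hl_ratio <- c(0.8, 1.2)
  expect_equal(protein_reference_ratio(q2)$z, 1.0)

  q3 <- q; q3$hl_ratio <- NA_real_
  expect_error(protein_reference_ratio(q3), "no valid normalization")
})

test_that("triplet assembly pairs variants separately and logs dropped combinations", {
  sim <- simulate_prm_experiment(prm_truth(sigma = 0), seed = 13)
  quants <- peptide_areas_from_transitions(sim$transitions)
  z_tbl <- protein_reference_ratio(
    quants[quants$modified_sequence %in% cl_normalization_peptides(), ])
  triplets <- assemble_ratio_triplets(quants, cl_peptide_panel(), z_tbl)
  # two variants per site and replicate (with / without missed cleavage)
  counts <- table(triplets$site_id, triplets$replicate)
  expect_true(all(counts == 2))

  # removing the unmodified counterpart drops the triplet with a reason
  q2 <- quants[quants$modified_sequence != "IEDVGSDEEDDSGK", ]
  t2 <- assemble_ratio_triplets(q2, cl_peptide_panel(), z_tbl)
  dropped <- attr(t2, "dropped")
  expect_true(all(dropped$site_id == "S255" & dropped$variant == "noMC"))
  expect_true(all(dropped$reason == "unmodified counterpart missing"))
})

test_that("H/L ratios and triplets are invariant to rescaling a replicate", {
  sim <- simulate_prm_experiment(prm_truth(sigma = 0.1), seed = 17)
  tr <- sim$transitions
  tr2 <- tr
  tr2$area[tr2$replicate == 2] <- tr2$area[tr2$replicate == 2] * 37.5
  pipe <- function(x) {
    q <- peptide_areas_from_transitions(x)
    z <- protein_reference_ratio(
      q[q$modified_sequence %in% cl_normalization_peptides(), ])
    assemble_ratio_triplets(q, cl_peptide_panel(), z)
  }
  t1 <- pipe(tr); t2 <- pipe(tr2)
  expect_equal(t1$x, t2$x, tolerance = 1e-12)
  expect_equal(t1$y, t2$y, tolerance = 1e-12)
  expect_equal(t1$z, t2$z, tolerance = 1e-12)
})

test_that("forward-model ratio identities hold exactly at sigma 0", {
  tr <- prm_truth(p_light = c(S226 = 0.9, S255 = 0.6), q_heavy = 0.02,
                  rho = 1.7, sigma = 0)
  sim <- simulate_prm_experiment(tr, seed = 23)
  est <- occupancy_pipeline(sim)
  for (i in seq_len(nrow(est))) {
    p <- tr$p_light[[est$site_id[i]]]; q <- tr$q_heavy[[est$site_id[i]]]
    expect_equal(est$x[i] / est$z[i], q / p, tolerance = 1e-9)
    expect_equal(est$y[i] / est$z[i], (1 - q) / (1 - p), tolerance = 1e-9)
  }
})

test_that("stress-response normalization contrasts treated against control", {
  d <- tibble::tibble(
    site_id = "S255",
    condition = rep(c("treated", "control"), each = 3),
    replicate = rep(1:3, 2),
    phospho_area = c(200, 210, 190, 100, 105, 95),
    input_abundance = c(100, 105, 95, 100, 105, 95))
  res <- stress_response_abundance(d)
  expect_equal(res$fold_change, 2.0, tolerance = 1e-12)
  expect_lt(res$p, 0.05)

  # identical normalized values: fold change 1, p = 1
  d2 <- d; d2$phospho_area <- d2$input_abundance
  res2 <- stress_response_abundance(d2)
  expect_equal(res2$fold_change, 1.0)
  expect_equal(res2$p, 1)

  d3 <- d; d3$input_abundance[1] <- 0
  expect_error(stress_response_abundance(d3), "input")
})
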