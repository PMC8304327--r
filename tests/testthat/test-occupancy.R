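test_that("closed-form occupancy matches hand-derived worked examples", {
  # near-complete dephosphorylation of the heavy channel: x -> 0 limit
  e1 <- compute_occupancy(1e-9, 2, 1)
  expect_equal(e1$occ_light, 0.5, tolerance = 1e-6)
  expect_equal(e1$occ_heavy, 0, tolerance = 1e-6)

  # forward model with p_light = 0.5, p_heavy = 0.95, rho = 1
  e2 <- compute_occupancy(1.9, 0.1, 1)
  expect_equal(e2$occ_light, 0.5, tolerance = 1e-12)
  expect_equal(e2$occ_heavy, 0.95, tolerance = 1e-12)

  e3 <- compute_occupancy(0.05, 10, 1)
  expect_equal(e3$occ_light, 0.9045, tolerance = 1e-4)
  expect_equal(e3$occ_heavy, 0.0452, tolerance = 1e-3)

  expect_error(compute_occupancy(-1, 1, 1), "positive")
  expect_error(compute_occupancy(1, Inf, 1), "finite")
})

test_that("x close to z is flagged degenerate; out-of-range values are unclamped", {
  e <- compute_occupancy(1 + 1e-9, 2, 1)
  expect_false(e$valid)
  expect_equal(e$flag, "x_equals_z")
  expect_true(is.na(e$occ_light))

  # noise-driven out-of-range: reported as-is with a flag
  e2 <- compute_occupancy(2, 3, 1)   # a = (1-3)/(2-1) = -2 -> occ_light = 2
  expect_equal(e2$flag, "out_of_range")
  expect_equal(e2$occ_light, 2, tolerance = 1e-12)
})

test_that("occ_light equals (z - y)/(x - y) for random valid triplets", {
  withr::local_seed(101)
  for (i in 1:200) {
    p_l <- runif(1, 0.02, 0.98); p_h <- runif(1, 0.02, 0.98)
    if (abs(p_l - p_h) < 0.01) next
    rho <- runif(1, 0.1, 10)
    tr <- forward_triplet(p_l, p_h, rho)
    e <- compute_occupancy(tr$x, tr$y, tr$z)
    expect_equal(e$occ_light, (tr$z - tr$y) / (tr$x - tr$y), tolerance = 1e-12)
  }
})

test_that("inversion recovers (p_light, p_heavy) to 1e-9 across the parameter cube", {
  withr::local_seed(202)
  for (i in 1:300) {
    p_l <- runif(1, 0.01, 0.99); p_h <- runif(1, 0.01, 0.99)
    if (abs(p_l - p_h) < 1e-4) next
    rho <- runif(1, 0.1, 10)
    tr <- forward_triplet(p_l, p_h, rho)
    e <- compute_occupancy(tr$x, tr$y, tr$z)
    expect_equal(e$occ_light, p_l, tolerance = 1e-9)
    expect_equal(e$occ_heavy, p_h, tolerance = 1e-9)
  }
})

test_that("closed form agrees with the grid-search oracle on sample triplets", {
  # small-n version of the acceptance-scale oracle-equivalence check
  withr::local_seed(303)
  for (i in 1:50) {
    p_l <- runif(1, 0.05, 0.95); p_h <- runif(1, 0.05, 0.95)
    if (abs(p_l - p_h) < 0.01) next
    tr <- forward_triplet(p_l, p_h, runif(1, 0.5, 2))
    e <- compute_occupancy(tr$x, tr$y, tr$z)
    g <- grid_invert_occupancy(tr$x, tr$y, tr$z)
    expect_equal(e$occ_light, g$occ_light, tolerance = 1e-9)
    expect_equal(e$occ_heavy, g$occ_heavy, tolerance = 1e-9)
  }
})

test_that("co-occupancy bounds reproduce the Frechet window", {
  b <- co_occupancy_bounds(0.95, 0.95)
  expect_equal(b$lower, 0.90, tolerance = 1e-12)
  expect_equal(b$upper, 0.95, tolerance = 1e-12)
  expect_equal(b$independent, 0.9025, tolerance = 1e-12)

  b2 <- co_occupancy_bounds(1.0, 0.3)
  expect_equal(b2$lower, 0.3); expect_equal(b2$upper, 0.3)

  b3 <- co_occupancy_bounds(0.4, 0.4)
  expect_equal(b3$lower, 0.0); expect_equal(b3$upper, 0.4)

  expect_error(co_occupancy_bounds(1.2, 0.5), "\\[0, 1\\]")
})

test_that("phosphate stoichiometry sums per-site occupancies", {
  expect_equal(phosphate_stoichiometry(c(0.95, 0.95)), 1.9)
  expect_equal(phosphate_stoichiometry(numeric(0)), 0)
  expect_equal(phosphate_stoichiometry(c(1, 1)), 2)
  expect_error(phosphate_stoichiometry(c(0.5, 1.1)), "\\[0, 1\\]")
})

test_that("summaries report mean/sd/n and BH-adjusted group comparisons", {
  est <- tibble::tibble(
    site_id = "S255", variant = "noMC",
    group = rep(c("CM", "cell"), each = 3),
    occ_light = c(0.938, 0.925, 0.936, 0.8, 0.9, 1.0),
    occ_heavy = 0.01, valid = TRUE, flag = "ok")
  s <- summarize_and_compare(est, comparison = "cell")
  cm <- s[s$group == "CM", ]
  expect_equal(cm$mean_occ, 0.933, tolerance = 1e-3)
  expect_equal(cm$sd_occ, 0.007, tolerance = 1e-3)
  expect_equal(cm$n, 3L)
  expect_true(is.na(s$p[s$group == "cell"]))

  # identical groups give t = 0, p = 1
  est2 <- est; est2$occ_light <- rep(c(0.8, 0.9, 1.0), 2)
  s2 <- summarize_and_compare(est2, comparison = "cell")
  expect_equal(s2$p[s2$group == "CM"], 1, tolerance = 1e-12)
})

test_that("out-of-range estimates beyond the excess tolerance are excluded", {
  est <- tibble::tibble(
    site_id = "S", variant = "v", group = "g",
    occ_light = c(0.95, 1.03, 1.2),
    occ_heavy = 0, valid = TRUE,
    flag = c("ok", "out_of_range", "out_of_range"))
  s <- summarize_and_compare(est)
  expect_equal(s$n, 2L)   # 1.2 excluded, 1.03 kept (excess <= 0.05)
  expect_equal(s$mean_occ, mean(c(0.95, 1.03)), tolerance = 1e-12)
})
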