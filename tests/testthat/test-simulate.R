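test_that("rejection accounting is internally consistent", {
  # near the anti-diagonal corner at strongly negative rho12, small-n
  # samples often land in the uncapped-MRR undefined region
  out <- mc_rejection_rates(pop_cor(-0.9, -0.6, 0.6), n = 20, reps = 2000,
                            tests = c("williams", "mrr", "zou"), seed = 21)
  expect_identical(nrow(out), 3L)
  expect_true(all(out$reject_lower + out$reject_upper + out$undefined <=
                    out$reps))
  expect_equal(out$rate, (out$reject_lower + out$reject_upper) / out$reps)
  expect_equal(out$se, sqrt(out$rate * (1 - out$rate) / out$reps))
  # the engine counts undefined statistics rather than failing
  expect_gt(out$undefined[out$test == "mrr"], 0)
  expect_identical(out$undefined[out$test == "williams"], 0L)
})

test_that("identical seed reproduces identical outcome tables", {
  a <- mc_rejection_rates(pop_cor(0.3, 0.2, 0.2), 50, 1000,
                          tests = c("williams", "zou"), seed = 5)
  b <- mc_rejection_rates(pop_cor(0.3, 0.2, 0.2), 50, 1000,
                          tests = c("williams", "zou"), seed = 5)
  expect_identical(a, b)
})

test_that("a level near one rejects almost every defined sample", {
  out <- mc_rejection_rates(pop_cor(0, 0.3, 0.3), 50, 1000,
                            tests = "williams", alpha = 0.9999, seed = 2)
  expect_gte(out$rate, 0.999)
})

test_that("Pearson-Filon and Olkin reject identically at matched conditions", {
  out <- mc_rejection_rates(pop_cor(0.45, 0.4, 0.4), 50, 5000,
                            tests = c("pearson_filon", "olkin"), seed = 31)
  expect_identical(out$reject_lower[1], out$reject_lower[2])
  expect_identical(out$reject_upper[1], out$reject_upper[2])
})

test_that("null tails are symmetric with symmetric marginals", {
  out <- mc_rejection_rates(pop_cor(0, 0.3, 0.3), 100, 2e4,
                            tests = "williams", seed = 17)
  tail_se <- sqrt(2e4 * 0.025 * 0.975)
  expect_lt(abs(out$reject_lower - out$reject_upper), 4 * sqrt(2) * tail_se)
})

test_that("power lattice construction invariants", {
  lat9 <- build_power_lattice(0.9)
  lat6 <- build_power_lattice(-0.6)
  # the lattice rays run along the anti-diagonal, so the point count
  # scales with sqrt(1 - rho12^2): the rho12 = -0.6 ellipse admits about
  # twice as many lattice points as the narrower rho12 = 0.9 one
  expect_gt(nrow(lat6), nrow(lat9))
  expect_gt(nrow(lat9), 0)
  for (r12 in c(0.9, -0.6)) {
    lat <- if (r12 == 0.9) lat9 else lat6
    expect_true(all(lat$rho2y > lat$rho1y))   # above the diagonal only
    expect_equal((lat$rho1y + lat$rho2y) / 2, lat$mean_rho)
    expect_true(all(vapply(seq_len(nrow(lat)), function(i)
      is_feasible(pop_cor(r12, lat$rho1y[i], lat$rho2y[i])), TRUE)))
  }
})

test_that("power grows along an off-diagonal ray", {
  rates <- vapply(1:3, function(k) {
    p <- pop_cor(0.45, 0.2 - k * 0.08, 0.2 + k * 0.08)
    mc_rejection_rates(p, 100, 4000, tests = "williams",
                       seed = 100 + k)$rate
  }, 0)
  pooled_se <- sqrt(2 * 0.25 / 4000)
  expect_true(all(diff(rates) > -2 * pooled_se))
  expect_gt(rates[3], rates[1])
})

test_that("sweeps run, are reproducible, and skip infeasible points", {
  cfg <- sim_config(tests = c("williams", "zou"),
                    rho12_values = c(-0.45, 0.6), diagonal_step = 0.3,
                    n_values = 20, reps = 500, seed = 42)
  a <- type1_sweep(cfg)
  b <- type1_sweep(cfg)
  expect_identical(a, b)
  # each (rho12, rho, n) condition contributes one row per test
  expect_identical(nrow(a) %% 2L, 0L)
  expect_true(all(a$rho1y == a$rho2y))
  # all null points respect the diagonal feasibility bound
  expect_true(all(abs(a$rho1y) < diagonal_range(a$rho12)))
  pw <- power_sweep(sim_config(tests = "williams", rho12_values = 0.6,
                               lattice_step = 0.3, n_values = 20,
                               reps = 200, seed = 7))
  expect_true(all(pw$rho2y > pw$rho1y))
  expect_true(all(c("delta", "mean_rho") %in% names(pw)))
})

test_that("null sweeps refuse mixed families for X1 and X2", {
  cfg <- sim_config(tests = "williams", rho12_values = 0,
                    diagonal_step = 0.5, n_values = 20, reps = 100,
                    dist_specs = list("uniform", "beta:2,5", "uniform"),
                    seed = 1)
  expect_error(type1_sweep(cfg), "share a distribution family")
})

test_that("lognormal null sweeps skip unattainable targets", {
  # rho12 = -0.6 is below the lognormal floor of -exp(-1)
  cfg <- sim_config(tests = "williams", rho12_values = c(-0.6, 0.3),
                    diagonal_step = 0.25, n_values = 20, reps = 200,
                    dist_specs = "lognormal", seed = 3)
  w <- testthat::capture_warnings(out <- robustness_sweep(cfg))
  expect_true(any(grepl("skipping", w)))
  expect_true(all(out$rho12 == 0.3))
  expect_identical(unique(out$dist), "lognormal")
})
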