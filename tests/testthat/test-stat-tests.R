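test_that("standard Williams reproduces the published worked examples", {
  cases <- list(
    # r1y, r2y, r12, n, t_W, p (p = NA when only the statistic is printed)
    list(-0.22, -0.13, 0.46, 73, -0.7420, 0.461),
    list(0.209, 0.086, 0.114, 112, 0.9846, 0.327),
    list(0.209, -0.086, 0.114, 112, 2.3795, 0.019),
    list(-0.11, 0.10, -0.45, 150, -1.5067, 0.134),
    list(-0.11, -0.03, -0.33, 150, -0.5979, 0.551),
    list(0.10, -0.03, -0.30, 150, 0.9817, 0.328),
    list(-0.22, 0.17, -0.35, 100, -2.4077, 0.018))
  for (cs in cases) {
    t <- cor_triplet(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_equal(williams_t(t), cs[[5]], tolerance = 5e-5 / abs(cs[[5]]))
    res <- dep_cor_test(t, "williams")
    expect_equal(res$p, cs[[6]], tolerance = 5e-4 / cs[[6]])
  }
  # unsigned-strength comparison via the sign-flip device
  f <- flip_for_unsigned(cor_triplet(-0.22, 0.17, -0.35, 100))
  expect_equal(abs(williams_t(f)), 0.4437, tolerance = 5e-5 / 0.4437)
  expect_equal(dep_cor_test(f, "williams")$p, 0.658,
               tolerance = 5e-4 / 0.658)
})

test_that("every statistic is zero at r1y = r2y and antisymmetric", {
  trips <- random_feasible_triplets(50, seed = 11)
  for (nm in ALL_STAT_TESTS) {
    f <- stat_fun(nm)
    # zero at equality
    for (r in c(-0.6, 0, 0.4)) {
      t0 <- cor_triplet(r, r, 0.3, 60)
      expect_equal(f(t0), 0, info = nm)
    }
    # swapping r1y and r2y negates the statistic
    for (i in seq_len(nrow(trips))) {
      a <- cor_triplet(trips[i, 1], trips[i, 2], trips[i, 3], 80)
      b <- cor_triplet(trips[i, 2], trips[i, 1], trips[i, 3], 80)
      sa <- f(a); sb <- f(b)
      expect_equal(is.na(sa), is.na(sb), info = nm)
      if (!is.na(sa)) expect_equal(sa, -sb, info = nm)
    }
  }
})

test_that("statistics match the independent equation oracle to 1e-10", {
  trips <- random_feasible_triplets(1000, seed = 7)
  ns <- c(20L, 50L, 100L, 200L)
  for (nm in ALL_STAT_TESTS) {
    f <- stat_fun(nm)
    got <- vapply(seq_len(nrow(trips)), function(i) {
      f(cor_triplet(trips[i, 1], trips[i, 2], trips[i, 3],
                    ns[1 + (i %% 4)]))
    }, 0)
    want <- vapply(seq_len(nrow(trips)), function(i) {
      oracle_stat(nm, trips[i, 1], trips[i, 2], trips[i, 3],
                  ns[1 + (i %% 4)])
    }, 0)
    both <- !is.na(got) & !is.na(want)
    expect_gt(mean(both), 0.95)
    relerr <- abs(got[both] - want[both]) /
      pmax(abs(want[both]), .Machine$double.eps)
    expect_lt(max(relerr), 1e-10)
  }
})

test_that("Hotelling dominates Williams and HSH in magnitude", {
  trips <- random_feasible_triplets(400, seed = 13)
  for (i in seq_len(nrow(trips))) {
    t <- cor_triplet(trips[i, 1], trips[i, 2], trips[i, 3], 50)
    th <- hotelling_t(t); tw <- williams_t(t); ts <- hsh_t(t)
    if (!anyNA(c(th, tw, ts))) {
      expect_gte(abs(th), abs(tw) - 1e-12)
      expect_gte(abs(th), abs(ts) - 1e-12)
    }
  }
})

test_that("HSH equals Hotelling exactly when r1y = r2y", {
  for (r12 in c(-0.4, 0.2, 0.7)) {
    t <- cor_triplet(0.35, 0.35, r12, 40)
    expect_identical(hsh_t(t), hotelling_t(t))
  }
})

test_that("the three covariance-style statistics coincide at r1y = r2y", {
  # with equal correlations the mean, the back-transformed mean z and the
  # individual correlations all collapse to the common value, so the
  # Dunn-Clark, Steiger and HMS statistics are identical (all zero) and,
  # more tellingly, their p-values and applicability agree
  for (r in c(-0.5, 0.2, 0.6)) {
    t <- cor_triplet(r, r, 0.25, 90)
    rd <- dep_cor_test(t, "dunn_clark")
    rs <- dep_cor_test(t, "steiger")
    rh <- dep_cor_test(t, "hms")
    expect_identical(rd$statistic, 0)
    expect_identical(rs$statistic, 0)
    expect_identical(rh$statistic, 0)
    expect_identical(c(rd$p, rs$p, rh$p), rep(1, 3))
  }
})

test_that("Meng-Rosenthal-Rubin capping behaves per its definition", {
  # at (.6, .6, -.5): f = 1.171875 exceeds 1 but stays below 1/r2bar,
  # so the uncapped variant is defined; capping substitutes f = 1, h = 1
  t <- cor_triplet(0.6, 0.6, -0.5, 50)
  expect_identical(mrr_z(t), 0)              # zero numerator either way
  expect_identical(mrr_z(t, cap_f = TRUE), 0)
  # check f and h through a nonzero-numerator neighbour
  t2 <- cor_triplet(0.62, 0.58, -0.5, 50)
  un <- mrr_z(t2); ca <- mrr_z(t2, cap_f = TRUE)
  expect_true(is.finite(un) && is.finite(ca))
  expect_true(abs(un) > abs(ca))  # f > 1 shrinks h, inflating the statistic
  # capped h = 1 exactly: statistic reduces to (z1-z2)*sqrt((n-3)/(2(1-r12)))
  z <- atanh(0.62) - atanh(0.58)
  r2b <- (0.62^2 + 0.58^2) / 2
  h_capped <- (1 - r2b) / (1 - r2b)
  expect_equal(ca, z * sqrt(47 / (2 * 1.5 * h_capped)))
  # uncapped variant undefined once f >= 1/r2bar
  t3 <- cor_triplet(0.9, 0.88, -0.9, 50)   # r2bar(3 - r12) > 2
  expect_true(is.na(mrr_z(t3)))
  expect_true(is.finite(mrr_z(t3, cap_f = TRUE)))
})

test_that("evaluate contract: p-values, tails, and undefined handling", {
  t <- cor_triplet(0.5, -0.3, 0.2, 60)
  for (nm in ALL_STAT_TESTS) {
    res <- dep_cor_test(t, nm, alpha = 0.05)
    expect_true(res$applicable)
    expect_true(res$p >= 0 && res$p <= 1)
    expect_false(res$reject_lower && res$reject_upper)
    ref_p <- if (res$reference == "student_t")
      2 * pt(-abs(res$statistic), df = t$n - 3)
    else 2 * pnorm(-abs(res$statistic))
    expect_equal(res$p, ref_p)
  }
  # lower-tail rejection for the signed example
  res <- dep_cor_test(cor_triplet(-0.22, 0.17, -0.35, 100), "williams")
  expect_true(res$reject_lower)
  expect_false(res$reject_upper)
  # undefined statistic: not applicable, no rejection
  und <- dep_cor_test(cor_triplet(0.95, -0.95, 0.9, 20), "hotelling")
  expect_false(und$applicable)
  expect_true(is.na(und$statistic) && is.na(und$p))
  expect_false(und$reject)
  expect_error(dep_cor_test(t, "nope"), "unknown test")
})

test_that("Dunn-Clark stays finite in its extreme-opposite-sign anomaly region", {
  # large opposite-sign correlations with large r12: the statistic exists
  # (and famously fails to reject there); just pin finiteness
  t <- cor_triplet(0.95, -0.95, 0.1, 50)
  expect_true(is.finite(dunn_clark_z(t)))
})
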