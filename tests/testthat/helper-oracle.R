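# Independent scalar re-evaluations of each test's equation, kept separate
# from the package code paths: Fisher z via log, the correlation-matrix
# determinant via det(), and the standard Williams statistic in its
# classical (n - 1)-numerator arrangement. Used to pin the package's
# vectorized kernels to high precision.

oracle_z <- function(r) 0.5 * log((1 + r) / (1 - r))

oracle_det <- function(r1y, r2y, r12) {
  det(matrix(c(1, r12, r1y, r12, 1, r2y, r1y, r2y, 1), 3, 3))
}

oracle_stat <- function(name, r1y, r2y, r12, n, cap_f = FALSE) {
  R <- oracle_det(r1y, r2y, r12)
  rbar <- (r1y + r2y) / 2
  switch(name,
    pearson_filon = {
      k <- r12 * (1 - r1y^2 - r2y^2) -
        (r1y * r2y / 2) * (1 - r1y^2 - r2y^2 - r12^2)
      den <- (1 - r1y^2)^2 + (1 - r2y^2)^2 - 2 * k
      if (den <= 0) return(NA_real_)
      (r1y - r2y) * sqrt(n) / sqrt(den)
    },
    olkin = {
      den <- (1 - r1y^2)^2 + (1 - r2y^2)^2 - 2 * r12^3 -
        (2 * r12 - r1y * r2y) * (1 - r1y^2 - r2y^2 - r12^2)
      if (den <= 0) return(NA_real_)
      (r1y - r2y) * sqrt(n) / sqrt(den)
    },
    hotelling = {
      if (R <= 0) return(NA_real_)
      (r1y - r2y) * sqrt((n - 3) * (1 + r12)) / sqrt(2 * R)
    },
    williams = {
      # classical arrangement with the (n - 1) numerator
      den <- 2 * R * (n - 1) / (n - 3) + rbar^2 * (1 - r12)^3
      if (den <= 0) return(NA_real_)
      (r1y - r2y) * sqrt((n - 1) * (1 + r12)) / sqrt(den)
    },
    hsh = {
      den <- 2 * R + (r1y - r2y)^2 * (1 - r12)^3 / (4 * (n - 1))
      if (den <= 0) return(NA_real_)
      (r1y - r2y) * sqrt((n - 3) * (1 + r12)) / sqrt(den)
    },
    dunn_clark = {
      cc <- (r12 * (1 - r1y^2 - r2y^2) -
               0.5 * r1y * r2y * (1 - r1y^2 - r2y^2 - r12^2)) /
        ((1 - r1y^2) * (1 - r2y^2))
      if (2 - 2 * cc <= 0) return(NA_real_)
      (oracle_z(r1y) - oracle_z(r2y)) * sqrt((n - 3) / (2 - 2 * cc))
    },
    steiger = {
      cc <- (r12 * (1 - 2 * rbar^2) -
               0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)) / (1 - rbar^2)^2
      if (2 - 2 * cc <= 0) return(NA_real_)
      (oracle_z(r1y) - oracle_z(r2y)) * sqrt((n - 3) / (2 - 2 * cc))
    },
    hms = {
      zb <- (oracle_z(r1y) + oracle_z(r2y)) / 2
      m <- (exp(2 * zb) - 1) / (exp(2 * zb) + 1)
      cc <- (r12 * (1 - 2 * m^2) -
               0.5 * m^2 * (1 - 2 * m^2 - r12^2)) / (1 - m^2)^2
      if (2 - 2 * cc <= 0) return(NA_real_)
      (oracle_z(r1y) - oracle_z(r2y)) * sqrt((n - 3) / (2 - 2 * cc))
    },
    mrr = {
      r2b <- (r1y^2 + r2y^2) / 2
      f <- (1 - r12) / (2 * (1 - r2b))
      if (cap_f) f <- min(f, 1)
      h <- (1 - f * r2b) / (1 - r2b)
      if (2 * (1 - r12) * h <= 0) return(NA_real_)
      (oracle_z(r1y) - oracle_z(r2y)) * sqrt((n - 3) / (2 * (1 - r12) * h))
    },
    stop("no oracle for ", name))
}

oracle_zou <- function(r1y, r2y, r12, n, alpha = 0.05) {
  q <- qnorm(1 - alpha / 2) / sqrt(n - 3)
  bt <- function(z) (exp(2 * z) - 1) / (exp(2 * z) + 1)
  l1 <- bt(oracle_z(r1y) - q); u1 <- bt(oracle_z(r1y) + q)
  l2 <- bt(oracle_z(r2y) - q); u2 <- bt(oracle_z(r2y) + q)
  cz <- ((r12 - 0.5 * r1y * r2y) * (1 - r1y^2 - r2y^2 - r12^2) + r12^3) /
    ((1 - r1y^2) * (1 - r2y^2))
  radL <- (r1y - l1)^2 + (u2 - r2y)^2 - 2 * cz * (r1y - l1) * (u2 - r2y)
  radU <- (u1 - r1y)^2 + (r2y - l2)^2 - 2 * cz * (u1 - r1y) * (r2y - l2)
  c(L = if (radL < 0) NA_real_ else r1y - r2y - sqrt(radL),
    U = if (radU < 0) NA_real_ else r1y - r2y + sqrt(radU))
}

# uniform draws over the open feasibility region (rejection sampling)
random_feasible_triplets <- function(k, seed = 1) {
  set.seed(seed)
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < k) {
    m <- matrix(runif(3 * 2 * k, -0.99, 0.99), ncol = 3)
    keep <- 1 - m[, 1]^2 - m[, 2]^2 - m[, 3]^2 +
      2 * m[, 1] * m[, 2] * m[, 3] > 1e-6
    out <- rbind(out, m[keep, , drop = FALSE])
  }
  out[seq_len(k), , drop = FALSE]  # columns: r1y, r2y, r12
}

stat_fun <- function(name) {
  switch(name,
    pearson_filon = pearson_filon_z, olkin = olkin_z,
    hotelling = hotelling_t, williams = williams_t, hsh = hsh_t,
    dunn_clark = dunn_clark_z, steiger = steiger_z, hms = hms_z,
    mrr = mrr_z)
}

ALL_STAT_TESTS <- c("pearson_filon", "olkin", "hotelling", "williams",
                    "hsh", "dunn_clark", "steiger", "hms", "mrr")
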