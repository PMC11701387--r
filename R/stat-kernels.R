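# Vectorized kernels for the ten test statistics. Each kernel accepts
# vectors of sample correlations (recycled against each other), a scalar n,
# and returns the statistic with NA_real_ wherever it is undefined. The
# same kernels serve the scalar user-facing functions, the applicability
# masks and the Monte Carlo engine, so undefined samples are a value, not
# an exception, and can be counted.

# A radicand (or a denominator entering one) at or below this tolerance is
# treated as undefined: boundary samples are measure-zero and any value
# this close to zero is numerically meaningless.
.RAD_TOL <- 1e-12

.det3 <- function(r1y, r2y, r12) {
  # determinant of the 3x3 correlation matrix
  1 - r1y^2 - r2y^2 - r12^2 + 2 * r1y * r2y * r12
}

.guard_sqrt <- function(rad) {
  # sqrt with the undefined-marker contract
  out <- rep(NA_real_, length(rad))
  ok <- is.finite(rad) & rad > .RAD_TOL
  out[ok] <- sqrt(rad[ok])
  out
}

.k_pearson_filon <- function(r1y, r2y, r12, n) {
  k <- r12 * (1 - r1y^2 - r2y^2) -
    0.5 * r1y * r2y * (1 - r1y^2 - r2y^2 - r12^2)
  rad <- (1 - r1y^2)^2 + (1 - r2y^2)^2 - 2 * k
  (r1y - r2y) * sqrt(n) / .guard_sqrt(rad)
}

.k_olkin <- function(r1y, r2y, r12, n) {
  rad <- (1 - r1y^2)^2 + (1 - r2y^2)^2 - 2 * r12^3 -
    (2 * r12 - r1y * r2y) * (1 - r1y^2 - r2y^2 - r12^2)
  (r1y - r2y) * sqrt(n) / .guard_sqrt(rad)
}

.k_hotelling <- function(r1y, r2y, r12, n) {
  R <- .det3(r1y, r2y, r12)
  den <- 2 * R
  rad <- ifelse(den > .RAD_TOL, (n - 3) * (1 + r12) / den, NA_real_)
  (r1y - r2y) * .guard_sqrt(rad)
}

.k_williams <- function(r1y, r2y, r12, n) {
  R <- .det3(r1y, r2y, r12)
  rbar <- (r1y + r2y) / 2
  den <- 2 * R + rbar^2 * ((n - 3) / (n - 1)) * (1 - r12)^3
  rad <- ifelse(den > .RAD_TOL, (n - 3) * (1 + r12) / den, NA_real_)
  (r1y - r2y) * .guard_sqrt(rad)
}

.k_hsh <- function(r1y, r2y, r12, n) {
  R <- .det3(r1y, r2y, r12)
  den <- 2 * R + (r1y - r2y)^2 * (1 - r12)^3 / (4 * (n - 1))
  rad <- ifelse(den > .RAD_TOL, (n - 3) * (1 + r12) / den, NA_real_)
  (r1y - r2y) * .guard_sqrt(rad)
}

# covariance-style term shared by the z-difference tests, evaluated at the
# supplied pair (a, b) standing in for (r1y, r2y) or their collapsed means
.c_num <- function(r12, a, b) {
  r12 * (1 - a^2 - b^2) - 0.5 * a * b * (1 - a^2 - b^2 - r12^2)
}

.k_dunn_clark <- function(r1y, r2y, r12, n) {
  cdc <- .c_num(r12, r1y, r2y) / ((1 - r1y^2) * (1 - r2y^2))
  rad <- ifelse(2 - 2 * cdc > .RAD_TOL, (n - 3) / (2 - 2 * cdc), NA_real_)
  (atanh(r1y) - atanh(r2y)) * .guard_sqrt(rad)
}

.c_collapsed <- function(r12, rbar) {
  (r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)) /
    (1 - rbar^2)^2
}

.k_steiger <- function(r1y, r2y, r12, n) {
  cs <- .c_collapsed(r12, (r1y + r2y) / 2)
  rad <- ifelse(2 - 2 * cs > .RAD_TOL, (n - 3) / (2 - 2 * cs), NA_real_)
  (atanh(r1y) - atanh(r2y)) * .guard_sqrt(rad)
}

.k_hms <- function(r1y, r2y, r12, n) {
  z1 <- atanh(r1y); z2 <- atanh(r2y)
  rbz <- tanh((z1 + z2) / 2)  # back-transformed mean z
  ch <- .c_collapsed(r12, rbz)
  rad <- ifelse(2 - 2 * ch > .RAD_TOL, (n - 3) / (2 - 2 * ch), NA_real_)
  (z1 - z2) * .guard_sqrt(rad)
}

.k_mrr <- function(r1y, r2y, r12, n, cap_f = FALSE) {
  r2bar <- (r1y^2 + r2y^2) / 2
  f <- (1 - r12) / (2 * (1 - r2bar))
  if (cap_f) f <- pmin(f, 1)
  h <- (1 - f * r2bar) / (1 - r2bar)
  den <- 2 * (1 - r12) * h
  rad <- ifelse(den > .RAD_TOL, (n - 3) / den, NA_real_)
  (atanh(r1y) - atanh(r2y)) * .guard_sqrt(rad)
}

# Zou's interval endpoints, vectorized; returns list(L, U) with NA where a
# radicand fails.
.k_zou <- function(r1y, r2y, r12, n, alpha = 0.05) {
  zc <- stats::qnorm(1 - alpha / 2)
  se <- zc / sqrt(n - 3)
  z1 <- atanh(r1y); z2 <- atanh(r2y)
  l1 <- tanh(z1 - se); u1 <- tanh(z1 + se)
  l2 <- tanh(z2 - se); u2 <- tanh(z2 + se)
  cz <- ((r12 - 0.5 * r1y * r2y) * (1 - r1y^2 - r2y^2 - r12^2) + r12^3) /
    ((1 - r1y^2) * (1 - r2y^2))
  radL <- (r1y - l1)^2 + (u2 - r2y)^2 - 2 * cz * (r1y - l1) * (u2 - r2y)
  radU <- (u1 - r1y)^2 + (r2y - l2)^2 - 2 * cz * (u1 - r1y) * (r2y - l2)
  okL <- is.finite(radL) & radL >= 0
  okU <- is.finite(radU) & radU >= 0
  L <- U <- rep(NA_real_, length(radL))
  d <- r1y - r2y
  L[okL] <- (d - sqrt(radL))[okL]
  U[okU] <- (d + sqrt(radU))[okU]
  list(L = L, U = U, l1 = l1, u1 = u1, l2 = l2, u2 = u2,
       l1_star = z1 - se, u1_star = z1 + se,
       l2_star = z2 - se, u2_star = z2 + se,
       c_z = cz, z_crit = zc)
}

# dispatch table: kernel + reference distribution
.TESTS <- list(
  pearson_filon = list(kernel = .k_pearson_filon, ref = "standard_normal"),
  olkin         = list(kernel = .k_olkin,         ref = "standard_normal"),
  hotelling     = list(kernel = .k_hotelling,     ref = "student_t"),
  williams      = list(kernel = .k_williams,      ref = "student_t"),
  hsh           = list(kernel = .k_hsh,           ref = "student_t"),
  dunn_clark    = list(kernel = .k_dunn_clark,    ref = "standard_normal"),
  steiger       = list(kernel = .k_steiger,       ref = "standard_normal"),
  hms           = list(kernel = .k_hms,           ref = "standard_normal"),
  mrr           = list(kernel = .k_mrr,           ref = "standard_normal"),
  zou           = list(kernel = NULL,             ref = "interval")
)

.test_names <- function() names(.TESTS)

.check_test_name <- function(name) {
  if (length(name) != 1L || is.na(match(name, names(.TESTS))))
    stop(sprintf("unknown test '%s'; choose one of: %s",
                 paste(name, collapse = ","),
                 paste(names(.TESTS), collapse = ", ")), call. = FALSE)
  name
}

# statistic vector for a named test; zou handled by callers
.stat_vec <- function(name, r1y, r2y, r12, n, cap_f = FALSE) {
  if (name == "mrr") return(.k_mrr(r1y, r2y, r12, n, cap_f = cap_f))
  .TESTS[[name]]$kernel(r1y, r2y, r12, n)
}
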