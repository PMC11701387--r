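#' Marginal distribution specification for simulated variables
#'
#' Describes the marginal distribution of one simulated variable. Four
#' families are supported: \code{"normal"} (standard normal),
#' \code{"beta"} with shapes \code{a}, \code{b} (uniform is beta(1, 1)),
#' \code{"lognormal"} (exp of a standard normal, i.e. Lognormal(0, 1)), and
#' \code{"mixture"} — a contaminated normal drawing from N(0, 1) with
#' probability \code{1 - mix_p} and from a same-correlation normal with
#' variance \code{mix_var} otherwise.
#'
#' @param family one of \code{"normal"}, \code{"beta"},
#'   \code{"lognormal"}, \code{"mixture"}.
#' @param a,b beta shape parameters (beta family only), both positive.
#' @param mix_p contamination probability in (0, 1) (mixture only;
#'   default 0.1).
#' @param mix_var variance of the contaminating component, greater than 1
#'   (mixture only).
#' @return an object of class \code{"dist_spec"}.
#' @examples
#' dist_spec("beta", a = 2, b = 5)
#' dist_spec("mixture", mix_var = 10)
#' @export
dist_spec <- function(family = c("normal", "beta", "lognormal", "mixture"),
                      a = NULL, b = NULL, mix_p = 0.1, mix_var = NULL) {
  family <- match.arg(family)
  if (family == "beta") {
    if (is.null(a) || is.null(b) || a <= 0 || b <= 0)
      stop("beta family needs shapes a > 0 and b > 0", call. = FALSE)
  } else if (family == "mixture") {
    if (is.null(mix_var) || mix_var <= 1)
      stop("mixture family needs mix_var > 1", call. = FALSE)
    if (mix_p <= 0 || mix_p >= 1)
      stop("mix_p must lie in (0, 1)", call. = FALSE)
  }
  structure(list(family = family, a = a, b = b,
                 mix_p = if (family == "mixture") mix_p else NULL,
                 mix_var = mix_var),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  lab <- switch(x$family,
    normal = "standard normal",
    beta = sprintf("Beta(%g, %g)", x$a, x$b),
    lognormal = "Lognormal(0, 1)",
    mixture = sprintf("%g N(0,1) + %g N(0, var = %g)",
                      1 - x$mix_p, x$mix_p, x$mix_var))
  cat("Marginal distribution:", lab, "\n")
  invisible(x)
}

.as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_dist_spec(x))
  stop("cannot coerce to dist_spec", call. = FALSE)
}

#' Parse a compact distribution label
#'
#' Accepts \code{"normal"}, \code{"uniform"}, \code{"beta:a,b"},
#' \code{"lognormal"} and \code{"mixture:v"} (contamination probability
#' fixed at 0.1) — the grammar the command line uses.
#'
#' @param s a single string.
#' @return a [dist_spec()].
#' @export
parse_dist_spec <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  if (s == "normal") return(dist_spec("normal"))
  if (s == "uniform") return(dist_spec("beta", a = 1, b = 1))
  if (s == "lognormal") return(dist_spec("lognormal"))
  if (grepl("^beta:", s)) {
    ab <- as.numeric(strsplit(sub("^beta:", "", s), ",")[[1]])
    if (length(ab) != 2 || any(is.na(ab)))
      stop("beta spec must be 'beta:a,b'", call. = FALSE)
    return(dist_spec("beta", a = ab[1], b = ab[2]))
  }
  if (grepl("^mixture:", s)) {
    v <- as.numeric(sub("^mixture:", "", s))
    if (is.na(v)) stop("mixture spec must be 'mixture:v'", call. = FALSE)
    return(dist_spec("mixture", mix_var = v))
  }
  stop(sprintf("unknown distribution '%s'", s), call. = FALSE)
}

#' Closed-form skewness and kurtosis of the simulation marginals
#'
#' Returns the population skewness and (non-excess) kurtosis of a marginal
#' family: normal (0, 3); Beta(a, b) by the standard beta-moment formulas;
#' Lognormal(0, 1) with skewness \eqn{(e + 2)\sqrt{e - 1}} and kurtosis
#' \eqn{e^4 + 2e^3 + 3e^2 - 3}; and the scale-contaminated normal with
#' skewness 0 and kurtosis \eqn{3(1 - p + pv^2)/(1 - p + pv)^2} where
#' \eqn{p} is the contamination probability and \eqn{v} the contaminating
#' variance.
#'
#' @param spec a [dist_spec()] or compact label string.
#' @return named numeric \code{c(skewness, kurtosis)}.
#' @examples
#' analytic_moments("uniform")               # (0, 1.8)
#' analytic_moments(dist_spec("beta", 2, 5)) # (0.596, 2.880)
#' analytic_moments("mixture:10")            # (0, 9.059)
#' @export
analytic_moments <- function(spec) {
  spec <- .as_dist_spec(spec)
  out <- switch(spec$family,
    normal = c(0, 3),
    beta = {
      a <- spec$a; b <- spec$b
      skew <- 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
      ex <- 6 * ((a - b)^2 * (a + b + 1) - a * b * (a + b + 2)) /
        (a * b * (a + b + 2) * (a + b + 3))
      c(skew, 3 + ex)
    },
    lognormal = {
      e <- exp(1)
      c((e + 2) * sqrt(e - 1), e^4 + 2 * e^3 + 3 * e^2 - 3)
    },
    mixture = {
      p <- spec$mix_p; v <- spec$mix_var
      c(0, 3 * (1 - p + p * v^2) / (1 - p + p * v)^2)
    })
  c(skewness = out[1], kurtosis = out[2])
}

#' Normal-scale correlation needed to hit a lognormal target
#'
#' When standard normal variables with correlation \eqn{\rho_z} are
#' exponentiated, the lognormal variables correlate
#' \eqn{\rho = (e^{\rho_z} - 1)/(e - 1)} ([lognormal_correlation()]).
#' This function inverts that map: \eqn{\rho_z = \log\{1 + \rho(e - 1)\}},
#' so a generating normal correlation can be chosen to land a lognormal
#' target. Because \eqn{\rho_z \ge -1}, lognormal targets below
#' \eqn{-e^{-1} \approx -0.3679} are unattainable.
#'
#' @param rho_target desired correlation between the lognormal variables,
#'   strictly greater than \code{-exp(-1)}.
#' @return the correlation to impose on the generating normals.
#' @examples
#' lognormal_base_correlation(-0.3)   # log(1 - 0.3 * (exp(1) - 1))
#' lognormal_correlation(lognormal_base_correlation(0.5))
#' @export
lognormal_base_correlation <- function(rho_target) {
  if (any(rho_target <= -exp(-1)))
    stop("lognormal correlations below -exp(-1) are impossible",
         call. = FALSE)
  log(1 + rho_target * (exp(1) - 1))
}

#' @rdname lognormal_base_correlation
#' @param rho_normal correlation between the generating standard normals.
#' @export
lognormal_correlation <- function(rho_normal) {
  (exp(rho_normal) - 1) / (exp(1) - 1)
}

# ntotal x 3 matrix of correlated standard normals, columns X1, X2, Y;
# uses the Cholesky root of the correlation matrix
.latent_normal <- function(p, ntotal) {
  S <- .pop_matrix(p)
  cf <- tryCatch(chol(S), error = function(e)
    stop("infeasible correlation matrix", call. = FALSE))
  z <- matrix(stats::rnorm(3 * ntotal), ncol = 3)
  z %*% cf
}

.new_sample <- function(m, seed, target) {
  structure(list(x1 = m[, 1], x2 = m[, 2], y = m[, 3],
                 seed = seed, target = target),
            class = "trivariate_sample")
}

#' @export
print.trivariate_sample <- function(x, ...) {
  cat(sprintf("Trivariate sample: n = %d triplets (seed %s)\n",
              length(x$y), format(x$seed)))
  cat(sprintf("  empirical r12 = %.3f, r1y = %.3f, r2y = %.3f\n",
              stats::cor(x$x1, x$x2), stats::cor(x$x1, x$y),
              stats::cor(x$x2, x$y)))
  invisible(x)
}

#' Draw correlated trivariate normal triplets
#'
#' Generates \code{n} independent triplets \eqn{(X_1, X_2, Y)} with zero
#' means, unit variances and the requested correlation matrix, via the
#' Cholesky root applied to independent standard normals. Deterministic
#' given \code{seed}.
#'
#' @param p a [pop_cor()]; must be feasible.
#' @param n number of triplets, at least 4.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return an object of class \code{"trivariate_sample"} with vectors
#'   \code{x1}, \code{x2}, \code{y}.
#' @examples
#' s <- sample_trivariate_normal(pop_cor(0.75, 0.8, 0.8), 50, seed = 1)
#' @export
sample_trivariate_normal <- function(p, n, seed = NULL) {
  p <- as_pop_cor(p)
  if (!is_feasible(p)) stop("infeasible correlation triplet", call. = FALSE)
  stopifnot(n >= 4)
  if (!is.null(seed)) set.seed(seed)
  .new_sample(.latent_normal(p, n), seed, p)
}

#' Inverse-transform latent normals to beta marginals
#'
#' Applies \eqn{X = F^{-1}\{\Phi(Z); a, b\}} componentwise, where
#' \eqn{\Phi} is the standard normal CDF and \eqn{F^{-1}} the beta
#' quantile function of each variable's spec. Marginals become exactly
#' Beta(a, b); pairwise correlations of the latent normals are very nearly
#' preserved for moderate shapes (the residual bias is not corrected).
#'
#' @param s a \code{trivariate_sample} of (latent) normals.
#' @param specs a list of three [dist_spec()]s, family \code{"beta"}, for
#'   X1, X2 and Y respectively; a single spec is recycled.
#' @return a \code{trivariate_sample} with beta marginals.
#' @examples
#' s <- sample_trivariate_normal(pop_cor(0, 0.3, 0.3), 100, seed = 1)
#' u <- transform_beta(s, dist_spec("beta", a = 1, b = 1))
#' @export
transform_beta <- function(s, specs) {
  stopifnot(inherits(s, "trivariate_sample"))
  if (inherits(specs, "dist_spec")) specs <- list(specs, specs, specs)
  stopifnot(length(specs) == 3)
  specs <- lapply(specs, .as_dist_spec)
  if (any(vapply(specs, function(d) d$family, "") != "beta"))
    stop("transform_beta() requires beta specs (uniform is beta(1,1))",
         call. = FALSE)
  tr <- function(z, d) stats::qbeta(stats::pnorm(z), d$a, d$b)
  .new_sample(cbind(tr(s$x1, specs[[1]]), tr(s$x2, specs[[2]]),
                    tr(s$y, specs[[3]])), s$seed, s$target)
}

#' Exponentiate latent normals to Lognormal(0, 1) marginals
#'
#' Applies \eqn{X = \exp(Z)} componentwise. For the transformed variables
#' to hit target correlations, the latent normals must be generated at the
#' pre-adjusted correlations given by [lognormal_base_correlation()].
#'
#' @param s a \code{trivariate_sample} of (latent) normals.
#' @return a \code{trivariate_sample} with lognormal marginals.
#' @export
transform_lognormal <- function(s) {
  stopifnot(inherits(s, "trivariate_sample"))
  .new_sample(cbind(exp(s$x1), exp(s$x2), exp(s$y)), s$seed, s$target)
}

#' Draw from a scale-contaminated trivariate normal
#'
#' Each triplet comes from the standard trivariate normal with correlation
#' matrix P with probability \code{1 - mix_p}, and from a trivariate
#' normal with the same correlation matrix but common variance \code{v}
#' (covariance \code{v * P}) with probability \code{mix_p}. Because both
#' components share the correlation matrix and differ only by a common
#' scale, the mixture's correlation matrix is exactly P; the marginals are
#' symmetric but heavy-tailed.
#'
#' @param p a [pop_cor()]; must be feasible.
#' @param v variance of the contaminating component (positive; \code{v =
#'   1} reduces to the plain normal).
#' @param mix_p contamination probability (default 0.1).
#' @param n number of triplets.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return a \code{trivariate_sample}.
#' @examples
#' s <- sample_mixture(pop_cor(0, 0, 0), v = 10, n = 200, seed = 1)
#' @export
sample_mixture <- function(p, v, mix_p = 0.1, n, seed = NULL) {
  p <- as_pop_cor(p)
  if (!is_feasible(p)) stop("infeasible correlation triplet", call. = FALSE)
  stopifnot(v > 0, mix_p > 0, mix_p < 1, n >= 4)
  if (!is.null(seed)) set.seed(seed)
  m <- .latent_normal(p, n)
  contaminated <- stats::runif(n) < mix_p
  m[contaminated, ] <- m[contaminated, , drop = FALSE] * sqrt(v)
  .new_sample(m, seed, p)
}
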