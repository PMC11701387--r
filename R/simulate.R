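# Monte Carlo engine: empirical Type I error, power and robustness of the
# ten tests. One condition = (population correlations, n, marginal
# distributions); each condition draws `reps` samples of n triplets,
# computes the three sample correlations per replication (vectorized over
# replications), evaluates each requested test two-sidedly, and counts
# rejections per tail plus undefined statistics. Undefined statistics
# count as non-rejections with denominator `reps` but are reported so the
# accounting is auditable.

.dist_label <- function(specs) {
  lab <- vapply(specs, function(d) switch(d$family,
    normal = "normal",
    beta = if (d$a == 1 && d$b == 1) "uniform"
           else sprintf("beta(%g,%g)", d$a, d$b),
    lognormal = "lognormal",
    mixture = sprintf("mixture(%g)", d$mix_var)), "")
  if (length(unique(lab)) == 1) lab[1] else paste(lab, collapse = "/")
}

.normalize_specs <- function(dists) {
  if (is.null(dists)) dists <- dist_spec("normal")
  if (inherits(dists, "dist_spec") || is.character(dists) &&
      length(dists) == 1)
    dists <- list(dists, dists, dists)
  if (is.character(dists)) dists <- as.list(dists)
  stopifnot(length(dists) == 3)
  lapply(dists, .as_dist_spec)
}

# ntotal x 3 matrix of observations with the requested marginals and
# target correlations. Lognormal marginals pre-adjust the latent
# correlations (and must be lognormal for all three variables); mixture
# contamination applies to whole triplets so the correlation matrix is
# preserved.
.gen_observations <- function(p, specs, ntotal) {
  fam <- vapply(specs, function(d) d$family, "")
  if (any(fam == "mixture")) {
    if (!all(fam == "mixture"))
      stop("mixture contamination applies to the whole triplet; ",
           "all three variables must share the mixture spec", call. = FALSE)
    v <- unique(vapply(specs, function(d) d$mix_var, 0))
    mp <- unique(vapply(specs, function(d) d$mix_p, 0))
    if (length(v) != 1 || length(mp) != 1)
      stop("all three mixture specs must share mix_var and mix_p",
           call. = FALSE)
    m <- .latent_normal(p, ntotal)
    hit <- stats::runif(ntotal) < mp
    m[hit, ] <- m[hit, , drop = FALSE] * sqrt(v)
    return(m)
  }
  if (any(fam == "lognormal")) {
    if (!all(fam == "lognormal"))
      stop("the lognormal correlation adjustment requires all three ",
           "variables to be lognormal", call. = FALSE)
    pz <- pop_cor(lognormal_base_correlation(p$rho12),
                  lognormal_base_correlation(p$rho1y),
                  lognormal_base_correlation(p$rho2y))
    if (!is_feasible(pz))
      stop("lognormal targets infeasible after back-adjustment",
           call. = FALSE)
    return(exp(.latent_normal(pz, ntotal)))
  }
  m <- .latent_normal(p, ntotal)
  for (j in 1:3) {
    d <- specs[[j]]
    if (d$family == "beta")
      m[, j] <- stats::qbeta(stats::pnorm(m[, j]), d$a, d$b)
  }
  m
}

# per-replication Pearson correlations of two n x reps matrices
.col_cor <- function(a, b, n) {
  sa <- colSums(a); sb <- colSums(b)
  sab <- colSums(a * b) - sa * sb / n
  saa <- colSums(a * a) - sa^2 / n
  sbb <- colSums(b * b) - sb^2 / n
  sab / sqrt(saa * sbb)
}

#' Empirical rejection rates of the tests at one simulation condition
#'
#' Draws \code{reps} samples of \code{n} triplets at the given population
#' correlations and marginal distributions, computes the sample
#' correlation triplet of every replication, evaluates each requested test
#' two-sidedly at level \code{alpha} (\eqn{\alpha/2} per tail), and
#' returns per-tail rejection counts, undefined-statistic counts and the
#' overall rejection rate. When the population satisfies
#' \eqn{\rho_{1Y} = \rho_{2Y}} the rate estimates the Type I error;
#' otherwise it estimates power. Undefined statistics count as
#' non-rejections out of \code{reps}.
#'
#' @param p a [pop_cor()]; must be feasible.
#' @param n triplets per replication.
#' @param reps number of replications.
#' @param tests character vector of test names (see [dep_cor_test()]).
#' @param dists marginal distributions: a single [dist_spec()] or compact
#'   label applied to all three variables, or a list of three (X1, X2, Y).
#' @param alpha nominal two-sided level.
#' @param seed integer seed for the condition; \code{NULL} leaves the RNG
#'   state alone.
#' @param cap_f cap the Meng-Rosenthal-Rubin f factor at 1.
#' @return a data frame with one row per test and columns \code{test},
#'   \code{dist}, \code{rho12}, \code{rho1y}, \code{rho2y}, \code{n},
#'   \code{reps}, \code{reject_lower}, \code{reject_upper},
#'   \code{undefined}, \code{rate}, \code{se} (binomial standard error of
#'   the rate) and \code{seed}.
#' @examples
#' mc_rejection_rates(pop_cor(0.75, 0.8, 0.8), n = 50, reps = 500,
#'                    tests = "williams", seed = 1)
#' @export
mc_rejection_rates <- function(p, n, reps, tests = "williams",
                               dists = "normal", alpha = 0.05,
                               seed = NULL, cap_f = FALSE) {
  p <- as_pop_cor(p)
  if (!is_feasible(p)) stop("infeasible correlation triplet", call. = FALSE)
  stopifnot(n >= 4, reps >= 1, alpha > 0, alpha < 1)
  tests <- vapply(tests, .check_test_name, "")
  specs <- .normalize_specs(dists)
  if (!is.null(seed)) set.seed(seed)
  m <- .gen_observations(p, specs, as.double(n) * reps)
  x1 <- matrix(m[, 1], nrow = n)
  x2 <- matrix(m[, 2], nrow = n)
  y  <- matrix(m[, 3], nrow = n)
  r1y <- .col_cor(x1, y, n)
  r2y <- .col_cor(x2, y, n)
  r12 <- .col_cor(x1, x2, n)
  rows <- lapply(tests, function(nm) {
    if (nm == "zou") {
      z <- .k_zou(r1y, r2y, r12, n, alpha = alpha)
      def <- is.finite(z$L) & is.finite(z$U)
      rl <- sum(def & z$U < 0)
      ru <- sum(def & z$L > 0)
    } else {
      stat <- .stat_vec(nm, r1y, r2y, r12, n, cap_f = cap_f)
      def <- is.finite(stat)
      crit <- if (.TESTS[[nm]]$ref == "student_t")
        stats::qt(1 - alpha / 2, df = n - 3)
      else stats::qnorm(1 - alpha / 2)
      rl <- sum(def & stat < -crit)
      ru <- sum(def & stat > crit)
    }
    rate <- (rl + ru) / reps
    data.frame(test = nm, dist = .dist_label(specs),
               rho12 = p$rho12, rho1y = p$rho1y, rho2y = p$rho2y,
               n = n, reps = reps,
               reject_lower = rl, reject_upper = ru,
               undefined = sum(!def), rate = rate,
               se = sqrt(rate * (1 - rate) / reps),
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
  do.call(rbind, rows)
}

#' Simulation configuration
#'
#' Bundles the design of a sweep: which tests, which values of
#' \eqn{\rho_{12}}, the spacing of null points along the equal-correlation
#' diagonal, the spacing of the power lattice, the sample sizes, the
#' replication count, the level, the marginal distributions and the master
#' seed. Defaults are desk-scale: full grids at these replication counts
#' run in minutes, and the replication count can be raised for full-scale
#' reproduction.
#'
#' @param tests character vector of test names.
#' @param rho12_values values of \eqn{\rho_{12}} to sweep.
#' @param diagonal_step spacing of null points on the diagonal.
#' @param lattice_step spacing of the power lattice.
#' @param n_values sample sizes.
#' @param reps replications per condition.
#' @param alpha nominal level.
#' @param dist_specs marginals (see [mc_rejection_rates()]).
#' @param seed master seed; per-condition seeds are derived
#'   deterministically from it and the condition index, so conditions are
#'   independently reproducible.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(tests = c("williams", "dunn_clark", "steiger",
                                 "mrr", "zou"),
                       rho12_values = round(seq(-0.9, 0.9, by = 0.15), 10),
                       diagonal_step = 0.02, lattice_step = 0.04,
                       n_values = c(20, 50, 100, 200), reps = 20000,
                       alpha = 0.05, dist_specs = "normal", seed = 1L) {
  stopifnot(reps >= 1, alpha > 0, alpha < 1,
            diagonal_step > 0, lattice_step > 0)
  structure(list(tests = tests, rho12_values = rho12_values,
                 diagonal_step = diagonal_step,
                 lattice_step = lattice_step, n_values = n_values,
                 reps = reps, alpha = alpha,
                 dist_specs = .normalize_specs(dist_specs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-condition substream seed (kept below 2^31)
.cond_seed <- function(master, idx) {
  as.integer((as.double(master) + 104729 * as.double(idx)) %% 2147483647)
}

# feasible null points (rho, rho) for one rho12: multiples of `step` with
# a step/2 safety margin away from the degeneracy boundary
.null_diagonal <- function(rho12, step) {
  b <- diagonal_range(rho12) - step / 2
  if (b < 0) return(numeric(0))
  k <- floor(b / step + 1e-10)
  round(seq(-k, k) * step, 10)
}

#' Sweep of empirical Type I error rates over the null diagonal
#'
#' For every combination of \eqn{\rho_{12}}, feasible common correlation
#' \eqn{\rho_{1Y} = \rho_{2Y}} on the diagonal (at the configured step,
#' with a half-step safety margin from the degeneracy boundary) and sample
#' size, runs [mc_rejection_rates()] under the configured marginals and
#' collects the outcome rows. Null points that are infeasible under the
#' configured marginals (possible with lognormal targets) are skipped with
#' a warning.
#'
#' @param cfg a [sim_config()].
#' @return a data frame of condition-by-test outcome rows.
#' @export
type1_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  labs <- vapply(cfg$dist_specs, function(d) .dist_label(list(d)), "")
  if (labs[1] != labs[2])
    stop("X1 and X2 must share a distribution family under a null sweep ",
         "(otherwise the null hypothesis would not hold)", call. = FALSE)
  out <- list()
  idx <- 0L
  for (r12 in cfg$rho12_values) {
    for (rho in .null_diagonal(r12, cfg$diagonal_step)) {
      for (n in cfg$n_values) {
        idx <- idx + 1L
        p <- pop_cor(r12, rho, rho)
        res <- tryCatch(
          mc_rejection_rates(p, n = n, reps = cfg$reps,
                             tests = cfg$tests, dists = cfg$dist_specs,
                             alpha = cfg$alpha,
                             seed = .cond_seed(cfg$seed, idx)),
          error = function(e) {
            warning(sprintf(
              "skipping (rho12 = %g, rho = %g, n = %d): %s",
              r12, rho, n, conditionMessage(e)), call. = FALSE)
            NULL
          })
        if (!is.null(res)) out[[length(out) + 1L]] <- res
      }
    }
  }
  do.call(rbind, out)
}

#' Lattice of alternative hypotheses for the power study
#'
#' Starting from reference points on the identity diagonal
#' (\eqn{\rho_{1Y} = \rho_{2Y}} from \eqn{-0.96} to \eqn{0.96} in steps of
#' \code{step}), off-diagonal points are created by progressively
#' subtracting \code{step} from the reference \eqn{\rho_{1Y}} and adding
#' it to \eqn{\rho_{2Y}}, keeping only points above the diagonal
#' (\eqn{\rho_{2Y} > \rho_{1Y}}; the tests are symmetric in the sign of
#' the difference) that are feasible at the given \eqn{\rho_{12}}. Every
#' point on one off-diagonal ray shares its mean correlation
#' \eqn{(\rho_{1Y} + \rho_{2Y})/2} with its diagonal reference.
#'
#' @param rho12 the fixed correlation between X1 and X2.
#' @param step lattice spacing (default 0.04).
#' @return a data frame with columns \code{rho1y}, \code{rho2y},
#'   \code{mean_rho} (the diagonal reference) and \code{delta}
#'   (\eqn{\rho_{2Y} - \rho_{1Y}}).
#' @examples
#' nrow(build_power_lattice(0.9))  # more points than at rho12 = -0.6
#' nrow(build_power_lattice(-0.6))
#' @export
build_power_lattice <- function(rho12, step = 0.04) {
  stopifnot(step > 0)
  refs <- round(seq(-0.96, 0.96, by = step), 10)
  rows <- list()
  for (ref in refs) {
    k <- 1L
    repeat {
      r1 <- round(ref - k * step, 10)
      r2 <- round(ref + k * step, 10)
      if (r1 <= -1 || r2 >= 1) break
      if (is_feasible(pop_cor(rho12, r1, r2)))
        rows[[length(rows) + 1L]] <-
          data.frame(rho1y = r1, rho2y = r2, mean_rho = ref,
                     delta = r2 - r1)
      k <- k + 1L
    }
  }
  if (!length(rows))
    return(data.frame(rho1y = numeric(0), rho2y = numeric(0),
                      mean_rho = numeric(0), delta = numeric(0)))
  do.call(rbind, rows)
}

#' Sweep of empirical power over the alternative lattice
#'
#' Runs [mc_rejection_rates()] at every feasible lattice point (see
#' [build_power_lattice()]) for each configured \eqn{\rho_{12}} and sample
#' size. The outcome rows carry \code{delta} \eqn{= |\rho_{1Y} -
#' \rho_{2Y}|} and \code{mean_rho} for effect-size summaries.
#'
#' @param cfg a [sim_config()] (its \code{lattice_step} sets the spacing).
#' @return a data frame of condition-by-test outcome rows.
#' @export
power_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- list()
  idx <- 0L
  for (r12 in cfg$rho12_values) {
    lat <- build_power_lattice(r12, cfg$lattice_step)
    for (i in seq_len(nrow(lat))) {
      for (n in cfg$n_values) {
        idx <- idx + 1L
        p <- pop_cor(r12, lat$rho1y[i], lat$rho2y[i])
        res <- tryCatch(
          mc_rejection_rates(p, n = n, reps = cfg$reps,
                             tests = cfg$tests, dists = cfg$dist_specs,
                             alpha = cfg$alpha,
                             seed = .cond_seed(cfg$seed, idx)),
          error = function(e) {
            warning(sprintf("skipping lattice point (%g, %g): %s",
                            lat$rho1y[i], lat$rho2y[i],
                            conditionMessage(e)), call. = FALSE)
            NULL
          })
        if (!is.null(res)) {
          res$delta <- lat$delta[i]
          res$mean_rho <- lat$mean_rho[i]
          out[[length(out) + 1L]] <- res
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Accuracy sweep under non-normal marginals
#'
#' A Type I error sweep ([type1_sweep()]) with non-normal marginal
#' distributions; \eqn{X_1} and \eqn{X_2} must share a family so the null
#' remains true. With lognormal marginals, null points whose targets fall
#' outside the attainable lognormal correlation range
#' (\eqn{> -e^{-1}}) are skipped with a warning.
#'
#' @param cfg a [sim_config()] whose \code{dist_specs} are non-normal.
#' @return a data frame of condition-by-test outcome rows.
#' @export
robustness_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fam <- vapply(cfg$dist_specs, function(d) d$family, "")
  if (all(fam == "normal"))
    warning("all marginals are normal; this is a plain type1_sweep()")
  type1_sweep(cfg)
}
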