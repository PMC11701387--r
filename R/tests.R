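#' The ten test statistics for two dependent overlapping correlations
#'
#' Each function computes one classical statistic for the null
#' \eqn{H_0: \rho_{1Y} = \rho_{2Y}} from the sample correlations and sample
#' size held in a [cor_triplet()]. Statistics referred to a standard normal
#' distribution: Pearson-Filon, Olkin (with the Hendrickson-Collins
#' correction), Dunn-Clark, Steiger, Hittner-May-Silver and
#' Meng-Rosenthal-Rubin. Statistics referred to a Student t distribution
#' with \eqn{n - 3} degrees of freedom: Hotelling, standard Williams and
#' Hendrickson-Stanley-Hills.
#'
#' Every statistic involves a square root whose radicand is a function of
#' the sample correlations and is not guaranteed to be positive. When it is
#' not, the statistic is undefined for that sample and \code{NA_real_} is
#' returned — a value, not an error, so simulations can count undefined
#' samples.
#'
#' For Meng-Rosenthal-Rubin, the factor
#' \eqn{f = (1 - r_{12}) / \{2(1 - \bar{r^2})\}} is used as computed when
#' \code{cap_f = FALSE} (the default), which leaves the statistic undefined
#' whenever \eqn{f \ge 1/\bar{r^2}}; the original prescription replaces any
#' \eqn{f > 1} with 1 (\code{cap_f = TRUE}), which makes the statistic
#' computable everywhere on the correlation cube.
#'
#' @param t a [cor_triplet()] (or a list with fields r1y, r2y, r12, n).
#' @param cap_f logical; cap the Meng-Rosenthal-Rubin \eqn{f} factor at 1.
#' @return the statistic as a length-1 numeric; \code{NA_real_} if
#'   undefined.
#' @examples
#' t <- cor_triplet(-0.22, -0.13, 0.46, 73)
#' williams_t(t)      # -0.7420
#' hotelling_t(t)
#' dunn_clark_z(t)
#' @name dep_cor_statistics
NULL

.stat1 <- function(name, t, cap_f = FALSE) {
  t <- as_cor_triplet(t)
  .stat_vec(name, t$r1y, t$r2y, t$r12, t$n, cap_f = cap_f)
}

#' @rdname dep_cor_statistics
#' @export
pearson_filon_z <- function(t) .stat1("pearson_filon", t)

#' @rdname dep_cor_statistics
#' @export
olkin_z <- function(t) .stat1("olkin", t)

#' @rdname dep_cor_statistics
#' @export
hotelling_t <- function(t) .stat1("hotelling", t)

#' @rdname dep_cor_statistics
#' @export
williams_t <- function(t) .stat1("williams", t)

#' @rdname dep_cor_statistics
#' @export
hsh_t <- function(t) .stat1("hsh", t)

#' @rdname dep_cor_statistics
#' @export
dunn_clark_z <- function(t) .stat1("dunn_clark", t)

#' @rdname dep_cor_statistics
#' @export
steiger_z <- function(t) .stat1("steiger", t)

#' @rdname dep_cor_statistics
#' @export
hms_z <- function(t) .stat1("hms", t)

#' @rdname dep_cor_statistics
#' @export
mrr_z <- function(t, cap_f = FALSE) .stat1("mrr", t, cap_f = cap_f)

#' Zou's confidence interval for the difference of two dependent
#' correlations
#'
#' Builds the \eqn{100(1-\alpha)\%} confidence interval \eqn{(L, U)} for
#' \eqn{\rho_{1Y} - \rho_{2Y}} from back-transformed Fisher-z limits of the
#' two individual correlations, combined with the estimated correlation
#' between the two correlation estimates. The null of equality is rejected
#' whenever \eqn{L > 0} or \eqn{U < 0}.
#'
#' @inheritParams dep_cor_statistics
#' @param alpha nominal level of the two-sided test (default 0.05).
#' @return an object of class \code{"zou_interval"}: a list with elements
#'   \code{L}, \code{U}, the per-correlation back-transformed limits
#'   \code{l1, u1, l2, u2}, their z-scale counterparts \code{l1_star},
#'   \code{u1_star}, \code{l2_star}, \code{u2_star}, the covariance term
#'   \code{c_z}, the critical value \code{z_crit}, \code{alpha}, and the
#'   decision flag \code{reject}. \code{L}/\code{U} are \code{NA} if a
#'   radicand is negative.
#' @examples
#' zou_interval(cor_triplet(0.209, 0.086, 0.114, 112))
#' @export
zou_interval <- function(t, alpha = 0.05) {
  t <- as_cor_triplet(t)
  stopifnot(alpha > 0, alpha < 1)
  z <- .k_zou(t$r1y, t$r2y, t$r12, t$n, alpha = alpha)
  applicable <- is.finite(z$L) && is.finite(z$U)
  structure(
    list(L = z$L, U = z$U,
         l1 = z$l1, u1 = z$u1, l2 = z$l2, u2 = z$u2,
         l1_star = z$l1_star, u1_star = z$u1_star,
         l2_star = z$l2_star, u2_star = z$u2_star,
         c_z = z$c_z, z_crit = z$z_crit, alpha = alpha,
         applicable = applicable,
         reject = applicable && (z$L > 0 || z$U < 0)),
    class = "zou_interval")
}

#' @export
print.zou_interval <- function(x, ...) {
  cat(sprintf("Zou %d%% CI for rho1y - rho2y: [%.4f, %.4f]  %s\n",
              round(100 * (1 - x$alpha)), x$L, x$U,
              if (!x$applicable) "(undefined)"
              else if (x$reject) "-> reject equality"
              else "-> no rejection"))
  invisible(x)
}

#' Run one named test and report its full decision record
#'
#' Computes the requested statistic, its two-sided p-value under the named
#' reference distribution (standard normal, or Student t with \eqn{n - 3}
#' degrees of freedom), and the per-tail rejection decisions at
#' \eqn{\alpha/2} per tail. For the Zou method the decision comes from the
#' interval and no p-value is produced. An undefined statistic yields
#' \code{applicable = FALSE} and no rejection.
#'
#' @param t a [cor_triplet()].
#' @param test one of \code{"pearson_filon"}, \code{"olkin"},
#'   \code{"hotelling"}, \code{"williams"}, \code{"hsh"},
#'   \code{"dunn_clark"}, \code{"steiger"}, \code{"hms"}, \code{"mrr"},
#'   \code{"zou"}.
#' @param alpha nominal two-sided level.
#' @param cap_f for \code{test = "mrr"}: cap the \eqn{f} factor at 1.
#' @return an object of class \code{"dep_cor_result"} with fields
#'   \code{test}, \code{statistic}, \code{reference}, \code{df} (NA for
#'   normal-reference tests), \code{p}, \code{reject_lower},
#'   \code{reject_upper}, \code{reject}, \code{applicable}, \code{alpha},
#'   and for zou the \code{interval}.
#' @examples
#' dep_cor_test(cor_triplet(-0.22, -0.13, 0.46, 73), "williams")
#' @export
dep_cor_test <- function(t, test = "williams", alpha = 0.05,
                         cap_f = FALSE) {
  t <- as_cor_triplet(t)
  test <- .check_test_name(test)
  stopifnot(alpha > 0, alpha < 1)
  ref <- .TESTS[[test]]$ref
  df <- if (ref == "student_t") t$n - 3L else NA_integer_
  interval <- NULL
  if (test == "zou") {
    interval <- zou_interval(t, alpha = alpha)
    applicable <- interval$applicable
    stat <- NA_real_
    p <- NA_real_
    rl <- applicable && interval$U < 0
    ru <- applicable && interval$L > 0
  } else {
    stat <- .stat1(test, t, cap_f = cap_f)
    applicable <- is.finite(stat)
    if (applicable) {
      if (ref == "student_t") {
        p <- 2 * stats::pt(-abs(stat), df = df)
        crit <- stats::qt(1 - alpha / 2, df = df)
      } else {
        p <- 2 * stats::pnorm(-abs(stat))
        crit <- stats::qnorm(1 - alpha / 2)
      }
      rl <- stat < -crit
      ru <- stat > crit
    } else {
      p <- NA_real_
      rl <- FALSE
      ru <- FALSE
    }
  }
  structure(
    list(test = test, statistic = stat, reference = ref, df = df, p = p,
         reject_lower = rl, reject_upper = ru, reject = rl || ru,
         applicable = applicable, alpha = alpha, cap_f = cap_f,
         interval = interval, input = t),
    class = "dep_cor_result")
}

#' @export
print.dep_cor_result <- function(x, ...) {
  cat(sprintf("Test of rho(X1,Y) = rho(X2,Y): %s\n", x$test))
  ti <- x$input
  cat(sprintf("  r1y = %.4f, r2y = %.4f, r12 = %.4f, n = %d\n",
              ti$r1y, ti$r2y, ti$r12, ti$n))
  if (!x$applicable) {
    cat("  statistic undefined for this sample (non-positive radicand)\n")
  } else if (x$test == "zou") {
    print(x$interval)
  } else {
    lab <- if (x$reference == "student_t")
      sprintf("t(%d)", x$df) else "z"
    cat(sprintf("  %s = %.4f, p = %.3f  (%s at alpha = %g)\n",
                lab, x$statistic, x$p,
                if (x$reject) "reject" else "no rejection", x$alpha))
  }
  invisible(x)
}

#' Run every test on one triplet
#'
#' @inheritParams dep_cor_test
#' @param tests character vector of test names; default all ten.
#' @return a data frame with one row per test: \code{test},
#'   \code{statistic}, \code{df}, \code{p}, \code{L}, \code{U},
#'   \code{reject}, \code{applicable}, \code{recommended} (the five tests
#'   with acceptable Type I error behaviour under normality).
#' @examples
#' dep_cor_test_all(cor_triplet(0.209, 0.086, 0.114, 112))
#' @export
dep_cor_test_all <- function(t, tests = .test_names(), alpha = 0.05,
                             cap_f = FALSE) {
  rows <- lapply(tests, function(nm) {
    r <- dep_cor_test(t, nm, alpha = alpha, cap_f = cap_f)
    data.frame(test = nm, statistic = r$statistic, df = r$df, p = r$p,
               L = if (is.null(r$interval)) NA_real_ else r$interval$L,
               U = if (is.null(r$interval)) NA_real_ else r$interval$U,
               reject = r$reject, applicable = r$applicable)
  })
  out <- do.call(rbind, rows)
  out$recommended <- out$test %in%
    c("williams", "dunn_clark", "steiger", "mrr", "zou")
  out
}

#' Region of empirical applicability of a test
#'
#' Evaluates, on a square grid over \eqn{(r_{1Y}, r_{2Y})} at a fixed
#' sample value of \eqn{r_{12}}, whether the named statistic is defined
#' (positive radicand). The Hotelling radicand reproduces exactly the
#' positive-definiteness condition of the sample correlation matrix; the
#' Hittner-May-Silver statistic is defined everywhere on the open cube; the
#' uncapped Meng-Rosenthal-Rubin statistic loses cells inside the
#' feasibility ellipse when \eqn{r_{12} < 0}.
#'
#' @param test test name (see [dep_cor_test()]); \code{"zou"} checks that
#'   both interval radicands are non-negative.
#' @param r12 fixed sample correlation between X1 and X2.
#' @param grid_step grid spacing in (0, 1); the grid covers
#'   \code{seq(-1 + grid_step, 1 - grid_step, by = grid_step)}.
#' @param n sample size used in the statistic.
#' @param cap_f cap the Meng-Rosenthal-Rubin f factor at 1.
#' @return a logical matrix with \code{r1y} on rows and \code{r2y} on
#'   columns (dimnames give the grid values); \code{TRUE} where defined.
#' @examples
#' m <- applicability_mask("hotelling", r12 = 0.5, grid_step = 0.25, n = 50)
#' @export
applicability_mask <- function(test, r12, grid_step = 0.02, n = 100,
                               cap_f = FALSE) {
  test <- .check_test_name(test)
  stopifnot(grid_step > 0, grid_step < 1, abs(r12) <= 1)
  g <- seq(-1 + grid_step, 1 - grid_step, by = grid_step)
  g <- round(g, 10)
  r1 <- rep(g, times = length(g))
  r2 <- rep(g, each = length(g))
  if (test == "zou") {
    z <- .k_zou(r1, r2, r12, n)
    ok <- is.finite(z$L) & is.finite(z$U)
  } else {
    ok <- is.finite(.stat_vec(test, r1, r2, r12, n, cap_f = cap_f))
  }
  matrix(ok, nrow = length(g), dimnames = list(r1y = g, r2y = g))
}
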