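#' Fisher's variance-stabilizing z transformation
#'
#' Maps a correlation \eqn{r} to \eqn{z = \frac{1}{2}\log\{(1+r)/(1-r)\}}.
#' The transformation is strictly increasing and odd; its inverse is
#' [inverse_fisher_z()].
#'
#' @param r numeric vector of correlations with \code{abs(r) < 1}.
#' @return numeric vector on the z scale.
#' @examples
#' fisher_z(0.5)           # 0.5 * log(3)
#' inverse_fisher_z(fisher_z(0.3))
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z() requires |r| < 1", call. = FALSE)
  atanh(r)
}

#' @rdname fisher_z
#' @param z numeric vector on the z scale.
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Bundle the sample quantities consumed by every test
#'
#' A correlation triplet holds the three pairwise Pearson correlations among
#' \eqn{X_1}, \eqn{X_2} and \eqn{Y} together with the common sample size
#' \eqn{n}: \code{r1y} = cor(X1, Y), \code{r2y} = cor(X2, Y) and
#' \code{r12} = cor(X1, X2).
#'
#' @param r1y,r2y,r12 correlations in \eqn{[-1, 1]}.
#' @param n integer sample size, at least 4 (so that \eqn{n - 3 \ge 1}
#'   degrees of freedom exist).
#' @return an object of class \code{"cor_triplet"}.
#' @seealso [correlations_from_data()] to build one from raw data,
#'   [dep_cor_test()] to run a test on it.
#' @examples
#' cor_triplet(-0.22, -0.13, 0.46, n = 73)
#' @export
cor_triplet <- function(r1y, r2y, r12, n) {
  stopifnot(length(r1y) == 1, length(r2y) == 1, length(r12) == 1,
            length(n) == 1)
  r <- c(r1y = r1y, r2y = r2y, r12 = r12)
  if (any(!is.finite(r)) || any(abs(r) > 1))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  n <- as.integer(n)
  if (!is.finite(n) || n < 4L)
    stop("n must be an integer >= 4", call. = FALSE)
  structure(list(r1y = r1y, r2y = r2y, r12 = r12, n = n),
            class = "cor_triplet")
}

#' @export
print.cor_triplet <- function(x, ...) {
  cat(sprintf("Correlation triplet (n = %d)\n", x$n))
  cat(sprintf("  r(X1,Y)  = % .4f\n  r(X2,Y)  = % .4f\n  r(X1,X2) = % .4f\n",
              x$r1y, x$r2y, x$r12))
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && dropped > 0L)
    cat(sprintf("  (%d incomplete rows dropped)\n", dropped))
  invisible(x)
}

as_cor_triplet <- function(x) {
  if (inherits(x, "cor_triplet")) return(x)
  if (is.list(x) && all(c("r1y", "r2y", "r12", "n") %in% names(x)))
    return(cor_triplet(x$r1y, x$r2y, x$r12, x$n))
  stop("cannot coerce to a cor_triplet", call. = FALSE)
}

#' Compute a correlation triplet from a raw three-column table
#'
#' Takes complete cases of a numeric table with columns ordered
#' \eqn{X_1, X_2, Y} and returns the three pairwise Pearson correlations and
#' the complete-case count. Rows with any missing value are dropped; the
#' number dropped is recorded in the \code{"dropped"} attribute so a single
#' \eqn{n} applies to all three correlations.
#'
#' @param table a data frame or matrix with at least three numeric columns
#'   (extra columns are ignored); column order is X1, X2, Y.
#' @return a [cor_triplet()] with attribute \code{dropped}.
#' @examples
#' set.seed(1)
#' d <- data.frame(X1 = rnorm(30), X2 = rnorm(30), Y = rnorm(30))
#' correlations_from_data(d)
#' @export
correlations_from_data <- function(table) {
  m <- as.matrix(as.data.frame(table)[, 1:3])
  storage.mode(m) <- "double"
  keep <- stats::complete.cases(m)
  dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 4L)
    stop("fewer than 4 complete rows", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column: correlations undefined", call. = FALSE)
  # snap correlations within rounding error of +/-1 to the boundary so
  # collinear inputs are flagged as such rather than yielding huge
  # finite Fisher z values
  snap <- function(r) if (abs(abs(r) - 1) < 1e-12) sign(r) else r
  out <- cor_triplet(r1y = snap(stats::cor(m[, 1], m[, 3])),
                     r2y = snap(stats::cor(m[, 2], m[, 3])),
                     r12 = snap(stats::cor(m[, 1], m[, 2])),
                     n = nrow(m))
  attr(out, "dropped") <- dropped
  out
}

#' Sign-flip transform for comparing unsigned correlation strength
#'
#' Testing \eqn{|\rho_{1Y}| = |\rho_{2Y}|} when the two sample correlations
#' differ in sign can be recast as the signed null
#' \eqn{\rho_{1Y} = \rho_{-2Y}}, where \eqn{-2} denotes the negated variable
#' \eqn{-X_2}. Negating \eqn{X_2} negates every correlation involving it, so
#' the transform maps \eqn{(r_{1Y}, r_{2Y}, r_{12})} to
#' \eqn{(r_{1Y}, -r_{2Y}, -r_{12})}. It is an involution. Note the sign of
#' a statistic computed on the flipped triplet depends on which variable is
#' negated; its magnitude and p-value do not.
#'
#' @param t a [cor_triplet()].
#' @return the flipped \code{cor_triplet}.
#' @examples
#' flip_for_unsigned(cor_triplet(-0.22, 0.17, -0.35, 100))
#' @export
flip_for_unsigned <- function(t) {
  t <- as_cor_triplet(t)
  cor_triplet(t$r1y, -t$r2y, -t$r12, t$n)
}
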