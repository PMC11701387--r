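#' Population correlations of the trivariate model
#'
#' Holds the three population correlations \eqn{(\rho_{12}, \rho_{1Y},
#' \rho_{2Y})} that define the 3x3 correlation matrix of \eqn{(X_1, X_2,
#' Y)}.
#'
#' @param rho12,rho1y,rho2y correlations in \eqn{[-1, 1]}.
#' @return an object of class \code{"pop_cor"}.
#' @export
pop_cor <- function(rho12, rho1y, rho2y) {
  r <- c(rho12 = rho12, rho1y = rho1y, rho2y = rho2y)
  if (any(!is.finite(r)) || any(abs(r) > 1))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  structure(list(rho12 = rho12, rho1y = rho1y, rho2y = rho2y),
            class = "pop_cor")
}

#' @export
print.pop_cor <- function(x, ...) {
  cat(sprintf(
    "Population correlations: rho12 = %.3f, rho1y = %.3f, rho2y = %.3f (%s)\n",
    x$rho12, x$rho1y, x$rho2y,
    if (is_feasible(x)) "feasible" else "infeasible"))
  invisible(x)
}

as_pop_cor <- function(x) {
  if (inherits(x, "pop_cor")) return(x)
  if (is.list(x) && all(c("rho12", "rho1y", "rho2y") %in% names(x)))
    return(pop_cor(x$rho12, x$rho1y, x$rho2y))
  if (is.numeric(x) && length(x) == 3) return(pop_cor(x[1], x[2], x[3]))
  stop("cannot coerce to pop_cor", call. = FALSE)
}

.pop_matrix <- function(p) {
  matrix(c(1, p$rho12, p$rho1y,
           p$rho12, 1, p$rho2y,
           p$rho1y, p$rho2y, 1), 3, 3)
}

#' Can a non-degenerate trivariate normal have these correlations?
#'
#' A non-degenerate trivariate normal distribution with correlations
#' \eqn{(\rho_{12}, \rho_{1Y}, \rho_{2Y})} exists if and only if the
#' determinant of the correlation matrix,
#' \eqn{1 - \rho_{1Y}^2 - \rho_{2Y}^2 - \rho_{12}^2 +
#' 2\rho_{1Y}\rho_{2Y}\rho_{12}}, is strictly positive. Boundary cases
#' (determinant zero) are degenerate and reported as infeasible.
#'
#' @param p a [pop_cor()] (or numeric c(rho12, rho1y, rho2y)).
#' @return logical flag.
#' @examples
#' is_feasible(pop_cor(0.75, 0.8, 0.8))   # TRUE
#' is_feasible(pop_cor(-0.9, 0.9, 0.9))   # FALSE
#' @export
is_feasible <- function(p) {
  p <- as_pop_cor(p)
  det3 <- 1 - p$rho1y^2 - p$rho2y^2 - p$rho12^2 +
    2 * p$rho1y * p$rho2y * p$rho12
  det3 > 0
}

#' Admissible range of one correlation given the other two
#'
#' Solving the positivity of the correlation-matrix determinant for
#' \eqn{\rho_{2Y}} gives the open interval
#' \deqn{\rho_{12}\rho_{1Y} \pm \sqrt{(1-\rho_{12}^2)(1-\rho_{1Y}^2)},}
#' which is non-empty for every interior pair
#' \eqn{(\rho_{12}, \rho_{1Y})}.
#'
#' @param rho12,rho1y correlations with absolute value strictly below 1.
#' @return named numeric \code{c(lo, hi)}; the open interval of feasible
#'   \eqn{\rho_{2Y}}. If either input sits on the boundary
#'   (\eqn{|\rho| = 1}) the interval is degenerate and a warning is
#'   issued.
#' @examples
#' rho2y_bounds(0.5, 0)   # +/- sqrt(0.75)
#' @export
rho2y_bounds <- function(rho12, rho1y) {
  stopifnot(abs(rho12) <= 1, abs(rho1y) <= 1)
  if (abs(rho12) == 1 || abs(rho1y) == 1)
    warning("boundary input: the feasible interval is degenerate")
  half <- sqrt((1 - rho12^2) * (1 - rho1y^2))
  c(lo = rho12 * rho1y - half, hi = rho12 * rho1y + half)
}

#' Feasible extent of the equal-correlation diagonal
#'
#' On the null diagonal \eqn{\rho_{1Y} = \rho_{2Y} = \rho}, the determinant
#' condition reduces to \eqn{|\rho| < \sqrt{(1 + \rho_{12})/2}}. The bound
#' widens from 0 at \eqn{\rho_{12} = -1} to 1 at \eqn{\rho_{12} = 1}, so
#' negative \eqn{\rho_{12}} leaves little room for large common
#' correlations.
#'
#' @param rho12 correlation in \eqn{[-1, 1]}.
#' @return the bound \eqn{b}; \eqn{\rho_{1Y} = \rho_{2Y} = \rho} is
#'   feasible iff \eqn{|\rho| < b}.
#' @examples
#' diagonal_range(0)     # sqrt(1/2)
#' diagonal_range(0.9)   # sqrt(0.95)
#' @export
diagonal_range <- function(rho12) {
  stopifnot(abs(rho12) <= 1)
  sqrt((1 + rho12) / 2)
}
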