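#' Clamped cubic B-spline trajectories
#'
#' Joint-angle and motor-current profiles are parameterized as clamped cubic
#' B-splines over the task interval \eqn{[0, T]}: the knot vector has
#' end-knot multiplicity 4 with uniformly spaced interior knots, so the
#' curve interpolates its first and last control points.  Evaluation and
#' differentiation are linear in the control points, which makes control
#' points natural design variables for gradient-based optimization.
#'
#' @param control_points Numeric vector of control points (length at least
#'   `degree + 1`).
#' @param duration Domain length T (s); the spline is defined on `[0, T]`.
#' @param degree Spline degree (cubic by default).
#' @return A `bspline_trajectory` object.
#' @examples
#' tr <- bspline_trajectory(c(0, 0.2, 0.8, 1, 1), duration = 1.44)
#' evaluate_trajectory(tr, c(0, 0.72, 1.44))
#' @export
bspline_trajectory <- function(control_points, duration, degree = 3L) {
  n_ctrl <- length(control_points)
  if (n_ctrl < degree + 1) {
    stop_liftopt("need at least degree + 1 control points",
                 "liftopt_validation_error")
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop_liftopt("`duration` must be positive", "liftopt_validation_error")
  }
  structure(
    list(
      control_points = as.numeric(control_points),
      degree = as.integer(degree),
      knots = clamped_knots(n_ctrl, c(0, duration), degree),
      duration = duration
    ),
    class = "bspline_trajectory"
  )
}

clamped_knots <- function(n_ctrl, domain, degree = 3L) {
  interior <- seq(domain[1], domain[2], length.out = n_ctrl - degree + 1)
  c(rep(domain[1], degree), interior, rep(domain[2], degree))
}

#' Basis matrix of a clamped B-spline
#'
#' Rows are evaluation points, columns control points; `deriv` selects the
#' derivative order.  Because evaluation is linear in the control points the
#' rows are exactly the sensitivities of value (or rate, acceleration) with
#' respect to the control points.
#'
#' @param traj A [bspline_trajectory()].
#' @param t Evaluation times in `[0, duration]`.
#' @param deriv Derivative order (0, 1, or 2).
#' @return A `length(t)` x `n_ctrl` matrix.
#' @export
basis_sensitivity <- function(traj, t, deriv = 0L) {
  check_domain(traj, t)
  splines::splineDesign(traj$knots, t, ord = traj$degree + 1L,
                        derivs = rep(deriv, length(t)))
}

#' Evaluate a B-spline trajectory
#'
#' @inheritParams basis_sensitivity
#' @return A list with numeric vectors `value`, `rate`, `acceleration`
#'   evaluated at `t`.
#' @export
evaluate_trajectory <- function(traj, t) {
  check_domain(traj, t)
  p <- traj$control_points
  list(
    value = drop(basis_sensitivity(traj, t, 0L) %*% p),
    rate = drop(basis_sensitivity(traj, t, 1L) %*% p),
    acceleration = drop(basis_sensitivity(traj, t, 2L) %*% p)
  )
}

check_domain <- function(traj, t) {
  if (any(!is.finite(t)) || any(t < traj$knots[1] - 1e-12) ||
      any(t > traj$duration + 1e-12)) {
    stop_liftopt("evaluation times must lie inside the spline domain",
                 "liftopt_validation_error")
  }
  invisible(TRUE)
}

#' Least-squares fit of a clamped cubic B-spline
#'
#' Finds the control points minimizing the sum of squared residuals between
#' the spline and the samples.
#'
#' @param samples A data frame (or tibble) with columns `abscissa` and
#'   `value`, or a two-column matrix.
#' @param n_ctrl Number of control points.
#' @param domain Length-2 fitting domain; defaults to the sample range.
#' @return A [bspline_trajectory()] over `domain` (shifted so the stored
#'   domain starts at `domain[1]`).
#' @export
fit_least_squares <- function(samples, n_ctrl, domain = NULL) {
  samples <- as.data.frame(samples)
  names(samples)[1:2] <- c("abscissa", "value")
  x <- samples$abscissa
  y <- samples$value
  if (length(x) < n_ctrl) {
    stop_liftopt("need at least `n_ctrl` samples", "liftopt_validation_error")
  }
  domain <- domain %||% range(x)
  if (diff(domain) <= 1e-12) {
    stop_liftopt("degenerate fitting domain: samples do not span an interval",
                 "liftopt_degenerate_domain")
  }
  # internally the trajectory domain is [0, width]
  width <- diff(domain)
  tr <- bspline_trajectory(rep(0, n_ctrl), width)
  B <- basis_sensitivity(tr, pmin(pmax(x - domain[1], 0), width), 0L)
  qrB <- qr(B)
  if (qrB$rank < n_ctrl) {
    stop_liftopt("rank-deficient fit: samples are too clustered for `n_ctrl`",
                 "liftopt_rank_deficient")
  }
  tr$control_points <- as.numeric(qr.coef(qrB, y))
  tr$origin <- domain[1]
  tr
}

#' @export
print.bspline_trajectory <- function(x, ...) {
  cat(sprintf(
    "<bspline_trajectory> degree %d, %d control points on [0, %.3g]\n",
    x$degree, length(x$control_points), x$duration
  ))
  invisible(x)
}
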