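#' Fit a torque-versus-angle controller map
#'
#' Converts an optimal exoskeleton torque time profile into a continuous
#' function of the assisted joint's encoder angle, for real-time lookup on
#' the device: a clamped cubic B-spline is least-squares fitted to the
#' (angle, torque) samples over the motion's angle range, and its control
#' points are then clamped to the device torque limit, which bounds the
#' whole map by the spline convex-hull property.  Where the motion visits
#' the same angle twice with different torques (descent/ascent hysteresis)
#' the single-valued fit averages the two branches.
#'
#' @param tau_opt Sampled optimal device torque (N m).
#' @param theta_opt Joint angles at the same sample times (rad).
#' @param n_ctrl Number of spline control points.
#' @param limit Device torque limit (N m); `Inf` disables clamping.
#' @return A `torque_angle_map` object.
#' @examples
#' th <- seq(0.3, 2, length.out = 50)
#' map <- fit_control_map(10 * sin(th), th, limit = 16)
#' lookup_torque(map, 1.2)
#' @export
fit_control_map <- function(tau_opt, theta_opt, n_ctrl = 8, limit = Inf) {
  stopifnot(length(tau_opt) == length(theta_opt))
  if (diff(range(theta_opt)) < 1e-6) {
    stop_liftopt("joint angle range is degenerate: cannot fit an angle-domain map",
                 "liftopt_degenerate_domain")
  }
  n_ctrl <- min(n_ctrl, length(unique(round(theta_opt, 9))))
  ord <- order(theta_opt)
  tr <- fit_least_squares(
    data.frame(abscissa = theta_opt[ord], value = tau_opt[ord]),
    n_ctrl = n_ctrl, domain = range(theta_opt)
  )
  tr$control_points <- pmin(pmax(tr$control_points, -limit), limit)
  fitted <- lookup_spline(tr, theta_opt)
  structure(
    list(
      spline = tr,
      domain = range(theta_opt),
      limit = limit,
      residual_rms = sqrt(mean((fitted - tau_opt)^2)),
      n_samples = length(tau_opt)
    ),
    class = "torque_angle_map"
  )
}

lookup_spline <- function(tr, theta) {
  th <- pmin(pmax(theta - tr$origin, 0), tr$duration)
  drop(basis_sensitivity(tr, th, 0L) %*% tr$control_points)
}

#' Evaluate a controller map at encoder angles
#'
#' @param map A [fit_control_map()] result.
#' @param theta Joint angle(s) (rad).  Outside the fitted domain the
#'   boundary value is held (`clamp = "hold"`) or zero torque is returned
#'   (`clamp = "zero"`).
#' @param clamp Out-of-domain behavior.
#' @return Torque value(s) (N m).
#' @export
lookup_torque <- function(map, theta, clamp = c("hold", "zero")) {
  clamp <- match.arg(clamp)
  out <- lookup_spline(map$spline, theta)
  if (clamp == "zero") {
    out[theta < map$domain[1] | theta > map$domain[2]] <- 0
  }
  out
}

#' @export
print.torque_angle_map <- function(x, ...) {
  cat(sprintf(
    "<torque_angle_map> angles [%.3f, %.3f] rad, limit %.1f N m, residual RMS %.3g N m\n",
    x$domain[1], x$domain[2], x$limit, x$residual_rms
  ))
  invisible(x)
}

#' Export a controller map as a lookup table
#'
#' @param map A [fit_control_map()] result.
#' @param n Number of table rows.
#' @return A tibble with `theta` (rad) and `tau` (N m).
#' @export
control_map_table <- function(map, n = 101) {
  theta <- seq(map$domain[1], map$domain[2], length.out = n)
  tibble::tibble(theta = theta, tau = lookup_torque(map, theta))
}

#' Controller map for a solved assisted case
#'
#' Samples the solved device torque and assisted-joint angle over the lift
#' and fits the angle-domain controller.
#'
#' @param solution A `lift_solution` with the device attached.
#' @param joint Assisted joint name (e.g. `"knee"`).
#' @param n_samples Time samples across the lift.
#' @param n_ctrl,limit Passed to [fit_control_map()]; the limit defaults to
#'   the device's configured torque limit.
#' @return A `torque_angle_map`.
#' @export
solution_control_map <- function(solution, joint = "knee", n_samples = 101,
                                 n_ctrl = 8, limit = NULL) {
  pr <- solution$problem
  e <- match(joint, vapply(pr$exos, `[[`, character(1), "joint"))
  if (is.na(e)) {
    stop_liftopt(sprintf("no exoskeleton at joint '%s'", joint),
                 "liftopt_validation_error")
  }
  exo <- pr$exos[[e]]
  ts <- seq(0, pr$task$duration, length.out = n_samples)
  ang <- evaluate_trajectory(solution_spline(solution, joint, "angle"), ts)
  cur <- evaluate_trajectory(solution_spline(solution, joint, "current"), ts)
  tau_e <- exo_torque(exo$motor, cur$value, joint_rate = ang$rate,
                      joint_accel = ang$acceleration)
  fit_control_map(tau_e, ang$value, n_ctrl = n_ctrl,
                  limit = limit %||% exo$tau_upper)
}
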