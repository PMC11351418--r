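#' Tidy a solved lift
#'
#' @param x A `lift_solution`.
#' @param ... Unused.
#' @return A long tibble with one row per grid time and joint: angles,
#'   rates, accelerations, human and device torques.
#' @method tidy lift_solution
#' @export
tidy.lift_solution <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a solved lift
#'
#' @param x A `lift_solution`.
#' @param ... Unused.
#' @return A one-row tibble: solver status, objective, constraint
#'   violation, mechanical energy, and peak torque magnitudes at the spine,
#'   shoulder, and knee.
#' @method glance lift_solution
#' @export
glance.lift_solution <- function(x, ...) {
  peaks <- x$trajectory |>
    dplyr::filter(.data$joint %in% c("spine", "shoulder", "knee")) |>
    dplyr::group_by(.data$joint) |>
    dplyr::summarise(peak = max(abs(.data$tau_human)), .groups = "drop")
  tibble::tibble(
    status = x$status,
    objective = x$objective,
    violation = x$violation,
    energy = x$energy,
    peak_spine = peaks$peak[peaks$joint == "spine"],
    peak_shoulder = peaks$peak[peaks$joint == "shoulder"],
    peak_knee = peaks$peak[peaks$joint == "knee"],
    iterations = x$iterations
  )
}

#' @method tidy torque_angle_map
#' @export
tidy.torque_angle_map <- function(x, ...) {
  control_map_table(x)
}

#' @method glance torque_angle_map
#' @export
glance.torque_angle_map <- function(x, ...) {
  tb <- control_map_table(x, n = 201)
  tibble::tibble(
    theta_min = x$domain[1], theta_max = x$domain[2],
    peak_torque = max(abs(tb$tau)),
    residual_rms = x$residual_rms,
    limit = x$limit, n_samples = x$n_samples
  )
}
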