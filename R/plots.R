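#' Stick-figure snapshots of a solved lift
#'
#' Draws the sagittal-plane skeleton at selected fractions of the lifting
#' cycle, with the carried box at the hand and markers on the
#' exoskeleton-assisted joints.
#'
#' @param solution A `lift_solution`.
#' @param times Fractions of the lift duration to draw.
#' @return A ggplot object (one facet per snapshot).
#' @export
plot_snapshots <- function(solution, times = c(0, 0.25, 0.5, 0.75, 1)) {
  pr <- solution$problem
  model <- pr$model
  frames <- purrr::map_dfr(times, function(fr) {
    t <- fr * pr$task$duration
    q <- vapply(model$joint_names, function(j) {
      evaluate_trajectory(solution_spline(solution, j, "angle"), t)$value
    }, numeric(1))
    A <- forward_kinematics(model, q)
    pts <- function(names) {
      purrr::map_dfr(names, function(nm) {
        p <- landmark(model, q, nm, fk = A)
        tibble::tibble(landmark = nm, y = p[2], z = p[3])
      })
    }
    upper <- pts(c("pelvis", "shoulder", "elbow", "wrist"))
    lower <- pts(c("pelvis", "knee", "ankle", "heel", "ball", "toe"))
    hand <- pts("hand")
    dplyr::bind_rows(
      dplyr::mutate(upper, chain = "upper"),
      dplyr::mutate(lower, chain = "lower"),
      dplyr::mutate(hand, chain = "hand")
    ) |>
      dplyr::mutate(cycle = sprintf("%d%%", round(100 * fr)))
  })
  frames$cycle <- factor(frames$cycle, levels = unique(frames$cycle))
  exo_joints <- vapply(pr$exos, `[[`, character(1), "joint")
  exo_pts <- frames |>
    dplyr::filter(.data$landmark %in% c(sub("spine", "pelvis", exo_joints),
                                        sub("shoulder", "shoulder", exo_joints),
                                        sub("knee", "knee", exo_joints)))
  p <- ggplot2::ggplot(frames, ggplot2::aes(x = .data$z, y = .data$y)) +
    ggplot2::geom_path(data = ~ dplyr::filter(.x, .data$chain == "upper"),
                       linewidth = 1) +
    ggplot2::geom_path(data = ~ dplyr::filter(.x, .data$chain == "lower"),
                       linewidth = 1) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$chain == "hand"),
                        shape = 15, size = 3, colour = "tan3") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~cycle, nrow = 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "anterior position z (m)", y = "height y (m)")
  if (nrow(exo_pts)) {
    p <- p + ggplot2::geom_point(data = exo_pts, colour = "orange", size = 3)
  }
  p
}

#' Plot a solved lift
#'
#' @param object A `lift_solution`.
#' @param what `"torque"` (human joint torques), `"angle"` (joint angles),
#'   `"grf"` (ground reactions and zero-moment point), or `"exo"` (device
#'   torques).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lift_solution
#' @export
autoplot.lift_solution <- function(object, what = c("torque", "angle", "grf", "exo"),
                                   ...) {
  what <- match.arg(what)
  anat <- c("spine", "shoulder", "elbow", "hip", "knee", "ankle")
  if (what == "torque") {
    dat <- dplyr::filter(object$trajectory, .data$joint %in% anat)
    ggplot2::ggplot(dat, ggplot2::aes(.data$t, .data$tau_human)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~joint, scales = "free_y") +
      ggplot2::labs(x = "time (s)", y = "human joint torque (N m)")
  } else if (what == "angle") {
    dat <- dplyr::filter(object$trajectory, .data$joint %in% anat)
    ggplot2::ggplot(dat, ggplot2::aes(.data$t, .data$q)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~joint, scales = "free_y") +
      ggplot2::labs(x = "time (s)", y = "joint angle (rad)")
  } else if (what == "grf") {
    dat <- tidyr::pivot_longer(object$grf, -"t")
    ggplot2::ggplot(dat, ggplot2::aes(.data$t, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~name, scales = "free_y") +
      ggplot2::labs(x = "time (s)", y = NULL)
  } else {
    ggplot2::ggplot(object$currents,
                    ggplot2::aes(.data$t, .data$tau_exo, colour = .data$exo)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "device torque (N m)", colour = "device")
  }
}

#' @method autoplot torque_angle_map
#' @export
autoplot.torque_angle_map <- function(object, ...) {
  ggplot2::ggplot(control_map_table(object),
                  ggplot2::aes(.data$theta, .data$tau)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$limit,
                        linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "joint angle (rad)", y = "assistive torque (N m)")
}
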