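#' Solve the lifting trajectory optimization
#'
#' Runs the sequential quadratic programming solver on an assembled
#' [lifting_nlp()].  The default start is the zero design vector; if it
#' fails to reach feasibility, the solver restarts from a spline
#' interpolation of the reference postures (a gradient-based local method
#' benefits from multiple starting points).  The best feasible result is
#' returned.
#'
#' @param problem A [lifting_nlp()], or a [human_model] (then `task` and
#'   `exos` are used to assemble one).
#' @param task,exos Used when `problem` is a model.
#' @param start `"zero"`, `"reference"`, or a numeric design vector.
#' @param multi_start Try the reference start when the primary start fails.
#' @param control Optional list of SQP control parameters (see details of
#'   the solver: `maxit`, `tol_feas`, ...).
#' @param ... Passed to [lifting_nlp()] when assembling from a model.
#' @return A `lift_solution` object: optimal design vector, objective,
#'   solver status, per-grid trajectories (tibble), ground reactions, peak
#'   torques, and mechanical energy.
#' @export
solve_lifting <- function(problem, task = NULL, exos = list(),
                          start = "zero", multi_start = TRUE,
                          control = list(), ...) {
  if (inherits(problem, "human_model")) {
    problem <- lifting_nlp(problem, task %||% lifting_task(), exos, ...)
  }
  stopifnot(inherits(problem, "lifting_nlp"))
  cache <- new.env(parent = emptyenv())
  fn <- function(x) {
    if (!is.null(cache$x) && identical(cache$x, x)) return(cache$ev)
    ev <- nlp_eval(problem, x)
    cache$x <- x
    cache$ev <- ev
    ev
  }
  ctrl <- modifyList(list(tol_feas = 1e-8), control)
  starts <- list(primary = design_start(problem, start))
  if (multi_start && !identical(start, "reference")) {
    starts$reference <- design_start(problem, "reference")
  }
  best <- NULL
  for (nm in names(starts)) {
    res <- sqp_solve(starts[[nm]], fn, problem$lower, problem$upper,
                     control = ctrl)
    res$start <- nm
    feasible <- res$violation <= 1e-6
    if (is.null(best) ||
        (feasible && best$violation > 1e-6) ||
        (feasible && best$violation <= 1e-6 && res$objective < best$objective)) {
      best <- res
    }
    if (feasible && nm == "primary") break
  }
  new_lift_solution(problem, best)
}

# initial design vectors: all-zero (the conventional cold start) or the clamped
# interpolation of the three reference postures
design_start <- function(problem, start) {
  if (is.numeric(start)) {
    stopifnot(length(start) == problem$n_x)
    return(as.numeric(start))
  }
  x <- numeric(problem$n_x)
  if (identical(start, "zero")) return(pmin(pmax(x, problem$lower), problem$upper))
  if (!identical(start, "reference")) {
    stop_liftopt("`start` must be \"zero\", \"reference\", or a design vector",
                 "liftopt_validation_error")
  }
  refs <- problem$reference_angles
  nc <- problem$n_ctrl
  for (d in seq_len(problem$model$n_dof)) {
    # rest at the ends (repeated end control points) and pass near the
    # mid reference
    ctrl_pts <- approx(c(0, 0.5, 1), refs[d, ], xout = seq(0, 1, length.out = nc))$y
    ctrl_pts[2] <- ctrl_pts[1]
    ctrl_pts[nc - 1] <- ctrl_pts[nc]
    x[problem$cols_q[[d]]] <- ctrl_pts
  }
  pmin(pmax(x, problem$lower), problem$upper)
}

new_lift_solution <- function(problem, res) {
  ev <- nlp_eval(problem, res$x, want_trajectory = TRUE)
  tr <- ev$trajectory
  n <- problem$model$n_dof
  joint <- factor(rep(problem$model$joint_names, each = problem$n_grid),
                  levels = problem$model$joint_names)
  tau_e_full <- matrix(0, problem$n_grid, n)
  for (e in seq_along(problem$exos)) {
    tau_e_full[, problem$exos[[e]]$joint_index] <- tr$tau_e[, e]
  }
  trajectory <- tibble::tibble(
    t = rep(tr$t, n),
    joint = joint,
    q = as.vector(tr$q),
    qdot = as.vector(tr$qd),
    qddot = as.vector(tr$qdd),
    tau_human = as.vector(tr$tau_h),
    tau_exo = as.vector(tau_e_full)
  )
  currents <- if (length(problem$exos)) {
    tibble::tibble(
      t = rep(tr$t, length(problem$exos)),
      exo = rep(vapply(problem$exos, `[[`, character(1), "joint"),
                each = problem$n_grid),
      current = as.vector(tr$current),
      tau_exo = as.vector(tr$tau_e)
    )
  } else {
    tibble::tibble(t = numeric(0), exo = character(0),
                   current = numeric(0), tau_exo = numeric(0))
  }
  grf <- tibble::tibble(
    t = tr$t,
    grf_horizontal = tr$grf[, "horizontal"],
    grf_vertical = tr$grf[, "vertical"],
    zmp = tr$grf[, "zmp"]
  )
  sol <- structure(
    list(
      problem = problem,
      x = res$x,
      objective = res$objective,
      status = res$status,
      violation = res$violation,
      worst_constraint = res$worst_constraint,
      iterations = res$iterations,
      start = res$start %||% "primary",
      trajectory = trajectory,
      currents = currents,
      grf = grf
    ),
    class = "lift_solution"
  )
  sol$energy <- mechanical_energy(sol)
  sol
}

#' @export
print.lift_solution <- function(x, ...) {
  cat(sprintf(
    "<lift_solution> status %s: objective %.4f, max violation %.2e\n",
    x$status, x$objective, x$violation
  ))
  cat(sprintf("  mechanical energy %.1f J; %d grid points, %d design variables\n",
              x$energy, x$problem$n_grid, x$problem$n_x))
  invisible(x)
}

#' Joint-angle or current spline of a solved trajectory
#'
#' @param solution A `lift_solution`.
#' @param joint Joint name (for angles) or exoskeleton joint (for currents).
#' @param what `"angle"` or `"current"`.
#' @return A [bspline_trajectory()].
#' @export
solution_spline <- function(solution, joint, what = c("angle", "current")) {
  what <- match.arg(what)
  pr <- solution$problem
  if (what == "angle") {
    d <- resolve_joint_index(pr$model, joint)
    pts <- solution$x[pr$cols_q[[d]]]
  } else {
    e <- match(joint, vapply(pr$exos, `[[`, character(1), "joint"))
    if (is.na(e)) {
      stop_liftopt(sprintf("no exoskeleton at joint '%s'", joint),
                   "liftopt_validation_error")
    }
    pts <- solution$x[pr$cols_I[[e]]]
  }
  bspline_trajectory(pts, pr$task$duration)
}

#' Human mechanical energy of a solved lift
#'
#' Time integral over the lift of the summed absolute joint mechanical
#' power of the anatomical joints (spine through subtalar),
#' \eqn{\int_0^T \sum_i |\tau_{h,i}\,\dot q_i|\,dt}, by trapezoid
#' quadrature.  Set `positive_work_only = TRUE` to integrate concentric
#' (positive) power only.
#'
#' @param solution A `lift_solution`.
#' @param n_grid Quadrature resolution; defaults to the solve grid.
#' @param positive_work_only Count only positive joint power.
#' @return Energy in joules.
#' @export
mechanical_energy <- function(solution, n_grid = NULL,
                              positive_work_only = FALSE) {
  pr <- solution$problem
  n_grid <- n_grid %||% pr$n_grid
  prf <- if (n_grid == pr$n_grid) pr
  else lifting_nlp(pr$model, pr$task, pr$exos, n_ctrl = pr$n_ctrl,
                   n_grid = n_grid, box_dynamics = pr$box_dynamics)
  tr <- nlp_eval(prf, solution$x, want_trajectory = TRUE)$trajectory
  power <- abs(tr$tau_h[, ANATOMICAL_DOFS] * tr$qd[, ANATOMICAL_DOFS])
  if (positive_work_only) {
    power <- pmax(tr$tau_h[, ANATOMICAL_DOFS] * tr$qd[, ANATOMICAL_DOFS], 0)
  }
  wq <- rep(pr$task$duration / (n_grid - 1), n_grid)
  wq[c(1, n_grid)] <- wq[1] / 2
  sum(wq * rowSums(power))
}

#' Percent reduction of a peak magnitude relative to a baseline
#'
#' @param baseline,assisted Peak values (N m or any common unit).
#' @return `100 * (baseline - assisted) / baseline`.
#' @examples
#' percent_reduction(268.60, 251.40)  # 6.40
#' @export
percent_reduction <- function(baseline, assisted) {
  100 * (baseline - assisted) / baseline
}

#' Peak-torque comparison across solved cases
#'
#' @param results Named list of `lift_solution`s; the first entry is the
#'   baseline for the percent reductions.
#' @param joints Joints to report.
#' @return A tibble with case, joint, peak absolute human torque (N m), and
#'   percent reduction relative to the baseline case.
#' @export
peak_torque_report <- function(results,
                               joints = c("spine", "shoulder", "knee")) {
  stopifnot(length(results) >= 1)
  if (is.null(names(results))) {
    names(results) <- paste0("case_", seq_along(results))
  }
  rows <- purrr::imap(results, function(sol, case) {
    sol$trajectory |>
      dplyr::filter(.data$joint %in% joints) |>
      dplyr::group_by(.data$joint) |>
      dplyr::summarise(peak_torque = max(abs(.data$tau_human)),
                       .groups = "drop") |>
      dplyr::mutate(case = case, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  base <- out |>
    dplyr::filter(.data$case == names(results)[1]) |>
    dplyr::select("joint", baseline_peak = "peak_torque")
  out |>
    dplyr::left_join(base, by = "joint") |>
    dplyr::mutate(
      reduction_pct = percent_reduction(.data$baseline_peak, .data$peak_torque)
    ) |>
    dplyr::select(-"baseline_peak") |>
    dplyr::mutate(joint = as.character(.data$joint))
}
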