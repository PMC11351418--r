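#' Number of design variables of the lifting NLP
#'
#' Joint-angle control points for every DOF plus current control points for
#' every powered exoskeleton.
#'
#' @param n_dof Number of model DOFs.
#' @param n_exo Number of attached exoskeletons.
#' @param n_ctrl Control points per spline.
#' @return Integer count `n_dof * n_ctrl + n_exo * n_ctrl`.
#' @examples
#' count_design_variables(10, 0, 5)  # 50
#' count_design_variables(10, 3, 5)  # 65
#' @export
count_design_variables <- function(n_dof, n_exo, n_ctrl) {
  stopifnot(n_dof >= 1, n_exo >= 0, n_ctrl >= 1)
  as.integer(n_dof * n_ctrl + n_exo * n_ctrl)
}

#' Assemble the lifting trajectory optimization problem
#'
#' Builds the nonlinear program whose design vector stacks the B-spline
#' control points of every joint-angle profile and of every exoskeleton
#' current profile.  The objective is the time integral of squared human
#' joint torques normalized by joint strength; the constraint registry
#' carries, per time-grid point, the torque limits, feet contact, hand
#' forward, collision avoidance, zero-moment-point stability, and device
#' torque limits, plus the time-independent box placement, end-point rest,
#' and posture tracking-band constraints.  Joint angle limits are enforced
#' as bounds on the control points (sufficient by the spline convex-hull
#' property).
#'
#' @param model A [human_model] (without the box; the lifted box is added
#'   internally as a rigidly carried hand point mass).
#' @param task A [lifting_task()].
#' @param exos List of [exoskeleton()] devices to attach.
#' @param n_ctrl Control points per spline.
#' @param n_grid Number of uniform collocation points on `[0, T]`.
#' @param box_dynamics `"full"` carries the box as a point mass (inertial
#'   and gravity effects); `"quasi_static"` applies its weight only.
#' @param feet_tol Contact tolerance (m) for the feet constraints at
#'   interior grid points.  At the static end points the feet constraints
#'   are exact equalities; in between, a spline with `n_ctrl` control
#'   points cannot hold the foot exactly fixed at arbitrarily many
#'   instants (the contact manifold is not polynomial in time), so contact
#'   is enforced within this tolerance at every grid point.
#' @return A `lifting_nlp` problem object.
#' @export
lifting_nlp <- function(model, task, exos = list(), n_ctrl = 5, n_grid = 25,
                        box_dynamics = c("full", "quasi_static"),
                        feet_tol = 0.002) {
  box_dynamics <- match.arg(box_dynamics)
  stopifnot(inherits(model, "human_model"), inherits(task, "lifting_task"))
  model_exo <- attach_exoskeletons(model, exos)
  exos <- model_exo$exoskeletons
  n_exo <- length(exos)
  hand_local <- c(model$palm_offset, 0, 0)
  loads <- NULL
  model_dyn <- model_exo
  if (task$box_mass > 0) {
    if (box_dynamics == "full") {
      model_dyn <- add_point_mass(model_exo, 6L, hand_local, task$box_mass)
    } else {
      loads <- list(list(frame = 6L, local = hand_local,
                         force = c(0, -task$box_mass * model$gravity, 0)))
    }
  }
  refs <- task$reference_angles %||% reference_postures(model, task)
  T_ <- task$duration
  tg <- seq(0, T_, length.out = n_grid)
  proto <- bspline_trajectory(rep(0, n_ctrl), T_)
  B0 <- basis_sensitivity(proto, tg, 0L)
  B1 <- basis_sensitivity(proto, tg, 1L)
  B2 <- basis_sensitivity(proto, tg, 2L)
  tband <- c(0, T_ / 2, T_)
  B0_band <- basis_sensitivity(proto, tband, 0L)
  # trapezoid quadrature weights
  wq <- rep(T_ / (n_grid - 1), n_grid)
  wq[c(1, n_grid)] <- wq[1] / 2

  n_x <- count_design_variables(model$n_dof, n_exo, n_ctrl)
  cols_q <- lapply(1:model$n_dof, function(d) (d - 1L) * n_ctrl + seq_len(n_ctrl))
  cols_I <- lapply(seq_len(n_exo), function(e)
    model$n_dof * n_ctrl + (e - 1L) * n_ctrl + seq_len(n_ctrl))

  lower <- numeric(n_x); upper <- numeric(n_x)
  for (d in 1:model$n_dof) {
    lower[cols_q[[d]]] <- model$q_lower[d]
    upper[cols_q[[d]]] <- model$q_upper[d]
  }
  for (e in seq_len(n_exo)) {
    lower[cols_I[[e]]] <- -exos[[e]]$motor$current_limit
    upper[cols_I[[e]]] <- exos[[e]]$motor$current_limit
  }

  structure(
    list(
      model = model, model_dyn = model_dyn, task = task, exos = exos,
      loads = loads, box_dynamics = box_dynamics,
      n_ctrl = n_ctrl, n_grid = n_grid, n_x = n_x,
      t_grid = tg, wq = wq, B0 = B0, B1 = B1, B2 = B2,
      t_band = tband, B0_band = B0_band,
      feet_tol = feet_tol,
      band_dofs = 4:9, reference_angles = refs,
      cols_q = cols_q, cols_I = cols_I,
      lower = lower, upper = upper,
      fsr = foot_support_region(model, task),
      f_min = 10,                 # minimum vertical GRF for unilateral contact
      hand_local = hand_local,
      obj_dofs = OBJECTIVE_DOFS, strength_dofs = ANATOMICAL_DOFS,
      ctx = dyn_context(model_dyn)
    ),
    class = "lifting_nlp"
  )
}

#' @export
print.lifting_nlp <- function(x, ...) {
  cat(sprintf(
    "<lifting_nlp> %d design variables (%d DOF x %d + %d exo x %d), %d grid points\n",
    x$n_x, x$model$n_dof, x$n_ctrl, length(x$exos), x$n_ctrl, x$n_grid
  ))
  invisible(x)
}

# reshape the design vector into the (n_ctrl x n_dof) angle control-point
# matrix and the (n_ctrl x n_exo) current control-point matrix
split_design <- function(problem, x) {
  Pq <- matrix(x[seq_len(problem$model$n_dof * problem$n_ctrl)],
               problem$n_ctrl, problem$model$n_dof)
  PI <- if (length(problem$exos)) {
    matrix(x[-seq_len(problem$model$n_dof * problem$n_ctrl)],
           problem$n_ctrl, length(problem$exos))
  } else {
    matrix(0, problem$n_ctrl, 0)
  }
  list(Pq = Pq, PI = PI)
}

# full evaluation of objective, constraints, and Jacobians at x
nlp_eval <- function(problem, x, want_trajectory = FALSE) {
  pr <- problem
  n <- pr$model$n_dof
  nc <- pr$n_ctrl
  ng <- pr$n_grid
  nx <- pr$n_x
  sp <- split_design(pr, x)
  Q <- pr$B0 %*% sp$Pq; Qd <- pr$B1 %*% sp$Pq; Qdd <- pr$B2 %*% sp$Pq
  Ival <- if (ncol(sp$PI)) pr$B0 %*% sp$PI else matrix(0, ng, 0)

  w_i <- 1 / (pr$model$tau_upper - pr$model$tau_lower)^2
  f <- 0
  gobj <- numeric(nx)
  H <- matrix(0, nx, nx)
  c_eq <- numeric(0); J_eq <- NULL; eq_rows <- list(); eq_names <- character(0)
  c_in <- numeric(0); in_rows <- list(); in_names <- character(0)
  tau_h_all <- matrix(NA_real_, ng, n)
  tau_e_all <- matrix(NA_real_, ng, length(pr$exos))
  grf_all <- matrix(NA_real_, ng, 3,
                    dimnames = list(NULL, c("horizontal", "vertical", "zmp")))

  add_eq <- function(val, row, name) {
    c_eq[length(c_eq) + 1L] <<- val
    eq_rows[[length(eq_rows) + 1L]] <<- row
    eq_names[length(eq_names) + 1L] <<- name
  }
  add_in <- function(val, row, name) {
    c_in[length(c_in) + 1L] <<- val
    in_rows[[length(in_rows) + 1L]] <<- row
    in_names[length(in_names) + 1L] <<- name
  }
  # map a gradient in (q, qd, qdd) at grid point g to a design-vector row
  state_row <- function(gq, gqd = NULL, gqdd = NULL, g) {
    row <- numeric(nx)
    for (d in which(gq != 0)) row[pr$cols_q[[d]]] <- gq[d] * pr$B0[g, ]
    if (!is.null(gqd)) {
      for (d in which(gqd != 0)) {
        row[pr$cols_q[[d]]] <- row[pr$cols_q[[d]]] + gqd[d] * pr$B1[g, ]
      }
    }
    if (!is.null(gqdd)) {
      for (d in which(gqdd != 0)) {
        row[pr$cols_q[[d]]] <- row[pr$cols_q[[d]]] + gqdd[d] * pr$B2[g, ]
      }
    }
    row
  }

  feet <- pr$task$feet_position[2:3]
  for (g in seq_len(ng)) {
    tg <- pr$t_grid[g]
    ev <- dyn_eval(pr$ctx, Q[g, ], Qd[g, ], Qdd[g, ], loads = pr$loads,
                   grad = TRUE, grf = TRUE, route_grf = TRUE)
    # torque rows: d tau_ID / d x for every DOF
    TJ <- matrix(0, n, nx)
    for (d in 1:n) {
      TJ[, pr$cols_q[[d]]] <-
        outer(ev$dtau_dq[, d], pr$B0[g, ]) +
        outer(ev$dtau_dqd[, d], pr$B1[g, ]) +
        outer(ev$dtau_dqdd[, d], pr$B2[g, ])
    }
    tau_h <- ev$tau
    # exoskeleton torques and their rows
    for (e in seq_along(pr$exos)) {
      exo <- pr$exos[[e]]
      j <- exo$joint_index
      mo <- exo$motor
      gb <- mo$gear_ratio
      tau_e <- gb * mo$torque_constant * Ival[g, e] -
        gb^2 * (mo$rotor_inertia * Qdd[g, j] + mo$viscous_friction * Qd[g, j])
      te_row <- numeric(nx)
      te_row[pr$cols_I[[e]]] <- gb * mo$torque_constant * pr$B0[g, ]
      te_row[pr$cols_q[[j]]] <- -gb^2 * (mo$rotor_inertia * pr$B2[g, ] +
                                           mo$viscous_friction * pr$B1[g, ])
      tau_h[j] <- tau_h[j] - tau_e
      TJ[j, ] <- TJ[j, ] - te_row
      tau_e_all[g, e] <- tau_e
      lim <- exo$tau_upper
      add_in(tau_e - lim, te_row,
             sprintf("exo_torque_upper[%s]@t=%.3f", exo$joint, tg))
      add_in(-tau_e - lim, -te_row,
             sprintf("exo_torque_lower[%s]@t=%.3f", exo$joint, tg))
    }
    tau_h_all[g, ] <- tau_h
    # objective: normalized squared torque, trapezoid quadrature
    wg <- pr$wq[g]
    for (i in pr$obj_dofs) {
      f <- f + wg * w_i[i] * tau_h[i]^2
      gobj <- gobj + 2 * wg * w_i[i] * tau_h[i] * TJ[i, ]
      H <- H + (2 * wg * w_i[i]) * tcrossprod(TJ[i, ])
    }
    # human torque limits at strength-limited joints
    for (i in pr$strength_dofs) {
      nm <- pr$model$joint_names[i]
      add_in(tau_h[i] - pr$model$tau_upper[i], TJ[i, ],
             sprintf("torque_upper[%s]@t=%.3f", nm, tg))
      add_in(pr$model$tau_lower[i] - tau_h[i], -TJ[i, ],
             sprintf("torque_lower[%s]@t=%.3f", nm, tg))
    }
    # feet contact: ankle pinned with the foot flat on the ground.  At the
    # end points (static postures) this is an exact equality; at interior
    # grid points it is a tight contact-tolerance band, because a spline
    # with few control points cannot follow the curved contact manifold
    # exactly at arbitrarily many instants.
    pa <- point_with_jacobian(pr$ctx, ev$fw, 8L, c(0, 0, 0))
    pb <- point_with_jacobian(pr$ctx, ev$fw, 9L, c(0, 0, 0))
    pt <- point_with_jacobian(pr$ctx, ev$fw, 10L, c(0, 0, 0))
    feet_vals <- c(pa$p[2] - feet[1], pa$p[3] - feet[2], pb$p[2], pt$p[2])
    feet_rows <- list(state_row(pa$J[2, ], g = g), state_row(pa$J[3, ], g = g),
                      state_row(pb$J[2, ], g = g), state_row(pt$J[2, ], g = g))
    feet_labs <- c("feet_ankle_y", "feet_ankle_z", "feet_ball_y", "feet_toe_y")
    if (g == 1L || g == ng) {
      for (k4 in 1:4) {
        add_eq(feet_vals[k4], feet_rows[[k4]],
               sprintf("%s@t=%.3f", feet_labs[k4], tg))
      }
    } else {
      for (k4 in 1:4) {
        add_in(feet_vals[k4] - pr$feet_tol, feet_rows[[k4]],
               sprintf("%s_upper@t=%.3f", feet_labs[k4], tg))
        add_in(-feet_vals[k4] - pr$feet_tol, -feet_rows[[k4]],
               sprintf("%s_lower@t=%.3f", feet_labs[k4], tg))
      }
    }
    # hand stays anterior of the pelvis
    pw <- point_with_jacobian(pr$ctx, ev$fw, 6L, c(0, 0, 0))
    pp <- point_with_jacobian(pr$ctx, ev$fw, 3L, c(0, 0, 0))
    add_in(pp$p[3] - pw$p[3], state_row(pp$J[3, ] - pw$J[3, ], g = g),
           sprintf("hand_forward@t=%.3f", tg))
    # collision avoidance: hand point clear of the body thickness circles
    ph <- point_with_jacobian(pr$ctx, ev$fw, 6L, pr$hand_local)
    for (ci in seq_along(pr$model$collision_circles)) {
      circ <- pr$model$collision_circles[[ci]]
      pc <- point_with_jacobian(pr$ctx, ev$fw, circ$frame, circ$local)
      dvec <- ph$p[2:3] - pc$p[2:3]
      val <- circ$radius^2 - sum(dvec^2)
      gq <- -2 * as.numeric(dvec %*% (ph$J[2:3, ] - pc$J[2:3, ]))
      add_in(val, state_row(gq, g = g),
             sprintf("collision[%d]@t=%.3f", ci, tg))
    }
    # dynamic stability: ZMP within the foot support region, in moment form
    # (heel*Fy <= Mnum <= toe*Fy with Fy positive)
    heel <- pr$fsr[1]; toe <- pr$fsr[2]
    r1q <- heel * ev$dFy$q - ev$dMnum$q
    r1qd <- heel * ev$dFy$qd - ev$dMnum$qd
    r1qdd <- heel * ev$dFy$qdd - ev$dMnum$qdd
    add_in(heel * ev$F_y - ev$Mnum, state_row(r1q, r1qd, r1qdd, g),
           sprintf("zmp_heel@t=%.3f", tg))
    r2q <- ev$dMnum$q - toe * ev$dFy$q
    r2qd <- ev$dMnum$qd - toe * ev$dFy$qd
    r2qdd <- ev$dMnum$qdd - toe * ev$dFy$qdd
    add_in(ev$Mnum - toe * ev$F_y, state_row(r2q, r2qd, r2qdd, g),
           sprintf("zmp_toe@t=%.3f", tg))
    add_in(pr$f_min - ev$F_y,
           state_row(-ev$dFy$q, -ev$dFy$qd, -ev$dFy$qdd, g),
           sprintf("grf_vertical_min@t=%.3f", tg))
    grf_all[g, ] <- c(ev$F_z, ev$F_y, ev$Mnum / ev$F_y)
    # box placement at the end points
    if (g == 1L || g == ng) {
      tgt <- if (g == 1L) pr$task$hand_initial else pr$task$hand_final
      lab <- if (g == 1L) "initial" else "final"
      add_eq(ph$p[2] - tgt[2], state_row(ph$J[2, ], g = g),
             sprintf("box_%s_y", lab))
      add_eq(ph$p[3] - tgt[3], state_row(ph$J[3, ], g = g),
             sprintf("box_%s_z", lab))
    }
  }
  # rest at both ends: all joint rates zero (linear in the control points)
  for (g in c(1L, ng)) {
    lab <- if (g == 1L) "0" else "T"
    for (d in 1:n) {
      row <- numeric(nx)
      row[pr$cols_q[[d]]] <- pr$B1[g, ]
      add_eq(sum(pr$B1[g, ] * sp$Pq[, d]), row,
             sprintf("rest[%s]@t=%s", pr$model$joint_names[d], lab))
    }
  }
  # posture tracking band around the reference angles
  eps <- pr$task$epsilon
  for (k in seq_along(pr$t_band)) {
    for (d in pr$band_dofs) {
      qv <- sum(pr$B0_band[k, ] * sp$Pq[, d])
      ref <- pr$reference_angles[d, k]
      row <- numeric(nx)
      row[pr$cols_q[[d]]] <- pr$B0_band[k, ]
      nm <- pr$model$joint_names[d]
      add_in(qv - ref - eps, row,
             sprintf("band_upper[%s]@t=%.3f", nm, pr$t_band[k]))
      add_in(ref - qv - eps, -row,
             sprintf("band_lower[%s]@t=%.3f", nm, pr$t_band[k]))
    }
  }
  J_eq <- do.call(rbind, eq_rows)
  J_in <- do.call(rbind, in_rows)
  names(c_eq) <- eq_names
  names(c_in) <- in_names
  out <- list(f = f, g = gobj, H = H, c_eq = c_eq, J_eq = J_eq,
              c_in = c_in, J_in = J_in)
  if (want_trajectory) {
    out$trajectory <- list(t = pr$t_grid, q = Q, qd = Qd, qdd = Qdd,
                           tau_h = tau_h_all, tau_e = tau_e_all,
                           current = Ival, grf = grf_all)
  }
  out
}

#' Objective of the lifting NLP
#'
#' Sum over rotational joints of the time integral of squared human torque
#' normalized by the joint's strength range, evaluated by trapezoid
#' quadrature on the problem's time grid.
#'
#' @param problem A [lifting_nlp()].
#' @param x Design vector.
#' @return Scalar objective value.
#' @export
nlp_objective <- function(problem, x) {
  nlp_eval(problem, x)$f
}

#' Constraint registry evaluation
#'
#' @param problem A [lifting_nlp()].
#' @param x Design vector.
#' @return A tibble with one row per constraint: `name`, `kind`
#'   (`"eq"`/`"ineq"`), `value` (equality residual or inequality slack,
#'   feasible when 0 / non-positive), and `violation`.
#' @export
nlp_constraints <- function(problem, x) {
  ev <- nlp_eval(problem, x)
  tibble::tibble(
    name = c(names(ev$c_eq), names(ev$c_in)),
    kind = c(rep("eq", length(ev$c_eq)), rep("ineq", length(ev$c_in))),
    value = c(unname(ev$c_eq), unname(ev$c_in)),
    violation = c(abs(unname(ev$c_eq)), pmax(unname(ev$c_in), 0))
  )
}
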