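#' Recursive Lagrangian dynamics
#'
#' Joint torques are computed from the motion state by the 4x4
#' homogeneous-transform form of Lagrangian dynamics.  For joint \eqn{i},
#' \deqn{\tau_i = \mathrm{tr}\!\left(\frac{\partial A_i}{\partial q_i} D_i\right)
#'       - g^T \frac{\partial A_i}{\partial q_i} E_i
#'       - f_k^T \frac{\partial A_i}{\partial q_i} F_i
#'       - G_i^T A_{i-1} z_0}
#' where \eqn{A_i} is the global frame of DOF \eqn{i} and \eqn{D_i, E_i,
#' F_i, G_i} are backward-recursive accumulations of, respectively, the
#' inertia/Coriolis matrices \eqn{J_k \ddot A_k^T}, the first-moment gravity
#' vectors, the external-force application points, and the external moments
#' of the subtree rooted at \eqn{i}.  The two body branches merge at the
#' global rotation, where their contributions sum.
#'
#' @name dynamics
#' @keywords internal
NULL

#' Kinematic state of the model
#'
#' @param q,qdot,qddot Generalized positions, rates, accelerations
#'   (length 10).
#' @return A `kinematic_state` list.
#' @export
kinematic_state <- function(q, qdot = NULL, qddot = NULL) {
  n <- length(q)
  structure(
    list(
      q = as.numeric(q),
      qdot = as.numeric(qdot %||% rep(0, n)),
      qddot = as.numeric(qddot %||% rep(0, n))
    ),
    class = "kinematic_state"
  )
}

#' External loads applied to the body
#'
#' @param forces List of `list(frame, local, force)` entries: a constant
#'   global force (N, length-3) applied at a point fixed in the given frame
#'   (local coordinates, m).
#' @param moments List of `list(frame, moment)` entries: a constant global
#'   moment (N m, length-3) applied to the given link.
#' @return An `external_load` list.
#' @export
external_load <- function(forces = list(), moments = list()) {
  for (f in forces) {
    stopifnot(length(f$force) == 3, all(is.finite(f$force)),
              length(f$local) == 3)
  }
  for (m in moments) stopifnot(length(m$moment) == 3, all(is.finite(m$moment)))
  structure(list(forces = forces, moments = moments), class = "external_load")
}

# 4x4 pseudo-inertia of each DOF's segment in its local frame, including
# rigidly attached point masses.  The segment spans (-length, 0, 0) to the
# frame origin along local x; its CoM sits at x = com_offset - length.
pseudo_inertias <- function(model) {
  lapply(seq_len(model$n_dof), function(i) {
    seg <- model$segments[[i]]
    J <- matrix(0, 4, 4)
    if (seg$mass > 0) {
      xbar <- seg$com_offset - seg$length
      J[1, 1] <- seg$inertia + seg$mass * xbar^2
      J[1, 4] <- J[4, 1] <- seg$mass * xbar
      J[4, 4] <- seg$mass
    }
    for (pm in model$point_masses) {
      if (pm$frame == i && pm$mass > 0) {
        h <- c(pm$local, 1)
        J <- J + pm$mass * (h %o% h)
      }
    }
    J
  })
}

children_of <- function(model) {
  lapply(seq_len(model$n_dof), function(i) which(model$parent == i))
}

ancestors_of <- function(model) {
  lapply(seq_len(model$n_dof), function(i) {
    out <- integer(0)
    while (i != 0L) {
      out <- c(i, out)
      i <- model$parent[i]
    }
    out
  })
}

#' Backward-recursive dynamics terms
#'
#' Accumulates, distal to proximal, the inertia/Coriolis matrices `D`,
#' gravity first-moment vectors `E`, external-force application vectors `F`
#' (one per applied force), and external moment sums `G` for every frame.
#'
#' @param model A [human_model].
#' @param state A [kinematic_state()].
#' @param load An optional [external_load()].
#' @return List with components `D` (list of 4x4), `E` (list of length-4),
#'   `F` (list over forces of lists of length-4), `G` (list of length-3).
#' @export
backward_recursion <- function(model, state, load = NULL) {
  n <- model$n_dof
  check_state_dim(model, state$q)
  tr <- local_transforms(model, state$q)
  A <- Ad <- Add <- vector("list", n)
  for (i in seq_len(n)) {
    p <- model$parent[i]
    Ti <- tr[[i]]
    if (p == 0L) {
      A[[i]] <- Ti$T
      Ad[[i]] <- Ti$T1 * state$qdot[i]
      Add[[i]] <- Ti$T2 * state$qdot[i]^2 + Ti$T1 * state$qddot[i]
    } else {
      A[[i]] <- A[[p]] %*% Ti$T
      Ad[[i]] <- Ad[[p]] %*% Ti$T + A[[p]] %*% Ti$T1 * state$qdot[i]
      Add[[i]] <- Add[[p]] %*% Ti$T + 2 * (Ad[[p]] %*% Ti$T1) * state$qdot[i] +
        A[[p]] %*% (Ti$T2 * state$qdot[i]^2 + Ti$T1 * state$qddot[i])
    }
  }
  J <- pseudo_inertias(model)
  kids <- children_of(model)
  forces <- if (is.null(load)) list() else load$forces
  moments <- if (is.null(load)) list() else load$moments

  D <- E <- G <- vector("list", n)
  Fv <- lapply(seq_along(forces), function(k) vector("list", n))
  for (i in rev(seq_len(n))) {
    Di <- J[[i]] %*% t(Add[[i]])
    Ei <- J[[i]][, 4]
    Gi <- c(0, 0, 0)
    for (m in moments) if (m$frame == i) Gi <- Gi + m$moment
    for (c_ in kids[[i]]) {
      Di <- Di + tr[[c_]]$T %*% D[[c_]]
      Ei <- Ei + tr[[c_]]$T %*% E[[c_]]
      Gi <- Gi + G[[c_]]
    }
    D[[i]] <- Di
    E[[i]] <- as.numeric(Ei)
    G[[i]] <- as.numeric(Gi)
    for (k in seq_along(forces)) {
      Fk <- if (forces[[k]]$frame == i) c(forces[[k]]$local, 1) else c(0, 0, 0, 0)
      for (c_ in kids[[i]]) Fk <- Fk + tr[[c_]]$T %*% Fv[[k]][[c_]]
      Fv[[k]][[i]] <- as.numeric(Fk)
    }
  }
  list(D = D, E = E, F = Fv, G = G,
       A = A, Ad = Ad, Add = Add, local = tr)
}

#' Inverse dynamics: joint torques from motion
#'
#' @inheritParams backward_recursion
#' @return Length-10 numeric vector of generalized joint forces: N for the
#'   two global translations, N m for the rotational DOFs.
#' @examples
#' model <- build_human_model(1.7, 68.75)
#' tau <- inverse_dynamics(model, kinematic_state(rep(0, 10)))
#' @export
inverse_dynamics <- function(model, state, load = NULL) {
  n <- model$n_dof
  rec <- backward_recursion(model, state, load)
  gvec <- c(0, -model$gravity, 0, 0)
  forces <- if (is.null(load)) list() else load$forces
  tau <- numeric(n)
  for (i in seq_len(n)) {
    p <- model$parent[i]
    Ap <- if (p == 0L) diag(4) else rec$A[[p]]
    dAi <- Ap %*% rec$local[[i]]$T1
    tau_i <- sum(diag(dAi %*% rec$D[[i]])) - sum(gvec * (dAi %*% rec$E[[i]]))
    for (k in seq_along(forces)) {
      fk <- c(forces[[k]]$force, 0)
      tau_i <- tau_i - sum(fk * (dAi %*% rec$F[[k]][[i]]))
    }
    if (model$kind[i] == "rotation" && any(rec$G[[i]] != 0)) {
      axis <- Ap[1:3, 3]
      tau_i <- tau_i - sum(rec$G[[i]] * axis)
    }
    tau[i] <- tau_i
  }
  tau
}

#' Human torques under exoskeleton assistance
#'
#' The coupled equations of motion state that human torque plus exoskeleton
#' torque equals the inverse-dynamics torque required by the motion, so the
#' human share at an assisted joint is the inverse-dynamics torque minus the
#' device torque.
#'
#' @inheritParams backward_recursion
#' @param exo_torques Named or indexed numeric vector of device torques
#'   (N m); names may be joint names or indices of rotational DOFs.
#' @return Length-10 vector of human joint torques.
#' @export
coupled_torques <- function(model, state, load = NULL, exo_torques = NULL) {
  tau <- inverse_dynamics(model, state, load)
  if (is.null(exo_torques) || length(exo_torques) == 0) return(tau)
  idx <- resolve_joint_index(model, names(exo_torques) %||%
                               as.character(seq_along(exo_torques)))
  if (is.null(names(exo_torques))) {
    stop_liftopt("`exo_torques` must be named by joint", "liftopt_validation_error")
  }
  if (any(model$kind[idx] != "rotation")) {
    stop_liftopt("exoskeleton torque specified at a translation DOF",
                 "liftopt_validation_error")
  }
  tau[idx] <- tau[idx] - as.numeric(exo_torques)
  tau
}

resolve_joint_index <- function(model, joint) {
  if (is.numeric(joint)) return(as.integer(joint))
  idx <- match(joint, model$joint_names)
  if (anyNA(idx)) {
    suppressWarnings(num <- as.integer(joint))
    idx[is.na(idx)] <- num[is.na(idx)]
  }
  if (anyNA(idx) || any(idx < 1) || any(idx > model$n_dof)) {
    stop_liftopt(
      sprintf("unknown joint '%s'", paste(joint[is.na(idx)], collapse = ", ")),
      "liftopt_validation_error"
    )
  }
  as.integer(idx)
}

#' Ground reaction force and zero-moment point
#'
#' Computed from a whole-body Newton-Euler balance over the segments: the
#' ground must supply the net rate of change of linear momentum not supplied
#' by gravity and external loads, and the zero-moment point is the ground
#' station about which the horizontal component of the net ground moment
#' vanishes.
#'
#' @inheritParams backward_recursion
#' @return List with `grf` (named vector: `horizontal` along global Z,
#'   `vertical` along global Y, in N) and `zmp` (anterior coordinate, m).
#' @export
ground_reaction <- function(model, state, load = NULL) {
  ne <- newton_euler_terms(model, state, load)
  list(grf = c(horizontal = ne$F_z, vertical = ne$F_y),
       zmp = ne$moment_num / ne$F_y)
}

# Newton-Euler aggregates: vertical/horizontal ground force and the
# numerator of the ZMP moment balance (zmp = moment_num / F_y)
newton_euler_terms <- function(model, state, load = NULL) {
  n <- model$n_dof
  rec <- backward_recursion(model, state, load)
  J <- pseudo_inertias(model)
  g <- model$gravity
  F_y <- 0; F_z <- 0; dLx <- 0; grav_mom <- 0
  for (i in seq_len(n)) {
    if (all(J[[i]] == 0)) next
    pdd <- rec$Add[[i]] %*% J[[i]][, 4]   # integral of segment accel * dm
    F_y <- F_y + pdd[2]
    F_z <- F_z + pdd[3]
    M <- rec$Add[[i]] %*% J[[i]] %*% t(rec$A[[i]])
    dLx <- dLx + (M[3, 2] - M[2, 3])
    grav_mom <- grav_mom + g * (rec$A[[i]] %*% J[[i]][, 4])[3]
  }
  mass_tot <- sum(vapply(J, function(j) j[4, 4], numeric(1)))
  F_y <- F_y + g * mass_tot
  ext_mom <- 0
  if (!is.null(load)) {
    for (f in load$forces) {
      p <- as.numeric(rec$A[[f$frame]] %*% c(f$local, 1))[1:3]
      F_y <- F_y - f$force[2]
      F_z <- F_z - f$force[3]
      ext_mom <- ext_mom + p[2] * f$force[3] - p[3] * f$force[2]
    }
    for (m in load$moments) ext_mom <- ext_mom + m$moment[1]
  }
  list(F_y = as.numeric(F_y), F_z = as.numeric(F_z),
       moment_num = as.numeric(grav_mom + ext_mom - dLx))
}

#' Load-bearing joint torques with the ground reaction routed through the feet
#'
#' The plain inverse dynamics of the floating chain attributes to each leg
#' joint only the weight and inertia of the segments distal to it, because
#' the virtual global DOFs at the pelvis absorb the support forces.  For a
#' subject standing on the ground the physically meaningful joint load is
#' obtained by applying the computed ground reaction wrench as an external
#' force at the planted foot (acting at the zero-moment point): leg joints
#' then carry the full body weight and the generalized forces at the
#' virtual global DOFs vanish identically.  This is the torque definition
#' used by the lifting optimization and its reports.
#'
#' @inheritParams backward_recursion
#' @return Length-10 vector of joint torques (N m; N at the translations,
#'   which are zero up to round-off).
#' @export
grounded_torques <- function(model, state, load = NULL) {
  ctx <- dyn_context(model)
  loads <- if (is.null(load)) NULL else load$forces
  dyn_eval(ctx, state$q, state$qdot, state$qddot, loads = loads,
           grf = TRUE, route_grf = TRUE)$tau
}

#' Signed stability margin of the zero-moment point
#'
#' @param zmp Anterior ZMP coordinate (m).
#' @param fsr Length-2 foot support region `[heel, toe]` (m).
#' @return Signed distance to the nearest FSR boundary: positive inside,
#'   zero on the boundary, negative outside.
#' @export
stability_margin <- function(zmp, fsr) {
  if (length(fsr) != 2 || fsr[1] >= fsr[2]) {
    stop_liftopt("`fsr` must be an increasing interval", "liftopt_validation_error")
  }
  min(zmp - fsr[1], fsr[2] - zmp)
}
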