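# Independent numerical Euler-Lagrange oracle for joint torques.
#
# Builds the mass matrix, Coriolis terms, and gravity vector from
# position-level forward kinematics only: centre-of-mass Jacobians by
# central finite differences, segment angular rates from the planar fact
# that every rotational axis of this model is the global +X axis.  It never
# touches the recursive D/E/F/G machinery it is used to check.

oracle_mass_points <- function(model) {
  pts <- list()
  for (i in seq_len(model$n_dof)) {
    seg <- model$segments[[i]]
    if (seg$mass > 0) {
      pts[[length(pts) + 1]] <- list(
        frame = i, local = c(seg$com_offset - seg$length, 0, 0),
        mass = seg$mass, inertia = seg$inertia
      )
    }
  }
  for (pm in model$point_masses) {
    if (pm$mass > 0) {
      pts[[length(pts) + 1]] <- list(frame = pm$frame, local = pm$local,
                                     mass = pm$mass, inertia = 0)
    }
  }
  pts
}

oracle_point_pos <- function(model, q, pt) {
  A <- forward_kinematics(model, q)
  as.numeric(A[[pt$frame]] %*% c(pt$local, 1))[1:3]
}

# 4th-order central difference: keeps roundoff small enough that the
# nested differentiation in oracle_torques stays below 1e-7
fd4 <- function(f, x, j, h) {
  xp <- function(s) { y <- x; y[j] <- y[j] + s * h; y }
  (f(xp(-2)) - 8 * f(xp(-1)) + 8 * f(xp(1)) - f(xp(2))) / (12 * h)
}

oracle_point_jac <- function(model, q, pt, h = 1e-4) {
  n <- model$n_dof
  Jc <- matrix(0, 3, n)
  for (j in seq_len(n)) {
    Jc[, j] <- fd4(function(qq) oracle_point_pos(model, qq, pt), q, j, h)
  }
  Jc
}

# indicator row of rotational ancestors (all axes +X, so the angular rate of
# segment i is the plain sum of its rotational ancestors' rates)
oracle_omega_row <- function(model, frame) {
  anc <- integer(0)
  i <- frame
  while (i != 0L) { anc <- c(anc, i); i <- model$parent[i] }
  row <- numeric(model$n_dof)
  row[anc[model$kind[anc] == "rotation"]] <- 1
  row
}

oracle_mass_matrix <- function(model, q) {
  pts <- oracle_mass_points(model)
  n <- model$n_dof
  M <- matrix(0, n, n)
  for (pt in pts) {
    Jc <- oracle_point_jac(model, q, pt)
    M <- M + pt$mass * crossprod(Jc)
    if (pt$inertia > 0) {
      w <- oracle_omega_row(model, pt$frame)
      M <- M + pt$inertia * (w %o% w)
    }
  }
  (M + t(M)) / 2
}

oracle_gravity_vec <- function(model, q) {
  pts <- oracle_mass_points(model)
  gv <- numeric(model$n_dof)
  for (pt in pts) {
    Jc <- oracle_point_jac(model, q, pt)
    gv <- gv + pt$mass * model$gravity * Jc[2, ]   # dV/dq, V = m g y
  }
  gv
}

# full Euler-Lagrange torque: M(q) qdd + Mdot qd - 1/2 d/dq (qd' M qd)
# + dV/dq - external generalized forces
oracle_torques <- function(model, state, load = NULL, h = 1e-3) {
  n <- model$n_dof
  q <- state$q; qd <- state$qdot; qdd <- state$qddot
  M <- oracle_mass_matrix(model, q)
  Mdot <- matrix(0, n, n)
  dqMq <- numeric(n)
  for (j in seq_len(n)) {
    dM <- fd4(function(qq) oracle_mass_matrix(model, qq), q, j, h)
    Mdot <- Mdot + dM * qd[j]
    dqMq[j] <- 0.5 * as.numeric(qd %*% dM %*% qd)
  }
  tau <- as.numeric(M %*% qdd + Mdot %*% qd) - dqMq + oracle_gravity_vec(model, q)
  if (!is.null(load)) {
    for (f in load$forces) {
      Jc <- oracle_point_jac(model, q, list(frame = f$frame, local = f$local))
      tau <- tau - as.numeric(f$force %*% Jc)
    }
    for (m in load$moments) {
      tau <- tau - m$moment[1] * oracle_omega_row(model, m$frame)
    }
  }
  tau
}

# small random but feasible-magnitude states for property tests
random_state <- function(model, rng_scale = 1) {
  n <- model$n_dof
  q <- runif(n, -0.6, 0.6) * rng_scale
  q[1:2] <- runif(2, -0.2, 0.2)
  kinematic_state(q, runif(n, -1, 1) * rng_scale, runif(n, -3, 3) * rng_scale)
}
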