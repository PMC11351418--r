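# Workhorse evaluation of the coupled dynamics with analytic sensitivities.
#
# For every frame the forward pass propagates the global transform A and its
# time derivatives, together with their partials with respect to joint
# positions, rates, and accelerations:
#
#   A_i    = A_p T_i
#   Adot_i = Adot_p T_i + A_p T'_i qd_i
#   Addot_i= Addot_p T_i + 2 Adot_p T'_i qd_i + A_p (T''_i qd_i^2 + T'_i qdd_i)
#
# Differentiating these recursions once (and twice for d2A) gives exact
# partials; every torque, ground-reaction, and landmark quantity below is an
# algebraic combination of the propagated matrices, so its gradient follows
# by the product rule.  The per-model constants are collected once in a
# context object so repeated evaluations (optimization!) stay cheap.

dyn_context <- function(model) {
  n <- model$n_dof
  anc <- ancestors_of(model)
  J <- pseudo_inertias(model)
  has_mass <- vapply(J, function(j) any(j != 0), logical(1))
  list(
    model = model, n = n, parent = model$parent, anc = anc, J = J,
    has_mass = has_mass,
    mass_tot = sum(vapply(J, function(j) j[4, 4], numeric(1))),
    g = model$gravity,
    # ground wrench application: the ankle material point of the foot link
    foot_frame = 9L,
    foot_local = c(-model$dh[[min(9L, n)]]$a, 0, 0)
  )
}

# forward kinematic pass with optional derivative bookkeeping
dyn_forward <- function(ctx, q, qd, qdd, grad = FALSE) {
  n <- ctx$n
  model <- ctx$model
  tr <- local_transforms(model, q)
  A <- Ad <- Add <- vector("list", n)
  dA <- dAd <- dAdd_q <- dAdd_qd <- dAd_qd <- lapply(1:n, function(i) vector("list", n))
  d2A <- vector("list", n)
  I4 <- diag(4)
  for (i in seq_len(n)) {
    p <- ctx$parent[i]
    Ti <- tr[[i]]
    Ap <- if (p == 0L) I4 else A[[p]]
    Adp <- if (p == 0L) NULL else Ad[[p]]
    Addp <- if (p == 0L) NULL else Add[[p]]
    Tq <- Ti$T2 * qd[i]^2 + Ti$T1 * qdd[i]
    if (p == 0L) {
      A[[i]] <- Ti$T
      Ad[[i]] <- Ti$T1 * qd[i]
      Add[[i]] <- Tq
    } else {
      A[[i]] <- Ap %*% Ti$T
      Ad[[i]] <- Adp %*% Ti$T + (Ap %*% Ti$T1) * qd[i]
      Add[[i]] <- Addp %*% Ti$T + 2 * (Adp %*% Ti$T1) * qd[i] + Ap %*% Tq
    }
    if (!grad) {
      # still need dA for landmarks/torque lead terms
      if (p != 0L) {
        for (j in ctx$anc[[p]]) dA[[i]][[j]] <- dA[[p]][[j]] %*% Ti$T
      }
      dA[[i]][[i]] <- Ap %*% Ti$T1
      next
    }
    d2A[[i]] <- lapply(1:n, function(k) vector("list", n))
    if (p != 0L) {
      for (j in ctx$anc[[p]]) {
        dA[[i]][[j]] <- dA[[p]][[j]] %*% Ti$T
        dAd[[i]][[j]] <- dAd[[p]][[j]] %*% Ti$T + (dA[[p]][[j]] %*% Ti$T1) * qd[i]
        dAdd_q[[i]][[j]] <- dAdd_q[[p]][[j]] %*% Ti$T +
          2 * (dAd[[p]][[j]] %*% Ti$T1) * qd[i] + dA[[p]][[j]] %*% Tq
        dAd_qd[[i]][[j]] <- dAd_qd[[p]][[j]] %*% Ti$T
        dAdd_qd[[i]][[j]] <- dAdd_qd[[p]][[j]] %*% Ti$T +
          2 * (dAd_qd[[p]][[j]] %*% Ti$T1) * qd[i]
      }
    }
    dA[[i]][[i]] <- Ap %*% Ti$T1
    dAd[[i]][[i]] <- (if (p == 0L) matrix(0, 4, 4) else Adp %*% Ti$T1) +
      (Ap %*% Ti$T2) * qd[i]
    dAdd_q[[i]][[i]] <- (if (p == 0L) matrix(0, 4, 4) else
      Addp %*% Ti$T1 + 2 * (Adp %*% Ti$T2) * qd[i]) +
      Ap %*% (Ti$T3 * qd[i]^2 + Ti$T2 * qdd[i])
    dAd_qd[[i]][[i]] <- Ap %*% Ti$T1
    dAdd_qd[[i]][[i]] <- (if (p == 0L) matrix(0, 4, 4) else 2 * (Adp %*% Ti$T1)) +
      2 * (Ap %*% Ti$T2) * qd[i]
    # second partials of A over ancestor pairs (n2 <= j2 stored, mirrored)
    for (n2 in ctx$anc[[i]]) {
      for (j2 in ctx$anc[[i]]) {
        if (j2 < n2) next
        v <- NULL
        if (p != 0L && !is.null(d2A[[p]][[n2]][[j2]])) {
          v <- d2A[[p]][[n2]][[j2]] %*% Ti$T
        }
        if (i == j2 && n2 != i && !is.null(dA[[p]][[n2]])) {
          v <- (v %||% 0) + dA[[p]][[n2]] %*% Ti$T1
        }
        if (i == n2 && j2 != i && !is.null(dA[[p]][[j2]])) {
          v <- (v %||% 0) + dA[[p]][[j2]] %*% Ti$T1
        }
        if (i == n2 && i == j2) {
          v <- (v %||% 0) + Ap %*% Ti$T2
        }
        if (!is.null(v)) {
          d2A[[i]][[n2]][[j2]] <- v
          d2A[[i]][[j2]][[n2]] <- v
        }
      }
    }
  }
  list(tr = tr, A = A, Ad = Ad, Add = Add, dA = dA, dAd = dAd,
       dAdd_q = dAdd_q, dAdd_qd = dAdd_qd, d2A = d2A)
}

# torques, ground reaction, and their exact state sensitivities.
# loads: list of list(frame, local, force) with constant global forces.
# With route_grf = TRUE (requires grf) the computed ground wrench is applied
# as an external load at the foot -- force at the ankle material point plus
# the moment transported from the zero-moment point -- so that joint torques
# reflect load bearing through the planted feet and the generalized forces
# at the virtual global DOFs vanish identically.
dyn_eval <- function(ctx, q, qd, qdd, loads = NULL, grad = FALSE,
                     grf = FALSE, route_grf = FALSE) {
  if (route_grf && !grf) grf <- TRUE
  n <- ctx$n
  fw <- dyn_forward(ctx, q, qd, qdd, grad = grad)
  g <- ctx$g
  tau <- numeric(n)
  if (grad) {
    dtau_dq <- matrix(0, n, n)
    dtau_dqd <- matrix(0, n, n)
    dtau_dqdd <- matrix(0, n, n)
  }
  if (grf) {
    F_y <- g * ctx$mass_tot; F_z <- 0; Mnum <- 0
    if (grad) {
      dFy <- list(q = numeric(n), qd = numeric(n), qdd = numeric(n))
      dFz <- list(q = numeric(n), qd = numeric(n), qdd = numeric(n))
      dMn <- list(q = numeric(n), qd = numeric(n), qdd = numeric(n))
    }
  }
  for (i in seq_len(n)) {
    if (!ctx$has_mass[i]) next
    Ji <- ctx$J[[i]]
    Je4 <- Ji[, 4]
    Addi <- fw$Add[[i]]
    for (nn in ctx$anc[[i]]) {
      PJ <- fw$dA[[i]][[nn]] %*% Ji
      tau[nn] <- tau[nn] + sum(PJ * Addi) + g * PJ[2, 4]
      if (grad) {
        for (jj in ctx$anc[[i]]) {
          dtau_dqdd[nn, jj] <- dtau_dqdd[nn, jj] + sum(PJ * fw$dA[[i]][[jj]])
          dtau_dqd[nn, jj] <- dtau_dqd[nn, jj] + sum(PJ * fw$dAdd_qd[[i]][[jj]])
          QJ <- fw$d2A[[i]][[nn]][[jj]] %*% Ji
          dtau_dq[nn, jj] <- dtau_dq[nn, jj] + sum(PJ * fw$dAdd_q[[i]][[jj]]) +
            sum(QJ * Addi) + g * QJ[2, 4]
        }
      }
    }
    if (grf) {
      v <- Addi %*% Je4
      F_y <- F_y + v[2]; F_z <- F_z + v[3]
      MJ <- Addi %*% Ji
      M4 <- MJ %*% t(fw$A[[i]])
      Mnum <- Mnum - (M4[3, 2] - M4[2, 3]) + g * (fw$A[[i]] %*% Je4)[3]
      if (grad) {
        for (jj in ctx$anc[[i]]) {
          aq <- fw$dAdd_q[[i]][[jj]] %*% Je4
          aqd <- fw$dAdd_qd[[i]][[jj]] %*% Je4
          aqdd <- fw$dA[[i]][[jj]] %*% Je4
          dFy$q[jj] <- dFy$q[jj] + aq[2]; dFz$q[jj] <- dFz$q[jj] + aq[3]
          dFy$qd[jj] <- dFy$qd[jj] + aqd[2]; dFz$qd[jj] <- dFz$qd[jj] + aqd[3]
          dFy$qdd[jj] <- dFy$qdd[jj] + aqdd[2]; dFz$qdd[jj] <- dFz$qdd[jj] + aqdd[3]
          skew <- function(X) X[3, 2] - X[2, 3]
          Mq <- fw$dAdd_q[[i]][[jj]] %*% Ji %*% t(fw$A[[i]]) + MJ %*% t(fw$dA[[i]][[jj]])
          dMn$q[jj] <- dMn$q[jj] - skew(Mq) +
            g * (fw$dA[[i]][[jj]] %*% Je4)[3]
          dMn$qd[jj] <- dMn$qd[jj] - skew(fw$dAdd_qd[[i]][[jj]] %*% Ji %*% t(fw$A[[i]]))
          dMn$qdd[jj] <- dMn$qdd[jj] - skew(fw$dA[[i]][[jj]] %*% Ji %*% t(fw$A[[i]]))
        }
      }
    }
  }
  # constant external point forces
  for (f in loads %||% list()) {
    fh <- c(f$force, 0)
    rh <- c(f$local, 1)
    b <- f$frame
    for (nn in ctx$anc[[b]]) {
      tau[nn] <- tau[nn] - sum(fh * (fw$dA[[b]][[nn]] %*% rh))
      if (grad) {
        for (jj in ctx$anc[[b]]) {
          dtau_dq[nn, jj] <- dtau_dq[nn, jj] -
            sum(fh * (fw$d2A[[b]][[nn]][[jj]] %*% rh))
        }
      }
    }
    if (grf) {
      p <- (fw$A[[b]] %*% rh)[1:3]
      F_y <- F_y - f$force[2]; F_z <- F_z - f$force[3]
      Mnum <- Mnum + p[2] * f$force[3] - p[3] * f$force[2]
      if (grad) {
        for (jj in ctx$anc[[b]]) {
          dp <- (fw$dA[[b]][[jj]] %*% rh)[1:3]
          dMn$q[jj] <- dMn$q[jj] + dp[2] * f$force[3] - dp[3] * f$force[2]
        }
      }
    }
  }
  if (route_grf) {
    bf <- ctx$foot_frame
    rh <- c(ctx$foot_local, 1)
    pa <- fw$A[[bf]] %*% rh
    y_a <- pa[2]; z_a <- pa[3]
    # wrench transported from the zero-moment point to the ankle point:
    # force (0, F_y, F_z) plus moment Mx about the out-of-plane axis
    Mx <- -y_a * F_z - Mnum + z_a * F_y
    rot_anc <- ctx$anc[[bf]][ctx$model$kind[ctx$anc[[bf]]] == "rotation"]
    Pn <- lapply(seq_len(n), function(nn) {
      if (is.null(fw$dA[[bf]][[nn]])) NULL else fw$dA[[bf]][[nn]] %*% rh
    })
    axis_x <- vapply(seq_len(n), function(nn) {
      p_ <- ctx$parent[nn]
      if (p_ == 0L) 0 else fw$A[[p_]][1, 3]
    }, numeric(1))
    if (grad) {
      dy_a <- dz_a <- numeric(n)
      for (jj in ctx$anc[[bf]]) {
        w <- fw$dA[[bf]][[jj]] %*% rh
        dy_a[jj] <- w[2]; dz_a[jj] <- w[3]
      }
      dMx <- list(
        q = -(dy_a * F_z + y_a * dFz$q) - dMn$q + dz_a * F_y + z_a * dFy$q,
        qd = -y_a * dFz$qd - dMn$qd + z_a * dFy$qd,
        qdd = -y_a * dFz$qdd - dMn$qdd + z_a * dFy$qdd
      )
    }
    for (nn in ctx$anc[[bf]]) {
      P <- Pn[[nn]]
      tau[nn] <- tau[nn] - (F_y * P[2] + F_z * P[3])
      if (nn %in% rot_anc) tau[nn] <- tau[nn] - Mx * axis_x[nn]
      if (grad) {
        ax <- if (nn %in% rot_anc) axis_x[nn] else 0
        dtau_dq[nn, ] <- dtau_dq[nn, ] -
          (dFy$q * P[2] + dFz$q * P[3] + dMx$q * ax)
        dtau_dqd[nn, ] <- dtau_dqd[nn, ] -
          (dFy$qd * P[2] + dFz$qd * P[3] + dMx$qd * ax)
        dtau_dqdd[nn, ] <- dtau_dqdd[nn, ] -
          (dFy$qdd * P[2] + dFz$qdd * P[3] + dMx$qdd * ax)
        for (jj in ctx$anc[[bf]]) {
          dP <- fw$d2A[[bf]][[nn]][[jj]]
          if (!is.null(dP)) {
            w <- dP %*% rh
            dtau_dq[nn, jj] <- dtau_dq[nn, jj] - (F_y * w[2] + F_z * w[3])
          }
          if (ax != 0) {
            p_ <- ctx$parent[nn]
            dax <- if (p_ != 0L && !is.null(fw$dA[[p_]][[jj]])) {
              fw$dA[[p_]][[jj]][1, 3]
            } else 0
            if (dax != 0) {
              dtau_dq[nn, jj] <- dtau_dq[nn, jj] - Mx * dax
            }
          }
        }
      }
    }
  }
  out <- list(tau = tau, fw = fw)
  if (grad) {
    out$dtau_dq <- dtau_dq; out$dtau_dqd <- dtau_dqd; out$dtau_dqdd <- dtau_dqdd
  }
  if (grf) {
    out$F_y <- as.numeric(F_y); out$F_z <- as.numeric(F_z)
    out$Mnum <- as.numeric(Mnum)
    out$zmp <- as.numeric(Mnum / F_y)
    if (grad) { out$dFy <- dFy; out$dFz <- dFz; out$dMnum <- dMn }
  }
  out
}

# global position of a point fixed in a frame, with its Jacobian wrt q
point_with_jacobian <- function(ctx, fw, frame, local) {
  rh <- c(local, 1)
  p <- (fw$A[[frame]] %*% rh)[1:3]
  Jc <- matrix(0, 3, ctx$n)
  for (j in ctx$anc[[frame]]) Jc[, j] <- (fw$dA[[frame]][[j]] %*% rh)[1:3]
  list(p = as.numeric(p), J = Jc)
}

# point velocity d/dt (A r) and its partials wrt qd (needed for hand
# velocity style quantities); rarely used, kept simple
point_velocity <- function(ctx, fw, frame, local) {
  rh <- c(local, 1)
  as.numeric(fw$Ad[[frame]] %*% rh)[1:3]
}
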