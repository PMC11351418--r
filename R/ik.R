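#' Synthesize reference lifting postures
#'
#' Generates deterministic squat-lift reference postures at times 0, T/2,
#' and T: a deep-squat start with the hand at the initial box position, an
#' intermediate posture, and a near-upright end with the hand at the final
#' box position.  Postures are built in closed form -- planar two-link
#' inverse kinematics for the legs (knee-anterior branch) and the arm
#' (elbow-posterior branch), a torso-lean rule that leans just far enough
#' for the hand target to be reachable -- and then polished by a damped
#' Gauss-Newton projection so the ankle-pin, foot-flat, and hand-target
#' constraints close to machine accuracy.  The procedure is seedless and
#' deterministic; the returned postures respect the model's joint limits.
#'
#' These synthetic postures stand in for motion-captured joint angles when
#' none are available; they anchor the posture tracking band of the lifting
#' optimization.
#'
#' @param model A [human_model].
#' @param task A [lifting_task()].
#' @return A 10 x 3 matrix of joint coordinates at t = 0, T/2, T.
#' @examples
#' model <- build_human_model(1.7, 68.75)
#' reference_postures(model, lifting_task())
#' @export
reference_postures <- function(model, task) {
  targets <- list(
    start = task$hand_initial[2:3],
    mid = (task$hand_initial[2:3] + task$hand_final[2:3]) / 2,
    end = task$hand_final[2:3]
  )
  feet <- task$feet_position[2:3]
  check_reach(model, targets, feet)
  L45 <- model$lengths[["L4"]] + model$lengths[["L5"]]
  # pelvis stations (fractions of leg length) and torso leans for the squat,
  # intermediate, and upright phases of a floor-to-shelf squat lift
  pelvis <- list(
    feet + c(0.45 * L45, -0.145 * L45),
    feet + c(0.72 * L45, -0.084 * L45),
    feet + c(0.995 * L45, -0.024 * L45)
  )
  lean <- c(1.0, 0.5, 0.08)
  out <- matrix(NA_real_, model$n_dof, 3,
                dimnames = list(model$joint_names, c("0", "T/2", "T")))
  for (k in 1:3) {
    q0 <- construct_posture(model, targets[[k]], feet, pelvis[[k]], lean[k])
    q0 <- pmin(pmax(q0, model$q_lower), model$q_upper)
    out[, k] <- polish_posture(model, q0, targets[[k]], feet)
  }
  out
}

check_reach <- function(model, targets, feet) {
  L <- model$lengths
  reach <- L[["L4"]] + L[["L5"]] + L[["L1"]] + L[["L2"]] + L[["L3"]] +
    model$palm_offset
  for (nm in names(targets)) {
    d <- sqrt(sum((targets[[nm]] - feet)^2))
    if (d > reach) {
      stop_liftopt(
        sprintf("hand target '%s' is %.3f m from the feet, beyond the %.3f m whole-body reach",
                nm, d, reach),
        "liftopt_infeasible"
      )
    }
  }
  invisible(TRUE)
}

# unit vector in the sagittal (Y, Z) plane at angle phi from +Y toward +Z
unit_yz <- function(phi) c(cos(phi), sin(phi))

# planar two-link inverse kinematics; returns the global direction angles of
# both links for the branch selected by the elbow-point z preference
two_link_ik <- function(S, target, l1, l2, elbow_anterior) {
  d <- target - S
  r <- min(sqrt(sum(d^2)), l1 + l2 - 1e-9)
  r <- max(r, abs(l1 - l2) + 1e-9)
  phid <- atan2(d[2], d[1])
  a <- acos(min(max((l1^2 + r^2 - l2^2) / (2 * l1 * r), -1), 1))
  cand <- lapply(c(1, -1), function(s) {
    phi1 <- phid + s * a
    E <- S + l1 * unit_yz(phi1)
    list(phi1 = phi1, phi2 = atan2(target[2] - E[2], target[1] - E[1]),
         elbow_z = E[2])
  })
  zs <- vapply(cand, `[[`, numeric(1), "elbow_z")
  cand[[if (elbow_anterior) which.max(zs) else which.min(zs)]]
}

# closed-form posture from pelvis station, torso lean, and hand target;
# segment direction angles are mapped exactly to the DH coordinates
construct_posture <- function(model, target, feet, pelvis, lean) {
  L <- model$lengths
  leg <- two_link_ik(pelvis, feet, L[["L4"]], L[["L5"]], elbow_anterior = TRUE)
  arm_len <- L[["L2"]] + L[["L3"]] + model$palm_offset
  reach_gap <- function(phi_t) {
    S <- pelvis + L[["L1"]] * unit_yz(phi_t)
    sqrt(sum((target - S)^2)) - 0.97 * arm_len
  }
  phi_t <- lean
  if (reach_gap(phi_t) > 0) {
    sol <- try(stats::uniroot(reach_gap, c(lean, 1.45), tol = 1e-10),
               silent = TRUE)
    phi_t <- if (inherits(sol, "try-error")) 1.45 else sol$root
  }
  S <- pelvis + L[["L1"]] * unit_yz(phi_t)
  arm <- two_link_ik(S, target, L[["L2"]], L[["L3"]] + model$palm_offset,
                     elbow_anterior = FALSE)
  q3 <- 0.4 * phi_t
  q <- numeric(model$n_dof)
  q[1] <- pelvis[2]
  q[2] <- pelvis[1] - (L[["L4"]] + L[["L5"]])
  q[3] <- q3
  q[4] <- phi_t - q3
  q[5] <- arm$phi1 - phi_t - pi
  q[6] <- arm$phi2 - arm$phi1
  q[7] <- leg$phi1 - q3 - pi
  q[8] <- leg$phi2 - leg$phi1
  q[9] <- pi - leg$phi2
  q[10] <- 0
  q[3:10] <- ((q[3:10] + pi) %% (2 * pi)) - pi
  q
}

# residual vector of the posture constraints: ankle pinned, foot flat,
# hand at target (all planar (y, z) components)
posture_residual <- function(model, q, hand_target, feet) {
  A <- forward_kinematics(model, q)
  c(landmark(model, q, "ankle", fk = A)[2:3] - feet,
    landmark(model, q, "ball", fk = A)[2],
    landmark(model, q, "toe", fk = A)[2],
    landmark(model, q, "hand", fk = A)[2:3] - hand_target)
}

posture_jacobian <- function(model, q) {
  dA <- transform_sensitivities(model, q)
  n <- model$n_dof
  J <- matrix(0, 6, n)
  pick <- function(frame, local, rows) {
    rh <- c(local, 1)
    sapply(seq_len(n), function(j) {
      if (is.null(dA[[frame]][[j]])) rep(0, length(rows))
      else (dA[[frame]][[j]] %*% rh)[rows]
    })
  }
  J[1:2, ] <- pick(8L, c(0, 0, 0), 2:3)
  J[3, ] <- pick(9L, c(0, 0, 0), 2)
  J[4, ] <- pick(10L, c(0, 0, 0), 2)
  J[5:6, ] <- pick(6L, c(model$palm_offset, 0, 0), 2:3)
  J
}

polish_posture <- function(model, q, hand_target, feet, tol = 1e-10) {
  for (it in 1:60) {
    r <- posture_residual(model, q, hand_target, feet)
    if (max(abs(r)) < tol) break
    J <- posture_jacobian(model, q)
    dq <- -as.numeric(t(J) %*% solve(J %*% t(J) + 1e-10 * diag(6), r))
    q <- pmin(pmax(q + dq, model$q_lower), model$q_upper)
  }
  r <- posture_residual(model, q, hand_target, feet)
  if (max(abs(r)) > 1e-7) {
    stop_liftopt(
      sprintf("posture synthesis did not converge (residual %.2e); the hand target may be unreachable with the feet pinned",
              max(abs(r))),
      "liftopt_infeasible"
    )
  }
  q
}
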