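#' Denavit-Hartenberg primitives
#'
#' The skeletal model is a branched kinematic chain in standard (distal)
#' Denavit-Hartenberg convention.  Each degree of freedom (DOF) contributes a
#' local homogeneous transform
#' \deqn{T = R_z(\theta)\,T_z(d)\,T_x(a)\,R_x(\alpha)}
#' where the free coordinate is \eqn{\theta} for a rotational DOF and
#' \eqn{d} for a translational DOF.  For fast evaluation every row is
#' factored as `pre %*% F(q) %*% post` with `F` either a z-rotation or a
#' z-translation, so that derivatives of the local transform with respect to
#' its own coordinate are obtained by swapping `F` for its derivative.
#'
#' @name dh
#' @keywords internal
NULL

rot_z <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, 0, -s, c, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1), 4, 4)
}

rot_x <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, 0, c, s, 0, 0, -s, c, 0, 0, 0, 0, 1), 4, 4)
}

trans_z <- function(d) {
  m <- diag(4); m[3, 4] <- d; m
}

trans_x <- function(a) {
  m <- diag(4); m[1, 4] <- a; m
}

# d/dq of Rz(q) equals Rz(q) %*% OMEGA_Z; d/dq of (I + q N_Z) equals N_Z
OMEGA_Z <- matrix(c(0, 1, 0, 0, -1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0), 4, 4)
N_Z <- local({ m <- matrix(0, 4, 4); m[3, 4] <- 1; m })

#' Construct one DH table row
#'
#' @param theta_offset Constant joint-angle offset (rad).
#' @param d Constant link offset along z (m); the free coordinate is added to
#'   it for translational rows.
#' @param a Link length along x (m).
#' @param alpha Link twist (rad), one of `0`, `pi/2`, `-pi/2`.
#' @param kind `"rotation"` or `"translation"`.
#' @param parent Index of the parent DOF (0 for the base).
#' @param branch `"global"`, `"upper"`, or `"lower"`.
#' @param name Human-readable joint name.
#' @return A `dh_row` list with precomputed `pre`/`post` factor matrices.
#' @keywords internal
dh_row <- function(theta_offset, d, a, alpha, kind, parent, branch, name) {
  stopifnot(kind %in% c("rotation", "translation"))
  if (min(abs(alpha - c(0, pi / 2, -pi / 2))) > 1e-12) {
    stop_liftopt("`alpha` must be 0 or +/- pi/2", "liftopt_validation_error")
  }
  if (kind == "rotation") {
    pre <- rot_z(theta_offset)
    post <- trans_z(d) %*% trans_x(a) %*% rot_x(alpha)
  } else {
    pre <- rot_z(theta_offset) %*% trans_z(d)
    post <- trans_x(a) %*% rot_x(alpha)
  }
  structure(
    list(
      theta_offset = theta_offset, d = d, a = a, alpha = alpha,
      kind = kind, parent = parent, branch = branch, name = name,
      pre = pre, post = post
    ),
    class = "dh_row"
  )
}

#' Local DH transform of one row
#'
#' @param row A [dh_row()].
#' @param q_value Value of the row's free coordinate (rad or m).
#' @param deriv Order of differentiation with respect to `q_value`
#'   (0 to 3).
#' @return A 4x4 homogeneous transform (or its `deriv`-th derivative).
#' @examples
#' r <- dh_row(0, 0, 0.4, 0, "rotation", 0, "upper", "demo")
#' dh_transform(r, pi / 2)
#' @export
dh_transform <- function(row, q_value, deriv = 0L) {
  if (!is.finite(q_value)) {
    stop_liftopt("joint coordinate must be finite", "liftopt_validation_error")
  }
  if (row$kind == "rotation") {
    f <- rot_z(q_value)
    if (deriv > 0) {
      for (k in seq_len(deriv)) f <- f %*% OMEGA_Z
    }
  } else {
    f <- if (deriv == 0) diag(4) + q_value * N_Z
    else if (deriv == 1) N_Z
    else matrix(0, 4, 4)
  }
  row$pre %*% f %*% row$post
}

# local transforms T_i and their first three own-coordinate derivatives for
# every DOF; returns list of list(T, T1, T2, T3)
local_transforms <- function(model, q) {
  lapply(seq_len(model$n_dof), function(i) {
    row <- model$dh[[i]]
    if (row$kind == "rotation") {
      f <- rot_z(q[i])
      f1 <- f %*% OMEGA_Z
      f2 <- f1 %*% OMEGA_Z
      f3 <- f2 %*% OMEGA_Z
      list(
        T = row$pre %*% f %*% row$post,
        T1 = row$pre %*% f1 %*% row$post,
        T2 = row$pre %*% f2 %*% row$post,
        T3 = row$pre %*% f3 %*% row$post
      )
    } else {
      z4 <- matrix(0, 4, 4)
      list(
        T = row$pre %*% (diag(4) + q[i] * N_Z) %*% row$post,
        T1 = row$pre %*% N_Z %*% row$post,
        T2 = z4, T3 = z4
      )
    }
  })
}

#' Forward kinematics of the branched chain
#'
#' Composes the global frame of every DOF, `A_i = A_parent(i) %*% T_i`.
#' The two body branches both chain from the global rotation.
#'
#' @param model A [human_model].
#' @param q Numeric vector of generalized coordinates (length `model$n_dof`);
#'   two global translations in metres, the rest joint angles in radians.
#' @return List of 4x4 global homogeneous transforms, one per DOF.
#' @export
forward_kinematics <- function(model, q) {
  check_state_dim(model, q)
  tr <- local_transforms(model, q)
  A <- vector("list", model$n_dof)
  for (i in seq_len(model$n_dof)) {
    p <- model$parent[i]
    A[[i]] <- if (p == 0L) tr[[i]]$T else A[[p]] %*% tr[[i]]$T
  }
  A
}

#' Analytic sensitivities of the global transforms
#'
#' Computes all partial derivatives `dA_i/dq_j`.  The partial is obtained by
#' replacing the local transform of DOF `j` with its coordinate derivative in
#' the chain product; it vanishes identically when `j` is not an ancestor of
#' `i` (in particular across branches).
#'
#' @inheritParams forward_kinematics
#' @return A list indexed `[[i]][[j]]` of 4x4 matrices (`NULL` entries are
#'   identically zero).
#' @export
transform_sensitivities <- function(model, q) {
  check_state_dim(model, q)
  tr <- local_transforms(model, q)
  n <- model$n_dof
  A <- vector("list", n)
  dA <- lapply(seq_len(n), function(i) vector("list", n))
  for (i in seq_len(n)) {
    p <- model$parent[i]
    if (p == 0L) {
      A[[i]] <- tr[[i]]$T
      dA[[i]][[i]] <- tr[[i]]$T1
    } else {
      A[[i]] <- A[[p]] %*% tr[[i]]$T
      for (j in seq_len(n)) {
        if (!is.null(dA[[p]][[j]])) dA[[i]][[j]] <- dA[[p]][[j]] %*% tr[[i]]$T
      }
      dA[[i]][[i]] <- A[[p]] %*% tr[[i]]$T1
    }
  }
  dA
}

check_state_dim <- function(model, q) {
  if (length(q) != model$n_dof || !is.numeric(q)) {
    stop_liftopt(
      sprintf("state must be a numeric vector of length %d", model$n_dof),
      "liftopt_validation_error"
    )
  }
  if (!all(is.finite(q))) {
    stop_liftopt("state contains non-finite values", "liftopt_validation_error")
  }
  invisible(TRUE)
}
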