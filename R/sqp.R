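# Dense SQP solver for the lifting NLP.
#
# Solves  min f(x)  s.t.  c_eq(x) = 0,  c_in(x) <= 0,  lb <= x <= ub
# by an l1-penalty sequential quadratic programming method (Fletcher's
# Sl1QP).  Each iteration solves the quadratic subproblem
#
#   min  g'p + 1/2 p'Bp + rho * ( sum|c_eq + J_eq p|_1
#                                 + sum max(0, c_in + J_in p) )
#
# over a trust box, with B a problem-supplied PSD (Gauss-Newton) Hessian
# approximation.  The l1 terms are handled by per-row slack variables, so
# the subproblem is always feasible and full-rank even when path equalities
# are collocated more finely than the spline can bend.  A backtracking line
# search on the matching l1 exact-penalty merit function globalizes the
# iteration, and a safeguarded damped Gauss-Newton projection polishes
# feasibility at the end.
#
# The problem callback `fn(x)` must return:
#   f      objective value
#   g      objective gradient
#   H      PSD Hessian approximation (optional)
#   c_eq   equality residuals (may be length 0)
#   J_eq   equality Jacobian
#   c_in   inequality values, feasible when <= 0 (may be length 0)
#   J_in   inequality Jacobian

sqp_solve <- function(x0, fn, lower, upper, control = list()) {
  ctrl <- modifyList(list(
    maxit = 150, tol_feas = 1e-8, tol_step = 1e-8,
    rho = 100, rho_max = 1e5, ridge = 1e-7, step_max = 0.5,
    polish_iters = 40, restore_first = TRUE, verbose = FALSE
  ), control)
  x <- pmin(pmax(x0, lower), upper)
  n <- length(x)
  rho <- ctrl$rho
  status <- "maxit"
  viol_of <- function(e) max(0, abs(e$c_eq), e$c_in)
  merit <- function(e) e$f + rho * (sum(abs(e$c_eq)) + sum(pmax(e$c_in, 0)))
  ev <- fn(x)
  n_eval <- 1L
  if (ctrl$restore_first && viol_of(ev) > ctrl$tol_feas) {
    rest <- restore_feasibility(fn, x, lower, upper, tol = ctrl$tol_feas,
                                maxit = ctrl$polish_iters)
    x <- rest$x; ev <- rest$ev
    n_eval <- n_eval + rest$n_eval
    if (ctrl$verbose) {
      message(sprintf("restored start: viol %.2e", viol_of(ev)))
    }
  }
  it <- 0L
  for (it in seq_len(ctrl$maxit)) {
    viol <- viol_of(ev)
    B <- ev$H %||% diag(n)
    B <- (B + t(B)) / 2 + ctrl$ridge * diag(n)
    qp <- solve_l1_qp(ev, B, x, lower, upper, rho, ctrl$step_max)
    if (is.null(qp)) { status <- "qp_failure"; break }
    p <- qp$p
    step_norm <- max(abs(p))
    # if the subproblem keeps substantial slack on a violated constraint,
    # the penalty is too weak for the linearized problem: raise it and retry
    if (qp$slack_used > max(10 * ctrl$tol_feas, 0.5 * viol) &&
        rho < ctrl$rho_max) {
      rho <- rho * 10
      next
    }
    if (step_norm < ctrl$tol_step && viol <= ctrl$tol_feas) {
      status <- "optimal"; break
    }
    m0 <- merit(ev)
    # predicted merit decrease from the QP model
    d_pred <- -(m0 - (ev$f + qp$model_value))
    alpha <- 1
    ok <- FALSE
    soc_tried <- FALSE
    for (ls in 1:30) {
      xt <- pmin(pmax(x + alpha * p, lower), upper)
      et <- fn(xt)
      n_eval <- n_eval + 1L
      if (merit(et) <= m0 + 1e-4 * alpha * min(d_pred, 0)) { ok <- TRUE; break }
      if (!soc_tried && alpha == 1) {
        # second-order correction: retract the constraint curvature picked
        # up over the full step before shrinking it
        soc_tried <- TRUE
        bad <- which(et$c_in > 0)
        Jc <- rbind(ev$J_eq, ev$J_in[bad, , drop = FALSE])
        cc <- c(et$c_eq, et$c_in[bad])
        if (length(cc)) {
          xs <- pmin(pmax(xt - damped_least_squares(Jc, cc), lower), upper)
          es <- fn(xs)
          n_eval <- n_eval + 1L
          if (merit(es) <= m0 + 1e-4 * min(d_pred, 0)) {
            xt <- xs; et <- es; ok <- TRUE; break
          }
        }
      }
      alpha <- alpha / 2
    }
    if (!ok) {
      status <- if (viol <= ctrl$tol_feas) "optimal" else "stalled"
      break
    }
    x <- xt
    ev <- et
    if (ctrl$verbose) {
      message(sprintf(
        "it %3d  f %.6e  viol %.2e  step %.2e  alpha %.3f  rho %.0e",
        it, ev$f, viol_of(ev), step_norm, alpha, rho))
    }
    if (step_norm * alpha < ctrl$tol_step && viol_of(ev) <= ctrl$tol_feas) {
      status <- "optimal"; break
    }
  }
  # final feasibility restoration
  if (viol_of(ev) > ctrl$tol_feas) {
    rest <- restore_feasibility(fn, x, lower, upper, tol = ctrl$tol_feas,
                                maxit = ctrl$polish_iters)
    if (viol_of(rest$ev) < viol_of(ev)) { x <- rest$x; ev <- rest$ev }
    n_eval <- n_eval + rest$n_eval
  }
  viol <- viol_of(ev)
  if (status %in% c("maxit", "stalled", "qp_failure") && viol <= 1e-6) {
    status <- "optimal"
  }
  list(x = x, objective = ev$f, violation = viol, status = status,
       iterations = it, n_eval = n_eval,
       worst_constraint = worst_constraint(ev), eval = ev)
}

# Feasibility restoration: minimal-norm steps toward the constraint set
# that keep the currently satisfied inequalities satisfied (each step is an
# l1-elastic QP with zero objective gradient and identity Hessian), with a
# backtracking safeguard on the max violation.
restore_feasibility <- function(fn, x, lower, upper, tol = 1e-9, maxit = 40) {
  n <- length(x)
  ev <- fn(x)
  n_eval <- 1L
  viol_of <- function(e) max(0, abs(e$c_eq), e$c_in)
  for (k in seq_len(maxit)) {
    viol <- viol_of(ev)
    if (viol <= tol) break
    ev0 <- ev
    ev0$g <- rep(0, n)
    qp <- solve_l1_qp(ev0, diag(n), x, lower, upper, rho = 1e4,
                      step_max = 1)
    if (is.null(qp) || max(abs(qp$p)) < 1e-14) break
    improved <- FALSE
    alpha <- 1
    for (ls in 1:12) {
      xt <- pmin(pmax(x + alpha * qp$p, lower), upper)
      et <- fn(xt)
      n_eval <- n_eval + 1L
      if (viol_of(et) < viol) { x <- xt; ev <- et; improved <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!improved) break
  }
  list(x = x, ev = ev, n_eval = n_eval)
}

# minimum-norm damped solution of J dx = c via SVD (rank-robust)
damped_least_squares <- function(J, c_, rel_tol = 1e-10) {
  sv <- svd(J)
  keep <- sv$d > rel_tol * max(sv$d, 1e-30)
  d_inv <- ifelse(keep, sv$d / (sv$d^2 + (1e-8 * max(sv$d))^2), 0)
  as.numeric(sv$v %*% (d_inv * crossprod(sv$u, c_)))
}

worst_constraint <- function(ev) {
  cand <- c(abs(ev$c_eq), pmax(ev$c_in, 0))
  nm <- c(names(ev$c_eq) %||% rep("eq", length(ev$c_eq)),
          names(ev$c_in) %||% rep("ineq", length(ev$c_in)))
  if (!length(cand)) return(NA_character_)
  nm[which.max(cand)]
}

# l1-penalty QP subproblem with per-row elastic slacks.
# Variables z = (p, s_eq_pos, s_eq_neg, s_vio) where s_eq absorb equality
# residuals and s_vio relax the currently violated inequalities; satisfied
# inequalities are imposed hard (p = 0 keeps them feasible).
solve_l1_qp <- function(ev, B, x, lower, upper, rho, step_max) {
  n <- length(x)
  m_eq <- length(ev$c_eq)
  vio <- which(ev$c_in > 0)
  sat <- which(ev$c_in <= 0)
  m_v <- length(vio)
  nz <- n + 2 * m_eq + m_v
  C <- diag(1e-8, nz)
  C[1:n, 1:n] <- B
  d <- c(ev$g, rep(rho, 2 * m_eq + m_v))
  Aeq <- beq <- NULL
  if (m_eq) {
    Aeq <- cbind(ev$J_eq, -diag(m_eq), diag(m_eq),
                 matrix(0, m_eq, m_v))
    beq <- -ev$c_eq
  }
  A <- NULL; b <- NULL
  if (m_v) {
    A <- cbind(ev$J_in[vio, , drop = FALSE], matrix(0, m_v, 2 * m_eq),
               -diag(m_v))
    b <- -ev$c_in[vio]
  }
  if (length(sat)) {
    A <- rbind(A, cbind(ev$J_in[sat, , drop = FALSE],
                        matrix(0, length(sat), 2 * m_eq + m_v)))
    b <- c(b, -ev$c_in[sat])
  }
  lb <- c(pmax(lower - x, -step_max), rep(0, 2 * m_eq + m_v))
  ub <- c(pmin(upper - x, step_max), rep(1e10, 2 * m_eq + m_v))
  for (ridge in c(0, 1e-6, 1e-4, 1e-2)) {
    sol <- tryCatch(
      pracma::quadprog(C + ridge * diag(nz), d, A, b, Aeq, beq, lb, ub),
      error = function(e) NULL
    )
    if (!is.null(sol) && all(is.finite(sol$xmin))) {
      z <- sol$xmin
      p <- z[1:n]
      slacks <- z[-(1:n)]
      model_value <- sum(ev$g * p) + 0.5 * sum(p * (B %*% p)) +
        rho * sum(slacks)
      return(list(p = p, slack_used = if (length(slacks)) max(slacks) else 0,
                  model_value = model_value))
    }
  }
  NULL
}
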