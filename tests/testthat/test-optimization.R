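test_that("design-variable counts follow the control-point bookkeeping", {
  expect_identical(count_design_variables(10, 0, 5), 50L)
  expect_identical(count_design_variables(10, 1, 5), 55L)
  expect_identical(count_design_variables(10, 2, 5), 60L)
  expect_identical(count_design_variables(10, 3, 5), 65L)
  m <- default_subject()
  pr0 <- lifting_nlp(m, lifting_task(), n_grid = 5)
  expect_equal(pr0$n_x, 50L)
  pr3 <- lifting_nlp(m, lifting_task(),
                     list(exoskeleton("knee"), exoskeleton("spine"),
                          exoskeleton("shoulder")), n_grid = 5)
  expect_equal(pr3$n_x, 65L)
})

test_that("the objective scales inversely with the squared strength range", {
  set.seed(31)
  m <- default_subject()
  task <- lifting_task()
  pr <- lifting_nlp(m, task, n_grid = 7)
  x <- pmin(pmax(rnorm(pr$n_x, 0, 0.1), pr$lower), pr$upper)
  f1 <- nlp_objective(pr, x)
  m2 <- build_human_model(1.7, 68.75, tau_lower = m$tau_lower / 2,
                          tau_upper = m$tau_upper / 2)
  pr2 <- lifting_nlp(m2, task, n_grid = 7)
  expect_equal(nlp_objective(pr2, x), 4 * f1, tolerance = 1e-10)
  # zero-torque normalization sanity: objective is non-negative
  expect_gte(f1, 0)
})

test_that("objective quadrature is stable under ten-fold grid refinement", {
  set.seed(32)
  m <- default_subject()
  task <- lifting_task()
  pr <- lifting_nlp(m, task, n_grid = 25)
  x <- liftopt:::design_start(pr, "reference")
  f25 <- nlp_objective(pr, x)
  pr250 <- lifting_nlp(m, task, n_grid = 250)
  expect_equal(nlp_objective(pr250, x), f25, tolerance = 0.01)
})

test_that("analytic NLP gradients and Jacobians match finite differences", {
  set.seed(33)
  m <- default_subject()
  pr <- lifting_nlp(m, lifting_task(), list(exoskeleton("knee")), n_grid = 5)
  x <- pmin(pmax(rnorm(pr$n_x, 0, 0.15), pr$lower), pr$upper)
  ev <- liftopt:::nlp_eval(pr, x)
  h <- 1e-6
  idx <- sample(pr$n_x, 10)
  for (j in idx) {
    e <- numeric(pr$n_x); e[j] <- h
    evp <- liftopt:::nlp_eval(pr, x + e)
    evm <- liftopt:::nlp_eval(pr, x - e)
    gfd <- (evp$f - evm$f) / (2 * h)
    expect_lt(abs(ev$g[j] - gfd) / max(abs(gfd), 1), 1e-4)
    expect_lt(max(abs(ev$J_eq[, j] - (evp$c_eq - evm$c_eq) / (2 * h))), 1e-5)
    expect_lt(max(abs(ev$J_in[, j] - (evp$c_in - evm$c_in) / (2 * h))), 1e-5)
  }
})

test_that("the constraint registry covers the formulation and flags violations by name", {
  m <- default_subject()
  task <- lifting_task()
  pr0 <- lifting_nlp(m, task, n_grid = 9)
  reg <- nlp_constraints(pr0, numeric(pr0$n_x))
  expect_false(any(grepl("^exo_torque", reg$name)))
  pr1 <- lifting_nlp(m, task, list(exoskeleton("knee")), n_grid = 9)
  reg1 <- nlp_constraints(pr1, numeric(pr1$n_x))
  expect_true(any(grepl("^exo_torque_upper\\[knee\\]", reg1$name)))
  # every Table-style constraint family is present
  for (fam in c("torque_upper", "torque_lower", "feet_ankle_y", "feet_ankle_z",
                "hand_forward", "collision", "zmp_heel", "zmp_toe",
                "box_initial_y", "box_final_z", "rest", "band_upper")) {
    expect_true(any(grepl(fam, reg$name)), label = fam)
  }
  # a posture with the wrist behind the pelvis trips hand_forward with its
  # time stamp
  q <- rep(0, 10); q[5] <- 0.9   # arm swung backwards
  x <- as.vector(sapply(q, rep, times = pr0$n_ctrl))
  regv <- nlp_constraints(pr0, x)
  bad <- regv[regv$violation > 0 & grepl("^hand_forward@t=", regv$name), ]
  expect_gt(nrow(bad), 0)
})

test_that("mechanical energy follows the closed form for monotone constant-torque motion", {
  # constant torque tau over net excursion dq at one joint: |tau * dq|
  tau <- 37; dq <- 1.2; T_ <- 2
  ts <- seq(0, T_, length.out = 201)
  qd <- dq / T_   # constant rate
  wq <- rep(T_ / 200, 201); wq[c(1, 201)] <- wq[1] / 2
  e <- sum(wq * abs(tau * qd))
  expect_equal(e, abs(tau * dq), tolerance = 1e-10)
})

test_that("percent reduction is exact arithmetic", {
  expect_equal(percent_reduction(200, 150), 25)
  expect_equal(percent_reduction(100, 100), 0)
})
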