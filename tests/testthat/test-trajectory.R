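test_that("clamped spline interpolates its end control points and is exact for constants", {
  tr <- bspline_trajectory(c(0.3, -0.1, 0.5, 0.2, 0.9), duration = 1.44)
  ev <- evaluate_trajectory(tr, c(0, 1.44))
  expect_equal(ev$value, c(0.3, 0.9))

  const <- bspline_trajectory(rep(0.7, 6), duration = 2)
  ts <- seq(0, 2, length.out = 11)
  evc <- evaluate_trajectory(const, ts)
  expect_equal(evc$value, rep(0.7, 11))
  expect_equal(evc$rate, rep(0, 11))
  expect_equal(evc$acceleration, rep(0, 11))
})

test_that("spline rates and accelerations match finite differences", {
  set.seed(1)
  tr <- bspline_trajectory(rnorm(7), duration = 1.44)
  # evaluation points clear of the interior knots, where the third
  # derivative jumps and one-sided differences would see the kink
  ts <- seq(0.05, 1.39, length.out = 8)
  h <- 1e-6
  ev <- evaluate_trajectory(tr, ts)
  vplus <- evaluate_trajectory(tr, ts + h)
  vminus <- evaluate_trajectory(tr, ts - h)
  expect_lt(max(abs((vplus$value - vminus$value) / (2 * h) - ev$rate)), 1e-6)
  expect_lt(max(abs((vplus$rate - vminus$rate) / (2 * h) - ev$acceleration)),
            1e-6)
})

test_that("basis rows form a partition of unity, sum to zero for rates, and are exact sensitivities", {
  set.seed(2)
  tr <- bspline_trajectory(rnorm(5), duration = 1)
  ts <- c(0, runif(5), 1)
  B0 <- basis_sensitivity(tr, ts, 0L)
  B1 <- basis_sensitivity(tr, ts, 1L)
  expect_equal(rowSums(B0), rep(1, length(ts)))
  expect_equal(rowSums(B1), rep(0, length(ts)), tolerance = 1e-12)
  dp <- rnorm(5)
  tr2 <- bspline_trajectory(tr$control_points + dp, 1)
  expect_equal(evaluate_trajectory(tr2, ts)$value,
               evaluate_trajectory(tr, ts)$value + drop(B0 %*% dp))
})

test_that("evaluation outside the domain errors", {
  tr <- bspline_trajectory(rep(0, 5), duration = 1)
  expect_error(evaluate_trajectory(tr, 1.01), class = "liftopt_error")
  expect_error(evaluate_trajectory(tr, -0.01), class = "liftopt_error")
})

test_that("least-squares fit recovers an exact spline and never worsens with more control points", {
  set.seed(3)
  truth <- bspline_trajectory(rnorm(5), duration = 2)
  ts <- seq(0, 2, length.out = 40)
  y <- evaluate_trajectory(truth, ts)$value
  fit <- fit_least_squares(data.frame(abscissa = ts, value = y), n_ctrl = 5,
                           domain = c(0, 2))
  expect_lt(max(abs(fit$control_points - truth$control_points)), 1e-9)

  # noisy samples: residual is monotone non-increasing in n_ctrl
  y2 <- y + 0.1 * sin(7 * ts)
  rss <- vapply(c(4, 5, 7, 9), function(nc) {
    f <- fit_least_squares(data.frame(abscissa = ts, value = y2), nc, c(0, 2))
    yhat <- drop(basis_sensitivity(f, ts, 0L) %*% f$control_points)
    sum((y2 - yhat)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))

  # constant samples give a constant spline
  fc <- fit_least_squares(data.frame(abscissa = ts, value = rep(2, 40)), 5)
  expect_equal(fc$control_points, rep(2, 5), tolerance = 1e-9)
})

test_that("degenerate fits are rejected", {
  expect_error(
    fit_least_squares(data.frame(abscissa = rep(1, 10), value = rnorm(10)), 4),
    class = "liftopt_degenerate_domain"
  )
  # clustered samples leave basis columns empty
  xs <- c(rep(0.01, 6), rep(1.99, 6))
  expect_error(
    fit_least_squares(data.frame(abscissa = xs, value = rnorm(12)), 6,
                      domain = c(0, 2)),
    class = "liftopt_rank_deficient"
  )
})
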