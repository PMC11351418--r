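# the NLP backend on small analytic problems with known optima

test_that("SQP solves an equality/inequality constrained quadratic", {
  fn <- function(x) {
    list(
      f = (x[1] - 2)^2 + (x[2] - 1)^2,
      g = c(2 * (x[1] - 2), 2 * (x[2] - 1)),
      H = 2 * diag(2),
      c_eq = x[1] + x[2] - 2, J_eq = matrix(c(1, 1), 1),
      c_in = x[1]^2 - x[2], J_in = matrix(c(2 * x[1], -1), 1)
    )
  }
  s <- sqp_solve(c(0, 0), fn, c(-5, -5), c(5, 5))
  expect_equal(s$x, c(1, 1), tolerance = 1e-6)
  expect_lt(s$violation, 1e-8)
  expect_equal(s$status, "optimal")
})

test_that("SQP handles a nonconvex objective with an active nonlinear constraint", {
  fn <- function(x) {
    J <- rbind(c(-20 * x[1], 10), c(-1, 0))
    list(
      f = 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2,
      g = c(-400 * x[1] * (x[2] - x[1]^2) - 2 * (1 - x[1]),
            200 * (x[2] - x[1]^2)),
      H = 2 * crossprod(J),
      c_eq = numeric(0), J_eq = matrix(0, 0, 2),
      c_in = sum(x^2) - 1, J_in = matrix(2 * x, 1)
    )
  }
  s <- sqp_solve(c(-1, 1), fn, c(-2, -2), c(2, 2),
                 control = list(maxit = 300))
  expect_lt(s$violation, 1e-8)
  expect_lt(abs(sum(s$x^2) - 1), 1e-6)   # constraint active at the optimum
  expect_equal(s$x, c(0.7864, 0.6177), tolerance = 1e-3)
})

test_that("restoration finds a feasible point of an infeasible start without breaking satisfied rows", {
  # feasible set: x1 + x2 = 1, x1 >= 0.2; start violates the equality badly
  fn <- function(x) {
    list(f = sum(x^2), g = 2 * x, H = 2 * diag(2),
         c_eq = x[1] + x[2] - 1, J_eq = matrix(c(1, 1), 1),
         c_in = 0.2 - x[1], J_in = matrix(c(-1, 0), 1))
  }
  r <- liftopt:::restore_feasibility(fn, c(3, 3), c(-5, -5), c(5, 5))
  expect_lt(max(abs(r$ev$c_eq), r$ev$c_in, 0), 1e-8)
})

test_that("bounds confine the SQP iterates", {
  fn <- function(x) {
    list(f = sum((x - 3)^2), g = 2 * (x - 3), H = 2 * diag(2),
         c_eq = numeric(0), J_eq = matrix(0, 0, 2),
         c_in = numeric(0), J_in = matrix(0, 0, 2))
  }
  s <- sqp_solve(c(0, 0), fn, c(-1, -1), c(1, 2))
  expect_equal(s$x, c(1, 2), tolerance = 1e-6)
})
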