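test_that("dh_transform reproduces the planar-link closed form", {
  r <- liftopt:::dh_row(0, 0, 0.4, 0, "rotation", 0L, "upper", "demo")
  Tq <- dh_transform(r, pi / 2)
  expect_equal(Tq[1:2, 4], 0.4 * c(cos(pi / 2), sin(pi / 2)))
  expect_equal(Tq[1:2, 1:2],
               matrix(c(0, 1, -1, 0), 2, 2), tolerance = 1e-12)
  # zero-parameter row at q = 0 is the identity
  r0 <- liftopt:::dh_row(0, 0, 0, 0, "rotation", 0L, "upper", "zero")
  expect_equal(dh_transform(r0, 0), diag(4))
  expect_error(dh_transform(r, Inf), class = "liftopt_error")
})

test_that("global branch composition places the root by the model convention", {
  m <- default_subject()
  L45 <- m$lengths[["L4"]] + m$lengths[["L5"]]
  q <- rep(0, 10)
  q[1] <- 0.21   # anterior translation
  q[2] <- -0.13  # vertical offset about standing hip height
  p <- landmark(m, q, "pelvis")
  expect_equal(p[2], L45 - 0.13, tolerance = 1e-12)
  expect_equal(p[3], 0.21, tolerance = 1e-12)
})

test_that("rotation blocks stay orthonormal with unit determinant over random states", {
  set.seed(11)
  m <- default_subject()
  for (k in 1:200) {
    q <- runif(10, -1.5, 1.5)
    A <- forward_kinematics(m, q)
    i <- sample(10, 1)
    R <- A[[i]][1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
})

test_that("branches are kinematically independent", {
  set.seed(12)
  m <- default_subject()
  q <- runif(10, -1, 1)
  A <- forward_kinematics(m, q)
  q2 <- q
  q2[8] <- q2[8] + 0.5   # knee: lower branch
  A2 <- forward_kinematics(m, q2)
  for (i in 4:6) expect_equal(A[[i]], A2[[i]])  # upper branch unchanged
  q3 <- q
  q3[5] <- q3[5] - 0.7   # shoulder: upper branch
  A3 <- forward_kinematics(m, q3)
  for (i in 7:10) expect_equal(A[[i]], A3[[i]])
})

test_that("analytic transform sensitivities match finite differences and respect branch locality", {
  set.seed(13)
  m <- default_subject()
  h <- 1e-6
  for (k in 1:25) {
    q <- runif(10, -1, 1)
    dA <- transform_sensitivities(m, q)
    i <- sample(10, 1)
    for (j in 1:10) {
      qp <- q; qm <- q
      qp[j] <- qp[j] + h; qm[j] <- qm[j] - h
      fd <- (forward_kinematics(m, qp)[[i]] -
               forward_kinematics(m, qm)[[i]]) / (2 * h)
      an <- dA[[i]][[j]]
      if (is.null(an)) {
        expect_lt(max(abs(fd)), 1e-6)   # cross-branch partial is zero
      } else {
        expect_lt(max(abs(fd - an)), 1e-6)
      }
    }
  }
  # translation-DOF sensitivity has no rotation part
  dA <- transform_sensitivities(m, runif(10, -1, 1))
  expect_equal(dA[[5]][[2]][1:3, 1:3], matrix(0, 3, 3))
})

test_that("landmarks have the expected geometry", {
  m <- default_subject()
  q <- rep(0, 10)
  expect_equal(landmark(m, q, "ankle")[2], 0, tolerance = 1e-12)
  expect_equal(landmark(m, q, "toe")[2], 0, tolerance = 1e-12)
  expect_equal(landmark(m, q, "heel")[3],
               -m$foot$heel_offset, tolerance = 1e-12)
  # hand = wrist + palm offset along the forearm axis
  m2 <- build_human_model(1.7, 68.75, palm_offset = 0.08)
  d <- landmark(m2, q, "hand") - landmark(m2, q, "wrist")
  expect_equal(sqrt(sum(d^2)), 0.08, tolerance = 1e-12)
  expect_error(landmark(m, q, "nose"), class = "liftopt_error")
})
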