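test_that("a static single link reproduces the textbook gravity torque", {
  # link of mass m with CoM at distance r from the pivot, angle q from the
  # +x (horizontal) axis: gravity torque = m g r cos(q)
  ch <- make_chain_model(0.8, 3, com_fracs = 0.6)
  r <- 0.6 * 0.8
  for (q in c(-1, -0.3, 0, 0.4, 1.2)) {
    tau <- inverse_dynamics(ch, kinematic_state(q))
    expect_equal(tau, 3 * ch$gravity * r * cos(q), tolerance = 1e-10)
  }
})

test_that("zero gravity, motion, and loads give zero torques; zero mass kills D and E", {
  ch <- make_chain_model(c(0.5, 0.4), c(2, 1))
  ch$gravity <- 0
  expect_equal(inverse_dynamics(ch, kinematic_state(c(0.3, -0.2))),
               c(0, 0), tolerance = 1e-12)
  ch0 <- make_chain_model(c(0.5, 0.4), c(0, 0))
  rec <- backward_recursion(ch0, random_chain_state(2))
  for (i in 1:2) {
    expect_equal(rec$D[[i]], matrix(0, 4, 4))
    expect_equal(rec$E[[i]], rep(0, 4))
  }
  # no external loads: F and G empty / zero
  expect_length(rec$F, 0)
  expect_equal(rec$G[[1]], c(0, 0, 0))
})

test_that("recursive torques match the numerical Euler-Lagrange oracle on random chains", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(2:3, 1)
    ch <- make_chain_model(runif(n, 0.3, 0.7), runif(n, 0.5, 4),
                           com_fracs = runif(n, 0.3, 0.7),
                           rog_fracs = runif(n, 0.2, 0.4))
    st <- random_chain_state(n)
    tau <- inverse_dynamics(ch, st)
    tau_o <- oracle_torques(ch, st)
    expect_lt(max(abs(tau - tau_o) / pmax(abs(tau_o), 1)), 1e-6)
  }
})

test_that("the full skeleton with box and external force matches the oracle", {
  set.seed(22)
  m <- add_point_mass(default_subject(), 6L, c(0.03, 0, 0), 10)
  ld <- external_load(
    forces = list(list(frame = 8L, local = c(-0.1, 0, 0),
                       force = c(0, -40, 15))),
    moments = list(list(frame = 4L, moment = c(5, 0, 0)))
  )
  for (rep in 1:3) {
    st <- random_state(m)
    tau <- inverse_dynamics(m, st, ld)
    tau_o <- oracle_torques(m, st, ld)
    expect_lt(max(abs(tau - tau_o) / pmax(abs(tau_o), 1)), 1e-6)
  }
})

test_that("exoskeleton coupling splits torques exactly", {
  set.seed(23)
  m <- default_subject()
  st <- random_state(m)
  tau0 <- inverse_dynamics(m, st)
  exo <- c(knee = 12.5, spine = -20)
  tau_h <- coupled_torques(m, st, exo_torques = exo)
  expect_equal(tau_h[8] + 12.5, tau0[8])
  expect_equal(tau_h[4] - 20, tau0[4])
  expect_equal(tau_h[-c(4, 8)], tau0[-c(4, 8)])
  expect_equal(coupled_torques(m, st), tau0)
  # full assistance zeroes the human share
  tau_full <- coupled_torques(m, st, exo_torques = c(knee = tau0[8]))
  expect_equal(tau_full[8], 0)
  expect_error(coupled_torques(m, st, exo_torques = c(global_ty = 5)),
               class = "liftopt_validation_error")
})

test_that("static ground reaction equals total weight and the ZMP is the CoM projection", {
  m <- default_subject()
  task <- lifting_task()
  refs <- reference_postures(m, task)
  for (k in 1:3) {
    st <- kinematic_state(refs[, k])
    gr <- ground_reaction(m, st)
    expect_equal(unname(gr$grf["vertical"]), m$total_mass * m$gravity,
                 tolerance = 1e-9)
    expect_equal(unname(gr$grf["horizontal"]), 0, tolerance = 1e-9)
    expect_equal(gr$zmp, landmark(m, refs[, k], "com")[3], tolerance = 1e-9)
  }
  # carrying the box adds its weight
  mb <- add_point_mass(m, 6L, c(0, 0, 0), task$box_mass)
  grb <- ground_reaction(mb, kinematic_state(refs[, 1]))
  expect_equal(unname(grb$grf["vertical"]),
               (68.75 + 10) * m$gravity, tolerance = 1e-9)
})

test_that("generalized forces at the global DOFs agree with the Newton-Euler ground reaction", {
  set.seed(24)
  m <- add_point_mass(default_subject(), 6L, c(0, 0, 0), 10)
  for (rep in 1:5) {
    st <- random_state(m)
    tau <- inverse_dynamics(m, st)
    gr <- ground_reaction(m, st)
    expect_equal(tau[1], unname(gr$grf["horizontal"]), tolerance = 1e-8)
    expect_equal(tau[2], unname(gr$grf["vertical"]), tolerance = 1e-8)
  }
})

test_that("stability margin is a signed distance to the support region", {
  expect_equal(stability_margin(0.125, c(0, 0.25)), 0.125)
  expect_equal(stability_margin(0, c(0, 0.25)), 0)
  expect_equal(stability_margin(0.30, c(0, 0.25)), -0.05)
  expect_equal(stability_margin(-0.02, c(0, 0.25)), -0.02)
  expect_error(stability_margin(0, c(1, 0)), class = "liftopt_error")
})
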