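test_that("motor electromechanics follow the closed forms", {
  sp <- motor_spec(resistance = 0.2, torque_constant = 0.1, gear_ratio = 100,
                   rotor_inertia = 1e-5, viscous_friction = 1e-4,
                   current_limit = 10)
  expect_equal(motor_torque(sp, 0), 0)
  expect_equal(motor_torque(sp, 2), 0.2)
  expect_equal(motor_torque(sp, 4), 2 * motor_torque(sp, 2))
  # static rotor: load torque is the motor torque
  expect_equal(load_torque(sp, 3), motor_torque(sp, 3))
  expect_equal(load_torque(sp, 0), 0)
  # friction-only spin-down
  expect_equal(load_torque(sp, 0, rotor_rate = 7), -sp$viscous_friction * 7)
  # torque chain through the gearbox, static
  expect_equal(exo_torque(sp, 1), 100 * 0.1 * 1)
  # voltage: Ohmic and back-EMF limits
  expect_equal(required_voltage(sp, 0), 0)
  expect_equal(required_voltage(sp, 2), 0.2 * 2)
  expect_equal(required_voltage(sp, 2, rotor_rate = 30),
               0.1 * 30 + 0.2 * 2)
})

test_that("device torque is affine in current with sensitivity GBr*K times the basis", {
  sp <- motor_spec(torque_constant = 0.05, gear_ratio = 50)
  # affinity at fixed kinematics
  t0 <- exo_torque(sp, 0, joint_rate = 1.3, joint_accel = -2)
  t1 <- exo_torque(sp, 2, joint_rate = 1.3, joint_accel = -2)
  t2 <- exo_torque(sp, 5, joint_rate = 1.3, joint_accel = -2)
  t12 <- exo_torque(sp, 7, joint_rate = 1.3, joint_accel = -2)
  expect_equal(t12 - t0, (t1 - t0) + (t2 - t0), tolerance = 1e-12)
  # analytic dtau/dI equals GBr*K and matches finite differences to 1e-8
  h <- 1e-6
  fd <- (exo_torque(sp, 2 + h, 1.3, -2) - exo_torque(sp, 2 - h, 1.3, -2)) / (2 * h)
  expect_equal(fd, sp$gear_ratio * sp$torque_constant, tolerance = 1e-8)
  # control-point sensitivity is the scaled basis row, independent of I
  tr <- bspline_trajectory(rep(0, 5), 1.44)
  B <- basis_sensitivity(tr, c(0.3, 0.9), 0L)
  S <- torque_current_sensitivity(sp, B)
  expect_equal(S, sp$gear_ratio * sp$torque_constant * B)
})

test_that("motor spec validation rejects non-physical constants", {
  expect_error(motor_spec(resistance = -1), class = "liftopt_validation_error")
  expect_error(motor_spec(gear_ratio = 0.5), class = "liftopt_validation_error")
})
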