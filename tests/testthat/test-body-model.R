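test_that("model construction conserves mass and scales anthropometrically", {
  m <- build_human_model(1.7, 68.75)
  expect_equal(m$total_mass, 68.75)
  expect_equal(sum(vapply(m$segments, `[[`, numeric(1), "mass")), 68.75)
  # doubling height doubles every link length
  m2 <- build_human_model(3.4, 68.75, foot_length = 0.5)
  expect_equal(unname(m2$lengths), unname(2 * m$lengths))
  expect_error(build_human_model(1.7, 0), class = "liftopt_validation_error")
  expect_error(build_human_model(-1, 70), class = "liftopt_validation_error")
  expect_error(build_human_model(1.7, 70, link_lengths = c(1, 2, 3)),
               class = "liftopt_validation_error")
})

test_that("the spine DH row matches the chain's table", {
  m <- build_human_model(1.7, 68.75)
  row <- m$dh[[4]]
  expect_equal(row$theta_offset, -pi / 2)
  expect_equal(row$a, unname(m$lengths[["L1"]]))
  expect_equal(row$alpha, 0)
  expect_equal(row$kind, "rotation")
  # branch structure: both branches hang off the global rotation
  expect_equal(m$parent[4], 3L)
  expect_equal(m$parent[7], 3L)
})

test_that("attaching exoskeletons adds exactly the device masses", {
  m <- build_human_model(1.7, 68.75)
  expect_identical(attach_exoskeletons(m, list()), m)
  mk <- attach_exoskeletons(m, list(exoskeleton("knee")))
  expect_equal(mk$total_mass, 71.00)
  m3 <- attach_exoskeletons(m, list(exoskeleton("knee"), exoskeleton("spine"),
                                    exoskeleton("shoulder")))
  expect_equal(m3$total_mass, 68.75 + 2.25 + 3.4 + 1.2)
  expect_equal(sum(vapply(m3$segments, `[[`, numeric(1), "mass")),
               m3$total_mass)
  expect_error(
    attach_exoskeletons(m, list(exoskeleton("knee"), exoskeleton("knee"))),
    class = "liftopt_validation_error"
  )
})

test_that("exoskeleton specs validate their torque reachability and joints", {
  exo <- exoskeleton("spine")
  expect_equal(exo$joint_index, 4L)
  expect_equal(exo$tau_lower, -exo$tau_upper)
  expect_error(exoskeleton("elbow"), class = "liftopt_validation_error")
  expect_error(
    exoskeleton("knee", motor = motor_spec(gear_ratio = 2)),
    class = "liftopt_validation_error"
  )
  expect_error(exoskeleton("global_ty"), class = "liftopt_validation_error")
})

test_that("reference postures close the forward-kinematics round trip", {
  m <- build_human_model(1.7, 68.75)
  task <- lifting_task()
  refs <- reference_postures(m, task)
  targets <- list(task$hand_initial, NULL, task$hand_final)
  for (k in c(1L, 3L)) {
    q <- refs[, k]
    hand <- landmark(m, q, "hand")
    expect_lt(max(abs(hand[2:3] - targets[[k]][2:3])), 1e-6)
    expect_lt(max(abs(landmark(m, q, "ankle")[2:3] -
                        task$feet_position[2:3])), 1e-6)
    expect_lt(abs(landmark(m, q, "toe")[2]), 1e-6)
  }
  expect_true(all(refs >= m$q_lower & refs <= m$q_upper))
  # upright end posture: knee near extension, squat start: deep flexion
  expect_lt(abs(refs["knee", 3]), 0.4)
  expect_gt(refs["knee", 1], 1.5)
})

test_that("unreachable hand targets are reported as infeasible", {
  m <- build_human_model(1.7, 68.75)
  task <- lifting_task(hand_final = c(0, 2.5, 1.5))
  expect_error(reference_postures(m, task), class = "liftopt_infeasible")
})

test_that("task validation rejects degenerate inputs", {
  expect_error(lifting_task(duration = 0), class = "liftopt_validation_error")
  expect_error(lifting_task(box_mass = -1), class = "liftopt_validation_error")
})
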