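test_that("the packaged configuration loads into model, devices, and task", {
  cfg_path <- system.file("extdata", "default_config.yaml", package = "liftopt")
  cfg <- load_config(cfg_path)
  expect_s3_class(cfg$model, "human_model")
  expect_equal(cfg$model$subject_mass, 68.75)
  expect_length(cfg$exoskeletons, 3)
  expect_equal(vapply(cfg$exoskeletons, `[[`, numeric(1), "tau_upper"),
               c(16, 36, 12))
  expect_equal(cfg$task$box_mass, 10)
  expect_equal(cfg$task$duration, 1.44)
})

test_that("configuration schema violations are reported with their key", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("subject:", "  height: 1.7"), bad)
  expect_error(load_config(bad), "subject.mass", fixed = TRUE)
  bad2 <- tempfile(fileext = ".yaml")
  writeLines(c("subject:", "  height: 1.7", "  mass: 70",
               "exoskeletons:", "  - joint: wrist"), bad2)
  expect_error(load_config(bad2), "exoskeletons.joint", fixed = TRUE)
  expect_error(load_config(tempfile()), class = "liftopt_config_error")
})

test_that("comparing a baseline with itself yields zero reductions", {
  sols <- cached_small_solutions()
  tab <- compare_cases(sols$none, same = sols$none)
  expect_equal(tab$reduction_pct[tab$case == "same"], rep(0, 3))
  expect_equal(unname(tab$energy[tab$case == "same"]),
               unname(tab$energy[tab$case != "same"]))
})

test_that("cases solved for different tasks refuse to be compared", {
  sols <- cached_small_solutions()
  other <- sols$none
  other$problem$task$box_mass <- 5
  expect_error(compare_cases(sols$none, other = other),
               class = "liftopt_validation_error")
})

test_that("case artifacts include per-device torque columns and a faithful summary", {
  sols <- cached_small_solutions()
  out <- file.path(tempdir(), "liftopt-case-test")
  sol <- sols$knee
  sol$case <- "knee"
  liftopt:::write_case_artifacts(sol, out)
  tr <- read.csv(file.path(out, "trajectory.csv"))
  expect_true(all(c("q_knee", "tau_human_knee", "tau_exo_knee",
                    "grf_vertical", "zmp") %in% names(tr)))
  sm <- jsonlite::read_json(file.path(out, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(sm$energy, sol$energy, tolerance = 1e-10)
  expect_equal(sm$n_design_variables, sol$problem$n_x)
  # determinism: identical configuration reproduces the identical summary
  out2 <- file.path(tempdir(), "liftopt-case-test2")
  liftopt:::write_case_artifacts(sol, out2)
  expect_identical(readLines(file.path(out, "summary.json")),
                   readLines(file.path(out2, "summary.json")))
  unlink(c(out, out2), recursive = TRUE)
})

test_that("run_case orchestrates config -> solve -> artifacts", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "subject: {height: 1.70, mass: 68.75}",
    "task: {box_mass: 10, duration: 1.44}",
    "solver: {n_ctrl: 5, n_grid: 9, maxit: 80}"
  ), cfg)
  out <- file.path(tempdir(), "liftopt-run-case")
  sol <- run_case(cfg, case = "none", out = out)
  expect_equal(sol$problem$n_x, 50L)
  expect_lte(sol$violation, 1e-6)
  expect_true(file.exists(file.path(out, "trajectory.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "snapshots", "snapshots.png")))
  unlink(out, recursive = TRUE)
})

test_that("mechanical energy is stable under quadrature refinement", {
  sols <- cached_small_solutions()
  # at the study quadrature resolution a ten-fold refinement moves the
  # integral by less than 1%
  e25 <- mechanical_energy(sols$none, n_grid = 25)
  e250 <- mechanical_energy(sols$none, n_grid = 250)
  expect_lt(abs(e250 - e25) / e25, 0.01)
  # positive-work-only energy is no larger than the absolute-work energy
  expect_lte(mechanical_energy(sols$none, positive_work_only = TRUE),
             sols$none$energy)
})

test_that("tidiers and plots expose the solution surfaces", {
  sols <- cached_small_solutions()
  td <- tidy(sols$none)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("t", "joint", "q", "tau_human") %in% names(td)))
  gl <- glance(sols$none)
  expect_equal(nrow(gl), 1)
  expect_true(gl$peak_spine > 0)
  expect_s3_class(autoplot(sols$none), "ggplot")
  expect_s3_class(autoplot(sols$knee, "exo"), "ggplot")
  expect_s3_class(plot_snapshots(sols$none, c(0, 0.5, 1)), "ggplot")
})
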