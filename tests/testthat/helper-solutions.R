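# Solved cases shared across test files, computed once per test run.
# The small solutions use a coarse time grid to keep unit tests fast; the
# study-scale solutions (full 25-point grid) are solved lazily by the
# acceptance tests.

.liftopt_test_cache <- new.env(parent = emptyenv())

cached_small_solutions <- function() {
  if (is.null(.liftopt_test_cache$small)) {
    m <- build_human_model(1.7, 68.75)
    task <- lifting_task()
    none <- solve_lifting(lifting_nlp(m, task, n_grid = 9),
                          control = list(maxit = 80))
    none$case <- "none"
    knee <- solve_lifting(lifting_nlp(m, task, list(exoskeleton("knee")),
                                      n_grid = 9),
                          control = list(maxit = 80))
    knee$case <- "knee"
    .liftopt_test_cache$small <- list(none = none, knee = knee)
  }
  .liftopt_test_cache$small
}

cached_study_solution <- function(which = c("all", "none", "knee",
                                            "knee_massless")) {
  which <- match.arg(which)
  key <- paste0("study_", which)
  if (is.null(.liftopt_test_cache[[key]])) {
    m <- build_human_model(1.7, 68.75)
    task <- lifting_task()
    exos <- switch(which,
      none = list(),
      knee = list(exoskeleton("knee")),
      knee_massless = list(exoskeleton("knee", mass = 1e-9)),
      all = list(exoskeleton("knee"), exoskeleton("spine"),
                 exoskeleton("shoulder"))
    )
    problem <- lifting_nlp(m, task, exos)
    start <- "zero"
    if (which == "knee_massless") {
      # start from the solved unassisted motion with zero current: this
      # point replicates the unassisted optimum exactly
      base <- cached_study_solution("none")
      start <- c(base$x, rep(0, 5))
    }
    sol <- solve_lifting(problem, start = start)
    sol$case <- which
    .liftopt_test_cache[[key]] <- sol
  }
  .liftopt_test_cache[[key]]
}
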