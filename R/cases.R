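#' Load a simulation configuration
#'
#' Reads a YAML (or JSON) configuration describing the subject, the
#' exoskeletons, and the lifting task.  All lengths are metres, masses kg,
#' times seconds, torques N m, currents amperes.  Recognized keys:
#'
#' * `subject`: `height`, `mass`, optional `links` (L1..L7), optional
#'   `foot_length`, `palm_offset`.
#' * `exoskeletons`: list of blocks with `joint` (knee/spine/shoulder),
#'   optional `mass`, `torque_limit`, and motor fields (`resistance`,
#'   `inductance`, `torque_constant`, `rotor_inertia`, `viscous_friction`,
#'   `gear_ratio`, `current_limit`).
#' * `task`: `box_mass`, `hand_initial`, `hand_final`, `duration`, optional
#'   `box_height`, `box_depth`, `epsilon`, `feet_position`.
#' * `solver` (optional): `n_ctrl`, `n_grid`, `maxit`.
#'
#' @param path Path to the configuration file.
#' @return A named list with `model`, `exoskeletons`, `task`, `solver`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_liftopt(sprintf("config file '%s' not found", path),
                 "liftopt_config_error")
  }
  cfg <- yaml::read_yaml(path)
  subj <- cfg$subject
  if (is.null(subj$height) || is.null(subj$mass)) {
    stop_liftopt("config: `subject.height` and `subject.mass` are required",
                 "liftopt_config_error")
  }
  model <- build_human_model(
    height = subj$height, mass = subj$mass,
    link_lengths = unlist(subj$links) %||% NULL,
    foot_length = subj$foot_length %||% 0.25,
    palm_offset = subj$palm_offset %||% 0
  )
  exos <- lapply(cfg$exoskeletons %||% list(), function(b) {
    if (is.null(b$joint) ||
        !b$joint %in% c("knee", "spine", "shoulder")) {
      stop_liftopt(
        sprintf("config: `exoskeletons.joint` must be knee/spine/shoulder, got '%s'",
                b$joint %||% "<missing>"),
        "liftopt_config_error"
      )
    }
    motor_args <- b[intersect(names(b), names(formals(motor_spec)))]
    motor <- if (length(motor_args)) {
      defaults <- EXO_DEFAULTS[[b$joint]]
      do.call(motor_spec, modifyList(list(gear_ratio = defaults$gear_ratio),
                                     motor_args))
    } else NULL
    exoskeleton(b$joint, mass = b$mass, tau_limit = b$torque_limit,
                motor = motor)
  })
  tk <- cfg$task %||% list()
  task <- lifting_task(
    box_mass = tk$box_mass %||% 10,
    box_height = tk$box_height %||% 0.15,
    box_depth = tk$box_depth %||% 0.65,
    hand_initial = unlist(tk$hand_initial) %||% c(0, 0.070, 0.418),
    hand_final = unlist(tk$hand_final) %||% c(0, 1.088, 0.417),
    duration = tk$duration %||% 1.44,
    feet_position = unlist(tk$feet_position) %||% c(0, 0, 0),
    epsilon = tk$epsilon %||% 0.2
  )
  list(model = model, exoskeletons = exos, task = task,
       solver = cfg$solver %||% list())
}

# the four studied device combinations
CASE_EXOS <- list(
  none = character(0),
  knee = "knee",
  spine_shoulder = c("spine", "shoulder"),
  all = c("knee", "spine", "shoulder")
)

#' Solve one lifting case and write its artifacts
#'
#' Builds the model from the configuration, attaches the case's
#' exoskeletons, solves the lifting optimization, and (optionally) writes
#' `trajectory.csv`, `summary.json`, and snapshot figures to the output
#' directory.  Deterministic given the configuration.
#'
#' @param config Path to a YAML config, or the list from [load_config()].
#' @param case One of `"none"`, `"knee"`, `"spine_shoulder"`, `"all"`.
#' @param out Output directory; `NULL` writes nothing.
#' @param ... Passed to [solve_lifting()].
#' @return A `lift_solution` (invisibly carries a `report` attribute
#'   tibble).
#' @export
run_case <- function(config, case = c("none", "knee", "spine_shoulder", "all"),
                     out = NULL, ...) {
  case <- match.arg(case)
  cfg <- if (is.character(config)) load_config(config) else config
  joints <- CASE_EXOS[[case]]
  have <- vapply(cfg$exoskeletons, `[[`, character(1), "joint")
  exos <- lapply(joints, function(j) {
    k <- match(j, have)
    if (is.na(k)) exoskeleton(j) else cfg$exoskeletons[[k]]
  })
  sv <- cfg$solver
  problem <- lifting_nlp(cfg$model, cfg$task, exos,
                         n_ctrl = sv$n_ctrl %||% 5,
                         n_grid = sv$n_grid %||% 25)
  sol <- solve_lifting(problem,
                       control = list(maxit = sv$maxit %||% 150), ...)
  sol$case <- case
  if (!is.null(out)) {
    write_case_artifacts(sol, out)
  }
  sol
}

write_case_artifacts <- function(sol, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wide <- sol$trajectory |>
    tidyr::pivot_wider(
      names_from = "joint",
      values_from = c("q", "qdot", "qddot", "tau_human", "tau_exo")
    ) |>
    dplyr::left_join(sol$grf, by = "t")
  write.csv(wide, file.path(out, "trajectory.csv"), row.names = FALSE)
  summary <- list(
    case = sol$case %||% NA_character_,
    status = sol$status,
    objective = sol$objective,
    violation = sol$violation,
    energy = sol$energy,
    peaks = as.list(setNames(
      glance(sol)[c("peak_spine", "peak_shoulder", "peak_knee")],
      c("spine", "shoulder", "knee")
    )),
    n_design_variables = sol$problem$n_x,
    n_grid = sol$problem$n_grid
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  snap_dir <- file.path(out, "snapshots")
  dir.create(snap_dir, showWarnings = FALSE)
  pl <- plot_snapshots(sol)
  ggplot2::ggsave(file.path(snap_dir, "snapshots.png"), pl,
                  width = 8, height = 4, dpi = 150)
  invisible(sol)
}

#' Compare assisted cases against a baseline
#'
#' Produces the peak-torque / mechanical-energy comparison table across
#' solved cases, with percent reductions relative to the baseline.
#'
#' @param baseline A solved `lift_solution` (typically the no-device case).
#' @param ... Further solved `lift_solution`s (named arguments become case
#'   labels).
#' @return A tibble with one row per case and joint.
#' @export
compare_cases <- function(baseline, ...) {
  assisted <- list(...)
  sols <- c(list(baseline), assisted)
  labels <- c(baseline$case %||% "baseline",
              purrr::imap_chr(assisted, function(s, nm) {
                if (nzchar(nm)) nm else s$case %||% "assisted"
              }))
  hashes <- vapply(sols, function(s) task_hash(s$problem$task), character(1))
  if (length(unique(hashes)) != 1) {
    stop_liftopt("cases were solved for different subjects or tasks",
                 "liftopt_validation_error")
  }
  names(sols) <- make.unique(labels)
  tab <- peak_torque_report(sols)
  energies <- tibble::tibble(
    case = names(sols),
    energy = vapply(sols, `[[`, numeric(1), "energy")
  )
  dplyr::left_join(tab, energies, by = "case")
}

task_hash <- function(task) {
  paste(signif(c(task$box_mass, task$hand_initial, task$hand_final,
                 task$duration, task$feet_position), 10), collapse = "|")
}
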