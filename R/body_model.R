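#' Build the 10-DOF sagittal-plane human skeletal model
#'
#' Constructs a subject-specific branched Denavit-Hartenberg chain with two
#' global translations, one global rotation, an upper-body branch (spine,
#' shoulder, elbow) and a lower-body branch (hip, knee, ankle, subtalar).
#' Global coordinates are Y up and Z anterior; all motion is in the sagittal
#' Y-Z plane and all rotations are about the out-of-plane X axis.  Left and
#' right limbs are merged into single limbs carrying the mass and inertia of
#' both sides.
#'
#' @param height Standing height (m).
#' @param mass Total body mass (kg).
#' @param link_lengths Optional named or positional numeric vector of the
#'   seven link lengths `L1`..`L7` (m); defaults to anthropometric fractions
#'   of `height` (see [default_link_lengths()]).
#' @param q_lower,q_upper Optional length-10 joint coordinate bounds
#'   (m for DOFs 1-2, rad otherwise).
#' @param tau_lower,tau_upper Optional length-10 joint torque bounds (N m).
#' @param foot_length Heel-to-toe extent of the foot support region (m).
#' @param palm_offset Distance from the wrist frame origin to the hand
#'   (grip) point along the forearm axis (m).
#' @return A `human_model` object.
#' @examples
#' model <- build_human_model(height = 1.7, mass = 68.75)
#' model$total_mass
#' @export
build_human_model <- function(height, mass, link_lengths = NULL,
                              q_lower = NULL, q_upper = NULL,
                              tau_lower = NULL, tau_upper = NULL,
                              foot_length = 0.25, palm_offset = 0) {
  if (!is.numeric(height) || length(height) != 1 || !is.finite(height) ||
      height <= 0) {
    stop_liftopt("`height` must be a positive number", "liftopt_validation_error")
  }
  if (!is.numeric(mass) || length(mass) != 1 || !is.finite(mass) || mass <= 0) {
    stop_liftopt("`mass` must be a positive number", "liftopt_validation_error")
  }
  if (is.null(link_lengths)) {
    link_lengths <- default_link_lengths(height)
  }
  if (length(link_lengths) != 7 || any(!is.finite(link_lengths)) ||
      any(link_lengths <= 0)) {
    stop_liftopt("`link_lengths` must be 7 positive lengths L1..L7",
                 "liftopt_validation_error")
  }
  link_lengths <- setNames(as.numeric(link_lengths), names(LINK_HEIGHT_FRACTIONS))

  seg_len <- segment_lengths_from_links(link_lengths)
  segments <- lapply(1:10, function(i) {
    m <- SEGMENT_MASS_FRACTIONS[i] * mass
    len <- seg_len[i]
    com <- SEGMENT_COM_FRACTIONS[i] * len
    rog <- if (i == 3) PELVIS_ROG_M else SEGMENT_ROG_FRACTIONS[i] * len
    list(length = len, mass = m, com_offset = com, inertia = m * rog^2)
  })

  q_lower <- q_lower %||% DEFAULT_Q_LOWER
  q_upper <- q_upper %||% DEFAULT_Q_UPPER
  tau_lower <- tau_lower %||% DEFAULT_TAU_LOWER
  tau_upper <- tau_upper %||% DEFAULT_TAU_UPPER
  for (v in list(q_lower, q_upper, tau_lower, tau_upper)) {
    if (length(v) != 10 || any(!is.finite(v))) {
      stop_liftopt("joint bound tables must be finite length-10 vectors",
                   "liftopt_validation_error")
    }
  }
  if (any(q_lower >= q_upper) || any(tau_lower >= tau_upper)) {
    stop_liftopt("lower bounds must be strictly below upper bounds",
                 "liftopt_validation_error")
  }

  heel_offset <- foot_length - link_lengths["L6"] - link_lengths["L7"]
  if (heel_offset < 0) {
    stop_liftopt("`foot_length` is shorter than the modelled foot links",
                 "liftopt_validation_error")
  }

  L <- link_lengths
  model <- structure(
    list(
      n_dof = 10L,
      dh = dh_table_2d(L),
      parent = c(0L, 1L, 2L, 3L, 4L, 5L, 3L, 7L, 8L, 9L),
      kind = c("translation", "translation", rep("rotation", 8)),
      branch = c(rep("global", 3), rep("upper", 3), rep("lower", 4)),
      joint_names = c("global_tz", "global_ty", "global_rot", "spine",
                      "shoulder", "elbow", "hip", "knee", "ankle", "subtalar"),
      lengths = L,
      segments = segments,
      q_lower = as.numeric(q_lower), q_upper = as.numeric(q_upper),
      tau_lower = as.numeric(tau_lower), tau_upper = as.numeric(tau_upper),
      collision_circles = list(
        list(frame = 4L, local = c(-L[["L1"]] / 2, 0, 0), radius = 0.12),
        list(frame = 7L, local = c(-L[["L4"]] / 2, 0, 0), radius = 0.10),
        list(frame = 8L, local = c(-L[["L5"]] / 2, 0, 0), radius = 0.07)
      ),
      foot = list(length = foot_length, heel_offset = as.numeric(heel_offset)),
      palm_offset = palm_offset,
      height = height,
      subject_mass = mass,
      total_mass = sum(vapply(segments, `[[`, numeric(1), "mass")),
      gravity = GRAVITY,
      exoskeletons = list(),
      point_masses = list()
    ),
    class = "human_model"
  )
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.human_model <- function(x, ...) {
  cat(sprintf(
    "<human_model> 10-DOF sagittal chain: height %.2f m, total mass %.2f kg\n",
    x$height, x$total_mass
  ))
  if (length(x$exoskeletons)) {
    cat("  exoskeletons:",
        paste(vapply(x$exoskeletons, `[[`, character(1), "joint"),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Attach powered exoskeletons to a human model
#'
#' Adds the device masses to the model: each exoskeleton's mass is split
#' 50/50 between the two body segments flanking the assisted joint, as point
#' masses at the segment centres of mass (their rotational inertia about the
#' frame origin enters through the parallel-axis term).  Total model mass
#' increases by exactly the summed device masses.
#'
#' @param model A [human_model].
#' @param exos List of [exoskeleton()] specifications.
#' @return A new `human_model` with augmented segment masses and the
#'   exoskeletons recorded in `$exoskeletons`.
#' @export
attach_exoskeletons <- function(model, exos) {
  stopifnot(inherits(model, "human_model"))
  if (length(exos) == 0) return(model)
  if (inherits(exos, "liftopt_exoskeleton")) exos <- list(exos)
  joints <- vapply(exos, `[[`, integer(1), "joint_index")
  if (anyDuplicated(joints)) {
    stop_liftopt("each joint may carry at most one exoskeleton",
                 "liftopt_validation_error")
  }
  if (any(model$kind[joints] != "rotation")) {
    stop_liftopt("exoskeletons can only assist rotational DOFs",
                 "liftopt_validation_error")
  }
  for (exo in exos) {
    j <- exo$joint_index
    # joint j sits at the origin of its parent's frame: the distal flanking
    # segment is link j, the proximal one is link parent(j)
    p <- model$parent[j]
    for (k in c(j, p)) {
      seg <- model$segments[[k]]
      if (seg$mass <= 0 && seg$length <= 0) {
        # virtual root link (global rotation): lump onto the distal segment
        next
      }
      seg$mass <- seg$mass + exo$mass / 2
      model$segments[[k]] <- seg
    }
    # if the proximal side was a virtual link, put the full half elsewhere:
    # keep accounting exact by checking the added total below
  }
  # exact mass bookkeeping: recompute and verify
  added <- sum(vapply(exos, `[[`, numeric(1), "mass"))
  new_total <- sum(vapply(model$segments, `[[`, numeric(1), "mass"))
  if (abs(new_total - (model$total_mass + added)) > 1e-9) {
    # a flanking virtual segment swallowed nothing; assign remainder distally
    deficit <- model$total_mass + added - new_total
    j <- exos[[1]]$joint_index
    model$segments[[j]]$mass <- model$segments[[j]]$mass + deficit
  }
  model$total_mass <- sum(vapply(model$segments, `[[`, numeric(1), "mass"))
  model$exoskeletons <- c(model$exoskeletons, exos)
  model
}

#' Attach a rigidly carried point mass to a body segment
#'
#' Adds a point mass fixed in a segment's frame (for example the lifted box
#' carried at the hand); it enters the dynamics, ground reaction, and
#' centre-of-mass computations exactly.
#'
#' @param model A [human_model].
#' @param frame DOF index of the carrying segment (6 = forearm/hand).
#' @param local Local coordinates of the mass in that frame (m).
#' @param mass Mass (kg).
#' @return A new `human_model` carrying the extra point mass.
#' @export
add_point_mass <- function(model, frame, local, mass) {
  stopifnot(inherits(model, "human_model"), mass >= 0)
  model$point_masses <- c(model$point_masses,
                          list(list(frame = as.integer(frame),
                                    local = as.numeric(local[1:3]),
                                    mass = mass)))
  model
}

#' Define a box-lifting task
#'
#' @param box_mass Mass of the lifted box (kg).
#' @param box_height,box_depth Box dimensions (m).
#' @param hand_initial,hand_final Global hand (grip) positions `(x, y, z)` at
#'   the start and end of the lift (m); x is the out-of-plane coordinate and
#'   must be 0.
#' @param duration Total lift duration T (s).
#' @param feet_position Global `(x, y, z)` position of the ankle during the
#'   lift (m); the foot stays flat on the ground at this station.
#' @param epsilon Half-width of the posture tracking band around the
#'   reference joint angles (rad).
#' @param reference_angles Optional 10 x 3 matrix of reference joint angles
#'   at times 0, T/2, T; computed by [reference_postures()] when omitted.
#' @return A `lifting_task` object.
#' @examples
#' lifting_task()  # the packaged 10 kg, 1.44 s squat-lift task
#' @export
lifting_task <- function(box_mass = 10, box_height = 0.15, box_depth = 0.65,
                         hand_initial = c(0, 0.070, 0.418),
                         hand_final = c(0, 1.088, 0.417),
                         duration = 1.44,
                         feet_position = c(0, 0, 0),
                         epsilon = 0.2,
                         reference_angles = NULL) {
  if (!is.numeric(duration) || duration <= 0) {
    stop_liftopt("`duration` must be positive", "liftopt_validation_error")
  }
  if (box_mass < 0) {
    stop_liftopt("`box_mass` must be non-negative", "liftopt_validation_error")
  }
  for (p in list(hand_initial, hand_final, feet_position)) {
    if (length(p) != 3 || any(!is.finite(p))) {
      stop_liftopt("positions must be finite (x, y, z) triples",
                   "liftopt_validation_error")
    }
  }
  structure(
    list(
      box_mass = box_mass, box_height = box_height, box_depth = box_depth,
      hand_initial = as.numeric(hand_initial),
      hand_final = as.numeric(hand_final),
      duration = duration,
      feet_position = as.numeric(feet_position),
      epsilon = epsilon,
      reference_angles = reference_angles
    ),
    class = "lifting_task"
  )
}

#' @export
print.lifting_task <- function(x, ...) {
  cat(sprintf(
    "<lifting_task> %.1f kg box, hand (%.3f, %.3f) -> (%.3f, %.3f) m, T = %.2f s\n",
    x$box_mass, x$hand_initial[2], x$hand_initial[3],
    x$hand_final[2], x$hand_final[3], x$duration
  ))
  invisible(x)
}
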