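#' Global position of a named body landmark
#'
#' @param model A [human_model].
#' @param q Generalized coordinates (length 10).
#' @param name One of `"hand"`, `"wrist"`, `"pelvis"`, `"shoulder"`,
#'   `"elbow"`, `"hip"`, `"knee"`, `"ankle"`, `"ball"`, `"toe"`, `"heel"`,
#'   or `"com"` (whole-body centre of mass).
#' @param fk Optional precomputed [forward_kinematics()] result.
#' @return Global `(x, y, z)` coordinates (m); x is always 0 for this planar
#'   model.
#' @export
landmark <- function(model, q, name, fk = NULL) {
  A <- fk %||% forward_kinematics(model, q)
  origin <- function(i) as.numeric(A[[i]][1:3, 4])
  point <- function(i, local) as.numeric(A[[i]] %*% c(local, 1))[1:3]
  switch(
    name,
    wrist = origin(6L),
    hand = point(6L, c(model$palm_offset, 0, 0)),
    pelvis = origin(3L),
    shoulder = origin(4L),
    elbow = origin(5L),
    hip = origin(3L),
    knee = origin(7L),
    ankle = origin(8L),
    ball = origin(9L),
    toe = origin(10L),
    heel = {
      ankle <- origin(8L)
      ball <- origin(9L)
      dir <- (ball - ankle) / max(sqrt(sum((ball - ankle)^2)), 1e-12)
      ankle - model$foot$heel_offset * dir
    },
    com = body_com(model, q, A),
    stop_liftopt(sprintf("unknown landmark '%s'", name),
                 "liftopt_validation_error")
  )
}

# whole-body centre of mass, including attached point masses
body_com <- function(model, q, fk = NULL) {
  A <- fk %||% forward_kinematics(model, q)
  total <- 0
  acc <- c(0, 0, 0)
  for (i in seq_len(model$n_dof)) {
    seg <- model$segments[[i]]
    if (seg$mass <= 0) next
    local <- c(seg$com_offset - seg$length, 0, 0, 1)
    p <- as.numeric(A[[i]] %*% local)[1:3]
    acc <- acc + seg$mass * p
    total <- total + seg$mass
  }
  for (pm in model$point_masses) {
    if (pm$mass <= 0) next
    p <- as.numeric(A[[pm$frame]] %*% c(pm$local, 1))[1:3]
    acc <- acc + pm$mass * p
    total <- total + pm$mass
  }
  acc / total
}

# foot support region [heel, toe] along global Z, for a foot flat on the
# ground at the task's feet station
foot_support_region <- function(model, task) {
  z_ankle <- task$feet_position[3]
  c(z_ankle - model$foot$heel_offset,
    z_ankle - model$foot$heel_offset + model$foot$length)
}
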