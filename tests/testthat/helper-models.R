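# Small planar serial-chain models built on the same DH machinery as the
# full skeleton; used for closed-form and oracle checks.  The chain rotates
# about the base z axis with gravity along -y, so a link at angle q from
# the +x axis has its tip at (L cos q, L sin q).

make_chain_model <- function(lengths, masses,
                             com_fracs = rep(0.5, length(lengths)),
                             rog_fracs = rep(0.3, length(lengths)),
                             theta_offsets = rep(0, length(lengths)),
                             gravity = 9.81) {
  n <- length(lengths)
  dh <- lapply(seq_len(n), function(i) {
    liftopt:::dh_row(theta_offsets[i], 0, lengths[i], 0, "rotation",
                     i - 1L, "upper", paste0("link", i))
  })
  segments <- lapply(seq_len(n), function(i) {
    list(length = lengths[i], mass = masses[i],
         com_offset = com_fracs[i] * lengths[i],
         inertia = masses[i] * (rog_fracs[i] * lengths[i])^2)
  })
  structure(
    list(
      n_dof = as.integer(n), dh = dh, parent = seq_len(n) - 1L,
      kind = rep("rotation", n), branch = rep("upper", n),
      joint_names = paste0("link", seq_len(n)),
      segments = segments,
      q_lower = rep(-pi, n), q_upper = rep(pi, n),
      tau_lower = rep(-1e3, n), tau_upper = rep(1e3, n),
      collision_circles = list(),
      foot = list(length = 0.25, heel_offset = 0.05),
      palm_offset = 0,
      height = sum(lengths), subject_mass = sum(masses),
      total_mass = sum(masses), gravity = gravity,
      exoskeletons = list(), point_masses = list()
    ),
    class = "human_model"
  )
}

random_chain_state <- function(n) {
  kinematic_state(runif(n, -pi / 2, pi / 2), runif(n, -2, 2), runif(n, -5, 5))
}

default_subject <- function() build_human_model(1.7, 68.75)
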