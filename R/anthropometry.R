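#' Anthropometric defaults
#'
#' Segment lengths, masses, centre-of-mass locations, and radii of gyration
#' are derived from total body height and mass using standard anthropometric
#' proportion tables (Drillis-Contini style length ratios; de Leva style mass
#' and inertia ratios).  Left and right limbs are merged into single limbs,
#' so arm and leg segments carry the mass and inertia of both sides.  The
#' trunk link carries the head and neck; the residual pelvis mass sits at the
#' model root.  All values can be overridden when building a model.
#'
#' @name anthropometry
#' @keywords internal
NULL

# link-length fractions of standing height for links L1..L7:
# L1 pelvis-shoulder (trunk), L2 upper arm, L3 forearm (to wrist),
# L4 thigh, L5 shank, L6 ankle-to-ball of foot, L7 ball-to-toe
LINK_HEIGHT_FRACTIONS <- c(
  L1 = 0.288, L2 = 0.186, L3 = 0.146,
  L4 = 0.245, L5 = 0.246, L6 = 0.080, L7 = 0.040
)

# per-DOF segment constants: fraction of body mass, CoM position as a
# fraction of segment length from the proximal end, and radius of gyration
# about the CoM as a fraction of segment length.  DOFs 1-2 are the massless
# global translations; DOF 3 is the pelvis residual at the model root.
SEGMENT_MASS_FRACTIONS <- c(0, 0, 0.1117, 0.3923, 0.0542, 0.0446,
                            0.2832, 0.0866, 0.0200, 0.0074)
SEGMENT_COM_FRACTIONS  <- c(0, 0, 0.000, 0.550, 0.577, 0.460,
                            0.410, 0.440, 0.500, 0.400)
SEGMENT_ROG_FRACTIONS  <- c(0, 0, 0.000, 0.350, 0.280, 0.300,
                            0.330, 0.300, 0.400, 0.400)
# pelvis modelled as a compact mass at the root with a fixed 0.10 m radius
# of gyration (its link length is zero, so a relative value is meaningless)
PELVIS_ROG_M <- 0.10

# default joint coordinate bounds, in the DH coordinates of the model.
# DOFs: 1 anterior translation (m), 2 vertical translation about standing
# hip height (m), 3 global pelvis rotation, 4 spine, 5 shoulder, 6 elbow,
# 7 hip, 8 knee, 9 ankle, 10 subtalar (all rad).  Ranges are generic
# ergonomic bounds wide enough to contain deep-squat lifting; they are
# deliberately one-sided where anatomy is (knee cannot hyperextend).
DEFAULT_Q_LOWER <- c(-0.5, -0.6, -0.5, -0.3, -2.2, -2.6, -2.3, -0.05, -1.3, -0.6)
DEFAULT_Q_UPPER <- c( 0.5,  0.25, 1.0,  1.5,  0.6,  0.05,  0.3,  2.6,  0.3,  0.6)

# default joint torque bounds (N m), merged-limb strengths typical of a
# healthy adult male; the two translations and the global rotation are
# virtual DOFs whose generalized forces are realized by the ground, so they
# get wide normalization constants and no strength constraint.
DEFAULT_TAU_LOWER <- c(-1e4, -1e4, -500, -300, -150, -100, -300, -250, -200, -50)
DEFAULT_TAU_UPPER <- -DEFAULT_TAU_LOWER

# DOFs treated as actuated anatomical joints (strength-limited)
ANATOMICAL_DOFS <- 4:10
# DOFs entering the effort objective (all rotational DOFs)
OBJECTIVE_DOFS <- 3:10

#' Link lengths from standing height
#'
#' @param height Standing height (m).
#' @return Named numeric vector `L1`..`L7` (m).
#' @export
default_link_lengths <- function(height) {
  if (!is.numeric(height) || length(height) != 1 || !is.finite(height) ||
      height <= 0) {
    stop_liftopt("`height` must be a positive number", "liftopt_validation_error")
  }
  LINK_HEIGHT_FRACTIONS * height
}

# Table-1 style DH rows for the 10-DOF planar model, given link lengths
dh_table_2d <- function(L) {
  L <- unname(L)
  list(
    dh_row(pi,      0,           0,    pi / 2,  "translation", 0L, "global", "global_tz"),
    dh_row(pi / 2,  L[4] + L[5], 0,   -pi / 2,  "translation", 1L, "global", "global_ty"),
    dh_row(0,       0,           0,    0,       "rotation",    2L, "global", "global_rot"),
    dh_row(-pi / 2, 0,           L[1], 0,       "rotation",    3L, "upper",  "spine"),
    dh_row(pi,      0,           L[2], 0,       "rotation",    4L, "upper",  "shoulder"),
    dh_row(0,       0,           L[3], 0,       "rotation",    5L, "upper",  "elbow"),
    dh_row(pi / 2,  0,           L[4], 0,       "rotation",    3L, "lower",  "hip"),
    dh_row(0,       0,           L[5], 0,       "rotation",    7L, "lower",  "knee"),
    dh_row(-pi / 2, 0,           L[6], 0,       "rotation",    8L, "lower",  "ankle"),
    dh_row(0,       0,           L[7], 0,       "rotation",    9L, "lower",  "subtalar")
  )
}

# lengths of the body segment associated with each DOF (0 for virtual DOFs)
segment_lengths_from_links <- function(L) {
  c(0, 0, 0, L[1], L[2], L[3], L[4], L[5], L[6], L[7])
}
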