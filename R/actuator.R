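#' DC motor and gearbox model
#'
#' Each exoskeleton is a 1-DOF device: a DC motor behind a rigid,
#' backlash-free gearbox whose output shaft is bound to one human joint, so
#' the rotor angle is the gearbox ratio times the joint angle.  The
#' electromechanics are
#' \deqn{L \dot I = V - K\dot\theta - RI, \quad T_{motor} = K I, \quad
#'       T_l = T_{motor} - J_m\ddot\theta - b\dot\theta, \quad
#'       \tau_e = GB_r\, T_l}
#' with \eqn{\theta} the rotor angle.  Motor current is the control input;
#' the supply voltage required to realize a current profile is a diagnostic
#' output, not a constraint.
#'
#' @param resistance Winding resistance R (Ohm).
#' @param inductance Winding inductance L (H).
#' @param torque_constant Torque constant K (N m/A; numerically equal to the
#'   back-EMF constant in V s/rad).
#' @param rotor_inertia Rotor moment of inertia Jm (kg m^2).
#' @param viscous_friction Viscous friction coefficient b (N m s/rad).
#' @param gear_ratio Gearbox ratio GBr (>= 1, dimensionless).
#' @param current_limit Symmetric current bound (A).
#' @return A `motor_spec` object.
#' @export
motor_spec <- function(resistance = 0.2, inductance = 3e-4,
                       torque_constant = 0.05, rotor_inertia = 1e-5,
                       viscous_friction = 1e-4, gear_ratio = 50,
                       current_limit = 10) {
  vals <- c(resistance, inductance, torque_constant, rotor_inertia,
            viscous_friction, gear_ratio, current_limit)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_liftopt("all motor constants must be positive", "liftopt_validation_error")
  }
  if (gear_ratio < 1) {
    stop_liftopt("`gear_ratio` must be at least 1", "liftopt_validation_error")
  }
  structure(
    list(resistance = resistance, inductance = inductance,
         torque_constant = torque_constant, rotor_inertia = rotor_inertia,
         viscous_friction = viscous_friction, gear_ratio = gear_ratio,
         current_limit = current_limit),
    class = "motor_spec"
  )
}

#' Motor output torque from current
#' @param spec A [motor_spec()].
#' @param current Motor current I (A).
#' @return Motor torque K I (N m).
#' @export
motor_torque <- function(spec, current) {
  spec$torque_constant * current
}

#' Load torque at the motor shaft
#'
#' @inheritParams motor_torque
#' @param rotor_rate,rotor_accel Rotor kinematics (rad/s, rad/s^2); with a
#'   rigid transmission these are the joint rate and acceleration times the
#'   gear ratio.
#' @return Load torque (N m) after rotor inertia and friction.
#' @export
load_torque <- function(spec, current, rotor_rate = 0, rotor_accel = 0) {
  motor_torque(spec, current) - spec$rotor_inertia * rotor_accel -
    spec$viscous_friction * rotor_rate
}

#' Exoskeleton output torque
#'
#' @inheritParams motor_torque
#' @param joint_rate,joint_accel Assisted joint kinematics (rad/s, rad/s^2).
#' @return Device torque at the joint, `GBr * Tl` (N m).  No saturation is
#'   applied here; torque limits are optimization constraints.
#' @export
exo_torque <- function(spec, current, joint_rate = 0, joint_accel = 0) {
  gb <- spec$gear_ratio
  gb * load_torque(spec, current, rotor_rate = gb * joint_rate,
                   rotor_accel = gb * joint_accel)
}

#' Supply voltage required by a current profile
#'
#' @inheritParams motor_torque
#' @param dI_dt Current slew rate (A/s).
#' @param rotor_rate Rotor rate (rad/s).
#' @return Required terminal voltage (V).
#' @export
required_voltage <- function(spec, current, dI_dt = 0, rotor_rate = 0) {
  spec$inductance * dI_dt + spec$torque_constant * rotor_rate +
    spec$resistance * current
}

#' Sensitivity of device torque to current-spline control points
#'
#' The device torque is affine in the current at fixed kinematics, so the
#' sensitivity to the current control points is `GBr * K` times the spline
#' basis row, independent of the current itself.
#'
#' @inheritParams motor_torque
#' @param basis_row Spline basis row vector(s) at the evaluation time(s)
#'   (see [basis_sensitivity()]).
#' @return Matrix (or vector) of partials of torque with respect to the
#'   current control points.
#' @export
torque_current_sensitivity <- function(spec, basis_row) {
  spec$gear_ratio * spec$torque_constant * basis_row
}

# packaged device defaults: masses and symmetric torque limits of the three
# assistive exoskeletons, with gear ratios sized so GBr*K*Imax exceeds the
# device torque limit
EXO_DEFAULTS <- list(
  knee = list(joint = "knee", mass = 2.25, tau_limit = 16, gear_ratio = 50),
  spine = list(joint = "spine", mass = 3.40, tau_limit = 36, gear_ratio = 80),
  shoulder = list(joint = "shoulder", mass = 1.20, tau_limit = 12, gear_ratio = 30)
)

#' Define a powered exoskeleton
#'
#' @param joint Assisted joint: `"knee"`, `"spine"`, or `"shoulder"` (or the
#'   index of any rotational DOF).
#' @param mass Device mass (kg).
#' @param tau_limit Symmetric output torque limit (N m).
#' @param motor A [motor_spec()]; a sensible default is chosen per joint.
#' @return A `liftopt_exoskeleton` object.
#' @examples
#' exoskeleton("knee")
#' @export
exoskeleton <- function(joint, mass = NULL, tau_limit = NULL, motor = NULL) {
  defaults <- EXO_DEFAULTS[[as.character(joint)]]
  mass <- mass %||% defaults$mass
  tau_limit <- tau_limit %||% defaults$tau_limit
  if (is.null(mass) || is.null(tau_limit)) {
    stop_liftopt("`mass` and `tau_limit` are required for a custom joint",
                 "liftopt_validation_error")
  }
  motor <- motor %||% motor_spec(gear_ratio = defaults$gear_ratio %||% 50)
  joint_index <- resolve_exo_joint(joint)
  if (motor$gear_ratio * motor$torque_constant * motor$current_limit <
      tau_limit) {
    stop_liftopt("motor cannot reach the device torque limit: increase the gear ratio or current limit",
                 "liftopt_validation_error")
  }
  structure(
    list(joint = if (is.character(joint)) joint else paste0("dof", joint),
         joint_index = joint_index, mass = mass,
         tau_lower = -tau_limit, tau_upper = tau_limit, motor = motor),
    class = "liftopt_exoskeleton"
  )
}

resolve_exo_joint <- function(joint) {
  names10 <- c("global_tz", "global_ty", "global_rot", "spine", "shoulder",
               "elbow", "hip", "knee", "ankle", "subtalar")
  idx <- if (is.character(joint)) match(joint, names10) else as.integer(joint)
  if (is.na(idx) || idx < 3 || idx > 10) {
    stop_liftopt(sprintf("unknown or non-rotational exoskeleton joint '%s'", joint),
                 "liftopt_validation_error")
  }
  idx
}

#' @export
print.liftopt_exoskeleton <- function(x, ...) {
  cat(sprintf(
    "<exoskeleton> %s: %.2f kg, torque limit +/- %.0f N m, gear ratio %.0f\n",
    x$joint, x$mass, x$tau_upper, x$motor$gear_ratio
  ))
  invisible(x)
}
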