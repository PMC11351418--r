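---
title: "Predictive simulation of exoskeleton-assisted lifting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive simulation of exoskeleton-assisted lifting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftopt)
```

## The problem

liftopt predicts how a person lifts a box from near the floor to shelf
height, and how much of the required joint torque a set of powered
exoskeletons (knee, spine, shoulder) can take over.  Nothing is tracked or
replayed: the motion itself is the unknown.  Joint-angle trajectories and
device motor currents are decision variables of a constrained optimization
that minimizes the human's normalized joint effort subject to physics
(inverse dynamics, ground reaction, balance) and the task (box start and
end positions, rest at both ends, posture plausibility).

## Skeletal model

The body is a planar 10-DOF branched chain in standard distal
Denavit-Hartenberg convention: two global translations and one global
rotation locate and orient the pelvis in the sagittal plane (Y up,
Z anterior, rotations about the out-of-plane X axis), an upper branch
carries spine, shoulder, and elbow rotations, and a lower branch carries
hip, knee, ankle, and a toe (subtalar) rotation.  Left and right limbs are
merged: each arm/leg segment carries the mass and inertia of both sides.

Segment lengths default to Drillis-Contini-style fractions of standing
height (`default_link_lengths()`), and segment masses, centre-of-mass
positions, and radii of gyration to de Leva-style fractions of body mass
and segment length.  The trunk link includes the head and neck; the
residual pelvis mass sits at the model root.  All of these are defaults a
subject-specific model can override; when only height and mass are known
the defaults apply, and absolute torque levels then characterize the
default subject rather than any measured individual.
Joint angle and torque limits are likewise shipped as documented
ergonomic defaults (see `R/anthropometry.R`): strength bounds of
±300 N·m (spine, hip), ±250 (knee), ±200 (ankle), ±150 (shoulder),
±100 (elbow), ±50 (toe) for merged limbs.  The torque bounds both constrain
the motion and normalize the objective.

## Dynamics

Joint torques come from the 4x4 recursive Lagrangian formulation: for DOF
$i$ with global frame $A_i$,

$$\tau_i = \mathrm{tr}\!\left(\frac{\partial A_i}{\partial q_i} D_i\right)
  - g^T \frac{\partial A_i}{\partial q_i} E_i
  - f_k^T \frac{\partial A_i}{\partial q_i} F_i
  - G_i^T A_{i-1} z_0,$$

where $D_i, E_i, F_i, G_i$ accumulate, distal to proximal, the
inertia/Coriolis matrices $J_k \ddot A_k^T$ ($J_k$ the 4x4 pseudo-inertia),
the gravity first moments, the external-force application points, and the
external moments of the subtree below $i$; the two body branches sum at the
global rotation.  The implementation propagates $A$, $\dot A$, $\ddot A$
and their exact partials with respect to joint positions, rates, and
accelerations along the chain, so all torque and ground-reaction
sensitivities used by the optimizer are analytic (verified against finite
differences to ~1e-7, and the torques themselves against an independent
finite-difference Euler-Lagrange oracle to better than 1e-6 relative).

**Ground reaction and balance.**  Whole-body Newton-Euler sums give the
vertical and horizontal ground reactions and the zero-moment point (ZMP),
the ground station where the horizontal component of the ground moment
vanishes.  In statics the vertical reaction is exactly total weight and the
ZMP is the centre-of-mass projection.  Dynamic balance requires the ZMP to
stay inside the foot support region (FSR), the heel-to-toe interval
(default 0.25 m).

**Load-bearing torques.**  A floating-base chain attributes to each leg
joint only the load of the segments distal to it — the virtual pelvis DOFs
absorb the support force, and a loaded deep squat would show a knee torque
of ~10 N·m.  Physically meaningful joint loads are obtained by applying the
computed ground wrench as an external force at the planted foot (force at
the ankle ground point plus the moment transported from the ZMP;
`grounded_torques()`).  The virtual global DOFs then carry exactly zero
generalized force, and the static squat knee torque matches an independent
free-body computation (about −107 N·m with the default subject and a 10 kg
box).  The optimization and all reports use this definition.

**The box** is modelled as a point mass rigidly carried at the hand from
start to end, entering the recursion exactly (gravity and inertial
effects); a quasi-static weight-only option exists
(`box_dynamics = "quasi_static"`).

## Exoskeleton model

Each device is a DC motor behind a rigid gearbox bound to one joint
(rotor angle = gear ratio x joint angle):

$$L\dot I = V - K\dot\theta - RI,\qquad T_{motor} = KI,\qquad
T_l = T_{motor} - J_m\ddot\theta - b\dot\theta,\qquad \tau_e = GB_r\,T_l.$$

Motor current is the control input; torque is affine in it, so sensitivities
to current control points are the gear ratio times the torque constant
times the spline basis row.  Supply voltage is a diagnostic, not a
constraint.  Device masses (2.25 / 3.4 / 1.2 kg for knee / spine /
shoulder) and torque limits (±16 / ±36 / ±12 N·m) are the packaged device
defaults; the device mass is split 50/50 onto the two segments flanking
the assisted joint.  Motor constants default to values typical of
a brushless exoskeleton actuator (R = 0.2 Ω, L = 0.3 mH, K = 0.05 N·m/A,
J~m~ = 1e-5 kg·m², b = 1e-4 N·m·s/rad) with gear ratios (50/80/30) sized so
each device can reach its torque limit within its ±10 A current bound —
documented, overridable defaults.

## Trajectory parameterization

Every joint angle and every motor current is a clamped cubic B-spline on
$[0, T]$ with `n_ctrl = 5` control points (uniform interior knots).  The
design vector stacks all control points: 50 variables without devices,
55/60/65 with the knee, spine+shoulder, and all-three combinations.
Evaluation and differentiation are linear in the control points, and the
convex-hull property lets joint-angle limits be imposed as plain bounds on
the control points.

## The optimization

Minimize $J(x) = \sum_{i=3}^{10} \int_0^T
\left(\tau_{h,i}(x)/(\tau_i^U - \tau_i^L)\right)^2 dt$ (trapezoid rule on a
25-point uniform grid) subject to, per grid point: human torque limits at
the anatomical joints, hand anterior of the pelvis, hand clear of body
thickness circles (torso 0.12 m, thigh 0.10 m, shank 0.07 m), ZMP in the
FSR (in moment form, avoiding division by the vertical force), vertical
reaction at least 10 N, and device torque limits; at the end points: hand
exactly at the box start/end positions and all joint rates zero; at
$t \in \{0, T/2, T\}$: six anatomical joints within ±0.2 rad of reference
postures.  With the ground wrench routed through the foot the $i = 3$
objective term is identically zero; it is kept for completeness.

**Feet contact.**  The contact manifold (ankle pinned, foot flat) is not
polynomial in time, so a 5-control-point spline cannot satisfy pointwise
contact equalities at arbitrarily many instants — the equality system is
generically inconsistent, which we verified numerically.  Contact is
therefore exact (equality) at the two static end points and enforced within
a ±2 mm tolerance band at every interior grid point.  The band is a
numerical contact tolerance, not a physical foot lift; tightening it
requires more control points.

**Reference postures.**  The tracking band needs reference angles at start,
middle, and end.  Motion-captured angles are not available, so
`reference_postures()` constructs them in closed form — planar two-link
inverse kinematics for the legs (knee-anterior branch) and the arm
(elbow-posterior branch), a torso-lean rule that leans just far enough to
reach the hand target, pelvis stations typical of a deep squat / upright
stance — followed by a damped Gauss-Newton polish that closes the
constraints to machine accuracy.  The construction is deterministic and
seedless.  These synthetic postures are statically balanced (CoM over the
foot) with the box in hand.

**Solver.**  The nonlinear program is solved by a dense $\ell_1$-penalty
SQP (Fletcher's S$\ell_1$QP): each iteration solves a convex QP in the step
with per-row elastic slacks on the equalities and on currently violated
inequalities (always feasible, always full rank), a Gauss-Newton Hessian
assembled from the least-squares structure of the objective, a
backtracking line search on the matching exact-penalty merit with a
second-order correction step, and a QP-based feasibility restoration used
both to produce a feasible starting point and to polish the final iterate.
The QP backend is `pracma::quadprog`.  The default start is the zero design
vector; if it fails to reach feasibility the solver restarts from the
spline interpolation of the reference postures (a local gradient method
benefits from multiple starts), and the best feasible result is returned.
Feasibility tolerance is 1e-8; solutions typically reach ~1e-13.

## What the defaults do and do not show

The packaged task (10 kg box, hands from (0, 0.070, 0.418) to
(0, 1.088, 0.417) m, T = 1.44 s, 1.70 m / 68.75 kg subject) solves to
machine feasibility for all four device combinations.  Assistance
reductions at the assisted joints are robust qualitative outcomes;
absolute peak torques and mechanical energies depend on the segment,
strength, and motor tables above, so they characterize this model's
default subject, not any particular experimental subject.  Mechanical
energy is reported as $\int_0^T \sum_i |\tau_{h,i}\dot q_i|\,dt$ over the
anatomical joints (a positive-work-only variant is available); no energy
formula is standard, so the definition is isolated in
`mechanical_energy()`.

Problem sizes are deliberately modest: 25 collocation points and 5 control
points per profile solve in roughly one to three minutes per case on a
single core.  Grid-refinement checks (10x denser quadrature changing the
objective by <1%) guard the discretization.

## Controller maps

For real-time control the optimal device torque is re-expressed in the
encoder-angle domain: `fit_control_map()` least-squares fits a clamped
cubic B-spline of torque against joint angle and clamps its control points
to the device limit, which bounds the whole map by the convex-hull
property.  Where descent and ascent visit the same angle with different
torques, the single-valued fit averages the hysteresis; out-of-domain
lookups hold the boundary value (configurable to zero).

## Known limitations

- 2D symmetric lifting only; no asymmetric or 3D motion.
- Contact is bilateral within tolerance: no foot rollover, slip, or flight.
- Single-valued controller maps average ascent/descent hysteresis.
- The SQP finds local optima; multi-start mitigates but does not remove
  this.
- Default anthropometry, strength, and motor tables are population-level
  stand-ins; subject-specific studies should override them.
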