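# Packaged box-lifting study configuration.
# Units: metres, kilograms, seconds, newton-metres, amperes, ohms, henries.
subject:
  height: 1.70        # standing height (m)
  mass: 68.75         # total body mass (kg)
  foot_length: 0.25   # heel-to-toe support length (m)
  palm_offset: 0.0    # wrist-to-grip offset along the forearm (m)

exoskeletons:
  - joint: knee
    mass: 2.25          # device mass (kg)
    torque_limit: 16    # symmetric output torque bound (N m)
    gear_ratio: 50
  - joint: spine
    mass: 3.40
    torque_limit: 36
    gear_ratio: 80
  - joint: shoulder
    mass: 1.20
    torque_limit: 12
    gear_ratio: 30

task:
  box_mass: 10                      # kg
  box_height: 0.15                  # m
  box_depth: 0.65                   # m
  hand_initial: [0.0, 0.070, 0.418] # (x, y, z) m; y up, z anterior
  hand_final: [0.0, 1.088, 0.417]
  duration: 1.44                    # s
  epsilon: 0.2                      # posture tracking band (rad)

solver:
  n_ctrl: 5    # control points per spline
  n_grid: 25   # collocation points on [0, T]
  maxit: 150
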