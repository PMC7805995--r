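# Default parameters of the bundled 1-DOF surrogate plants.
# Units: SI throughout (m, s, rad, N, N.m); stimulations dimensionless 0..1.
# Changing these is allowed but invalidates the frozen fixture expectations
# used by the package tests.
pointing:
  shared:
    J: 0.05            # link moment of inertia [kg m^2]
    damping: 1.3       # viscous joint damping [N m s / rad]
    L: 0.30            # link length, shoulder to end-effector [m]
    q0: 0.0            # initial joint angle [rad]
    qd0: 0.0           # initial joint velocity [rad/s]
    q_goal: 1.0        # target joint angle [rad]
    q_lo: -0.5         # soft joint limits [rad]
    q_hi: 2.0
    k_lim: 30.0        # joint-limit stiffness [N m / rad]
    dt: 0.001          # integrator step [s]
    tick: 0.01         # controller sampling interval [s]
    T: 1.0             # movement duration [s]
  muscle:
    F_max: 200.0       # maximum isometric force per muscle [N]
    l_opt: 0.05        # optimal fiber length [m]
    gamma: 0.35        # normalized fiber-length change per rad of joint angle
    q_ref_flex: 0.0    # joint angle at which the flexor is at optimal length
    q_ref_ext: 0.6     # same for the extensor (its parallel-elastic engages above)
    k_pas: 28.0        # passive force coefficient [F_max per unit stretch^2]
    tau_act: 0.03      # activation time constant [s]
    fl_width: 0.45     # force-length bell width (normalized length)
    v_max: 10.0        # maximum shortening velocity [optimal lengths / s]
    fv_curv: 0.25      # Hill force-velocity curvature
    fv_ecc: 1.5        # eccentric force cap (times isometric)
    c0: 0.05           # stimulation co-contraction baseline
    kp: 12.0           # stimulation feedback gain [1/rad]
    kd: 1.2            # stimulation velocity gain [s/rad]
    delay: 0.03        # sensor delay [s]
    noise_sd: 0.01     # controller output noise (stimulation units)
  torque:
    limit: 20.0        # torque saturation [N m]
    kP: -8.0           # PD position gain [N m / rad]
    kD: -1.0           # PD velocity gain [N m s / rad]
    delay: 0.0         # sensor delay [s]
    noise_sd: 0.05     # controller output noise [N m]
periodic:
  shared:
    J: 1.0             # leg-mode moment of inertia [kg m^2]
    damping: 3.0       # [N m s / rad]
    l_leg: 1.3         # virtual leg length [m]
    amp: 0.3           # reference oscillation amplitude [rad]
    t_cyc: 1.2         # reference cycle period [s]
    phi0: 0.0          # initial angle [rad]
    q_lo: -1.0         # soft joint limits [rad]
    q_hi: 1.0
    k_lim: 400.0       # [N m / rad]
    dt: 0.001
    tick: 0.01
    t_settle: 1.0      # settling phase before evaluation [s]
    T_eval: 5.0        # evaluation window = discretization window [s]
    y_min: 1.22        # height floor of the hip analogue [m]
    speed_band: 0.06   # admissible relative deviation from reference speed
  muscle:
    F_max: 2000.0
    l_opt: 0.08
    gamma: 1.25
    q_ref_flex: -0.25  # symmetric pair: passive centering past +/-0.25 rad
    q_ref_ext: 0.25
    k_pas: 5.0
    tau_act: 0.02
    fl_width: 0.45
    v_max: 12.0
    fv_curv: 0.25
    fv_ecc: 1.5
    c0: 0.1
    kp: 4.0
    kd: 0.8
    delay: 0.01        # single configurable neural delay [s]
    noise_sd: 0.0
  torque:
    limit: ~           # null: set to 1.5 x peak muscle reference torque
    kP: -1000.0
    kD: -45.0
    delay: 0.0
    noise_sd: 0.0
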