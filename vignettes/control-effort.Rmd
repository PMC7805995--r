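---
title: "Measuring control effort: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring control effort: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrleffort)
```

## The idea

A controller — a nervous system or a robot's computer — has to process
information to produce a movement: it reads sensors and emits actuator
commands. How much information is *necessary*? The package answers this by
degrading the resolution of the control signals until the movement breaks,
and calling the information content at the coarsest still-working
resolution the **control effort** of the system for that task. Because the
measure is evaluated on the closed loop, it captures contributions of the
body itself: if visco-elastic muscle properties stabilize the movement
("morphological computation", "preflexes"), the controller can get away
with fewer bits, and the measure shows it.

Each signal $u_i(t)$ is quantized to $n_i$ amplitude levels and sampled
$m_i$ times over the movement window of length $T$, held constant in
between (zero-order hold). Under the working assumption that all levels
are equally likely, the information of all signals is
$I(\mathbf r) = \sum_i m_i \log_2 n_i$ with
$\mathbf r = (n_1, m_1, \dots)$, and the control effort is the value of
the integer program $\min I(\mathbf r)$ s.t. $P(\mathbf r) \le 0$, where
$P$ simulates the movement and checks the task criterion. At the optimum
we re-simulate and report the **empirical** information
$I_{\min} = \sum_i m_i H_i$, with $H_i$ the Shannon entropy of the symbol
frequencies the signal actually emitted; it is bounded above by
$I(\mathbf r_{\text{opt}})$ and is the headline number.

## The three-phase search

The cost $I$ is trivial to evaluate and monotone in every entry; the
constraint requires a full closed-loop simulation and returns only
pass/fail. The solver is therefore a pattern search that (a) always
evaluates the cost first and skips the simulation whenever a candidate is
not strictly cheaper than the incumbent, and (b) memoizes every constraint
outcome keyed on the integer vector, including across phases:

* **Phase 1** polls with the single all-ones direction; the mesh starts at
  $(\mathbf r_{\text{init}} - 1)/2$, doubles after a success and halves
  after a failure, stopping when all mesh entries fall below 1. It is a
  parallel bisection toward the feasibility border.
* **Phase 2** polls the $2N_u$ unit directions in fixed index order with
  first-improvement acceptance and the same mesh adaptation (mesh
  re-initialized to $\max(1, \mathbf r/4)$). After a fully unsuccessful
  base sweep, an augmented direction set derived from the most recent
  successful direction adds $+0.5$ mesh on that entry ("going back" in one
  parameter) to escape shallow local minima.
* **Phase 3** fixes the mesh at ones and sweeps all directions with 1, 2,
  or 3 simultaneous unit decrements, restarting from any improvement. On
  termination it computes the discreteness error
  $\Delta I_{\text{opt}} = \max_l [I(\mathbf r_{\text{opt}}) -
  I(\mathbf r_{\text{opt}} - e_l)]$ over admissible single decrements —
  an upper bound on what one further integer step could save. Phase 3 can
  be disabled (`phase3 = FALSE`) when its combinatorial sweep is too
  expensive relative to the expected gain.

Candidate entries are rounded to the nearest integer with ties toward the
smaller value (the cheap-first rule filters over-eager candidates safely)
and clamped at 1. Stochastic constraints own their averaging and their
seed stream — each candidate's repeats are seeded from the master seed and
a hash of the candidate, so the optimizer sees a deterministic function
and identical runs are bit-identical.

### What the search does and does not guarantee

On monotone separable constraints (feasible iff every entry exceeds its
threshold) the search provably lands on the threshold corner, and the test
suite verifies exact agreement with a brute-force oracle on 100 random
problems. Two structural caveats, both surfaced by the tests rather than
hidden:

* *Equal-cost plateaus.* Once an amplitude entry reaches $n_i = 1$, that
  signal's cost term is 0 for any $m_i$, and the cheap-first rule never
  polls equal-cost candidates; an isolated phase 2 therefore leaves $m_i$
  wherever it was. The optimal *value* is unaffected.
* *Coupled borders.* When feasibility trades amplitude against time
  resolution (e.g. a weighted-sum border), the constrained optimum tends
  to sit at extreme amplitude corners, which the uniform phase-1 descent
  abandons and downward-only polling cannot re-climb; the returned cost
  can then exceed the global optimum by much more than
  $\Delta I_{\text{opt}}$. The optimizer tests compare against the oracle
  and report how often the gap exceeds $\Delta I_{\text{opt}}$ instead of
  asserting a fixed success rate.

Phase-1 evaluation counts also deserve a note: on the toy problems the
count stays below $2\lceil\log_2 \max \mathbf r_{\text{init}}\rceil + 2$,
but because the mesh vector freezes the *ratio* of step widths at
$(\mathbf r_{\text{init}}-1)/2$, a feasibility border far from
proportional to $\mathbf r_{\text{init}}$ makes phase 1 descend as a slow
staircase (thousands of evaluations on the periodic scenarios). This is a
property of the vector-mesh bisection itself, not of its implementation.

## The bundled surrogate plants

The plants are deliberately small — one mechanical degree of freedom —
so that every scenario is exercisable in seconds and every claim about
the artifact can be tested. They are not reductions of any published
musculoskeletal model; parameters live in
`inst/extdata/plant_defaults.yaml` and are version-controlled (changing
them invalidates the frozen test expectations).

**Pointing.** A link of inertia $J = 0.05\,$kg m² and length 0.3 m moves
in the horizontal plane (no gravity) from $q_0 = 0$ toward
$q_{\text{goal}} = 1$ rad in $T = 1$ s. The muscle variant uses an
antagonistic pair of Hill-type actuators: first-order activation dynamics
($\tau = 30$ ms), a bell force–length factor (width 0.45 normalized
lengths), a Hill force–velocity factor (curvature 0.25, eccentric cap
1.5), a quadratic parallel-elastic force beyond the optimal length, and a
constant moment arm ($\gamma\,l_{\text{opt}} = 17.5$ mm). The geometry
places the flexor's optimum at $q = 0$ and lets the extensor's passive
stretch engage above $q = 0.6$, so that full flexor stimulation with a
silent extensor has a *stable equilibrium essentially on the goal* — the
morphological-computation property under study, and the reason the STIM
optimum collapses to one constant 2-level command (0 bit of symbol
entropy). The feedback law maps the 30 ms-delayed joint error to
stimulations around a small co-contraction baseline
($u_{1,2} = \mathrm{clip}(c_0 \pm (k_p e + k_d \dot e))$, $k_p = 12$,
$k_d = 1.2$), with additive Gaussian output noise (sd 0.01) standing in
for controller stochasticity; the criterion averages 5 repeats. The torque
twin replaces the muscles by a PD-controlled ideal torque source
($k_P = -8$, $k_D = -1$, zero delay, saturation ±20 N m, command noise sd
0.05 N m).

**Periodic locomotion analogue.** A leg-like link ($J = 1$ kg m²) tracks
$\varphi_{\text{ref}}(t) = 0.3\sin(2\pi t/1.2)$ rad; a compass-gait
kinematic map converts its state into a hip analogue with forward speed
$\dot x = l \cos\varphi\,|\dot\varphi|$ and height $y = l\cos\varphi$
($l = 1.3$ m). After a 1 s settling phase, the 5 s evaluation window is
also the discretization window. The run aborts when the sliding-window
mean speed (window = one cycle) leaves a 6% band around the reference
speed — estimated from the undiscretized run by least squares — or when
the height falls to 1.22 m ("falling"); the performance value is the time
missing to the full duration. The torque twin tracks the same reference
with its saturation set to 1.5× the peak actuator torque of the muscle
reference run.

### Which features of real systems the surrogates do and do not capture

They capture: activation low-pass filtering, force–length/velocity
nonlinearity, posture stabilization by antagonistic visco-elasticity,
sensor delay, sampled control, actuator saturation, stochastic controller
output, and the complete discretize–simulate–criterion loop. They do not
capture: multi-joint redundancy, learned policies, tendon elasticity,
contact dynamics, or a self-stabilizing gait. Two measured consequences,
reported here because the tests surface them:

* On the pointing task the muscle plant needs strictly less information
  than the torque twin (empirical effort 0 bit for STIM and SENS vs
  ≈ 4.3 bit for TORQUE at the shipped seed), and delay manipulations move
  the effort in the expected directions (removing the physiological delay
  does not lower the muscle plant's effort; adding delay raises the torque
  plant's). This ordering is asserted by the acceptance tests *for these
  fixtures*; it is a property of the bundled surrogates, not a
  reproduction of any published effect size.
* On the periodic task the ordering **inverts** (muscle scenarios need
  ≈ 1.3–1.5 kbit vs ≈ 0.4 kbit for the torque twin): pure reference
  tracking with a tight speed band is a servo problem, and the ideal
  actuator's unfiltered bandwidth wins. A 1-DOF driven oscillator simply
  lacks the self-stabilizing limit-cycle dynamics that favor muscles in a
  real gait — an instructive illustration that control effort is a
  *system* property that can favor either morphology depending on the
  task. The headline-ordering tests therefore run on the pointing task.

The pointing STIM constraint is also genuinely **non-monotone in the time
resolution**: $m \in \{1, 2\}$ succeeds through the open-loop equilibrium,
intermediate $m$ (command holds of 100–250 ms interacting with the 30 ms
delay) destabilizes the sampled loop even at near-continuous amplitude,
and $m \ge 50$ succeeds again. The near-monotone "clear border" the
optimization assumes holds only piecewise here; the criteria tests probe
and report the violation rate instead of asserting one.

## Numerical choices

* Fixed-step RK4 at $dt = 1$ ms; controller tick 10 ms with zero-order
  hold; delays realized as whole-step ring buffers (initial value emitted
  until filled). Fixed-step integration makes discretization timing exact
  and runs bit-reproducible.
* Discretizer sample times are $t_k = t_0 + (k-1)T/m$; when $m$ exceeds
  the number of integrator steps in the window, extra samples repeat the
  held value and the result is flagged (`m_saturated`) — effective
  resolution saturates at the loop's own sampling.
* Amplitude levels span $[u_{\min}, u_{\max}]$ inclusively with $n-1$
  equal gaps; assignment is to the nearest level with ties toward the
  larger level; out-of-range values are clamped (reference-run ranges
  cannot guarantee coverage of perturbed runs); $n = 1$ or a degenerate
  range yields the midpoint.
* Default initial resolution: $n_i = 2^{16}$ levels and one sample per
  controller tick — the finest resolution distinguishable in the loop; a
  nominally infinite initial resolution would only saturate there.
* Signal ranges for SENS (and periodic TORQUE) are the exact min/max of
  the undiscretized, noise-free reference over the discretization window;
  STIM uses $[0, 1]$, pointing TORQUE ±20 N m.
* Empirical entropies use the convention $0\log_2 0 = 0$; the empirical
  measure is the $m_i$-weighted per-sample entropy, the only reading that
  is non-negative and reduces to the uniform cost when all levels are
  equally occupied.
* Rates divide by the discretization window (1 s pointing, 5 s periodic),
  never by the settling phase.

## Problem sizes used by the tests

The suite runs the full pointing scenario set (six optimizations at the
default resolution) plus reduced-resolution scenario runs for the
serialization and determinism checks, 100 separable and ~60 weighted-sum
toy problems, and a few hundred randomized codec property cases — about
three minutes on one core. The periodic scenarios are exercised at the
plant/criterion level (reference feasibility, abort behaviour, range
extraction); their full optimizations run in minutes each and are reported
above from dedicated runs rather than re-executed on every test pass.

## Limitations

Beyond the surrogate-fidelity limits above: the optimizer explores only
downward (plus half-mesh backsteps), so its optimality guarantee is local
except on separable borders; the measure depends on the shipped controller
gains (a controller property is entangled with the system property
whenever the controller is far from well-tuned); and the empirical effort
of an $m = 1$ signal is always 0 bit, which makes coarse-in-time optima
look free — the uniform value $I(\mathbf r_{\text{opt}})$ is reported
alongside for exactly that reason.
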