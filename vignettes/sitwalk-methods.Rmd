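---
title: "Methods: a planar reflex-controlled sit-to-walk simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a planar reflex-controlled sit-to-walk simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sitwalk` generates stand-up-and-walk movements *de novo*: no motion data
is tracked. A planar musculoskeletal model is driven by a delayed-reflex
control policy whose free parameters are found by shooting optimization
(CMA-ES) against a high-level movement objective. This vignette documents
the model, the controller, the objective, the numerical choices, and the
open design decisions the package resolves, so that every green test can
be read for exactly what it establishes.

## The musculoskeletal model

The model is a sagittal-plane adult (1.80 m, 75 kg) with nine rigid
segments — pelvis, lumbar, torso (head and arms lumped in), and per side a
femur, tibia, and foot — and 11 degrees of freedom: a planar-free
pelvis-ground connection (x, y, tilt) plus pin joints at both hips, knees,
and ankles and at the lumbar and thoracic levels. The lumbar and thoracic
joints are torque-driven; all other joints are actuated by 20 Hill-type
muscle-tendon units (MTUs), ten per side: GMAX, HAM, BFSH, ILIAC, PSOAS,
RFEM, VAS, GAS, SOL, TA — lumped groups representing the major sagittal
muscle functions.

Segment inertial parameters are scaled from standard anthropometric
tables; peak isometric forces are lumped-group values in the spirit of the
classic lower-limb models. Neither is prescribed to more precision by the
method: what matters is the closed loop of geometry, muscle dynamics, and
reflexes.

**Muscle paths.** Paths are ordered via-point chains; the muscle-tendon
length is the chain length in the ground frame and moment arms are exact
path-length gradients (`-dL/dq`, verified against central finite
differences at 1e-5 relative tolerance). A planar via-point model has no
wrapping surfaces, so a straight path segment can drift across its joint
center at deep flexion and flip the sign of its moment arm. The shipped
fixture places every joint-crossing via-point pair by an *angular-window
rule*: the two points bracketing a joint keep their chord on one
anatomical side of the joint over the entire coordinate range. Sign
correctness over the full range was preferred over matching any single
tabulated moment-arm magnitude; magnitudes are plausible (3–5 cm at the
hip and knee in mid-range, shrinking toward the range ends, as wrapping
anatomy also does).

**Joint limits.** Coordinate ranges carry one-sided "ligament" torques:
500 N·m/rad beyond the range with a parallel damping of 0.5 N·m·s/rad
that ramps in over the first 0.02 rad of excess, keeping the torque
continuous at the boundary. The printed limit stiffness ("500 N/m") is
dimensionally inconsistent for a pin joint; the rotational reading is
used. Every pin joint additionally carries a small *passive* viscous
damping (0.3 N·m·s/rad at limb joints, 2.0 at the lumbar and thoracic
joints), representing passive tissue. This is not cosmetic: the trunk PD
controllers act through 30–35 ms neural delays, and an undamped trunk
mode near 45 rad/s (quarter period ≈ the delay) is otherwise resonantly
destabilized by *any* delayed velocity feedback, which poisons the
optimization landscape far from physiological gains.

## Contact

Foot-ground and buttock-chair contact are compliant Hunt–Crossley
elements: normal force `k·x^{3/2}(1 + 1.5 c ẋ)`, clamped at zero (no
adhesion), with dissipation c = 1 s/m, and velocity-regularized friction
(tanh ramp with 0.01 m/s slip tolerance, Stribeck decay from the static
0.9 to the dynamic 0.6 coefficient; the magnitude never exceeds the
static cone). Each foot has heel and toe spheres (r = 3 cm), the pelvis a
buttock sphere (r = 12 cm), and the chair is a 40×12×5 cm box fixed in
the ground frame at the scenario's seat height; sphere-box closest-point
queries handle face and corner cases.

Two documented departures from the literal single-sphere description:

* **Stiffness scale.** The printed plane-strain moduli (17500 N/m² feet,
  10000 N/m² chair) are kept verbatim in the model file, but inserted
  into the Hertz coefficient `k = 4/3 E* sqrt(R)` they produce
  decimetre-scale static penetration — the source engine's parameter
  convention is not recoverable. A single dimensionless scale factor
  (300), chosen once so that quiet standing penetrates ≈ 3 mm, bridges
  the convention; the feet/chair ratio is preserved.
* **Contact-patch damping.** A rolling sphere makes quiet sitting a
  knife-edge: an inverted pendulum pivoting on a freely rolling contact.
  Real buttock/thigh contact is distributed and resists pitch. The
  buttock-chair contact therefore carries a purely dissipative rotational
  torque proportional to the normal load (0.02 N·m per N·rad/s).

## Muscle-tendon dynamics

Activation follows first-order dynamics with τ_act = 10 ms and
τ_deact = 40 ms (conventional values in the reflex-gait literature).
The contractile element uses a smooth standard Hill set: a Gaussian
active force-length (width 0.5, value 1 at optimal length), a
hyperbolic/exponential force-velocity with `f(0) = 1`, `f(-v_max) = 0`,
eccentric plateau 1.5, and slope continuity at zero velocity (the curve
is invertible in closed form, which the contraction dynamics exploit), a
cubic passive curve that is zero at or below optimal length, and a
quadratic tendon curve reaching the maximal isometric force at 4.5%
strain. The elastic-tendon contraction step inverts the force-velocity
relation against the tendon load (CE-tendon equilibrium) and advances
the fiber length explicitly; a rigid-tendon mode provides the analytic
oracle used in tests. v_max = 10 l_opt/s for all units.

## The controller

**Reflex law.** Every muscle pathway contributes
`C0 + K_L (L(t-δ) - L0) + K_F F(t-δ) + K_V V(t-δ)`, where L is the
normalized CE length, F the normalized tendon force, V the normalized CE
velocity (l_opt/s, lengthening positive), and δ the pathway's neural
latency. Monosynaptic length feedback is excitatory, antagonistic
feedback inhibitory; the per-muscle sum is clamped to [0, 1]. During the
stand-up phases L0 is fixed at 1 (a free offset would be indistinguishable
from C0); the gait controller's length pathways carry free offsets.

**Latencies** live on a 5 ms grid. The soleus monosynaptic loop is the
H-reflex latency (30.2 ms) plus the distal motor latency (3.3 ms),
rounded to 35 ms; GAS and TA share it. Proximal muscles subtract twice
the motor-distance difference (0.55 m) over the conduction velocity
(50 m/s), floored to the grid (10 ms for GMAX, ILIAC, PSOAS). RFEM stems
from the patellar reflex (21 → 20 ms), VAS and BFSH share its path
length, HAM is one grid step shorter (15 ms). Antagonistic latencies are
pair means rounded half-up (so the 17.5 ms HAM/VAS mean maps to 20 ms).
Vestibular latencies anchor on the 55 ms soleus response:
`55 - 35/2 + δ_muscle/2`, floored to the grid; the lumbar joint uses
`55 - 35/2` → 35 ms and the thoracic joint a 30 ms central estimate.
`latency_table()` reproduces the full table.

**Stand-up control** runs in two phases, P1 and P2, each with an
independent parameter set: per muscle a constant C0, monosynaptic
(K_L, K_F, K_V) gains, antagonistic (K_L, K_F, K_V) gains per antagonist
pair, and a vestibular PD on delayed pelvis tilt (free-signed K_p, K_v,
shared tilt reference θ0 per phase); the lumbar and thoracic joints run
delayed PD controllers (stiffness, damping, setpoint) saturated at
±1000 N·m and filtered by a 20 ms first-order actuator lag.

**Gait control** is a per-leg three-state machine (Stance, Lift-off,
Swing) gated by the leg load against a free stance-load threshold with a
20 ms dwell-time hysteresis: Stance → Lift-off when the load drops below
the threshold with the contralateral leg loaded, Lift-off → Swing when
the load reaches ~0 (< 0.01 BW), re-entry to Stance on loading. The
pathway set follows the classic positive-force-feedback reflex gait
controller, extended with BFSH and RFEM (per-state monosynaptic length
and force feedback), hip-flexor pathways for ILIAC and PSOAS, stance
vestibular balance on the hip-crossing muscles (extensors excited,
flexors inhibited by forward tilt error) plus RFEM, a knee-angle
suppression of VAS near full extension, HAM-force couplings onto BFSH,
HAM-length inhibition of the hip flexors and RFEM in swing, and
state-independent trunk PD. Pathways whose gains do not modulate between
states (SOL and GAS force feedback, the TA length/SOL-inhibition loop)
carry a single shared gain.

**The 551 free parameters.** The total is a stated property of the
controller; its per-block breakdown is not, so the shipped enumeration —
which reaches the total exactly and is pinned by a test — owns it:

| block | count |
|---|---|
| stand-up: 2 phases × 2 legs × (10·C0 + 10×3 mono + 16×3 antagonist + 10×2 vestibular) | 432 |
| stand-up: θ0 per phase | 2 |
| stand-up: trunk PD (2 phases × 2 joints × Kp/Kv/setpoint) | 12 |
| gait: per leg 48 (SOL 1, GAS 1, VAS 5, TA 3, BFSH 9, RFEM 10, HAM 3, GMAX 3, ILIAC 6, PSOAS 6, θ0 1) | 96 |
| gait: trunk PD (2 joints × 3) | 6 |
| global: T1, T2, stance load threshold | 3 |
| **total** | **551** |

Left/right gains are independent (`per_leg` sharing, the default, needed
both for asymmetric strategies and to reach the stated count); a
`symmetric` mode mirrors the left side onto the right (287 free
parameters). Any residual mismatch between this enumeration and the
original's internal breakdown cannot be checked against the text and is
therefore owned by this table, not silently absorbed elsewhere.

## Simulation

Dynamics are assembled per step from point Jacobians (planar mass matrix
plus velocity bias) and integrated by semi-implicit Euler at a fixed
dt = 2×10⁻⁴ s; the controller and muscles update every step and
trajectories are sampled at 100 Hz. The integrator is validated by
invariants rather than by reference output: a passive pendulum conserves
energy to better than 1% over 5 s, static standing reproduces the body
weight in the ground reaction within 2%, and linear momentum balances
the external forces at every sample within 1% of body weight. Rollouts
are bit-deterministic on one platform. Delayed signals live in per-step
ring buffers (all latencies are exact multiples of the step); the
R-level `delay_buffer` mirrors the semantics with linear interpolation
and a hold-at-start rule.

A rollout ends at 12 s or when the whole-body COM height drops below 0.6
of its initial value (strict inequality: a ratio of exactly 0.60 is not
a fall).

## The movement objective

* **Mimic measure** — mean squared exceedance of the pelvis COM outside
  a ±0.10 m band around a reference stand-up path: a quintic blend from
  the seated pelvis COM to a point above the mid-ankle at standing
  pelvis height. The reference is *time-indexed* over a fixed 1.5 s
  window (a typical unhurried stand-up). The measured corridor it
  replaces was also a time trajectory; with a purely spatial band a
  permanently seated model would score zero, defeating the measure's
  stated purpose of giving the optimizer a rough stand-up path. Zero
  once the motion stays inside the band.
* **Gait velocity** — average forward pelvis velocity from the end of
  the third step (heel strike through 30 N after ≥ 50 ms unloaded) to
  the end of the rollout, penalized by its shortfall below 0.8 m/s; with
  fewer than four steps the full post-stand-up interval is used.
* **Range measures** — time-integrated exceedance (deg·s) of lumbar
  (−50…0°), thoracic (−15…15°), pelvis tilt (−50…30°), and ankle
  (−60…60°) angles; for the knees, the integrated joint-limit torque
  magnitude (the knee's ligament loading) above a zero threshold.
* **Head acceleration** — integrated exceedance of the head-point
  (top-of-torso) acceleration magnitude above 1 m/s², finite-differenced
  at the sampling rate.
* **Energy** — `J_act` (summed time-average cubed activations), `J_T`
  (summed time-average squared trunk torques), and `J_mb`, a muscle-level
  metabolic rate (activation/maintenance heat, shortening heat, positive
  CE work, basal rate; coefficients are documented constants in
  `sitwalk:::.metabolic_constants`) normalized per duration during
  stand-up and per distance during gait (cost of transport). The energy
  total is `J = 0.01 J_mb + 0.1 J_act + 0.0003 J_T` and is the sole
  non-zero term of a fully satisfying rollout.
* **Fall penalty** — additive `1000 × (1 − t_end/12)` when the rollout
  terminated by the fall rule.

The task weights (mimic 1000 per m², velocity 100 per m/s, range 0.2 per
deg·s, knee 0.005 per N·m·s, head 0.2 per m/s) are package choices,
documented here and fixed; they only shape the search; the model's stated
constants above are honored as printed.

## Optimization

Shooting: decode parameters → simulate → score. CMA-ES runs in a
normalized box (every free parameter scaled to [0, 1] by its bounds) with
population size 10; the initial step size 0.1 equals the documented "10%
of the bound range". Above 100 dimensions the covariance is restricted
to its diagonal (sep-CMA) with the standard accelerated learning rate —
with a few thousand evaluations a full 551² covariance could not be
learned anyway; the full-matrix path is used in low dimension and
verified on a convex quadratic. Candidates are clipped into the box
before evaluation; several runs with a shared initial mean and distinct
seeds can be kept in parallel and the best returned; warm starting
replaces the initial mean by a saved parameter file.

**Initial guess.** The shipped initial mean is *not* all-zero gains: the
stand-up phases start from a small calibrated quiet-sitting policy
(vestibular and trunk-PD gains plus muscle tone found once by a reduced
CMA-ES run on the sitting task, stored as the defaults), with gait gains
loosely after the classic reflex-gait gain sets. Seated balance in
this model is actively unstable — an inverted pendulum on a compliant
rolling contact controlled through 40–55 ms delays — and a zero-gain
start spends the whole desk-scale budget rediscovering posture before
any stand-up attempt. Starting from quiet sitting preserves the search
problem that matters (discovering the stand-up and the transition to
gait) at desk scale.

## What the synthetic world does and does not establish

The generator (model fixture + corridor + scenarios) emulates: the
reference structure (11 DOF, 20 MTUs, 75 kg, contact geometry and
materials, latency table, 551-parameter policy, objective constants),
seat heights of 0.44/0.35 m, symmetric and asymmetric foot placements,
and a physically consistent closed loop validated by conservation
invariants. It does not emulate: the original engine's contact parameter
semantics (bridged by one documented scale), measured pelvis corridors,
3-D effects (pelvis list/rotation, arm push-off), or any
trained reference controllers. A green test therefore establishes structural and
numerical fidelity plus qualitative behavior (seat-off, no fall, forward
progress, condition orderings) — not trace-level reproduction of reference
trajectories, which requires cluster-scale optimization.

## Known limitations

* Desk-scale CMA-ES budgets (population 10, a few hundred generations)
  discover seat-off and forward stepping bursts, but in our experiments
  they have not sufficed to stabilize a sustained gait limit cycle: the
  optimization smoke test in the acceptance suite asserts the full
  seat-off / no-fall / >1 m milestones and is expected to fail at this
  budget (it is kept honest rather than weakened). Reproducing converged
  reference-quality trajectories requires cluster-scale optimization.
* The planar model cannot express medial-lateral balance or pelvis
  rotation; deep-flexion moment arms are conservative (no wrapping).
* The buttock is one sphere: chair unloading is abrupt compared to
  thighs rolling off a seat; the patch-damping term mitigates but does
  not remove this.
* Joint "loading" is reported as the resultant intersegmental force
  magnitude including muscle contributions; compressive/shear splits are
  out of scope.
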