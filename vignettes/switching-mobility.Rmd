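---
title: "The switching mobility sidestep model: mechanics, control, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The switching mobility sidestep model: mechanics, control, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidestepr)
```

# The scientific problem

Bipedal locomotion models built around optimal control or neural
oscillators adapt well to external disturbances but assume the *task*
stays fixed. This package studies the complementary problem — switching
adaptation — on the smallest system where it is non-trivial: a frontal-plane
sidestepper made of a trunk and two feet that must reverse its direction of
travel the instant the command flips, at a moment it cannot anticipate. The
interesting question is not whether a trajectory to the new target exists,
but whether purely local, rule-switching actuators can reorganize
propulsion, balance, and leg swing online, with no planner and no clock.

# Mechanical model

Three point masses (trunk `m_trunk`, two feet `m_foot`) move in the
lateral–vertical plane under gravity, three actuator force pairs, and
passive viscoelasticity:

* **Leg spring-dampers** about the natural length `L0` (set by the
  equilateral rest triangle, `L0 = 2 h / sqrt(3)` for trunk height `h`).
  The elastic coefficient takes a larger value while the foot is in ground
  contact (`k_leg_contact`) than in flight (`k_leg_flight`), and elongation
  beyond `ext_ratio * L0` engages a branch stiffened by `ext_mult`. The
  stiffened branch is piecewise-linear and *continuous* at the breakpoint;
  an offset jump there would inject energy discontinuously and defeat the
  momentum bookkeeping the tests enforce.
* **Inter-leg spring-damper** between the two feet about the same natural
  length. Besides representing hip ab/adductor tissue, this element bounds
  how far the command-mixing rule (below) can fling the swing foot; its
  stiffness is one of the two parameters that most shape the gait.
* **Ground**: unilateral Kelvin–Voigt in the vertical
  (`max(0, -k_ground z - b_ground ż)`, so the ground can push but never
  pull) plus viscous horizontal resistance `-b_friction ẋ` while
  penetrating. A compliant ground is required because ground elasticity is
  itself a swept parameter of the sensitivity protocol. The horizontal term
  must be strong: stance feet carry multi-kN propulsive reactions, and with
  weak resistance they slide instead of anchoring.
* **Auxiliary trunk viscoelasticity**: when the horizontal trunk–foot
  distance drops strictly below `d_aux` = 0.15 m, a horizontal
  spring-damper pair pushes trunk and that foot apart. It is the
  last-resort catch that keeps the trunk from toppling over the leading
  foot.

Integration is explicit forward Euler at `dt` = 1e-5 s (positions advance
with current velocities, velocities with current accelerations). A fixed
small step keeps every run bit-reproducible; with the default stiffnesses
the fastest mode sits two decades below the stability limit. A trial is
declared a fall when the trunk drops below `fall_z` = 0.4 m — the model has
no knees to recover from a posture that low, and the threshold sits far
below anything a successful run visits.

# Switching mobility control

Each control step (every `dt`) runs the same pipeline for the command
`v_d = (v_x, 0)`:

1. **Roles and axes.** A foot is grounded iff its height is ≤ 0. The
   anterior (leading) foot is the one farther along the commanded
   direction, so roles flip instantly when the command flips. Axes:
   trailing→leading foot for the inter-leg, foot→trunk for each leg.
2. **Switching coefficients** `a_i ∈ {−1, −½, 0, ½, 1}`. Legs default to
   +1 (propulsion), halved in flight; the sign flips for the anterior leg
   when the trunk comes within `d_balance` = 0.2 m horizontally
   (balancing, any phase), or for an airborne posterior leg extended past
   `L0` (swing retraction). The inter-leg is 0 whenever either foot is
   grounded, ±½ in double flight, and −1 in anterior-leg support when the
   airborne posterior leg exceeds `swing_ratio * L0` (−½ in double flight,
   the flight halving composing with the sign).
3. **Local/residual split** `v_dil = a_i (e_i · v_d) e_i`,
   `v_dir = v_d − v_dil`.
4. **Mobility** `k_i = exp[−4 ln2 (‖v_dil − v_i‖² + ε₁)/(‖v_dil‖² + ε₂)]`,
   strictly inside (0, 1).
5. **Command mixing**: mobile neighbours inhibit an actuator's own local
   command and recruit it for their residuals' projections.
6. **Force** `F_ai = G (ṽ_di − v_i)` along the axis, as an internal
   equal-and-opposite pair.

## The produced velocity `v_i` — the one genuinely open reading

The quantity `v_i` is defined as the velocity the actuator *produces at
the trunk*. Two readings are possible: the relative velocity of the
actuator's endpoints (an actuator-centric rate), or the trunk's own
velocity projected on the axis (a trunk-centric outcome). The package
implements the trunk-centric reading: for the legs, `v_i` is the trunk
velocity projected on the leg axis; for the inter-leg actuator, whose
endpoints are the two feet and which moves the trunk only indirectly,
`v_i ≡ 0`.

This choice was decisive, and we document it because the alternative is
tempting. Under the endpoint-relative reading, a *stance* leg scores as
mobile (its small relative rate easily matches a small local command) and a
*flight* leg as immobile — precisely backwards from the intended semantics,
in which mobility should flag actuators able to serve the global goal. The
mis-ordering propagates through the mixing rule: the stance leg's large
residual hijacks the inter-leg actuator, the swing foot is flung away, the
stance widens, and the system either wedges into a static force balance or
falls. In an extensive scan of the passive-parameter space (hundreds of
configurations) no sustained locomotion exists under that reading. Under
the trunk-centric reading, leg mobility is high in flight and low in
stance, inter-leg mobility is high whenever a foot is planted, and
locomotion and at-any-moment direction reversal both emerge. The convention
is isolated in one place in the compiled core and mirrored by
`produced_velocity()`.

Two consequences are worth knowing. First, the actuator force on an
*airborne* foot contains no feedback on the foot's own rate — the foot's
flail is restrained only by the passive leg damper, the inter-leg
viscoelasticity, and gravity, which is why `b_leg`, `b_inter`, and the foot
mass matter so much for post-switch recovery. Second, in double support the
inter-leg actuator trivially satisfies its (zero) local command, its
mobility saturates near 1, and the legs are then driven almost entirely by
raw residual projections — whose unique consistent solution is exactly the
commanded horizontal trunk velocity. That is the propulsive phase.

## Other rule-level choices

* **Leg axis direction** foot→trunk, so positive actuator action drives
  the trunk along the axis. The formulas are quadratic in the axis, so the
  opposite convention is observationally identical.
* **Precedence** within a leg: balancing overrides swing overrides
  default. The two overrides target different legs (anterior vs posterior),
  so the precedence only matters through the code path, not the physics.
* **Inter-leg baseline in single support** is 0, not the propulsive +1.
  Both were implemented and compared: a propulsive baseline adds nothing
  (the request pathway already carries propulsion when a leg is mobile),
  and an always-on retraction variant pins the leading foot and kills
  forward progress.
* **Thresholds** (0.15 m, 0.2 m, 1.1 L0, 0.6 L0) use strict inequalities;
  roles are recomputed every step. On the measure-zero tie for the
  anterior label, the foot on the commanded side is taken, which keeps the
  rule mirror-equivariant.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `m_trunk`, `m_foot` | 48, 12 | kg | trunk-dominant human-like split; heavier feet resist post-switch flailing |
| `trunk_height` | 0.92 | m | initial apex; sets `L0` = 1.062 m |
| `k_leg_contact` / `k_leg_flight` | 16000 / 6000 | N/m | stance support vs swing compliance |
| `b_leg` | 350 | N s/m | only rate feedback on an airborne foot |
| `ext_mult`, `ext_ratio` | 10, 1.1 | — | extension limit beyond 1.1 L0 |
| `k_inter`, `b_inter` | 10000, 2000 | N/m, N s/m | stance-width keeper and swing-fling damper |
| `k_ground`, `b_ground`, `b_friction` | 30000, 2500, 20000 | N/m, N s/m | compliant, dissipative, anchoring ground |
| `k_aux`, `b_aux`, `d_aux` | 6000, 300, 0.15 | N/m, N s/m, m | trunk-foot anti-topple catch |
| `d_balance`, `swing_ratio` | 0.2, 0.6 | m, — | switching thresholds |
| `gain` | 3000 | kg/s | proportional gain of all actuators |
| `eps1`, `eps2` | 1e-10, 1e-4 | — | mobility regularizers |
| `dt` | 1e-5 | s | forward Euler step |
| `fall_z` | 0.4 | m | fall criterion |

The controller constants (gain, thresholds, regularizers, step) are fixed
by the model definition. The passive viscoelasticities are not published
for the original study, so the defaults above were calibrated by the
package authors with a two-stage search (broad Latin-hypercube and grid
scans, then full-protocol evaluation) toward the study conditions: a
sustained lateral gait with sub-second mixed stepping, direction-change
success at *every* switch timing of the evaluation grid, and reaching-time
and step-interval means near the reference values. Calibration used only
the default protocol; it is a property of the parameter set, not of any
individual test.

# The evaluation protocol

`run_sidestep()` holds a constant command; `direction_change_trial()`
switches +2 → −2 m/s at `t_switch` and reports the reaching time — the
interval until the trunk has moved 2 m in the new direction relative to its
position at the switch, resolved at the integrator step, with a 15-s cap
(the slowest successful default trial is under 3 s, so the cap only labels
genuine failures). `sweep_timings()` runs 101 trials spaced 0.03 s starting
at 1.5 s — after the gait is established, and wide enough (three seconds)
to sample every phase of the step cycle many times. Each trial is labelled
by whether the pre-switch trailing foot is grounded at the switch instant;
the leading foot's state is deliberately ignored, which makes the label a
pure stance/swing classification of the propelling leg.
`sensitivity_sweep()` scales leg elasticity (both phase values together),
ground elasticity, or the gain by half-decade factors and reruns a reduced
10-timing sweep per condition.

Problem sizes used by the test suite and the acceptance script: the full
101-trial sweep, a 60-s straight run (enough for 100+ touchdowns per foot,
so the stable-step window spans touchdowns 11–100), and 10-timing reduced
sweeps per sensitivity condition. These are the study conditions
themselves, not abbreviations.

# Gait analytics

Touchdowns and liftoffs are contact-flag transitions on the uniformly
decimated trajectory (default logging every 1 ms); contact or flight
episodes shorter than a 20-ms debounce are treated as chatter and absorbed,
which guarantees strict alternation. A *step* is a touchdown; step
intervals are successive same-foot touchdowns, and the stable-step window
keeps intervals closing with touchdowns 11–100. Step counts over the
post-switch window use the half-open convention `[switch, reach)`, so a
foot planted exactly at the command instant is counted once and the landing
at the reaching instant is not. Peak foot heights are per-flight-episode
maxima, normalized by the trunk height for histogramming. The two summary
statistics mirror the study's choices exactly: Pearson correlation with
`df = n − 2`, and the pooled-variance (Student, not Welch) two-sample
t-test — the Student form is forced by the reported degrees of freedom,
which equal `n1 + n2 − 2`.

# What the simulator does and does not emulate

Everything in this package is self-generated by the deterministic
simulator; there is no noise model, no sensor model, and no biological
data. Passing tests therefore demonstrate properties of the *model* — that
the rule set reorganizes roles fast enough to reverse at any tested moment,
that trailing-stance switches are slower, that more post-switch steps mean
slower reversals — not properties of human sidestepping. Known departures
of the calibrated defaults from the reference behaviour, measured by the
acceptance suite itself: the gait settles into a near-periodic limit cycle,
so its step-interval variability is far below the highly irregular
reference gait (and the reaching-time spread is correspondingly compressed,
weakening the step-count correlation); the cruising speed sits about a
third above the reference mean; and the robustness basin is narrower — some
half-decade parameter scalings that should preserve all-timing success do
not. Exploratory scans found irregular-gait regimes (low inter-leg damping)
and slower regimes, but every one of them sacrificed the all-timings
success that is the model's headline property, and that trade was not
taken. All four gaps most likely trace to the unpublished original
viscoelastic parameter set.

Other limitations: the model is strictly 2D with point feet and no joint
or muscle structure; the controller is evaluated at the integrator rate
(no sensorimotor delay); the ground is a smooth viscoelastic layer, so
impact transients are parameter-dependent; and results are specific to the
±2 m/s sidestep task — no claim is made about forward gait.

# Numerical and reproducibility notes

The simulator is deterministic end to end: identical configurations yield
bit-identical trajectories, and the mirror map (x → −x, feet swapped,
command negated) commutes with the full control+dynamics step to exact
floating-point identity. The compiled core accumulates the two legs'
force contributions as commutative pairwise sums specifically so the
mirror swap cannot reorder floating-point additions. Result files are
written with fixed 12-significant-digit formatting and sorted JSON keys,
so byte-level diffs are meaningful; configuration hashes are computed on a
key-sorted canonical form and are stable under reordering.
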