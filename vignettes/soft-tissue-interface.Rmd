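---
title: "Modeling soft-tissue compliance at the human-orthosis interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling soft-tissue compliance at the human-orthosis interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afosim)
```

## The problem

Musculoskeletal simulations of wearable assistive devices usually attach
the device rigidly (or through a single kinematic degree of freedom) to
the body model. In reality an ankle-foot orthosis (AFO) presses on skin,
fat and muscle; the soft tissue yields, the device moves relative to the
limb, the effective point of force application shifts, and both the
transmitted support and the predicted muscle activations change. `afosim`
models this compliance explicitly: the device shells are coupled to the
foot and shank through six degree-of-freedom viscoelastic spring-damper
("bushing") elements, and the coupled system is simulated over gait cycles
under assistance-as-needed support torques for foot-drop patient variants.

The package targets a desk-scale, fully synthetic reproduction of this
study design: every input (gait kinematics, ground reaction, support
profile) is generated by code under a seed, so all results are
reproducible and all claims testable.

## The interface element

Each element penalizes the pose deviation of a shell-side frame from its
segment-side frame, per axis:

$$F_i = -(k_{t,i}\,\Delta x_i + c_{t,i}\,\Delta\dot x_i),\qquad
  M_i = -(k_{r,i}\,\Delta\theta_i + c_{r,i}\,\Delta\dot\theta_i),
  \qquad i \in \{x, y, z\},$$

with translational stiffness in N/m, rotational stiffness in Nm/rad and
damping of 5 in each axis's native unit. Rotational deviations use a
fixed-order small-angle (x, y, z) convention; interface rotations stay
within a few degrees, so the per-axis law is well defined. The wrench acts
on the shell side; the reaction on the segment is its negation. Stiffness
is symmetric in each direction (the same coefficient for positive and
negative deflection); direction-dependent stiffness, nonlinear tissue
curves and strap contact mechanics are out of scope.

The default parameterization encodes where straps fix the device and
where compressible tissue lies in series: the stiffest translational
direction (10,000 N/m) is vertical on the tibia and fore-aft on the foot;
the tibia's fore-aft and mediolateral directions, backed by calf muscle
bulk, get 100 N/m; the foot's softer directions 500 N/m. Rotations braced
by the straps get 500 Nm/rad, all others 200 Nm/rad.

```{r}
default_interface_params("tibia")
```

## Model topology

The sagittal-plane model (x anterior, y up, z the ankle flexion axis)
assembles:

* a foot segment (toes lumped in) pinned to the shank at the ankle,
* a prescribed base: hip and knee follow the reference gait exactly, which
  fixes the ankle-center trajectory and shank orientation,
* an auxiliary body of mass $10^{-5}$ kg attached to the ankle center
  (plus any axis-misalignment offset) by a joint free in the three
  translations and locked in rotation,
* foot shell and calf shell, each pinned to the auxiliary body about z at
  the device center of rotation,
* four interface elements: two between foot and foot shell (instep and
  heel-cup anchors), two between tibia and calf shell (strap and upper-rim
  anchors).

The free coordinates are the ankle rotation, the three auxiliary-body
translations and the two shell rotations. Axis misalignment shifts the
auxiliary body relative to the ankle axis (front/back $\pm x$, up/down
$\pm y$, inside/outside $\mp z$, default 2 cm); the shells keep their
anchor points on the leg, so the elements stay unloaded in the neutral
pose and only the pivot moves.

The anchor points and marker locations are not prescribed by any
measurement; they are configuration-exposed plausible landmarks (e.g.
instep at (0.09, -0.02) m in the foot frame, calf strap at (0.03, 0.25) m
on the shank). One marker sits on each shell with a twin on the segment,
coincident in the initial state; relative movement is the shell marker's
displacement in the segment frame. Because the shells rotate about the
device pivot, the sign and magnitude of the x/y trace components depend
directly on where these markers sit; the package's markers are placed at
the instep and calf-cuff landmarks, where the rotation of the shells
dominates the readout. Only the structure of the traces (a single
dominant negative foot-pair y excursion ending near stance end, near-zero
z, orderings across weakening levels) is a stable prediction; millimeter
values are specific to the chosen geometry.

## Muscle groups, weakening and support

Ankle musculature is lumped into two groups with constant moment arms:
plantarflexors (4000 N maximum isometric force, 5 cm arm, 200 Nm
capacity) and dorsiflexors (1200 N, 4 cm, 48 Nm). The ankle moment is
$\mathrm{sign} \cdot a\, w\, F_{max} r$ with activation $a \in [0,1]$ and
weakening factor $w$. Patient variants PF25-PF100 retain 25-100% of
plantarflexor capacity and paralyze the dorsiflexors ($w = 0$).

The support torque acts about the device axis between the two shells
(positive dorsiflexion). Profiles are sized by a documented
assistance-as-needed style rule from the inverse-dynamics ankle moment
demand $\tau_{id}$ of the trial: a late-stance plantarflexion lobe equal
to $(1-w)$ of the plantarflexion demand (the share the weakened muscles
cannot produce), and a swing dorsiflexion lobe equal to the full
dorsiflexion demand (the dorsiflexors are paralyzed in every variant),
smoothed with a periodic raised-cosine kernel of 5% cycle width. With
$w = 1$ and intact dorsiflexors the profile vanishes. The healthy
reference activation — the comparison baseline for activation deviation —
is the quasi-static activation an unweakened plantarflexor group needs
for the plantarflexion part of the same demand.

## Controller

The ankle is tracked in the style of computed muscle control: a PD law on
the reference trajectory produces a desired acceleration
$\ddot q_{des} = \ddot q_{ref} + k_v(\dot q_{ref}-\dot q)
+ k_p(q_{ref}-q)$, the equations of motion convert it into a required
ankle torque, and the torque is allocated by minimizing
$a_{pf}^2 + a_{df}^2 + \lambda (r/s)^2$ subject to meeting the torque,
with activations bounded to $[0,1]$ and a reserve actuator $r$ (optimal
scale $s = 2$ Nm) that is roughly two orders of magnitude more expensive
than muscle. The knee and ankle carry task weight 10 against 1 for all
other coordinates; in this implementation the knee (weight 10) is
realized exactly as a prescribed base coordinate, so the weighting
materializes in the ankle task and in the general weighted solver
(`weighted_task_solve()`), which resolves competing tasks when a model
exposes more of them.

Two controller choices deserve explanation:

* **Update rate and gains.** The foot's generalized inertia about the
  ankle is about 0.009 kg m$^2$, while the interface elements couple it
  to the shells with an effective 400+ Nm/rad. A torque held constant
  over a 10 ms window cannot stabilize this coordinate (the coupled mode
  lives at ~200 rad/s), and soft gains leave degree-scale wander. The
  controller therefore updates at every 1 ms integration step with
  $k_p = 2500$ s$^{-2}$, $k_v = 100$ s$^{-1}$ (critically damped at 50
  rad/s). Both gains are configuration-exposed.
* **Excitation commands.** Activations follow first-order dynamics
  (15 ms activation, 50 ms deactivation). Commanding the optimizer's
  target directly puts the deactivation lag inside the PD loop and
  produces a ~6 Hz limit cycle; the controller instead inverts the
  activation filter within the $[0,1]$ excitation bounds, so the realized
  activation reaches the target within a step unless slew-limited. The
  reserve picks up exactly the torque the muscles could not produce —
  saturation, paralysis or slew — which makes reserve traces a faithful
  record of muscle insufficiency and keeps them near zero otherwise.

## Integrator

The stiffest interface axis (10,000 N/m) acts on a device assembly of a
few hundred grams carried by a $10^{-5}$ kg auxiliary body, giving
translational modes above 200 rad/s. The stepper is a fixed-step linearly
implicit Euler at $dt = 1$ ms: the spring-damper contribution to the
force Jacobian is assembled exactly from the element Jacobians
($J^\top K J$, $J^\top C J$) and moved to the left-hand side, so the step
solves $(M + dt\,C_g + dt^2 K_g)\,v^+ = Mv + dt\,Q + dt\,C_g v$. This is
unconditionally stable for the linear interface forces without
iteration. The matrices are refreshed every 10 steps (they depend only on
slowly varying angles); the generalized forces every step. The scheme is
first order: the work-energy audit in the test suite closes to within
about 2% of the injected work at the default step and the defect halves
with the step size.

## Bootstrap

The gait initial pose differs from the model's neutral pose, so the
device coordinates have no obvious initial condition. Before each cycle
the tasked joint angles ramp linearly from neutral to the gait initial
pose within 10 controller windows, with gait forces excluded and the
pelvis held by virtual supports; the interface then settles (default 1.2
s, rate tolerance $10^{-3}$) at the final pose; non-settling is flagged,
never silent. The bootstrap always runs on the unweakened model, so all
weakening levels and misalignments of a subject and speed start the cycle
from the same pose; `run_grid()` computes one bootstrap per direction and
shares it across the four levels.

## Synthetic gait

The generator stands in for motion-lab recordings and is first-class,
tested code. Joint angles are truncated Fourier series (4 harmonics)
fitted through normative gait key points, amplitude- and duration-scaled
per speed (cycle 1.25/1.05/0.90 s, stance 62/60/58%, stride speed
1.0/1.25/1.5 m/s for slow/medium/fast, around the cohort anthropometry of
a 72 kg, 1.76 m adult). The vertical ground reaction is a double-bump
profile over stance, zero in swing, with peaks of 1.04/1.08/1.12 body
weight chosen so that the per-leg stance impulse equals half the body
weight times the cycle duration (both legs together must carry body
weight over a full cycle); the anteroposterior component is a
braking/propulsion sine and the center of pressure rolls heel to toe.
Seeded jitter adds only smooth low-order perturbations (0.8 degree angle
harmonics, 2% ground-reaction scale) to avoid non-physiological
accelerations; every trial is deterministic per (speed, seed).

What the generator does **not** emulate: inter-subject anthropometric
variation (a single segment parameter set is used), double-support force
sharing, out-of-plane motion, measured support curves, and any
subject-specific tissue parameters. Passing the property suite therefore
demonstrates internal consistency of the method under controlled
conditions, not agreement with any individual's recorded gait.

## Outcome measures and residual plausibility

Relative movement is resampled to a 101-point heel-strike-to-heel-strike
phase grid (a standard gait convention) and reported in millimeters.
Stance is the phase where the vertical ground reaction exceeds 2% of its
peak. Activation deviation is the stance mean of
$|a_{sim} - a_{ref}| \times 100$; grid aggregation is the mean of
per-subject means.

Residual plausibility uses two records: the net interface load on the
human segments (the reference motion was recorded without a device, so in
a full-body simulation the virtual supports would have to absorb this
load), checked against 5% of the peak ground-reaction magnitude; and the
ankle reserve torque, checked against a 25 Nm threshold. The boundary
convention is inclusive (a residual exactly at the threshold passes).
Under the default conditions the reserve peaks at about 5 Nm — the
dynamic dorsiflexion shortfall that the quasi-statically sized swing lobe
does not cover — approaching but not exceeding the bound.

## Study conditions and problem sizes

The default grid is 4 weakening levels x 3 speeds x 7 misalignment
directions = 84 conditions per synthetic subject, about 20 s of CPU per
subject at the 1 ms step. The test suite runs one subject; the acceptance
script (`scripts/acceptance.R`) runs three and reports cell means. At
these sizes the qualitative structure is stable across seeds: activation
deviation decreases monotonically from PF25 to PF100 and grows from slow
to fast; the peak foot-pair |y| displacement (13-18 mm, late stance)
decreases with increasing strength; the spread across misalignment
directions stays an order of magnitude below the spread across levels;
and the mediolateral (z) deflection is numerically zero, as expected with
ideal z-aligned axes and purely sagittal loading.

Magnitudes are smaller than a full-scale study reports (activation
deviations of a few percent rather than around ten): the synthetic
demand curves are smooth, the controller is not window-limited, and a
single parameter set replaces fifteen participants. The orderings, not
the magnitudes, are the reproducible content at this scale.

## Known limitations

* Sagittal-plane mechanics only; z enters through interface translation.
* Constant muscle moment arms; no force-length/velocity properties.
* Ground reaction and center of pressure are prescribed, not emulated by
  a contact model, so foot-ground consistency is kinematic only.
* The linearly implicit Euler step is first-order dissipative; energy
  audits, not long-horizon conservation, are the intended check.
* Marker placement is a free design choice that scales the millimeter
  values of the relative-motion traces (see above).
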