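---
title: "An anatomically constrained multibody model of the elbow"
author: "elbowsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An anatomically constrained multibody model of the elbow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elbowsim)
```

## The model

Most musculoskeletal arm models idealize the elbow as a mechanical hinge.
This package instead simulates the joint the way it is actually held
together: three free rigid bodies — humerus, ulna, radius, 18 degrees of
freedom in total and no kinematic joints — constrained only by

* **tension-only nonlinear ligament bundles** (3 bundles each for the
  anterior and posterior parts of the medial collateral ligament, the
  lateral ulnar collateral ligament and the radial collateral ligament,
  plus 2 annular bundles, 14 in all),
* **frictionless compliant cartilage contact**, evaluated element-wise on a
  grid of roughly 3 x 3 mm patches tiled over the humeral cartilage, and
* **muscle actuators** (triceps long/lateral/medial, biceps long/short,
  brachialis) driven by PID controllers.

Units are millimetres, kilograms, seconds, newtons and MPa.

### Ligament force law

Each bundle produces force only in tension, with a parabolic "toe" region
that models fibre crimp:

$$
f(\varepsilon) = \begin{cases}
\tfrac{1}{4}\,k\,\varepsilon^2/\varepsilon_l & 0 \le \varepsilon \le 2\varepsilon_l \\
k\,(\varepsilon - \varepsilon_l) & \varepsilon > 2\varepsilon_l \\
0 & \varepsilon < 0
\end{cases}
\qquad
\varepsilon = \frac{l - l_0}{l_0}
$$

with $\varepsilon_l = 0.03$ by default. The two branches agree in value and
slope at $\varepsilon = 2\varepsilon_l$, so the law is $C^1$. Bundle paths
may thread via points and wrap over analytic sphere or cylinder obstacles;
the wrapped length is the tangent–arc–tangent geodesic, and the wrap
reaction acts through the obstacle centre so the ligament system transmits
zero net wrench.

The zero-load length $l_0$ of every bundle is calibrated from a passive
laxity sweep: $l_0 = 0.8 \times \max_t l(t)$, the 80 percent correction
compensating the small force the examiner applies during the test. The
factor is global but can be overridden per bundle. Whether the maximum
should use the wrapped path or the straight insertion–origin distance is
not prescribed anywhere; the wrapped path is the default here
(`straight_line = TRUE` selects the alternative).

### Cartilage contact

The humeral cartilage is discretized into elements of approximately
3 x 3 mm cross-section (`discretize_cartilage()`). Each element carries a
centroid, outward normal and true patch area; the chart used for tiling is
a developable or equal-area projection (plane, unrolled cylinder, or
Lambert azimuthal projection for spheres), and triangle areas are
distributed over chart cells by exact polygon clipping, so the summed
element area equals the mesh area to rounding. Element penetration
$\delta$ into the opposing cartilage produces the compliant normal force

$$F_c = k_c\,\delta^{n} + B_c(\delta)\,\dot\delta$$

with the optimized parameter set $k_c = 40$ N/mm, $n = 3.05$,
$B_c^{max} = 5$ Ns/mm at an interpenetration scale of $0.1$ mm. Two
choices the source formulation leaves implicit are made explicit here:

* $B_c(\delta)$ ramps in as the cubic smooth-step
  $3u^2 - 2u^3$, $u = \delta / 0.1\,\mathrm{mm}$, clamped to $[0,1]$, so
  first touch is force-continuous;
* the total element force is clamped at zero so damping can never produce
  adhesion during separation.

Contact acts along the element outward normal at the element centroid
(frictionless), with the reaction applied to the opposing body at the same
point. The ulnohumeral and radiohumeral pairings are element grids against
the opposing articular surface; the radioulnar articulation is modelled as
sphere-in-cup point constraints under the same force law.

### Muscles and control

Muscle paths are polylines (origin, via points, insertion) with no smooth
wrapping surfaces. The simulation runs the standard two-phase protocol:

1. **Inverse kinematics** — the trial poses are replayed kinematically and
   each muscle's length pattern is recorded (`run_inverse_kinematics()`).
2. **Forward dynamics** — the kinematic constraints are removed and each
   muscle's PID controller tracks its recorded length
   (`run_forward_dynamics()`).

Controller gains scale linearly with physiological cross-sectional area:
$P_i = \mathrm{PCSA}_i / 487\,\mathrm{mm}^2 \times P_{global}$ with global
gains $P = 50$, $I = 5$, $D = 0.0005$, and similarly for $I_i$, $D_i$. The
error convention is $e = l_{current} - l_{target}$, so a longer-than-target
muscle develops tension; the output is clamped to $[0, F_{max}]$ (muscles
pull, never push) with integral anti-windup while the clamp is active. The
controller runs at the dynamics step (the co-simulation rate is not
specified elsewhere; one shared step is the simplest consistent choice).

### Integration scheme

The engine advances each free body's centre-of-mass position, linear
velocity, orientation quaternion and **world-frame angular momentum** with
a fixed-step semi-implicit update (default $10^{-4}$ s internally, outputs
resampled to the 0.01 s reporting step). Two numerical choices matter:

* **Contact damping is implicit.** Summed over ~100 loaded elements the
  damping coefficient reaches several hundred Ns/mm, far beyond what any
  explicit step can integrate stably at a practical $\Delta t$. Each step
  therefore solves a 6 x 6 per-body linear system
  $[M/(1000\,\Delta t) + D]\,u' = M u/(1000\,\Delta t) + W$ in which the
  damping wrench (matrix $D = \sum_i c_i J_i J_i^\top$ over contact
  Jacobians $J_i$) acts at the new velocity; all other forces are explicit.
* **Angular momentum is the integrated quantity.** Because $L$ rather than
  $\omega$ is the state, torque-free motion conserves $|L|$ exactly and no
  gyroscopic term is needed; with conservative forces only, total energy
  drift stays below 1 percent over 10 s at the default step.

One consequence of the implicit damping treatment: the no-adhesion clamp
is applied to the recorded and reported element forces, but the velocity
solve itself uses the unclamped linear damping model. Transient adhesive
impulses are bounded by the smooth-step ramp (damping vanishes as
$\delta \to 0$) and were never observed to matter in practice.

## The synthetic subject

No subject data ship with this kind of model, so `generate_subject()`
builds a deterministic parametric elbow that exercises every pipeline
stage. Geometry is analytic-primitive-based: a cylindrical trochlea
(radius 12 mm) with a congruent ulnar notch spanning 200 degrees, a
spherical capitellum (radius 9 mm) with a congruent radial-head dish, and
a sphere-in-cup radioulnar articulation. Congruence is exact at the
neutral pose (zero penetration), as an assembled joint should be.

Conventions: body-local frames coincide with the world frame at full
extension; +x is medial, +y anterior, +z proximal (with this orientation
the medial/anterior/proximal triad is right-handed); flexion is a rotation
about +x. The humerus is prescribed (static in the bundled trials, as for
an arm strapped into a dynamometer); ulna and radius are free.

Choices a scientist had to make, and why:

* **Masses and inertias** come from the stated densities (bone
  1600 kg/m^3, soft tissue/cartilage 1000 kg/m^3) applied to a bone core
  plus a soft-tissue sleeve per segment — forearm segments of ~0.7 kg
  (ulna side) and ~0.3 kg (radius side), the order of a real forearm.
* **Ligament stiffness defaults** (350/300/350/300/200 N per unit strain
  for MCL-anterior/MCL-posterior/LUCL/RCL/annular bundles) are whole-
  ligament linear stiffnesses from the cadaver literature (~40–70 N/mm)
  split across each ligament's bundles and scaled by typical bundle
  lengths (~15 mm). They are config-driven and overridable.
* **Collateral origins sit on the epicondylar axis.** Real collateral
  ligaments originate at the flexion axis and are therefore nearly
  isometric through flexion; placing the synthetic origins off-axis
  produces large spurious flexion moments from calibration pre-tension
  that no real elbow exhibits.
* **Muscle via points** stand in for the soft-tissue wrap over the distal
  humerus and are placed so flexor moment arms stay in the literature
  20–30 mm band across the flexion range (flexor arms peak near 90
  degrees of flexion). PCSA defaults follow upper-limb model literature
  (570/450/450 triceps, 310/270 biceps, 710 brachialis, mm^2);
  $F_{max} = 0.5\,\mathrm{MPa} \times \mathrm{PCSA}$.
* **Passive joint dampers** (0.3 N m s/rad humerus–ulna, 0.15 ulna–radius)
  represent the measurable passive viscous damping of a human elbow
  (~0.2–0.7 N m s/rad in relaxed arms). They matter: with perfectly
  congruent frictionless surfaces the flexion axis is otherwise entirely
  undamped, and the pull-only force clamp then drives a relaxation
  oscillation that no physical arm shows. The conservative energy-audit
  configuration carries no dampers.
* **Trials**: isokinetic ramps at 10 and 60 deg/s with half-cosine on/off
  ramps and 0.5 s rest holds; a "free" trial with a raised-cosine velocity
  bell peaking at 300 deg/s (the order of a fast volitional movement); a
  16 s laxity sweep covering the flexion range with ±4 degree varus–valgus
  excursions (the in-vivo laxity scale) and smaller internal–external
  wiggles. Default flexion range is 5–95 degrees, chosen so the polyline
  muscle paths keep monotone flexor shortening (beyond ~100 degrees a
  fixed-via polyline re-lengthens, an artefact real wrap surfaces avoid).
  Forearm pose channels carry seeded Gaussian jitter of 0.2 mm / 0.2 deg
  emulating marker noise; the humerus is noise-free (prescribed driver).
* **Surrogate EMG** is a seeded zero-mean Gaussian carrier, amplitude
  modulated by each muscle's normalized force envelope plus a 2 percent
  baseline, at 1400 Hz, so that the EMG processing chain (demean, rectify,
  2nd-order Butterworth low-pass at 6 Hz, trial-maximum normalization)
  recovers the driving envelope.

### What a green closed-loop test does and does not establish

The tracking criterion (flexion–extension RMS error below 3 degrees at
correlation above 0.98, translations below 2 mm, on the synthetic
60 deg/s trial) shows that the whole pipeline — calibration, contact,
ligaments, gain scaling, two-phase control — closes the loop on a
physically plausible joint. It does not validate the model against a real
elbow: the synthetic geometry is idealized (perfectly congruent circular
surfaces, polyline muscles, no capsule), the reference trial is generated
by the same geometry the simulator uses, and the residual ~2 degree bias
is a real property of this class of model (calibration pre-tension
compresses the cartilage by ~1 mm, which feedback controllers tracking
muscle *lengths* cannot distinguish from flexion error).

## Numerical notes and limitations

* Euler sequence for reporting: body-fixed flexion–extension →
  varus–valgus → internal–external about the humeral M–L/A–P/S–I axes (a
  joint-coordinate-system convention); translations are the child frame
  origin in humeral coordinates. Varus–valgus within 1 degree of gimbal
  lock triggers a warning, not an error.
* The Butterworth filter is a single causal pass by default (the
  specification of "second-order" is taken literally); `zero_phase = TRUE`
  applies it forward–backward, doubling the effective order.
* Correlations and RMS errors are computed after linear resampling of the
  prediction onto the reference time grid. "Good correlation" means
  r > 0.8 on the signed coefficient; flat (zero-variance) channels report
  `NA` and are never flagged good.
* The run manifests written by the `cmd_*` commands contain no timestamps
  so that identical inputs and seed produce byte-identical outputs.
* Known limitations: no joint capsule (its mechanical properties are not
  available), no Hill-type activation dynamics (pure PID force control),
  elastic-only ligaments, fixed-step integration, and analytic rather than
  subject-specific geometry in the synthetic subject.

## A short session

```{r, eval = FALSE}
sub <- generate_subject()
model <- sub$model

lax <- generate_trial(model, trial_spec("laxity"))
model$ligaments <- estimate_zero_load_lengths(model$ligaments, lax)

trial <- generate_trial(model, trial_spec("60deg/s"))
targets <- run_inverse_kinematics(model, trial)
res <- run_forward_dynamics(model, trial, targets, duration = 3.2)

ref <- decompose_kinematics(trial, model$frames)
prd <- decompose_kinematics(list(time = res$time, poses = res$poses),
                            model$frames)
build_report(ref, prd)
```
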