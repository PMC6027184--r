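# elbowsim

Multibody simulation of the human elbow in which the joint is held together
by soft tissue and contact rather than an idealized hinge. The package is
aimed at musculoskeletal biomechanists who want concurrent predictions of
bone kinematics, ligament bundle loads, muscle forces and cartilage contact
pressure from a single dynamic simulation.

## The model

Three rigid bodies (humerus, ulna, radius; 18 degrees of freedom, no
kinematic joints) interact through:

* **Ligament bundles** — tension-only nonlinear springs with a parabolic
  toe region,

  f(ε) = ¼ k ε²/εl  for 0 ≤ ε ≤ 2εl,  k (ε − εl)  for ε > 2εl,  0 in
  compression, with ε = (l − l0)/l0 and εl = 0.03. The default complex has
  3 MCL-anterior, 3 MCL-posterior, 3 LUCL, 3 RCL and 2 annular bundles.
  Zero-load lengths l0 are calibrated from a passive laxity sweep as 80 %
  of the maximum (wrapped) origin–insertion path length.

* **Compliant cartilage contact** — the humeral cartilage is tiled into
  ~3 × 3 mm elements; each element exerts the frictionless normal force
  Fc = kc δⁿ + Bc(δ) δ̇ (kc = 40 N/mm, n = 3.05, Bc up to 5 Ns/mm ramping
  in over 0.1 mm of penetration), clamped so damping never adheres.

* **Muscle actuators** — triceps (long/lateral/medial), biceps
  (long/short) and brachialis polyline paths driven by PID controllers
  whose gains scale with cross-sectional area,
  Pᵢ = PCSAᵢ / 487 mm² × 50 (and likewise I = 5, D = 0.0005), forces
  clamped to [0, Fmax] (muscles pull, never push).

Simulation follows the two-phase protocol: *inverse kinematics* replays a
motion trial and records every muscle's length pattern; *forward dynamics*
removes the kinematic constraints and lets the controllers track those
lengths while ulna and radius evolve under gravity, ligament, contact and
muscle forces. Evaluation decomposes the forearm motion into anatomical
rotations (F–E, VR–VL, I–E) and translations (M–L, A–P, S–I) relative to
the humerus and reports per-channel RMS error and Pearson correlation;
EMG is processed by demeaning, rectification, a 2nd-order 6 Hz Butterworth
low-pass and trial-maximum normalization.

A deterministic synthetic subject (parametric bone/cartilage geometry,
laxity sweep, isokinetic 10 and 60 deg/s trials, a fast bell-velocity
trial, surrogate EMG) makes the whole pipeline runnable without subject
data — see the methods vignette (`vignettes/elbow-model.Rmd`) for every
modelling choice and its rationale.

## Worked example

```r
library(elbowsim)

sub <- generate_subject()              # deterministic synthetic subject
model <- sub$model
print(model)
#> elbow_model: 3 bodies (humerus, ulna, radius), 18 DOF, 0 kinematic constraints
#>   ligaments: 14 bundles (annular x2, LUCL x3, MCL-anterior x3, MCL-posterior x3, RCL x3)
#>   muscles: 6; contact pairs: ulnohumeral, radiohumeral, radioulnar-proximal, radioulnar-distal

lax <- generate_trial(model, trial_spec("laxity"))
model$ligaments <- estimate_zero_load_lengths(model$ligaments, lax)
head(attr(model$ligaments, "report"), 3)
#>                   bundle max_length_mm    l0_mm
#> 1  MCL-anterior-anterior      17.08013 13.66411
#> 2   MCL-anterior-central      19.16783 15.33426
#> 3 MCL-anterior-posterior      22.11906 17.69524

trial   <- generate_trial(model, trial_spec("60deg/s"))
targets <- run_inverse_kinematics(model, trial)
res     <- run_forward_dynamics(model, trial, targets, duration = 3.2)

ref <- decompose_kinematics(trial, model$frames)
prd <- decompose_kinematics(list(time = res$time, poses = res$poses),
                            model$frames)
build_report(list(time = ref$time[seq_along(res$time)],
                  channels = ref$channels[seq_along(res$time), ]), prd)
#> kinematics_report: 12 channels, 2/12 good correlations (r > 0.8)
#>    channel unit rms_error correlation  good
#>    ulna_IE  deg      2.28        0.07 FALSE
#>    ulna_VV  deg      3.18        0.03 FALSE
#>    ulna_FE  deg      2.61        1.00  TRUE
#>  radius_IE  deg      1.73        0.02 FALSE
#>  radius_VV  deg      5.16       -0.01 FALSE
#>  radius_FE  deg      2.38        1.00  TRUE
#>    ulna_SI   mm      0.65       -0.00 FALSE
#>    ulna_AP   mm      0.78       -0.06 FALSE
#>    ulna_ML   mm      1.09        0.03 FALSE
#>  radius_SI   mm      0.48        0.13 FALSE
#>  radius_AP   mm      1.24        0.01 FALSE
#>  radius_ML   mm      0.34        0.10 FALSE

max(res$contact$ulnohumeral$peak_pressure)
#> [1] 4.13   # MPa, on the medial (ulnohumeral) cartilage
```

Reading the table: forward dynamics tracks the flexion–extension reference
to within ~2.5 degrees RMS at correlation 1.00 on both forearm bones, and
translations stay within ~1 mm; the off-axis rotation channels are
dominated by joint laxity and marker-noise-scale wobble, mirroring how
such models behave against real experiments. Peak medial contact pressure
during the 60 deg/s flexion is ~4 MPa.

The same pipeline is scriptable from the shell:

```sh
Rscript inst/cli/elbowsim.R synth     --out demo --seed 1
Rscript inst/cli/elbowsim.R calibrate --config demo/model.yaml --laxity demo/trial_laxity.csv
Rscript inst/cli/elbowsim.R simulate  --config demo/model_calibrated.yaml \
                                      --trial demo/trial_60deg_s.csv --out demo/sim
Rscript inst/cli/elbowsim.R evaluate  --config demo/model_calibrated.yaml \
                                      --reference demo/trial_60deg_s.csv \
                                      --result demo/sim --out demo/eval
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantities from
scratch against the installed package (currently the PCSA-based controller
gain assignment, built through the muscle-actuator constructor) and writes
them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
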