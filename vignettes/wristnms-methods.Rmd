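---
title: "Model-based myoelectric mapping at the wrist: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based myoelectric mapping at the wrist: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wristnms)
```

## The problem

Myoelectric interfaces estimate a user's intended joint motion from muscle
electrical activity. The classical route extracts amplitude and complexity
features from the interference surface EMG and trains a generic regressor
(here: a small feed-forward ANN) directly on joint angles. `wristnms`
implements the model-based alternative: high-density EMG decomposition
yields motor-neuron discharge timings (taken as input here — the
decomposition itself is out of scope), discharge counts are mapped by
robust linear regression to *muscle excitations*, and a musculoskeletal
model of the wrist turns those excitations into joint kinematics by
open-loop forward dynamics. The promise of the model-based path is
robustness: missing spikes and missing units perturb a median ensemble of
per-unit regressors far less than they perturb a monolithic regression,
and the biomechanical model constrains the output to physically coherent
trajectories.

The package contains every stage plus a synthetic neuromuscular data
generator, so the whole chain is testable end to end without any recorded
data.

## Pipeline

1. **Windowing** (`build_window_grid`): all stages share one sliding-window
   grid of 100-ms windows. The window increment defaults to 10 ms. The
   phrase "10-ms overlap" in the motivating literature is ambiguous
   between a 10-ms increment and a 90-ms increment; both grids work
   everywhere in this package. The 10-ms increment is the default because
   it is the standard in myoelectric regression and because at 2.5-s
   trials the 90-ms grid leaves too few windows (27 per trial) to train
   the per-muscle fallback ANNs without memorization.
2. **DSC feature** (`extract_dsc`): per window and motor unit, the number
   of discharges in the half-open interval `[start, start + 0.1)`.
   Half-open windows count boundary spikes exactly once; a spike at
   exactly the trial end falls outside the last window and is dropped.
3. **Calibration** (`tracking_excitations`): from recorded kinematics,
   scaled to the model's joint limits (`fit_scaler`), a computed-muscle-
   control style loop derives the excitations that reproduce the motion:
   PD acceleration tracking (`kp = 400 1/s^2`, `kv = 40 1/s`, one window
   step of lookahead), muscle redundancy resolved per control step by
   minimizing the sum of squared activations subject to the required
   torque (a bounded least-squares problem, since the rigid-tendon Hill
   force is linear in activation), and antagonists forced to zero while
   the actuated angle's magnitude grows (slope of a 50-ms moving average).
   Excitations are recovered by exact inversion of the first-order
   activation dynamics and clipped to `[0, 1]`. Because the loop advances
   the model itself with the computed excitations, the result is
   dynamically consistent: replaying it open loop reproduces the tracked
   kinematics (this is the package's core integration test, R^2 >= 0.95
   per DoF).
4. **Neural mapping** (`assign_units`, `fit_unit_regressor`,
   `train_neural_model`, `predict_excitations`): units are assigned to
   every muscle whose calibration excitation is positive (tolerance 1e-6)
   at >= 80% of their discharges, pooled over all calibration trials;
   each assigned (muscle, unit) pair gets a robust linear model
   (IRLS, Tukey bisquare, c = 4.685, MAD scale, fitted only on the unit's
   spike-containing windows); prediction takes the median over the
   currently active units' estimates (even count: midpoint), clamped to
   `[0, 1]`, falling back to a per-muscle ANN on time-domain EMG features
   when no assigned unit fires in a window.
5. **Musculoskeletal model** (`wrist_model`, `forward_simulate`): six
   rigid-tendon Hill-type muscle-tendon units (FCR, FCU, ECRL, ECU, PT,
   SUP) with constant signed moment arms on three DoFs, Gaussian active
   force-length (width 0.45), hyperbolic force-velocity (1 at zero
   velocity, eccentric plateau 1.8), exponential passive force that is
   zero at and below optimal length, first-order activation dynamics
   (tau 15/60 ms), per-DoF lumped inertia, passive stiffness and damping,
   integrated by fixed-step RK4 at 1 kHz with zero-order-held excitations
   and clamp-and-zero-velocity joint limits.
6. **Gating and output** (`gate_excitations`, `run_dsc_nms`): single-DoF
   gating (below), forward simulation, inverse scaling to recorded units.
7. **Baselines** (`preprocess_emg`, `extract_td`, `fit_pca`, `train_ann`,
   `predict_ann_dof`): rectification then zero-phase 4th-order Butterworth
   band-pass 20-500 Hz (in exactly that order, as the comparison method
   prescribes; a switch offers the conventional order), RMS/SSC/ZC/WL per
   channel and window (deadband 1% of channel RMS), PCA retaining 98% of
   training variance (loadings from training folds only), one 3-hidden-
   neuron tanh network per DoF trained by Levenberg-Marquardt, best of 50
   random restarts selected on a held-out 20% validation split, estimates
   low-pass filtered at 1.5 Hz (zero phase). `td_dsc` concatenates the
   DSC block behind the TD block before the same PCA and regression. The
   model-based path is never low-pass filtered.
8. **Evaluation** (`crossvalidate`, `compare_methods`): three-fold
   cross-validation over the three repetitions (an independent random
   permutation per direction-of-DoF task per repeat; two repetitions
   train, one tests), 10 repeats by default, R^2 and RMSE (degrees,
   recorded units) per DoF on test trajectories concatenated across test
   trials (a per-trial switch exists). Everything fitted — scaler, CMC
   excitations, assignment, unit regressors, PCA loadings, ANNs — sees
   training folds only.

## Single-DoF gating

A DoF-direction counts as actuated when *all* its agonists are active:
flexion {FCR, FCU}, extension {ECRL, ECU}, radial {FCR, ECRL}, ulnar
{FCU, ECU}, pronation {PT}, supination {SUP}, with activity threshold
`eps = 0.01` excitation units and set strength defined as the smallest
agonist excitation. Three design choices extend the published rule, which
only specifies the unique-complete-pair case:

- **Segment claims.** Gating is decided per movement segment (maximal run
  of windows with any muscle active). If any complete set occurs in the
  segment, the set with the largest time-integrated strength claims its
  DoF for the whole segment and the other DoFs are reported as zero.
  Window-by-window gating is unusable in practice: at movement onset one
  agonist always crosses the threshold a few windows before its partner,
  which would dribble drive into the wrong DoF in every trial. Ranking by
  integrated rather than peak strength makes the claim immune to
  single-window noise spikes in the fallback estimates.
- **Lone muscles.** If a segment never completes a set, a lone
  flexor/extensor/deviator leaves both wrist DoFs estimated (as the rule
  prescribes) and pronation/supination follows its own agonist.
- **Spike evidence.** Detection rests on neural evidence: for gating
  purposes a muscle counts as active in a window only when at least 25%
  of its assigned units (at least one) are discharging, and segments
  without any such evidence are treated as rest. Two failure modes force
  this. First, the ANN fallback's output at rest is extrapolation — its
  noise would otherwise open spurious movement segments. Second, the 80%
  coincidence rule multi-assigns units liberally (as the motivating
  method's own assignment tables show), and in windows where *only*
  cross-assigned units fire — e.g. two flexor-generated units among the
  twenty-two assigned to an extensor — the median over those units
  fabricates antagonist activity. A genuinely recruited muscle fires many
  of its low-threshold units simultaneously, so a pool-fraction criterion
  separates the two cases without any amplitude threshold. The
  excitations that *drive* the model keep their full median/fallback
  estimates; only detection is restricted.

## The synthetic world

The generator emulates the stated experimental protocol: triangular
single-DoF tasks (1-s ramp, 500-ms pause, 1-s return; ranges of motion
FE 1.2, RU 0.4, PS 1.4 rad), three repetitions of each direction of each
DoF in seed-randomized order (18 trials per subject).

- **Ground truth** excitations come from `tracking_excitations` on the
  noiseless model, so truth is dynamically consistent by construction.
- **Motoneuron pools**: 20 units per muscle, recruitment thresholds
  uniform in [0, 0.6], rate `min(35, 8 + g (e - theta))` pps with gains
  `g` in [40, 60], Gaussian-renewal inter-spike intervals with CoV 0.2
  (truncated at 20% of the mean interval). This is the simplest
  physiologically plausible operationalization of rate coding; it yields
  unit counts per trial (~20-40 active) consistent with published
  decomposition yields (~19 per DoF).
- **Decomposition-like corruption**: each spike deleted with probability
  0.1; each unit deleted from a repetition with probability 0.15; all
  spikes deleted while the actuated angle is below 20% of the range of
  motion — the failure modes reported for dynamic-contraction
  decomposition.
- **Surrogate EMG** (2048 Hz): one interference source per muscle,
  amplitude-modulated by the muscle's excitation and spectrally shifted
  from a 20-150 Hz band towards 150-500 Hz as excitation grows, mixed
  across channels by a fixed per-subject montage (each channel dominated
  by the muscle it sits over, weaker crosstalk from the rest) plus
  independent per-channel baseline noise (sd 0.02). Three properties of
  real high-density recordings matter and are deliberately reproduced:
  channels are strongly correlated (volume conduction — a single shared
  source per muscle), the montage is fixed across trials of a subject
  (an electrode grid does not move between repetitions), and both
  amplitude and complexity features carry excitation information (the
  spectral shift). What is *not* modelled: motor-unit action potential
  waveforms, electrode geometry, motion artifacts. A green baseline test
  therefore establishes that the TD+ANN machinery works, not that it
  would reach the same accuracy on real EMG.

## Model constants and why

| quantity | value | rationale |
|---|---|---|
| f_max (N) | FCR 100, FCU 130, ECRL 120, ECU 90, PT 300, SUP 250 | wrist-scale isometric strengths; chosen so peak task torques need mid-range excitations without saturation |
| l_opt | 6 cm, v_max 10 l_opt/s | typical forearm fiber scale |
| moment arms | 8-15 mm, signs per muscle function; PT/SUP wrist cross-moments 0 | their contribution to FE/RU is negligible in this reduced model |
| inertia | FE/RU 0.004, PS 0.002 kg m^2 | hand-about-wrist scale |
| stiffness K | FE 1.0, RU 2.5, PS 1.0 N m/rad | passive posture holding; K_RU is larger so that the deviation DoF (smallest range, 0.4 rad) also operates at mid-range excitations — with uniform K its peak excitation is ~0.2 and the discharge-count feature (1-2 spikes per 100-ms window) cannot resolve it |
| damping B | 0.2 N m s/rad per DoF | well-damped return without feedback |
| activation tau | 15 ms / 60 ms | standard Hill-model values |
| integrator | RK4, 1 kHz, zero-order-held excitations | step-halving changes trials by < 1e-4 rad |
| rest offset | passive muscle force is zero at rest; posture held by K | replaces the published trick of rescaling maximal forces so rest excitations are zero; functionally equivalent and verifiable (`verify_rest_equilibrium`) |

Numerical tolerances: static-optimization torque residual 1e-3 N m (above
it the step is flagged saturated and the best bounded solution is used);
IRLS convergence 1e-8 on coefficients, 50 iterations; a perfect fit
(MAD scale below 1e-12) terminates IRLS at the OLS solution, since
reweighting is undefined; LM stops on gradient < 1e-10, relative SSE
improvement < 1e-7, damping > 1e8 or 50 iterations, keeping the cost of
hundreds of restarted fits bounded.

## Degenerate inputs and edge rules

- A zero-variance reference makes R^2 undefined: `r2` refuses rather than
  returning a sentinel.
- A unit whose spike counts never vary cannot identify a slope:
  `fit_unit_regressor` raises a rank-deficiency error and
  `train_neural_model` simply skips the pair (the muscle then relies on
  its other units or the fallback).
- A muscle with no assigned units is flagged fallback-only.
- Scaling requires a nonzero recorded range in both directions of every
  DoF; the scaler maps positive and negative excursions separately so the
  rest position is preserved exactly.
- Excitations and activations are clamped to `[0, 1]` wherever dynamics
  inversion or regression overshoots.

## What the synthetic comparison can and cannot show

Decomposition corruption (missed spikes, per-repetition unit dropout, the
low-angle silent band) degrades only the spike-train path. The surrogate
EMG is synthesized directly from the true excitations and is never
corrupted, so the TD baseline sees an uncorrupted, highly informative
signal — an advantage real interference EMG does not have (motor-unit
action-potential superposition, noise and nonstationarity are explicitly
outside the generator's scope). Measured over five corrupted subjects,
the model-based path degrades gracefully (per-subject mean held-out R^2
roughly 0.3-0.7 against 0.94 pristine) while the TD baseline holds near
0.5; the published finding that the model-based path *outperforms* TD
under decomposition stress rests exactly on the real-EMG nonidealities
this generator does not model, and is therefore not reproduced (nor
contradicted) here. What the corrupted world does establish, and what the
suite tests, is that single-DoF gating keeps claiming the correct DoF for
every corrupted trial and that the assignment step still recovers >= 90%
of units.

## Assignment tolerance

"Excitation greater than zero" at discharge times needs a tolerance. The
calibration's PD loop leaves numerical dust in mechanically idle windows,
so the tolerance sits at 1e-3 — the same scale as the static
optimization's torque-residual tolerance — rather than machine-epsilon
territory; below that floor, units are cross-assigned to muscles that
merely twitched numerically.

## Known limitations

- The wrist model is a desk-scale substitute for a full musculoskeletal
  model: rigid tendons, constant moment arms, lumped inertia, no gravity
  or grasp DoFs. All constants are surfaced in `wrist_model()` and the
  YAML round-trip, and are stand-ins, not anthropometry.
- The synthetic world shares its calibration machinery with the method
  under test (truth is CMC-generated), which is exactly what makes the
  end-to-end recovery test well-posed, but also means the tests cannot
  detect a bias common to both directions of the model.
- Multi-DoF simultaneous movements and online operation are out of scope.
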