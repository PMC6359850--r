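---
title: "Gait phase recognition with logistic model trees: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait phase recognition with logistic model trees: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
```

## The problem

A stance-control knee-ankle-foot orthosis must engage knee-flexion
resistance while the limb bears weight and release it for swing. Switching
at the wrong instant is not symmetric in cost: releasing during stance can
drop the user, while a late release merely perturbs swing. The controller
therefore needs a per-instant estimate of the current gait phase from
sensors local to the brace — knee flexion angle and a thigh-mounted IMU
(triaxial angular velocity and acceleration) — with decision latency on the
order of 10 ms.

The stride is partitioned into four phases delimited by four events:

| Phase | From | To |
|---|---|---|
| Loading Response (LR) | initial contact | mid-stance |
| Push-Off (PO) | mid-stance | foot-off |
| Swing | foot-off | maximum knee flexion |
| Terminal Swing (TSw) | maximum knee flexion | next initial contact |

Phase intervals are half-open, `[start, end)`: each sample carries exactly
one label, and the pairing of the four events to the four phase onsets is
the only order-consistent assignment of a cyclic sequence of four events to
four cyclic phases.

## Recognition pipeline

Signals are processed at 200 Hz. A 0.1-s window (20 samples) slides in
0.01-s steps (90% overlap); each window yields 20 features and is labeled
by its **last** sample, because the prediction is consumed "now", at the
newest instant the window covers. The features are plain window statistics
(means, population variance, range, extrema), per-axis sign-sums
(+1 per positive sample, −1 per negative, 0 for an exact zero), the peak
count of the resultant acceleration, the dominant non-DC FFT frequency of
the y-axis angular velocity, and the Pearson correlation between the z-
(gravity-aligned in stance) and y-axis (heading-aligned) accelerations.
None requires more than one pass over 20 samples, which is what makes the
pipeline realistic for embedded joint electronics.

Three interpretation choices are deliberately pinned down and documented
because window statistics admit variants:

* *"maximum difference"* is the range `max − min` (the separate min/max
  features imply the range is a distinct statistic);
* *variance* is the population form (divide by *n*): a window is the whole
  population of interest and *n* is fixed at 20, so the choice is a pure
  rescaling — but it must be fixed for reproducibility;
* the *principal frequency* excludes the DC bin (offset-bearing channels
  would otherwise always report 0 Hz) and resolves magnitude ties —
  including floating-point near-ties within 1e-9 relative — toward the
  lowest frequency, so the feature is deterministic across platforms.

## The classifier

The Logistic Model Tree combines a decision tree's piecewise partition with
logistic models in the leaves:

* **Splits** maximize information gain on the class variable; candidate
  thresholds are midpoints between consecutive distinct sorted values of
  each feature. Ties in gain resolve to the lower feature index, then the
  lower threshold. A node is split only while it holds at least
  `min_instances` (default 15) instances, is impure, and a positive-gain
  split exists.
* **Leaves** hold one coefficient vector per class, built by multiclass
  LogitBoost: each iteration fits one weighted simple linear regression
  (best single feature) per class to the working responses and adds the
  centred update `(J−1)/J (f_j − mean_k f_k)` to the class scores. Because
  every base learner is linear, the committee collapses to a single linear
  score per class, and class probabilities are the softmax
  `exp(F_i)/Σ_j exp(F_j)` — in the two-class case exactly the logistic
  sigmoid. With four phases a cross-class normalization is required; the
  softmax is the one the multiclass LogitBoost formulation induces, and it
  reduces to the binary form when two classes remain.
* **Warm starts**: each child continues boosting from its parent's
  coefficients, so deep leaves refine rather than restart.
* **Iteration count**: chosen once at the root by stratified 5-fold
  cross-validation over 1..200 iterations and reused at every node (the
  fast-regression heuristic; the default). Setting
  `fast_regression = FALSE` re-selects the count at every node, which is
  the full heuristic but substantially slower.
* **Pruning**: CART cost-complexity pruning. The weakest-link α sequence is
  computed on the error-*rate* scale (so thresholds are comparable between
  the full tree and fold trees grown on less data), the α grid is evaluated
  by stratified 5-fold cross-validation, and the largest α within one
  binomial standard error of the minimum is selected (1-SE rule). The
  procedure's CV trace is kept on the model (`model$pruning`), and the
  contract — the chosen tree's CV error is within one SE of both the
  CV-minimal and the unpruned tree — is asserted on that trace. An
  *external* re-estimate of this comparison on 90%-overlapping windows at
  small scale is dominated by estimator noise and is not a guarantee any
  cost-complexity implementation makes.

Numerical safeguards: leaf scores are clipped to ±500 before
exponentiation, and the softmax exponent is floored at −700, so
probabilities are always finite, strictly positive, and sum to 1 without
changing any argmax. Working responses are clipped at |z| ≤ 3 (the usual
LogitBoost stabilization). Plain Newton-style LogitBoost steps do not
guarantee a monotone objective, so each iteration backtracks the step size
(1, ½, ¼, ⅛) until the training negative log-likelihood does not increase,
and boosting stops early if no step helps; this makes "the objective is
non-increasing per iteration" a hard invariant rather than a tendency. The
only randomness in training is the internal CV fold assignment, controlled
by `lmt_control(seed = )`; induction is otherwise deterministic given the
data.

The split criterion is plain information gain, not C4.5's gain ratio: the
two are not equivalent, the reference description names information gain on
the class variable explicitly, and gain ratio's normalization matters
mostly for many-valued categorical attributes, which do not occur here (all
20 features are numeric with binary splits).

## TSVC: sequence correction

The corrector is purely symbolic — it never consults the classifier's
probabilities — and fires only when the three previously *accepted* labels
are identical (a stable history `h`):

* **Rule A**: an incoming label that differs from `h` and is not
  `successor(h)` is an impossible transition (it would skip at least one
  phase) and is relabeled to `h`. This also covers two-ahead jumps such as
  LR → Swing.
* **Rule B**: an incoming `successor(h)` is ambiguous — a real transition
  or an isolated outlier — so it is held for exactly one step. If the next
  label returns to `h`, the held instance is relabeled to `h`; otherwise it
  is released unchanged. The cost is one window step (10 ms) of latency,
  the only latency the corrector introduces.

When the history is not stable (including the first three instances of a
stream) no relabeling is applied: the rules are defined relative to a
stable three-label history, and correcting against a disagreeing history
would amount to guessing. The streaming state is explicit
(`tsvc_state()` / `tsvc_step()` / `tsvc_flush()`), emission order equals
arrival order, and the batch wrapper `tsvc_correct()` is idempotent on its
own output. Phase changes in the corrected stream indirectly mark the gait
events (TSw → LR is initial contact, and so on), which is how the pipeline
reports events without a dedicated event detector.

## Evaluation conventions

Metrics are one-vs-rest per phase (sensitivity, specificity, precision,
F-score, Matthews correlation coefficient) from a pooled confusion matrix,
with instance-weighted averages `W_m = Σ m_i I_i / Σ I_i`. Ratios with a
zero denominator are reported as 0 and *flagged* rather than propagated as
`NaN`: weighted averages must remain computable, and the flag preserves
auditability. Cross-validation is stratified per class (per-class fold
sizes differ by at most one). Pooled-CV reporting is the default;
resubstitution is available because "reiterating through the supplied
training set" is a defensible alternative reading of how training metrics
can be computed. TSVC is applied to the pooled predictions per contiguous
recording in window order — never across recording boundaries, where a
label history would be meaningless.

## What the simulator emulates — and what it does not

The simulator exists so every downstream stage is testable without any
proprietary motion-capture data. Each stride is a deterministic template
plus seeded stochasticity:

* knee angle: a stance flexion wave (raised cosine near 16% of the stride)
  plus an asymmetric swing flexion peak of ≈ 55–60° confined to
  (foot-off, next contact), whose realized argmax *defines* the
  max-knee-flexion annotation;
* x-axis angular velocity proportional to the knee-angle rate (so its zero
  crossings sit near knee-angle extrema); y- and z-axes are low-order
  sinusoids;
* z-axis acceleration carries the gravity offset (≈ 9.81 m/s²) through
  stance and dips in swing; y-axis carries a push-off burst.

Speed acts through three monotone couplings chosen to mirror the
qualitative structure of treadmill data: stride time
`1.1 · sqrt(1.33 / v)` s (≈ 1.1 s self-paced, ≈ 2.0 s at 0.4 m/s — no
cadence data exist to calibrate against, so a smooth inverse relation
anchored at the self-paced point is used); stance flexion amplitude
`2 + 16 (v/1.33)^1.2` degrees (stance knee motion shrinks as walking
slows); and both inter-stride jitter and additive channel noise scale with
`1.33 / v` (variability grows as walking slows). Surfaces are mild additive
template modifiers (up-slope raises stance knee flexion, cross-slopes bias
the medio-lateral channels) rather than regime changes, matching the
observation that curve shapes stay similar across surfaces. Default
per-channel noise SDs are 0.5° (knee angle), 0.05 rad/s (angular velocity)
and 0.25 m/s² (acceleration) — plausible magnitudes for filtered IMU-grade
signals. The jitter and noise scalings are kept on separate knobs
(`variability_scale`, `noise_sd`) so either source can be switched off
independently.

Two cohort presets mirror the study design the simulator stands in for:
`"training"` (30 virtual subjects × 4 speeds × 5 surfaces × 10 strides,
self-paced speed ~ N(1.33, 0.04) m/s) and `"validation"` (12 subjects ×
self-paced ~ N(1.41, 0.34) × 5 surfaces × 6 strides). Every dimension can
be overridden for reduced runs.

What passing tests on this generator shows: the pipeline's plumbing,
determinism, and separability mechanics — that the features carry phase
information, the LMT recovers it far above the majority baseline, and TSVC
repairs sequence violations. What it does **not** show: performance on real
gait. The templates are not biomechanically validated; there is no
soft-tissue artifact, sensor drift, pathological gait, or inter-subject
kinematic idiosyncrasy beyond amplitude/timing jitter. Synthetic
accuracies (≈ 97%) therefore characterize the implementation, not the
clinical problem, and the original study's printed accuracies are neither
reproducible from — nor asserted against — this generator. Only right-limb
conventions are emulated; left-limb sign conventions are undefined in the
source material and are deliberately not invented here.

## Numerical and degenerate-input choices

* Zero-phase (forward-backward) Butterworth filtering is used for offline
  conditioning, since phase lag would shift event annotations; the signal
  is reflect-padded (odd symmetry, 10 / f_c seconds per side) so startup
  transients decay outside the retained segment. The streaming path
  classifies raw windows and does not filter.
* Linear resampling preserves the first sample exactly and spans the same
  duration; at equal rates it is the identity.
* A constant window reports principal frequency 0 (no non-DC energy) and
  correlation 0 (zero variance), keeping every feature finite on degenerate
  input.
* `sign_sum` scores exact zeros as 0: zero is neither positive nor
  negative.
* Peaks are strict interior maxima with no prominence threshold — counts
  are deterministic on plateau-free synthetic data, and a plateau
  contributes no strict maximum.
* Serialized models are JSON at full floating-point precision; a round
  trip preserves predictions exactly (class decisions) and probabilities to
  ≤ 1e−12.

## Problem sizes

The test suite runs its end-to-end recovery check on a reduced cohort (3
virtual subjects × 2 speeds × 2 surfaces × 3 strides ≈ 10⁴ windows);
`scripts/acceptance.R` uses 4 subjects × 2 speeds × 3 surfaces × 3 strides
(≈ 10⁴ labeled windows) for cross-validation and a 3-subject validation
cohort, sizes at which the full pipeline — feature extraction, iteration
selection, growth, pruning, 5-fold CV, TSVC — completes in a few minutes on
a single core while leaving the accuracy-versus-baseline margin (> 60
percentage points) far above the ≥ 30-point criterion it is checked
against.

## Known limitations

* The tree is binary with axis-aligned numeric splits only; nominal
  attributes and WEKA's auxiliary options (AIC-based stopping, weight
  trimming, residual splits) are out of scope.
* TSVC assumes a single cyclic grammar; standing still, turning, or
  stopping mid-stride violate its premise, and very slow walking — where
  signal variation approaches the noise floor — would need either a
  static-versus-dynamic state gate or speed-specialized models.
* The pruning CV re-grows fold trees with the root-selected iteration
  count rather than re-running iteration selection per fold: a deliberate
  cost/fidelity trade-off, consistent with the fast-regression heuristic.
* `fast_regression = FALSE` is implemented faithfully but is quadratic-ish
  in practice; it exists for completeness, not routine use.
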