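---
title: "Stable-pressure extraction and concurrent validity for bridging tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable-pressure extraction and concurrent validity for bridging tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgepress)
```

## The measurement problem

Supine lumbopelvic movement — here, modified hip bridging performed inside
an MRI bore — cannot be monitored with the usual tools: optical markers and
surface EMG electrodes are inaccessible under a supine participant, and most
of the movement happens out of sight. A closed air-pressure system solves
this with four bladders: one under each knee (channels RK, LK) embedded in a
rigid foam roll, and one under each side of the lower back (RB, LB). Two
readouts run in parallel on the same closed air circuit:

* a **digital** differential-pressure stream at 28 Hz, for offline
  time-series analysis, and
* four **analog** dial gauges, watched in real time and read to their 2 mmHg
  precision, one reading per trial.

A bridge (pelvic lift) presses the knees into the roll — knee pressure rises
— and lifts the lower back off its bladders — back pressure falls. The three
tasks are a bilateral bridge (BB, both knees press) and unilateral right and
left bridges (URB, ULB, one knee presses while the other must not). Each
task is repeated six times with a 10 s hold.

`bridgepress` implements the full analysis chain for such recordings:
stable-pressure extraction from the digital stream, task-compliance
classification, and the concurrent-validity statistics comparing digital
against analog readings — plus a calibrated simulator that generates
sessions with known ground truth, so every stage can be tested by parameter
recovery rather than on unavailable recordings.

## Stable-pressure extraction

For each trial and channel the quantity of interest is the *stable
pressure*: the plateau held during the bridge (a stable maximum for rising
channels, a stable minimum for falling ones). The pipeline is:

1. **Zero-phase low-pass filtering** (`filter_dualpass()`). A Butterworth
   filter (order 2 per pass, 2 Hz cutoff) is applied forward and then
   backward. The dual pass cancels phase lag — event times are not shifted —
   and squares the magnitude response, so the gain at the cutoff is
   $(2^{-1/2})^2 = 1/2$ and the DC gain is exactly 1. The signal is extended
   at both ends by odd reflection and each pass starts from its steady
   state, confining edge transients to the discarded extension; traces must
   be at least `3 * (order + 1)` samples long.
2. **Velocity** (`compute_velocity()`): central differences on interior
   samples (exact for quadratics), one-sided at the edges, in mmHg/s.
3. **Event detection** (`extract_stable_value()`): within the first 2 s
   after the movement cue, the signed velocity extremum is found — maximum
   for a rising channel, minimum for a falling one. The first later sample
   where the velocity changes sign (exact zeros count) marks the end of the
   movement ramp.
4. **Plateau averaging**: after a 1 s delay from that zero-crossing, 4 s of
   filtered pressure are averaged. Trials fail with an explicit reason
   rather than a value: `no_movement` (peak velocity below 1 mmHg/s),
   `no_zero_crossing`, or `window_truncated` (the 1 + 4 s window does not
   fit inside the plateau — any hold under 5 s is unextractable by
   construction).
5. **Six-trial averaging** (`summarize_trials()`): the per-task mean over
   valid trials only, with `n_valid` reported and empty cells flagged
   missing instead of silently zero.

Design choices in this chain that the methodology leaves open:

* **Filter order**: order 2 per pass, the common biomechanics convention;
  configurable through `filter_spec()`.
* **Peak velocity on falling channels** is the signed *minimum* (most
  negative velocity), since back pressure falls during the lift.
* **Zero-crossing localisation** is the first grid sample whose velocity
  sign differs from the peak's; no sub-sample interpolation is attempted,
  because the subsequent 1 s delay and 4 s average make sub-sample timing
  immaterial.
* **Search windows**: the peak is searched within 2 s of the cue; the
  zero-crossing search then runs to the end of the plateau by default. An
  optional `zc_search_limit_s` restricts it to a fixed horizon after the
  peak for recordings where a bounded search is preferred. The unrestricted
  default is the more robust reading: a crossing slightly later than 2 s
  after the peak still yields a window well inside a 10 s hold.
* **Movement threshold**: 1 mmHg/s on the peak velocity, to reject
  no-movement trials; small but non-zero so the slight unloading of the
  unused knee (about 2–3 mmHg over a 1.5 s ramp) still registers as
  movement.
* **Extraction direction** (`extraction_directions()`): knees rise and
  backs fall, except the *unloaded* knee of a unilateral bridge, which
  partially unloads as the pelvis lifts from one side; it is extracted as a
  decrease. This follows the observed behaviour of the system — the
  unloaded-knee cells are part of the validity analysis, so they must be
  extractable — rather than a literal knee-always-rises convention, which
  would discard them as `no_movement`.

## Task compliance

`expected_pattern()` fixes the per-channel direction requirements: BB — both
knees increase, both backs decrease; URB — RK increases, LK must *not*
increase, both backs decrease; ULB is the exact mirror. `classify_trial()`
thresholds the per-trial change (stable value minus the mean filtered
pressure over the 2 s before the cue) at ±3 mmHg: an increase requires
delta ≥ +3, a decrease delta ≤ −3, and `no_increase` passes while
delta < +3. The 3 mmHg default matches the scale of digital–analog
agreement, so compliance is never asserted on changes smaller than the two
readouts agree with each other; the pre-cue local baseline makes the deltas
robust to slow drift. A trial with an unextractable channel is
*non-assessable*, a distinct outcome from non-compliant. Because how
non-compliant trials were handled upstream of published summary tables is
generally unknown, the validity layer makes no compliance-based exclusion;
users can filter on the compliance table themselves.

## Concurrent validity

`build_validity_report()` computes, per task × channel cell of paired
digital/analog stable values:

* **Spearman's rho** with a 95% CI from the Fisher z transform using the
  Bonett–Wright standard error $\sqrt{(1 + \rho^2/2)/(n-3)}$,
  back-transformed. The CI construction used with the original recordings
  is not documented anywhere, so this standard rank-correlation interval
  was chosen; a percentile bootstrap is available via
  `ci_method = "bootstrap"` as a sensitivity check. Cells below the
  acceptability rule ρ ≥ 0.9 are flagged.
* **Bland–Altman** agreement: differences d = digital − analog (this sign
  convention is fixed package-wide), bias = mean(d), limits of agreement
  bias ± 1.96 sd(d) with the n−1 sample SD, the count of differences
  outside the limits, and a proportional-bias slope from regressing d on
  the pair means.
* **Normality screening** (`normality_screen()`, Shapiro–Wilk at 0.05)
  motivates the rank-based correlation; pressure plateaus are bounded and
  often skewed, and rank methods cost little when normality holds.
* No multiplicity correction is applied across the 12 cells; the report
  carries raw p-values and records the number of tests.

**Pairing level.** At `level = "trial"` each repetition contributes one
pair, pooled across participants (23 participants × 6 trials = 138 pairs
per cell); at `level = "participant"` the six trials are averaged first.
Trial-level pairing is the default: confidence intervals as narrow as those
reported for this system (e.g. 0.970 [0.958, 0.979]) arise from
hundred-scale n, not from 23 participant means. Both levels are
implemented, and neither is asserted to be "the" published computation.

**Power analysis.** `required_sample_size()` implements the Fisher z
approximation
$n = \lceil ((z_{1-\alpha} + z_{power}) / (\operatorname{atanh}\rho_1 -
\operatorname{atanh}\rho_0))^2 + 3 \rceil$.
With $\rho_1 = 0.9$, $\rho_0 = 0.7$, power 0.80 and α = 0.05 it returns 20
**one-tailed** (25 two-tailed). One-tailed is the package default because it
is the variant that reproduces the design value of 20 under this
approximation, and because the design question is directional (is the
correlation *at least* as strong as required).

## What the simulator emulates

`simulate_session()` generates the underlying continuous trajectory of each
channel as baseline + delta × smoothstep ramp per trial (+ optional
random-walk drift), then renders it through both readouts: the digital
stream (28 Hz samples + i.i.d. Gaussian sensor noise) and the analog
reading (trajectory averaged over the middle half of the hold + Gaussian
observer noise, rounded to the 2 mmHg gauge precision). Defaults and the
reasoning behind them:

* **Plateaus** (`reference_session_config()`): calibrated so the noiseless
  plateaus equal the published digital means per task × channel (e.g. BB RK
  50.84 mmHg, ULB LK 56.54 mmHg). Knees rest at 44 mmHg and backs at
  20 mmHg; baselines are not published, and these values make every delta's
  sign physical: pressed knees +7 to +14, backs −7 to −11, the unloaded
  knee of a unilateral bridge −2 to −3 (the published means show that knee
  dropping below its bilateral value).
* **Ramp**: smoothstep (C¹ sigmoid) over 1.5 s — a smooth transition with a
  single well-defined velocity peak, matching the qualitative shape of real
  traces; no published value exists.
* **Timing**: 10 s holds, six repetitions per task, 5 s rest before each
  cue (rest duration is unpublished; 5 s comfortably exceeds the 2 s
  pre-cue baseline window). Trials are laid out in task blocks with
  explicit cue times; ordering affects no computed statistic.
* **Noise**: digital sensor noise SD 0.5 mmHg (a visually realistic jitter
  for a silicon differential sensor at this range); analog observer noise
  SD 1.4 mmHg, chosen so the combined trial-level digital−analog difference
  SD lands near 1.5 mmHg — consistent with reported mean differences under
  3 mmHg and no visible bias. Drift defaults to 0 and is exposed for
  robustness experiments.
* **Cohort heterogeneity** (`simulate_cohort()`): per-participant baseline
  offsets (SD 5 mmHg per channel — each participant's system is pressurised
  to their own posture) and a log-normal effort multiplier per participant
  × channel (sdlog 0.25), which scales deltas without flipping their sign.
  Together these reproduce between-participant stable-pressure SDs of
  5–7 mmHg, the published scale. Heterogeneity is what makes trial-level
  correlation meaningful: within one session the true plateau is constant,
  so digital–analog ranks are pure noise.

What the simulator does **not** emulate: air-hose transmission dynamics,
bladder mechanics, scanner vibration, head-motion artefacts, video reading
errors beyond Gaussian-plus-quantization, non-stationary participant
fatigue, and any systematic analog-vs-digital offset (published means show
channel-specific offsets up to about 2 mmHg; the simulator's analog readout
is unbiased). Passing recovery and validity tests on simulated sessions
therefore demonstrates the correctness of the algorithms under realistic
signal structure — not the field performance of the hardware.

## Numerical and degenerate-input behaviour

* Filtering a constant trace returns it exactly (steady-state
  initialisation); cutoffs at or above Nyquist and too-short traces are
  rejected with explicit messages.
* Extraction is equivariant under constant pressure shifts, and all timing
  marks are reported on the sample grid.
* `spearman_with_ci()` refuses n < 4, missing pairs, and zero rank
  variance, naming the offending cell; at |ρ| = 1 the Fisher interval
  degenerates to the point itself. Within `build_validity_report()` a
  degenerate cell is reported as missing values rather than aborting the
  whole report.
* Quantization uses round-to-nearest-multiple; in the zero-observer-noise
  limit the analog error is bounded by half the gauge precision.
* Seeding: one session seed deterministically derives independent
  substreams per channel for sensor noise, drift, and observer noise, so
  results are bit-reproducible and one channel's realisation never depends
  on another's presence.

## Problem sizes used in the test suite

The bundled tests run the full chain at the study's own scale where that is
what is being claimed — the end-to-end validity gate simulates 23
participants × 18 trials × 4 channels (1,656 extractions, 138 pairs per
cell) — and at reduced scale where only algorithmic correctness is at
stake (e.g. parameter recovery over 216 trials at noise SD 1 mmHg,
exhaustive rank-correlation checks over all permutations up to n = 6).

## Known limitations

* The analog reading model treats the human video reading as
  Gaussian-plus-quantization; real observers may commit gross reading
  errors that rank statistics would absorb but Bland–Altman limits would
  not.
* Compliance thresholds are step functions; changes straddling ±3 mmHg
  flip classification with measurement noise. The threshold is
  configurable, and borderline sessions should be inspected rather than
  auto-classified.
* The extractor assumes one movement per trial window; double pumps or
  corrections within a trial yield an early zero-crossing and may average
  part of the transient.
* `normality_screen()` is capped at 5,000 observations (the Shapiro–Wilk
  implementation's limit).
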