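---
title: "Methods: decoding working-memory load and stimulus modality from EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding working-memory load and stimulus modality from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegwmdecode)
```

This vignette documents the scientific model implemented by `eegwmdecode`,
the numerical choices behind it, and the reasoning for each place where the
underlying study design left a decision open. All chunks are illustrative
(`eval = FALSE`); the same computations are exercised, with assertions, in
the package test suite.

## 1. The experiment being modeled

Participants learn stimulus–response associations in a staircase
acquired-equivalence task while 64-channel EEG (10-10 montage, 256 Hz
per-channel sampling, referenced recordings high-passed at 0.5 Hz) is
recorded. Each participant performs the acquisition twice: once with visual
stimuli and once with audiovisual stimuli. The staircase introduces a new
association pair only after the previous ones are mastered, so the number
of associations held in working memory grows stepwise; the recording is cut
into **six load segments** (21–37 s each) bracketed by 60 s pre- and
post-task baselines.

The analysis question is whether three per-channel EEG feature families —
band power, inter-site phase synchronization, and cross-frequency coupling
— carry enough information to decode (a) the **stimulus modality** (visual
vs. audiovisual, 2 classes), (b) the **working-memory load** (low = segments
1–3 vs. high = segments 4–6), and (c) the joint **four-class** scheme
(modality x load). With 18 participants x 2 tasks x 6 segments, every
feature family yields a 216 x 64 matrix.

## 2. Synthetic cohorts as the testing surface

No external data ship with the package. Instead, `cohortConfig()` /
`generateRecording()` simulate the full design with **plantable, known
effects**, and parameter recovery is the acceptance surface: an effect the
generator plants must be recovered by the pipeline, and only that effect.

The generator composes, per channel:

* a 1/f + white-floor background (frequency-domain synthesis, per-sample
  SD = `noiseSd`, DC-free);
* a **modality band-power effect**: band-limited noise added per power band
  so the task/baseline PSD ratio equals the requested dB offset exactly in
  expectation (defaults: visual `r c(3, 2, 1, 0.5, 0.5)` dB, audiovisual
  `r c(5, 2, 2.5, 0.5, 2)` dB over theta, alpha, beta, low/high gamma);
* a **load-dependent coupling effect**: fronto-parietal oscillator pairs
  whose phase lag is von Mises distributed with concentration kappa set per
  load segment (monotone decreasing with load by default, theta and alpha);
* a **CFC effect**: an amplitude-modulated narrowband carrier
  (theta-phase modulating beta amplitude) whose modulation depth differs by
  modality (defaults 0.2 visual vs. 0.6 audiovisual on theta–beta).

Two invariance rules keep the planted effects orthogonal, both decided at
design time:

* the CFC carrier is scaled by `1 / sqrt(1 + depth^2 / 2)` so its band
  power is identical across modulation depths — modality information lives
  in the *coupling*, not in beta power;
* the coupling oscillator amplitude is `couplingSnr` x the RMS of
  everything else in its band (background x the modality dB offset, plus
  any CFC carrier variance overlapping the band), so the connectivity SI is
  task-invariant and carries *load* information only.

`GroundTruth` records every planted magnitude per segment, band and
channel pair, so tests can assert recovery against it.

## 3. Signal primitives

**Zero-phase band-pass.** All narrowband filtering uses an odd-length
linear-phase least-squares FIR applied "two-way" (forward and backward),
implemented in the frequency domain: the reflection-padded signal spectrum
is multiplied by the squared magnitude response `|B(w)|^2`, which equals
forward–backward time-domain application exactly and cancels the phase.
Padded lengths are rounded up to 2-3-5-smooth values for fast mixed-radix
FFTs, and filter designs are memoized.

The FIR order starts at the common "three cycles of the low edge"
convention (`3 * floor(fs / fLo)`) but is raised to
`1.8 * fs / min(trans * fLo, fHi - fLo)` whenever that convention cannot
realize the requested transition width: for the narrow 3 Hz CFC bands the
three-cycle order leaves the pass band 11% low, violating the ±5% gain
contract the rest of the pipeline assumes. With the raised order the
measured two-way interior gain over every band used in the study grids lies
in [0.976, 1.039] with stop-band leakage below 0.1%. The least-squares
target ramps linearly across transition regions rather than leaving them
unconstrained, which suppresses design ripple.

**High-pass.** The 0.5 Hz high-pass is a fourth-order Butterworth applied
as its zero-phase squared magnitude response in the frequency domain
(reflection-padded, like the FIRs); DC is removed exactly.

**Analytic signal.** Hilbert transform via the standard frequency-domain
step response; the instantaneous phase is its argument.

**Synchronization index.** For two phase series of equal length n,

```
SI = | mean( exp(i * (phi2 - phi1)) ) |^2
```

the *squared* mean resultant length of the phase differences. SI is 1 for
identical series, lies in [0, 1] always, is swap-symmetric and invariant to
a global phase shift, and for independent phases has expectation 1/n. The
squared form follows the study's printed formula; the unsquared resultant
is available via `phaseSI(..., squared = FALSE)`, and the two are
order-preserving transforms of each other, so no downstream conclusion
depends on the choice. A printed remark about dividing the resultant by
the series length again was read as a restatement of the 1/n in the mean,
not an extra division — applying it twice would collapse all SIs by 1/n.

## 4. Feature families

**Band power.** Welch PSD (2 s Hann windows, 50% overlap, one-sided
density) per channel and segment; task segments are normalized as
`10 * log10(task / baseline)` bin-wise, with the baseline PSD the
arithmetic mean of the pre- and post-task baselines; dB values are then
averaged over the five bands theta 4–8, alpha 8–13, beta 13–30, low gamma
30–45, high gamma 55–70 Hz (band edges inclusive, bins assigned by center
frequency). No 50 Hz notch: the 45–55 Hz gap between bands avoids line
noise by construction.

**Phase connectivity.** Per band, the SI between the Hilbert phases of the
band-limited signals of every non-neighboring channel pair (neighbors by
Delaunay triangulation of the planar-projected montage are excluded, so
volume-conduction-dominated pairs never enter). The first and last 200 ms
of every segment are trimmed after filtering to drop edge transients. The
pair SIs are reduced to a 64-column feature vector by averaging, per
channel, over all its non-neighbor partners; four-ROI summaries
(left/right frontal, left/right parieto-occipital) are computed for
reporting only.

**Cross-frequency coupling** (phase-of-power). For a modulating center
`fLow` and a modulated center `fHigh`, both filtered with 3 Hz widths: the
SI between (a) the Hilbert phase of the `fLow`-band signal and (b) the
Hilbert phase of the `fHigh`-band *power envelope* after that envelope is
itself band-passed at the `fLow` band. Grid: `fLow` in 5–13 Hz (2 Hz
steps), `fHigh` in 15–45 Hz (3 Hz steps); grid points are grouped into the
four band pairs theta–beta, theta–low-gamma, alpha–beta, alpha–low-gamma
(CFC band table: theta 4–7, alpha 8–13, beta 14–30, low gamma 31–45 Hz)
and averaged per channel and segment.

A physical note documented because it shapes what "strong coupling" means
here: amplitude modulation at `fLow` puts sidebands at `fHigh ± fLow`, and
a 3 Hz-wide envelope filter passes only fluctuations up to ±1.5 Hz, so even
a fully modulated (depth 1) carrier yields an SI of ~0.1, not ~1, through
the study's filter widths. The SI remains strongly monotone in depth
(depth 0 sits at the 1/n null), which is what the decoding uses; the test
suite verifies near-complete recovery (SI > 0.98) once the envelope filter
is widened enough to pass the sidebands, and monotonicity at the study's
widths.

## 5. Decoding protocol

Gaussian-kernel SVM emulating the "medium Gaussian" preset: RBF kernel
with kernel scale `sqrt(P)` (i.e. `gamma = 1/P`, with P = 64 features),
unit box constraint, one-vs-one multiclass, features standardized by
train-set mean/SD. Rows are split 172/22/22 (train/cv/test) by stratified
largest-remainder allocation; the cv fold is held out and reported but
never used for tuning. The protocol repeats over 200 random splits (50 in
the acceptance tests), all derived from one master seed.

The chance level is estimated by the same protocol with the labels of the
train and cv rows randomly permuted before each fit; test labels are never
touched. With informative features this null is *not* a tight binomial
around 1/k: a permuted-label SVM still sees the class clusters and tends to
predict each cluster's (random) majority label, so the null accuracy
distribution becomes wide and multi-modal while remaining centered near the
no-information rate. Comparisons against the null therefore use its
empirical quantiles, not a normal approximation.

## 6. Statistics

Accuracy distributions are compared by one-way ANOVA across bands and
two-way ANOVA (band x condition, condition = actual vs. chance), reporting
F, p, partial eta-squared `SS_effect / (SS_effect + SS_error)` and observed
power under the noncentral-F convention `lambda = F * df_effect`. All
ANOVA arithmetic is cross-checked against `stats::aov` in the tests.

## 7. Orchestration and I/O

`runPipeline()` drives simulate → features → decode → report from a YAML
run configuration, streaming one participant at a time (a full default
cohort never holds more than one recording in memory), and writes
tab-separated feature/accuracy/ANOVA tables plus a manifest and log.
Recordings round-trip through 16-bit EDF (or 24-bit BDF input), with
events in a plain-text TSV sidecar (`onset_s`, `duration_s`, `label`);
segment durations are whole seconds so EDF 1 s records are exact.

## 8. Open-design resolutions

* **216 x 64 connectivity matrix**: the study reports per-channel
  connectivity features without stating the reduction from pairs to
  channels; we use the per-channel mean SI over non-neighbor partners
  (keeps locality, matches the stated matrix shape).
* **SI exponent**: squared mean resultant (the printed formula's trailing
  exponent), unsquared exposed as an option.
* **Two band tables**: the power-spectra section and the CFC section print
  different band edges; both are kept, each used by its own module.
* **Split convention**: 216 rows at 80-10-10 is reproduced as 172/22/22
  (`n_test = n_cv = round(0.1 * n)`), stratified per class.
* **Welch parameters**: 2 s Hann, 50% overlap (the study names only "fast
  Fourier transform"); stable on 21–37 s segments.
* **Baseline combination**: arithmetic mean of pre- and post-task baseline
  PSDs.
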