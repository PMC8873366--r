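---
title: "Methods: fNIRS brain-network fingerprinting with nirsBFN"
author: "nirsBFN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fNIRS brain-network fingerprinting with nirsBFN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsBFN)
```

## The analysis model

`nirsBFN` treats a subject's brain functional network (BFN) — the matrix of
pairwise Pearson correlations between channel time series — as a biometric.
The working assumptions are the standard ones of connectome fingerprinting:

* a subject's channel-covariance structure is **intrinsic**: largely stable
  across task states and recording sessions;
* between-subject variation in that structure exceeds within-subject
  variation across states, so a nearest-neighbour match on network
  similarity can recover identity;
* the two hemoglobin views (Oxy-Hb, Deoxy-Hb) reflect the same underlying
  physiology with opposite sign, but not identically — each view carries
  view-specific components.

The pipeline applied to each recording is fixed in order: band-pass
filtering, then global-signal subtraction, then segmentation, then network
estimation, then class averaging. The order is enforced by
`preprocessRecording()` and recorded in the recording's metadata. Filtering
precedes baseline correction because the global mean is itself dominated by
drift and systemic physiology; subtracting it after filtering removes only
the spatially uniform part of what survives the filter.

Identification works on a *source* set (one fingerprint per subject, one
state, one view) and a *target* set. Each target fingerprint is assigned the
subject whose source fingerprint is most similar; accuracy is the fraction
of correct assignments. All 16 ordered state pairs form the cross-task
matrix (per view), and the same combinatorics across views forms the two
cross-view matrices.

## Tunable parameters

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `lowCut`, `highCut` | 0.01, 0.1 | Hz | the canonical fNIRS functional band: removes drift below, Mayer wave/respiration/heartbeat above |
| filter `order` | 3 | – | third-order Butterworth, the field's standard compromise of roll-off vs ringing |
| `causal` | `FALSE` | – | zero-phase filtering leaves no inter-channel lag to bias correlations; a causal single pass is available for comparison |
| `restWindow` | 15 | s | spans exactly 200 samples at the default sampling rate and leaves ≥ 1 s guard inside the shortest (17 s) rest phase |
| `samplingRate` | 30003/2250 ≈ 13.3347 | Hz | the only rate consistent with a 30003-sample recording covering the ~2250 s paradigm; yields the 133-sample task epoch |
| `vectorization` | `"upper"` | – | similarity uses strictly upper-triangular weights: the diagonal is constant and the lower triangle duplicates information; `"full"` provided for comparison |
| `fisherZ` | `FALSE` | – | class averaging uses raw correlation elements; the z-scale average is available but off by default |
| `subjectEffect` | 1 | – | scale of all subject-specific structure in the simulator; 0 gives an exchangeable cohort, ~3 a strongly identifiable one |
| `kappa` | 0.5 | – | Deoxy-Hb carries −κ times the shared slow/evoked components (the canonical anticorrelation, at reduced amplitude) |
| `viewDistortion` | 0.5 | – | relative variance of each view's private network component; drives the cross-task > cross-view gap |

## The synthetic cohort generator

The generator emulates a block-design motor experiment: 30 subjects, 3
sessions × 25 trials, each trial a 2 s cue, 10 s of task (`RHT`/`LHT`/`FT`,
balanced 25/25/25, order randomised per seed) and 17–19 s of rest (uniform,
rounded half-up to whole samples), 20 channels at 30003/2250 Hz.

Per subject and view, the signal is the sum of:

* a **slow structured signal** with spatial covariance
  `I + subjectEffect · LLᵀ` (`L` a channels × 4 loading) — the intrinsic
  network. Temporally it is white noise smoothed by a 0.3 Hz low-pass, so
  its energy covers the analysis band while its coherence time (~3 s) stays
  short against trial spacing;
* a **view-private structured component** with covariance
  `subjectEffect · viewDistortion · L_v L_vᵀ`, an independent loading per
  view, stable over the recording. Both views share the core network; each
  adds its own stable distortion. Deoxy-Hb additionally carries the shared
  components scaled by −κ;
* **evoked responses**: each task block's boxcar convolved with a canonical
  double-gamma hemodynamic response (peak ~6 s, undershoot ~16 s),
  normalised so an isolated block peaks at the task gain. Gains are a fixed
  smooth activation topography per task (amplitude 0.3, lateralised bumps)
  plus subject deviations of sd `0.1 · subjectEffect` — evoked activity is
  deliberately a modest perturbation of the spontaneous fluctuations, as in
  real fNIRS;
* **systemic physiology**: sinusoids at 0.1 Hz (Mayer), 0.25 Hz
  (respiration) and 1 Hz (heartbeat) with amplitudes 0.4/0.3/0.25, random
  phase per component and recording, *identical across channels*. Systemic
  oscillations are spatially unspecific, which is precisely why
  global-signal subtraction is the appropriate correction — and the
  simulated component is removed by it exactly;
* **white measurement noise** (sd 0.3) and a **slow per-channel drift**
  (random walk, sd 0.1 over the recording).

All amplitudes are in the same arbitrary concentration units; the analysis
is scale-free (Pearson correlations), so only ratios matter. Every
subject-specific quantity — loadings, gain deviations, view-private
components — scales with `subjectEffect`, so at 0 the cohort is
statistically exchangeable by construction.

What the generator does **not** emulate: motion artifacts, channel-specific
physiological coupling (the global sinusoids are perfectly uniform),
non-stationarity across sessions, optical calibration (no Lambert–Beer
conversion: the simulator emits concentration changes directly), and any
realistic anatomical channel layout. Passing tests therefore demonstrate
correctness of the pipeline and the qualitative behaviour of the method on
data satisfying its assumptions — not performance on recorded fNIRS.

## Numerical choices

* **Second-order sections.** The 0.01 Hz band edge puts filter poles within
  0.002 of the unit circle; a single sixth-order recursion loses enough
  precision to break linearity at the 1e-4 level. The filter is therefore
  applied as a cascade of biquads derived from the zero-pole-gain form,
  which restores exact linearity to machine precision.
* **Demeaning before filtering.** The band-pass blocks DC, so subtracting
  each channel's mean does not change the ideal output, but it removes the
  step that would otherwise excite the slow (~100 s) start-up transient.
* **Edge handling.** Odd reflection (point symmetry about the end sample)
  of half a low-cut period (50 s) at each end, trimmed after filtering. A
  recording must be at least three settling lengths (150 s at defaults);
  shorter input is an error, not a silent artifact.
* **Rounding.** All duration-to-sample conversions in the scheduler round
  half *up* (not banker's rounding) for cross-platform reproducibility.
  Epoch lengths use `floor()`. When the rest-phase guard around the centred
  rest window is odd, the extra sample is left before the window.
* **Indices.** Sample indices are 1-based everywhere, including the JSON
  interchange sidecar. Trials are contiguous: each onset is the previous
  onset plus the previous trial's sample count.
* **Ties.** An exact similarity tie in the nearest-neighbour argmax breaks
  to the lowest subject index, with a warning: ties are measure-zero on
  continuous data but the behaviour must be deterministic.
* **Degenerate input.** A zero-variance channel makes the Pearson weight
  undefined; `pearsonNetwork()` raises an error naming the channel rather
  than propagating `NaN`.
* **Seeds.** Every stochastic step takes a named seed; cohort-level seeds
  are derived from one master seed by an integer hash kept inside the
  32-bit range. No function touches the global RNG state (seeds are scoped
  with `withr::with_seed`).

## Design decisions that were genuinely open

* **Rest window of 15 s.** Only the epoch size (200 samples) is a fixed
  design fact; at the derived sampling rate a fixed *duration* of 15 s
  reproduces it exactly and generalises to other rates, so duration is the
  parameter and the sample count follows.
* **Zero-phase default.** A causal pass shifts all channels identically, so
  correlations are in fact lag-invariant; zero-phase was chosen anyway
  because downstream consumers of epochs (e.g. evoked-amplitude summaries)
  are not lag-invariant, and the squared magnitude response is accounted
  for in the filter tests. `causal = TRUE` restores a single pass.
* **Global-signal subtraction is per-timepoint, across channels** — not a
  per-trial temporal baseline. After it, each time point's channel mean is
  exactly zero; this constrains every epoch's correlation matrix (weights
  cannot all be positive). That is a faithful property of the pipeline
  order, documented rather than "fixed".
* **No Fisher z before averaging, no thresholding.** Fingerprints are dense
  signed averages of raw correlations; both alternatives exist in the
  literature but change the estimand.
* **Accuracy summaries** are reported for off-diagonal cells by default
  (the same-view diagonal is a trivial self-match) and for the full matrix
  on request, since reasonable aggregation conventions differ.

## A methodological caveat: epoch adjacency

One property of this pipeline deserves emphasis. Band-passing to
0.01–0.1 Hz imposes a coherence time of roughly 1/bandwidth ≈ 11 s on
*everything* in band, including noise. Each trial's rest epoch starts only
~1–1.5 s after that trial's task epoch, so the correlation-estimation
errors of the two epochs are not independent. Because a subject's REST
fingerprint averages the rest epochs of the same trials whose task epochs
form the task fingerprints, within-subject REST↔task similarity carries a
positive bias that does not vanish with more trials (bias and
between-subject noise shrink at the same rate, and the effect is invariant
to the noise scale — it occurs even for a pure white-noise cohort). On an
exchangeable cohort, task↔task identification sits at chance, but
REST↔task modes run a few multiples of chance. Any analysis that averages
interleaved, temporally adjacent epochs into class templates under
narrowband filtering inherits this confound; claims about rest-state
fingerprints being especially identifiable should be checked against it.

## Problem sizes used by the test suite

Unit and property tests run on reduced cohorts (2–12 subjects, one
6–12-trial session, 8–20 channels) chosen so each property is decidable in
seconds; the segmentation combinatorics, the strong-effect identification
run and the acceptance script use the full default paradigm (30 subjects, 3
sessions × 25 trials, 20 channels). The chance-level replication uses 30
subjects × 20 seeds at one 12-trial session per subject — chance behaviour
does not depend on trial count, while the strong-effect claims are made at
full scale.

## Known limitations

* Pearson correlation captures marginal, not conditional, dependence;
  partial-correlation or regularised estimators would change fingerprints.
* The nearest-neighbour rule is the simplest possible classifier; no
  significance testing of accuracies is provided.
* The generator's exchangeability at `subjectEffect = 0` is exact only
  because *all* subject-specific components scale with it; real cohorts
  have no such switch.
* SNIRF/HDF5 ingest is not implemented; recordings enter through the
  TSV + JSON interchange pair (`readRecording()`), and an adapter for other
  formats should construct `Recording` objects directly.
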