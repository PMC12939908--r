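---
title: "Multi-entropy template matching for single-channel EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-entropy template matching for single-channel EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The pipeline

`mefc` classifies subjects as Alzheimer's disease (AD), frontotemporal
dementia (FTD), or healthy control (HC) from a single EEG channel by

1. **Rhythm decomposition** — a four-level discrete wavelet transform
   (Daubechies-4, symmetric boundary extension) of a 128 Hz segment,
   with each subband reconstructed back to the time domain:
   `A4` &rarr; delta (0–4 Hz), `D4` &rarr; theta (4–8), `D3` &rarr; alpha
   (8–16), `D2` &rarr; beta (16–32), `D1` &rarr; gamma (32–64).
2. **Entropy features** — permutation entropy (PE), sample entropy
   (SE), and singular-spectrum entropy (SSE) computed per rhythm and
   concatenated, in that fixed order, into one multi-entropy feature
   vector per (channel, rhythm).
3. **Template classification** — per-class mean feature vectors built
   from the training subjects; an unknown subject is assigned to the
   class whose template it is most similar to, under one of four
   measures: dynamic time warping (DTW, a distance), Pearson
   correlation (PCC), wavelet coherence (WC), or Hilbert envelope
   correlation (HTC).
4. **Leave-one-out cross-validation** — each subject is held out once,
   templates are rebuilt from the remainder, and accuracy is the trace
   of the pooled confusion matrix over its total. With one subject per
   fold this micro accuracy equals the mean of per-fold accuracies.

A channel × rhythm × measure grid (19 × 5 × 4 = 380 cells) reports
per-cell accuracy, the best channel per (rhythm, measure), and the mean
absolute deviation (MAD) of accuracy across channels as an
inter-channel stability statistic. MAD here is the mean absolute
deviation about the mean, `mean(|acc_c - mean(acc)|)`, the standard
definition.

# Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| wavelet, levels | db4, 4 | short support for EEG transients, enough vanishing moments for clean band splits; 4 levels at 128 Hz put the five rhythms on the dyadic grid |
| boundary mode | symmetric | minimizes edge discontinuities in reconstructed bands |
| PE order / delay | 3 / 1 | smallest order giving 6 ordinal patterns; robust on 256-sample windows |
| SE embedding `m` | 2 | the method's fixed choice |
| SE tolerance `r` | 0.15 × SD | the method's fixed choice; in sliding mode the SD is the window's own (windows are self-contained) |
| SSA window `L` | min(⌊N/2⌋, 20) | caps the trajectory matrix and keeps the `ln L` ceiling comparable across 8 s and 30 s inputs |
| sliding window / step | 2 s / 1 s | long enough for SE at m = 2 on 256 samples, short enough to give 7 windows from 8 s and 29 from 30 s |
| WC wavelet, scales | cmor1–1.5, 1:0.5:10 | complex Morlet with bandwidth 1, center frequency 1.5; per-scale coherence is averaged (unweighted) into one scalar |
| feature mode | windowed | the trajectory-based measures (DTW/WC/HTC) need sequences; scalar 3-vectors are supported but rejected by WC/HTC, which need ≥ 4 points |

The dyadic band edges (e.g. beta as 16–32 Hz) approximate the clinical
definitions (beta 13–30 Hz); the edges actually used are recorded in
every `rhythm_set`.

# Numerical choices

* **DWT.** Analysis extends the signal symmetrically by `F − 1`
  samples, convolves with the db4 filter pair, and keeps every second
  sample; synthesis upsamples, convolves with the reconstruction pair,
  and trims `F − 2` leading samples. The transform is exactly
  invertible, and because the five band reconstructions partition the
  coefficient arrays, their sum reproduces the input to machine
  precision (the tests assert 1e−8 relative L2; observed errors are
  ~1e−15).
* **Resampling** is rational-factor polyphase: zero-stuffing by `p`, a
  Kaiser (β = 5) windowed-sinc low-pass at the common Nyquist
  frequency with `10 · max(p, q)` taps per side, decimation by `q`.
  The FIR is linear-phase and its integer group delay is removed
  exactly, so the operation is zero-phase.
* **PE ties** are broken by stable earlier-index-first ranking, making
  the symbolization deterministic; PE uses the natural log with no
  normalization, so its ceiling is `ln(order!)`.
* **SE degenerate cases.** A constant series (SD = 0) and the case
  `B_{m+1} = 0` raise classed errors rather than returning numbers. In
  sliding mode such windows are imputed with the maximum finite SE of
  the same series and flagged — imputing zero would assert "perfectly
  regular" exactly where the statistic is uninformative.
* **SSE rank tolerance.** Singular values below
  `max(sv) · max(dim) · eps` are treated as exact zeros, so a constant
  series has SSE exactly 0.
* **WC smoothing** is the arithmetic time mean per scale, under which
  the `1/s` normalization cancels algebraically; coherence of any
  signal with itself is exactly 1 at every scale.
* **HTC** mean-removes each sequence before the analytic signal, since
  a DC offset otherwise dominates the envelope.
* **Tie-breaking** among equal classification scores follows the fixed
  class order AD < FTD < HC, with a warning — determinism over silent
  randomness.
* **LOOCV templates** are computed from per-class running sums
  (subtracting the held-out subject), which is algebraically identical
  to re-averaging the remaining subjects and keeps the grid run cheap.

# The synthetic cohort generator

Real cohorts of the kind this method targets are clinical recordings
that cannot ship with a package, so `mefc` includes a seeded generator
whose cohorts exercise every pipeline stage. Each channel is a sum of
five band-centered oscillations (2, 6, 12, 24, 45 Hz sinusoids whose
phase follows a smoothed random walk), a `1/f^α` background, and white
noise. Class profiles perturb a shared baseline along the
**oscillation-dominance vs broadband-irregularity** axis:

* **AD** — strong, phase-locked theta and beta oscillations over a
  suppressed noise floor (pathologically regular, oscillation-dominated
  activity; in-band entropies collapse);
* **FTD** — moderately strengthened beta over an unchanged floor (an
  intermediate oscillation/noise mix);
* **HC** — a raised noise floor and wandering phases (broadband
  irregular, the variability of a healthy system).

A scalar `separation` parameter scales every contrast; at 0 the three
profiles are identical, which is the null condition used by the
calibration and permutation tests.

Two findings from calibrating this design are worth recording because
they are properties of the *method*, not accidents of the generator:

1. **Band-limited sample entropy is non-monotone in irregularity.**
   After narrowband reconstruction, background noise becomes a smooth
   oscillation-like signal; windowed SE is lowest for a clean dominant
   tone (~0.49 nats in theta), intermediate for pure band noise
   (~0.64), and *highest* for balanced tone + noise mixtures (~0.73).
   A strict three-way ordering of theta-band SE across classes is
   therefore not achievable simultaneously with robust classification;
   the design guarantees the AD < HC direction on theta and carries the
   full three-way gradation on the wider beta band, whose larger
   bandwidth (16 Hz) admits rough in-band noise and hence a much larger
   entropy dynamic range.
2. **PCC sees only the shape of the block vector.** Correlation is
   affine-invariant, so class contrasts that scale the
   `[PE, SE, SSE]` blocks proportionally are nearly invisible to it
   (template cosine similarity ≈ 0.99). Contrasts must flip the
   SSE-versus-PE relationship across classes — exactly what the
   noise-floor gradation does — to give PCC separable shapes. DTW, by
   contrast, uses absolute levels and separates level-graded classes
   easily.

**What the generator does not emulate:** volume conduction and
inter-channel correlation (channels are independent draws from the same
profile), artifacts (blinks, muscle, line noise), non-stationarity over
minutes, topographic specificity (every channel carries the class
signal, so channel selection exercises the code path but has no
physiological meaning), and realistic inter-subject variability beyond
independent noise realizations. Passing tests therefore demonstrate
that the pipeline recovers the complexity contrasts it is designed to
detect, not that those contrasts are detectable in clinical EEG.

# Problem sizes

The test suite and the acceptance script run cohorts of 10 subjects per
class (30 total): 30 s segments for the single-channel label-recovery
and permutation-null experiments, and 8 s segments for the full
19-channel × 5-rhythm × 4-measure grid — the two segment lengths the
method is defined for. Oracle comparisons use 20–1000-sample series;
DTW is checked against exhaustive path enumeration for sequences up to
length 6 (1000 seeded pairs).

# Known limitations

* The EDF reader handles continuous 16-bit EDF/EDF+ recordings with a
  uniform sampling rate across signal channels; discontinuous EDF+D
  files and per-channel rates are rejected.
* The rhythm band map requires `fs = 8 · 2^levels` (128 Hz at 4
  levels); other rates must be resampled first, which is what
  `eeg_resample()` is for.
* Scalar-mode feature vectors (length 3) are incompatible with WC and
  HTC; the windowed mode is the default for this reason.
* Wavelet coherence on short sequences (7 windows from 8 s recordings,
  hence 21-point vectors) uses scales whose support exceeds the
  sequence; zero padding then attenuates large-scale coefficients
  identically for both inputs, which is harmless for the coherence
  ratio but means the scale axis should not be over-interpreted.
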