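# mefc

Multi-entropy template matching for single-channel EEG classification
of Alzheimer's disease (AD), frontotemporal dementia (FTD), and healthy
controls (HC).

Early dementia screening needs methods that work with little data per
subject, generalize across subjects, and run on wearable single-channel
EEG. `mefc` implements a lightweight, training-free pipeline for that
setting: instead of fitting a model, it characterizes each subject by
the nonlinear complexity of their brain rhythms and classifies by
similarity to per-class prototypes.

## The method

For one channel of a resting-state EEG segment (128 Hz):

1. A four-level **discrete wavelet transform** (db4) separates the five
   classical rhythms, each reconstructed to the time domain:
   A₄ → delta (0–4 Hz), D₄ → theta (4–8), D₃ → alpha (8–16),
   D₂ → beta (16–32), D₁ → gamma (32–64).
2. For each rhythm, three complementary entropies are computed on
   sliding windows (2 s window, 1 s step) and concatenated into a
   **multi-entropy feature vector**

   MEFC_rhythm = [ PE ‖ SE ‖ SSE ]

   * **Permutation entropy** PE = −Σⱼ p(πⱼ) ln p(πⱼ) over ordinal
     patterns (order 3, delay 1) — temporal disorder;
   * **Sample entropy** SE(m, r) = −ln(B_{m+1}/B_m) with m = 2,
     r = 0.15 σ, Chebyshev distance — irregularity/unpredictability;
   * **Singular-spectrum entropy** SSE = −Σᵢ ρᵢ ln ρᵢ, where
     ρᵢ = σᵢ²/Σσᵢ² are normalized squared singular values of the
     Hankel trajectory matrix — structural energy spread.
3. Each class's **template** is the elementwise mean of its training
   subjects' vectors. An unknown subject is assigned to the class with
   the highest similarity (or smallest distance) under one of four
   measures: **DTW** (elastic alignment distance), **PCC** (Pearson
   correlation), **WC** (complex-Morlet wavelet coherence, cmor1–1.5,
   scales 1–10), or **HTC** (correlation of Hilbert envelopes).
4. Performance is estimated by **leave-one-out cross-validation**;
   accuracy = 100 · trace(confusion)/n. A 19-channel × 5-rhythm ×
   4-measure grid reports per-cell accuracy and the mean absolute
   deviation (MAD) of accuracy across channels.

Because the clinical cohorts such methods are evaluated on cannot ship
with a package, `mefc` includes a seeded synthetic cohort generator
whose class profiles encode the mechanism the classifier exploits —
pathologically regular, oscillation-dominated activity (AD) versus
broadband-irregular activity (HC), with FTD in between. See the methods
vignette (`vignettes/mefc-methods.Rmd`) for the design rationale.

## Worked example

```r
library(mefc)

spec <- cohort_spec(n_per_class = c(AD = 10L, FTD = 10L, HC = 10L),
                    seed = 42L, separation = 2)
cohort <- generate_cohort(spec)
cohort$records$AD01
#> <eeg_record> subject AD01, label AD
#>   19 channel(s) x 3840 samples @ 128 Hz (30.00 s)
#>   channels: FP1 FP2 F7 F3 FZ F4 F8 T3 C3 CZ C4 T4 T5 P3 PZ P4 T6 O1 O2

feats <- extract_features(cohort$records, channels = "FP2")
res <- loocv(feats$features$FP2$beta, feats$labels, measure_spec("PCC"))
res
#> <loocv_result> PCC: accuracy 100.00% over 30 folds
#>      predicted
#> true  AD FTD HC
#>   AD  10   0  0
#>   FTD  0  10  0
#>   HC   0   0 10
```

Thirty synthetic subjects are generated at strong class contrast
(`separation = 2`); the windowed beta-rhythm feature vectors of the FP2
channel (29 windows × 3 entropies = 87 values each) are classified by
correlation to leave-one-out mean templates. All 30 subjects are
recovered; at `separation = 0` the same experiment sits at chance
(~33%). Real EEG inputs enter the same way via
`read_eeg("file.edf")` (or CSV + JSON sidecar), `eeg_segment()`, and
`eeg_resample(rec, 128)`.

A thin command-line front end is installed at `inst/cli/mefc`:

```sh
Rscript inst/cli/mefc simulate --n-per-class 10 --duration 30 --separation 2 --seed 42 --out cohort/
Rscript inst/cli/mefc loocv --in cohort/ --channel FP2 --rhythm beta --measure pcc
Rscript inst/cli/mefc grid  --in cohort/ --measures dtw,pcc,wc,htc --out grid.csv
```

## Converting other formats

EEGLAB `.set`/`.fdt` recordings can be exported to EDF from EEGLAB
(File → Export), or to the CSV + sidecar fixture format with any tool
that can dump a channels × samples matrix; the sidecar is
`{"fs": <Hz>, "subject_id": "...", "label": "AD|FTD|HC"}`.
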