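---
title: "Integrating SSEP features with MRI compression grading: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating SSEP features with MRI compression grading: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssepmri)
```

## The problem

Spinal cord compression (SCC) is routinely staged on T2-weighted MRI, but the
degree of anatomical narrowing correlates only weakly with how well the cord
actually conducts. Somatosensory evoked potentials (SSEPs) — scalp responses
to repeated tibial-nerve stimulation — probe exactly that conduction. This
package implements the combined analysis: grade the MRI morphometry (grades
0–3), extract three SSEP features (peak-to-peak amplitude, latency of the
maximal positive peak, and time–frequency power in a fixed region), flag each
compressed patient's features as abnormal relative to the control group, and
quantify how the abnormality categories distribute within and across MRI
grades.

## Feature extraction

**ERP.** Trials are averaged pointwise, `ERP[t] = (1/N) * sum_n X_n[t]`.
Averaging attenuates non-stimulus-locked noise by `sqrt(N)` and is linear, so
feature extraction is invariant to trial order and commutes with amplitude
rescaling.

**Amplitude and latency.** Within a configurable search window (default the
full 0–100 ms analysis window, because the clinical procedure takes global
extrema), amplitude is `max − min` of the averaged trace in microvolts and
latency is the time of the maximum, ties resolved to the earliest sample.
These definitions are exactly reproducible by a brute-force scan, which the
test suite uses as an oracle.

**TFA power.** The averaged trace is decomposed with a short-time Fourier
transform (`signal::specgram`): Hann window spanning 25% of the epoch, 75%
frame overlap, 4× zero-padding. Power is the squared magnitude normalised by
the squared window sum times a fixed unit constant (1.45) that puts
microvolt-scale tibial SSEPs on a convenient order-10 scale; the TFA feature
is the sum of the cells whose centres fall in a fixed rectangle, by default
0–100 ms × 10–100 Hz. The units are arbitrary but consistent — downstream
analysis only ever uses percent change against a control reference, which is
invariant to the unit constant and to the sum-versus-mean choice over a
fixed region. One framing quirk is pinned by tests: `specgram` starts frames
at the first sample and advances by `window − overlap` while a full window
fits strictly inside the signal, so a tail shorter than one window is not
framed; Parseval-type energy checks are therefore stated over the framed
samples.

A note on acquisition metadata: clinical reports for this kind of recording
sometimes quote a 200 Hz sampling rate alongside a 10–500 Hz bandpass, which
is not internally consistent (Nyquist). The synthetic protocol defaults to
2000 samples/s with the 10–500 Hz bandpass; both are configurable, and the
constructor refuses rates below twice the bandpass top.

## Morphometry and grading

Two standard indices are computed from measured cord diameters:

* **CCR** = AP diameter / transverse diameter at the level of maximal
  compression (lower = flatter = more compressed);
* **MSCC** = `(1 − d_i / ((d_a + d_b)/2)) × 100`, the percent AP reduction
  against the mean of the adjacent normal levels. The adjacent-level form is
  the standard one; negative values (a locally thick cord) are retained by
  default, with a `clamp_zero` flag for workflows that floor at zero.

Grades follow the descriptor rules: grade 3 = deformation with
intramedullary signal change; grade 2 = deformation without signal change;
grade 1 = no deformation but ≥ 50% CSF occlusion; grade 0 otherwise. Two
boundary conventions had to be fixed: exactly 50% occlusion (left unassigned
by the verbal < 50% / > 50% definitions) counts as grade 1, and deformation
takes precedence over low occlusion, because the higher grades are defined
by the cord itself rather than the CSF space.

## Abnormality classification

Per-patient percent changes are computed against the **mean** (not median)
of the control group's features on the analysis side — the right side by
default, where the grade separation is strongest. The cuts are inclusive:
amplitude reduction ≥ 50%, TFA power loss ≥ 30%, latency delay ≥ 10% (the
delay wording in clinical sources mixes "> 10%" with "(inclusive)"; ≥ is
used for consistency with the other two cuts). The amplitude × power flag
pair defines four categories: A (neither abnormal), B (amplitude only),
C (amplitude with power loss), D (power only). D is structurally
representable and counted even though observed cohorts typically show an
empty D cell. Negative changes — a patient better than the control mean —
are kept as negative fractions and always classify as normal.

## Statistics

The statistical layer is authored in the package and cross-checked in the
tests against both enumeration oracles and the corresponding base-R tests:

* **Fisher's exact test** (2×2, two-sided) uses the probability-mass rule:
  the p-value sums the hypergeometric probabilities of all tables with the
  observed margins that are no more probable than the observed table, with a
  1e-7 relative tolerance on the comparison and an internal normalisation
  check. A zero margin admits no alternative tables and returns p = 1.
* **Kendall's tau-b** uses the tie-corrected denominator and a two-tailed
  p-value from the tie-adjusted normal approximation of `C − D`; for
  samples of ten or fewer without ties an exact p-value from the
  inversion-number null distribution is available (and is the automatic
  choice there). Interpretation bands: |tau| < 0.3 low, 0.3–0.7 moderate,
  above 0.7 high.
* **Kruskal–Wallis H** with mid-ranks and the usual tie-correction divisor,
  chi-square reference with k − 1 degrees of freedom.
* **Mann–Whitney U** reports `min(U_x, U_y)`; the p-value is exact (full
  enumeration of group assignments of the observed mid-ranks, which remains
  valid under ties) when `n_x + n_y ≤ 12`, otherwise a tie-corrected normal
  approximation with continuity correction.

Raw p-values are reported without multiple-testing adjustment, matching the
descriptive use of these tables. Medians and quartiles everywhere use the
linear-interpolation convention (R quantile type 7), recorded in the report
provenance.

## The synthetic cohort generator

The generator exists so the whole pipeline is testable end-to-end without
any patient data. Its defaults emulate a 136-patient surgical cohort:
10/35/57/34 patients in grades 0–3, grade-wise median targets for the six
side-specific SSEP features, CCR and MSCC, and a per-grade
abnormality-category mixture matching the reference contingency structure.

* Positive quantities (amplitude, power, CCR) are log-normal around the
  grade median, which guarantees positivity and exact median-targeting;
  latency is normal truncated to the epoch; MSCC is normal (it may be
  legitimately negative at grade 0). A shared latent severity factor loads
  amplitude and power down and latency and MSCC up, reproducing the sign
  structure of the observed cross-feature correlations.
* **Dispersions** default to about a 20% coefficient of variation. This is
  deliberately tighter than the quartile spreads of real cohorts (log-SD
  near 0.6): with 10 patients in the control group, the sampling error of a
  sample median under realistic dispersion is itself ~16%, so grade-wise
  median calibration would be unverifiable at the cohort's own group sizes.
  The package treats median identifiability at the default group sizes as
  part of the generator's contract; real-data-scale dispersions remain one
  config field away. Consequently, passing calibration tests demonstrate
  correct targeting of the generator, not that real cohorts are this tight.
* **Waveforms.** Each trial is a deterministic template plus independent
  band-limited Gaussian noise (white noise shaped by a 4th-order Butterworth
  magnitude response, zero-phase, renormalised to the configured per-sample
  SD). The template family is a 45 Hz cosine phase-locked to the latency
  under an envelope that morphs from a narrow Gaussian burst (the classic
  biphasic wavelet) to a sustained, softly clipped oscillation. The family
  is built so that (i) the envelope strictly peaks at the latency, so the
  grid argmax is always the sample nearest the true latency; (ii) the
  waveform is rescaled to the exact true peak-to-peak span; and (iii)
  spectral energy per squared peak-to-peak span rises monotonically along
  the single shape coordinate. The generator solves that coordinate against
  the package's own extractor so the noiseless extracted TFA power equals
  the patient's power truth. Power at fixed amplitude is shape-bounded
  (about 2–9 units per squared microvolt under default extraction
  settings); targets outside the reachable range clamp to its edge, which
  affects only the tails of the power distribution, not grade medians.
* **Noise level.** The default single-trial noise SD is 0.35 µV with 300
  trials per average, chosen as a pair with the 10% classification guard
  band: after averaging, three standard deviations of feature-estimation
  error stay inside the guard band, so a forced category can never be
  flipped by estimation noise. Real single-trial EEG noise is larger;
  raising `noise_sd` (and `n_trials`) moves the simulation toward realistic
  single-trial SNR at the cost of wider calibration error.
* **Category modes.** `emergent` draws features freely and lets categories
  arise; `mixture` samples each compressed patient's category from the
  configured mixture and draws amplitude/power from guard-banded truncated
  log-normals on the category's side of the cuts (relative to the
  configured reference means); `exact` fixes the per-grade category counts
  by largest-remainder allocation, reproducing a printed contingency table
  exactly. Conditioned draws are kept jointly feasible with the template
  family's reachable power range. In conditioned modes the pipeline
  classifies against the configured reference rather than the estimated
  control mean, since an estimated reference would jitter forced counts.
* **Morphometry** is emitted as measured scalars: adjacent-level AP
  diameters are drawn near 8 mm, and the compressed-level AP and transverse
  diameters are solved so that `compute_mscc()` and `compute_ccr()` recover
  the patient's truths exactly; occlusion and the deformation/signal flags
  are drawn from the grade's defining ranges, so generated patients re-grade
  to their assigned grade.
* **Reproducibility.** Every patient owns an RNG stream derived from
  `(master seed, patient index)`, so enlarging a cohort leaves existing
  patients' draws untouched; epoch sets take their own derived seeds.

What the generator does *not* emulate: artifacts and trial non-stationarity,
anesthesia or temperature effects, inter-rater variability of the human MRI
grader, per-vertebral-level structure, and realistic between-patient
dispersion (see above). Green tests on synthetic cohorts therefore validate
the analysis machinery and its calibration contract, not clinical
performance on real recordings.

## Pipeline and provenance

`run_pipeline()` executes simulate → extract → grade → classify → analyze;
stages communicate via plain CSV/JSON artifacts when an output directory is
given, each run is stamped with a content hash of its configuration, and
identical `(config, seed)` produce byte-identical reports. Externally
supplied feature and morphometry tables substitute for the simulation
stages without code changes. A thin command-line wrapper ships in
`inst/cli/ssep-pipeline.R`. Problem sizes used by the shipped tests: the
full default cohort (136 patients, 300 trials × 200 samples per side) for
calibration checks, reduced cohorts (8–14 patients, 4–20 trials) elsewhere.

## Known limitations

* The logistic-regression feature-importance analysis of the source
  platform is out of scope (split and seed unrecoverable); the association
  layer covers the same question via tau-b.
* TFA power medians track their targets only within the template family's
  reachable shape range; extreme power/amplitude combinations clamp.
* The latency features are generated but deliberately drive no abnormality
  difference between grades (matching the observed absence of latency
  separation), so latency-related outputs exercise only the classification
  plumbing.
* Left-side analysis is fully supported but defaults mirror the right side,
  where the control reference means are defined.
* The default (emergent) cohort does not reproduce the reference
  contingency structure: with grade-wise power medians falling to roughly
  half the control median, most compressed patients sit beyond the 30%
  power-loss cut, which is why the `mixture` and `exact` category modes
  exist. Printed summaries of real cohorts are not always internally
  consistent on this point (a reported control power mean can sit far below
  the same group's reported median), so the generator treats the median
  table as the source of truth and derives its reference from it.
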