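# ssepmri

Combined analysis of somatosensory evoked potentials (SSEPs) and MRI-based
spinal cord compression (SCC) grading, for neurophysiologists and biomedical
analysts who want a reproducible, testable implementation of the workflow:

1. **SSEP features** — average stimulus-locked trials into the ERP
   (`ERP[t] = (1/N) Σₙ Xₙ[t]`), extract the peak-to-peak amplitude (µV, the
   max − min of the averaged trace), the latency of the maximal positive
   peak (ms), and the time–frequency (TFA) power, i.e. the short-time
   Fourier spectrogram `|STFT{x}(τ, ω)|²` summed over a fixed
   0–100 ms × 10–100 Hz region.
2. **MRI morphometry** — cord compression ratio `CCR = d_AP / d_transverse`,
   maximum spinal cord compression
   `MSCC = (1 − d_i / ((d_a + d_b)/2)) × 100`, and the 0–3 compression grade
   from CSF occlusion, cord deformation and intramedullary signal change.
3. **Abnormality classification** — percent change of each patient's
   features against the control-group means, with inclusive cuts at 50%
   amplitude reduction, 30% TFA power loss and 10% latency delay, yielding
   categories A (no amplitude/power abnormality), B (amplitude only),
   C (amplitude + power) and D (power only).
4. **Integration statistics** — per-grade 2×2 amplitude × power contingency
   tables with an exact two-sided Fisher test (probability-mass rule),
   Kendall tau-b with tie corrections, Kruskal–Wallis H and Mann–Whitney U,
   all authored in the package and oracle-tested.
5. **A seeded synthetic cohort generator** that emulates the grade-wise
   structure of a 136-patient surgical cohort (10/35/57/34 patients in
   grades 0–3), so the entire pipeline is exercised end-to-end without any
   patient data.

Everything is data-frame-first and pipe-friendly: features, calls, tables
and report blocks are tibbles; test results have broom-style `tidy()` /
`glance()` methods; ERPs, spectrograms and reports have `autoplot()`
methods.

## Worked example

```r
library(ssepmri)

# exact Fisher test of a per-grade contingency table
tidy(fisher_exact_2x2(matrix(c(27, 4, 0, 4), 2, byrow = TRUE)))
#> # A tibble: 1 × 4
#>   statistic p.value method                            n
#>       <dbl>   <dbl> <chr>                         <dbl>
#> 1       Inf 0.00134 Fisher exact test (two-sided)    35

# full pipeline on a synthetic cohort whose per-grade category counts are
# forced to the reference contingency structure
cfg <- pipeline_config(cohort = cohort_config(category_mode = "exact"))
report <- run_pipeline(cfg, seed = 42)
report
#> <ssep_report> ssepmri 0.1.0 seed 42 hash 1ef6a6ce
#>   patients per grade 0-3: 10/35/57/34
#> # A tibble: 3 × 7
#>   grade     n pct_no_abnormality pct_amp_only pct_amp_power pct_power_only empty
#>   <int> <int>              <dbl>        <dbl>         <dbl>          <dbl> <lgl>
#> 1     1    35               77.1         11.4          11.4              0 FALSE
#> 2     2    57               42.1         43.9          14.0              0 FALSE
#> 3     3    34               44.1         35.3          20.6              0 FALSE
```

The distribution reads as the clinical picture: at grade 1 most patients
(77.1%) show no amplitude or power abnormality; at grades 2–3 the majority
have at least an amplitude abnormality, and the share with accompanying
power loss grows (11.4% → 14.0% → 20.6%) — power loss appearing only after
amplitude has already dropped. `report$grade_tables$fisher_p` carries the
exact Fisher p-values of the per-grade tables (0.0013, 0.016, 0.011 for the
counts above), `report$association` the tau-b / Kruskal–Wallis layer, and
`autoplot(report)` the stacked per-grade category distribution.

`run_pipeline(cfg, seed, out_dir = "run1")` persists every stage artifact
(cohort, features, grades, calls CSVs; analysis and report JSON; a text
summary) stamped with a configuration hash; identical `(config, seed)` give
byte-identical reports. Externally measured feature/morphometry tables can
replace the simulation stages (`run_pipeline(cfg, seed, features = ...,
morphometry = ...)`). A thin CLI wrapper lives at
`inst/cli/ssep-pipeline.R`.

See the vignette (`vignettes/ssep-mri-integration.Rmd`) for the model,
parameter and calibration details, including what the synthetic generator
does and does not emulate.

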