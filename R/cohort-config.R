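#' Synthetic cohort configuration
#'
#' Defines the study conditions a generated cohort emulates: per-grade
#' patient counts, per-grade median targets for the SSEP features and the
#' cord morphometry indices, dispersions, the per-grade abnormality-category
#' mixture, and the epoch noise level.
#'
#' Median targets default to the grade-wise medians observed in a 136-patient
#' tibial-SSEP / MRI-graded surgical cohort (grades 0-3 with 10/35/57/34
#' patients): right-side amplitudes 2.39/1.90/1.15/1.00 uV, latencies around
#' 40.6-43.8 ms, TFA power 12.78/8.55/6.60/7.46 (arbitrary spectral units),
#' CCR 0.48/0.42/0.37/0.39 and MSCC 2.14/13.23/38.38/52.82%. Dispersions
#' default to roughly a 20% coefficient of variation — tight enough that the
#' per-grade sample medians are identifiable at these group sizes.
#'
#' Category handling (`category_mode`):
#' * `"emergent"` (default) — feature scales are drawn freely around the
#'   grade medians and abnormality categories arise downstream.
#' * `"mixture"` — each compressed patient's category (A/B/C/D) is drawn from
#'   `category_mix` and the amplitude/power truths are drawn from the grade
#'   distribution truncated to the category's side of the thresholds
#'   (relative to the configured control reference means).
#' * `"exact"` — per-grade category counts are fixed to
#'   `round(category_mix * n)` via largest-remainder allocation, so the
#'   per-grade contingency tables are reproduced exactly.
#'
#' @param n_per_grade Integer length-4, patients in grades 0-3.
#' @param amplitude_median,latency_median,tfa_power_median Named lists with
#'   `left`/`right` length-4 numeric vectors of grade 0-3 medians
#'   (uV, ms, spectral units).
#' @param ccr_median,mscc_median Length-4 grade medians for the cord
#'   compression ratio (dimensionless) and maximum spinal cord compression
#'   (percent).
#' @param amplitude_log_sd,tfa_power_log_sd Log-scale SDs of the log-normal
#'   feature draws.
#' @param latency_sd Latency SD in ms (normal, truncated to the epoch).
#' @param ccr_log_sd Log-scale SD of the CCR draw.
#' @param mscc_sd Length-4 SDs of the MSCC draw per grade (percent).
#' @param noise_sd Single-trial additive noise SD in uV (band-limited
#'   Gaussian). The default pairs with `n_trials` and `guard_band` so that
#'   three standard deviations of post-averaging feature-estimation error
#'   stay inside the guard band around every classification cut.
#' @param n_trials Trials per average (overrides the protocol when set).
#' @param category_mix 3 x 4 matrix of category proportions (rows grades
#'   1-3, columns A/B/C/D), each row summing to 1.
#' @param category_mode `"emergent"`, `"mixture"` or `"exact"`.
#' @param reference_amplitude,reference_tfa_power Control reference means
#'   used for conditioned category draws (right side). `NULL` for the power
#'   reference means "the mean implied by the grade-0 log-normal".
#' @param guard_band Fractional guard band kept clear around the
#'   classification cuts in conditioned draws, so estimation noise cannot
#'   flip a forced category.
#' @param severity_loading Loading of a shared per-patient latent severity
#'   factor on the feature draws (induces the cross-feature correlation
#'   structure seen in real cohorts). 0 disables it.
#' @return A `ssep_cohort_config` list.
#' @examples
#' cfg <- cohort_config()
#' cfg$n_per_grade
#' @export
cohort_config <- function(
    n_per_grade = c(10L, 35L, 57L, 34L),
    amplitude_median = list(left  = c(2.39, 1.94, 1.40, 1.42),
                            right = c(2.39, 1.90, 1.15, 1.00)),
    latency_median   = list(left  = c(40.47, 41.25, 41.56, 43.99),
                            right = c(40.63, 41.41, 42.19, 43.76)),
    tfa_power_median = list(left  = c(12.07, 8.94, 7.56, 7.79),
                            right = c(12.78, 8.55, 6.60, 7.46)),
    ccr_median = c(0.48, 0.42, 0.37, 0.39),
    mscc_median = c(2.14, 13.23, 38.38, 52.82),
    amplitude_log_sd = 0.20,
    tfa_power_log_sd = 0.20,
    latency_sd = 2.0,
    ccr_log_sd = 0.10,
    mscc_sd = pmax(0.2 * mscc_median, 0.4),
    noise_sd = 0.35,
    n_trials = 300L,
    category_mix = default_category_mix(),
    category_mode = c("emergent", "mixture", "exact"),
    reference_amplitude = 2.58,
    reference_tfa_power = NULL,
    guard_band = 0.10,
    severity_loading = 0.5) {
  category_mode <- match.arg(category_mode)
  stopifnot(length(n_per_grade) == 4L, all(n_per_grade >= 0),
            all(n_per_grade == round(n_per_grade)))
  if (sum(n_per_grade) < 1) {
    abort("cohort must contain at least one patient")
  }
  for (tab in list(amplitude_median, latency_median, tfa_power_median)) {
    stopifnot(is.list(tab), all(c("left", "right") %in% names(tab)))
    for (v in tab[c("left", "right")]) {
      if (length(v) != 4L || !all(is.finite(v)) || !all(v > 0)) {
        abort("per-grade median targets must be 4 positive finite numbers")
      }
    }
  }
  stopifnot(length(ccr_median) == 4L, all(is.finite(ccr_median)), all(ccr_median > 0))
  stopifnot(length(mscc_median) == 4L, all(is.finite(mscc_median)))
  stopifnot(length(mscc_sd) == 4L, all(mscc_sd >= 0))
  check_number(amplitude_log_sd, "amplitude_log_sd", lower = 0)
  check_number(tfa_power_log_sd, "tfa_power_log_sd", lower = 0)
  check_number(latency_sd, "latency_sd", lower = 0)
  check_number(ccr_log_sd, "ccr_log_sd", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_trials, "n_trials", lower = 1)
  check_number(guard_band, "guard_band", lower = 0, upper = 0.4)
  check_number(severity_loading, "severity_loading", lower = 0, upper = 0.95)
  stopifnot(is.matrix(category_mix), nrow(category_mix) == 3L, ncol(category_mix) == 4L)
  if (any(category_mix < 0) || any(abs(rowSums(category_mix) - 1) > 1e-8)) {
    abort("each `category_mix` row must be non-negative and sum to 1")
  }
  check_number(reference_amplitude, "reference_amplitude", lower = 1e-9)
  if (is.null(reference_tfa_power)) {
    reference_tfa_power <-
      exp(log(tfa_power_median$right[1]) + tfa_power_log_sd^2 / 2)
  }
  check_number(reference_tfa_power, "reference_tfa_power", lower = 1e-9)
  structure(
    list(
      n_per_grade = as.integer(n_per_grade),
      amplitude_median = amplitude_median,
      latency_median = latency_median,
      tfa_power_median = tfa_power_median,
      ccr_median = as.numeric(ccr_median),
      mscc_median = as.numeric(mscc_median),
      amplitude_log_sd = amplitude_log_sd,
      tfa_power_log_sd = tfa_power_log_sd,
      latency_sd = latency_sd,
      ccr_log_sd = ccr_log_sd,
      mscc_sd = as.numeric(mscc_sd),
      noise_sd = noise_sd,
      n_trials = as.integer(n_trials),
      category_mix = category_mix,
      category_mode = category_mode,
      reference_amplitude = reference_amplitude,
      reference_tfa_power = reference_tfa_power,
      guard_band = guard_band,
      severity_loading = severity_loading
    ),
    class = "ssep_cohort_config"
  )
}

#' Default per-grade abnormality-category mixture
#'
#' Category proportions for grades 1-3 matching the contingency structure of
#' the reference cohort: rows grades 1-3, columns A (no amplitude/power
#' abnormality), B (amplitude only), C (amplitude + power), D (power only).
#'
#' @return A 3 x 4 matrix with rows summing to 1.
#' @export
default_category_mix <- function() {
  m <- rbind(
    c(27, 4, 4, 0) / 35,
    c(24, 25, 8, 0) / 57,
    c(15, 12, 7, 0) / 34
  )
  dimnames(m) <- list(paste0("grade", 1:3), c("A", "B", "C", "D"))
  m
}

#' @export
print.ssep_cohort_config <- function(x, ...) {
  cat("<ssep_cohort_config>\n")
  cat(sprintf("  patients per grade 0-3: %s (total %d)\n",
              paste(x$n_per_grade, collapse = "/"), sum(x$n_per_grade)))
  cat(sprintf("  right amplitude medians (uV): %s\n",
              paste(x$amplitude_median$right, collapse = ", ")))
  cat(sprintf("  MSCC medians (%%): %s\n", paste(x$mscc_median, collapse = ", ")))
  cat(sprintf("  category mode: %s; noise SD %g uV; %d trials\n",
              x$category_mode, x$noise_sd, x$n_trials))
  invisible(x)
}
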