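# ---- waveform templates -----------------------------------------------------

# Evoked-burst template family: a 45 Hz cosine carrier phase-locked to the
# latency under an envelope that morphs, along a single shape coordinate
# theta in [0, 1], from a narrow Gaussian burst (a biphasic/triphasic
# wavelet, the classic P40-like complex) to a sustained, softly clipped
# oscillation filling the analysis window. Spectral energy per squared
# peak-to-peak span rises monotonically along the path, which is what lets
# a patient's TFA-power truth be dialled independently of the amplitude
# truth. The envelope always peaks at the latency (with a strict hump over
# any other carrier peak), so the global maximum of every family member
# sits at the sample nearest the latency.
burst_template <- function(t_ms, latency_ms, theta, carrier_hz = 45) {
  sigma <- 2.5 + (25 - 2.5) * min(theta / 0.5, 1)
  floor_ <- 0.9 * min(max((theta - 0.5) / 0.35, 0), 1)
  clip <- 0.02 + 3 * max((theta - 0.85) / 0.15, 0)
  d <- t_ms - latency_ms
  carrier <- tanh(clip * cos(2 * pi * carrier_hz * d / 1000)) / tanh(clip)
  env <- floor_ + (1 - floor_) * exp(-d^2 / (2 * sigma^2))
  edge <- pmin(1, pmax(0, (t_ms - 2) / 8)) *
    pmin(1, pmax(0, (max(t_ms) - 2 - t_ms) / 8))
  carrier * env * edge
}

# Scale a family member to an exact on-grid peak-to-peak amplitude; the
# argmax position is unaffected by scaling.
build_template <- function(t_ms, amplitude_uv, latency_ms, theta) {
  if (amplitude_uv == 0) {
    return(rep(0, length(t_ms)))
  }
  u <- burst_template(t_ms, latency_ms, theta)
  ptp <- max(u) - min(u)
  amplitude_uv / ptp * u
}

template_power <- function(t_ms, amplitude_uv, latency_ms, theta, fs,
                           params, region) {
  tpl <- build_template(t_ms, amplitude_uv, latency_ms, theta)
  erp <- erp_from_vector(tpl, fs)
  compute_tfa_power(erp, params, region)$tfa_power
}

# Conservative bounds (under the default extraction settings) on the
# reachable TFA power of a unit-amplitude template; power scales exactly
# with amplitude^2, so the reachable interval for amplitude A is
# A^2 * [power_shape_min, power_shape_max]. Used by the generator to keep
# conditioned feature draws jointly feasible.
power_shape_min <- 2.05
power_shape_max <- 8.9

solve_shape <- function(t_ms, amplitude_uv, latency_ms, power_target, fs,
                        params, region) {
  f <- function(theta) {
    template_power(t_ms, amplitude_uv, latency_ms, theta, fs, params, region) -
      power_target
  }
  f0 <- f(0)
  if (f0 >= 0) {
    return(0) # even the narrowest complex exceeds the target: clamp
  }
  f1 <- f(1)
  if (f1 <= 0) {
    return(1) # target above the reachable range: clamp
  }
  uniroot(f, c(0, 1), tol = 1e-4)$root
}

# ---- band-limited noise -----------------------------------------------------

# Zero-phase band-limited Gaussian noise: white noise shaped in the frequency
# domain by a 4th-order Butterworth magnitude response, renormalised so the
# per-sample SD equals `sd`. Vectorised over trials (one FFT pair per epoch
# set).
band_limited_noise <- function(n_trials, n_samples, sampling_rate, band, sd) {
  if (sd == 0) {
    return(matrix(0, n_trials, n_samples))
  }
  white <- matrix(rnorm(n_trials * n_samples), n_trials, n_samples)
  f <- (seq_len(n_samples) - 1) / n_samples * sampling_rate
  f <- pmin(f, sampling_rate - f) # two-sided spectrum folded to magnitude
  k <- 4
  hp <- ifelse(f == 0, 0, (f / band[1])^k / sqrt(1 + (f / band[1])^(2 * k)))
  lp <- 1 / sqrt(1 + (f / band[2])^(2 * k))
  mag <- hp * lp
  mag <- mag / sqrt(mean(mag^2)) # unit average power gain
  spec <- mvfft(t(white)) * mag
  sd * t(Re(mvfft(spec, inverse = TRUE))) / n_samples
}

# ---- cohort generation ------------------------------------------------------

# per-grade demographic anchors (medians/ratios of the emulated cohort)
demo_anchors <- list(
  male_frac = c(6 / 10, 20 / 35, 36 / 57, 23 / 34),
  age = c(52, 55, 55, 53),
  height = c(166.55, 166.40, 164.10, 165.05),
  weight = c(66.5, 66.0, 69.1, 71.35)
)

# largest-remainder allocation of n patients over mixture probabilities
allocate_counts <- function(n, probs) {
  raw <- probs * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# bounds on a feature truth implied by a category, around the configured
# reference mean, with a guard band so downstream estimation noise cannot
# flip the call
category_bounds <- function(category, ref, cut, guard, which = c("amplitude", "power")) {
  which <- match.arg(which)
  keep_high <- if (which == "amplitude") category %in% c("A", "D") else category %in% c("A", "B")
  edge <- (1 - cut) * ref
  if (keep_high) {
    c(lower = edge * (1 + guard), upper = Inf)
  } else {
    c(lower = 0, upper = edge * (1 - guard))
  }
}

#' Generate a synthetic patient cohort
#'
#' Draws one virtual patient per requested slot: MRI grade, demographics,
#' side-specific true SSEP feature scales (amplitude, latency, TFA power),
#' and cord-morphometry truths (CCR, MSCC, CSF occlusion, deformation and
#' signal-change flags). Positive quantities are log-normal around the
#' grade's median target; latency is normal, truncated to the analysis
#' window; a shared latent severity factor induces realistic cross-feature
#' correlation. Each patient owns an RNG stream derived from
#' `(seed, patient index)`, so cohorts are stable under count changes.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return A tibble with one row per patient (the cohort manifest): truth
#'   parameters, demographics, category (for conditioned modes) and the
#'   per-patient seed.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_grade = c(2, 2, 2, 2)), seed = 1)
#' table(cohort$grade)
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "ssep_cohort_config"))
  check_number(seed, "seed")
  n_total <- sum(config$n_per_grade)
  grades <- rep(0:3, times = config$n_per_grade)

  # category assignment (grade 0 is always 'A': it defines the reference)
  categories <- rep(NA_character_, n_total)
  if (config$category_mode == "exact") {
    for (g in 1:3) {
      idx <- which(grades == g)
      if (length(idx) == 0) next
      counts <- allocate_counts(length(idx), config$category_mix[g, ])
      categories[idx] <- rep(c("A", "B", "C", "D"), times = counts)
    }
    categories[grades == 0] <- "A"
  }

  lam <- config$severity_loading
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    g <- grades[i]
    gi <- g + 1
    patient_seed <- derive_seed(seed, i)
    rows[[i]] <- withr::with_seed(patient_seed, {
      z <- rnorm(1) # latent severity
      mix <- function(load) load * z + sqrt(1 - load^2) * rnorm(1)

      if (config$category_mode == "mixture" && g > 0) {
        category <- sample(c("A", "B", "C", "D"), 1,
                           prob = config$category_mix[g, ])
      } else if (config$category_mode == "exact") {
        category <- categories[i]
      } else {
        category <- NA_character_
      }

      draw_feature <- function(median, log_sd, bounds = c(0, Inf), load = lam) {
        if (all(is.infinite(bounds) | bounds == 0)) {
          exp(log(median) + log_sd * mix(-load))
        } else {
          rlnorm_med(1, median, log_sd, bounds[1], bounds[2])
        }
      }

      if (!is.na(category) && g > 0) {
        amp_bounds <- category_bounds(category, config$reference_amplitude,
                                      threshold_config()$amplitude_reduction_cut,
                                      config$guard_band, "amplitude")
        pow_bounds <- category_bounds(category, config$reference_tfa_power,
                                      threshold_config()$power_loss_cut,
                                      config$guard_band, "power")
        # joint feasibility: the template family reaches powers in
        # amplitude^2 * [power_shape_min, power_shape_max] only, so keep the
        # amplitude draw where the category's power band is realisable ...
        if (pow_bounds[["lower"]] > 0) {
          amp_bounds[["lower"]] <- max(amp_bounds[["lower"]],
                                       sqrt(pow_bounds[["lower"]] /
                                              (power_shape_max * 0.98)))
        }
        if (is.finite(pow_bounds[["upper"]])) {
          amp_bounds[["upper"]] <- min(amp_bounds[["upper"]],
                                       sqrt(pow_bounds[["upper"]] /
                                              (power_shape_min * 1.02)))
        }
      } else {
        amp_bounds <- c(lower = 0, upper = Inf)
        pow_bounds <- c(lower = 0, upper = Inf)
      }

      amplitude_right <- draw_feature(config$amplitude_median$right[gi],
                                      config$amplitude_log_sd, amp_bounds)
      amplitude_left <- draw_feature(config$amplitude_median$left[gi],
                                     config$amplitude_log_sd)
      if (!is.na(category) && g > 0) {
        # ... and keep the power draw inside the reachable interval of the
        # amplitude that was just drawn
        pow_bounds[["lower"]] <- max(pow_bounds[["lower"]],
                                     power_shape_min * 1.02 * amplitude_right^2)
        pow_bounds[["upper"]] <- min(pow_bounds[["upper"]],
                                     power_shape_max * 0.98 * amplitude_right^2)
      }
      tfa_right <- draw_feature(config$tfa_power_median$right[gi],
                                config$tfa_power_log_sd, pow_bounds)
      tfa_left <- draw_feature(config$tfa_power_median$left[gi],
                               config$tfa_power_log_sd)
      latency_right <- rnorm_trunc(1, config$latency_median$right[gi] +
                                     config$latency_sd * 0.4 * z,
                                   config$latency_sd * sqrt(1 - 0.16), 20, 90)
      latency_left <- rnorm_trunc(1, config$latency_median$left[gi] +
                                    config$latency_sd * 0.4 * z,
                                  config$latency_sd * sqrt(1 - 0.16), 20, 90)

      mscc_true <- rnorm_trunc(1, config$mscc_median[gi] +
                                 config$mscc_sd[gi] * 0.5 * z,
                               config$mscc_sd[gi] * sqrt(0.75), -20, 95)
      ccr_true <- exp(log(config$ccr_median[gi]) + config$ccr_log_sd * mix(-0.4))

      occlusion <- switch(gi,
        runif(1, 0.05, 0.45),
        runif(1, 0.55, 0.95),
        runif(1, 0.60, 1.00),
        runif(1, 0.70, 1.00)
      )
      tibble::tibble(
        patient_id = sprintf("P%03d", i),
        grade = g,
        sex = if (runif(1) < demo_anchors$male_frac[gi]) "M" else "F",
        age = round(rnorm_trunc(1, demo_anchors$age[gi], 8, 20, 69)),
        height = round(rnorm_trunc(1, demo_anchors$height[gi], 6, 146, 190), 1),
        weight = round(rnorm_trunc(1, demo_anchors$weight[gi], 12, 44, 101), 1),
        category = category,
        amplitude_left = amplitude_left, amplitude_right = amplitude_right,
        latency_left = latency_left, latency_right = latency_right,
        tfa_power_left = tfa_left, tfa_power_right = tfa_right,
        ccr_true = ccr_true, mscc_true = mscc_true,
        csf_occlusion = occlusion,
        deformation = g >= 2,
        signal_change = g == 3,
        patient_seed = patient_seed
      )
    })
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  out
}

#' Simulate the stimulus-locked epoch set of one patient/side
#'
#' Each trial is a deterministic template — a biphasic complex whose positive
#' peak sits at the patient's true latency and whose peak-to-trough span
#' equals the true amplitude, with lobe width and an oscillatory tail solved
#' so the noiseless extracted TFA power matches the patient's true spectral
#' scale — plus independent band-limited Gaussian noise.
#'
#' @param truth One cohort row (one-row data frame or list) from
#'   [generate_cohort()].
#' @param protocol A [stimulation_protocol()].
#' @param seed Integer seed for this epoch set.
#' @param side `"right"` or `"left"`.
#' @param noise_sd Single-trial noise SD in uV.
#' @param params,region STFT settings the power calibration targets (use the
#'   same settings later at extraction).
#' @return A [ssep_epochs()] object.
#' @export
generate_epoch_set <- function(truth, protocol = stimulation_protocol(), seed = 1,
                               side = c("right", "left"), noise_sd = 1.0,
                               params = stft_params(), region = tfa_region()) {
  side <- match.arg(side)
  stopifnot(inherits(protocol, "ssep_protocol"))
  truth <- as.list(truth)
  amplitude <- truth[[paste0("amplitude_", side)]]
  latency <- truth[[paste0("latency_", side)]]
  power <- truth[[paste0("tfa_power_", side)]]
  stopifnot(is.finite(amplitude), amplitude >= 0, is.finite(latency))

  fs <- protocol$sampling_rate
  n <- round(protocol$epoch_length / 1000 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  if (latency <= 0 || latency >= protocol$epoch_length) {
    abort("true latency falls outside the epoch window")
  }

  if (amplitude == 0) {
    template <- rep(0, n)
  } else {
    theta <- solve_shape(t_ms, amplitude, latency, power, fs, params, region)
    template <- build_template(t_ms, amplitude, latency, theta)
  }

  noise <- withr::with_seed(as.integer(seed), {
    band_limited_noise(protocol$n_trials, n, fs, protocol$bandpass, noise_sd)
  })
  data <- matrix(template, nrow = protocol$n_trials, ncol = n, byrow = TRUE) + noise
  ssep_epochs(data, sampling_rate = fs, onset_index = 1L, side = side,
              patient_id = as.character(truth$patient_id %||% "P000"))
}

#' Emit measured cord morphometry for cohort patients
#'
#' Converts each patient's morphometry truths into the scalars a reader
#' would measure on T2 images: AP and transverse diameters at maximal
#' compression, AP diameters at the adjacent normal levels, CSF occlusion
#' fraction and the deformation / signal-change flags. Diameters are solved
#' so that [compute_mscc()] and [compute_ccr()] recover the patient's truth
#' exactly, and the descriptor flags re-grade to the assigned grade.
#'
#' @param truth Cohort rows from [generate_cohort()] (any number of rows).
#' @param seed Integer master seed for the adjacent-level diameter draws.
#' @return A tibble, one row per patient: `patient_id`, `ap_diameter`,
#'   `transverse_diameter`, `ap_above`, `ap_below`, `csf_occlusion`,
#'   `deformation`, `signal_change`.
#' @export
generate_morphometry <- function(truth, seed = 1) {
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("patient_id", "mscc_true", "ccr_true", "csf_occlusion",
                  "deformation", "signal_change") %in% names(truth)))
  purrr::pmap_dfr(
    list(seq_len(nrow(truth)), truth$patient_id, truth$mscc_true,
         truth$ccr_true, truth$csf_occlusion, truth$deformation,
         truth$signal_change),
    function(i, id, mscc, ccr, occl, deform, sig) {
      withr::with_seed(derive_seed(seed, i), {
        ap_above <- rnorm_trunc(1, 8.0, 0.3, 6.5, 9.5)
        ap_below <- rnorm_trunc(1, 8.0, 0.3, 6.5, 9.5)
        ap <- (1 - mscc / 100) * (ap_above + ap_below) / 2
        tibble::tibble(
          patient_id = id,
          ap_diameter = ap,
          transverse_diameter = ap / ccr,
          ap_above = ap_above, ap_below = ap_below,
          csf_occlusion = occl,
          deformation = deform, signal_change = sig
        )
      })
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
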