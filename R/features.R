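#' Stimulus-locked SSEP epoch set
#'
#' Container for the raw trials of one patient/side: a trials x samples
#' matrix in microvolts plus the acquisition metadata needed to interpret
#' it.
#'
#' @param data Numeric matrix, trials in rows, samples in columns (uV).
#' @param sampling_rate Samples per second.
#' @param onset_index 1-based sample index of the stimulus.
#' @param side `"left"` or `"right"`.
#' @param patient_id Character scalar.
#' @return A `ssep_epochs` object.
#' @export
ssep_epochs <- function(data, sampling_rate, onset_index = 1L,
                        side = c("right", "left"), patient_id = "P000") {
  side <- match.arg(side)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric trials x samples matrix")
  }
  check_number(sampling_rate, "sampling_rate", lower = 1e-9)
  check_number(onset_index, "onset_index", lower = 1, upper = ncol(data))
  structure(
    list(data = data, sampling_rate = sampling_rate,
         onset_index = as.integer(onset_index), side = side,
         patient_id = as.character(patient_id)),
    class = "ssep_epochs"
  )
}

#' @export
print.ssep_epochs <- function(x, ...) {
  cat(sprintf("<ssep_epochs> %s/%s: %d trials x %d samples at %g samples/s\n",
              x$patient_id, x$side, nrow(x$data), ncol(x$data),
              x$sampling_rate))
  invisible(x)
}

#' Average trials into the event-related potential (ERP)
#'
#' The ERP is the pointwise arithmetic mean over trials,
#' `ERP[t] = sum_n X_n[t] / N`; averaging suppresses non-time-locked noise
#' by a factor of `sqrt(N)` while leaving the stimulus-locked response
#' intact.
#'
#' @param epochs A [ssep_epochs()] object with at least one trial.
#' @return A `ssep_erp` tibble with columns `time_ms` (post-stimulus) and
#'   `amplitude_uv`, carrying `sampling_rate`, `side` and `patient_id`
#'   attributes.
#' @examples
#' ep <- ssep_epochs(rbind(c(0, 1, 0), c(0, 3, 0)), sampling_rate = 1000)
#' compute_erp(ep)$amplitude_uv
#' @export
compute_erp <- function(epochs) {
  stopifnot(inherits(epochs, "ssep_epochs"))
  if (nrow(epochs$data) < 1L) {
    abort("epoch set contains zero trials")
  }
  if (anyNA(epochs$data) || !all(is.finite(epochs$data))) {
    abort("epoch data contain NA or non-finite samples")
  }
  values <- colMeans(epochs$data)
  time_ms <- (seq_along(values) - epochs$onset_index) / epochs$sampling_rate * 1000
  out <- tibble::tibble(time_ms = time_ms, amplitude_uv = values)
  attr(out, "sampling_rate") <- epochs$sampling_rate
  attr(out, "side") <- epochs$side
  attr(out, "patient_id") <- epochs$patient_id
  class(out) <- c("ssep_erp", class(out))
  out
}

# build an ssep_erp directly from a waveform vector (internal + testing)
erp_from_vector <- function(values, sampling_rate, onset_index = 1L,
                            side = "right", patient_id = "P000") {
  compute_erp(ssep_epochs(matrix(values, nrow = 1), sampling_rate,
                          onset_index, side, patient_id))
}

#' Peak-to-peak amplitude and latency of the maximal positive peak
#'
#' Within the search window, amplitude is the difference between the highest
#' and lowest ERP values (uV, always >= 0) and latency is the post-stimulus
#' time of the highest value (ms). Ties on the maximum resolve to the
#' earliest sample.
#'
#' @param erp A `ssep_erp` from [compute_erp()].
#' @param window Length-2 numeric, search window in ms post-stimulus;
#'   `NULL` uses the full epoch.
#' @return A one-row tibble with `amplitude_uv` and `latency_ms`.
#' @examples
#' erp <- compute_erp(ssep_epochs(matrix(c(0, 3, -1, 0), 1), 1000))
#' extract_amplitude_latency(erp)
#' @export
extract_amplitude_latency <- function(erp, window = NULL) {
  stopifnot(inherits(erp, "ssep_erp"))
  keep <- if (is.null(window)) {
    rep(TRUE, nrow(erp))
  } else {
    stopifnot(length(window) == 2L, window[2] > window[1])
    erp$time_ms >= window[1] & erp$time_ms <= window[2]
  }
  if (!any(keep)) {
    abort("search window contains no samples")
  }
  v <- erp$amplitude_uv[keep]
  t_ms <- erp$time_ms[keep]
  i_max <- which.max(v) # first maximum: earliest-time tie rule
  tibble::tibble(
    amplitude_uv = max(v) - min(v),
    latency_ms = t_ms[i_max]
  )
}

# fixed unit scale of the TFA power convention (see compute_tfa_power)
tfa_unit_scale <- 1.45

# STFT geometry shared by compute_tfa_power and the Parseval tests
stft_geometry <- function(n_samples, sampling_rate, params) {
  wl <- max(4L, round(params$window_frac * n_samples))
  wl <- min(wl, n_samples)
  noverlap <- min(wl - 1L, floor(params$overlap_frac * wl))
  nfft <- as.integer(2 * ceiling(params$zero_pad * wl / 2)) # even
  w <- switch(params$window_type,
    hann = as.numeric(signal::hanning(wl)),
    rect = rep(1, wl)
  )
  list(wl = wl, noverlap = noverlap, nfft = nfft, window = w)
}

#' Spectrogram and fixed-region time-frequency (TFA) power
#'
#' Decomposes the averaged SSEP with a short-time Fourier transform and sums
#' the squared magnitude over a fixed time x frequency rectangle. The
#' spectrogram is normalised by the squared window sum, so a unit-amplitude
#' sinusoid contributes cell power of order 1/4 per frame; the resulting TFA
#' power is a consistent arbitrary unit — only changes relative to a control
#' reference are interpreted downstream.
#'
#' @param erp A `ssep_erp` from [compute_erp()].
#' @param params [stft_params()].
#' @param region [tfa_region()]; a spectrogram cell counts when its centre
#'   falls inside the rectangle.
#' @return A list with `spectrogram` (a `ssep_spectrogram`: power matrix
#'   `freq x time`, axes, window descriptor) and `tfa_power` (numeric
#'   scalar, >= 0).
#' @examples
#' erp <- compute_erp(ssep_epochs(matrix(sin(2 * pi * 50 * (0:199) / 2000),
#'                                       nrow = 1), 2000))
#' compute_tfa_power(erp)$tfa_power
#' @export
compute_tfa_power <- function(erp, params = stft_params(), region = tfa_region()) {
  stopifnot(inherits(erp, "ssep_erp"), inherits(params, "ssep_stft_params"),
            inherits(region, "ssep_tfa_region"))
  fs <- attr(erp, "sampling_rate")
  x <- erp$amplitude_uv
  geom <- stft_geometry(length(x), fs, params)
  if (geom$wl < 2L) {
    abort("STFT window shorter than 2 samples")
  }
  sp <- signal::specgram(x, n = geom$nfft, Fs = fs, window = geom$window,
                         overlap = geom$noverlap)
  # unit convention: squared magnitude over squared window sum, times a
  # fixed package constant that puts microvolt-scale tibial SSEPs on a
  # convenient order-10 scale; only ratios to a control reference are
  # interpreted downstream
  power <- tfa_unit_scale * Mod(sp$S)^2 / sum(geom$window)^2
  freq_hz <- as.numeric(sp$f)
  # specgram timestamps frames by their 1-based start sample / Fs; convert to
  # window-centre times on the post-stimulus axis
  start_idx <- round(as.numeric(sp$t) * fs)
  centre_ms <- erp$time_ms[1] + (start_idx - 1 + (geom$wl - 1) / 2) / fs * 1000
  in_t <- centre_ms >= region$time_ms[1] & centre_ms <= region$time_ms[2]
  in_f <- freq_hz >= region$freq_hz[1] & freq_hz <= region$freq_hz[2]
  if (!any(in_t) || !any(in_f)) {
    abort("TFA region is disjoint from the spectrogram axes")
  }
  spec <- structure(
    list(power = power, freq_hz = freq_hz, time_ms = centre_ms,
         window = list(type = params$window_type, length = geom$wl,
                       overlap = geom$noverlap, nfft = geom$nfft),
         region = region),
    class = "ssep_spectrogram"
  )
  list(spectrogram = spec, tfa_power = sum(power[in_f, in_t]))
}

#' @export
print.ssep_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<ssep_spectrogram> %d freq bins x %d frames (%s window, %d samples, overlap %d)\n",
    nrow(x$power), ncol(x$power), x$window$type, x$window$length, x$window$overlap))
  invisible(x)
}

#' Extract the SSEP feature set of one epoch set
#'
#' Runs trial averaging, amplitude/latency extraction and fixed-region TFA
#' power in one call.
#'
#' @inheritParams compute_tfa_power
#' @param epochs A [ssep_epochs()] object.
#' @param window Latency/amplitude search window in ms (`NULL` = full epoch).
#' @return A one-row tibble: `patient_id`, `side`, `amplitude_uv`,
#'   `latency_ms`, `tfa_power`.
#' @export
extract_features <- function(epochs, window = NULL, params = stft_params(),
                             region = tfa_region()) {
  erp <- compute_erp(epochs)
  al <- extract_amplitude_latency(erp, window)
  tfa <- compute_tfa_power(erp, params, region)
  tibble::tibble(
    patient_id = epochs$patient_id,
    side = epochs$side,
    amplitude_uv = al$amplitude_uv,
    latency_ms = al$latency_ms,
    tfa_power = tfa$tfa_power
  )
}
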