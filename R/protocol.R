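#' Tibial-nerve SSEP stimulation and acquisition protocol
#'
#' Describes how stimulus-locked epochs are acquired: stimulation settings,
#' epoch geometry, and the acquisition bandpass. Defaults follow routine
#' intraoperative tibial SSEP practice: 22 mA, 0.2 ms pulses at 2.66
#' stimuli/s, a 100 ms post-stimulus analysis window, and a 10-500 Hz
#' bandpass. The sampling rate defaults to 2000 samples/s so the bandpass
#' sits below Nyquist; clinical gear sometimes reports lower nominal rates,
#' but a rate above twice the bandpass top is required here.
#'
#' @param stim_rate Stimuli per second.
#' @param pulse_width Stimulus pulse width, ms.
#' @param intensity Stimulus intensity, mA.
#' @param n_trials Number of stimulus repetitions entering the average.
#' @param sampling_rate Samples per second.
#' @param epoch_length Post-stimulus analysis window, ms.
#' @param bandpass Length-2 numeric, acquisition bandpass (low, high) in Hz.
#' @return A `ssep_protocol` list.
#' @examples
#' stimulation_protocol()
#' @export
stimulation_protocol <- function(stim_rate = 2.66,
                                 pulse_width = 0.2,
                                 intensity = 22,
                                 n_trials = 300,
                                 sampling_rate = 2000,
                                 epoch_length = 100,
                                 bandpass = c(10, 500)) {
  check_number(stim_rate, "stim_rate", lower = 1e-9)
  check_number(pulse_width, "pulse_width", lower = 1e-9)
  check_number(intensity, "intensity", lower = 0)
  check_number(n_trials, "n_trials", lower = 1)
  check_number(sampling_rate, "sampling_rate", lower = 1e-9)
  check_number(epoch_length, "epoch_length", lower = 1e-9)
  stopifnot(length(bandpass) == 2L, bandpass[1] > 0, bandpass[2] > bandpass[1])
  if (sampling_rate <= 2 * bandpass[2]) {
    abort("`sampling_rate` must exceed twice the bandpass high edge (Nyquist)")
  }
  structure(
    list(
      stim_rate = stim_rate, pulse_width = pulse_width, intensity = intensity,
      n_trials = as.integer(n_trials), sampling_rate = sampling_rate,
      epoch_length = epoch_length, bandpass = as.numeric(bandpass)
    ),
    class = "ssep_protocol"
  )
}

#' @export
print.ssep_protocol <- function(x, ...) {
  cat("<ssep_protocol>\n")
  cat(sprintf("  stimulation: %g mA, %g ms pulses at %g /s\n",
              x$intensity, x$pulse_width, x$stim_rate))
  cat(sprintf("  epochs: %d trials x %g ms at %g samples/s, bandpass %g-%g Hz\n",
              x$n_trials, x$epoch_length, x$sampling_rate,
              x$bandpass[1], x$bandpass[2]))
  invisible(x)
}

#' Short-time Fourier transform parameters
#'
#' Window and framing settings for the time-frequency decomposition of the
#' averaged SSEP. Defaults: Hann window covering 25% of the epoch, 75%
#' frame overlap, and 4x zero-padding for finer frequency sampling.
#'
#' @param window_frac Window length as a fraction of the epoch samples.
#' @param overlap_frac Frame overlap as a fraction of the window length.
#' @param zero_pad FFT zero-padding factor (nfft = zero_pad x window length).
#' @param window_type `"hann"` or `"rect"`.
#' @return A `ssep_stft_params` list.
#' @export
stft_params <- function(window_frac = 0.25,
                        overlap_frac = 0.75,
                        zero_pad = 4,
                        window_type = c("hann", "rect")) {
  window_type <- match.arg(window_type)
  check_number(window_frac, "window_frac", lower = 1e-9, upper = 1)
  check_number(overlap_frac, "overlap_frac", lower = 0, upper = 0.99)
  check_number(zero_pad, "zero_pad", lower = 1)
  structure(
    list(window_frac = window_frac, overlap_frac = overlap_frac,
         zero_pad = zero_pad, window_type = window_type),
    class = "ssep_stft_params"
  )
}

#' Fixed time-frequency region for TFA power
#'
#' The rectangle of the spectrogram over which power is summed: by default
#' the whole 100 ms analysis window crossed with 10-100 Hz, covering the
#' band where tibial P40 energy concentrates.
#'
#' @param time_ms Length-2 numeric, post-stimulus time range in ms.
#' @param freq_hz Length-2 numeric, frequency range in Hz.
#' @return A `ssep_tfa_region` list.
#' @export
tfa_region <- function(time_ms = c(0, 100), freq_hz = c(10, 100)) {
  stopifnot(length(time_ms) == 2L, time_ms[2] > time_ms[1])
  stopifnot(length(freq_hz) == 2L, freq_hz[2] > freq_hz[1], freq_hz[1] >= 0)
  structure(list(time_ms = as.numeric(time_ms), freq_hz = as.numeric(freq_hz)),
            class = "ssep_tfa_region")
}

#' Abnormality thresholds for SSEP feature changes
#'
#' Percent-change cuts, relative to control-group means, beyond which a
#' feature is called abnormal: amplitude reduced by >= 50%, TFA power
#' reduced by >= 30%, latency delayed by >= 10%. All cuts are inclusive.
#'
#' @param amplitude_reduction_cut Fractional amplitude reduction cut.
#' @param power_loss_cut Fractional TFA power loss cut.
#' @param latency_delay_cut Fractional latency delay cut.
#' @return A `ssep_thresholds` list.
#' @export
threshold_config <- function(amplitude_reduction_cut = 0.50,
                             power_loss_cut = 0.30,
                             latency_delay_cut = 0.10) {
  for (nm in c("amplitude_reduction_cut", "power_loss_cut", "latency_delay_cut")) {
    check_number(get(nm), nm, lower = 1e-9, upper = 1 - 1e-9)
  }
  structure(
    list(amplitude_reduction_cut = amplitude_reduction_cut,
         power_loss_cut = power_loss_cut,
         latency_delay_cut = latency_delay_cut),
    class = "ssep_thresholds"
  )
}
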