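test_that("ERP averaging is the pointwise trial mean", {
  tpl <- c(0, 1, 3, -1, 0)
  ep <- ssep_epochs(matrix(tpl, nrow = 5, ncol = 5, byrow = TRUE), 1000)
  expect_equal(compute_erp(ep)$amplitude_uv, tpl) # identity under averaging
  ep2 <- ssep_epochs(rbind(tpl, -tpl), 1000)
  expect_equal(compute_erp(ep2)$amplitude_uv, rep(0, 5)) # symmetry
  ep3 <- ssep_epochs(rbind(c(1, 0), c(2, 0), c(6, 0)), 1000)
  expect_equal(compute_erp(ep3)$amplitude_uv[1], 3) # hand mean of {1,2,6}
  bad <- ssep_epochs(rbind(tpl, tpl), 1000)
  bad$data[1, 2] <- NaN
  expect_error(compute_erp(bad), "NA or non-finite")
})

test_that("ERP and features are invariant to trial order", {
  set.seed(5)
  m <- matrix(rnorm(40), nrow = 8)
  ep <- ssep_epochs(m, 2000)
  ep_perm <- ssep_epochs(m[sample(8), ], 2000)
  expect_equal(compute_erp(ep)$amplitude_uv, compute_erp(ep_perm)$amplitude_uv)
})

test_that("amplitude is max - min and latency the earliest maximum", {
  erp <- compute_erp(ssep_epochs(matrix(c(0, 3, -1, 0), 1), 1000))
  al <- extract_amplitude_latency(erp)
  expect_equal(al$amplitude_uv, 4)
  expect_equal(al$latency_ms, 1) # sample 2 at 1000 samples/s, onset index 1
  # flat waveform: zero amplitude, tie resolves to the window start
  flat <- compute_erp(ssep_epochs(matrix(0, 1, 6), 1000))
  al0 <- extract_amplitude_latency(flat)
  expect_equal(al0$amplitude_uv, 0)
  expect_equal(al0$latency_ms, 0)
  # duplicate maxima: earliest wins
  erp2 <- compute_erp(ssep_epochs(matrix(c(0, 2, 1, 2, 0), 1), 1000))
  expect_equal(extract_amplitude_latency(erp2)$latency_ms, 1)
  # windowing restricts the search
  erp3 <- compute_erp(ssep_epochs(matrix(c(9, 0, 1, 5, 0), 1), 1000))
  al3 <- extract_amplitude_latency(erp3, window = c(1, 4))
  expect_equal(al3$amplitude_uv, 5)
  expect_equal(al3$latency_ms, 3)
  expect_error(extract_amplitude_latency(erp3, window = c(10, 20)),
               "no samples")
})

test_that("amplitude extraction equals a brute-force scan oracle", {
  set.seed(31)
  for (i in 1:20) {
    v <- rnorm(100)
    erp <- compute_erp(ssep_epochs(matrix(v, 1), 2000))
    al <- extract_amplitude_latency(erp)
    expect_equal(al$amplitude_uv, max(v) - min(v))
    expect_equal(al$latency_ms, erp$time_ms[which(v == max(v))[1]])
  }
})

test_that("TFA power concentrates at the stimulus frequency", {
  # a second of signal so the default window (25% of the epoch) resolves
  # 50 Hz well inside a 20 Hz-wide band
  fs <- 2000
  x <- sin(2 * pi * 50 * (0:1999) / fs)
  erp <- compute_erp(ssep_epochs(matrix(x, 1), fs))
  reg <- function(lo, hi) tfa_region(time_ms = c(0, 1000), freq_hz = c(lo, hi))
  total <- compute_tfa_power(erp, region = reg(0, 999))
  at_50 <- compute_tfa_power(erp, region = reg(40, 60))
  away <- compute_tfa_power(erp, region = reg(150, 200))
  expect_gt(at_50$tfa_power / total$tfa_power, 0.95)
  expect_lt(away$tfa_power / total$tfa_power, 0.01)
})

test_that("TFA power is quadratic in amplitude, monotone in region, zero for silence", {
  fs <- 2000
  set.seed(3)
  x <- as.numeric(stats::filter(rnorm(200), rep(0.2, 5), circular = TRUE))
  erp <- compute_erp(ssep_epochs(matrix(x, 1), fs))
  erp3 <- compute_erp(ssep_epochs(matrix(3 * x, 1), fs))
  p1 <- compute_tfa_power(erp)$tfa_power
  expect_equal(compute_tfa_power(erp3)$tfa_power, 9 * p1, tolerance = 1e-12)

  zero <- compute_erp(ssep_epochs(matrix(0, 1, 200), fs))
  expect_equal(compute_tfa_power(zero)$tfa_power, 0)

  small <- compute_tfa_power(erp, region = tfa_region(c(20, 60), c(20, 60)))$tfa_power
  big <- compute_tfa_power(erp, region = tfa_region(c(10, 90), c(10, 90)))$tfa_power
  full <- compute_tfa_power(erp, region = tfa_region(c(0, 100), c(0, 999)))$tfa_power
  expect_true(small <= big && big <= full)

  expect_error(compute_tfa_power(erp, region = tfa_region(c(0, 100), c(1200, 1500))),
               "disjoint")
})

test_that("rectangular-window spectrogram satisfies a Parseval-type energy identity", {
  fs <- 2000
  x <- sin(2 * pi * 35 * (0:199) / fs) + 0.5 * sin(2 * pi * 80 * (0:199) / fs)
  erp <- compute_erp(ssep_epochs(matrix(x, 1), fs))
  params <- stft_params(window_frac = 0.25, overlap_frac = 0, zero_pad = 4,
                        window_type = "rect")
  out <- compute_tfa_power(erp, params, tfa_region(c(0, 100), c(0, 999)))
  spec <- out$spectrogram
  # non-overlapping rectangular frames tile the signal; for a signal with no
  # DC/Nyquist energy the retained half-spectrum carries half of
  # nfft * energy, times the package unit scale over the squared window sum
  wl <- spec$window$length
  nfft <- spec$window$nfft
  n_frames <- ncol(spec$power)
  covered <- x[seq_len(n_frames * wl)] # frames tile the framed prefix
  expected <- ssepmri:::tfa_unit_scale * nfft * sum(covered^2) / (2 * wl^2)
  expect_equal(sum(spec$power), expected, tolerance = 0.01)
})

test_that("spectrogram frames match a direct windowed-DFT oracle", {
  fs <- 2000
  set.seed(17)
  x <- rnorm(200)
  erp <- compute_erp(ssep_epochs(matrix(x, 1), fs))
  params <- stft_params(window_frac = 0.25, overlap_frac = 0.75,
                        zero_pad = 4, window_type = "hann")
  spec <- compute_tfa_power(erp, params)$spectrogram
  wl <- spec$window$length
  step <- wl - spec$window$overlap
  nfft <- spec$window$nfft
  w <- as.numeric(signal::hanning(wl))
  starts <- seq(1, length(x) - wl, by = step) # specgram framing convention
  oracle <- vapply(starts, function(s0) {
    seg <- x[s0:(s0 + wl - 1)] * w
    X <- stats::fft(c(seg, rep(0, nfft - wl)))
    sum(Mod(X[seq_len(nfft / 2)])^2) * ssepmri:::tfa_unit_scale / sum(w)^2
  }, numeric(1))
  expect_equal(length(starts), ncol(spec$power))
  expect_equal(colSums(spec$power), oracle, tolerance = 1e-10)
})
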