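small_cfg <- function(...) {
  cohort_config(n_per_grade = c(2, 2, 2, 2), n_trials = 10, ...)
}

test_that("cohort generation is deterministic and respects grade counts", {
  cfg <- cohort_config(n_per_grade = c(3, 5, 7, 2))
  co1 <- generate_cohort(cfg, seed = 4)
  co2 <- generate_cohort(cfg, seed = 4)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 17)
  expect_equal(as.integer(table(factor(co1$grade, levels = 0:3))), c(3, 5, 7, 2))
  expect_false(identical(co1$amplitude_right,
                         generate_cohort(cfg, seed = 5)$amplitude_right))
  expect_error(cohort_config(n_per_grade = c(0, 0, 0, 0)), "at least one")
  expect_error(cohort_config(amplitude_median = list(left = rep(1, 4),
                                                     right = c(1, 1, Inf, 1))),
               "positive finite")
})

test_that("per-patient RNG streams keep existing patients stable under count changes", {
  strip <- function(d) {
    attr(d, "config") <- NULL
    attr(d, "seed") <- NULL
    d
  }
  co_small <- generate_cohort(cohort_config(n_per_grade = c(2, 2, 2, 2)), seed = 9)
  co_big <- generate_cohort(cohort_config(n_per_grade = c(2, 2, 2, 3)), seed = 9)
  expect_identical(strip(co_small), strip(co_big[seq_len(nrow(co_small)), ]))
})

test_that("zero dispersion collapses every draw onto the grade median", {
  cfg <- cohort_config(n_per_grade = c(3, 3, 3, 3),
                       amplitude_log_sd = 0, tfa_power_log_sd = 0,
                       latency_sd = 0, ccr_log_sd = 0, mscc_sd = rep(0, 4))
  co <- generate_cohort(cfg, seed = 2)
  for (g in 0:3) {
    sub <- co[co$grade == g, ]
    expect_equal(sub$amplitude_right, rep(cfg$amplitude_median$right[g + 1], 3))
    expect_equal(sub$latency_right, rep(cfg$latency_median$right[g + 1], 3))
    expect_equal(sub$mscc_true, rep(cfg$mscc_median[g + 1], 3))
  }
  # grade-0 morphometry at zero dispersion measures back the target MSCC
  m <- grade_morphometry(generate_morphometry(co[co$grade == 0, ], seed = 1))
  expect_equal(m$mscc, rep(2.14, 3))
  expect_equal(m$ccr, rep(0.48, 3))
})

test_that("epoch simulation is reproducible and honours the truth parameters", {
  co <- generate_cohort(small_cfg(), seed = 1)
  proto <- tiny_protocol(10)
  e1 <- generate_epoch_set(co[3, ], proto, seed = 42, noise_sd = 0.4)
  e2 <- generate_epoch_set(co[3, ], proto, seed = 42, noise_sd = 0.4)
  expect_identical(e1$data, e2$data) # bit-identical under the same seed
  expect_equal(dim(e1$data), c(10L, 200L))

  # noiseless trials are all identical to the template and extraction
  # recovers the truth to one sample period
  e0 <- generate_epoch_set(co[3, ], proto, seed = 42, noise_sd = 0)
  expect_equal(e0$data[1, ], e0$data[10, ])
  f <- extract_features(e0)
  expect_equal(f$amplitude_uv, co$amplitude_right[3], tolerance = 1e-12)
  expect_lte(abs(f$latency_ms - co$latency_right[3]), 1000 / proto$sampling_rate)

  bad <- co[3, ]; bad$latency_right <- 150
  expect_error(generate_epoch_set(bad, proto, seed = 1), "outside the epoch")
})

test_that("averaging suppresses noise roughly as 1/sqrt(N) for a null template", {
  tr <- truth_row(amplitude = 0, latency = 40, power = 0)
  proto <- stimulation_protocol(n_trials = 400)
  ep <- generate_epoch_set(tr, proto, seed = 8, noise_sd = 1)
  f <- extract_features(ep)
  # residual ERP noise SD is 1/sqrt(400) = 0.05 uV; the peak-to-peak of the
  # averaged trace stays an order of magnitude below any grade median
  expect_lt(f$amplitude_uv, 0.5)
  expect_gt(f$amplitude_uv, 0) # but not exactly zero
})

test_that("noiseless extracted amplitude is monotone in the true amplitude", {
  proto <- tiny_protocol(4)
  amps <- c(2.4, 1.8, 1.2, 0.6)
  got <- vapply(amps, function(a) {
    ep <- generate_epoch_set(truth_row(amplitude = a, power = 3 * a^2),
                             proto, seed = 1, noise_sd = 0)
    extract_features(ep)$amplitude_uv
  }, numeric(1))
  expect_true(all(diff(got) < 0))
})

test_that("generated morphometry re-grades to the assigned grade", {
  co <- generate_cohort(cohort_config(n_per_grade = c(10, 10, 10, 10)), seed = 6)
  graded <- grade_morphometry(generate_morphometry(co, seed = 3))
  expect_gte(mean(graded$grade == co$grade), 0.99)
  # descriptor flags follow the grade definitions
  expect_true(all(co$deformation[co$grade >= 2]))
  expect_true(all(co$signal_change[co$grade == 3]))
  expect_true(all(!co$deformation[co$grade <= 1]))
  expect_true(all(co$csf_occlusion[co$grade == 1] > 0.5))
})

test_that("exact category mode reproduces the configured per-grade counts", {
  cfg <- cohort_config(category_mode = "exact")
  co <- generate_cohort(cfg, seed = 12)
  counts <- table(factor(co$category[co$grade > 0], levels = c("A", "B", "C", "D")),
                  co$grade[co$grade > 0])
  expect_equal(unname(counts[, "1"]), c(27L, 4L, 4L, 0L))
  expect_equal(unname(counts[, "2"]), c(24L, 25L, 8L, 0L))
  expect_equal(unname(counts[, "3"]), c(15L, 12L, 7L, 0L))
  # truths respect the category bounds around the configured reference
  red <- 1 - co$amplitude_right / cfg$reference_amplitude
  loss <- 1 - co$tfa_power_right / cfg$reference_tfa_power
  cmp <- co$grade > 0
  expect_true(all((red[cmp] >= 0.5) == (co$category[cmp] %in% c("B", "C"))))
  expect_true(all((loss[cmp] >= 0.3) == (co$category[cmp] %in% c("C", "D"))))
})

test_that("epoch writer and reader round-trip the matrix and metadata", {
  co <- generate_cohort(small_cfg(), seed = 2)
  ep <- generate_epoch_set(co[1, ], tiny_protocol(5), seed = 3, noise_sd = 0.2)
  prefix <- file.path(withr::local_tempdir(), "p001_right")
  write_epochs(ep, prefix)
  back <- read_epochs(prefix)
  expect_equal(back$data, ep$data, tolerance = 1e-12)
  expect_identical(back$side, ep$side)
  expect_identical(back$patient_id, ep$patient_id)
  expect_equal(back$sampling_rate, ep$sampling_rate)
})
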