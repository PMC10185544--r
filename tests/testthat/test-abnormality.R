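features_row <- function(id, amp, lat, pow, side = "right") {
  tibble::tibble(patient_id = id, side = side, amplitude_uv = amp,
                 latency_ms = lat, tfa_power = pow)
}

test_that("control reference is the per-side arithmetic mean with SEM", {
  f <- dplyr::bind_rows(
    features_row("C1", 2, 40, 5), features_row("C2", 3, 42, 7),
    features_row("C1", 2.5, 41, 6, side = "left")
  )
  ref <- build_control_reference(f)
  right <- ref[ref$side == "right", ]
  expect_equal(right$mean_amplitude, 2.5) # two-point mean
  expect_equal(right$mean_tfa_power, 6)
  expect_equal(right$sem_amplitude, stats::sd(c(2, 3)) / sqrt(2))
  left <- ref[ref$side == "left", ]
  expect_equal(left$n_controls, 1L)
  expect_true(is.na(left$sem_amplitude)) # SEM undefined for n = 1
  expect_error(build_control_reference(f[0, ]), "non-empty")
})

ref_list <- list(mean_amplitude = 2.58, mean_latency = 40, mean_tfa_power = 6.37)

test_that("percent changes and flags follow the inclusive 50/30/10 criteria", {
  calls <- classify_abnormality(features_row("P1", 1.00, 40, 6.37), ref_list)
  expect_equal(calls$amplitude_reduction, 1 - 1.00 / 2.58) # about 0.612
  expect_true(calls$amplitude_abnormal)
  expect_identical(calls$category, "B")

  # power loss 1 - 4.70/6.37 = 0.262 < 0.30: no power abnormality
  calls <- classify_abnormality(features_row("P2", 1.00, 40, 4.70), ref_list)
  expect_false(calls$power_abnormal)
  expect_identical(calls$category, "B")

  # patient identical to the reference: all changes zero, category A
  calls <- classify_abnormality(features_row("P3", 2.58, 40, 6.37), ref_list)
  expect_equal(calls$amplitude_reduction, 0)
  expect_equal(calls$power_loss, 0)
  expect_equal(calls$latency_delay, 0)
  expect_identical(calls$category, "A")

  # cuts are inclusive: exactly 50% reduction / 30% loss / 10% delay count
  calls <- classify_abnormality(
    features_row("P4", 2.58 / 2, 40 * 1.1, 6.37 * 0.7), ref_list)
  expect_true(calls$amplitude_abnormal)
  expect_true(calls$power_abnormal)
  expect_true(calls$latency_abnormal)
  expect_identical(calls$category, "C")

  # power-only abnormality is representable (category D)
  calls <- classify_abnormality(features_row("P5", 2.58, 40, 2.0), ref_list)
  expect_identical(calls$category, "D")

  # patient better than control keeps a negative reduction, still normal
  calls <- classify_abnormality(features_row("P6", 3.5, 38, 9), ref_list)
  expect_lt(calls$amplitude_reduction, 0)
  expect_identical(calls$category, "A")
})

test_that("classification is invariant to a common amplitude rescaling", {
  f <- dplyr::bind_rows(features_row("P1", 1.1, 40, 5),
                        features_row("P2", 2.6, 44, 3))
  c1 <- classify_abnormality(f, ref_list)
  f2 <- dplyr::mutate(f, amplitude_uv = amplitude_uv * 7.3)
  ref2 <- ref_list; ref2$mean_amplitude <- ref_list$mean_amplitude * 7.3
  c2 <- classify_abnormality(f2, ref2)
  expect_identical(c1$category, c2$category)
  expect_equal(c1$amplitude_reduction, c2$amplitude_reduction)
})

test_that("missing reference side and non-positive means are rejected", {
  f <- features_row("P1", 1, 40, 5, side = "left")
  ref_right_only <- tibble::tibble(side = "right", mean_amplitude = 2,
                                   mean_latency = 40, mean_tfa_power = 5)
  expect_error(classify_abnormality(f, ref_right_only), "no control reference")
  bad_ref <- list(mean_amplitude = -1, mean_latency = 40, mean_tfa_power = 5)
  expect_error(classify_abnormality(f, bad_ref), "positive")
})

test_that("per-grade tabulation reproduces engineered cell counts and proportions", {
  calls <- dplyr::bind_rows(
    engineered_calls(1, 27, 4, 4, 0),
    engineered_calls(2, 24, 25, 8, 0),
    engineered_calls(3, 15, 12, 7, 0)
  )
  tabs <- tabulate_by_grade(calls)
  g1 <- tabs[tabs$grade == 1, ]
  expect_equal(g1$n, 35)
  expect_equal(unlist(g1[, c("n_normal", "n_amp_only", "n_amp_power",
                             "n_power_only")], use.names = FALSE),
               c(27, 4, 4, 0))
  expect_equal(g1$table[[1]],
               matrix(c(27, 4, 0, 4), 2, byrow = TRUE,
                      dimnames = dimnames(g1$table[[1]])))
  expect_equal(round(100 * unlist(g1[, c("p_normal", "p_amp_only",
                                         "p_amp_power", "p_power_only")],
                                  use.names = FALSE), 1),
               c(77.1, 11.4, 11.4, 0))
  # conservation: cells sum to the grade count
  expect_true(all(tabs$n_normal + tabs$n_amp_only + tabs$n_amp_power +
                    tabs$n_power_only == tabs$n))
})

test_that("degenerate tabulations are handled explicitly", {
  all_a <- engineered_calls(2, 6, 0, 0, 0)
  tabs <- tabulate_by_grade(all_a, grade_levels = 2)
  expect_equal(tabs$table[[1]][1, 1], 6)
  expect_equal(sum(tabs$table[[1]]) - tabs$table[[1]][1, 1], 0)

  empty <- tabulate_by_grade(all_a, grade_levels = 3)
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$p_normal)) # proportions undefined on empty strata

  # a call whose patient has no grade is an error
  grades <- tibble::tibble(patient_id = all_a$patient_id[-1], grade = 2)
  expect_error(tabulate_by_grade(dplyr::select(all_a, -grade), grades),
               "without a grade")
})
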