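#' Control-group reference means
#'
#' Per-side arithmetic means (with standard errors) of amplitude, latency
#' and TFA power over the control (grade 0) patients. These means are the
#' denominators of the percent-change abnormality criteria.
#'
#' @param control_features Feature tibble (from [extract_features()] rows)
#'   for control patients only; columns `side`, `amplitude_uv`,
#'   `latency_ms`, `tfa_power`.
#' @return A `ssep_control_reference` tibble: one row per side with
#'   `n_controls`, `mean_*` and `sem_*` columns (`sem_*` is `NA` when
#'   `n_controls == 1`).
#' @export
build_control_reference <- function(control_features) {
  control_features <- tibble::as_tibble(control_features)
  needed <- c("side", "amplitude_uv", "latency_ms", "tfa_power")
  if (!all(needed %in% names(control_features)) || nrow(control_features) == 0) {
    abort("control feature table must be non-empty with columns side, amplitude_uv, latency_ms, tfa_power")
  }
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  out <- control_features |>
    dplyr::group_by(.data$side) |>
    dplyr::summarise(
      n_controls = dplyr::n(),
      mean_amplitude = mean(.data$amplitude_uv),
      sem_amplitude = sem(.data$amplitude_uv),
      mean_latency = mean(.data$latency_ms),
      sem_latency = sem(.data$latency_ms),
      mean_tfa_power = mean(.data$tfa_power),
      sem_tfa_power = sem(.data$tfa_power),
      .groups = "drop"
    )
  if (any(out$mean_amplitude <= 0) || any(out$mean_tfa_power <= 0) ||
      any(out$mean_latency <= 0)) {
    abort("control reference means must be positive")
  }
  class(out) <- c("ssep_control_reference", class(out))
  out
}

#' Classify SSEP feature changes against a control reference
#'
#' Computes, per patient/side, the fractional amplitude reduction
#' `1 - amplitude/ref`, TFA power loss `1 - power/ref` and latency delay
#' `latency/ref - 1`; flags each as abnormal at the (inclusive) thresholds;
#' and assigns the category:
#' \describe{
#'   \item{A}{no amplitude or power abnormality}
#'   \item{B}{amplitude abnormal, no power loss}
#'   \item{C}{amplitude abnormal with power loss}
#'   \item{D}{power abnormal without amplitude abnormality}
#' }
#' Negative changes (patient better than the control mean) are retained as
#' negative fractions and always classify as normal.
#'
#' @param features Feature tibble with columns `patient_id`, `side`,
#'   `amplitude_uv`, `latency_ms`, `tfa_power`.
#' @param reference A [build_control_reference()] result, or a named list
#'   with `mean_amplitude`, `mean_latency`, `mean_tfa_power` (applied to
#'   every side present).
#' @param thresholds A [threshold_config()].
#' @return A tibble of abnormality calls: the change fractions, the three
#'   flags and `category`.
#' @export
classify_abnormality <- function(features, reference,
                                 thresholds = threshold_config()) {
  features <- tibble::as_tibble(features)
  stopifnot(inherits(thresholds, "ssep_thresholds"))
  if (inherits(reference, "ssep_control_reference") || is.data.frame(reference)) {
    ref <- tibble::as_tibble(reference)[, c("side", "mean_amplitude",
                                            "mean_latency", "mean_tfa_power")]
    missing_side <- setdiff(unique(features$side), ref$side)
    if (length(missing_side)) {
      abort(paste("no control reference for side:", paste(missing_side, collapse = ", ")))
    }
    joined <- dplyr::left_join(features, ref, by = "side")
  } else {
    joined <- dplyr::mutate(features,
      mean_amplitude = reference$mean_amplitude,
      mean_latency = reference$mean_latency,
      mean_tfa_power = reference$mean_tfa_power
    )
  }
  if (any(joined$mean_amplitude <= 0) || any(joined$mean_tfa_power <= 0) ||
      any(joined$mean_latency <= 0)) {
    abort("reference means must be positive")
  }
  joined |>
    dplyr::mutate(
      amplitude_reduction = 1 - .data$amplitude_uv / .data$mean_amplitude,
      power_loss = 1 - .data$tfa_power / .data$mean_tfa_power,
      latency_delay = .data$latency_ms / .data$mean_latency - 1,
      amplitude_abnormal = .data$amplitude_reduction >= thresholds$amplitude_reduction_cut,
      power_abnormal = .data$power_loss >= thresholds$power_loss_cut,
      latency_abnormal = .data$latency_delay >= thresholds$latency_delay_cut,
      category = dplyr::case_when(
        .data$amplitude_abnormal & .data$power_abnormal ~ "C",
        .data$amplitude_abnormal ~ "B",
        .data$power_abnormal ~ "D",
        TRUE ~ "A"
      )
    ) |>
    dplyr::select(-dplyr::all_of(c("mean_amplitude", "mean_latency",
                                   "mean_tfa_power")))
}

#' Per-grade 2x2 contingency tables of amplitude reduction x power loss
#'
#' For each MRI grade, counts patients in the four cells of amplitude
#' reduction (below / at-or-above the cut) crossed with TFA power loss
#' (below / at-or-above the cut), together with cell proportions of the
#' grade's patient count and the category (A/B/D/C) mapping.
#'
#' @param calls Abnormality calls from [classify_abnormality()].
#' @param grades Data frame with `patient_id` and `grade` (every call must
#'   match a grade), or omitted when `calls` already has a `grade` column.
#' @param grade_levels Grades to tabulate (default the compression grades
#'   1-3).
#' @return A `ssep_grade_tables` tibble: one row per grade with `n` and the
#'   cell counts `n_normal` (A), `n_amp_only` (B), `n_amp_power` (C),
#'   `n_power_only` (D), matching `p_*` proportions (NA when `n = 0`), and
#'   a list-column `table` holding the 2x2 matrix (rows: power loss < cut /
#'   >= cut; columns: amplitude reduction < cut / >= cut).
#' @export
tabulate_by_grade <- function(calls, grades = NULL, grade_levels = 1:3) {
  calls <- tibble::as_tibble(calls)
  if (!is.null(grades)) {
    grades <- tibble::as_tibble(grades)[, c("patient_id", "grade")]
    unmatched <- setdiff(calls$patient_id, grades$patient_id)
    if (length(unmatched)) {
      abort(paste("calls without a grade:", paste(head(unmatched, 5), collapse = ", ")))
    }
    calls <- dplyr::left_join(dplyr::select(calls, -dplyr::any_of("grade")),
                              grades, by = "patient_id")
  }
  if (!"grade" %in% names(calls)) {
    abort("supply `grades` or include a `grade` column in `calls`")
  }
  purrr::map_dfr(grade_levels, function(g) {
    sub <- calls[calls$grade == g, ]
    n <- nrow(sub)
    counts <- c(
      A = sum(sub$category == "A"), B = sum(sub$category == "B"),
      C = sum(sub$category == "C"), D = sum(sub$category == "D")
    )
    tab <- matrix(c(counts["A"], counts["B"], counts["D"], counts["C"]),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(power_loss = c("<cut", ">=cut"),
                                  amplitude_reduction = c("<cut", ">=cut")))
    tibble::tibble(
      grade = g, n = n,
      n_normal = counts[["A"]], n_amp_only = counts[["B"]],
      n_amp_power = counts[["C"]], n_power_only = counts[["D"]],
      p_normal = if (n > 0) counts[["A"]] / n else NA_real_,
      p_amp_only = if (n > 0) counts[["B"]] / n else NA_real_,
      p_amp_power = if (n > 0) counts[["C"]] / n else NA_real_,
      p_power_only = if (n > 0) counts[["D"]] / n else NA_real_,
      table = list(tab)
    )
  }) |>
    structure(class = c("ssep_grade_tables", class(tibble::tibble())))
}
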