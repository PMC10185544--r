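interpret_tau <- function(tau) {
  dplyr::case_when(
    abs(tau) < 0.3 ~ "low",
    abs(tau) <= 0.7 ~ "moderate",
    TRUE ~ "high"
  )
}

# long feature table -> one row per patient with side-prefixed columns
widen_features <- function(features) {
  features |>
    tibble::as_tibble() |>
    dplyr::select(dplyr::all_of(c("patient_id", "side", "amplitude_uv",
                                  "latency_ms", "tfa_power"))) |>
    tidyr::pivot_wider(
      names_from = "side",
      values_from = c("amplitude_uv", "latency_ms", "tfa_power"),
      names_glue = "{side}_{.value}"
    ) |>
    dplyr::rename_with(~ sub("_uv$|_ms$", "", .x))
}

#' Grade-wise association summary of morphometry and SSEP features
#'
#' Assembles the statistical layer in one report: the Kendall tau-b matrix
#' over CCR, MSCC and the six side-specific SSEP features (with two-tailed
#' p-values and low/moderate/high interpretation bands at |tau| 0.3 and
#' 0.7), a Kruskal-Wallis test across the four MRI grades for every
#' continuous variable, and the per-grade 2x2 Fisher tests of amplitude
#' reduction x power loss on the analysis side.
#'
#' @param features Long feature tibble (`patient_id`, `side`,
#'   `amplitude_uv`, `latency_ms`, `tfa_power`), both sides per patient.
#' @param grades Data frame with `patient_id` and `grade`.
#' @param morphometry Data frame with `patient_id`, `ccr`, `mscc` (e.g. from
#'   [grade_morphometry()]).
#' @param side Analysis side for the abnormality contingency tables.
#' @param thresholds A [threshold_config()].
#' @return A `ssep_association_summary` list: `tau` (pairwise tibble),
#'   `kruskal`, `grade_tables` (with Fisher p-values), and the `calls`
#'   behind them.
#' @export
grade_association_summary <- function(features, grades, morphometry,
                                      side = c("right", "left"),
                                      thresholds = threshold_config()) {
  side <- match.arg(side)
  wide <- widen_features(features)
  grades <- tibble::as_tibble(grades)[, c("patient_id", "grade")]
  morpho <- tibble::as_tibble(morphometry)[, c("patient_id", "ccr", "mscc")]
  ids <- sort(wide$patient_id)
  if (!identical(ids, sort(grades$patient_id)) ||
      !identical(ids, sort(morpho$patient_id))) {
    abort("features, grades and morphometry must cover the same patients")
  }
  df <- wide |>
    dplyr::inner_join(grades, by = "patient_id") |>
    dplyr::inner_join(morpho, by = "patient_id")

  vars <- c("ccr", "mscc",
            "left_amplitude", "right_amplitude",
            "left_latency", "right_latency",
            "left_tfa_power", "right_tfa_power")
  vars <- intersect(vars, names(df))
  pairs <- combn(vars, 2)
  tau_tbl <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    v1 <- pairs[1, j]; v2 <- pairs[2, j]
    res <- kendall_tau_b(df[[v1]], df[[v2]])
    tibble::tibble(var1 = v1, var2 = v2, tau = res$statistic,
                   p_value = res$p_value, band = interpret_tau(res$statistic))
  })

  kw_tbl <- purrr::map_dfr(vars, function(v) {
    groups <- split(df[[v]], df$grade)
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2) {
      return(tibble::tibble(variable = v, h = NA_real_, p_value = NA_real_))
    }
    res <- kruskal_wallis_h(groups)
    tibble::tibble(variable = v, h = res$statistic, p_value = res$p_value)
  })

  controls <- df$patient_id[df$grade == 0]
  feats <- tibble::as_tibble(features)
  calls <- NULL
  tables <- NULL
  if (length(controls) > 0) {
    ref <- build_control_reference(feats[feats$patient_id %in% controls, ])
    calls <- classify_abnormality(feats[feats$side == side, ], ref, thresholds)
    tables <- tabulate_by_grade(calls, grades)
    tables$fisher_p <- vapply(seq_len(nrow(tables)), function(k) {
      if (tables$n[k] == 0) NA_real_ else fisher_exact_2x2(tables$table[[k]])$p_value
    }, numeric(1))
  }

  structure(
    list(tau = tau_tbl, kruskal = kw_tbl, grade_tables = tables,
         calls = calls, side = side, thresholds = thresholds,
         quantile_type = 7),
    class = "ssep_association_summary"
  )
}

#' @export
print.ssep_association_summary <- function(x, ...) {
  cat("<ssep_association_summary>\n")
  cat(sprintf("  %d tau-b pairs; %d Kruskal-Wallis tests; analysis side: %s\n",
              nrow(x$tau), nrow(x$kruskal), x$side))
  if (!is.null(x$grade_tables)) {
    cat("  per-grade Fisher p:",
        paste(sprintf("grade %d = %.3f", x$grade_tables$grade,
                      x$grade_tables$fisher_p), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-grade medians and quartiles of cohort variables
#'
#' Summarises each continuous variable as `median (Q1, Q3)` within each MRI
#' grade with a Kruskal-Wallis p-value across grades — the demographic /
#' morphometry / feature summary table of the analysis. Quartiles use the
#' linear-interpolation convention (R type 7).
#'
#' @param data Per-patient data frame containing `grade` and the variables.
#' @param variables Character vector of column names to summarise.
#' @return A tibble: `variable`, `grade`, `n`, `q1`, `median`, `q3`, and
#'   the across-grade `kw_p` (repeated within variable).
#' @export
summarise_by_grade <- function(data, variables) {
  data <- tibble::as_tibble(data)
  stopifnot("grade" %in% names(data), all(variables %in% names(data)))
  purrr::map_dfr(variables, function(v) {
    groups <- split(data[[v]], data$grade)
    groups <- groups[lengths(groups) > 0]
    kw_p <- if (length(groups) >= 2 && length(unique(unlist(groups))) > 1) {
      kruskal_wallis_h(groups)$p_value
    } else {
      NA_real_
    }
    purrr::map_dfr(names(groups), function(g) {
      qs <- quartiles(groups[[g]])
      tibble::tibble(variable = v, grade = as.integer(g),
                     n = length(groups[[g]]),
                     q1 = qs[["q1"]], median = qs[["median"]], q3 = qs[["q3"]],
                     kw_p = kw_p)
    })
  })
}
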