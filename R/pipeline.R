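#' Pipeline configuration
#'
#' Bundles every stage's settings: the synthetic-cohort configuration, the
#' acquisition protocol, STFT and TFA-region parameters, abnormality
#' thresholds, the analysis side, and how the control reference is obtained.
#'
#' @param cohort A [cohort_config()].
#' @param protocol A [stimulation_protocol()].
#' @param stft A [stft_params()].
#' @param region A [tfa_region()].
#' @param thresholds A [threshold_config()].
#' @param side Analysis side for classification, `"right"` or `"left"`.
#' @param window Amplitude/latency search window in ms (`NULL` = full
#'   epoch).
#' @param reference `"estimated"` builds the control reference from the
#'   generated grade-0 patients; `"configured"` uses the fixed reference
#'   means in the cohort config (default when the cohort forces exact
#'   category counts, so the forced contingency structure is preserved).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `ssep_pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            protocol = stimulation_protocol(),
                            stft = stft_params(),
                            region = tfa_region(),
                            thresholds = threshold_config(),
                            side = c("right", "left"),
                            window = NULL,
                            reference = NULL,
                            log_level = c("info", "quiet")) {
  side <- match.arg(side)
  log_level <- match.arg(log_level)
  stopifnot(inherits(cohort, "ssep_cohort_config"),
            inherits(protocol, "ssep_protocol"),
            inherits(stft, "ssep_stft_params"),
            inherits(region, "ssep_tfa_region"),
            inherits(thresholds, "ssep_thresholds"))
  if (is.null(reference)) {
    reference <- if (cohort$category_mode == "exact") "configured" else "estimated"
  }
  reference <- match.arg(reference, c("estimated", "configured"))
  structure(
    list(cohort = cohort, protocol = protocol, stft = stft, region = region,
         thresholds = thresholds, side = side, window = window,
         reference = reference, log_level = log_level),
    class = "ssep_pipeline_config"
  )
}

log_stage <- function(config, stage, detail) {
  if (config$log_level == "info") {
    message(sprintf("[ssepmri] stage=%s %s", stage, detail))
  }
  invisible(NULL)
}

run_stage <- function(config, out_dir, stage, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir)) {
      writeLines(conditionMessage(e),
                 file.path(out_dir, paste0("FAILED_", stage)))
    }
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

write_stage_csv <- function(df, out_dir, name) {
  if (!is.null(out_dir)) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  invisible(df)
}

#' Run the simulate - extract - grade - classify - analyze pipeline
#'
#' Executes all stages in order on a synthetic cohort (or on supplied
#' feature / morphometry tables) and assembles a reproducible report:
#' per-grade feature medians, the tau-b / Kruskal-Wallis association layer,
#' the per-grade amplitude x power contingency tables with exact Fisher
#' p-values, and the per-grade abnormality-category distribution. Identical
#' `(config, seed)` give an identical report; every artifact carries the
#' configuration hash.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, each stage persists its
#'   CSV/JSON artifact there.
#' @param features,morphometry Optional externally supplied long feature
#'   table and morphometry table (columns as produced by
#'   [extract_features()] / [generate_morphometry()] plus `patient_id`,
#'   `grade` in `morphometry` after grading); when supplied the simulate /
#'   extract stages are skipped.
#' @return A `ssep_report` list.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort = cohort_config(n_per_grade = c(3, 3, 3, 3),
#'                                               n_trials = 20))
#' rep <- run_pipeline(cfg, seed = 1)
#' rep$grade_tables
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1, out_dir = NULL,
                         features = NULL, morphometry = NULL) {
  stopifnot(inherits(config, "ssep_pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  hash <- config_hash(config)
  protocol <- config$protocol
  protocol$n_trials <- config$cohort$n_trials
  simulated <- is.null(features)

  cohort <- NULL
  if (simulated) {
    cohort <- run_stage(config, out_dir, "simulate", {
      co <- generate_cohort(config$cohort, seed)
      log_stage(config, "simulate",
                sprintf("n=%d hash=%s", nrow(co), hash))
      write_stage_csv(co, out_dir, "cohort.csv")
    })
    features <- run_stage(config, out_dir, "extract", {
      rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
        purrr::map_dfr(c("right", "left"), function(sd) {
          ep <- generate_epoch_set(
            cohort[i, ], protocol,
            seed = derive_seed(seed, 2 * i + (sd == "left")),
            side = sd, noise_sd = config$cohort$noise_sd,
            params = config$stft, region = config$region
          )
          extract_features(ep, window = config$window,
                           params = config$stft, region = config$region)
        })
      })
      log_stage(config, "extract", sprintf("rows=%d", nrow(rows)))
      write_stage_csv(rows, out_dir, "features.csv")
    })
  } else {
    features <- tibble::as_tibble(features)
    if (is.null(morphometry)) {
      abort("supply `morphometry` alongside externally supplied `features`")
    }
    log_stage(config, "extract", "using supplied features")
  }

  graded <- run_stage(config, out_dir, "grade", {
    m <- if (is.null(morphometry)) {
      generate_morphometry(cohort, seed = derive_seed(seed, 900001))
    } else {
      tibble::as_tibble(morphometry)
    }
    g <- grade_morphometry(m)
    log_stage(config, "grade", sprintf("n=%d", nrow(g)))
    write_stage_csv(g, out_dir, "grades.csv")
  })
  grades <- graded[, c("patient_id", "grade")]

  classified <- run_stage(config, out_dir, "classify", {
    side_feats <- features[features$side == config$side, ]
    if (config$reference == "configured") {
      ref <- list(mean_amplitude = config$cohort$reference_amplitude,
                  mean_latency = config$cohort$latency_median[[config$side]][1],
                  mean_tfa_power = config$cohort$reference_tfa_power)
      ref_tbl <- tibble::tibble(side = config$side,
                                n_controls = NA_integer_,
                                mean_amplitude = ref$mean_amplitude,
                                mean_latency = ref$mean_latency,
                                mean_tfa_power = ref$mean_tfa_power)
    } else {
      controls <- grades$patient_id[grades$grade == 0]
      if (length(controls) == 0) {
        abort("no grade-0 patients to build the control reference from")
      }
      ref_tbl <- build_control_reference(
        features[features$patient_id %in% controls, ])
      ref <- NULL
    }
    calls <- if (is.null(ref)) {
      classify_abnormality(side_feats, ref_tbl, config$thresholds)
    } else {
      classify_abnormality(side_feats, ref, config$thresholds)
    }
    log_stage(config, "classify", sprintf("reference=%s", config$reference))
    write_stage_csv(calls, out_dir, "calls.csv")
    list(calls = calls, reference = ref_tbl)
  })

  analysis <- run_stage(config, out_dir, "analyze", {
    tables <- tabulate_by_grade(classified$calls, grades)
    tables$fisher_p <- vapply(seq_len(nrow(tables)), function(k) {
      if (tables$n[k] == 0) NA_real_ else fisher_exact_2x2(tables$table[[k]])$p_value
    }, numeric(1))
    assoc <- NULL
    has_both_sides <- all(c("left", "right") %in% features$side)
    if (has_both_sides && any(grades$grade == 0)) {
      assoc <- grade_association_summary(features, grades,
                                         graded[, c("patient_id", "ccr", "mscc")],
                                         side = config$side,
                                         thresholds = config$thresholds)
    }
    wide <- widen_features(features) |>
      dplyr::inner_join(grades, by = "patient_id") |>
      dplyr::inner_join(graded[, c("patient_id", "ccr", "mscc")],
                        by = "patient_id")
    feat_vars <- intersect(
      c("ccr", "mscc", "left_amplitude", "right_amplitude", "left_latency",
        "right_latency", "left_tfa_power", "right_tfa_power"),
      names(wide)
    )
    medians <- summarise_by_grade(wide, feat_vars)
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(tables = dplyr::select(tables, -dplyr::all_of("table")),
             medians = medians),
        file.path(out_dir, "analysis.json"), auto_unbox = TRUE, digits = NA
      )
    }
    log_stage(config, "analyze", sprintf("grades=%s",
                                         paste(tables$grade, collapse = ",")))
    list(tables = tables, medians = medians, assoc = assoc)
  })

  distribution <- analysis$tables |>
    dplyr::transmute(
      grade = .data$grade, n = .data$n,
      pct_no_abnormality = 100 * .data$p_normal,
      pct_amp_only = 100 * .data$p_amp_only,
      pct_amp_power = 100 * .data$p_amp_power,
      pct_power_only = 100 * .data$p_power_only,
      empty = .data$n == 0
    )

  report <- structure(
    list(
      provenance = list(
        package = "ssepmri",
        version = as.character(utils::packageVersion("ssepmri")),
        seed = seed, config_hash = hash, side = config$side,
        reference = config$reference, simulated = simulated,
        quantile_type = 7,
        thresholds = unclass(config$thresholds),
        stft = unclass(config$stft), region = unclass(config$region)
      ),
      cohort_n = as.list(table(factor(grades$grade, levels = 0:3))),
      control_reference = classified$reference,
      medians = analysis$medians,
      association = if (!is.null(analysis$assoc)) {
        list(tau = analysis$assoc$tau, kruskal = analysis$assoc$kruskal)
      } else NULL,
      grade_tables = dplyr::select(analysis$tables, -dplyr::all_of("table")),
      category_distribution = distribution,
      calls = classified$calls
    ),
    class = "ssep_report"
  )
  if (!is.null(out_dir)) {
    render_report(report, out_dir, format = "both")
  }
  report
}

#' @export
print.ssep_report <- function(x, ...) {
  cat("<ssep_report>", x$provenance$package, x$provenance$version,
      "seed", x$provenance$seed, "hash", x$provenance$config_hash, "\n")
  cat("  patients per grade 0-3:",
      paste(unlist(x$cohort_n), collapse = "/"), "\n")
  print(x$category_distribution)
  invisible(x)
}

#' Render a pipeline report to files
#'
#' Writes the machine-readable report JSON and/or a human-readable text
#' summary (per-grade category distribution, thresholds, Fisher p-values).
#'
#' @param report A `ssep_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param format `"json"`, `"text"`, or `"both"`.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, out_dir, format = c("json", "text", "both")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "ssep_report"))
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  written <- character()
  if (format %in% c("json", "both")) {
    path <- file.path(out_dir, "report.json")
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    written <- c(written, path)
  }
  if (format %in% c("text", "both")) {
    path <- file.path(out_dir, "summary.txt")
    lines <- c(
      sprintf("ssepmri report (seed %s, config %s, side %s, reference %s)",
              report$provenance$seed, report$provenance$config_hash,
              report$provenance$side, report$provenance$reference),
      sprintf("thresholds: amplitude >= %.0f%%, power >= %.0f%%, latency >= %.0f%%",
              100 * report$provenance$thresholds$amplitude_reduction_cut,
              100 * report$provenance$thresholds$power_loss_cut,
              100 * report$provenance$thresholds$latency_delay_cut),
      sprintf("patients per grade 0-3: %s",
              paste(unlist(report$cohort_n), collapse = "/")),
      "",
      "per-grade abnormality-category distribution:"
    )
    cd <- report$category_distribution
    for (i in seq_len(nrow(cd))) {
      if (isTRUE(cd$empty[i])) {
        lines <- c(lines, sprintf("  grade %d: empty stratum", cd$grade[i]))
      } else {
        lines <- c(lines, sprintf(
          "  grade %d (n=%d): no abnormality %.1f%% | amplitude only %.1f%% | amplitude+power %.1f%% | power only %.1f%%",
          cd$grade[i], cd$n[i], cd$pct_no_abnormality[i], cd$pct_amp_only[i],
          cd$pct_amp_power[i], cd$pct_power_only[i]))
      }
    }
    gt <- report$grade_tables
    if (!is.null(gt) && nrow(gt) > 0) {
      lines <- c(lines, "", "per-grade Fisher exact p (amplitude x power):",
                 sprintf("  grade %d: p = %.3f", gt$grade, gt$fisher_p))
    }
    writeLines(lines, path)
    written <- c(written, path)
  }
  invisible(written)
}
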