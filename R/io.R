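#' Write / read an epoch set as TSV + JSON sidecar
#'
#' The trials x samples matrix goes to `<prefix>.tsv` (tab-separated, no
#' header, microvolts) and the acquisition metadata to `<prefix>.json`
#' (sampling rate, stimulus-onset index, side, patient id, units).
#' Any producer writing this pair can feed the pipeline in place of the
#' simulator.
#'
#' @param epochs A [ssep_epochs()] object.
#' @param prefix File path prefix (without extension).
#' @return `write_epochs()` the prefix, invisibly; `read_epochs()` a
#'   [ssep_epochs()] object.
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "ssep_epochs"))
  utils::write.table(epochs$data, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(
    sampling_rate = epochs$sampling_rate,
    onset_index = epochs$onset_index,
    side = epochs$side,
    patient_id = epochs$patient_id,
    units = "uV",
    n_trials = nrow(epochs$data),
    n_samples = ncol(epochs$data)
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(data) <- NULL
  if (!is.null(meta$n_trials) &&
      (nrow(data) != meta$n_trials || ncol(data) != meta$n_samples)) {
    abort("epoch matrix shape does not match its sidecar")
  }
  ssep_epochs(data, meta$sampling_rate, meta$onset_index, meta$side,
              meta$patient_id)
}
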