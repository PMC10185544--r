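#' Cord compression ratio (CCR)
#'
#' Ratio of the anteroposterior (sagittal) cord diameter to the transverse
#' diameter at the level of maximal compression. A flatter cord gives a
#' lower CCR, so lower values indicate more severe compression.
#'
#' @param ap_diameter AP diameter at maximal compression, mm.
#' @param transverse_diameter Transverse diameter at the same level, mm.
#' @return Numeric vector of CCR values (dimensionless, > 0).
#' @examples
#' compute_ccr(4, 8)
#' @export
compute_ccr <- function(ap_diameter, transverse_diameter) {
  if (any(!is.finite(ap_diameter)) || any(ap_diameter <= 0) ||
      any(!is.finite(transverse_diameter)) || any(transverse_diameter <= 0)) {
    abort("diameters must be positive finite numbers")
  }
  ap_diameter / transverse_diameter
}

#' Maximum spinal cord compression (MSCC)
#'
#' Percent reduction of the AP diameter at maximal compression relative to
#' the mean of the AP diameters at the adjacent normal levels:
#' `(1 - d_i / ((d_a + d_b)/2)) * 100`. Zero when the compressed level
#' equals the adjacent mean; negative values (cord locally thicker than its
#' neighbours) are kept unless `clamp_zero = TRUE`.
#'
#' @param ap_diameter AP diameter at maximal compression (d_i), mm.
#' @param ap_above AP diameter at the normal level above (d_a), mm.
#' @param ap_below AP diameter at the normal level below (d_b), mm.
#' @param clamp_zero Clamp negative values to 0.
#' @return Numeric vector of MSCC values in percent.
#' @examples
#' compute_mscc(4, 5, 5)
#' @export
compute_mscc <- function(ap_diameter, ap_above, ap_below, clamp_zero = FALSE) {
  if (any(!is.finite(ap_above)) || any(ap_above <= 0) ||
      any(!is.finite(ap_below)) || any(ap_below <= 0)) {
    abort("adjacent-level diameters must be positive finite numbers")
  }
  if (any(!is.finite(ap_diameter)) || any(ap_diameter <= 0)) {
    abort("`ap_diameter` must be positive and finite")
  }
  mscc <- (1 - ap_diameter / ((ap_above + ap_below) / 2)) * 100
  if (clamp_zero) pmax(mscc, 0) else mscc
}

#' Assign the 0-3 MRI compression grade
#'
#' Grade 3: cord deformation with intramedullary signal change. Grade 2:
#' deformation without signal change. Grade 1: no deformation but >= 50% CSF
#' occlusion of the subarachnoid space. Grade 0: otherwise. Deformation
#' takes precedence over the occlusion rule (grades 2-3 are defined by the
#' cord itself, irrespective of the CSF space), and exactly 50% occlusion
#' counts as grade 1.
#'
#' @param csf_occlusion CSF occlusion fraction in `[0, 1]`.
#' @param deformation Logical, visible cord deformation.
#' @param signal_change Logical, intramedullary signal change.
#' @return Integer vector of grades in `{0, 1, 2, 3}`.
#' @examples
#' assign_grade(0.3, FALSE, FALSE)
#' assign_grade(0.9, TRUE, TRUE)
#' @export
assign_grade <- function(csf_occlusion, deformation, signal_change) {
  if (any(!is.finite(csf_occlusion)) || any(csf_occlusion < 0) ||
      any(csf_occlusion > 1)) {
    abort("`csf_occlusion` must lie in [0, 1]")
  }
  stopifnot(is.logical(deformation), is.logical(signal_change))
  dplyr::case_when(
    deformation & signal_change ~ 3L,
    deformation ~ 2L,
    csf_occlusion >= 0.5 ~ 1L,
    TRUE ~ 0L
  )
}

#' Grade a morphometry table
#'
#' Adds `ccr`, `mscc` and `grade` columns to a per-patient morphometry data
#' frame (as produced by [generate_morphometry()] or read from a
#' measurements CSV).
#'
#' @param morphometry Data frame with columns `ap_diameter`,
#'   `transverse_diameter`, `ap_above`, `ap_below`, `csf_occlusion`,
#'   `deformation`, `signal_change`.
#' @param clamp_zero Passed to [compute_mscc()].
#' @return The input as a tibble with `ccr`, `mscc`, `grade` appended.
#' @examples
#' m <- tibble::tibble(
#'   patient_id = "P001", ap_diameter = 6, transverse_diameter = 12.5,
#'   ap_above = 8, ap_below = 8, csf_occlusion = 0.7,
#'   deformation = FALSE, signal_change = FALSE
#' )
#' grade_morphometry(m)
#' @export
grade_morphometry <- function(morphometry, clamp_zero = FALSE) {
  morphometry <- tibble::as_tibble(morphometry)
  needed <- c("ap_diameter", "transverse_diameter", "ap_above", "ap_below",
              "csf_occlusion", "deformation", "signal_change")
  missing <- setdiff(needed, names(morphometry))
  if (length(missing)) {
    abort(paste("morphometry table lacks columns:", paste(missing, collapse = ", ")))
  }
  dplyr::mutate(
    morphometry,
    ccr = compute_ccr(.data$ap_diameter, .data$transverse_diameter),
    mscc = compute_mscc(.data$ap_diameter, .data$ap_above, .data$ap_below,
                        clamp_zero = clamp_zero),
    grade = assign_grade(.data$csf_occlusion, .data$deformation,
                         .data$signal_change)
  )
}
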