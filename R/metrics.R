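#' Oxygen consumption rate trace for a Mito Stress Test
#'
#' Timepoints with OCR values and the injection phase of each measurement.
#' Phases must appear in the canonical order baseline, oligomycin, FCCP,
#' rot_AA (rotenone + antimycin A), each with at least 2 measurements.
#'
#' @param timepoints increasing numeric vector (minutes).
#' @param ocr numeric OCR values (pmol O2/min, pre-normalised).
#' @param phase character vector of phase labels.
#' @return A data.frame of class `ocr_trace`.
#' @export
ocr_trace <- function(timepoints, ocr, phase) {
  phases <- c("baseline", "oligomycin", "FCCP", "rot_AA")
  if (length(timepoints) != length(ocr) || length(ocr) != length(phase)) {
    stopf("'timepoints', 'ocr' and 'phase' must have equal length")
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stopf("'timepoints' must be strictly increasing")
  }
  bad <- setdiff(unique(phase), phases)
  if (length(bad)) stopf("unknown phase label '%s'", bad[1L])
  present <- phases[phases %in% phase]
  missing_phase <- setdiff(phases, present)
  if (length(missing_phase)) {
    stopf("missing phase '%s'", missing_phase[1L])
  }
  # non-interleaved and in canonical order
  runs <- rle(phase)$values
  if (!identical(runs, phases)) {
    stopf("phases must appear once each, in the order %s",
          paste(phases, collapse = " -> "))
  }
  if (any(table(phase) < 2L)) {
    few <- names(which(table(phase) < 2L))[1L]
    stopf("phase '%s' needs at least 2 measurements", few)
  }
  structure(data.frame(timepoints = timepoints, ocr = ocr, phase = phase,
                       stringsAsFactors = FALSE),
            class = c("ocr_trace", "data.frame"))
}

#' Mito Stress Test parameters from an OCR trace
#'
#' Plateaus are the mean of the last 3 measurements of a phase (or all of
#' them if fewer); maximal respiration is the maximum of the FCCP-phase
#' measurements. By default the non-mitochondrial OCR (rotenone +
#' antimycin A plateau) is subtracted so basal and maximal are
#' mitochondrial rates; `raw = TRUE` skips the subtraction.
#'
#' Derived parameters: spare respiratory capacity `src = maximal - basal`;
#' `atp_linked = basal_raw - oligomycin plateau`; `proton_leak =
#' oligomycin plateau - non_mito`. By construction
#' `basal = atp_linked + proton_leak` whenever non-mito is subtracted.
#'
#' @param trace an [ocr_trace].
#' @param raw do not subtract non-mitochondrial OCR from basal/maximal.
#' @return List of class `mito_stress_params` with `basal`, `maximal`,
#'   `src`, `atp_linked`, `proton_leak`, `non_mito`.
#' @examples
#' tr <- ocr_trace(1:8, c(50, 50, 20, 20, 80, 80, 10, 10),
#'                 rep(c("baseline", "oligomycin", "FCCP", "rot_AA"),
#'                     each = 2))
#' mito_stress_params(tr)
#' @export
mito_stress_params <- function(trace, raw = FALSE) {
  stopifnot(inherits(trace, "ocr_trace"))
  plateau <- function(ph) {
    v <- trace$ocr[trace$phase == ph]
    mean(tail(v, 3L))
  }
  basal_raw <- plateau("baseline")
  oligo <- plateau("oligomycin")
  non_mito <- plateau("rot_AA")
  maximal_raw <- max(trace$ocr[trace$phase == "FCCP"])

  basal <- if (raw) basal_raw else basal_raw - non_mito
  maximal <- if (raw) maximal_raw else maximal_raw - non_mito
  structure(list(basal = basal,
                 maximal = maximal,
                 src = maximal - basal,
                 atp_linked = basal_raw - oligo,
                 proton_leak = oligo - non_mito,
                 non_mito = non_mito),
            class = "mito_stress_params")
}

#' @export
print.mito_stress_params <- function(x, ...) {
  v <- unlist(x)
  cat("mito_stress_params:\n")
  for (nm in names(v)) cat(sprintf("  %-12s %8.3f\n", nm, v[[nm]]))
  invisible(x)
}

#' Respiratory exchange ratio
#'
#' `RER = VCO2 / VO2`.
#'
#' @param vco2 CO2 release (volume per time, >= 0).
#' @param vo2 O2 consumption (same units, > 0).
#' @return Numeric RER (vectorised).
#' @export
rer <- function(vco2, vo2) {
  if (any(vo2 <= 0)) stopf("'vo2' must be > 0")
  if (any(vco2 < 0)) stopf("'vco2' must be >= 0")
  vco2 / vo2
}

#' Energy expenditure from RER and VO2
#'
#' `EE = (3.185 + 1.232 * RER) * VO2`.
#'
#' @param rer_value respiratory exchange ratio.
#' @param vo2 O2 consumption (> 0).
#' @return Numeric EE (vectorised).
#' @examples
#' energy_expenditure(1, 1)  # 4.417
#' @export
energy_expenditure <- function(rer_value, vo2) {
  if (any(vo2 <= 0)) stopf("'vo2' must be > 0")
  (3.185 + 1.232 * rer_value) * vo2
}

#' Read an OCR trace from TSV (columns: time, value, phase)
#' @param path path to the TSV file.
#' @return An [ocr_trace].
#' @export
read_ocr_trace <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("time", "value", "phase")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stopf("OCR trace lacks column(s): %s",
                          paste(miss, collapse = ", "))
  ocr_trace(tab$time, tab$value, tab$phase)
}

#' Read an indirect-calorimetry table and derive RER and EE
#'
#' Input TSV columns: `interval`, `vo2`, `vco2`. The returned table adds
#' `rer` and `ee` per interval.
#'
#' @param path path to the TSV file.
#' @return A data.frame with `interval`, `vo2`, `vco2`, `rer`, `ee`.
#' @export
read_calorimetry <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("interval", "vo2", "vco2")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stopf("calorimetry table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tab$rer <- rer(tab$vco2, tab$vo2)
  tab$ee <- energy_expenditure(tab$rer, tab$vo2)
  tab
}
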