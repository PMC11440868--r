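#' PET scanner calibration from a uniform phantom
#'
#' A cylindrical phantom of known volume filled with a known activity
#' provides the factor converting reconstructed image counts (cps/mL) into
#' activity concentration (MBq/mL).
#'
#' @param phantom_volume_mL Phantom volume, mL.
#' @param phantom_activity_MBq Activity in the phantom at scan time, MBq.
#' @param measured_cps_per_mL Mean ROI count rate measured in the phantom
#'   image, cps/mL.
#' @return An object of class `pet_calibration` with the derived
#'   `calibration_factor` in (MBq/mL)/(cps/mL).
#' @export
#' @examples
#' pet_calibration(25.7, 2.02, measured_cps_per_mL = 0.0786)
pet_calibration <- function(phantom_volume_mL, phantom_activity_MBq,
                            measured_cps_per_mL) {
  vals <- c(phantom_volume_mL, phantom_activity_MBq, measured_cps_per_mL)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("phantom volume, activity and measured rate must all be positive",
         call. = FALSE)
  }
  structure(
    list(phantom_volume_mL = phantom_volume_mL,
         phantom_activity_MBq = phantom_activity_MBq,
         measured_cps_per_mL = measured_cps_per_mL,
         calibration_factor =
           (phantom_activity_MBq / phantom_volume_mL) / measured_cps_per_mL),
    class = "pet_calibration"
  )
}

#' @export
print.pet_calibration <- function(x, ...) {
  cat(sprintf(
    "<pet_calibration> %.4g MBq in %.4g mL -> factor %.4g (MBq/mL)/(cps/mL)\n",
    x$phantom_activity_MBq, x$phantom_volume_mL, x$calibration_factor))
  invisible(x)
}

#' Phantom calibration factor
#'
#' The true activity concentration of the phantom divided by the count rate
#' measured in its ROI.
#'
#' @param measured_cps_per_mL Measured count rate, cps/mL.
#' @param phantom_volume_mL Phantom volume, mL.
#' @param phantom_activity_MBq Phantom activity, MBq.
#' @return Calibration factor, (MBq/mL) per (cps/mL).
#' @export
phantom_calibration_factor <- function(measured_cps_per_mL,
                                       phantom_volume_mL,
                                       phantom_activity_MBq) {
  pet_calibration(phantom_volume_mL, phantom_activity_MBq,
                  measured_cps_per_mL)$calibration_factor
}

#' A PET region-of-interest time series
#'
#' @param roi_id Character label.
#' @param time_min Times post-administration, minutes, strictly increasing.
#' @param values Non-negative ROI values.
#' @param unit One of `"cps_per_mL"`, `"MBq_per_mL"`, `"MBq_per_g"`.
#' @param decay_corrected Was the series decay-corrected by the scanner
#'   software? Reconstructed series usually are.
#' @return An object of class `roi_series`.
#' @export
roi_series <- function(roi_id, time_min, values,
                       unit = c("cps_per_mL", "MBq_per_mL", "MBq_per_g"),
                       decay_corrected = TRUE) {
  unit <- match.arg(unit)
  if (length(time_min) != length(values)) {
    stop("`time_min` and `values` must have equal length", call. = FALSE)
  }
  if (any(diff(time_min) <= 0)) {
    stop("`time_min` must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) stop("ROI values must be non-negative", call. = FALSE)
  structure(
    list(roi_id = roi_id, time_min = as.numeric(time_min),
         values = as.numeric(values), unit = unit,
         decay_corrected = isTRUE(decay_corrected)),
    class = "roi_series"
  )
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> '%s': %d points, unit %s, decay_corrected = %s\n",
              x$roi_id, length(x$time_min), x$unit, x$decay_corrected))
  invisible(x)
}

#' Apply a phantom calibration to a raw ROI series
#'
#' Multiplies a cps/mL series by the calibration factor, yielding MBq/mL.
#' The operation is linear and exactly invertible.
#'
#' @param series A [roi_series()] in cps/mL.
#' @param calibration A [pet_calibration()].
#' @return A calibrated [roi_series()] in MBq/mL.
#' @export
apply_pet_calibration <- function(series, calibration) {
  stopifnot(inherits(series, "roi_series"),
            inherits(calibration, "pet_calibration"))
  if (series$unit != "cps_per_mL") {
    stop("series is already calibrated (unit ", series$unit, ")",
         call. = FALSE)
  }
  roi_series(series$roi_id, series$time_min,
             series$values * calibration$calibration_factor,
             unit = "MBq_per_mL", decay_corrected = series$decay_corrected)
}

#' Percent injected activity per gram
#'
#' Normalises an activity concentration to the administered activity:
#' `100 * conc / injected`.
#'
#' @param conc_MBq_per_g Activity concentration, MBq/g (density 1 g/mL is
#'   assumed when converting from MBq/mL unless the caller converts first).
#' @param injected_MBq Administered activity, MBq, strictly positive.
#' @return Percent injected activity per gram (%IA/g). Vectorised.
#' @export
#' @examples
#' to_percent_injected_activity(0.5, 10) # 5 %IA/g
to_percent_injected_activity <- function(conc_MBq_per_g, injected_MBq) {
  if (!is.numeric(injected_MBq) || any(injected_MBq <= 0)) {
    stop("`injected_MBq` must be strictly positive", call. = FALSE)
  }
  100 * conc_MBq_per_g / injected_MBq
}

#' Time-integrated activity of an ROI series
#'
#' Trapezoidal integration of a calibrated ROI time-activity curve, with an
#' optional analytic physical-decay tail beyond the last sample. If the
#' series was decay-corrected during reconstruction and the physically
#' decaying integral is wanted, set `undo_decay_correction = TRUE` to
#' multiply the samples by the decay factor first.
#'
#' @param series A calibrated [roi_series()] (MBq/mL or MBq/g).
#' @param nuclide A [radionuclide()].
#' @param extrapolate_tail Add the analytic physical-decay tail?
#' @param undo_decay_correction Re-apply physical decay to a
#'   decay-corrected series before integrating.
#' @return Time-integrated activity in MBq.h per mL or per g, matching the
#'   series unit.
#' @export
time_integrated_activity <- function(series, nuclide = f18(),
                                     extrapolate_tail = FALSE,
                                     undo_decay_correction = FALSE) {
  stopifnot(inherits(series, "roi_series"))
  if (series$unit == "cps_per_mL") {
    stop("calibrate the series first (see apply_pet_calibration())",
         call. = FALSE)
  }
  values <- series$values
  if (undo_decay_correction) {
    if (!series$decay_corrected) {
      stop("series is not decay-corrected; nothing to undo", call. = FALSE)
    }
    values <- values * 2^(-series$time_min / nuclide$half_life_min)
  }
  tac <- activity_time_course(series$time_min, values)
  cumulated_activity_trapezoid(tac, nuclide = nuclide,
                               extrapolate_tail = extrapolate_tail)
}

#' Read an ROI series from CSV
#'
#' Expects the dialect `roi_id,time_min,value,unit,decay_corrected`; a file
#' may hold several ROIs.
#'
#' @param path Path to a CSV file.
#' @return A named list of [roi_series()], one per `roi_id`.
#' @export
read_roi_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("roi_id", "time_min", "value", "unit", "decay_corrected")
  if (!all(required %in% names(df))) {
    stop("ROI CSV must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$roi_id), function(d) {
    d <- d[order(d$time_min), ]
    unit <- unique(d$unit)
    dc <- unique(d$decay_corrected)
    if (length(unit) != 1L || length(dc) != 1L) {
      stop("inconsistent unit/decay_corrected within ROI '",
           d$roi_id[1], "'", call. = FALSE)
    }
    roi_series(d$roi_id[1], d$time_min, d$value, unit = unit,
               decay_corrected = as.logical(dc))
  })
  out
}
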