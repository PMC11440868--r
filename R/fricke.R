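#' Constants of the Fricke dose equation
#'
#' The absorbed dose in water derived from the change in optical absorbance
#' of an irradiated Fricke solution is
#' \deqn{D = \frac{\Delta OA \; R_F \, K_{vial} \, K_{dd} \, K_E}
#'               {\varepsilon G(Fe^{3+}) \, \rho \, l}}
#' where \eqn{\Delta OA} is the background-corrected absorbance change at
#' 304 nm, \eqn{R_F} the water-to-Fricke dose ratio, the K factors are
#' geometric/energy correction factors, \eqn{\varepsilon G(Fe^{3+})} the
#' product of the ferric molar extinction coefficient and its radiation
#' chemical yield (cm2/J), \eqn{\rho} the solution density (kg/cm3) and
#' \eqn{l} the optical path length (cm).
#'
#' `eps_g` depends on radiation quality: 3.5060 cm2/J for 60Co gamma rays and
#' 3.498 cm2/J for 18F positron irradiation. The G-value is approximately
#' energy independent for low-LET radiation, so other qualities must be
#' supplied explicitly by the user.
#'
#' @param quality `"F18"` or `"Co60"`; selects the default `eps_g`.
#' @param r_f Water-to-Fricke dose ratio (dimensionless).
#' @param k_vial Vial-wall perturbation correction (dimensionless).
#' @param k_dd Field non-uniformity correction (dimensionless).
#' @param k_e Energy-dependence correction of G(Fe3+) (dimensionless).
#' @param eps_g Molar extinction coefficient times chemical yield, cm2/J.
#'   Overrides the quality default when given.
#' @param rho Solution density at 25 C, kg/cm3.
#' @param path_length_cm Cuvette optical path, cm.
#'
#' @return An object of class `fricke_constants`.
#' @export
#' @examples
#' fricke_constants("Co60")$eps_g
fricke_constants <- function(quality = c("F18", "Co60"),
                             r_f = 1.0032, k_vial = 1.00, k_dd = 1.00,
                             k_e = 1.00, eps_g = NULL,
                             rho = 1.0227e-3, path_length_cm = 1) {
  quality <- match.arg(quality)
  if (is.null(eps_g)) {
    eps_g <- switch(quality, F18 = 3.498, Co60 = 3.5060)
  }
  vals <- c(r_f = r_f, k_vial = k_vial, k_dd = k_dd, k_e = k_e,
            eps_g = eps_g, rho = rho, path_length_cm = path_length_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all Fricke constants must be finite and strictly positive",
         call. = FALSE)
  }
  structure(
    list(quality = quality, r_f = r_f, k_vial = k_vial, k_dd = k_dd,
         k_e = k_e, eps_g = eps_g, rho = rho,
         path_length_cm = path_length_cm),
    class = "fricke_constants"
  )
}

#' @export
print.fricke_constants <- function(x, ...) {
  cat(sprintf(paste0(
    "<fricke_constants> quality = %s\n",
    "  R_F = %.4f  K_vial = %.2f  K_dd = %.2f  K_E = %.2f\n",
    "  epsG(Fe3+) = %.4f cm2/J  rho = %.4e kg/cm3  l = %g cm\n"),
    x$quality, x$r_f, x$k_vial, x$k_dd, x$k_e, x$eps_g, x$rho,
    x$path_length_cm))
  invisible(x)
}

#' A single optical-density measurement
#'
#' @param sample_id Character label of the vial.
#' @param time_min Minutes since tracer addition (or post-irradiation for an
#'   external beam), non-negative.
#' @param od_304 Absorbance at 304 nm, non-negative.
#' @param condition One of `"radioactive"`, `"fdg_control"`, `"blank"`.
#' @return An object of class `od_record`.
#' @export
od_record <- function(sample_id, time_min, od_304,
                      condition = c("radioactive", "fdg_control", "blank")) {
  condition <- match.arg(condition)
  if (!is.numeric(time_min) || any(time_min < 0)) {
    stop("`time_min` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(od_304) || any(od_304 < 0)) {
    stop("`od_304` must be non-negative", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, time_min = time_min, od_304 = od_304,
         condition = condition),
    class = "od_record"
  )
}

#' Background-corrected absorbance difference
#'
#' Subtracts the control absorbance (blank or non-radioactive FDG control)
#' from the sample absorbance. The signed difference is returned by default
#' so low-dose measurement noise remains visible; set `clip_negative = TRUE`
#' to floor the result at zero.
#'
#' @param sample An [od_record()] (or plain numeric absorbance).
#' @param control The control [od_record()] (or numeric), condition `"blank"`
#'   or `"fdg_control"`.
#' @param clip_negative Floor negative differences at 0? Default `FALSE`.
#' @return Dimensionless absorbance difference.
#' @export
delta_od <- function(sample, control, clip_negative = FALSE) {
  s_od <- if (inherits(sample, "od_record")) sample$od_304 else sample
  c_od <- if (inherits(control, "od_record")) control$od_304 else control
  if (inherits(sample, "od_record") && sample$condition != "radioactive" &&
      inherits(control, "od_record")) {
    stop("`sample` must be the irradiated/radioactive series; ",
         "got condition '", sample$condition, "'", call. = FALSE)
  }
  if (inherits(control, "od_record") &&
      !control$condition %in% c("blank", "fdg_control")) {
    stop("`control` must be a blank or fdg_control record", call. = FALSE)
  }
  d <- s_od - c_od
  if (clip_negative) d <- pmax(d, 0)
  d
}

#' Absorbed dose from an absorbance change
#'
#' Applies the Fricke dose equation (see [fricke_constants()]). The response
#' is strictly linear in the absorbance change. Negative inputs (possible
#' after background correction of a noisy low-dose measurement) yield
#' negative doses and are deliberately not clipped.
#'
#' @param doa Background-corrected absorbance difference at 304 nm.
#'   Vectorised.
#' @param constants A [fricke_constants()].
#' @return Absorbed dose in water, Gy.
#' @export
#' @examples
#' dose_from_delta_od(0.01, fricke_constants("F18"))
dose_from_delta_od <- function(doa, constants = fricke_constants()) {
  stopifnot(inherits(constants, "fricke_constants"))
  doa * constants$r_f * constants$k_vial * constants$k_dd * constants$k_e /
    (constants$eps_g * constants$rho * constants$path_length_cm)
}

#' Absorbance change producing a given dose
#'
#' Exact inverse of [dose_from_delta_od()]; round-trips to machine
#' precision. Used by the synthetic-data generator and when constructing an
#' external-beam calibration curve.
#'
#' @param dose_Gy Absorbed dose in water, Gy. Vectorised.
#' @param constants A [fricke_constants()].
#' @return Dimensionless absorbance difference at 304 nm.
#' @export
delta_od_for_dose <- function(dose_Gy, constants = fricke_constants()) {
  stopifnot(inherits(constants, "fricke_constants"))
  dose_Gy * constants$eps_g * constants$rho * constants$path_length_cm /
    (constants$r_f * constants$k_vial * constants$k_dd * constants$k_e)
}

#' Correct a radiotracer dose for the non-radioactive FDG background
#'
#' The dose measured in a Fricke solution containing the non-radioactive
#' carrier (FDG) is subtracted from the dose measured in the radioactive
#' solution, so that the corrected dose reflects only the radiation emitted
#' by the radiotracer. Both doses must have been computed with the same
#' constants.
#'
#' @param dose_radio_Gy Dose from the radiotracer-containing solution, Gy.
#' @param dose_fdg_control_Gy Dose from the matched non-radioactive control,
#'   Gy.
#' @return Corrected dose (Gy) with the two inputs attached as attributes
#'   `"dose_radio"` and `"dose_control"` for provenance.
#' @export
fdg_background_correct <- function(dose_radio_Gy, dose_fdg_control_Gy) {
  out <- dose_radio_Gy - dose_fdg_control_Gy
  attr(out, "dose_radio") <- dose_radio_Gy
  attr(out, "dose_control") <- dose_fdg_control_Gy
  out
}

#' Read an optical-density series from CSV
#'
#' Expects the dialect `sample_id,time_min,od_304,condition` with condition
#' one of `radioactive`, `fdg_control`, `blank`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with validated columns.
#' @export
read_od_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "time_min", "od_304", "condition")
  if (!all(required %in% names(df))) {
    stop("OD CSV must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$condition),
                 c("radioactive", "fdg_control", "blank"))
  if (length(bad)) {
    stop("unknown condition value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$od_304 < 0) || any(df$time_min < 0)) {
    stop("od_304 and time_min must be non-negative", call. = FALSE)
  }
  df
}
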