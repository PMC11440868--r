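#' Reference 18F-FDG Fricke calibration measurements
#'
#' Measured absorbed doses (Gy) in 3 mL Fricke vials 1450 min (about 13
#' half-lives) after spiking with 15-80 MBq of 18F-FDG, the dataset behind
#' the dose-per-administered-activity calibration line. Shipped as plain CSV
#' under `extdata`.
#'
#' @return A data.frame with columns `activity_MBq` and `dose_Gy`.
#' @export
#' @examples
#' fit_through_origin(fdg_fricke_calibration()$activity_MBq,
#'                    fdg_fricke_calibration()$dose_Gy)
fdg_fricke_calibration <- function() {
  path <- system.file("extdata", "fricke_fdg_calibration.csv",
                      package = "frickedose", mustWork = TRUE)
  utils::read.csv(path)
}

#' Illustrative mouse biodistribution fixture
#'
#' An intratumoral-injection organ uptake table (time-integrated activity
#' per gram after 15 MBq i.t. administration) paired with synthetic organ
#' masses, for demonstrating the organ-dose report. The masses are
#' illustrative values typical of a nude mouse, not measured data, and must
#' be replaced by study-specific masses for any real analysis.
#'
#' @return A list of [organ_uptake()] objects.
#' @export
mouse_uptake_fixture <- function() {
  path <- system.file("extdata", "mouse_uptake_it_synthetic_masses.csv",
                      package = "frickedose", mustWork = TRUE)
  read_uptake_csv(path)
}
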