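#' Linear regression through the origin
#'
#' Fits `y = b x` with the intercept fixed at zero, the convention used for
#' dosimeter and scanner calibration lines that must vanish at zero
#' administered activity. The slope has the closed form
#' \eqn{b = \sum x_i y_i / \sum x_i^2}; the goodness of fit is reported as
#' the uncentered R-squared \eqn{1 - SS_{res} / \sum y_i^2}, the appropriate
#' convention for a forced-origin model (the centered form understates the
#' fit because the model has no free mean).
#'
#' @param x Predictor values (e.g. administered activity, MBq).
#' @param y Response values (e.g. absorbed dose, Gy); same length as `x`.
#' @param weights Optional non-negative weights (default: unweighted).
#' @return An object of class `calibration_fit`: `slope`, `r2_uncentered`,
#'   `n`, `stderr` (slope standard error from residuals), `residuals`,
#'   `fitted`.
#' @export
#' @examples
#' fit_through_origin(c(1, 2, 3), c(2, 4, 6)) # slope 2, R2 = 1
fit_through_origin <- function(x, y, weights = NULL) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least two points", call. = FALSE)
  if (all(x == 0)) {
    stop("degenerate input: all predictor values are zero", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  if (length(w) != length(x) || any(w < 0)) {
    stop("`weights` must be non-negative and match `x`", call. = FALSE)
  }
  slope <- sum(w * x * y) / sum(w * x^2)
  fitted <- slope * x
  res <- y - fitted
  ss_res <- sum(w * res^2)
  ss_tot <- sum(w * y^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  # residual-based standard error of the slope, n - 1 df (one parameter)
  stderr <- sqrt(ss_res / (length(x) - 1) / sum(w * x^2))
  structure(
    list(slope = slope, r2_uncentered = r2, n = length(x), stderr = stderr,
         residuals = res, fitted = fitted),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> slope = %.4g +/- %.2g (n = %d, uncentered R2 = %.4f)\n",
    x$slope, x$stderr, x$n, x$r2_uncentered))
  invisible(x)
}

#' Derive the dose-per-cumulated-activity conversion factor
#'
#' Combines the two calibration slopes of the Fricke/PET cross-calibration:
#' the dose per administered activity (Gy/MBq, from the Fricke dosimeter)
#' divided by the time-integrated activity per administered activity
#' (MBq.h/MBq, from PET) gives the conversion factor C in Gy per MBq.h used
#' to turn organ-level time-integrated activities into absorbed doses.
#'
#' @param dose_per_activity Gy/MBq slope (or a `calibration_fit`).
#' @param tia_per_activity MBq.h/MBq slope (or a `calibration_fit`).
#' @return An object of class `conversion_factor` with `value` (Gy/MBq.h)
#'   and the two input slopes as provenance.
#' @export
#' @examples
#' derive_conversion_factor(0.17, 2.69) # ~0.063 Gy/MBq.h
derive_conversion_factor <- function(dose_per_activity, tia_per_activity) {
  d <- if (inherits(dose_per_activity, "calibration_fit")) {
    dose_per_activity$slope
  } else {
    dose_per_activity
  }
  a <- if (inherits(tia_per_activity, "calibration_fit")) {
    tia_per_activity$slope
  } else {
    tia_per_activity
  }
  if (!is.finite(d) || d <= 0 || !is.finite(a) || a <= 0) {
    stop("both slopes must be finite and positive", call. = FALSE)
  }
  structure(
    list(value = d / a,
         dose_per_activity_Gy_MBq = d,
         tia_per_activity_MBqh_MBq = a),
    class = "conversion_factor"
  )
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf(
    "<conversion_factor> C = %.4g Gy/MBq.h (= %.4g Gy/MBq / %.4g MBq.h/MBq)\n",
    x$value, x$dose_per_activity_Gy_MBq, x$tia_per_activity_MBqh_MBq))
  invisible(x)
}
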