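#' Define a positron-emitting radionuclide
#'
#' A radionuclide is described by the physical quantities internal dosimetry
#' needs: the physical half-life, the positron branching ratio and the mean
#' positron energy. The decay constant \eqn{\lambda = \ln 2 / T_{1/2}} is
#' always derived from the half-life, never stored separately, so the two can
#' never disagree.
#'
#' @param name Character label, e.g. `"F-18"`.
#' @param half_life_min Physical half-life in minutes. Must be positive.
#' @param positron_branching Fraction of decays emitting a positron, in
#'   \[0, 1\].
#' @param mean_positron_energy_keV Mean kinetic energy of the emitted
#'   positron (keV). Informational; not used in the dose arithmetic.
#'
#' @return An object of class `radionuclide`.
#' @seealso [f18()] for the fluorine-18 default, [activity_at()],
#'   [cumulated_activity_analytic()].
#' @export
#' @examples
#' radionuclide("C-11", half_life_min = 20.36)
radionuclide <- function(name, half_life_min, positron_branching = 1,
                         mean_positron_energy_keV = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_min) || length(half_life_min) != 1L ||
      !is.finite(half_life_min) || half_life_min <= 0) {
    stop("`half_life_min` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(positron_branching) || positron_branching < 0 ||
      positron_branching > 1) {
    stop("`positron_branching` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      name = name,
      half_life_min = as.numeric(half_life_min),
      positron_branching = as.numeric(positron_branching),
      mean_positron_energy_keV = as.numeric(mean_positron_energy_keV)
    ),
    class = "radionuclide"
  )
}

#' Fluorine-18
#'
#' The default radionuclide: physical half-life 109.77 min, positron
#' branching 0.967, mean positron energy 250 keV (maximum 634 keV). Other
#' emitters (11C, 68Ga, ...) are drop-in replacements via [radionuclide()].
#'
#' @return A `radionuclide` object for 18F.
#' @export
#' @examples
#' f18()$half_life_min
f18 <- function() {
  radionuclide("F-18", half_life_min = 109.77, positron_branching = 0.967,
               mean_positron_energy_keV = 250)
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide> %s: T1/2 = %.4g min, beta+ branching = %.3f\n",
              x$name, x$half_life_min, x$positron_branching))
  invisible(x)
}

#' Decay constant of a radionuclide
#'
#' @param nuclide A [radionuclide()].
#' @param unit Time unit of the returned rate: `"per_min"` (default),
#'   `"per_hour"` or `"per_sec"`.
#' @return \eqn{\lambda = \ln 2 / T_{1/2}} in the requested unit.
#' @export
decay_constant <- function(nuclide, unit = c("per_min", "per_hour", "per_sec")) {
  unit <- match.arg(unit)
  lam <- log(2) / nuclide$half_life_min
  switch(unit,
         per_min = lam,
         per_hour = lam * 60,
         per_sec = lam / 60)
}

#' Activity after pure physical decay
#'
#' \eqn{A(t) = A_0 \, 2^{-t/T_{1/2}}}. No biological clearance is applied:
#' this is the decay of a sealed source.
#'
#' @param a0 Initial activity (MBq), non-negative.
#' @param t_min Time since `a0` was measured (minutes), non-negative.
#'   Vectorised.
#' @param nuclide A [radionuclide()]; defaults to [f18()].
#' @return Activity at `t_min` (MBq).
#' @export
#' @examples
#' activity_at(60, 109.77) # one half-life -> 30 MBq
activity_at <- function(a0, t_min, nuclide = f18()) {
  if (!is.numeric(a0) || any(a0 < 0)) {
    stop("`a0` must be non-negative (MBq)", call. = FALSE)
  }
  if (!is.numeric(t_min) || any(t_min < 0)) {
    stop("`t_min` must be non-negative (minutes)", call. = FALSE)
  }
  a0 * 2^(-t_min / nuclide$half_life_min)
}

#' Cumulated activity of a purely decaying source, closed form
#'
#' The time integral of \eqn{A_0 e^{-\lambda t}} from 0 to `t_end_h`:
#' \eqn{(A_0/\lambda)(1 - e^{-\lambda t})}, in MBq.h. With `t_end_h = Inf`
#' this is \eqn{A_0 T_{1/2} / \ln 2}, the total number of disintegrations in
#' activity units.
#'
#' @param a0 Initial activity (MBq).
#' @param nuclide A [radionuclide()].
#' @param t_end_h Upper integration limit in hours; `Inf` for complete decay.
#' @return Cumulated (time-integrated) activity in MBq.h.
#' @export
#' @examples
#' cumulated_activity_analytic(1) # 18F: 2.639 MBq.h per MBq administered
cumulated_activity_analytic <- function(a0, nuclide = f18(), t_end_h = Inf) {
  if (!is.numeric(a0) || any(a0 < 0)) {
    stop("`a0` must be non-negative (MBq)", call. = FALSE)
  }
  if (any(t_end_h < 0)) stop("`t_end_h` must be non-negative", call. = FALSE)
  lam_h <- decay_constant(nuclide, "per_hour")
  (a0 / lam_h) * (1 - exp(-lam_h * t_end_h))
}

#' Construct an activity time course
#'
#' A sampled activity curve: strictly increasing times (minutes) and matched
#' non-negative activities (MBq).
#'
#' @param time_min Sampling times in minutes since administration.
#' @param activity_MBq Activities at those times (MBq).
#' @param a0 Initial activity (MBq); defaults to the first sampled value.
#' @return An object of class `activity_time_course`.
#' @export
activity_time_course <- function(time_min, activity_MBq, a0 = activity_MBq[1]) {
  if (length(time_min) != length(activity_MBq)) {
    stop("`time_min` and `activity_MBq` must have equal length", call. = FALSE)
  }
  if (length(time_min) < 2L) {
    stop("an activity time course needs at least two time points", call. = FALSE)
  }
  if (any(diff(time_min) <= 0)) {
    stop("`time_min` must be strictly increasing", call. = FALSE)
  }
  if (time_min[1] < 0) stop("times must start at or after 0", call. = FALSE)
  if (any(activity_MBq < 0)) stop("activities must be non-negative", call. = FALSE)
  structure(
    list(time_min = as.numeric(time_min),
         activity_MBq = as.numeric(activity_MBq),
         a0 = as.numeric(a0)),
    class = "activity_time_course"
  )
}

#' @export
print.activity_time_course <- function(x, ...) {
  cat(sprintf("<activity_time_course> %d points, %.4g-%.4g min, a0 = %.4g MBq\n",
              length(x$time_min), min(x$time_min), max(x$time_min), x$a0))
  invisible(x)
}

#' Cumulated activity by trapezoidal integration
#'
#' Trapezoid rule over the sampled points of an activity time course,
#' optionally extended beyond the last sample by the analytic physical-decay
#' tail \eqn{A(t_{last})/\lambda}. The tail assumes the tracer undergoes only
#' physical decay with no biological elimination after the last sample.
#'
#' For a convex decaying exponential the trapezoid rule overestimates the
#' analytic integral; the bias vanishes as the sampling grid is refined.
#'
#' @param tac An [activity_time_course()].
#' @param nuclide A [radionuclide()]; used only for the tail.
#' @param extrapolate_tail If `TRUE`, add the analytic tail after the last
#'   sample.
#' @return Cumulated activity in MBq.h.
#' @export
#' @examples
#' tac <- activity_time_course(seq(0, 240, 60), activity_at(1, seq(0, 240, 60)))
#' cumulated_activity_trapezoid(tac, extrapolate_tail = TRUE)
cumulated_activity_trapezoid <- function(tac, nuclide = f18(),
                                         extrapolate_tail = FALSE) {
  stopifnot(inherits(tac, "activity_time_course"))
  t_h <- tac$time_min / 60
  a <- tac$activity_MBq
  auc <- sum(diff(t_h) * (utils::head(a, -1) + utils::tail(a, -1)) / 2)
  if (extrapolate_tail) {
    lam_h <- decay_constant(nuclide, "per_hour")
    auc <- auc + a[length(a)] / lam_h
  }
  auc
}

#' Read an activity time course from CSV
#'
#' Expects the two-column dialect `time_min,activity_MBq`, times 0-based from
#' administration.
#'
#' @param path Path to a CSV file.
#' @return An [activity_time_course()].
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_min", "activity_MBq")
  if (!all(required %in% names(df))) {
    stop("TAC CSV must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  activity_time_course(df$time_min, df$activity_MBq)
}
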