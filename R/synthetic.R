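# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable small integer derived from a string, for per-organ seed offsets.
string_offset <- function(x) {
  sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) %% 10000L
}

#' Default organ kinetic profiles for the synthetic mouse
#'
#' Per-organ uptake and clearance parameters used by [make_pet_tac()]:
#' `uptake_frac_per_g` is the plateau activity concentration as a fraction
#' of the injected activity per gram of tissue, `k_up` the uptake rate
#' (/min), `k_bio` an optional biological clearance rate (/min) and
#' `sigma_log` the log-scale standard deviation of the lognormal
#' inter-animal variation. The defaults emulate an intratumoral-injection
#' biodistribution: very high tumor retention, strong bladder excretion
#' signal, modest uptake elsewhere.
#'
#' @return A named list of profile lists.
#' @export
default_organ_profiles <- function() {
  list(
    tumor   = list(uptake_frac_per_g = 0.95, k_up = 0.15, k_bio = 0,
                   sigma_log = 0.10, mass_g = 0.126),
    bladder = list(uptake_frac_per_g = 0.55, k_up = 0.03, k_bio = 0,
                   sigma_log = 0.50, mass_g = 0.10),
    kidney  = list(uptake_frac_per_g = 0.07, k_up = 0.10, k_bio = 0,
                   sigma_log = 0.30, mass_g = 0.30),
    liver   = list(uptake_frac_per_g = 0.025, k_up = 0.10, k_bio = 0,
                   sigma_log = 0.40, mass_g = 1.20),
    heart   = list(uptake_frac_per_g = 0.12, k_up = 0.10, k_bio = 0,
                   sigma_log = 0.50, mass_g = 0.15),
    brain   = list(uptake_frac_per_g = 0.04, k_up = 0.10, k_bio = 0,
                   sigma_log = 0.40, mass_g = 0.40)
  )
}

#' Configuration of the synthetic-data generator
#'
#' One object collecting every knob of the simulated study: the vial design
#' (initial activities and optical-density sampling times), the ground-truth
#' dose-per-activity slope, the measurement noise levels and the organ
#' kinetic profiles. With a fixed seed every generator is bit-reproducible.
#'
#' @param seed Integer RNG seed.
#' @param initial_activities_MBq Administered activities of the vial series,
#'   MBq.
#' @param sample_times_min Optical-density sampling times, minutes.
#' @param dose_per_mbq Ground-truth dose per administered activity at
#'   complete decay, Gy/MBq.
#' @param od_noise_frac Relative repeatability of an OD reading: the
#'   additive Gaussian noise sd as a fraction of the radiation- and
#'   carrier-induced absorbance change (spectrophotometer repeatability is
#'   quoted in percent of the signal).
#' @param pet_noise_frac Proportional Gaussian noise on PET ROI values.
#' @param blank_od Absorbance of the unirradiated blank solution.
#' @param fdg_offset Constant absorbance offset contributed by the
#'   non-radioactive carrier (FDG).
#' @param pet_times_min Sampling times of dynamic PET, minutes.
#' @param organ_profiles Named list of organ profiles, see
#'   [default_organ_profiles()].
#' @param nuclide A [radionuclide()].
#' @param constants A [fricke_constants()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         initial_activities_MBq = c(15, 20, 30, 40, 60, 80),
                         sample_times_min = c(0, 30, 60, 110, 240, 350, 430, 1450),
                         dose_per_mbq = 0.17,
                         od_noise_frac = 0.03,
                         pet_noise_frac = 0.03,
                         blank_od = 0.050,
                         fdg_offset = 0.003,
                         pet_times_min = seq(0, 120, by = 10),
                         organ_profiles = default_organ_profiles(),
                         nuclide = f18(),
                         constants = fricke_constants("F18")) {
  stopifnot(od_noise_frac >= 0, pet_noise_frac >= 0, dose_per_mbq > 0,
            all(initial_activities_MBq >= 0), blank_od >= 0, fdg_offset >= 0)
  structure(
    list(seed = as.integer(seed),
         initial_activities_MBq = initial_activities_MBq,
         sample_times_min = sample_times_min,
         dose_per_mbq = dose_per_mbq,
         od_noise_frac = od_noise_frac,
         pet_noise_frac = pet_noise_frac,
         blank_od = blank_od,
         fdg_offset = fdg_offset,
         pet_times_min = pet_times_min,
         organ_profiles = organ_profiles,
         nuclide = nuclide,
         constants = constants),
    class = "synth_config"
  )
}

#' Ground-truth cumulative dose of a synthetic vial
#'
#' Dose accrues in proportion to the cumulated-activity fraction of the
#' decaying source: \eqn{D(t) = s \, A_0 (1 - 2^{-t/T_{1/2}})}, where `s` is
#' the configured dose per administered activity at complete decay. The
#' curve rises steeply over the first hours and plateaus as the source
#' decays away.
#'
#' @param cfg A [synth_config()].
#' @param a0_MBq Administered activity, MBq.
#' @param t_min Time since administration, minutes. Vectorised.
#' @return Cumulative absorbed dose, Gy.
#' @export
synthetic_dose_at <- function(cfg, a0_MBq, t_min) {
  stopifnot(inherits(cfg, "synth_config"))
  cfg$dose_per_mbq * a0_MBq * (1 - 2^(-t_min / cfg$nuclide$half_life_min))
}

#' Generate a synthetic optical-density study
#'
#' For every configured administered activity, generates the OD time series
#' of the radioactive vial together with a matched non-radioactive carrier
#' control and a blank. The radioactive reading is
#' `blank + fdg_offset + delta_od_for_dose(D(t)) + noise`, with additive
#' Gaussian noise whose sd is `od_noise_frac` times the above-blank signal.
#'
#' @param cfg A [synth_config()].
#' @return A data.frame in the OD-series dialect
#'   (`sample_id,time_min,od_304,condition`).
#' @export
#' @examples
#' od <- make_od_series(synth_config(seed = 7, od_noise_frac = 0))
#' head(od)
make_od_series <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    rows <- list()
    noisy <- function(signal_above_blank) {
      sd <- cfg$od_noise_frac * signal_above_blank
      cfg$blank_od + signal_above_blank +
        stats::rnorm(length(signal_above_blank), 0, sd)
    }
    for (a0 in cfg$initial_activities_MBq) {
      t <- cfg$sample_times_min
      doa <- delta_od_for_dose(synthetic_dose_at(cfg, a0, t), cfg$constants)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("vial_%03.0fMBq", a0), time_min = t,
        od_304 = pmax(noisy(cfg$fdg_offset + doa), 0),
        condition = "radioactive", stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("ctrl_%03.0fMBq", a0), time_min = t,
        od_304 = pmax(noisy(rep(cfg$fdg_offset, length(t))), 0),
        condition = "fdg_control", stringsAsFactors = FALSE)
    }
    t <- cfg$sample_times_min
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = "blank", time_min = t,
      od_304 = rep(cfg$blank_od, length(t)),
      condition = "blank", stringsAsFactors = FALSE)
    do.call(rbind, rows)
  })
}

# Analytic AUC (MBq.h per g) of an organ profile over [0, t_end] minutes:
# injected * uf * integral of (1 - e^(-k_up t)) e^(-(k_bio + lambda) t).
profile_auc_analytic <- function(profile, injected_MBq, nuclide,
                                 t_end_min = Inf) {
  lam <- log(2) / nuclide$half_life_min            # /min
  kd <- profile$k_bio + lam
  ku <- profile$k_up
  int_exp <- function(r, t) if (is.infinite(t)) 1 / r else (1 - exp(-r * t)) / r
  auc_min <- int_exp(kd, t_end_min) - int_exp(kd + ku, t_end_min)
  injected_MBq * profile$uptake_frac_per_g * auc_min / 60
}

#' Generate a synthetic PET time-activity curve
#'
#' Activity concentration per gram of tissue follows
#' `injected * uf * (1 - exp(-k_up t)) * exp(-k_bio t) * exp(-lambda t)`
#' plus proportional Gaussian noise. With `organ = "vial"` (uptake fraction
#' 1, instantaneous uptake, no clearance) the curve reduces to the pure
#' physical decay of a sealed source.
#'
#' @param cfg A [synth_config()].
#' @param organ Organ name present in `cfg$organ_profiles`, or `"vial"`.
#' @param injected_MBq Administered activity, MBq.
#' @param replicate Animal replicate index; each replicate draws its own
#'   lognormal uptake deviation (median = the configured uptake fraction).
#' @param times_min Sampling times; defaults to `cfg$pet_times_min`.
#' @return A [roi_series()] in MBq/g (not decay-corrected).
#' @export
make_pet_tac <- function(cfg, organ, injected_MBq, replicate = 1L,
                         times_min = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (identical(organ, "vial")) {
    profile <- list(uptake_frac_per_g = 1, k_up = Inf, k_bio = 0,
                    sigma_log = 0)
  } else {
    profile <- cfg$organ_profiles[[organ]]
    if (is.null(profile)) {
      stop("unknown organ '", organ, "'; configure it in `organ_profiles`",
           call. = FALSE)
    }
  }
  if (is.null(times_min)) times_min <- cfg$pet_times_min
  lam <- log(2) / cfg$nuclide$half_life_min
  seed <- (cfg$seed + string_offset(organ) + 131L * as.integer(replicate) +
             17L * as.integer(round(100 * injected_MBq))) %%
    .Machine$integer.max
  with_seed(seed, {
    uf <- profile$uptake_frac_per_g *
      exp(stats::rnorm(1, 0, profile$sigma_log))
    uptake <- if (is.infinite(profile$k_up)) {
      rep(1, length(times_min))
    } else {
      1 - exp(-profile$k_up * times_min)
    }
    conc <- injected_MBq * uf * uptake *
      exp(-(profile$k_bio + lam) * times_min)
    conc <- conc * (1 + stats::rnorm(length(conc), 0, cfg$pet_noise_frac))
    roi_series(paste0(organ, "_rep", replicate), times_min, pmax(conc, 0),
               unit = "MBq_per_g", decay_corrected = FALSE)
  })
}

#' Generate a complete synthetic benchmark bundle
#'
#' One call writes every input the pipeline consumes to a directory: the
#' OD study (`od_series.csv`), sealed-vial PET curves for each administered
#' activity (`vial_tacs.csv`), an organ biodistribution
#' (`organ_tacs.csv` and `organ_uptake.csv`), a self-dose S-value table
#' (`svalues.csv`, with S equal to the ground-truth conversion factor so
#' both dose formalisms coincide by construction) and the generating
#' parameters (`ground_truth.json`).
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if absent).
#' @param injected_MBq Administered activity of the synthetic animal, MBq.
#' @return Invisibly, the ground-truth list.
#' @export
make_benchmark_bundle <- function(cfg, dir, injected_MBq = 15) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  od <- make_od_series(cfg)
  utils::write.csv(od, file.path(dir, "od_series.csv"), row.names = FALSE)

  vial_times <- seq(0, 240, by = 60)
  vial_rows <- lapply(cfg$initial_activities_MBq, function(a0) {
    tac <- make_pet_tac(cfg, "vial", a0, times_min = vial_times)
    data.frame(roi_id = sprintf("vial_%03.0fMBq", a0),
               time_min = tac$time_min, value = tac$values,
               unit = "MBq_per_mL", decay_corrected = FALSE,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, vial_rows),
                   file.path(dir, "vial_tacs.csv"), row.names = FALSE)

  organs <- names(cfg$organ_profiles)
  organ_rows <- list()
  uptake_rows <- list()
  for (org in organs) {
    tac <- make_pet_tac(cfg, org, injected_MBq)
    organ_rows[[org]] <- data.frame(
      roi_id = org, time_min = tac$time_min, value = tac$values,
      unit = "MBq_per_g", decay_corrected = FALSE, stringsAsFactors = FALSE)
    tia <- time_integrated_activity(tac, cfg$nuclide)
    uptake_rows[[org]] <- data.frame(
      organ = org, tia_MBq_h_per_g = tia,
      mass_g = cfg$organ_profiles[[org]]$mass_g, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, organ_rows),
                   file.path(dir, "organ_tacs.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, uptake_rows),
                   file.path(dir, "organ_uptake.csv"), row.names = FALSE)

  c_true <- cfg$dose_per_mbq / cumulated_activity_analytic(1, cfg$nuclide)
  utils::write.csv(
    data.frame(source = organs, target = organs, S_Gy_per_MBq_h = c_true,
               stringsAsFactors = FALSE),
    file.path(dir, "svalues.csv"), row.names = FALSE)

  truth <- list(
    seed = cfg$seed,
    dose_per_mbq_Gy_MBq = cfg$dose_per_mbq,
    tia_per_mbq_MBqh_MBq = cumulated_activity_analytic(1, cfg$nuclide),
    conversion_factor_Gy_per_MBq_h = c_true,
    injected_MBq = injected_MBq,
    organ_auc_MBq_h_per_g = stats::setNames(
      lapply(organs, function(org) {
        profile_auc_analytic(cfg$organ_profiles[[org]], injected_MBq,
                             cfg$nuclide,
                             t_end_min = max(cfg$pet_times_min))
      }), organs)
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

#' Recover the calibration constants from a benchmark bundle
#'
#' Runs the full analysis on the files written by
#' [make_benchmark_bundle()]: final-time background-corrected doses are
#' fitted through the origin against administered activity; sealed-vial PET
#' curves are trapezoid-integrated with the analytic decay tail and fitted
#' the same way; the ratio of the two slopes gives the conversion factor.
#'
#' @param dir Directory holding a benchmark bundle.
#' @param constants [fricke_constants()] used to invert the OD readings.
#' @param nuclide A [radionuclide()].
#' @return A list: `dose_fit` and `tia_fit` ([fit_through_origin()] objects)
#'   and `conversion` (a [derive_conversion_factor()] result).
#' @export
analyze_benchmark_bundle <- function(dir, constants = fricke_constants("F18"),
                                     nuclide = f18()) {
  od <- read_od_series(file.path(dir, "od_series.csv"))
  last_t <- max(od$time_min)
  final <- od[od$time_min == last_t, ]
  radio <- final[final$condition == "radioactive", ]
  ctrl <- final[final$condition == "fdg_control", ]
  blank_od <- final$od_304[final$condition == "blank"][1]
  a0 <- as.numeric(sub("vial_([0-9]+)MBq", "\\1", radio$sample_id))
  ctrl_a0 <- as.numeric(sub("ctrl_([0-9]+)MBq", "\\1", ctrl$sample_id))
  ctrl <- ctrl[match(a0, ctrl_a0), ]
  dose_radio <- dose_from_delta_od(radio$od_304 - blank_od, constants)
  dose_ctrl <- dose_from_delta_od(ctrl$od_304 - blank_od, constants)
  doses <- fdg_background_correct(dose_radio, dose_ctrl)
  dose_fit <- fit_through_origin(a0, as.numeric(doses))

  tacs <- read_roi_series(file.path(dir, "vial_tacs.csv"))
  tia <- vapply(tacs, time_integrated_activity, numeric(1),
                nuclide = nuclide, extrapolate_tail = TRUE)
  tac_a0 <- as.numeric(sub("vial_([0-9]+)MBq", "\\1", names(tacs)))
  tia_fit <- fit_through_origin(tac_a0, tia)

  list(dose_fit = dose_fit, tia_fit = tia_fit,
       conversion = derive_conversion_factor(dose_fit, tia_fit))
}
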