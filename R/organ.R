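#' Organ uptake record
#'
#' Time-integrated activity per gram of tissue together with the tissue
#' mass. The mass is mandatory: the conversion-factor dose method needs it
#' and no default is defensible.
#'
#' @param organ Character label.
#' @param tia_MBq_h_per_g Time-integrated activity per gram, MBq.h/g,
#'   non-negative.
#' @param mass_g Tissue mass, g, strictly positive.
#' @return An object of class `organ_uptake`.
#' @export
organ_uptake <- function(organ, tia_MBq_h_per_g, mass_g) {
  if (missing(mass_g) || is.null(mass_g) || is.na(mass_g)) {
    stop("`mass_g` is required: organ masses must be supplied explicitly",
         call. = FALSE)
  }
  if (!is.numeric(tia_MBq_h_per_g) || tia_MBq_h_per_g < 0) {
    stop("`tia_MBq_h_per_g` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(mass_g) || mass_g <= 0) {
    stop("`mass_g` must be strictly positive", call. = FALSE)
  }
  structure(list(organ = organ, tia_MBq_h_per_g = tia_MBq_h_per_g,
                 mass_g = mass_g),
            class = "organ_uptake")
}

#' S-value table for the MIRD formalism
#'
#' Mean absorbed dose to a target region per unit cumulated activity in a
#' source region, Gy/MBq.h. Every target must have a self-dose entry
#' (source == target): for short-range positron emitters self-dose
#' dominates, and a table without it is almost certainly malformed.
#'
#' @param source,target Character vectors of organ labels (recycled
#'   together).
#' @param s_Gy_per_MBq_h Non-negative S-values, Gy/MBq.h.
#' @return An object of class `s_value_table` (a data.frame).
#' @export
#' @examples
#' s_value_table(c("tumor", "liver"), c("tumor", "liver"), c(0.51, 0.13))
s_value_table <- function(source, target, s_Gy_per_MBq_h) {
  df <- data.frame(source = as.character(source),
                   target = as.character(target),
                   s_Gy_per_MBq_h = as.numeric(s_Gy_per_MBq_h),
                   stringsAsFactors = FALSE)
  if (any(df$s_Gy_per_MBq_h < 0)) {
    stop("S-values must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(df[c("source", "target")])) {
    stop("duplicate (source, target) pairs", call. = FALSE)
  }
  targets <- unique(df$target)
  has_self <- targets %in% df$source[df$source == df$target]
  if (!all(has_self)) {
    stop("missing self-dose entry for target(s): ",
         paste(targets[!has_self], collapse = ", "), call. = FALSE)
  }
  class(df) <- c("s_value_table", class(df))
  df
}

#' Look up an S-value
#'
#' @param s_table An [s_value_table()].
#' @param source,target Organ labels.
#' @param missing_as_zero Return 0 (with a warning) for an absent pair
#'   instead of erroring.
#' @return S-value in Gy/MBq.h.
#' @export
s_value <- function(s_table, source, target, missing_as_zero = TRUE) {
  stopifnot(inherits(s_table, "s_value_table"))
  hit <- s_table$source == source & s_table$target == target
  if (!any(hit)) {
    if (missing_as_zero) {
      warning("no S-value for ", source, " -> ", target, "; using 0",
              call. = FALSE)
      return(0)
    }
    stop("no S-value for ", source, " -> ", target, call. = FALSE)
  }
  s_table$s_Gy_per_MBq_h[hit][1]
}

#' Organ absorbed dose by the conversion-factor method
#'
#' \eqn{D = A \times M \times C}: time-integrated activity per gram times
#' tissue mass times the Fricke-derived conversion factor (Gy/MBq.h). This
#' is a local-energy-deposition (self-dose) estimate: the short positron
#' range makes self-dose dominant, and cross-fire is not modelled here.
#'
#' @param uptake An [organ_uptake()].
#' @param conversion A [conversion_factor()] or a bare numeric in Gy/MBq.h.
#' @return Absorbed dose, Gy.
#' @export
#' @examples
#' dose_fricke(organ_uptake("tumor", 19.8, 0.126), 0.064)
dose_fricke <- function(uptake, conversion) {
  stopifnot(inherits(uptake, "organ_uptake"))
  c_val <- if (inherits(conversion, "conversion_factor")) {
    conversion$value
  } else {
    conversion
  }
  if (!is.numeric(c_val) || c_val <= 0) {
    stop("conversion factor must be positive (Gy/MBq.h)", call. = FALSE)
  }
  uptake$tia_MBq_h_per_g * uptake$mass_g * c_val
}

#' Target organ dose by the MIRD formalism
#'
#' \eqn{D_{target} = \sum_i \tilde{A}_i \, S(i \rightarrow target)}: the
#' sum over source organs of the cumulated activity times the S-value
#' kernel. Source organs without an S-value for the target contribute zero
#' with a warning.
#'
#' @param tias_MBq_h Named numeric vector: cumulated activity per source
#'   organ, MBq.h.
#' @param s_table An [s_value_table()].
#' @param target Target organ label.
#' @return Absorbed dose to the target, Gy.
#' @export
#' @examples
#' s <- s_value_table("tumor", "tumor", 0.5)
#' dose_mird(c(tumor = 1), s, "tumor")
dose_mird <- function(tias_MBq_h, s_table, target) {
  if (!length(tias_MBq_h)) {
    stop("`tias_MBq_h` must name at least one source organ", call. = FALSE)
  }
  if (is.null(names(tias_MBq_h)) || any(!nzchar(names(tias_MBq_h)))) {
    stop("`tias_MBq_h` must be a named vector of source-organ TIAs",
         call. = FALSE)
  }
  if (any(tias_MBq_h < 0)) stop("TIAs must be non-negative", call. = FALSE)
  s_vals <- vapply(names(tias_MBq_h), function(src) {
    s_value(s_table, src, target, missing_as_zero = TRUE)
  }, numeric(1))
  sum(tias_MBq_h * s_vals)
}

#' Per-organ dose comparison report
#'
#' Computes, for every organ, the absorbed dose by the conversion-factor
#' method and by the MIRD formalism (every organ acting as a source for
#' every target), their ratio and the normalised uptake, and returns them as
#' one table.
#'
#' @param uptakes A list of [organ_uptake()] objects.
#' @param s_table An [s_value_table()] (may cover only some pairs; missing
#'   pairs count 0 with a warning).
#' @param conversion A [conversion_factor()] or numeric, Gy/MBq.h.
#' @param injected_MBq Administered activity, MBq (for the %IA.h/g column).
#' @return A data.frame with columns `organ`, `tia_MBq_h_per_g`, `mass_g`,
#'   `pct_ia_h_per_g`, `dose_fricke_Gy`, `dose_mird_Gy`, `ratio_fricke_mird`.
#'   The conversion factor used is recorded in attribute
#'   `"conversion_Gy_per_MBq_h"`.
#' @export
dose_report <- function(uptakes, s_table, conversion, injected_MBq) {
  if (!length(uptakes)) stop("need at least one organ", call. = FALSE)
  stopifnot(all(vapply(uptakes, inherits, logical(1), "organ_uptake")))
  c_val <- if (inherits(conversion, "conversion_factor")) {
    conversion$value
  } else {
    conversion
  }
  organs <- vapply(uptakes, `[[`, character(1), "organ")
  tia_g <- vapply(uptakes, `[[`, numeric(1), "tia_MBq_h_per_g")
  mass <- vapply(uptakes, `[[`, numeric(1), "mass_g")
  tia_total <- stats::setNames(tia_g * mass, organs)  # MBq.h per whole organ
  fricke <- vapply(uptakes, dose_fricke, numeric(1), conversion = c_val)
  mird <- vapply(organs, function(tg) dose_mird(tia_total, s_table, tg),
                 numeric(1))
  out <- data.frame(
    organ = organs,
    tia_MBq_h_per_g = tia_g,
    mass_g = mass,
    pct_ia_h_per_g = to_percent_injected_activity(tia_g, injected_MBq),
    dose_fricke_Gy = fricke,
    dose_mird_Gy = mird,
    ratio_fricke_mird = ifelse(mird > 0, fricke / mird, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "conversion_Gy_per_MBq_h") <- c_val
  out
}

#' Read an organ uptake table from CSV
#'
#' Expects the dialect `organ,tia_MBq_h_per_g,mass_g`.
#'
#' @param path Path to a CSV file.
#' @return A list of [organ_uptake()] objects.
#' @export
read_uptake_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("organ", "tia_MBq_h_per_g", "mass_g")
  if (!all(required %in% names(df))) {
    stop("uptake CSV must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    organ_uptake(df$organ[i], df$tia_MBq_h_per_g[i], df$mass_g[i])
  })
}

#' Read an S-value table from CSV
#'
#' Expects the dialect `source,target,S_Gy_per_MBq_h`.
#'
#' @param path Path to a CSV file.
#' @return An [s_value_table()].
#' @export
read_svalue_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("source", "target", "S_Gy_per_MBq_h")
  if (!all(required %in% names(df))) {
    stop("S-value CSV must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  s_value_table(df$source, df$target, df$S_Gy_per_MBq_h)
}
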