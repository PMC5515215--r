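# LC-MS/MS quantification logic: matrix-matched calibration with LOD/LOQ at
# S/N 3.3 and 10, extraction-efficiency correction, and MRM identity
# confirmation by retention time, transitions and intensity ratio.

#' Fit a matrix-matched calibration curve with LOD and LOQ
#'
#' Ordinary least squares of peak area on standard concentration. The limits
#' of detection and quantification are computed at signal-to-noise ratios of
#' 3.3 and 10 respectively: `lod = 3.3 * noise_sd / slope`,
#' `loq = 10 * noise_sd / slope`, so `loq / lod = 10 / 3.3` always holds.
#' When no baseline noise estimate is supplied, the residual standard
#' deviation of the fit is used.
#'
#' @param data Data frame with columns `level_ugL` (>= 3 distinct standard
#'   concentrations, each within 0.5-200 ug/l) and `area`.
#' @param noise_sd Baseline area noise SD; `NULL` (default) uses the fit's
#'   residual SD.
#' @param sn_lod,sn_loq Signal-to-noise multipliers (defaults 3.3 and 10).
#' @return A `calibration_curve` object with `slope`, `intercept`,
#'   `r_squared`, `noise_sd`, `lod`, `loq` and `status` (`"failed"` with a
#'   reason when the fitted slope is non-positive).
#' @examples
#' cal <- gen_calibration(slope = 2, intercept = 1, noise_sd = 0)
#' fit_calibration(cal)
#' @export
fit_calibration <- function(data, noise_sd = NULL, sn_lod = 3.3, sn_loq = 10) {
  data <- as_tibble(data)
  assert_columns(data, c("level_ugL", "area"), "data")
  if (length(unique(data$level_ugL)) < 3) {
    abort("calibration needs >= 3 distinct standard levels")
  }
  if (any(data$level_ugL < 0.5 | data$level_ugL > 200)) {
    abort("calibration levels must lie within 0.5-200 ug/l")
  }
  m <- lm(area ~ level_ugL, data = data)
  slope <- unname(coef(m)[2])
  intercept <- unname(coef(m)[1])
  r2 <- suppressWarnings(summary(m)$r.squared)
  out <- list(
    slope = slope, intercept = intercept, r_squared = r2,
    noise_sd = NA_real_, lod = NA_real_, loq = NA_real_,
    sn_lod = sn_lod, sn_loq = sn_loq, n = nrow(data),
    level_range = range(data$level_ugL),
    status = "ok", reason = NA_character_, data = data
  )
  if (slope <= 0) {
    out$status <- "failed"
    out$reason <- "fitted slope is non-positive"
    return(structure(out, class = "calibration_curve"))
  }
  out$noise_sd <- noise_sd %||% sqrt(sum(residuals(m)^2) / m$df.residual)
  out$lod <- sn_lod * out$noise_sd / slope
  out$loq <- sn_loq * out$noise_sd / slope
  structure(out, class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> status: %s\n", x$status))
  if (x$status == "ok") {
    cat(sprintf("  area = %.4g + %.4g * conc (R2 = %.5f), n = %d\n",
                x$intercept, x$slope, x$r_squared, x$n))
    cat(sprintf("  LOD = %.4g ug/l (S/N %.1f), LOQ = %.4g ug/l (S/N %.1f)\n",
                x$lod, x$sn_lod, x$loq, x$sn_loq))
  } else cat("  ", x$reason, "\n")
  invisible(x)
}

#' @describeIn fit_calibration Tidy coefficient summary.
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, noise_sd = x$noise_sd,
         lod = x$lod, loq = x$loq, status = x$status)
}

#' @describeIn fit_calibration One-row fit summary.
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n,
         level_min = x$level_range[1], level_max = x$level_range[2],
         status = x$status)
}

#' Estimate extraction efficiency from spike recoveries
#'
#' Extraction efficiency is the mean, over the spike levels, of the mean
#' recovered concentration divided by the nominal spiked concentration
#' (standards added to the heat-inactivated sludge supernatant matrix,
#' conventionally at 5 and 50 ug/l).
#'
#' @param data Data frame with columns `nominal_ugL` and `recovered_ugL`
#'   (one row per replicate).
#' @param levels Spike levels that must all be present (default `c(5, 50)`).
#' @return The efficiency as a single proportion. Values above 1.5 are
#'   rejected as implausible.
#' @examples
#' extraction_efficiency(
#'   data.frame(nominal_ugL = c(5, 50), recovered_ugL = c(4, 40))
#' )
#' @export
extraction_efficiency <- function(data, levels = c(5, 50)) {
  data <- as_tibble(data)
  assert_columns(data, c("nominal_ugL", "recovered_ugL"), "data")
  missing <- setdiff(levels, unique(data$nominal_ugL))
  if (length(missing) > 0) {
    abort(sprintf("missing spike level(s): %s",
                  paste(missing, collapse = ", ")))
  }
  eff <- data |>
    filter(.data$nominal_ugL %in% levels) |>
    group_by(.data$nominal_ugL) |>
    summarise(ratio = mean(.data$recovered_ugL) / .data$nominal_ugL[1],
              .groups = "drop") |>
    pull(.data$ratio) |>
    mean()
  if (eff > 1.5) abort("extraction efficiency > 1.5 is implausible")
  if (eff <= 0) abort("extraction efficiency must be positive")
  eff
}

#' Quantify sample peak areas against a calibration curve
#'
#' Converts areas to raw concentrations via the inverse calibration line,
#' applies LOD/LOQ censoring, and corrects quantifiable values for
#' extraction efficiency: `corrected = raw / efficiency`. Concentrations
#' below the LOD (including negative inverse predictions) are reported as 0
#' with an explicit `below_lod` flag rather than `NA`, so downstream
#' correlation analyses keep numeric series while the censoring information
#' is preserved.
#'
#' @param area Numeric vector of peak areas.
#' @param curve A `calibration_curve` from [fit_calibration()].
#' @param efficiency Extraction efficiency in `(0, 1.5]`.
#' @return A tibble with `area`, `raw_conc`, `censoring_flag`
#'   (`quantified` / `below_loq` / `below_lod`) and `corrected_conc`.
#' @export
quantify <- function(area, curve, efficiency = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$status != "ok") abort("cannot quantify against a failed calibration")
  if (!is.numeric(efficiency) || length(efficiency) != 1 ||
      efficiency <= 0 || efficiency > 1.5) {
    abort("`efficiency` must be a single value in (0, 1.5]")
  }
  raw <- (area - curve$intercept) / curve$slope
  flag <- dplyr::case_when(
    raw < curve$lod ~ "below_lod",
    raw < curve$loq ~ "below_loq",
    TRUE ~ "quantified"
  )
  tibble(
    area = area,
    raw_conc = raw,
    censoring_flag = flag,
    corrected_conc = ifelse(flag == "below_lod", 0, raw / efficiency)
  )
}

#' Convert extract concentrations to biomass-normalised amounts
#'
#' Optional conversion from ug/l of extract to pmol per gram of biomass,
#' requiring the analyte molar mass and the biomass concentration of the
#' extracted volume.
#'
#' @param conc_ugL Concentration in ug/l.
#' @param molar_mass_g_mol Analyte molar mass (g/mol).
#' @param biomass_g_L Biomass per litre of extracted sample (g/l).
#' @return Amount in pmol per gram biomass.
#' @export
ug_per_l_to_pmol_per_g <- function(conc_ugL, molar_mass_g_mol, biomass_g_L) {
  assert_number(molar_mass_g_mol, "molar_mass_g_mol", lower = 0,
                strict_lower = TRUE)
  assert_number(biomass_g_L, "biomass_g_L", lower = 0, strict_lower = TRUE)
  # ug/l -> pmol/l is conc * 1e6 / M; divide by biomass g/l for pmol/g.
  conc_ugL * 1e6 / molar_mass_g_mol / biomass_g_L
}

#' Confirm analyte identity against an MRM reference
#'
#' An observation is accepted as the reference analyte iff its retention
#' time is within `rt_tol` minutes of the reference, both transition ions
#' are observed with positive intensity, and the transition intensity ratio
#' agrees with the reference on the log scale within `log(1 + ratio_tol)`.
#' Every failed criterion is listed in the reasons.
#'
#' @param candidate Data frame with columns `rt`, `t1_int`, `t2_int` (one
#'   row per observation; missing intensities as `NA` or 0).
#' @param reference List or one-row data frame with `retention_time` and
#'   `intensity_ratio` (transition 2 over transition 1).
#' @param rt_tol Retention-time tolerance in minutes (default 0.2).
#' @param ratio_tol Relative intensity-ratio tolerance (default 0.3, i.e.
#'   +/- 30%).
#' @return A tibble with `accepted` and a list-column `reasons`.
#' @export
confirm_identity <- function(candidate, reference, rt_tol = 0.2,
                             ratio_tol = 0.3) {
  candidate <- as_tibble(candidate)
  assert_columns(candidate, c("rt", "t1_int", "t2_int"), "candidate")
  if (rt_tol <= 0 || ratio_tol <= 0) abort("tolerances must be > 0")
  ref_rt <- reference$retention_time
  ref_ratio <- reference$intensity_ratio
  stopifnot(is.numeric(ref_rt), is.numeric(ref_ratio), ref_ratio > 0)
  out <- purrr::pmap(candidate[c("rt", "t1_int", "t2_int")],
                     function(rt, t1_int, t2_int) {
    reasons <- character(0)
    if (is.na(rt) || abs(rt - ref_rt) > rt_tol) {
      reasons <- c(reasons, "retention time outside tolerance")
    }
    t1_ok <- !is.na(t1_int) && t1_int > 0
    t2_ok <- !is.na(t2_int) && t2_int > 0
    if (!t1_ok || !t2_ok) {
      reasons <- c(reasons, "transition absent")
    } else if (abs(log((t2_int / t1_int) / ref_ratio)) > log(1 + ratio_tol)) {
      reasons <- c(reasons, "transition intensity ratio outside tolerance")
    }
    list(accepted = length(reasons) == 0, reasons = reasons)
  })
  tibble(
    accepted = purrr::map_lgl(out, "accepted"),
    reasons = purrr::map(out, "reasons")
  )
}
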