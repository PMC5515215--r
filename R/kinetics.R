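# AHL inactivation kinetics: zero- and first-order half-life estimation from
# spiked time-course data, adsorption partitioning from controls, Holm-Sidak
# multiple comparisons and the chain-length trend summary.

new_kinetic_fit <- function(order, c0_hat = NA_real_, rate_k = NA_real_,
                            half_life = NA_real_, half_life_se = NA_real_,
                            r_squared = NA_real_, n = NA_integer_,
                            status = "ok", reason = NA_character_,
                            data = NULL) {
  structure(
    list(order = order, c0_hat = c0_hat, rate_k = rate_k,
         half_life = half_life, half_life_se = half_life_se,
         r_squared = r_squared, n = n, status = status, reason = reason,
         data = data),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> order %d, status: %s\n", x$order, x$status))
  if (x$status == "ok") {
    cat(sprintf("  k = %.4g %s, C0 = %.4g uM, t1/2 = %.3g +/- %.2g h, R2 = %.4f\n",
                x$rate_k, if (x$order == 0) "uM/h" else "1/h",
                x$c0_hat, x$half_life, x$half_life_se, x$r_squared))
  } else if (!is.na(x$reason)) {
    cat("  ", x$reason, "\n")
  }
  invisible(x)
}

#' @describeIn fit_first_order Tidy one-row coefficient summary.
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(
    order = x$order, c0_hat = x$c0_hat, rate_k = x$rate_k,
    half_life = x$half_life, half_life_se = x$half_life_se,
    status = x$status
  )
}

#' @describeIn fit_first_order One-row goodness-of-fit summary.
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(order = x$order, r_squared = x$r_squared, n = x$n, status = x$status)
}

check_series <- function(data) {
  data <- as_tibble(data)
  assert_columns(data, c("time_h", "concentration"), "data")
  data <- data |> arrange(.data$time_h)
  if (nrow(data) < 3) return(list(ok = FALSE, reason = "fewer than 3 timepoints"))
  if (sd(data$concentration) == 0) {
    return(list(ok = FALSE, reason = "constant concentrations"))
  }
  list(ok = TRUE, data = data)
}

# r^2 of a fitted mean curve against observations, on the raw scale, so that
# zero- and first-order fits are comparable.
raw_r_squared <- function(obs, fit) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - fit)^2) / ss_tot
}

#' Fit zero-order decay kinetics
#'
#' Ordinary least squares of concentration on time: `C(t) = C0 - k t`. The
#' half-life of a zero-order process depends on the starting concentration,
#' `t1/2 = C0 / (2 k)`; its standard error comes from the delta method using
#' the full coefficient covariance.
#'
#' @param data Data frame with columns `time_h` and `concentration` for a
#'   single decay series (>= 3 timepoints, not all equal).
#' @return A `kinetic_fit` object. A non-positive fitted rate gives status
#'   `"non_degrading"` with undefined half-life; degenerate input gives
#'   status `"failed"` with a reason.
#' @examples
#' d <- tibble::tibble(time_h = 0:5, concentration = 10 - 2 * (0:5))
#' fit_zero_order(d)
#' @export
fit_zero_order <- function(data) {
  chk <- check_series(data)
  if (!chk$ok) return(new_kinetic_fit(0, status = "failed", reason = chk$reason))
  d <- chk$data
  m <- lm(concentration ~ time_h, data = d)
  c0 <- unname(coef(m)[1])
  k <- -unname(coef(m)[2])
  r2 <- raw_r_squared(d$concentration, fitted(m))
  if (k <= 0) {
    return(new_kinetic_fit(0, c0_hat = c0, rate_k = k, r_squared = r2,
                           n = nrow(d), status = "non_degrading",
                           reason = "fitted rate is non-positive", data = d))
  }
  # Delta method on t1/2 = c0/(2k); gradient (1/(2k), c0/(2k^2)) wrt (c0, k),
  # and cov(c0, k) = -cov(intercept, slope).
  V <- suppressWarnings(vcov(m))  # perfect fits trip summary.lm
  g <- c(1 / (2 * k), c0 / (2 * k^2))
  Vck <- matrix(c(V[1, 1], -V[1, 2], -V[2, 1], V[2, 2]), 2, 2)
  hl_se <- sqrt(drop(t(g) %*% Vck %*% g))
  new_kinetic_fit(0, c0_hat = c0, rate_k = k, half_life = c0 / (2 * k),
                  half_life_se = hl_se, r_squared = r2, n = nrow(d),
                  data = d)
}

#' Fit first-order decay kinetics
#'
#' Log-linear least squares of `log(C)` on time gives starting values
#' (`C(t) = C0 exp(-k t)`, so `log C = log C0 - k t`), optionally refined by
#' a nonlinear least-squares pass on the raw concentration scale
#' (Levenberg-Marquardt). The half-life is `t1/2 = log(2) / k`, independent
#' of the starting concentration; its SE follows from the rate SE by the
#' delta method. The reported r-squared is computed on the raw scale so it
#' is directly comparable with the zero-order fit.
#'
#' Zero concentrations are floored at `floor` before the log transform
#' (default: half the smallest positive observed concentration, a standard
#' left-censoring device; pass the instrument LOQ/2 when known). A series
#' whose trailing zeros make up more than half the points is refused.
#'
#' @inheritParams fit_zero_order
#' @param floor Replacement for zero concentrations before the log
#'   transform; `NULL` (default) uses half the smallest positive value.
#' @param refine Run the nonlinear refinement pass (default `TRUE`).
#' @return A `kinetic_fit` object.
#' @examples
#' d <- tibble::tibble(time_h = 0:5, concentration = 5 * exp(-log(2) * (0:5)))
#' fit_first_order(d)
#' @export
fit_first_order <- function(data, floor = NULL, refine = TRUE) {
  chk <- check_series(data)
  if (!chk$ok) return(new_kinetic_fit(1, status = "failed", reason = chk$reason))
  d <- chk$data
  zero_tail <- rev(cumprod(rev(d$concentration == 0)))
  if (sum(zero_tail) > nrow(d) / 2) {
    return(new_kinetic_fit(1, status = "failed",
                           reason = "all-zero tail covers more than half the series"))
  }
  conc <- d$concentration
  if (any(conc <= 0)) {
    floor <- floor %||% (min(conc[conc > 0]) / 2)
    conc[conc <= 0] <- floor
  }
  m <- lm(log(conc) ~ time_h, data = d)
  c0 <- exp(unname(coef(m)[1]))
  k <- -unname(coef(m)[2])
  k_se <- suppressWarnings(sqrt(vcov(m)[2, 2]))
  if (refine && k > 0) {
    nl <- tryCatch(
      minpack.lm::nlsLM(
        concentration ~ c0 * exp(-k * time_h),
        data = d, start = list(c0 = c0, k = k),
        lower = c(0, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(nl)) {
      c0 <- unname(coef(nl)["c0"])
      k <- unname(coef(nl)["k"])
      k_se <- sqrt(vcov(nl)["k", "k"])
    }
  }
  r2 <- raw_r_squared(d$concentration, c0 * exp(-k * d$time_h))
  if (k <= 0) {
    return(new_kinetic_fit(1, c0_hat = c0, rate_k = k, r_squared = r2,
                           n = nrow(d), status = "non_degrading",
                           reason = "fitted rate is non-positive", data = d))
  }
  new_kinetic_fit(1, c0_hat = c0, rate_k = k, half_life = log(2) / k,
                  half_life_se = log(2) / k^2 * k_se, r_squared = r2,
                  n = nrow(d), data = d)
}

#' Select between the zero- and first-order fits
#'
#' Returns whichever fit explains more raw-scale variance; when the two
#' r-squared values agree within `1e-6` the first-order fit is preferred
#' (exponential loss is the default expectation for enzymatic signal
#' degradation).
#'
#' @param fit0,fit1 Zero- and first-order `kinetic_fit` objects for the same
#'   series.
#' @return The selected `kinetic_fit`, or a failed fit when both failed.
#' @export
select_model <- function(fit0, fit1) {
  stopifnot(inherits(fit0, "kinetic_fit"), inherits(fit1, "kinetic_fit"))
  ok0 <- fit0$status == "ok"
  ok1 <- fit1$status == "ok"
  if (!ok0 && !ok1) {
    return(new_kinetic_fit(NA_integer_, status = "failed",
                           reason = "both kinetic fits failed"))
  }
  if (!ok0) return(fit1)
  if (!ok1) return(fit0)
  if (fit0$r_squared - fit1$r_squared > 1e-6) fit0 else fit1
}

#' Estimate the adsorptive loss fraction from the two controls
#'
#' Adsorption of AHLs to sludge biomass is estimated by comparing residual
#' concentrations in the sterile synthetic-wastewater control and the
#' heat-inactivated sludge control, immediately after addition and after
#' 1 h of incubation:
#' `fraction = 1 - mean(heat at {0, 1 h}) / mean(sww at {0, 1 h})`,
#' clamped to `[0, 1]`.
#'
#' @param sww,heat Data frames with `time_h` and `concentration` for the
#'   SWW and heat-inactivated control series; both must contain `t = 0` and
#'   a point within 0.25 h of 1 h.
#' @return A list with `fraction`, plus the per-series means used.
#' @export
adsorption_fraction <- function(sww, heat) {
  pick <- function(d, label) {
    d <- as_tibble(d)
    assert_columns(d, c("time_h", "concentration"), label)
    t0 <- d$concentration[d$time_h == 0]
    if (length(t0) == 0) abort(sprintf("`%s` has no t = 0 point", label))
    near1 <- d |> filter(abs(.data$time_h - 1) <= 0.25)
    if (nrow(near1) == 0) {
      abort(sprintf("`%s` has no point within 0.25 h of 1 h", label))
    }
    c1 <- near1$concentration[which.min(abs(near1$time_h - 1))]
    mean(c(mean(t0), c1))
  }
  m_sww <- pick(sww, "sww")
  m_heat <- pick(heat, "heat")
  frac <- 1 - m_heat / m_sww
  if (frac < 0) {
    warn("heat-inactivated control above SWW control; adsorption clamped to 0")
  }
  list(fraction = min(1, max(0, frac)), mean_sww = m_sww, mean_heat = m_heat)
}

#' Rescale a live series to isolate biological decay
#'
#' Divides concentrations at `t > 0` by `1 - adsorption` so the fitted decay
#' reflects enzymatic loss rather than the instantaneous adsorptive drop.
#'
#' @param data Series data frame (`time_h`, `concentration`).
#' @param adsorption Adsorbed fraction in `[0, 1)`.
#' @return The rescaled series.
#' @export
correct_adsorption <- function(data, adsorption) {
  assert_number(adsorption, "adsorption", lower = 0, upper = 1,
                strict_upper = TRUE)
  data |>
    mutate(concentration = ifelse(.data$time_h > 0,
                                  .data$concentration / (1 - adsorption),
                                  .data$concentration))
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' Sorts the raw p-values ascending and sets
#' `adj_(i) = max_{j <= i} 1 - (1 - p_(j))^(m - j + 1)`, capped at 1 — the
#' Sidak analogue of Holm's step-down procedure, controlling the family-wise
#' error rate.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_sidak(c(0.01, 0.04))  # 1 - 0.99^2 = 0.0199, then 0.04
#' @export
holm_sidak <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Compare replicate half-lives between two groups per AHL
#'
#' Runs a two-sample Welch t-test per AHL (e.g. live sludge versus the
#' heat-inactivated control) on replicate half-life estimates and adjusts
#' the p-values across AHLs with the Holm-Sidak step-down procedure.
#'
#' @param data Data frame with columns `ahl`, `group` (exactly two levels)
#'   and `half_life` (one row per replicate).
#' @return A tibble per AHL with group means, the t statistic, raw and
#'   adjusted p-values. AHLs with fewer than two replicates in either group
#'   are excluded with a message.
#' @export
compare_half_lives <- function(data) {
  data <- as_tibble(data)
  assert_columns(data, c("ahl", "group", "half_life"), "data")
  groups <- sort(unique(data$group))
  if (length(groups) != 2) abort("`group` must have exactly two levels")
  per_ahl <- data |>
    group_by(.data$ahl) |>
    summarise(
      n_a = sum(.data$group == groups[1]),
      n_b = sum(.data$group == groups[2]),
      .groups = "drop"
    )
  excluded <- per_ahl |> filter(.data$n_a < 2 | .data$n_b < 2)
  if (nrow(excluded) > 0) {
    inform(sprintf("excluding AHL(s) with < 2 replicates per group: %s",
                   paste(excluded$ahl, collapse = ", ")))
  }
  keep <- setdiff(per_ahl$ahl, excluded$ahl)
  if (length(keep) == 0) abort("no AHL has >= 2 replicates in both groups")
  res <- purrr::map(keep, function(a) {
    d <- data |> filter(.data$ahl == a)
    x <- d$half_life[d$group == groups[1]]
    y <- d$half_life[d$group == groups[2]]
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
      # identical constant groups: no evidence of difference
      return(tibble(ahl = a, mean_a = mean(x), mean_b = mean(y),
                    statistic = 0, p_raw = 1))
    }
    tt <- t.test(x, y, var.equal = FALSE)
    tibble(ahl = a, mean_a = mean(x), mean_b = mean(y),
           statistic = unname(tt$statistic), p_raw = tt$p.value)
  }) |> bind_rows()
  res |>
    mutate(p_adj = holm_sidak(.data$p_raw)) |>
    rename(!!paste0("mean_", groups[1]) := "mean_a",
           !!paste0("mean_", groups[2]) := "mean_b")
}

#' Summarise the half-life versus acyl-chain-length trend
#'
#' Computes the Spearman rank correlation between half-life and acyl chain
#' length within each C3-substitution class, flagging an inverse trend
#' (shorter half-lives for longer chains) when the correlation is negative.
#'
#' @param fits Data frame with columns `ahl` and `half_life`; chain length
#'   and substitution are parsed from the acronym via [ahl_info()] unless
#'   `chain_length`/`substitution` columns are supplied.
#' @param min_ahls Minimum AHLs per substitution class (default 3); smaller
#'   classes are skipped with a message.
#' @return A tibble per substitution class: `n`, `spearman_rho`,
#'   `inverse_trend`. Classes where all half-lives tie give `NA` correlation.
#' @export
chain_length_trend <- function(fits, min_ahls = 3) {
  fits <- as_tibble(fits)
  assert_columns(fits, c("ahl", "half_life"), "fits")
  if (!all(c("chain_length", "substitution") %in% names(fits))) {
    fits <- fits |> left_join(ahl_info(unique(fits$ahl)), by = "ahl")
  }
  small <- fits |> count(.data$substitution) |> filter(.data$n < min_ahls)
  if (nrow(small) > 0) {
    inform(sprintf("skipping substitution class(es) with < %d AHLs: %s",
                   min_ahls, paste(small$substitution, collapse = ", ")))
  }
  eligible <- fits |>
    group_by(.data$substitution) |>
    filter(dplyr::n() >= .env$min_ahls) |>
    ungroup()
  if (nrow(eligible) == 0) {
    return(tibble(substitution = character(0), n = integer(0),
                  spearman_rho = numeric(0), inverse_trend = logical(0)))
  }
  eligible |>
    group_by(.data$substitution) |>
    summarise(
      n = dplyr::n(),
      spearman_rho = if (sd(.data$half_life) == 0) NA_real_ else
        suppressWarnings(cor(.data$half_life, .data$chain_length,
                             method = "spearman")),
      .groups = "drop"
    ) |>
    mutate(inverse_trend = !is.na(.data$spearman_rho) & .data$spearman_rho < 0)
}
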