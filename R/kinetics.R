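# Enzyme characterization maths: Michaelis-Menten fitting, catalytic
# efficiencies with report-style rounding, kinetic isotope effects,
# thermal-shift melting temperatures, flavin extinction coefficients and
# pH-activity profiles.

#' Construct a rate dataset
#'
#' @param substrate_mM Substrate concentrations, mM (> 0).
#' @param rate_per_s Initial rates as per-enzyme turnover, 1/s (>= 0).
#' @param replicate Optional replicate ids.
#' @param label Enzyme/substrate label.
#' @param assay Assay type: `"oxygen_electrode"` (direct O2 consumption) or
#'   `"hrp_aap_dchbs"` (peroxidase-coupled dye assay).
#' @return A tibble of class `rate_dataset`.
#' @export
rate_dataset <- function(substrate_mM, rate_per_s, replicate = 1L,
                         label = "dataset",
                         assay = c("oxygen_electrode", "hrp_aap_dchbs")) {
  assay <- match.arg(assay)
  if (any(substrate_mM <= 0)) abort("substrate concentrations must be > 0")
  if (any(rate_per_s < 0)) abort("rates must be >= 0")
  out <- tibble(substrate_mM = substrate_mM, rate_per_s = rate_per_s,
                replicate = replicate, label = label, assay = assay)
  class(out) <- c("rate_dataset", class(out))
  out
}

#' Fit Michaelis-Menten kinetics
#'
#' Unit-weight nonlinear least squares of `v = kcat * S / (km + S)`
#' (Levenberg-Marquardt), initialized from a Hanes-Woolf linearization
#' (`S/v` regressed on `S`). Needs at least 5 distinct substrate
#' concentrations; warns when the data do not approach saturation (maximum
#' concentration below `km`), since `kcat` is then poorly identified.
#'
#' @param data A [rate_dataset()] or any tibble with `substrate_mM` and
#'   `rate_per_s` columns.
#' @return An object of class `mm_fit` with elements `kcat`, `km` (point
#'   estimates), `kcat_se`, `km_se`, `efficiency` (in 1/(M s), exactly
#'   `kcat/(km/1000)`), `converged`, `residual_sd`, `n`, `data`, `fit`.
#' @export
fit_mm <- function(data) {
  if (length(unique(data$substrate_mM)) < 5) {
    abort("need at least 5 distinct substrate concentrations")
  }
  s <- data$substrate_mM
  v <- data$rate_per_s
  pos <- v > 0
  hw <- lm((s / v)[pos] ~ s[pos])
  vmax0 <- unname(1 / coef(hw)[2])
  km0 <- unname(coef(hw)[1] * vmax0)
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(s)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ kcat * s / (km + s),
      start = list(kcat = vmax0, km = km0),
      lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- structure(
      list(kcat = NA_real_, km = NA_real_, kcat_se = NA_real_,
           km_se = NA_real_, efficiency = NA_real_, converged = FALSE,
           residual_sd = NA_real_, n = length(v), data = data, fit = NULL),
      class = "mm_fit"
    )
    return(out)
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  if (max(s) < est[["km"]]) {
    warn("no saturating substrate concentrations; kcat is poorly identified")
  }
  structure(
    list(
      kcat = unname(est[["kcat"]]), km = unname(est[["km"]]),
      kcat_se = unname(se[1]), km_se = unname(se[2]),
      efficiency = unname(est[["kcat"]] / (est[["km"]] / 1000)),
      converged = fit$convInfo$isConv %||% TRUE,
      residual_sd = stats::sigma(fit), n = length(v),
      data = data, fit = fit
    ),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<mm_fit> did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<mm_fit> kcat = %.3g +/- %.2g 1/s, KM = %.3g +/- %.2g mM, kcat/KM = %.3g 1/(M s)\n",
    x$kcat, x$kcat_se, x$km, x$km_se, x$efficiency
  ))
  invisible(x)
}

#' @rdname fit_mm
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("kcat", "km"),
    estimate = c(x$kcat, x$km),
    std.error = c(x$kcat_se, x$km_se),
    unit = c("1/s", "mM")
  )
}

#' @rdname fit_mm
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(
    kcat = x$kcat, km = x$km, efficiency = x$efficiency,
    residual_sd = x$residual_sd, n = x$n, converged = x$converged
  )
}

#' Catalytic efficiency kcat/KM
#'
#' Exact arithmetic: `kcat` in 1/s divided by `km` converted from mM to M.
#'
#' @param kcat Turnover number, 1/s.
#' @param km Michaelis constant, mM.
#' @return Efficiency in 1/(M s).
#' @export
efficiency <- function(kcat, km) {
  kcat / (km / 1000)
}

#' Report-style rounding of catalytic efficiency
#'
#' Values below 1000 are rounded to the nearest integer, larger values to
#' two significant figures, matching how efficiencies are reported in
#' enzyme-characterization tables.
#'
#' @param x Efficiency value(s), 1/(M s).
#' @return Rounded value(s).
#' @export
report_efficiency <- function(x) {
  ifelse(x < 1000, round(x), signif(x, 2))
}

#' Convert a dye-formation absorbance slope to per-enzyme turnover
#'
#' For the peroxidase-coupled assay: the absorbance slope (AU/min) is
#' converted with the dye extinction coefficient (default 26 1/(mM cm), the
#' 515 nm value for the AAP/DCHBS chromophore) and the enzyme concentration
#' into a turnover rate. One dye molecule per hydrogen peroxide (hence per
#' substrate turnover) is assumed.
#'
#' @param slope Absorbance slope, AU/min.
#' @param enzyme_conc Enzyme concentration, uM.
#' @param epsilon Dye extinction coefficient, 1/(mM cm).
#' @param path Optical path length, cm.
#' @return Turnover rate, 1/s.
#' @export
rate_from_absorbance <- function(slope, enzyme_conc, epsilon = 26, path = 1) {
  # AU/min -> mM dye/min -> uM/s -> per uM enzyme
  (slope / (epsilon * path)) * 1000 / 60 / enzyme_conc
}

#' Kinetic isotope effect from paired fits
#'
#' Ratio of the protiated and deuterated turnover numbers, with the standard
#' error propagated from the two fits. A ratio above one is annotated as
#' hydrogen transfer being partially rate limiting.
#'
#' @param fit_h,fit_d `mm_fit` objects for protiated / deuterated substrate.
#' @return A one-row tibble: `kie`, `kie_se`, `interpretation`.
#' @export
kie <- function(fit_h, fit_d) {
  ratio <- fit_h$kcat / fit_d$kcat
  se <- ratio * sqrt((fit_h$kcat_se / fit_h$kcat)^2 +
                       (fit_d$kcat_se / fit_d$kcat)^2)
  tibble(
    kie = ratio,
    kie_se = se,
    interpretation = ifelse(ratio > 1,
                            "H-transfer partially rate-limiting",
                            "no normal isotope effect")
  )
}

#' Melting temperature from a thermal-shift curve
#'
#' The melting temperature is the maximum of the smoothed first derivative
#' dF/dT (moving average, window of 3 points), the standard read-out of
#' flavin-fluorescence thermal shift assays. Curves without a transition
#' (monotone-flat derivative) are flagged.
#'
#' @param curve A tibble with ascending `temperature_c` and `fluorescence`.
#' @return A one-row tibble (`tm_result`): `tm` (degC, `NA` when no
#'   transition), `has_transition`, `max_slope`.
#' @export
tm_from_melt <- function(curve) {
  t <- curve$temperature_c
  f <- curve$fluorescence
  if (is.unsorted(t)) abort("temperature grid must be ascending")
  df <- diff(f) / diff(t)
  tm_grid <- (head(t, -1) + t[-1]) / 2
  if (length(df) >= 3) {
    sm <- stats::filter(df, rep(1 / 3, 3), sides = 2)
    keep <- !is.na(sm)
    df <- as.numeric(sm[keep])
    tm_grid <- tm_grid[keep]
  }
  i <- which.max(df)
  # a real unfolding transition concentrates slope near the midpoint; a flat
  # or monotone signal has a nearly uniform derivative
  has_transition <- max(df) > 4 * pmax(stats::median(abs(df)), 1e-12) &&
    max(df) > 1e-6
  tibble(
    tm = if (has_transition) tm_grid[i] else NA_real_,
    has_transition = has_transition,
    max_slope = max(df)
  )
}

#' Melting-temperature difference
#'
#' @param a,b `tm_result` rows (or anything with a `tm` column/value).
#' @return `a$tm - b$tm`, degC.
#' @export
delta_tm <- function(a, b) {
  ta <- if (is.data.frame(a)) a$tm else a
  tb <- if (is.data.frame(b)) b$tm else b
  ta - tb
}

#' Extinction coefficient of protein-bound flavin
#'
#' From the flavin absorbance of the native enzyme and of the same sample
#' after denaturation (which releases the flavin), referenced to free FAD:
#' `eps_bound = eps_free * A_native / A_denatured`.
#'
#' @param a_native_452,a_denatured_452 Absorbances at 452 nm before/after
#'   denaturation.
#' @param epsilon_free_fad Extinction coefficient of free FAD, 1/(mM cm)
#'   (default 11.3, the standard literature value at ~450 nm).
#' @return Bound-flavin extinction coefficient, 1/(mM cm).
#' @export
extinction_coefficient <- function(a_native_452, a_denatured_452,
                                   epsilon_free_fad = 11.3) {
  if (a_denatured_452 <= 0) abort("denatured absorbance must be > 0")
  epsilon_free_fad * a_native_452 / a_denatured_452
}

#' Normalized pH-activity profile
#'
#' Normalizes rates to the maximum (= 100%) and reports the optimum pH. With
#' an all-flat profile the lowest pH is reported with a note.
#'
#' @param activities Tibble with columns `buffer`, `ph`, `rate`.
#' @return A list with `profile` (tibble with `relative_activity`, percent)
#'   and `optimum_ph`.
#' @export
ph_profile <- function(activities) {
  if (nrow(activities) == 0) abort("empty activity table")
  vmax <- max(activities$rate)
  prof <- activities %>%
    mutate(relative_activity = 100 * .data$rate / vmax) %>%
    arrange(.data$ph)
  flat <- diff(range(activities$rate)) < 1e-12 && nrow(activities) > 1
  opt <- prof$ph[which.max(prof$relative_activity)]
  list(
    profile = prof,
    optimum_ph = opt,
    note = if (flat) "flat profile; optimum reported as the lowest pH" else NULL
  )
}
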