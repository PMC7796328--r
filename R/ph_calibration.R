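#' Henderson-Hasselbalch deprotonated-buffer fraction
#'
#' Fraction of a weak buffer present as its conjugate base at a given pH:
#' `f = 1 / (1 + 10^(pKa - pH))`. Strictly increasing in pH, 0.5 at
#' `pH = pKa`. Default pKa is 7.55, HEPES at 20 degC.
#'
#' @param pH pH value(s).
#' @param pKa buffer pKa.
#' @return Base fraction(s) in (0, 1).
#' @examples
#' hh_base_fraction(7.55)   # 0.5
#' hh_base_fraction(6.0)    # 0.0274
#' @export
hh_base_fraction <- function(pH, pKa = 7.55) {
  stopifnot(all(is.finite(pH)), is.finite(pKa))
  1 / (1 + 10^(pKa - pH))
}

#' Strong-base amount for one titration step
#'
#' Amount of KOH (umol) that moves a HEPES-buffered volume from `pH_from` to
#' `pH_to`: the base added deprotonates buffer, so
#' `amount = buffer_mM * volume_mL * (f(pH_to) - f(pH_from))` with `f` the
#' Henderson-Hasselbalch base fraction. When a stock concentration is given,
#' the corresponding stock volume is attached.
#'
#' @param buffer_mM buffer concentration (mM, > 0).
#' @param volume_mL buffered volume (mL).
#' @param pH_from,pH_to step endpoints; `pH_to >= pH_from`.
#' @param pKa buffer pKa (7.55 for HEPES at 20 degC).
#' @param stock_mM optional KOH stock concentration (mM) to also report the
#'   stock volume (uL) to pipette.
#' @return Amount of KOH in umol; attribute `stock_volume_uL` when
#'   `stock_mM` is given.
#' @examples
#' koh_addition_amount(25, 1, 6.00, 6.25)  # 0.508 umol
#' @export
koh_addition_amount <- function(buffer_mM, volume_mL, pH_from, pH_to,
                                pKa = 7.55, stock_mM = NULL) {
  stopifnot(buffer_mM > 0, volume_mL > 0)
  if (pH_to < pH_from) stop("pH_to must not be below pH_from")
  amount <- buffer_mM * volume_mL *
    (hh_base_fraction(pH_to, pKa) - hh_base_fraction(pH_from, pKa))
  if (!is.null(stock_mM))
    attr(amount, "stock_volume_uL") <- amount / stock_mM * 1000
  amount
}

#' KOH ladder for the in vivo pH calibration
#'
#' Per-step KOH amounts for the titration from `pH_start` to `pH_end` in
#' `step` increments (defaults: 6.0 to 8.0 in 0.25 steps, i.e. 8 additions
#' into H+Cal medium: 25 mM HEPES at pH 6.0). The per-step amounts telescope:
#' their sum equals the single-step amount for the full range.
#'
#' @inheritParams koh_addition_amount
#' @param pH_start,pH_end,step ladder definition.
#' @return Data frame with columns `pH_from`, `pH_to`, `koh_umol`.
#' @export
koh_schedule <- function(buffer_mM = 25, volume_mL = 1, pH_start = 6.0,
                         pH_end = 8.0, step = 0.25, pKa = 7.55) {
  stopifnot(pH_end > pH_start, step > 0)
  lo <- seq(pH_start, pH_end - step, by = step)
  hi <- lo + step
  data.frame(pH_from = lo, pH_to = hi,
             koh_umol = vapply(seq_along(lo), function(i)
               as.numeric(koh_addition_amount(buffer_mM, volume_mL,
                                              lo[i], hi[i], pKa)),
               numeric(1)))
}

#' Fit the BCECF fluorescence vs pH calibration line
#'
#' Least squares of `log10(median F)` against extracellular pH over the
#' nigericin titration points: `log10(F) = m pH + c`. The model is linear on
#' the log-fluorescence axis; either slope sign is accepted and reported.
#' Refused for fewer than four distinct pH points, any non-positive
#' fluorescence, or R^2 below `r2_min`.
#'
#' @param pHe titration pH values.
#' @param median_F plateau median fluorescence at each pH (a.u., > 0).
#' @param r2_min minimum acceptable R^2.
#' @return A `ph_calibration_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `points`.
#' @export
fit_ph_calibration <- function(pHe, median_F, r2_min = 0.9) {
  stopifnot(length(pHe) == length(median_F))
  if (length(unique(pHe)) < 4)
    stop("calibration needs at least 4 distinct pH values")
  if (any(median_F <= 0))
    stop("median fluorescence must be positive for the log-linear fit")
  logF <- log10(median_F)
  fit <- stats::lm(logF ~ pHe)
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (is.finite(r2) && r2 < r2_min)
    stop(sprintf("calibration fit rejected: R^2 = %.3f < %.2f; re-acquire",
                 r2, r2_min))
  structure(list(slope = unname(stats::coef(fit)["pHe"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = r2,
                 p_value = sm$coefficients["pHe", "Pr(>|t|)"],
                 points = data.frame(pHe = pHe, median_F = median_F)),
            class = "ph_calibration_fit")
}

#' @export
print.ph_calibration_fit <- function(x, ...) {
  cat(sprintf("<ph_calibration_fit> log10(F) = %.3f * pH + %.3f  (R^2 = %.3f, p = %.2g, %d points)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, nrow(x$points)))
  invisible(x)
}

#' Interpolate intracellular pH from fluorescence
#'
#' Inverts the calibration line: `pHi = (log10(F) - c) / m`. Values outside
#' the titration range (6.0-8.0 by default) warn but are returned.
#'
#' @param fit a `ph_calibration_fit`.
#' @param median_F fluorescence value(s) (a.u., > 0).
#' @return Intracellular pH value(s).
#' @export
interpolate_ph <- function(fit, median_F) {
  stopifnot(inherits(fit, "ph_calibration_fit"))
  if (fit$slope == 0) stop("zero calibration slope; cannot interpolate")
  if (any(median_F <= 0)) stop("fluorescence must be positive")
  ph <- (log10(median_F) - fit$intercept) / fit$slope
  rng <- range(fit$points$pHe)
  if (any(ph < rng[1] | ph > rng[2]))
    warning("pH outside the calibration range [", rng[1], ", ", rng[2],
            "]; extrapolating")
  ph
}

#' Classify the capacitation-induced pH change
#'
#' `dpHi = pHi_CAP - pHi_NC`; beyond +threshold alkalinized, beyond
#' -threshold acidified, within the band (boundary inclusive) unchanged.
#'
#' @param ph_nc,ph_cap intracellular pH under the two conditions.
#' @param threshold classification threshold in pH units; default 0.1.
#' @return `"alkalinized"`, `"unchanged"` or `"acidified"`, with attribute
#'   `delta`.
#' @export
classify_delta_ph <- function(ph_nc, ph_cap, threshold = 0.1) {
  stopifnot(is.finite(ph_nc), is.finite(ph_cap))
  delta <- ph_cap - ph_nc
  cat_ <- if (delta < -threshold) "acidified"
          else if (delta > threshold) "alkalinized"
          else "unchanged"
  structure(cat_, delta = delta)
}

#' NH4Cl responsiveness control
#'
#' Every pH determination carries an NH4Cl pulse as a positive control:
#' ammonium enters as NH3 and alkalinizes responsive cells. The control
#' passes when the calibrated post-addition plateau exceeds the baseline by
#' strictly more than `min_rise` pH units.
#'
#' @param trace [bin_median_trace()] of the fl1 channel from the HTF aliquot.
#' @param schedule the aliquot's [stimulus_schedule()]; must contain an
#'   NH4Cl addition.
#' @param fit the sample's `ph_calibration_fit`, used to express both levels
#'   in pH units.
#' @param settle_s,width_s plateau placement after the addition.
#' @param min_rise minimum pH increase to pass (strict inequality).
#' @return List with `pass`, `magnitude` (pH units), `baseline_ph`,
#'   `response_ph`.
#' @export
nh4cl_responsiveness <- function(trace, schedule, fit,
                                 settle_s = 90, width_s = 30,
                                 min_rise = 0.1) {
  stopifnot(inherits(trace, "kinetic_trace"),
            inherits(schedule, "stimulus_schedule"),
            inherits(fit, "ph_calibration_fit"))
  i <- which(schedule$compound == "NH4Cl")
  if (!length(i)) stop("schedule lacks an NH4Cl addition")
  t_add <- schedule$time_s[i[1]]
  base_s <- attr(schedule, "baseline_s")
  win_median <- function(lo, hi) {
    sel <- trace$valid & trace$time_s >= lo & trace$time_s < hi
    if (!any(sel)) stop("no valid bins in window [", lo, ", ", hi, ")")
    mean(trace$median[sel])
  }
  f_base <- win_median(0, base_s)
  f_resp <- win_median(t_add + settle_s, t_add + settle_s + width_s)
  ph_base <- suppressWarnings(interpolate_ph(fit, f_base))
  ph_resp <- suppressWarnings(interpolate_ph(fit, f_resp))
  mag <- ph_resp - ph_base
  list(pass = mag > min_rise, magnitude = mag,
       baseline_ph = ph_base, response_ph = ph_resp)
}
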