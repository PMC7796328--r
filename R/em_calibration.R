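#' Nernst potential of a monovalent cation
#'
#' Equilibrium membrane potential for K+ given extracellular and
#' intracellular concentrations: `Em = (R T / F) ln([K]out / [K]in)`, in mV.
#' With valinomycin the sperm membrane behaves as a K+ electrode and rests at
#' this potential. Defaults: 120 mM intracellular K+ and 293.15 K (20 degC
#' room-temperature acquisition), which reproduce the calibration targets
#' -80, -63, -52, -40 and -28 mV for 5, 10, 15, 25 and 40 mM external K+.
#'
#' @param K_out_mM extracellular K+ concentration (mM, > 0); vectorized.
#' @param K_in_mM intracellular K+ concentration (mM, > 0).
#' @param temperature_K absolute temperature (K, > 0).
#' @return Membrane potential(s) in mV.
#' @examples
#' nernst_em(c(5, 10, 15, 25, 40))
#' @export
nernst_em <- function(K_out_mM, K_in_mM = 120, temperature_K = 293.15) {
  if (any(K_out_mM <= 0) || any(K_in_mM <= 0))
    stop("concentrations must be positive")
  if (temperature_K <= 0) stop("temperature must be positive")
  R_gas <- 8.314462618   # J / (mol K)
  faraday <- 96485.33212 # C / mol
  1000 * R_gas * temperature_K / faraday * log(K_out_mM / K_in_mM)
}

#' KCl volume for one calibration step
#'
#' Volume of KCl stock needed to raise the tube's K+ concentration from
#' `current_K_mM` to `target_K_mM`, solving the mass balance
#' `(C0 V + Cs x) / (V + x) = Ct` for `x`. Sequential steps must account for
#' the dilution of earlier additions; [kcl_schedule_volumes()] composes this
#' over a whole ladder.
#'
#' @param current_volume current tube volume (any volume unit; result is in
#'   the same unit).
#' @param current_K_mM current K+ concentration (mM, >= 0).
#' @param stock_K_mM KCl stock concentration (mM).
#' @param target_K_mM desired final concentration (mM); must satisfy
#'   `stock > target > current`.
#' @return Volume of stock to add (same unit as `current_volume`).
#' @examples
#' kcl_addition_volume(1000, 5, 1000, 10)  # 5.05 uL into 1 mL
#' @export
kcl_addition_volume <- function(current_volume, current_K_mM, stock_K_mM,
                                target_K_mM) {
  stopifnot(current_volume > 0, current_K_mM >= 0)
  if (target_K_mM < current_K_mM) stop("target below current concentration")
  if (target_K_mM >= stock_K_mM)
    stop("target concentration must lie below the stock concentration")
  current_volume * (target_K_mM - current_K_mM) / (stock_K_mM - target_K_mM)
}

#' Sequential KCl addition ladder
#'
#' Composes [kcl_addition_volume()] over an increasing target ladder,
#' tracking the growing tube volume so that each post-addition concentration
#' hits its target exactly despite cumulative dilution.
#'
#' @param initial_volume starting tube volume.
#' @param initial_K_mM starting K+ concentration (for HTF medium about 5 mM:
#'   4.68 mM KCl + 0.37 mM KH2PO4).
#' @param stock_K_mM KCl stock concentration (mM).
#' @param targets_mM increasing vector of target concentrations; targets at
#'   or below the running concentration get zero volume (the 5 mM point is
#'   the unamended baseline).
#' @return Data frame with columns `target_mM`, `volume_added`,
#'   `volume_total`, `K_mM` (achieved concentration).
#' @export
kcl_schedule_volumes <- function(initial_volume, initial_K_mM = 5.05,
                                 stock_K_mM = 1000,
                                 targets_mM = c(5, 10, 15, 25, 40)) {
  vol <- initial_volume; conc <- initial_K_mM
  out <- data.frame(target_mM = targets_mM, volume_added = 0,
                    volume_total = 0, K_mM = 0)
  for (i in seq_along(targets_mM)) {
    tg <- targets_mM[i]
    x <- if (tg > conc) kcl_addition_volume(vol, conc, stock_K_mM, tg) else 0
    conc <- (conc * vol + stock_K_mM * x) / (vol + x)
    vol <- vol + x
    out$volume_added[i] <- x
    out$volume_total[i] <- vol
    out$K_mM[i] <- conc
  }
  out
}

#' Fit the Disc fluorescence vs membrane potential calibration line
#'
#' Ordinary least squares of plateau median fluorescence against the Nernst
#' target potentials, `F = a Em + b`. The fit is refused when fewer than
#' three distinct potentials are supplied or when R^2 falls below `r2_min`
#' (re-acquire the calibration rather than interpolate from a bad line).
#'
#' @param em_mV calibration potentials (mV).
#' @param median_F plateau median fluorescence at each potential (a.u.).
#' @param r2_min minimum acceptable R^2.
#' @return An `em_calibration_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value` and the calibration `points`.
#' @export
fit_em_calibration <- function(em_mV, median_F, r2_min = 0.9) {
  stopifnot(length(em_mV) == length(median_F))
  if (length(unique(em_mV)) < 3)
    stop("calibration needs at least 3 distinct Em values")
  fit <- stats::lm(median_F ~ em_mV)
  sm <- summary(fit)
  r2 <- sm$r.squared
  pv <- sm$coefficients["em_mV", "Pr(>|t|)"]
  if (is.finite(r2) && r2 < r2_min)
    stop(sprintf("calibration fit rejected: R^2 = %.3f < %.2f; re-acquire",
                 r2, r2_min))
  structure(list(slope = unname(stats::coef(fit)["em_mV"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = r2, p_value = pv,
                 points = data.frame(em_mV = em_mV, median_F = median_F)),
            class = "em_calibration_fit")
}

#' @export
print.em_calibration_fit <- function(x, ...) {
  cat(sprintf("<em_calibration_fit> F = %.1f * Em + %.1f  (R^2 = %.3f, p = %.2g, %d points)\n",
              x$slope, x$intercept, x$r_squared, x$p_value,
              nrow(x$points)))
  invisible(x)
}

#' Interpolate membrane potential from fluorescence
#'
#' Inverts the calibration line: `Em = (F - b) / a`. Fluorescence outside the
#' range spanned by the calibration points triggers an extrapolation warning
#' but still returns a value.
#'
#' @param fit an `em_calibration_fit`.
#' @param median_F fluorescence value(s) to convert (a.u.).
#' @return Membrane potential(s) in mV.
#' @export
interpolate_em <- function(fit, median_F) {
  stopifnot(inherits(fit, "em_calibration_fit"))
  if (fit$slope == 0) stop("zero calibration slope; cannot interpolate")
  rng <- range(fit$points$median_F)
  if (any(median_F < rng[1] | median_F > rng[2]))
    warning("fluorescence outside the calibration range; extrapolating")
  (median_F - fit$intercept) / fit$slope
}

#' Classify the capacitation-induced membrane-potential change
#'
#' `dEm = Em_CAP - Em_NC`; a change beyond -threshold is hyperpolarized,
#' beyond +threshold depolarized, and anything within the band (boundary
#' inclusive) unchanged.
#'
#' @param em_nc,em_cap resting potentials (mV) under non-capacitating and
#'   capacitating conditions.
#' @param threshold_mV classification threshold (mV); default 5.
#' @return Character scalar: `"hyperpolarized"`, `"unchanged"` or
#'   `"depolarized"`, with attribute `delta`.
#' @export
classify_delta_em <- function(em_nc, em_cap, threshold_mV = 5) {
  stopifnot(is.finite(em_nc), is.finite(em_cap))
  delta <- em_cap - em_nc
  cat_ <- if (delta < -threshold_mV) "hyperpolarized"
          else if (delta > threshold_mV) "depolarized"
          else "unchanged"
  structure(cat_, delta = delta)
}
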