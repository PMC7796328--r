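#' Normalized progesterone peak (F_Peak)
#'
#' Maximum of the baseline-normalized bin medians within the progesterone
#' window — the peak fractional Fluo3 rise after the stimulus. The trace must
#' come from [normalize_trace()], so the basal level sits at zero.
#'
#' @param trace a normalized [bin_median_trace()] result.
#' @param window numeric `c(start_s, end_s)`; defaults to \[120, 300) s
#'   (progesterone at 120 s, ionomycin at 300 s).
#' @return F_Peak (dimensionless), with attribute `peak_time_s`.
#' @export
extract_fpeak <- function(trace, window = c(120, 300)) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (is.null(attr(trace, "normalized")))
    stop("extract_fpeak expects a baseline-normalized trace")
  sel <- trace$valid & trace$time_s >= window[1] & trace$time_s < window[2]
  if (!any(sel))
    stop("no valid bins in the stimulus window [", window[1], ", ",
         window[2], ")")
  i <- which(sel)[which.max(trace$median[sel])]
  structure(trace$median[i], peak_time_s = trace$time_s[i])
}

#' Dynamic-range quality control for a calcium recording
#'
#' Ionomycin saturates the indicator (maximum signal) and Mn2+ quenches it
#' (minimum signal); on the normalized scale those extremes must bracket the
#' baseline, `min < 0 < max`, and the progesterone peak cannot exceed the
#' ionomycin maximum. Violations are flags in the returned record, not
#' errors — the trace is still reported, just marked unreliable.
#'
#' @param trace a normalized [bin_median_trace()] result.
#' @param f_peak the extracted F_Peak (optional; saturation check skipped if
#'   `NULL`).
#' @param iono_window,mn_window windows for the extremes; defaults
#'   \[300, 540) and \[540, 600) s.
#' @return List with `iono_max`, `mn_min`, `ordering_ok`, `saturation_ok`,
#'   `pass`.
#' @export
dynamic_range_qc <- function(trace, f_peak = NULL,
                             iono_window = c(300, 540),
                             mn_window = c(540, 600)) {
  stopifnot(inherits(trace, "kinetic_trace"))
  win_vals <- function(w) {
    sel <- trace$valid & trace$time_s >= w[1] & trace$time_s < w[2]
    trace$median[sel]
  }
  iono <- win_vals(iono_window); mn <- win_vals(mn_window)
  iono_max <- if (length(iono)) max(iono) else NA_real_
  mn_min <- if (length(mn)) min(mn) else NA_real_
  ordering_ok <- isTRUE(mn_min < 0 && iono_max > 0)
  saturation_ok <- is.null(f_peak) || isTRUE(f_peak <= iono_max)
  list(iono_max = iono_max, mn_min = mn_min,
       ordering_ok = ordering_ok, saturation_ok = saturation_ok,
       pass = ordering_ok && saturation_ok)
}

#' Classify the capacitation-induced progesterone response change
#'
#' `dF_Peak = F_Peak_CAP - F_Peak_NC`; beyond +threshold increased, beyond
#' -threshold decreased, within the band (boundary inclusive) unchanged.
#'
#' @param fpeak_nc,fpeak_cap normalized peaks under the two conditions.
#' @param threshold classification threshold; default 0.25.
#' @return `"increased"`, `"unchanged"` or `"decreased"`, with attribute
#'   `delta`.
#' @export
classify_delta_fpeak <- function(fpeak_nc, fpeak_cap, threshold = 0.25) {
  stopifnot(is.finite(fpeak_nc), is.finite(fpeak_cap))
  delta <- fpeak_cap - fpeak_nc
  cat_ <- if (delta > threshold) "increased"
          else if (delta < -threshold) "decreased"
          else "unchanged"
  structure(cat_, delta = delta)
}
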