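#' Stimulus schedule
#'
#' Ordered reagent additions of a TLFC recording: time of addition, compound
#' and target amount (final concentration in the tube). The first addition
#' must come after the baseline window so every protocol has a clean basal
#' segment.
#'
#' @param time_s addition times in seconds, strictly increasing.
#' @param compound character vector of compound names.
#' @param amount numeric target amounts (final concentrations).
#' @param unit character vector of units for `amount`.
#' @param duration_s total recording duration (s).
#' @param baseline_s length of the pre-stimulus baseline window (s).
#' @return A data frame of class `stimulus_schedule` with attributes
#'   `duration_s` and `baseline_s`.
#' @export
stimulus_schedule <- function(time_s, compound, amount, unit,
                              duration_s, baseline_s = 120) {
  stopifnot(length(time_s) == length(compound),
            length(amount) == length(compound),
            length(unit) == length(compound))
  if (any(diff(time_s) <= 0)) stop("addition times must be strictly increasing")
  if (any(time_s >= duration_s)) stop("additions must fall within the recording")
  if (length(time_s) && time_s[1] < baseline_s)
    stop("first addition must not precede the baseline window (",
         baseline_s, " s)")
  structure(data.frame(time_s = time_s, compound = compound,
                       amount = amount, unit = unit,
                       stringsAsFactors = FALSE),
            duration_s = duration_s, baseline_s = baseline_s,
            class = c("stimulus_schedule", "data.frame"))
}

#' Default protocol schedules
#'
#' Shipped stimulus schedules for the three TLFC protocols:
#' * `em_schedule()` — membrane-potential calibration: valinomycin 1 uM at
#'   120 s (clamping Em to the Nernst potential of the ~5 mM K+ already in
#'   HTF), then KCl raising extracellular K+ to 10, 15, 25 and 40 mM every
#'   120 s; 720 s total.
#' * `ca_schedule()` — calcium protocol: progesterone 4 uM at 120 s,
#'   ionomycin 10 uM at 300 s, MnCl2 5 mM at 540 s; 600 s total.
#' * `ph_htf_schedule()` — pH measurement aliquot: NH4Cl 20 mM at 120 s;
#'   300 s total.
#' * `ph_cal_schedule()` — nigericin/H+Cal titration: KOH steps of 0.25 pH
#'   units every 120 s from pHe 6.0 up to 8.0 (8 additions); 1080 s total.
#' @return A [stimulus_schedule()].
#' @export
em_schedule <- function() {
  stimulus_schedule(
    time_s = c(120, 240, 360, 480, 600),
    compound = c("valinomycin", "KCl", "KCl", "KCl", "KCl"),
    amount = c(1, 10, 15, 25, 40),
    unit = c("uM", "mM", "mM", "mM", "mM"),
    duration_s = 720)
}

#' @rdname em_schedule
#' @export
ca_schedule <- function() {
  stimulus_schedule(
    time_s = c(120, 300, 540),
    compound = c("progesterone", "ionomycin", "MnCl2"),
    amount = c(4, 10, 5),
    unit = c("uM", "uM", "mM"),
    duration_s = 600)
}

#' @rdname em_schedule
#' @export
ph_htf_schedule <- function() {
  stimulus_schedule(time_s = 120, compound = "NH4Cl", amount = 20,
                    unit = "mM", duration_s = 300)
}

#' @rdname em_schedule
#' @export
ph_cal_schedule <- function() {
  ph_steps <- seq(6.25, 8.0, by = 0.25)
  stimulus_schedule(
    time_s = 120 * seq_along(ph_steps),
    compound = rep("KOH", length(ph_steps)),
    amount = ph_steps,
    unit = rep("pH", length(ph_steps)),
    duration_s = 120 * (length(ph_steps) + 1))
}

#' Time-binned median kinetic trace
#'
#' The population "smoothed trace" of a recording: uniform time bins, and per
#' bin the median intensity of the chosen channel plus the event count. Bins
#' holding fewer than `min_events` events are flagged invalid and excluded
#' from downstream fits.
#'
#' @param events gated [event_table()].
#' @param channel channel column name (`"fl1_a"`, `"fl4_a"`, ...).
#' @param bin_width_s bin width in seconds (> 0).
#' @param duration_s recording duration; defaults to the last event time.
#' @param min_events minimum events for a bin median to be considered valid.
#' @return A data frame of class `kinetic_trace` with columns `time_s` (bin
#'   centre), `median`, `n`, `valid`.
#' @export
bin_median_trace <- function(events, channel, bin_width_s = 2,
                             duration_s = NULL, min_events = 10) {
  events <- as_event_table(events)
  if (!channel %in% names(events)) stop("channel not present: ", channel)
  stopifnot(bin_width_s > 0)
  if (is.null(duration_s))
    duration_s <- if (nrow(events)) max(events$time_s) else bin_width_s
  n_bins <- max(1L, ceiling(duration_s / bin_width_s))
  bin <- pmin(n_bins, floor(events$time_s / bin_width_s) + 1L)
  med <- rep(NA_real_, n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  grp <- split(events[[channel]], bin)
  med[as.integer(names(grp))] <- vapply(grp, stats::median, numeric(1))
  structure(data.frame(time_s = (seq_len(n_bins) - 0.5) * bin_width_s,
                       median = med, n = cnt,
                       valid = cnt >= min_events & !is.na(med)),
            bin_width_s = bin_width_s, channel = channel,
            class = c("kinetic_trace", "data.frame"))
}

#' Plateau windows after each addition
#'
#' For each addition at `t`, the half-open window
#' `[t + settle_s, t + settle_s + width_s)` in which the response is read
#' after it has plateaued. With the defaults (90 s settle, 30 s width) on
#' 120-s spaced additions each window is the last 30 s before the next
#' addition.
#'
#' @param schedule a [stimulus_schedule()].
#' @param settle_s time allowed for the response to plateau after an addition.
#' @param width_s window width.
#' @return A data frame of class `plateau_windows` with columns `start_s`,
#'   `end_s`, `label`.
#' @export
plateau_windows <- function(schedule, settle_s = 90, width_s = 30) {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            settle_s >= 0, width_s > 0)
  t_add <- schedule$time_s
  t_next <- c(t_add[-1], attr(schedule, "duration_s"))
  end <- t_add + settle_s + width_s
  if (any(end > t_next + 1e-9))
    stop("plateau windows (settle ", settle_s, " s + width ", width_s,
         " s) overlap the next addition")
  structure(data.frame(start_s = t_add + settle_s, end_s = end,
                       label = paste0(schedule$compound, "_",
                                      schedule$amount, schedule$unit),
                       stringsAsFactors = FALSE),
            class = c("plateau_windows", "data.frame"))
}

#' Plateau median of a stimulus window
#'
#' Median intensity of the chosen channel over a plateau window. With
#' `subpop = "responding"` and a bimodal window (valley detection as in the
#' gating module), only the component on the expected side of the valley is
#' used — the algorithmic replacement for the manually drawn responding-
#' subpopulation boxes; a unimodal window falls back to the plain median.
#'
#' @param events gated [event_table()].
#' @param channel channel column name.
#' @param window either a single row of [plateau_windows()] output or a
#'   numeric `c(start_s, end_s)`.
#' @param subpop `"all"` or `"responding"`.
#' @param direction expected response direction: `"high"` keeps the upper
#'   component (e.g. Disc after valinomycin, BCECF after KOH), `"low"` the
#'   lower one.
#' @param min_events minimum events required in the window.
#' @return Median intensity (a.u.), with attribute `n_events`.
#' @export
plateau_median <- function(events, channel, window,
                           subpop = c("all", "responding"),
                           direction = c("high", "low"),
                           min_events = 200) {
  subpop <- match.arg(subpop); direction <- match.arg(direction)
  events <- as_event_table(events)
  if (!channel %in% names(events)) stop("channel not present: ", channel)
  if (is.data.frame(window)) window <- c(window$start_s[1], window$end_s[1])
  x <- events[[channel]][events$time_s >= window[1] & events$time_s < window[2]]
  if (length(x) < min_events)
    stop("plateau window [", window[1], ", ", window[2], ") holds only ",
         length(x), " events (minimum ", min_events, ")")
  if (subpop == "responding") {
    v <- histogram_valley(log10(x + 1))
    if (!is.null(v)) {
      keep <- if (direction == "high") log10(x + 1) > v$valley
              else log10(x + 1) <= v$valley
      if (sum(keep) >= min_events / 4) x <- x[keep]
    }
  }
  structure(stats::median(x), n_events = length(x))
}

#' Baseline-normalize a kinetic trace
#'
#' Maps every bin median F to `(F - F0) / F0` where `F0` is the mean of the
#' valid bin medians over the baseline window, so the basal level sits at
#' zero and responses are expressed as fractional changes.
#'
#' @param trace a [bin_median_trace()] result.
#' @param baseline numeric `c(start_s, end_s)` baseline window; default the
#'   first 120 s.
#' @return A `kinetic_trace` on the dimensionless normalized scale, with
#'   attribute `F0`.
#' @export
normalize_trace <- function(trace, baseline = c(0, 120)) {
  stopifnot(inherits(trace, "kinetic_trace"))
  base <- trace$valid & trace$time_s >= baseline[1] & trace$time_s < baseline[2]
  if (!any(base)) stop("no valid bins in the baseline window")
  f0 <- mean(trace$median[base])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline mean F0 must be positive (got ", format(f0), ")")
  out <- trace
  out$median <- (trace$median - f0) / f0
  attr(out, "F0") <- f0
  attr(out, "normalized") <- TRUE
  out
}
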