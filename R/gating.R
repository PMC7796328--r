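#' Gate configuration
#'
#' Numeric gate parameters for the fixed debris -> singlet -> viability gate
#' order. Such gates are traditionally drawn by hand on density plots; here
#' they are explicit numbers so a run is reproducible. `viability = "auto"` locates
#' the valley between the dead-cell and viable-cell fluorescence modes of the
#' sample itself (see [auto_viability_threshold()] for the two-tube,
#' heat-killed-control variant).
#'
#' @param fsc_min,ssc_min debris thresholds (intensity a.u., `>= 0`); events
#'   below either are discarded.
#' @param singlet_band length-2 numeric, allowed interval for the
#'   `fsc_h / fsc_a` pulse-geometry ratio.
#' @param viability minimum fl1 intensity for viable cells, or `"auto"`.
#' @param viability_window time window (s) whose events define the automatic
#'   threshold. Stimuli move the viable fl1 mode during the recording, so the
#'   valley is located on the resting (baseline) segment and then applied to
#'   every event.
#' @return A list of class `gate_config`.
#' @export
gate_config <- function(fsc_min = 5e4, ssc_min = 2e4,
                        singlet_band = c(0.75, 1.05),
                        viability = "auto",
                        viability_window = c(0, 120)) {
  stopifnot(fsc_min >= 0, ssc_min >= 0, length(singlet_band) == 2,
            singlet_band[1] < singlet_band[2],
            length(viability_window) == 2,
            viability_window[1] < viability_window[2])
  if (!identical(viability, "auto"))
    stopifnot(is.numeric(viability), viability >= 0)
  structure(list(fsc_min = fsc_min, ssc_min = ssc_min,
                 singlet_band = as.numeric(singlet_band),
                 viability = viability,
                 viability_window = as.numeric(viability_window)),
            class = "gate_config")
}

# column-wise row subset avoiding data.frame row-name bookkeeping
subset_events <- function(events, keep) {
  cols <- lapply(unclass(events), function(col) col[keep])
  structure(cols, row.names = c(NA_integer_, -length(cols[[1]])),
            class = c("event_table", "data.frame"))
}

empty_gated <- function(events, gate) {
  warning("gate '", gate, "' removed every event; downstream stages must ",
          "refuse this recording")
  out <- events[0, , drop = FALSE]
  attr(out, "empty_gate") <- gate
  out
}

#' Debris exclusion gate
#'
#' Keeps events with `fsc_a >= fsc_min` and `ssc_a >= ssc_min`; small-scatter
#' events are cellular debris.
#'
#' @param events an [event_table()]; must be non-empty.
#' @param cfg a [gate_config()].
#' @return The retained subset, with attribute `retained_fraction`.
#' @export
apply_debris_gate <- function(events, cfg = gate_config()) {
  events <- as_event_table(events)
  if (nrow(events) == 0) stop("debris gate refused: empty input")
  keep <- events$fsc_a >= cfg$fsc_min & events$ssc_a >= cfg$ssc_min
  if (!any(keep)) return(empty_gated(events, "debris"))
  out <- subset_events(events, keep)
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Singlet (aggregate-exclusion) gate
#'
#' Pulse-geometry gate on the `fsc_h / fsc_a` ratio: doublets and larger
#' aggregates have roughly additive area but sub-additive height, pushing the
#' ratio below the singlet band.
#'
#' @inheritParams apply_debris_gate
#' @return The retained subset, with attribute `retained_fraction`.
#' @export
apply_singlet_gate <- function(events, cfg = gate_config()) {
  events <- as_event_table(events)
  if (nrow(events) == 0) stop("singlet gate refused: empty input")
  if (any(events$fsc_a <= 0))
    stop("singlet gate requires fsc_a > 0 (apply the debris gate first)")
  ratio <- events$fsc_h / events$fsc_a
  keep <- ratio >= cfg$singlet_band[1] & ratio <= cfg$singlet_band[2]
  if (!any(keep)) return(empty_gated(events, "singlet"))
  out <- subset_events(events, keep)
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Viability gate
#'
#' Keeps events whose fl1 intensity (Fluo3 or BCECF, retained only by intact
#' cells) exceeds the viability threshold. With `viability = "auto"` the
#' threshold is the valley between the two dominant modes of the sample's own
#' log10 fl1 histogram (dead cells form the lower mode).
#'
#' @inheritParams apply_debris_gate
#' @return The retained subset, with attributes `retained_fraction` and
#'   `viability_threshold`.
#' @export
apply_viability_gate <- function(events, cfg = gate_config()) {
  events <- as_event_table(events)
  if (nrow(events) == 0) stop("viability gate refused: empty input")
  thr <- cfg$viability
  if (identical(thr, "auto")) {
    w <- cfg$viability_window %||% c(0, 120)
    ref <- events$fl1_a[events$time_s >= w[1] & events$time_s < w[2]]
    if (length(ref) < 200) ref <- events$fl1_a
    v <- histogram_valley(log10(ref + 1))
    if (is.null(v))
      stop("fl1 distribution is unimodal; cannot place an automatic ",
           "viability threshold - supply a manual value in gate_config()")
    thr <- 10^v$valley - 1
  }
  keep <- events$fl1_a >= thr
  if (!any(keep)) return(empty_gated(events, "viability"))
  out <- subset_events(events, keep)
  attr(out, "retained_fraction") <- mean(keep)
  attr(out, "viability_threshold") <- thr
  out
}

#' Apply the full gate chain
#'
#' Debris, singlet and viability gates in the fixed order. Gates are filters,
#' so the chain is idempotent.
#'
#' @inheritParams apply_debris_gate
#' @return Gated [event_table()] with attribute `retention` (named fractions
#'   per gate) and `viability_threshold`.
#' @export
gate_events <- function(events, cfg = gate_config()) {
  g1 <- apply_debris_gate(events, cfg)
  if (nrow(g1) == 0) return(g1)
  g2 <- apply_singlet_gate(g1, cfg)
  if (nrow(g2) == 0) return(g2)
  g3 <- apply_viability_gate(g2, cfg)
  attr(g3, "retention") <- c(debris = attr(g1, "retained_fraction"),
                             singlet = attr(g2, "retained_fraction"),
                             viability = attr(g3, "retained_fraction"))
  g3
}

#' Automatic viability threshold from a heat-killed control
#'
#' Places the viability threshold at the minimum of the smoothed log-intensity
#' histogram between the killed-cell fl1 mode and the viable-cell mode.
#' Heat-killed cells fluoresce above unstained background but below viable
#' cells, so the two modes bracket a valley; the threshold is strictly between
#' them. When the two distributions do not separate, an error instructs the
#' user to set a manual threshold.
#'
#' @param stained an [event_table()] of the stained (mostly viable) sample.
#' @param killed an [event_table()] of the heat-killed control.
#' @param min_separation minimum distance between the two modes, in decades,
#'   below which they are declared inseparable.
#' @return Threshold fl1 intensity (a.u.).
#' @export
auto_viability_threshold <- function(stained, killed, min_separation = 0.3) {
  stained <- as_event_table(stained); killed <- as_event_table(killed)
  if (nrow(stained) == 0 || nrow(killed) == 0)
    stop("both stained and killed tables must be non-empty")
  lk <- log10(killed$fl1_a + 1)
  ls <- log10(stained$fl1_a + 1)
  killed_mode <- histogram_mode(lk)
  # viable mode: dominant stained mode above the killed mode
  viable_mode <- histogram_mode(ls[ls > killed_mode + min_separation / 2])
  if (!is.finite(viable_mode) || viable_mode - killed_mode < min_separation)
    stop("killed and viable fl1 modes are not separable; ",
         "set the viability threshold manually")
  combined <- c(lk, ls)
  h <- smoothed_log_hist(combined)
  inside <- which(h$mids > killed_mode & h$mids < viable_mode)
  if (!length(inside))
    stop("no histogram bins between the killed and viable modes; ",
         "set the viability threshold manually")
  lo <- inside[valley_index(h$counts[inside])]
  10^h$mids[lo] - 1
}

# --- shared valley-finding machinery ------------------------------------

# 256-bin histogram of a log10 intensity vector, 5-bin moving average
smoothed_log_hist <- function(x, bins = 256L, smooth = 5L) {
  rng <- range(x)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(x, brk, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  sm <- stats::filter(counts, rep(1 / smooth, smooth), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  list(mids = (brk[-1] + brk[-length(brk)]) / 2, counts = as.numeric(sm))
}

histogram_mode <- function(x) {
  if (!length(x)) return(NA_real_)
  h <- smoothed_log_hist(x)
  h$mids[which.max(h$counts)]
}

# centre of the minimal run within a count vector (ties -> middle of the run)
valley_index <- function(counts) {
  lo <- which(counts == min(counts))
  lo[ceiling(length(lo) / 2)]
}

# Valley between the two highest well-separated local maxima of the smoothed
# log10 histogram. A candidate pair is accepted only when the valley between
# the peaks dips below `depth` times the lower peak; shallow wiggles on a
# single mode are thereby ignored. Returns NULL when effectively unimodal.
histogram_valley <- function(x, depth = 0.6, min_gap_bins = 8L) {
  if (length(x) < 20) return(NULL)
  h <- smoothed_log_hist(x)
  n <- length(h$counts)
  cnt <- h$counts
  is_max <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) cnt[i - 1] else -Inf
    r <- if (i < n) cnt[i + 1] else -Inf
    cnt[i] > l && cnt[i] >= r
  }, logical(1))
  peaks <- which(is_max)
  # a genuine second mode carries real mass; ignore sparse tail bumps
  peaks <- peaks[cnt[peaks] >= 0.05 * max(cnt)]
  if (length(peaks) < 2) return(NULL)
  peaks <- peaks[order(cnt[peaks], decreasing = TRUE)]
  # merge: scan peak pairs from the strongest down, accept the first pair
  # whose inter-peak valley is deep enough
  top <- peaks[1]
  for (p in peaks[-1]) {
    i1 <- min(top, p); i2 <- max(top, p)
    if (i2 - i1 < min_gap_bins) next
    seg <- cnt[i1:i2]
    vi <- valley_index(seg)
    if (seg[vi] <= depth * min(cnt[i1], cnt[i2])) {
      return(list(valley = h$mids[i1 + vi - 1L],
                  modes = sort(c(h$mids[i1], h$mids[i2]))))
    }
  }
  NULL
}
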