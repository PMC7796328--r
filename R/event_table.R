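#' Per-event acquisition table
#'
#' An `event_table` is the universal carrier between pipeline stages: one row
#' per recorded cellular event, holding the acquisition time and the five
#' intensity channels of a BD Accuri-like instrument. Optional `label` column
#' carries ground-truth class labels when the table comes from the simulator.
#'
#' @param time_s numeric, seconds since acquisition start; must be
#'   non-decreasing and non-negative.
#' @param fsc_a,fsc_h,ssc_a forward-scatter area/height and side-scatter area
#'   (arbitrary units, non-negative).
#' @param fl1_a green fluorescence (Fluo3 or BCECF, a.u., non-negative).
#' @param fl4_a far-red fluorescence (DiSC3(5), a.u., non-negative).
#' @param label optional character vector of per-event class labels
#'   (simulator ground truth).
#' @return A data frame of class `c("event_table", "data.frame")`.
#' @examples
#' ev <- event_table(time_s = c(0, 0.1), fsc_a = c(1e5, 2e5),
#'                   fsc_h = c(9e4, 1.8e5), ssc_a = c(5e4, 6e4),
#'                   fl1_a = c(1e4, 2e4), fl4_a = c(3e5, 4e5))
#' nrow(ev)
#' @export
event_table <- function(time_s, fsc_a, fsc_h, ssc_a, fl1_a, fl4_a,
                        label = NULL) {
  df <- data.frame(time_s = as.numeric(time_s),
                   fsc_a = as.numeric(fsc_a),
                   fsc_h = as.numeric(fsc_h),
                   ssc_a = as.numeric(ssc_a),
                   fl1_a = as.numeric(fl1_a),
                   fl4_a = as.numeric(fl4_a))
  if (!is.null(label)) df$label <- as.character(label)
  validate_event_table(df)
  class(df) <- c("event_table", "data.frame")
  df
}

#' @rdname event_table
#' @param x object to coerce or test.
#' @export
as_event_table <- function(x) {
  if (inherits(x, "event_table")) return(x)  # already validated
  req <- c("time_s", "fsc_a", "fsc_h", "ssc_a", "fl1_a", "fl4_a")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("cannot build event_table, missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(x)[, c(req, intersect("label", names(x))), drop = FALSE]
  validate_event_table(df)
  class(df) <- c("event_table", "data.frame")
  df
}

#' @rdname event_table
#' @export
is_event_table <- function(x) inherits(x, "event_table")

validate_event_table <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (is.unsorted(df$time_s)) stop("time_s must be non-decreasing")
  if (df$time_s[1] < 0) stop("time_s must be non-negative")
  for (ch in c("fsc_a", "fsc_h", "ssc_a", "fl1_a", "fl4_a")) {
    v <- df[[ch]]
    if (anyNA(v) || any(v < 0))
      stop("channel ", ch, " must be non-negative and non-missing")
  }
  invisible(df)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events, %.1f s", nrow(x),
              if (nrow(x)) max(x$time_s) else 0))
  if (!is.null(x$label)) {
    tab <- table(x$label)
    cat(" | labels: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "))
  }
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Channel-role map for an instrument
#'
#' Maps instrument parameter short names (`$PnN` keywords in an FCS file) to
#' pipeline roles. The defaults follow BD Accuri C6 naming: `Time`, `FSC-A`,
#' `FSC-H`, `SSC-A`, `FL1-A` (Fluo3/BCECF) and `FL4-A` (DiSC3(5)).
#'
#' @param time,fsc_a,fsc_h,ssc_a,fl1,fl4 instrument parameter names for each
#'   role.
#' @param time_step seconds per raw time tick, used only when the file does
#'   not declare `$TIMESTEP`.
#' @return A list of class `channel_map`.
#' @export
channel_map <- function(time = "Time", fsc_a = "FSC-A", fsc_h = "FSC-H",
                        ssc_a = "SSC-A", fl1 = "FL1-A", fl4 = "FL4-A",
                        time_step = 0.01) {
  stopifnot(is.numeric(time_step), time_step > 0)
  roles <- list(time = time, fsc_a = fsc_a, fsc_h = fsc_h, ssc_a = ssc_a,
                fl1 = fl1, fl4 = fl4)
  if (anyDuplicated(unlist(roles)))
    stop("each role must map to a distinct parameter name")
  structure(list(roles = roles, time_step = time_step),
            class = "channel_map")
}

# human-readable dye label per role, used in error messages
role_label <- function(role) {
  switch(role,
         fl1 = "fl1 (fluo3/bcecf)",
         fl4 = "fl4 (disc)",
         role)
}
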