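#' Pipeline configuration for a protocol run
#'
#' Bundles the knobs of an end-to-end run: gates, bin width, plateau
#' placement, classification thresholds and QC floors.
#'
#' @param gates a [gate_config()].
#' @param bin_width_s kinetic-trace bin width (s).
#' @param settle_s,width_s plateau placement after each addition.
#' @param min_events minimum events for a plateau median.
#' @param subpop `"responding"` or `"all"` for calibration plateau medians.
#' @param em_threshold_mV,ph_threshold,fpeak_threshold classification bands.
#' @param r2_min minimum calibration R^2 before the result is flagged.
#' @param min_retention minimum overall gate retention before flagging.
#' @return A list of class `tlfc_config`.
#' @export
tlfc_config <- function(gates = gate_config(), bin_width_s = 2,
                        settle_s = 90, width_s = 30, min_events = 200,
                        subpop = "responding",
                        em_threshold_mV = 5, ph_threshold = 0.1,
                        fpeak_threshold = 0.25,
                        r2_min = 0.9, min_retention = 0.1) {
  structure(list(gates = gates, bin_width_s = bin_width_s,
                 settle_s = settle_s, width_s = width_s,
                 min_events = min_events, subpop = subpop,
                 em_threshold_mV = em_threshold_mV,
                 ph_threshold = ph_threshold,
                 fpeak_threshold = fpeak_threshold,
                 r2_min = r2_min, min_retention = min_retention),
            class = "tlfc_config")
}

load_input <- function(x, role) {
  if (is.null(x))
    stop("missing required input for role '", role, "'")
  if (is.character(x)) {
    if (!file.exists(x))
      stop("input for role '", role, "' not found: ", x)
    return(read_fcs(x))
  }
  as_event_table(x)
}

gate_or_refuse <- function(events, cfg, what) {
  g <- gate_events(events, cfg$gates)
  if (nrow(g) == 0)
    stop("all events of the ", what, " recording were gated out")
  g
}

overall_retention <- function(gated) {
  r <- attr(gated, "retention")
  if (is.null(r)) NA_real_ else prod(r)
}

# Em analysis of one gated recording: resting window median, calibration
# plateau medians against the Nernst targets, fit, interpolation
analyze_em_recording <- function(gated, schedule, cfg) {
  base_s <- attr(schedule, "baseline_s")
  rest_f <- plateau_median(gated, "fl4_a",
                           c(base_s - cfg$width_s, base_s),
                           subpop = "all", min_events = cfg$min_events)
  wins <- plateau_windows(schedule, cfg$settle_s, cfg$width_s)
  k_out <- c(5, schedule$amount[schedule$compound == "KCl"])
  targets <- nernst_em(k_out)
  med <- vapply(seq_len(nrow(wins)), function(i)
    as.numeric(plateau_median(gated, "fl4_a", wins[i, ],
                              subpop = cfg$subpop, direction = "high",
                              min_events = cfg$min_events)),
    numeric(1))
  fit <- fit_em_calibration(targets, med, r2_min = 0)
  em <- suppressWarnings(interpolate_em(fit, as.numeric(rest_f)))
  list(em_mV = em, fit = fit, resting_F = as.numeric(rest_f),
       trace = bin_median_trace(gated, "fl4_a", cfg$bin_width_s,
                                attr(schedule, "duration_s")))
}

# pH analysis: calibration fit from the H+Cal aliquot, interpolated basal
# pHi and NH4Cl control from the HTF aliquot
analyze_ph_pair <- function(gated_htf, gated_cal, sched_htf, sched_cal, cfg) {
  base_s <- attr(sched_cal, "baseline_s")
  f_60 <- plateau_median(gated_cal, "fl1_a", c(base_s - cfg$width_s, base_s),
                         subpop = "all", min_events = cfg$min_events)
  wins <- plateau_windows(sched_cal, cfg$settle_s, cfg$width_s)
  med <- vapply(seq_len(nrow(wins)), function(i)
    as.numeric(plateau_median(gated_cal, "fl1_a", wins[i, ],
                              subpop = cfg$subpop, direction = "high",
                              min_events = cfg$min_events)),
    numeric(1))
  fit <- fit_ph_calibration(c(6.0, sched_cal$amount),
                            c(as.numeric(f_60), med), r2_min = 0)
  base_htf <- attr(sched_htf, "baseline_s")
  f_basal <- plateau_median(gated_htf, "fl1_a",
                            c(base_htf - cfg$width_s, base_htf),
                            subpop = "all", min_events = cfg$min_events)
  phi <- suppressWarnings(interpolate_ph(fit, as.numeric(f_basal)))
  trace_htf <- bin_median_trace(gated_htf, "fl1_a", cfg$bin_width_s,
                                attr(sched_htf, "duration_s"))
  control <- nh4cl_responsiveness(trace_htf, sched_htf, fit,
                                  cfg$settle_s, cfg$width_s)
  list(phi = phi, fit = fit, nh4cl = control, trace = trace_htf)
}

# calcium analysis of one gated recording: normalized trace, peak, QC
analyze_ca_recording <- function(gated, schedule, cfg) {
  trace <- bin_median_trace(gated, "fl1_a", cfg$bin_width_s,
                            attr(schedule, "duration_s"))
  base_s <- attr(schedule, "baseline_s")
  norm <- normalize_trace(trace, c(0, base_s))
  t_pg <- schedule$time_s[schedule$compound == "progesterone"][1]
  t_io <- schedule$time_s[schedule$compound == "ionomycin"][1]
  t_mn <- schedule$time_s[schedule$compound == "MnCl2"][1]
  fpeak <- extract_fpeak(norm, c(t_pg, t_io))
  qc <- dynamic_range_qc(norm, as.numeric(fpeak),
                         c(t_io, t_mn),
                         c(t_mn, attr(schedule, "duration_s")))
  list(fpeak = as.numeric(fpeak), qc = qc, trace = norm)
}

#' Run one end-to-end TLFC protocol on an NC/CAP sample pair
#'
#' Executes gate -> trace -> plateau/peak -> calibrate -> classify for one
#' sample. Inputs are FCS paths or [event_table()]s:
#' * `protocol = "em"`: `inputs$nc`, `inputs$cap` (each recording carries its
#'   own valinomycin/KCl calibration).
#' * `protocol = "ph"`: `inputs$nc`, `inputs$cap` (HTF aliquots) plus
#'   `inputs$cal_nc`, `inputs$cal_cap` (matching H+Cal aliquots).
#' * `protocol = "ca"`: `inputs$nc`, `inputs$cap`.
#'
#' QC failures below the hard floors (calibration R^2, overall gate
#' retention, NH4Cl control, calcium dynamic range) do not suppress values;
#' they set `status = "flagged"` with the reasons listed.
#'
#' @param protocol `"em"`, `"ph"` or `"ca"`.
#' @param inputs named list of recordings (paths or event tables).
#' @param config a [tlfc_config()].
#' @param sample_id,donor_class sample metadata carried into the result.
#' @param schedules optional named list overriding the default protocol
#'   schedules (`em`, `ca`, `htf`, `cal`).
#' @return A `sample_result` list: `sample_id`, `donor_class`, `parameter`,
#'   `nc`, `cap`, `delta`, `category`, `qc`, `status`, `detail`.
#' @export
run_protocol <- function(protocol = c("em", "ph", "ca"), inputs,
                         config = tlfc_config(),
                         sample_id = "sample", donor_class = "unspecified",
                         schedules = list()) {
  protocol <- match.arg(protocol)
  flags <- character(0)
  qc <- list()

  if (protocol == "em") {
    sched <- schedules$em %||% em_schedule()
    g_nc <- gate_or_refuse(load_input(inputs$nc, "nc"), config, "NC")
    g_cap <- gate_or_refuse(load_input(inputs$cap, "cap"), config, "CAP")
    a_nc <- analyze_em_recording(g_nc, sched, config)
    a_cap <- analyze_em_recording(g_cap, sched, config)
    val_nc <- a_nc$em_mV; val_cap <- a_cap$em_mV
    category <- classify_delta_em(val_nc, val_cap, config$em_threshold_mV)
    qc <- list(retention_nc = overall_retention(g_nc),
               retention_cap = overall_retention(g_cap),
               r2_nc = a_nc$fit$r_squared, r2_cap = a_cap$fit$r_squared)
    if (min(qc$r2_nc, qc$r2_cap) < config$r2_min)
      flags <- c(flags, "calibration R^2 below floor")
    detail <- list(fit_nc = a_nc$fit, fit_cap = a_cap$fit,
                   trace_nc = a_nc$trace, trace_cap = a_cap$trace)
    parameter <- "Em"
  } else if (protocol == "ph") {
    sh <- schedules$htf %||% ph_htf_schedule()
    sc <- schedules$cal %||% ph_cal_schedule()
    g_nc <- gate_or_refuse(load_input(inputs$nc, "nc"), config, "NC")
    g_cap <- gate_or_refuse(load_input(inputs$cap, "cap"), config, "CAP")
    g_cal_nc <- gate_or_refuse(load_input(inputs$cal_nc, "cal_nc"),
                               config, "NC calibration")
    g_cal_cap <- gate_or_refuse(load_input(inputs$cal_cap, "cal_cap"),
                                config, "CAP calibration")
    a_nc <- analyze_ph_pair(g_nc, g_cal_nc, sh, sc, config)
    a_cap <- analyze_ph_pair(g_cap, g_cal_cap, sh, sc, config)
    val_nc <- a_nc$phi; val_cap <- a_cap$phi
    category <- classify_delta_ph(val_nc, val_cap, config$ph_threshold)
    qc <- list(retention_nc = overall_retention(g_nc),
               retention_cap = overall_retention(g_cap),
               r2_nc = a_nc$fit$r_squared, r2_cap = a_cap$fit$r_squared,
               nh4cl_nc = a_nc$nh4cl$pass, nh4cl_cap = a_cap$nh4cl$pass)
    if (min(qc$r2_nc, qc$r2_cap) < config$r2_min)
      flags <- c(flags, "calibration R^2 below floor")
    if (!qc$nh4cl_nc || !qc$nh4cl_cap)
      flags <- c(flags, "NH4Cl responsiveness control failed")
    detail <- list(fit_nc = a_nc$fit, fit_cap = a_cap$fit,
                   nh4cl_nc = a_nc$nh4cl, nh4cl_cap = a_cap$nh4cl,
                   trace_nc = a_nc$trace, trace_cap = a_cap$trace)
    parameter <- "pHi"
  } else {
    sched <- schedules$ca %||% ca_schedule()
    g_nc <- gate_or_refuse(load_input(inputs$nc, "nc"), config, "NC")
    g_cap <- gate_or_refuse(load_input(inputs$cap, "cap"), config, "CAP")
    a_nc <- analyze_ca_recording(g_nc, sched, config)
    a_cap <- analyze_ca_recording(g_cap, sched, config)
    val_nc <- a_nc$fpeak; val_cap <- a_cap$fpeak
    category <- classify_delta_fpeak(val_nc, val_cap,
                                     config$fpeak_threshold)
    qc <- list(retention_nc = overall_retention(g_nc),
               retention_cap = overall_retention(g_cap),
               dynamic_range_nc = a_nc$qc$pass,
               dynamic_range_cap = a_cap$qc$pass)
    if (!qc$dynamic_range_nc || !qc$dynamic_range_cap)
      flags <- c(flags, "ionomycin/Mn dynamic-range QC failed")
    detail <- list(qc_nc = a_nc$qc, qc_cap = a_cap$qc,
                   trace_nc = a_nc$trace, trace_cap = a_cap$trace)
    parameter <- "Ca"
  }

  if (min(qc$retention_nc, qc$retention_cap, na.rm = TRUE) <
        config$min_retention)
    flags <- c(flags, "gate retention below floor")

  structure(list(sample_id = sample_id, donor_class = donor_class,
                 parameter = parameter,
                 nc = val_nc, cap = val_cap, delta = val_cap - val_nc,
                 category = as.character(category),
                 qc = qc,
                 status = if (length(flags)) "flagged" else "ok",
                 flags = flags, detail = detail),
            class = "sample_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("<sample_result> %s [%s] %s: NC = %.3f, CAP = %.3f, delta = %.3f -> %s (%s)\n",
              x$sample_id, x$donor_class, x$parameter, x$nc, x$cap,
              x$delta, x$category, x$status))
  invisible(x)
}

#' Serialize a sample result to JSON
#'
#' Writes the scalar fields and QC block (not the trace/fit detail) with a
#' schema version, so downstream tools can consume results without R.
#'
#' @param result a `sample_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_result <- function(result, path) {
  stopifnot(inherits(result, "sample_result"))
  out <- result[c("sample_id", "donor_class", "parameter", "nc", "cap",
                  "delta", "category", "qc", "status", "flags")]
  out$schema <- "tlfc-sample-result/1"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized sample result
#' @param path JSON path written by [write_sample_result()].
#' @return A `sample_result` (without the detail block).
#' @export
read_sample_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "sample_result")
}

#' Cohort-level summary of sample results
#'
#' Groups `sample_result`s by donor class (all must share one parameter),
#' then per group: the paired NC-vs-CAP comparison, the one-sample test of
#' the deltas against zero, and the category-distribution table.
#'
#' @param results a list of `sample_result`s, or a directory of result JSON
#'   files.
#' @param min_n minimum samples per donor class.
#' @return A list of class `cohort_report`: per donor class, `summary`
#'   ([summarize_cohort()] table), `paired` ([paired_compare()] report) and
#'   `delta` ([delta_vs_zero()] report).
#' @export
run_cohort <- function(results, min_n = 3) {
  if (is.character(results) && length(results) == 1 && dir.exists(results)) {
    files <- list.files(results, pattern = "\\.json$", full.names = TRUE)
    results <- lapply(files, read_sample_result)
  }
  if (!length(results)) stop("no sample results to summarize")
  stopifnot(all(vapply(results, inherits, logical(1), "sample_result")))
  params <- unique(vapply(results, `[[`, "", "parameter"))
  if (length(params) != 1)
    stop("mixed parameters in one cohort summary: ",
         paste(params, collapse = ", "))
  classes <- vapply(results, `[[`, "", "donor_class")
  out <- lapply(split(results, classes), function(rs) {
    if (length(rs) < min_n)
      stop("fewer than ", min_n, " samples for donor class '",
           rs[[1]]$donor_class, "'")
    nc <- vapply(rs, `[[`, numeric(1), "nc")
    cap <- vapply(rs, `[[`, numeric(1), "cap")
    cats <- vapply(rs, `[[`, "", "category")
    list(summary = summarize_cohort(cats, rs[[1]]$donor_class),
         paired = paired_compare(nc, cap),
         delta = delta_vs_zero(cap - nc))
  })
  structure(list(parameter = params, classes = out),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> parameter:", x$parameter, "\n")
  for (cl in names(x$classes)) {
    g <- x$classes[[cl]]
    cat(sprintf("  %s (n = %d): %s branch, p = %.4g; delta p = %.4g\n",
                cl, g$paired$n, g$paired$test, g$paired$p_value,
                g$delta$p_value))
    s <- g$summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("    %-15s %d/%d (%d%%)\n", s$category[i], s$count[i],
                  attr(s, "n"), s$percent[i]))
  }
  invisible(x)
}

#' Cohort report as a flat table
#'
#' @param report a `cohort_report`.
#' @return Data frame with columns `donor_class`, `parameter`, `category`,
#'   `count`, `percent` (the CSV layout of the `cohort` CLI subcommand).
#' @export
cohort_table <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  do.call(rbind, lapply(report$classes, function(g) {
    s <- as.data.frame(g$summary)
    s$parameter <- report$parameter
    s[, c("donor_class", "parameter", "category", "count", "percent")]
  }))
}
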