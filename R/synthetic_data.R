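#' Simulation configuration
#'
#' Study conditions for the synthetic TLFC event stream. The default event
#' rate, 700 events/s, is the product of the acquisition flow rate
#' (14 uL/min) and the working cell concentration (3e6 cells/mL). Event
#' classes (viable cell, dead cell, debris, doublet) are drawn with fixed
#' fractions; per-class scatter and fluorescence intensities are log-normal.
#' Viable responder fluorescence follows the protocol's generating model —
#' linear in membrane potential for DiSC3(5), log-linear in pH for BCECF —
#' with per-event multiplicative log-normal noise of the stated CV and
#' median 1, so population medians sit exactly on the generating curve.
#'
#' @param rate event rate (events/s).
#' @param noise_cv coefficient of variation of the per-event multiplicative
#'   intensity noise.
#' @param responder_fraction fraction of viable cells that follow the
#'   stimulus kinetics; the rest hold their baseline level.
#' @param fractions named fractions of `viable`, `dead`, `debris`, `doublet`
#'   events; must sum to 1.
#' @param tau_s relaxation time constant (s) toward each segment's target
#'   level after an addition.
#' @param em_slope,em_intercept generating Disc line `F = a Em + b`
#'   (a.u./mV, a.u.).
#' @param ph_slope,ph_intercept generating BCECF log-line
#'   `log10 F = m pH + c`.
#' @param fl1_viable baseline fl1 intensity of a viable cell (a.u.); also the
#'   F0 of the calcium protocol.
#' @param fl1_dead,fl4_dead dead-cell intensity modes (a.u.).
#' @param seed integer seed; every `simulate_*` call is deterministic given
#'   the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(rate = 700, noise_cv = 0.25, responder_fraction = 1,
                       fractions = c(viable = 0.75, dead = 0.10,
                                     debris = 0.10, doublet = 0.05),
                       tau_s = 20,
                       em_slope = -10682.4, em_intercept = -264308,
                       ph_slope = 0.30, ph_intercept = 1.5,
                       fl1_viable = 1e4, fl1_dead = 1e2, fl4_dead = 3e4,
                       seed = 1L) {
  stopifnot(rate > 0, noise_cv >= 0,
            responder_fraction >= 0, responder_fraction <= 1,
            all(c("viable", "dead", "debris", "doublet") %in%
                  names(fractions)),
            abs(sum(fractions) - 1) < 1e-9, tau_s > 0)
  structure(list(rate = rate, noise_cv = noise_cv,
                 responder_fraction = responder_fraction,
                 fractions = fractions, tau_s = tau_s,
                 em_slope = em_slope, em_intercept = em_intercept,
                 ph_slope = ph_slope, ph_intercept = ph_intercept,
                 fl1_viable = fl1_viable, fl1_dead = fl1_dead,
                 fl4_dead = fl4_dead, seed = as.integer(seed)),
            class = "sim_config")
}

# run fn() under a temporary RNG state seeded with `seed`
with_sim_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  fn()
}

# median-preserving multiplicative log-normal noise factors
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

# piecewise exponential relaxation toward successive targets.
# t_adds / targets: addition times and the level each addition drives the
# responding cells toward; `resting` holds before the first addition.
relax_profile <- function(times, t_adds, targets, resting, tau) {
  val <- rep(resting, length(times))
  level <- resting
  bounds <- c(t_adds, Inf)
  for (k in seq_along(t_adds)) {
    sel <- times >= t_adds[k] & times < bounds[k + 1]
    if (any(sel))
      val[sel] <- targets[k] + (level - targets[k]) *
        exp(-(times[sel] - t_adds[k]) / tau)
    # carry the level reached at the end of this segment into the next
    seg_end <- min(bounds[k + 1], max(times, t_adds[k]))
    level <- targets[k] + (level - targets[k]) *
      exp(-(seg_end - t_adds[k]) / tau)
  }
  val
}

# draw per-event class labels and the static channels (scatter, baseline fl)
draw_event_frame <- function(cfg, duration) {
  n <- stats::rpois(1, cfg$rate * duration)
  if (n == 0) stop("simulated zero events; increase rate or duration")
  t <- sort(stats::runif(n, 0, duration))
  cls <- sample(names(cfg$fractions), n, replace = TRUE,
                prob = cfg$fractions)
  is_resp <- cls %in% c("viable", "doublet") &
    stats::runif(n) < cfg$responder_fraction
  cls[cls == "viable" & !is_resp] <- "nonresponder"

  fsc <- stats::rlnorm(n, log(2e5), 0.15)
  ratio <- stats::rnorm(n, 0.92, 0.03)
  ssc <- stats::rlnorm(n, log(8e4), 0.20)
  fsc_a <- fsc; fsc_h <- fsc * ratio

  dead <- cls == "dead"
  fsc_a[dead] <- stats::rlnorm(sum(dead), log(1.5e5), 0.20)
  fsc_h[dead] <- fsc_a[dead] * stats::rnorm(sum(dead), 0.92, 0.03)

  deb <- cls == "debris"
  fsc_a[deb] <- stats::rlnorm(sum(deb), log(1e4), 0.5)
  fsc_h[deb] <- fsc_a[deb] * stats::rnorm(sum(deb), 0.9, 0.1)
  ssc[deb] <- stats::rlnorm(sum(deb), log(5e3), 0.5)

  # doublets: summed pulse areas, sub-additive height
  dbl <- cls == "doublet"
  fsc_a[dbl] <- 2 * fsc[dbl]
  fsc_h[dbl] <- 1.2 * fsc[dbl] * ratio[dbl]
  ssc[dbl] <- 2 * ssc[dbl]

  list(n = n, time_s = t, class = cls,
       fsc_a = pmax(fsc_a, 0), fsc_h = pmax(fsc_h, 0),
       ssc_a = pmax(ssc, 0),
       responding = cls %in% c("viable", "doublet"),
       dead = dead, debris = deb, doublet = dbl)
}

# assemble fl channels from viable-target levels and the class model.
# fl1_target / fl4_target: per-event generating medians for responding
# viable cells; fl1_base / fl4_base: levels non-responders hold.
assemble_events <- function(cfg, fr, fl1_target, fl4_target,
                            fl1_base, fl4_base) {
  n <- fr$n
  fl1 <- fl1_target; fl4 <- fl4_target
  nonr <- fr$class == "nonresponder"
  fl1[nonr] <- fl1_base[nonr]; fl4[nonr] <- fl4_base[nonr]
  fl1[fr$dead] <- cfg$fl1_dead
  fl4[fr$dead] <- cfg$fl4_dead
  fl1[fr$debris] <- 30
  fl4[fr$debris] <- 100
  fl1[fr$doublet] <- 2 * fl1[fr$doublet]
  fl4[fr$doublet] <- 2 * fl4[fr$doublet]
  fl1 <- fl1 * ln_noise(n, cfg$noise_cv)
  fl4 <- fl4 * ln_noise(n, cfg$noise_cv)
  event_table(time_s = fr$time_s, fsc_a = fr$fsc_a, fsc_h = fr$fsc_h,
              ssc_a = fr$ssc_a, fl1_a = pmax(fl1, 0), fl4_a = pmax(fl4, 0),
              label = fr$class)
}

#' Simulate a membrane-potential (Em) recording
#'
#' Seeded Poisson event stream for the valinomycin/KCl protocol: viable
#' responders' Disc (fl4) generating median follows `F = a Em(t) + b`, where
#' `Em(t)` starts at the true resting potential and relaxes exponentially to
#' each calibration target (-80, -63, -52, -40, -28 mV) after the
#' corresponding addition. Non-responders hold the resting level; dead
#' cells, debris and doublets follow the class models of [sim_config()].
#'
#' @param cfg a [sim_config()].
#' @param true_em_mV true resting membrane potential (mV, in \[-100, 0\]).
#' @param schedule the Em protocol schedule; default [em_schedule()].
#' @param seed seed override (defaults to `cfg$seed`).
#' @return List of class `tlfc_sim` with `events` ([event_table()]) and
#'   `truth` (true Em, calibration targets, config echo).
#' @export
simulate_em_run <- function(cfg = sim_config(), true_em_mV,
                            schedule = em_schedule(), seed = cfg$seed) {
  if (true_em_mV < -100 || true_em_mV > 0)
    stop("true resting Em must lie in [-100, 0] mV")
  with_sim_seed(seed, function() {
    duration <- attr(schedule, "duration_s")
    targets <- nernst_em(c(5, schedule$amount[schedule$compound == "KCl"]))
    fr <- draw_event_frame(cfg, duration)
    em_t <- relax_profile(fr$time_s, schedule$time_s, targets,
                          true_em_mV, cfg$tau_s)
    fl4_resp <- cfg$em_slope * em_t + cfg$em_intercept
    fl4_rest <- rep(cfg$em_slope * true_em_mV + cfg$em_intercept, fr$n)
    fl1 <- rep(cfg$fl1_viable, fr$n)
    events <- assemble_events(cfg, fr, fl1, fl4_resp, fl1, fl4_rest)
    structure(list(events = events,
                   truth = list(protocol = "em", true_em_mV = true_em_mV,
                                targets_mV = targets, seed = seed,
                                schedule = schedule)),
              class = "tlfc_sim")
  })
}

#' Simulate a pH (pHi) experiment: HTF and H+Cal aliquots
#'
#' Generates both recordings of one pH determination. The HTF aliquot holds
#' the true intracellular pH, then alkalinizes by `nh4cl_step` after the
#' NH4Cl control pulse. The H+Cal aliquot starts clamped at pHe 6.0 by
#' nigericin and tracks the KOH ladder (+0.25 pH per addition up to 8.0).
#' BCECF (fl1) generating medians follow `log10 F = m pH + c`.
#'
#' @param cfg a [sim_config()].
#' @param true_phi true intracellular pH (in \[6, 8\]).
#' @param nh4cl_step alkalinization produced by the NH4Cl control (pH units).
#' @param schedule_htf,schedule_cal aliquot schedules; defaults
#'   [ph_htf_schedule()] and [ph_cal_schedule()].
#' @param seed seed override.
#' @return List of class `tlfc_sim` with `htf`, `cal` ([event_table()]s) and
#'   `truth`.
#' @export
simulate_ph_run <- function(cfg = sim_config(), true_phi, nh4cl_step = 0.56,
                            schedule_htf = ph_htf_schedule(),
                            schedule_cal = ph_cal_schedule(),
                            seed = cfg$seed) {
  if (true_phi < 6 || true_phi > 8)
    stop("true pHi must lie in [6, 8]")
  ph_to_f <- function(ph) 10^(cfg$ph_slope * ph + cfg$ph_intercept)
  with_sim_seed(seed, function() {
    # HTF aliquot: baseline at true pHi, NH4Cl step
    fr1 <- draw_event_frame(cfg, attr(schedule_htf, "duration_s"))
    ph1 <- relax_profile(fr1$time_s, schedule_htf$time_s,
                         true_phi + nh4cl_step, true_phi, cfg$tau_s)
    bg1 <- rep(1e3, fr1$n)  # Disc channel unstained in the pH protocol
    htf <- assemble_events(cfg, fr1, ph_to_f(ph1), bg1,
                           rep(ph_to_f(true_phi), fr1$n), bg1)
    # H+Cal aliquot: nigericin clamp at 6.0, KOH ladder
    fr2 <- draw_event_frame(cfg, attr(schedule_cal, "duration_s"))
    ph2 <- relax_profile(fr2$time_s, schedule_cal$time_s,
                         schedule_cal$amount, 6.0, cfg$tau_s)
    bg2 <- rep(1e3, fr2$n)
    cal <- assemble_events(cfg, fr2, ph_to_f(ph2), bg2,
                           rep(ph_to_f(6.0), fr2$n), bg2)
    structure(list(htf = htf, cal = cal,
                   truth = list(protocol = "ph", true_phi = true_phi,
                                nh4cl_step = nh4cl_step, seed = seed)),
              class = "tlfc_sim")
  })
}

# normalized calcium generating trace: transient-plus-plateau progesterone
# response, ionomycin maximum, Mn2+ quench minimum
ca_generating_trace <- function(times, peak, schedule,
                                tau_rise = 10, tau_decay = 60,
                                plateau_frac = 0.4,
                                iono_max = 3.0, mn_min = -0.8,
                                tau_step = 10) {
  t_pg <- schedule$time_s[schedule$compound == "progesterone"][1]
  t_io <- schedule$time_s[schedule$compound == "ionomycin"][1]
  t_mn <- schedule$time_s[schedule$compound == "MnCl2"][1]
  shape <- function(u) (1 - exp(-u / tau_rise)) *
    (plateau_frac + (1 - plateau_frac) * exp(-u / tau_decay))
  grid <- seq(0, t_io - t_pg, by = 0.1)
  scale <- if (peak > 0) peak / max(shape(grid)) else 0
  g <- numeric(length(times))
  pg <- times >= t_pg & times < t_io
  g[pg] <- scale * shape(times[pg] - t_pg)
  g_at_io <- scale * shape(t_io - t_pg)
  io <- times >= t_io & times < t_mn
  g[io] <- iono_max + (g_at_io - iono_max) * exp(-(times[io] - t_io) / tau_step)
  g_at_mn <- iono_max + (g_at_io - iono_max) * exp(-(t_mn - t_io) / tau_step)
  mn <- times >= t_mn
  g[mn] <- mn_min + (g_at_mn - mn_min) * exp(-(times[mn] - t_mn) / tau_step)
  g
}

#' Simulate a progesterone calcium-response pair (NC and CAP)
#'
#' Generates the two recordings of one sample's calcium determination on the
#' normalized generating scale: baseline 0; progesterone response rising
#' with a 10-s time constant to the stated peak, decaying (60 s) toward a
#' plateau at 0.4 x peak; ionomycin step to `iono_max`; Mn2+ quench to
#' `mn_min`. Raw Fluo3 is `F = F0 (1 + g(t))` with multiplicative noise.
#'
#' @param cfg a [sim_config()].
#' @param peak_nc,peak_cap true normalized peaks for the two conditions
#'   (>= 0).
#' @param schedule calcium schedule; default [ca_schedule()].
#' @param iono_max,mn_min normalized ionomycin maximum and Mn2+ minimum.
#' @param seed seed override.
#' @return List of class `tlfc_sim` with `nc`, `cap` ([event_table()]s) and
#'   `truth`.
#' @export
simulate_ca_run <- function(cfg = sim_config(), peak_nc, peak_cap,
                            schedule = ca_schedule(),
                            iono_max = 3.0, mn_min = -0.8,
                            seed = cfg$seed) {
  stopifnot(peak_nc >= 0, peak_cap >= 0, mn_min > -1)
  with_sim_seed(seed, function() {
    one <- function(peak) {
      fr <- draw_event_frame(cfg, attr(schedule, "duration_s"))
      g <- ca_generating_trace(fr$time_s, peak, schedule,
                               iono_max = iono_max, mn_min = mn_min)
      f0 <- cfg$fl1_viable
      bg <- rep(1e3, fr$n)  # Disc channel unstained in the calcium protocol
      assemble_events(cfg, fr, f0 * (1 + g), bg, rep(f0, fr$n), bg)
    }
    structure(list(nc = one(peak_nc), cap = one(peak_cap),
                   truth = list(protocol = "ca", peak_nc = peak_nc,
                                peak_cap = peak_cap, iono_max = iono_max,
                                mn_min = mn_min, seed = seed)),
              class = "tlfc_sim")
  })
}
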