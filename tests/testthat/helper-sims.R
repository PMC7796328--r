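# Shared fixtures built in code.

# Reduced event rate for unit tests: plateau windows still hold thousands of
# events, but runs stay fast. The acceptance suite uses the full-rate default.
quick_cfg <- function(seed = 1L, ...) {
  sim_config(rate = 150, seed = seed, ...)
}

# small hand-built event table
toy_events <- function(n = 10) {
  event_table(time_s = seq(0, by = 0.1, length.out = n),
              fsc_a = rep(2e5, n), fsc_h = rep(1.8e5, n),
              ssc_a = rep(8e4, n),
              fl1_a = seq(1e3, 1e4, length.out = n),
              fl4_a = seq(1e5, 5e5, length.out = n))
}

# events uniformly spread over a window with given fl values
window_events <- function(fl1, lo = 0, hi = 30, channel = "fl1_a") {
  n <- length(fl1)
  t <- seq(lo, hi - (hi - lo) / n, length.out = n)
  args <- list(time_s = t, fsc_a = rep(2e5, n), fsc_h = rep(1.8e5, n),
               ssc_a = rep(8e4, n), fl1_a = rep(1e4, n),
               fl4_a = rep(1e5, n))
  args[[channel]] <- fl1
  do.call(event_table, args)
}
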