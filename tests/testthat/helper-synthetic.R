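# Shared fixture builders: everything is generated in code at test time.

# minimal two-state network with given mean dwell times and observation levels
two_state_network <- function(mean_f = 1.4, mean_u = 1.3, dz_u = 18.2,
                              dvar_u = 5.8, bell = FALSE, delta_x_total = 12,
                              ref_force = 8.5) {
  conf <- data.frame(label = c("F", "U"), state = "i",
                     dz_nm = c(0, dz_u), dvar_nm2 = c(0, dvar_u),
                     stringsAsFactors = FALSE)
  tt <- data.frame(from = c("F", "U"), to = c("U", "F"),
                   mean_time_s = c(mean_f, mean_u), stringsAsFactors = FALSE)
  net <- network_from_tables(conf, tt)
  if (bell) {
    net <- set_bell_sensitivity(net, "F", "U", delta_x_total / 2, "unfolding",
                                ref_force)
    net <- set_bell_sensitivity(net, "U", "F", delta_x_total / 2, "folding",
                                ref_force)
  }
  net
}

# simulate + render a two-state recording in one call
two_state_trajectory <- function(duration = 200, fs = 1000, seed = 1,
                                 force = 8.5, baseline = 0.85, ...) {
  net <- two_state_network(...)
  p <- simulate_state_path(net, duration, force_pN = force, initial = "F",
                           seed = seed)
  render_trajectory(p, observation_spec(sampling_rate_hz = fs,
                                        baseline_sd_nm = baseline),
                    conformations = net$conformations, seed = seed + 1000L)
}

# noise-free square wave visiting `levels` with the given dwell (s) per level
square_wave_trajectory <- function(levels = c(0, 18.2), dwell_s = 1,
                                   fs = 100, n_cycles = 5) {
  per <- round(dwell_s * fs)
  z <- rep(rep(levels, n_cycles), each = per)
  trajectory(seq_along(z) / fs, z, 8.5, sampling_rate = fs)
}

# hand-built idealization with exact alternating dwells (label vector a/b)
alternating_idealization <- function(dur_a = 1, dur_b = 1, n_cycles = 100,
                                     fs = 100, labels = c("N", "U")) {
  levels <- c(0, 18.2)
  pa <- round(dur_a * fs); pb <- round(dur_b * fs)
  z <- rep(rep(levels, n_cycles), times = rep(c(pa, pb), n_cycles))
  tr <- trajectory(seq_along(z) / fs, z, 8.5, sampling_rate = fs)
  label_and_excise(tr, thresholds(levels, labels), min_dwell = 1)
}
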