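test_that("pooled transition table: exact alternating dwells and empty input", {
  id <- alternating_idealization(dur_a = 1, dur_b = 1, n_cycles = 100)
  tt <- build_transition_table(list(id, id))
  expect_equal(tt$mean_s, c(1, 1))
  expect_identical(tt$n, c(198L, 198L))
  z <- rep(0, 200)
  tr <- trajectory(seq_along(z) / 100, z, 8.5)
  id1 <- suppressWarnings(label_and_excise(tr, thresholds(c(0, 18.2))))
  expect_identical(nrow(build_transition_table(id1)), 0L)
})

test_that("the simulated native network round-trips through the pipeline", {
  tr <- two_state_trajectory(duration = 2000, fs = 500, seed = 101)
  id <- label_and_excise(tr, estimate_levels(tr, 2))
  tt <- build_transition_table(id)
  for (edge in list(c("N", "U", 1.4), c("U", "N", 1.3))) {
    row <- tt[tt$from == edge[1] & tt$to == edge[2], ]
    expect_lt(abs(row$mean_s - as.numeric(edge[3])), 3 * row$sem_s)
  }
  # detailed-balance sanity: forward/backward counts differ by at most 1
  expect_lte(abs(tt$n[1] - tt$n[2]), 1L)
})

test_that("internal dynamics of the multi-conformation regions are recovered", {
  confs <- talin_conformations()
  tt <- talin_transition_times()
  # region vi: M1 <-> M2 hopping with the tabulated clocks
  vi <- confs[confs$label %in% c("M1", "M2"), c("label", "dz_nm", "dvar_nm2")]
  net <- network_from_tables(vi, tt[tt$from %in% vi$label &
                                      tt$to %in% vi$label, ])
  p <- simulate_state_path(net, 800, force_pN = 8.5, initial = "M1",
                           seed = 111)
  trj <- render_trajectory(p, observation_spec(sampling_rate_hz = 1000),
                           conformations = vi, seed = 112)
  th <- thresholds(c(7.45, 14.3), c("M1", "M2"))
  tab <- build_transition_table(label_and_excise(trj, th))
  m12 <- tab[tab$from == "M1", ]
  m21 <- tab[tab$from == "M2", ]
  expect_lt(abs(m12$mean_s - 0.91), 3 * m12$sem_s)
  expect_lt(abs(m21$mean_s - 0.25), 3 * m21$sem_s + 0.25 * 0.05)
  # region v chain: only adjacent-level transitions should be seen
  v <- confs[confs$state == "v", c("label", "dz_nm", "dvar_nm2")]
  netv <- network_from_tables(v, tt[tt$from %in% v$label & tt$to %in% v$label, ])
  pv <- simulate_state_path(netv, 600, force_pN = 8.5, initial = "L2",
                            seed = 113)
  trv <- render_trajectory(pv, observation_spec(sampling_rate_hz = 1000),
                           conformations = v, seed = 114)
  tabv <- build_transition_table(
    label_and_excise(trv, thresholds(c(3.3, 7.6, 14.9), c("L1", "L2", "L3"))))
  l12 <- tabv[tabv$from == "L1" & tabv$to == "L2", ]
  expect_lt(abs(l12$mean_s - 0.37), 3 * l12$sem_s + 0.37 * 0.05)
  # non-adjacent L1 -> L3 jumps only arise from missed sub-resolution L2
  # visits and must stay rare
  n13 <- sum(tabv$n[tabv$from == "L1" & tabv$to == "L3"])
  expect_lt(n13, 0.01 * l12$n)
})

test_that("rare-state entry and exit clocks are realized as constructed", {
  # path-level check (no rendering): region iv entry/exit over a long run
  confs <- talin_conformations()
  tt <- talin_transition_times()
  keep <- c("F", "U", "H")
  net <- network_from_tables(confs[confs$label %in% keep,
                                   c("label", "dz_nm", "dvar_nm2")],
                             tt[tt$from %in% keep & tt$to %in% keep, ])
  p <- simulate_state_path(net, 6e4, force_pN = 8.5, seed = 115)
  dur <- diff(p$entry_time_s)
  from <- p$label[-nrow(p)]; to <- p$label[-1]
  h_exit <- dur[from == "H"]
  expect_gt(length(h_exit), 10)
  expect_lt(abs(mean(h_exit) - 96.3), 3 * sd(h_exit) / sqrt(length(h_exit)))
  # U dwells are cut short by H entries: mean U dwell = 1/(sum of exits)
  u_dwell <- dur[from == "U"]
  exp_u <- 1 / (1 / 1.3 + 1 / 1251.8)
  expect_lt(abs(mean(u_dwell) - exp_u), 3 * sd(u_dwell) / sqrt(length(u_dwell)))
})

test_that("running unfolded fraction: exact arithmetic and window limits", {
  id <- alternating_idealization(dur_a = 1, dur_b = 1, n_cycles = 30)
  pu <- running_unfolded_fraction(id, n = 10)
  expect_true(all(pu$p_u == 0.5))
  # t_U = 3 t_F exactly
  id3 <- alternating_idealization(dur_a = 1, dur_b = 3, n_cycles = 30)
  pu3 <- running_unfolded_fraction(id3, n = 10)
  expect_true(all(pu3$p_u == 0.75))
  expect_true(all(pu3$p_u >= 0 & pu3$p_u <= 1))
  # window equal to all transitions reproduces the whole-trace fraction
  nt <- sum(id3$segments$label != "TP") - 1L
  pu_all <- running_unfolded_fraction(id3, n = nt)
  expect_identical(nrow(pu_all), 1L)
  expect_equal(pu_all$p_u, 0.75)
  expect_warning(running_unfolded_fraction(id3, n = 1000), "fewer than")
})

test_that("isomer switches are detected with hysteresis and correct durations", {
  flat <- data.frame(window = 1:50, t_s = 1:50, p_u = rep(0.5, 50),
                     mean_t_u = 1, mean_t_f = 1)
  class(flat) <- c("pu_series", "data.frame")
  expect_identical(nrow(detect_isomer_switches(flat)), 0L)

  # synthetic cis -> trans -> cis episode built from dwell kinetics:
  # occupancy jumps from 0.5 to ~0.96 for ~63 s
  net_cis <- two_state_network(mean_f = 1.4, mean_u = 1.3)
  net_trans <- two_state_network(mean_f = 0.07, mean_u = 3.2)
  p1 <- simulate_state_path(net_cis, 150, force_pN = 8.5, seed = 121)
  p2 <- simulate_state_path(net_trans, 63, force_pN = 8.5, seed = 122)
  p3 <- simulate_state_path(net_cis, 150, force_pN = 8.5, seed = 123)
  shift <- function(p, t0) {
    p$entry_time_s <- p$entry_time_s + t0
    p
  }
  path <- rbind(p1, shift(p2, 150), shift(p3, 213))
  attr(path, "duration_s") <- 363
  attr(path, "force_protocol") <- force_protocol(363, 8.5)
  class(path) <- c("state_path", "data.frame")
  trj <- render_trajectory(path, observation_spec(sampling_rate_hz = 500),
                           conformations = two_state_network()$conformations,
                           seed = 124)
  id <- label_and_excise(trj, thresholds(c(0, 18.2)))
  pu <- running_unfolded_fraction(id, n = 10)
  sw <- detect_isomer_switches(pu)
  expect_identical(nrow(sw), 1L)
  expect_lt(abs(sw$duration_s - 63) / 63, 0.35)
  expect_lt(abs(sw$onset_s - 150), 15)

  # two well-separated synthetic switches
  pu2 <- data.frame(window = 1:100, t_s = 1:100,
                    p_u = c(rep(0.5, 20), rep(0.95, 20), rep(0.5, 20),
                            rep(0.95, 20), rep(0.5, 20)),
                    mean_t_u = 1, mean_t_f = 1)
  class(pu2) <- c("pu_series", "data.frame")
  expect_identical(nrow(detect_isomer_switches(pu2)), 2L)
})

test_that("isomerization-rate fit: identity, recovery and degeneracy", {
  p_u <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  k <- 0.0017
  fit <- fit_isomerization_rate(switch_counts = p_u * k * 1e5,
                                observation_time_s = rep(1e5, 5), p_u = p_u)
  expect_equal(fit$k_per_s, 0.0017, tolerance = 1e-12)
  expect_equal(fit$timescale_s, 1 / 0.0017, tolerance = 1e-12)

  # Poisson-count realization across 5 forces: recovery within 15%
  set.seed(131)
  t_obs <- rep(2e5, 5)
  counts <- rpois(5, p_u * k * t_obs)
  fit2 <- fit_isomerization_rate(counts, t_obs, p_u)
  expect_lt(abs(fit2$k_per_s - k) / k, 0.15)

  expect_warning(f0 <- fit_isomerization_rate(c(0, 0, 0), rep(10, 3),
                                              rep(0, 3)), "unidentifiable")
  expect_false(f0$identifiable)
  expect_error(fit_isomerization_rate(c(1, 1, 1), c(10, 0, 10),
                                      c(0.5, 0.5, 0.5)), "observation time")
})

test_that("coexistence-force fit: exact symmetric case and degeneracies", {
  dat <- data.frame(force_pN = c(7.5, 8.5, 9.5),
                    folded_fraction = c(0.9, 0.5, 0.1))
  fr <- folded_fraction_vs_force(dat)
  expect_equal(fr$f05_pN, 8.5, tolerance = 1e-6)
  expect_error(folded_fraction_vs_force(
    data.frame(force_pN = c(7, 8, 9, 10), folded_fraction = c(1, 1, 0, 0))),
    NA)  # step-like but non-degenerate input still fits
  expect_error(folded_fraction_vs_force(
    data.frame(force_pN = c(7, 8, 9, 10), folded_fraction = rep(1, 4))),
    "degenerate")
})

test_that("occupancy-based force response recovers the Bell construction", {
  forces <- c(7.5, 8.0, 8.5, 9.0, 9.5)
  net <- two_state_network(mean_f = 1.35, mean_u = 1.35, bell = TRUE)
  ideals <- lapply(seq_along(forces), function(i) {
    p <- simulate_state_path(net, 400, force_pN = forces[i], seed = 140 + i)
    trj <- render_trajectory(p, observation_spec(sampling_rate_hz = 500),
                             conformations = net$conformations,
                             seed = 240 + i)
    label_and_excise(trj, thresholds(c(0, 18.2)))
  })
  fr <- folded_fraction_vs_force(ideals, forces)
  expect_lt(abs(fr$f05_pN - 8.5), 0.15)
  expect_lt(abs(fr$width_10_90_pN - 4.11 * log(81) / 12) /
              (4.11 * log(81) / 12), 0.2)
})

test_that("rescue probability: binomial arithmetic and escape-rate model", {
  out <- data.frame(force_pN = rep(10, 10),
                    rescued = c(rep(TRUE, 7), rep(FALSE, 3)))
  rp <- rescue_probability(out)
  expect_equal(rp$probability, 0.7)
  expect_equal(rp$sem, sqrt(0.7 * 0.3 / 10), tolerance = 1e-12)
  all_good <- rescue_probability(data.frame(force_pN = 15, rescued = rep(TRUE, 8)))
  expect_equal(all_good$probability, 1)
  expect_equal(all_good$sem, 0)

  # synthetic escape-rate model: P(rescue) = 1 - exp(-k_esc(F) * 15 s)
  set.seed(151)
  k_esc <- function(f) 0.02 * exp((f - 4) * 1.2 / 4.11)
  forces <- c(6, 10, 14, 18)
  trials <- 60
  outcomes <- do.call(rbind, lapply(forces, function(f) {
    data.frame(force_pN = f,
               rescued = runif(trials) < 1 - exp(-k_esc(f) * 15))
  }))
  rp2 <- rescue_probability(outcomes)
  expected <- 1 - exp(-k_esc(forces) * 15)
  se <- sqrt(expected * (1 - expected) / trials)
  expect_true(all(abs(rp2$probability - expected) < 3 * se + 1e-9))
  expect_true(all(diff(rp2$probability) >= -2 * max(se))) # force helps rescue
})

test_that("a recording recovering native dynamics is recognized", {
  id <- alternating_idealization(dur_a = 1.5, dur_b = 1.5, n_cycles = 10)
  expect_true(native_dynamics_recovered(id))
  idq <- alternating_idealization(dur_a = 1.5, dur_b = 1.5, n_cycles = 2)
  expect_false(native_dynamics_recovered(idq))
})
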