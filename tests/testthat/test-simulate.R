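test_that("identical seeds give bit-identical paths and trajectories", {
  net <- talin_network("i")
  p1 <- simulate_state_path(net, 50, force_pN = 8.5, seed = 7)
  p2 <- simulate_state_path(net, 50, force_pN = 8.5, seed = 7)
  expect_identical(p1, p2)
  t1 <- render_trajectory(p1, observation_spec(sampling_rate_hz = 200), seed = 8)
  t2 <- render_trajectory(p2, observation_spec(sampling_rate_hz = 200), seed = 8)
  expect_identical(t1$extension_nm, t2$extension_nm)
  p3 <- simulate_state_path(net, 50, force_pN = 8.5, seed = 8)
  expect_false(identical(p1$entry_time_s, p3$entry_time_s))
})

test_that("a symmetric two-state network equilibrates at half occupancy", {
  net <- two_state_network(mean_f = 1, mean_u = 1)
  p <- simulate_state_path(net, 2e4, force_pN = 8.5, seed = 3)
  dur <- diff(c(p$entry_time_s, attr(p, "duration_s")))
  occ_f <- sum(dur[p$label == "F"]) / sum(dur)
  n <- nrow(p)
  expect_gt(n, 1e4)
  # occupancy s.e. ~ sqrt(2 * mean^2 * n_cycles) / T for alternating renewals
  se <- sqrt(n / 2 * 2) / 2e4
  expect_lt(abs(occ_f - 0.5), 3 * se)
})

test_that("a single conformation yields a constant path (absorbing warning)", {
  one <- network_from_tables(data.frame(label = "F", dz_nm = 0, dvar_nm2 = 0),
                             NULL)
  p <- simulate_state_path(one, 10, force_pN = 8.5, seed = 1)
  expect_identical(nrow(p), 1L)
  expect_identical(p$label, "F")
  conf <- data.frame(label = c("F", "U"), dz_nm = c(0, 18.2),
                     dvar_nm2 = c(0, 5.8))
  tt <- data.frame(from = "F", to = "U", mean_time_s = 1)
  expect_warning(simulate_state_path(network_from_tables(conf, tt), 10,
                                     force_pN = 8.5, seed = 1), "absorbing")
})

test_that("exit branching from U follows the edge-rate ratios", {
  net <- talin_network(bell = FALSE)
  p <- simulate_state_path(net, 1e5, force_pN = 8.5, initial = "U", seed = 42)
  from_u <- which(p$label[-nrow(p)] == "U")
  dest <- p$label[from_u + 1L]
  tt <- talin_transition_times()
  u_rates <- 1 / tt$mean_time_s[tt$from == "U"]
  names(u_rates) <- tt$to[tt$from == "U"]
  p_h <- u_rates[["H"]] / sum(u_rates)
  n <- length(dest)
  obs <- mean(dest == "H")
  expect_lt(abs(obs - p_h), 3 * sqrt(p_h * (1 - p_h) / n))
})

test_that("dwell times are exponential with the constructed total exit rate", {
  net <- two_state_network(mean_f = 1.4, mean_u = 1.3)
  p <- simulate_state_path(net, 3e3, force_pN = 8.5, seed = 5)
  dur <- diff(p$entry_time_s)
  d_f <- dur[p$label[-nrow(p)] == "F"]
  expect_gt(length(d_f), 1e3)
  expect_lt(abs(mean(d_f) - 1.4), 3 * 1.4 / sqrt(length(d_f)))
  ks <- suppressWarnings(ks.test(d_f, pexp, rate = 1 / 1.4))
  expect_gt(ks$p.value, 0.01)
})

test_that("Bell-sensitive edges shift occupancy with force as constructed", {
  net <- two_state_network(mean_f = 1.35, mean_u = 1.35, bell = TRUE)
  occ <- sapply(c(7.5, 9.5), function(f) {
    p <- simulate_state_path(net, 1500, force_pN = f, seed = 17)
    dur <- diff(c(p$entry_time_s, attr(p, "duration_s")))
    sum(dur[p$label == "F"]) / sum(dur)
  })
  expect_gt(occ[1], 0.9)
  expect_lt(occ[2], 0.1)
})

test_that("rendering reproduces levels, sample counts and noise variances", {
  # noise-free: exact piecewise-constant square wave at the level offsets
  net <- two_state_network(dvar_u = 0)
  p <- simulate_state_path(net, 30, force_pN = 8.5, seed = 2)
  tr0 <- render_trajectory(p, observation_spec(sampling_rate_hz = 500,
                                               baseline_sd_nm = 0),
                           conformations = net$conformations, seed = 3)
  expect_equal(nrow(tr0), 30 * 500)
  expect_true(all(tr0$extension_nm %in% c(0, 18.2)))
  # sample-count conservation against the protocol duration
  prot <- force_protocol(c(10, 5, 15), c(8.5, 4, 8.5))
  p2 <- simulate_state_path(net, force_protocol = prot, seed = 4)
  tr2 <- render_trajectory(p2, observation_spec(sampling_rate_hz = 333),
                           conformations = net$conformations, seed = 5)
  expect_equal(nrow(tr2), 30 * 333)
  expect_equal(tr2$force_pN[c(1000, 4000, 8000)], c(8.5, 4, 8.5))

  # baseline-only noise variance within 3 s.e. of 0.85^2
  one <- network_from_tables(data.frame(label = "F", dz_nm = 0, dvar_nm2 = 0),
                             NULL)
  pf <- simulate_state_path(one, 100, force_pN = 8.5, seed = 6)
  trf <- render_trajectory(pf, observation_spec(sampling_rate_hz = 1000,
                                                baseline_sd_nm = 0.85),
                           conformations = data.frame(label = "F", dz_nm = 0,
                                                      dvar_nm2 = 0),
                           seed = 7)
  n <- nrow(trf)
  se_var <- 0.7225 * sqrt(2 / (n - 1))
  expect_lt(abs(var(trf$extension_nm) - 0.7225), 3 * se_var)

  # U-state excess variance from the FJC forward model for 42.5 nm at 8.5 pN
  v_u <- 42.5 * fjc_variance_factor(8.5)
  oneu <- network_from_tables(data.frame(label = "U", dz_nm = 18.2,
                                         dvar_nm2 = v_u), NULL)
  pu <- simulate_state_path(oneu, 100, force_pN = 8.5, initial = "U", seed = 8)
  tru <- render_trajectory(pu, observation_spec(sampling_rate_hz = 1000,
                                                baseline_sd_nm = 0.85),
                           conformations = oneu$conformations, seed = 9)
  tot <- v_u + 0.7225
  n <- nrow(tru)
  expect_lt(abs(var(tru$extension_nm) - tot), 3 * tot * sqrt(2 / (n - 1)))
})

test_that("finite transition-path ramps interpolate between levels", {
  net <- two_state_network(dvar_u = 0)
  p <- simulate_state_path(net, 30, force_pN = 8.5, seed = 10)
  tr <- render_trajectory(p, observation_spec(sampling_rate_hz = 500,
                                              baseline_sd_nm = 0,
                                              transition_path_duration_s = 0.05),
                          conformations = net$conformations, seed = 11)
  mid <- tr$extension_nm > 0.5 & tr$extension_nm < 17.7
  expect_gt(sum(mid), 0)                       # ramp samples exist
  expect_true(all(tr$extension_nm >= 0 & tr$extension_nm <= 18.2))
})

test_that("drift options move the baseline as configured", {
  one <- network_from_tables(data.frame(label = "F", dz_nm = 0, dvar_nm2 = 0),
                             NULL)
  p <- simulate_state_path(one, 100, force_pN = 8.5, seed = 1)
  tr <- render_trajectory(p, observation_spec(sampling_rate_hz = 100,
                                              baseline_sd_nm = 0,
                                              drift_rate_nm_s = 0.01),
                          conformations = one$conformations, seed = 2)
  expect_equal(max(tr$extension_nm), 0.01 * (nrow(tr) - 0.5) / 100,
               tolerance = 1e-10)
})
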