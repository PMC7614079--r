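test_that("fragment statistics recover construction on constant fragments", {
  id <- alternating_idealization(dur_a = 1, dur_b = 1, n_cycles = 5)
  tr <- square_wave_trajectory(c(0, 18.2), dwell_s = 1, fs = 100, n_cycles = 5)
  fr <- fragment_statistics(id, tr, "N")
  expect_equal(fr$dz_nm[fr$label == "U"], rep(18.2, 5))
  expect_equal(fr$dvar_nm2[fr$label == "U"], rep(0, 5))
  expect_equal(fr$dz_nm[fr$label == "N"], rep(0, 5))
  expect_error(fragment_statistics(id, tr, "X"), "absent")
})

test_that("mean excess variance of generated U fragments matches the generator", {
  V <- 5.8
  tr <- two_state_trajectory(duration = 300, fs = 1000, seed = 61, dvar_u = V)
  id <- label_and_excise(tr, thresholds(c(0, 18.2)))
  fr <- fragment_statistics(id, tr, "N")
  u <- fr[fr$label == "U" & !fr$censored, ]
  n_samp <- sum(u$end - u$start + 1)
  m <- weighted.mean(u$dvar_nm2, u$duration_s)
  # sampling error of a variance over ~n_samp effective samples
  se <- (V + 0.7225) * sqrt(2 / n_samp)
  expect_lt(abs(m - V), 3 * se)
})

test_that("state summary is Table-shaped: zero reference row, FJC conversion, fractions", {
  V <- 42.5 * fjc_variance_factor(8.5)
  tr <- two_state_trajectory(duration = 400, fs = 1000, seed = 71, dvar_u = V)
  id <- label_and_excise(tr, thresholds(c(0, 18.2)))
  fr <- fragment_statistics(id, tr, "N")
  su <- summarize_state(fr, force = 8.5)
  expect_equal(su$dz_nm[su$label == "N"], 0)
  expect_equal(su$dvar_nm2[su$label == "N"], 0)
  expect_equal(su$lc_nm[su$label == "N"], 0)
  # forward/inverse round trip plus sampling error: within 2%
  expect_lt(abs(su$lc_nm[su$label == "U"] - 42.5) / 42.5, 0.02)
  expect_equal(su$lc_pct[su$label == "U"], 100)
  # explicit reference: the tabulated M2 ratio
  expect_equal(unstructured_fraction(25.2, 42.5), 100 * 25.2 / 42.5)
  su2 <- summarize_state(fr, force = 8.5, reference_Lc = 42.5)
  expect_equal(su2$lc_pct[su2$label == "U"],
               100 * su2$lc_nm[su2$label == "U"] / 42.5)
})

test_that("few-fragment conformations are flagged low_n", {
  id <- alternating_idealization(dur_a = 2, dur_b = 2, n_cycles = 2)
  tr <- square_wave_trajectory(c(0, 18.2), dwell_s = 2, fs = 100, n_cycles = 2)
  fr <- fragment_statistics(id, tr, "N")
  su <- summarize_state(fr, force = 8.5)
  expect_true(all(su$low_n))
})

test_that("transition-path excision lowers the measured fragment variance", {
  # finite 40 ms ramps: naive segmentation (midpoint crossing, no excision)
  # inflates the variance relative to the excised idealization
  net <- two_state_network(dvar_u = 0)
  p <- simulate_state_path(net, 120, force_pN = 8.5, seed = 81)
  tr <- render_trajectory(p, observation_spec(sampling_rate_hz = 500,
                                              baseline_sd_nm = 0.4,
                                              transition_path_duration_s = 0.04),
                          conformations = net$conformations, seed = 82)
  id <- label_and_excise(tr, thresholds(c(0, 18.2)))
  fr <- fragment_statistics(id, tr, "N")
  u <- fr[fr$label == "U", ]
  excised <- weighted.mean(u$dvar_nm2, u$duration_s)
  naive_lab <- ifelse(tr$extension_nm > 9.1, "U", "N")
  naive_var <- var(tr$extension_nm[naive_lab == "U"]) -
    var(tr$extension_nm[naive_lab == "N"])
  expect_lt(excised, naive_var)
})

test_that("region classification rules match the catalog signatures", {
  expect_identical(classify_region(c(0, 18.2), 0.5), "i")
  expect_identical(classify_region(c(0.4, 17.9), 0.97), "ii")
  expect_identical(classify_region(5.4), "iii")
  expect_identical(classify_region(15.6), "iv")
  expect_identical(classify_region(c(3.3, 7.6, 14.9)), "v")
  expect_identical(classify_region(c(7.45, 14.3)), "vi")
  expect_identical(classify_region(c(0, 9)), "unknown")
  expect_identical(classify_region(25), "unknown")
})

test_that("classification accuracy >= 95% on a labeled synthetic corpus", {
  # 100 stretches spanning all six regions, fixed seed. Multi-conformation
  # regions are simulated with their internal kinetics balanced enough that
  # every conformation is populated within the stretch (as in force-probed
  # recordings); single-conformation regions are plain noisy levels.
  confs <- talin_conformations(include_trans = TRUE)
  cf <- function(labs) confs[match(labs, confs$label),
                             c("label", "dz_nm", "dvar_nm2")]
  make_stretch <- function(region, seed) {
    fs <- 500
    switch(region,
      i = two_state_trajectory(duration = 40, fs = fs, seed = seed),
      ii = {
        net <- two_state_network(mean_f = 0.3, mean_u = 3.2)
        p <- simulate_state_path(net, 60, force_pN = 8.5, initial = "U",
                                 seed = seed)
        render_trajectory(p, observation_spec(sampling_rate_hz = fs),
                          conformations = net$conformations, seed = seed + 1)
      },
      iii = {
        net <- network_from_tables(cf("I"), NULL)
        p <- simulate_state_path(net, 8, force_pN = 8.5, seed = seed)
        render_trajectory(p, observation_spec(sampling_rate_hz = fs),
                          conformations = net$conformations, seed = seed + 1)
      },
      iv = {
        net <- network_from_tables(cf("H"), NULL)
        p <- simulate_state_path(net, 30, force_pN = 8.5, seed = seed)
        render_trajectory(p, observation_spec(sampling_rate_hz = fs),
                          conformations = net$conformations, seed = seed + 1)
      },
      v = {
        tt <- data.frame(from = c("L1", "L2", "L2", "L3"),
                         to = c("L2", "L1", "L3", "L2"),
                         mean_time_s = c(0.4, 0.4, 0.6, 0.5))
        net <- network_from_tables(cf(c("L1", "L2", "L3")), tt)
        p <- simulate_state_path(net, 60, force_pN = 8.5, initial = "L2",
                                 seed = seed)
        render_trajectory(p, observation_spec(sampling_rate_hz = fs),
                          conformations = net$conformations, seed = seed + 1)
      },
      vi = {
        tt <- data.frame(from = c("M1", "M2"), to = c("M2", "M1"),
                         mean_time_s = c(0.91, 0.25))
        net <- network_from_tables(cf(c("M1", "M2")), tt)
        p <- simulate_state_path(net, 60, force_pN = 8.5, initial = "M1",
                                 seed = seed)
        render_trajectory(p, observation_spec(sampling_rate_hz = fs),
                          conformations = net$conformations, seed = seed + 1)
      })
  }
  regions <- rep(c("i", "ii", "iii", "iv", "v", "vi"),
                 c(17, 17, 17, 17, 16, 16))
  calls <- mapply(function(r, s) classify_stretch(make_stretch(r, s)),
                  regions, 1000 + seq_along(regions) * 7)
  expect_gte(mean(calls == regions), 0.95)
})
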