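#' Pooled transition table across recordings
#'
#' Pools the directed transition events of one or more idealized recordings
#' into a kinetic table: mean waiting time preceding each directed
#' transition, standard error, and event count (the shape of the measured
#' kinetic network).
#'
#' @param ideals An `idealization` or a list of them.
#' @return data.frame of class `transition_table`: `from`, `to`, `mean_s`,
#'   `sem_s`, `n`. Empty idealizations give an empty table.
#' @export
build_transition_table <- function(ideals) {
  if (inherits(ideals, "idealization")) ideals <- list(ideals)
  evs <- lapply(seq_along(ideals), function(i) {
    ev <- transition_events(ideals[[i]])
    if (nrow(ev)) ev$recording <- i
    ev
  })
  ev <- do.call(rbind, evs[vapply(evs, nrow, 0L) > 0])
  if (is.null(ev) || !nrow(ev)) {
    out <- data.frame(from = character(), to = character(), mean_s = numeric(),
                      sem_s = numeric(), n = integer())
    class(out) <- c("transition_table", "data.frame")
    return(out)
  }
  evc <- ev[!is.na(ev$dwell_s), , drop = FALSE]
  key <- paste(evc$from, evc$to, sep = "\r")
  sp <- split(evc$dwell_s, key)
  out <- data.frame(
    from = sub("\r.*", "", names(sp)),
    to = sub(".*\r", "", names(sp)),
    mean_s = vapply(sp, mean, 0),
    sem_s = vapply(sp, function(x)
      if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_, 0),
    n = lengths(sp), stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$from, out$to), , drop = FALSE]
  attr(out, "events") <- ev
  class(out) <- c("transition_table", "data.frame")
  out
}

#' Running unfolded fraction over a sliding transition window
#'
#' Computes `P_U = <t_U> / (<t_U> + <t_F>)` over a sliding window of `n`
#' consecutive folding/unfolding transitions (stride one transition), where
#' `<t_U>` and `<t_F>` are the mean unfolded and folded dwell times inside
#' the window. An abrupt, sustained change in this series is the signature
#' of a proline cis-trans isomer switch.
#'
#' @param ideal An `idealization` containing the folded/unfolded dynamics.
#' @param n Window size in transitions (default 10).
#' @param folded_label,unfolded_label Conformation labels.
#' @return data.frame of class `pu_series`: `window`, `t_s` (time of the
#'   window's last transition), `p_u`, `mean_t_u`, `mean_t_f`. Empty (with a
#'   warning) when the recording has fewer than `n` transitions.
#' @export
running_unfolded_fraction <- function(ideal, n = 10, folded_label = "N",
                                      unfolded_label = "U") {
  seg <- ideal$segments
  dw <- seg[seg$label %in% c(folded_label, unfolded_label), , drop = FALSE]
  nt <- nrow(dw) - 1L
  empty <- data.frame(window = integer(), t_s = numeric(), p_u = numeric(),
                      mean_t_u = numeric(), mean_t_f = numeric())
  class(empty) <- c("pu_series", "data.frame")
  if (nt < n) {
    warning("fewer than n = ", n, " transitions; empty running series")
    return(empty)
  }
  nw <- nrow(dw) - n
  rows <- vector("list", nw)
  for (i in seq_len(nw)) {
    j <- i:(i + n)                       # n + 1 dwells = n transitions
    d <- dw[j, ]
    tu <- mean(d$duration_s[d$label == unfolded_label])
    tf <- mean(d$duration_s[d$label == folded_label])
    rows[[i]] <- c(t_s = d$t_end_s[nrow(d) - 1L], p_u = tu / (tu + tf),
                   mean_t_u = tu, mean_t_f = tf)
  }
  m <- do.call(rbind, rows)
  out <- data.frame(window = seq_len(nw), m)
  class(out) <- c("pu_series", "data.frame")
  out
}

#' Detect isomer switches in a running unfolded-fraction series
#'
#' Hysteresis change detector for the trans-proline state: a switch onset is
#' declared when `P_U` stays at or above `high_cut` for at least
#' `min_windows` consecutive windows, and the switch ends when `P_U` stays
#' at or below `low_cut` likewise. An event still open at the end of the
#' series gets `offset_s = NA`.
#'
#' @param pu A `pu_series` from [running_unfolded_fraction()].
#' @param high_cut,low_cut Hysteresis cutoffs on `P_U`.
#' @param min_windows Minimal run length of windows beyond a cutoff.
#' @return data.frame: `onset_s`, `offset_s`, `duration_s` (one row per
#'   switch event; zero rows when none).
#' @export
detect_isomer_switches <- function(pu, high_cut = 0.8, low_cut = 0.6,
                                   min_windows = 3) {
  stopifnot(high_cut > low_cut)
  out <- data.frame(onset_s = numeric(), offset_s = numeric(),
                    duration_s = numeric())
  if (!nrow(pu)) return(out)
  hi <- pu$p_u >= high_cut
  lo <- pu$p_u <= low_cut
  state <- 0L    # 0 = cis, 1 = trans
  run_hi <- 0L; run_lo <- 0L
  onset <- NA_real_
  for (i in seq_len(nrow(pu))) {
    run_hi <- if (hi[i]) run_hi + 1L else 0L
    run_lo <- if (lo[i]) run_lo + 1L else 0L
    if (state == 0L && run_hi >= min_windows) {
      state <- 1L
      onset <- pu$t_s[i - min_windows + 1L]
    } else if (state == 1L && run_lo >= min_windows) {
      state <- 0L
      off <- pu$t_s[i - min_windows + 1L]
      out <- rbind(out, data.frame(onset_s = onset, offset_s = off,
                                   duration_s = off - onset))
      onset <- NA_real_
    }
  }
  if (state == 1L)
    out <- rbind(out, data.frame(onset_s = onset, offset_s = NA_real_,
                                 duration_s = NA_real_))
  out
}

#' Fit a force-independent isomerization rate
#'
#' Models the observed per-force switching rate as
#' `r(F) = P_U(F) * k`, where `P_U(F)` is the independently measured
#' unfolded fraction and `k` the intrinsic (force-independent)
#' isomerization rate of the unfolded chain. Per-force rates are estimated
#' as events per observation time; `k` is the least-squares slope of
#' `r ~ 0 + P_U`.
#'
#' @param switch_counts Integer switch events per force.
#' @param observation_time_s Observation time per force, s (all > 0).
#' @param p_u Unfolded fraction per force, in `[0, 1]`.
#' @param force_pN Optional force labels carried into the output.
#' @return List of class `isomer_fit`: `k_per_s`, `timescale_s = 1/k`,
#'   `rates` (per-force data.frame), `identifiable`.
#' @export
fit_isomerization_rate <- function(switch_counts, observation_time_s, p_u,
                                   force_pN = NULL) {
  stopifnot(length(switch_counts) == length(observation_time_s),
            length(p_u) == length(switch_counts))
  if (length(p_u) < 3) stop("need at least 3 force points")
  if (any(observation_time_s <= 0)) stop("zero or negative observation time")
  if (any(p_u < 0 | p_u > 1)) stop("p_u must lie in [0, 1]")
  r <- switch_counts / observation_time_s
  identifiable <- any(p_u > 0)
  k <- if (identifiable) sum(p_u * r) / sum(p_u^2) else NA_real_
  if (!identifiable)
    warning("P_U is zero at all forces: isomerization rate unidentifiable")
  out <- list(k_per_s = k,
              timescale_s = if (identifiable) 1 / k else NA_real_,
              rates = data.frame(force_pN = force_pN %||% NA_real_,
                                 rate_per_s = r, p_u = p_u,
                                 sem_per_s = sqrt(switch_counts) /
                                   observation_time_s),
              identifiable = identifiable)
  class(out) <- "isomer_fit"
  out
}

#' @export
print.isomer_fit <- function(x, ...) {
  cat(sprintf("Isomerization fit: k = %.4g 1/s (timescale %.4g s)\n",
              x$k_per_s, x$timescale_s))
  invisible(x)
}

#' Folded fraction versus force and coexistence-force fit
#'
#' Computes the occupancy-based folded fraction (time in the folded
#' conformation over time in folded + unfolded, censored dwells included)
#' of idealized recordings held at different forces, and fits a
#' two-parameter logistic force response
#' `f(F) = 1 / (1 + exp((F - F_0.5) / w))`, returning the coexistence force
#' `F_0.5` and the width `w` (the 10-90% width is `w * ln 81`).
#'
#' @param ideals List of `idealization`s, one per force (or a data.frame
#'   with columns `force_pN`, `folded_fraction` to fit directly).
#' @param forces Forces in pN matching `ideals`.
#' @param folded_label,unfolded_label Conformation labels.
#' @return List of class `force_response`: `data` (per-force fractions),
#'   `f05_pN`, `width_pN`, `width_10_90_pN`.
#' @export
folded_fraction_vs_force <- function(ideals, forces = NULL,
                                     folded_label = "N",
                                     unfolded_label = "U") {
  if (is.data.frame(ideals)) {
    dat <- data.frame(force_pN = ideals$force_pN,
                      folded_fraction = ideals$folded_fraction)
  } else {
    stopifnot(length(ideals) == length(forces))
    frac <- vapply(ideals, function(id) {
      dw <- id$segments[id$segments$label %in% c(folded_label, unfolded_label), ]
      tf <- sum(dw$duration_s[dw$label == folded_label])
      tf / sum(dw$duration_s)
    }, 0)
    dat <- data.frame(force_pN = forces, folded_fraction = frac)
  }
  if (nrow(dat) < 4 && length(unique(dat$folded_fraction)) < 3)
    stop("need at least 4 forces spanning the transition (or 3 distinct fractions)")
  if (all(dat$folded_fraction == 0) || all(dat$folded_fraction == 1))
    stop("degenerate folded fractions (all 0 or 1): logistic fit impossible")
  fit <- suppressWarnings(
    glm(folded_fraction ~ force_pN, family = quasibinomial("logit"), data = dat))
  b <- coef(fit)
  if (!is.finite(b[2]) || b[2] >= 0)
    stop("folded fraction does not decrease with force: no coexistence fit")
  f05 <- -b[[1]] / b[[2]]
  width <- -1 / b[[2]]
  out <- list(data = dat, f05_pN = f05, width_pN = width,
              width_10_90_pN = width * log(81))
  class(out) <- "force_response"
  out
}

#' @export
print.force_response <- function(x, ...) {
  cat(sprintf("Force response: F_0.5 = %.3f pN, 10-90%% width = %.2f pN (%d forces)\n",
              x$f05_pN, x$width_10_90_pN, nrow(x$data)))
  invisible(x)
}

#' Did a recording recover native two-state folding dynamics?
#'
#' Success criterion for a rescue trial: at least `min_transitions`
#' transitions between the folded and unfolded conformations within
#' `window_s` of the start of the post-pulse stretch.
#'
#' @param ideal Idealization of the post-pulse stretch.
#' @param min_transitions Minimal number of native transitions.
#' @param window_s Post-pulse observation window, s.
#' @param folded_label,unfolded_label Conformation labels.
#' @return Logical.
#' @export
native_dynamics_recovered <- function(ideal, min_transitions = 5,
                                      window_s = 200, folded_label = "N",
                                      unfolded_label = "U") {
  ev <- transition_events(ideal)
  if (!nrow(ev)) return(FALSE)
  t0 <- ideal$segments$t_start_s[1]
  native <- ev$from %in% c(folded_label, unfolded_label) &
    ev$to %in% c(folded_label, unfolded_label) &
    ev$t_s <= t0 + window_s
  sum(native) >= min_transitions
}

#' Rescue probability per force
#'
#' Binomial summary of force-pulse rescue trials: the probability that a
#' high-force pulse returned the molecule to its native folding dynamics,
#' per pulse force, with the standard error of the proportion.
#'
#' @param outcomes data.frame with columns `force_pN` and logical `rescued`
#'   (one row per trial).
#' @return data.frame: `force_pN`, `n_trials`, `n_rescued`, `probability`,
#'   `sem`.
#' @export
rescue_probability <- function(outcomes) {
  stopifnot(is.data.frame(outcomes),
            all(c("force_pN", "rescued") %in% names(outcomes)))
  if (!nrow(outcomes)) stop("need at least one trial")
  sp <- split(outcomes$rescued, outcomes$force_pN)
  out <- data.frame(
    force_pN = as.numeric(names(sp)),
    n_trials = lengths(sp),
    n_rescued = vapply(sp, sum, 0L),
    row.names = NULL
  )
  out$probability <- out$n_rescued / out$n_trials
  out$sem <- sqrt(out$probability * (1 - out$probability) / out$n_trials)
  out[order(out$force_pN), , drop = FALSE]
}
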