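#' Force protocol
#'
#' Ordered constant-force segments describing how the applied force evolves
#' over a recording, e.g. a coexistence-force hold, a quench to low force,
#' or a brief high-force rescue pulse.
#'
#' @param duration_s Segment durations in s (strictly positive).
#' @param force_pN Segment forces in pN (non-negative), same length.
#' @return A data.frame of class `force_protocol` with segment start/end times.
#' @examples
#' # hold at 8.5 pN, quench to 4 pN, 15 s rescue pulse at 15 pN, back to 8.5
#' force_protocol(c(500, 7200, 15, 500), c(8.5, 4, 15, 8.5))
#' @export
force_protocol <- function(duration_s, force_pN) {
  stopifnot(length(duration_s) == length(force_pN), length(duration_s) >= 1)
  if (any(!is.finite(duration_s)) || any(duration_s <= 0))
    stop("segment durations must be strictly positive")
  if (any(!is.finite(force_pN)) || any(force_pN < 0))
    stop("segment forces must be non-negative")
  t_end <- cumsum(duration_s)
  out <- data.frame(duration_s = duration_s, force_pN = force_pN,
                    t_start_s = c(0, head(t_end, -1)), t_end_s = t_end)
  class(out) <- c("force_protocol", "data.frame")
  out
}

#' Observation model for rendered trajectories
#'
#' Describes how a true conformational state path is turned into a sampled
#' extension recording: camera sampling rate, instrument point-spread noise,
#' optional drift and optional finite-duration transition paths.
#'
#' @param sampling_rate_hz Sampling rate, Hz (camera frame rates of
#'   1,000-1,600 Hz are typical; lower values are useful for quick tests).
#' @param baseline_sd_nm Instrument/bead point-spread noise sd, nm
#'   (default 0.85 nm, the reference-bead value). Per-conformation noise is
#'   `sqrt(baseline^2 + excess variance)`.
#' @param drift_rate_nm_s Linear drift, nm/s (default 0: the instrument is
#'   driftless on these timescales).
#' @param drift_amplitude_nm,drift_period_s Optional slow sinusoidal drift
#'   used to exercise robustness of the analysis; amplitude 0 disables it.
#' @param transition_path_duration_s Duration of a linear ramp between
#'   conformation levels at each transition (default 0: instantaneous jumps;
#'   a finite value, e.g. 0.002 s, exercises transition-path excision).
#' @param noise `"white"` (default) or `"ar1"` for noise with an exponential
#'   correlation time `ar_tau_s` (bead relaxation).
#' @param ar_tau_s Correlation time of AR(1) noise, s.
#' @return An `observation_spec` list.
#' @export
observation_spec <- function(sampling_rate_hz = 1500, baseline_sd_nm = 0.85,
                             drift_rate_nm_s = 0, drift_amplitude_nm = 0,
                             drift_period_s = 100,
                             transition_path_duration_s = 0,
                             noise = c("white", "ar1"), ar_tau_s = 0.01) {
  noise <- match.arg(noise)
  stopifnot(sampling_rate_hz > 0, baseline_sd_nm >= 0,
            transition_path_duration_s >= 0, ar_tau_s > 0)
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 baseline_sd_nm = baseline_sd_nm,
                 drift_rate_nm_s = drift_rate_nm_s,
                 drift_amplitude_nm = drift_amplitude_nm,
                 drift_period_s = drift_period_s,
                 transition_path_duration_s = transition_path_duration_s,
                 noise = noise, ar_tau_s = ar_tau_s),
            class = "observation_spec")
}

# edge rates at a given force, applying Bell rescaling where configured
.edge_rates_at <- function(edges, force, kT) {
  r <- edges$rate_per_s
  fd <- which(edges$delta_x_nm != 0 & !is.na(edges$ref_force_pN))
  if (length(fd)) {
    r[fd] <- r[fd] * exp(edges$direction[fd] * (force - edges$ref_force_pN[fd]) *
                           edges$delta_x_nm[fd] / kT)
  }
  r
}

#' Simulate a conformational state path (Gillespie)
#'
#' Realizes the continuous-time Markov jump process defined by a kinetic
#' network: exponential dwell in each conformation with its total exit rate,
#' next conformation chosen proportionally to the outgoing edge rates.
#' Under a force protocol, Bell-sensitive edges are rescaled per segment;
#' the process is memoryless, so the clock is simply redrawn at segment
#' boundaries.
#'
#' @param network A `kinetic_network`.
#' @param duration_s Total duration, s (ignored when `force_protocol` is
#'   given, which fixes the duration).
#' @param force_protocol Optional [force_protocol()]; default is a single
#'   constant-force segment at `force_pN`.
#' @param force_pN Constant force when no protocol is given, pN.
#' @param initial Label of the starting conformation (default: first in the
#'   network).
#' @param seed Integer seed for reproducibility (same seed, same path).
#' @return A data.frame of class `state_path` with columns `label`,
#'   `entry_time_s`, and attributes `duration_s` and `force_protocol`.
#' @examples
#' net <- talin_network("i")
#' p <- simulate_state_path(net, 100, force_pN = 8.5, seed = 1)
#' @export
simulate_state_path <- function(network, duration_s = NULL,
                                force_protocol = NULL, force_pN = 8.5,
                                initial = NULL, seed = NULL) {
  stopifnot(inherits(network, "kinetic_network"))
  if (is.null(force_protocol)) {
    if (is.null(duration_s) || duration_s <= 0)
      stop("`duration_s` must be positive when no force protocol is given")
    force_protocol <- force_protocol(duration_s, force_pN)
  }
  total <- sum(force_protocol$duration_s)
  labs <- network$conformations$label
  initial <- initial %||% labs[1]
  if (!initial %in% labs) stop("unknown initial conformation: ", initial)
  kT <- 4.11
  edges <- network$edges
  edge_from <- match(edges$from, labs)
  edge_to <- match(edges$to, labs)
  # warn once about absorbing conformations
  no_exit <- setdiff(seq_along(labs), unique(edge_from))
  if (length(no_exit) && nrow(edges) > 0)
    warning("absorbing conformation(s) with no exit: ",
            paste(labs[no_exit], collapse = ", "))

  with_seed(seed, {
    cap <- 1024L
    out_lab <- integer(cap); out_t <- numeric(cap)
    m <- 1L
    cur <- match(initial, labs)
    out_lab[1] <- cur; out_t[1] <- 0
    for (s in seq_len(nrow(force_protocol))) {
      t <- force_protocol$t_start_s[s]
      t_end <- force_protocol$t_end_s[s]
      rates <- .edge_rates_at(edges, force_protocol$force_pN[s], kT)
      # per-conformation exit structure for this segment
      out_idx <- split(seq_len(nrow(edges)), edge_from)
      repeat {
        ex <- out_idx[[as.character(cur)]]
        if (is.null(ex) || !length(ex)) { t <- t_end } else {
          R <- sum(rates[ex])
          t <- t + rexp(1L, R)
        }
        if (t >= t_end) break
        cur <- if (length(ex) == 1L) edge_to[ex] else
          edge_to[ex[sample.int(length(ex), 1L, prob = rates[ex])]]
        m <- m + 1L
        if (m > cap) {
          cap <- cap * 2L
          length(out_lab) <- cap; length(out_t) <- cap
        }
        out_lab[m] <- cur; out_t[m] <- t
      }
    }
    path <- data.frame(label = labs[out_lab[seq_len(m)]],
                       entry_time_s = out_t[seq_len(m)],
                       stringsAsFactors = FALSE)
    attr(path, "duration_s") <- total
    attr(path, "force_protocol") <- force_protocol
    class(path) <- c("state_path", "data.frame")
    path
  })
}

#' Render a state path into a sampled extension trajectory
#'
#' Turns a true conformational path into a magnetic-tweezers-like recording:
#' each sample gets the extension offset of the occupied conformation plus
#' Gaussian observation noise with sd `sqrt(baseline^2 + excess variance)`,
#' optional drift, and (optionally) a finite linear ramp at each transition
#' standing in for the diffusive transition path. Only the unstructured part
#' of the chain contributes to the excess variance, which is what makes the
#' per-conformation noise level a structural fingerprint.
#'
#' @param path A `state_path` from [simulate_state_path()].
#' @param observation An [observation_spec()].
#' @param conformations data.frame with `label`, `dz_nm`, `dvar_nm2` (e.g.
#'   [talin_conformations()]); must cover every label in the path.
#' @param seed Integer seed (noise realization).
#' @return A [trajectory()] with the true path attached as attribute
#'   `true_path` (ground truth for recovery tests).
#' @examples
#' net <- talin_network("i")
#' p <- simulate_state_path(net, 20, force_pN = 8.5, seed = 1)
#' tr <- render_trajectory(p, observation_spec(sampling_rate_hz = 200), seed = 2)
#' @export
render_trajectory <- function(path, observation = observation_spec(),
                              conformations = talin_conformations(),
                              seed = NULL) {
  stopifnot(inherits(path, "state_path"), nrow(path) >= 1)
  idx <- match(path$label, conformations$label)
  if (anyNA(idx)) stop("path labels missing from `conformations`: ",
                       paste(unique(path$label[is.na(idx)]), collapse = ", "))
  fs <- observation$sampling_rate_hz
  duration <- attr(path, "duration_s")
  n <- round(duration * fs)
  t <- (seq_len(n) - 0.5) / fs     # mid-frame timestamps
  seg <- findInterval(t, path$entry_time_s)
  seg[seg < 1L] <- 1L
  off <- conformations$dz_nm[idx]
  sds <- sqrt(observation$baseline_sd_nm^2 + conformations$dvar_nm2[idx])
  mean_z <- off[seg]
  sd_z <- sds[seg]
  tp <- observation$transition_path_duration_s
  if (tp > 0 && nrow(path) > 1) {
    since <- t - path$entry_time_s[seg]
    ramp <- pmin(1, since / tp)
    prev_off <- c(off[1], off[-length(off)])[seg]
    mean_z <- prev_off + (mean_z - prev_off) * ramp
  }
  with_seed(seed, {
    eps <- rnorm(n)
    if (observation$noise == "ar1") {
      phi <- exp(-1 / (fs * observation$ar_tau_s))
      eps <- as.numeric(stats::filter(eps * sqrt(1 - phi^2), phi,
                                      method = "recursive"))
    }
    z <- mean_z + sd_z * eps
    if (observation$drift_rate_nm_s != 0)
      z <- z + observation$drift_rate_nm_s * t
    if (observation$drift_amplitude_nm != 0)
      z <- z + observation$drift_amplitude_nm *
        sin(2 * pi * t / observation$drift_period_s)
    prot <- attr(path, "force_protocol")
    f <- if (is.null(prot)) NA_real_ else
      prot$force_pN[pmax(1L, findInterval(t, prot$t_start_s))]
    tr <- trajectory(t, z, f, sampling_rate = fs, molecule_id = "synthetic")
    attr(tr, "true_path") <- path
    attr(tr, "observation") <- observation
    tr
  })
}

#' Quartic double-well free-energy profile
#'
#' Analytic double-well landscape
#' \eqn{G(z) = B\,[((z - c)^2/a^2 - 1)^2]} with minima `separation_nm`
#' apart, barrier exactly `barrier_kT` at the midpoint, used as ground truth
#' for landscape-reconstruction tests.
#'
#' @param barrier_kT Barrier height in kT.
#' @param separation_nm Distance between the two basins, nm.
#' @param z_min Position of the lower basin, nm.
#' @param grid_step_nm Grid step for the tabulated profile, nm.
#' @param pad_nm Grid padding beyond the minima, nm.
#' @return List with `grid_nm`, `free_energy_kT`, `density` (Boltzmann
#'   density, normalized to sum 1 over the grid), and the parameters.
#' @export
double_well_landscape <- function(barrier_kT = 4, separation_nm = 18.2,
                                  z_min = 0, grid_step_nm = 0.01,
                                  pad_nm = 8) {
  a <- separation_nm / 2
  cc <- z_min + a
  grid <- seq(z_min - pad_nm, z_min + separation_nm + pad_nm, by = grid_step_nm)
  G <- barrier_kT * (((grid - cc)^2 / a^2) - 1)^2
  p <- exp(-G)
  p <- p / sum(p)
  list(grid_nm = grid, free_energy_kT = G, density = p,
       barrier_kT = barrier_kT, separation_nm = separation_nm, z_min = z_min)
}

#' Sample noisy extension values from a free-energy landscape
#'
#' Draws i.i.d. extensions from the Boltzmann density of a tabulated
#' landscape (inverse-CDF on the fine grid, with uniform jitter within a
#' grid cell) and adds Gaussian measurement noise, emulating the measured
#' extension histogram of an equilibrium recording.
#'
#' @param landscape Output of [double_well_landscape()] (or any list with
#'   `grid_nm` and `density`).
#' @param n Number of samples.
#' @param noise_sd_nm Gaussian point-spread noise sd, nm.
#' @param seed Integer seed.
#' @return Numeric vector of extensions, nm.
#' @export
sample_extensions <- function(landscape, n, noise_sd_nm = 0.85, seed = NULL) {
  with_seed(seed, {
    i <- sample.int(length(landscape$grid_nm), n, replace = TRUE,
                    prob = landscape$density)
    step <- diff(landscape$grid_nm[1:2])
    z <- landscape$grid_nm[i] + runif(n, -step / 2, step / 2)
    z + rnorm(n, 0, noise_sd_nm)
  })
}
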