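#' Conformational catalog of the talin R3 domain
#'
#' The nine conformations that make up the six regions (states i-vi) of the
#' talin R3 conformational space observed in long equilibrium recordings at
#' the coexistence force, with their measured end-to-end extension offsets
#' and excess variances relative to the folded conformation `F`, and the
#' unstructured contour lengths derived from the FJC fluctuation model.
#'
#' Columns: `label` (conformation), `state` (region, roman numeral),
#' `dz_nm`/`dz_sd` (extension offset relative to F), `dvar_nm2`/`dvar_sd`
#' (excess variance), `lc_nm`/`lc_sd` (unstructured contour length),
#' `lc_pct`/`lc_pct_sd` (fraction of unstructured sequence, normalized by
#' the 42.5 nm increment of the unfolded state).
#'
#' @param include_trans Also include the proline trans-isomer conformations
#'   `F_trans`/`U_trans` (state ii), which share the observables of `F`/`U`
#'   but not their kinetics, so that the catalog covers every endpoint of
#'   [talin_transition_times()].
#' @return A data.frame, one row per conformation.
#' @export
talin_conformations <- function(include_trans = FALSE) {
  out <- data.frame(
    label      = c("F", "U", "I", "H", "L1", "L2", "L3", "M1", "M2"),
    state      = c("i", "i", "iii", "iv", "v", "v", "v", "vi", "vi"),
    dz_nm      = c(0, 18.2, 5.4, 15.6, 3.3, 7.6, 14.9, 7.45, 14.3),
    dz_sd      = c(0, 0.7, 0.5, 0.3, 0.5, 0.7, 0.6, 0.2, 0.1),
    dvar_nm2   = c(0, 5.8, 0.16, 2.8, 0.6, 3.4, 4.6, 2.8, 2.8),
    dvar_sd    = c(0, 0.7, 0.1, 0.4, 0.7, 0.7, 0.6, 0.4, 0.4),
    lc_nm      = c(0, 42.5, 1.3, 22.6, 4.4, 24.9, 33.7, 26.7, 25.2),
    lc_sd      = c(0, 5.2, 0.7, 3.0, 5.1, 5.1, 4.4, 1.9, 5.7),
    lc_pct     = c(0, 100, 5.5, 63, 10, 58.6, 79.3, 53, 59),
    lc_pct_sd  = c(0, NA, 0.7, 6.9, 12, 12, 10, 8.9, 14),
    stringsAsFactors = FALSE
  )
  if (include_trans) {
    out <- rbind(out, data.frame(
      label = c("F_trans", "U_trans"), state = "ii",
      dz_nm = c(0, 18.2), dz_sd = c(0, 0.7),
      dvar_nm2 = c(0, 5.8), dvar_sd = c(0, 0.7),
      lc_nm = c(0, 42.5), lc_sd = c(0, 5.2),
      lc_pct = c(0, 100), lc_pct_sd = c(0, NA),
      stringsAsFactors = FALSE))
  }
  out
}

#' Mean transition times of the talin R3 kinetic network
#'
#' Directed mean transition times (and event counts) between the
#' conformations of the talin R3 conformational space, measured at the
#' coexistence force from recordings of at least 10,000 s. The reciprocal of
#' each mean time is the exponential clock rate of that directed edge in the
#' competing-clocks interpretation used by the simulator.
#'
#' The proline trans-isomer rows (state ii) are represented with the labels
#' `F_trans`/`U_trans`: the molecule enters the trans sub-network from the
#' unfolded cis conformation (`U -> U_trans`) and returns by re-isomerizing
#' (`U_trans -> U`); within the trans state the folded form is short-lived.
#'
#' @return A data.frame with columns `state`, `from`, `to`, `mean_time_s`,
#'   `sem_s`, `n_events`.
#' @export
talin_transition_times <- function() {
  tab <- rbind(
    c("i",   "F",       "U",       1.4,     0.1,    522721),
    c("i",   "U",       "F",       1.3,     0.1,    522721),
    c("ii",  "U",       "U_trans", 1372.5,  100.2,  152),
    c("ii",  "F_trans", "U_trans", 0.07,    0.10,   1504),
    c("ii",  "U_trans", "F_trans", 3.2,     0.2,    1505),
    c("ii",  "U_trans", "U",       63.4,    8.7,    154),
    c("iii", "U",       "I",       6135,    3500,   11),
    c("iii", "F",       "I",       12504,   6054,   2),
    c("iii", "I",       "U",       7.8,     0.3,    12),
    c("iii", "I",       "F",       6.5,     5.4,    4),
    c("iv",  "U",       "H",       1251.8,  140.3,  108),
    c("iv",  "H",       "U",       96.3,    12.3,   108),
    c("v",   "U",       "L3",      2153.4,  310.6,  57),
    c("v",   "L3",      "L2",      0.09,    0.01,   1985),
    c("v",   "L2",      "L1",      0.42,    0.01,   12298),
    c("v",   "L1",      "L2",      0.37,    0.01,   12298),
    c("v",   "L2",      "L3",      2.52,    0.11,   1985),
    c("v",   "L3",      "U",       270.4,   790.8,  57),
    c("vi",  "U",       "M2",      1744,    211,    79),
    c("vi",  "M1",      "M2",      0.91,    0.02,   15980),
    c("vi",  "M2",      "M1",      0.25,    0.03,   15981),
    c("vi",  "M2",      "U",       122.0,   8.3,    79)
  )
  out <- data.frame(
    state = tab[, 1], from = tab[, 2], to = tab[, 3],
    mean_time_s = as.numeric(tab[, 4]), sem_s = as.numeric(tab[, 5]),
    n_events = as.integer(tab[, 6]), stringsAsFactors = FALSE
  )
  out
}

#' Build a kinetic network from a conformation catalog and transition times
#'
#' Converts a summary table of conformations (extension offsets and excess
#' variances) plus a table of directed mean transition times into a
#' `kinetic_network` object usable by the simulator. Each directed edge gets
#' an exponential clock rate equal to the reciprocal of its printed mean
#' transition time; the total exit rate of a conformation is the sum of its
#' outgoing clocks, so the expected dwell is `1 / sum(rates)`.
#'
#' @param conformations data.frame with at least `label`, `dz_nm`,
#'   `dvar_nm2` columns (e.g. [talin_conformations()]); a `state` column is
#'   carried through if present.
#' @param transitions data.frame with `from`, `to`, `mean_time_s` columns
#'   (e.g. [talin_transition_times()]). May be empty (no edges).
#' @return A `kinetic_network`: list with `conformations` and `edges`
#'   data.frames. Edges carry `rate_per_s` plus Bell-model columns
#'   `delta_x_nm` (0 = force-independent), `direction` (+1 rate grows with
#'   force, -1 shrinks) and `ref_force_pN`.
#' @examples
#' net <- network_from_tables(talin_conformations(), talin_transition_times())
#' @export
network_from_tables <- function(conformations, transitions) {
  stopifnot(is.data.frame(conformations),
            all(c("label", "dz_nm", "dvar_nm2") %in% names(conformations)))
  if (anyDuplicated(conformations$label))
    stop("duplicate conformation labels")
  if (any(conformations$dvar_nm2 < 0))
    stop("excess variances must be non-negative")
  conf <- conformations
  if (is.null(conf$state)) conf$state <- NA_character_

  if (is.null(transitions) || nrow(transitions) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        rate_per_s = numeric(), delta_x_nm = numeric(),
                        direction = numeric(), ref_force_pN = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("from", "to", "mean_time_s") %in% names(transitions)))
    missing <- setdiff(unique(c(transitions$from, transitions$to)), conf$label)
    if (length(missing))
      stop("transition endpoints without a conformation entry: ",
           paste(missing, collapse = ", "))
    if (any(!is.finite(transitions$mean_time_s) | transitions$mean_time_s <= 0))
      stop("mean transition times must be strictly positive")
    edges <- data.frame(
      from = transitions$from, to = transitions$to,
      rate_per_s = 1 / transitions$mean_time_s,
      delta_x_nm = 0, direction = 1, ref_force_pN = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  structure(list(conformations = conf, edges = edges), class = "kinetic_network")
}

#' @export
print.kinetic_network <- function(x, ...) {
  cat(sprintf("Kinetic network: %d conformations, %d directed edges\n",
              nrow(x$conformations), nrow(x$edges)))
  invisible(x)
}

#' Attach Bell-model force sensitivity to a network edge
#'
#' Marks a directed edge as force-dependent with distance-to-transition-state
#' `delta_x` so the simulator rescales its clock by
#' `exp(direction * (F - ref_force) * delta_x / kT)`.
#'
#' @param network A `kinetic_network`.
#' @param from,to Edge endpoints (conformation labels).
#' @param delta_x Distance to the transition state, nm.
#' @param direction `"unfolding"` (rate grows with force) or `"folding"`.
#' @param ref_force Force at which the tabulated rate was measured, pN.
#' @return The modified network.
#' @export
set_bell_sensitivity <- function(network, from, to, delta_x,
                                 direction = c("unfolding", "folding"),
                                 ref_force = 8.5) {
  stopifnot(inherits(network, "kinetic_network"))
  direction <- match.arg(direction)
  i <- which(network$edges$from == from & network$edges$to == to)
  if (!length(i)) stop("no edge ", from, " -> ", to)
  network$edges$delta_x_nm[i] <- delta_x
  network$edges$direction[i] <- if (direction == "unfolding") 1 else -1
  network$edges$ref_force_pN[i] <- ref_force
  network
}

#' Talin R3 kinetic network at the coexistence force
#'
#' Convenience constructor for the full (or partial) talin R3 network built
#' from [talin_conformations()] and [talin_transition_times()]. The native
#' folding/unfolding edges (F <-> U) carry Bell force sensitivity with a
#' total distance to the transition state of 12 nm split symmetrically,
#' which reproduces the steep ~1.5 pN width of the native folded-fraction
#' force response; rare-state entry/exit clocks are left force-independent.
#'
#' @param states Character vector of regions to include (subset of
#'   `c("i","ii","iii","iv","v","vi")`). Conformations are included when
#'   they participate in a kept transition.
#' @param bell Logical: attach Bell sensitivity to the native F <-> U edges.
#' @param delta_x_total_nm Total distance to the transition state, nm, split
#'   equally between unfolding and folding.
#' @param ref_force_pN Coexistence force at which the tabulated rates hold.
#' @param include_bound Add a stub vinculin-bound conformation `B` (3 nm
#'   contraction of the unfolded extension, fluctuations like the
#'   helix-stabilized state) reachable from `U`; it has no exit and exists
#'   only so simulated recordings can contain a binding arrest.
#' @return A `kinetic_network`.
#' @examples
#' talin_network("i")                  # native two-state hopping
#' talin_network(c("i", "iv"))
#' @export
talin_network <- function(states = c("i", "ii", "iii", "iv", "v", "vi"),
                          bell = TRUE, delta_x_total_nm = 12,
                          ref_force_pN = 8.5, include_bound = FALSE) {
  states <- match.arg(states, c("i", "ii", "iii", "iv", "v", "vi"),
                      several.ok = TRUE)
  tt <- talin_transition_times()
  tt <- tt[tt$state %in% states, , drop = FALSE]
  conf <- talin_conformations(include_trans = "ii" %in% states)
  if (include_bound) {
    conf <- rbind(conf, data.frame(
      label = "B", state = "bound",
      dz_nm = 18.2 - 3, dz_sd = NA, dvar_nm2 = 2.8, dvar_sd = NA,
      lc_nm = NA, lc_sd = NA, lc_pct = NA, lc_pct_sd = NA,
      stringsAsFactors = FALSE))
    tt <- rbind(tt, data.frame(state = "bound", from = "U", to = "B",
                               mean_time_s = 30, sem_s = NA,
                               n_events = NA_integer_))
  }
  keep <- unique(c("F", "U", tt$from, tt$to))
  conf <- conf[conf$label %in% keep, , drop = FALSE]
  net <- network_from_tables(conf, tt)
  if (bell && "i" %in% states) {
    dx <- delta_x_total_nm / 2
    net <- set_bell_sensitivity(net, "F", "U", dx, "unfolding", ref_force_pN)
    net <- set_bell_sensitivity(net, "U", "F", dx, "folding", ref_force_pN)
  }
  net
}

#' Bell-model force rescaling of a rate
#'
#' Exponential force dependence of a transition rate through a distance to
#' the transition state: `rate(F) = base_rate * exp(s (F - F_ref) dx / kT)`
#' with `s = +1` for unfolding-like transitions (rate accelerated by force)
#' and `s = -1` for folding-like ones.
#'
#' @param base_rate Rate at the reference force, 1/s.
#' @param force Force at which to evaluate, pN.
#' @param ref_force Reference force, pN.
#' @param delta_x Distance to the transition state, nm.
#' @param direction `"unfolding"` or `"folding"`.
#' @param kT Thermal energy, pN nm.
#' @return Rescaled rate, 1/s.
#' @export
bell_rate <- function(base_rate, force, ref_force, delta_x,
                      direction = c("unfolding", "folding"), kT = 4.11) {
  direction <- match.arg(direction)
  if (kT <= 0) stop("kT must be positive")
  s <- if (direction == "unfolding") 1 else -1
  base_rate * exp(s * (force - ref_force) * delta_x / kT)
}
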