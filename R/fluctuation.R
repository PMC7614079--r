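#' Per-fragment extension and fluctuation statistics
#'
#' For every dwell fragment of an idealized recording, computes the relative
#' extension `dz = <z_j> - z_ref` and the relative fluctuations
#' `dvar = var(z_j) - <var_ref>`, taking one conformation (normally the
#' natively folded one) as reference. The reference extension and variance
#' are duration-weighted means over all reference dwells; the reference
#' conformation's own fragments have `dz = dvar = 0` by definition.
#' Transition-path samples never enter any statistic.
#'
#' @param ideal An `idealization` from [label_and_excise()].
#' @param traj The [trajectory()] the idealization came from.
#' @param reference_label Conformation used as reference (default `"N"`).
#' @return data.frame of class `fragment_stats` with one row per dwell:
#'   `fragment` (index within its conformation), `label`, `start`, `end`,
#'   `duration_s`, `dz_nm`, `dvar_nm2`, `censored`. Attributes: `z_ref`,
#'   `var_ref`, `reference_label`.
#' @export
fragment_statistics <- function(ideal, traj, reference_label = "N") {
  seg <- ideal$segments
  dw <- seg[seg$label != "TP", , drop = FALSE]
  if (!any(dw$label == reference_label))
    stop("reference conformation '", reference_label,
         "' absent from the idealization")
  mom <- fragment_moments_cpp(traj$extension_nm, dw$start, dw$end)
  mu <- mom[, 1]; vv <- mom[, 2]
  is_ref <- dw$label == reference_label
  w <- dw$duration_s[is_ref]
  z_ref <- weighted.mean(mu[is_ref], w)
  var_ref <- weighted.mean(vv[is_ref], w)
  out <- data.frame(
    fragment = stats::ave(seq_len(nrow(dw)), dw$label, FUN = seq_along),
    label = dw$label, start = dw$start, end = dw$end,
    duration_s = dw$duration_s,
    dz_nm = ifelse(is_ref, 0, mu - z_ref),
    dvar_nm2 = ifelse(is_ref, 0, vv - var_ref),
    censored = dw$censored, stringsAsFactors = FALSE
  )
  attr(out, "z_ref") <- z_ref
  attr(out, "var_ref") <- var_ref
  attr(out, "reference_label") <- reference_label
  class(out) <- c("fragment_stats", "data.frame")
  out
}

# duration-weighted mean and (population) sd
.wstats <- function(x, w) {
  m <- weighted.mean(x, w)
  c(mean = m, sd = sqrt(weighted.mean((x - m)^2, w)))
}

#' Summarize conformations: extension, fluctuations, unstructured contour length
#'
#' Aggregates fragment statistics per conformation and converts the mean
#' excess variance into an unstructured contour length through the FJC
#' inversion (mean-then-convert: the average change in contour length is
#' estimated from the average excess variance). The fraction of unstructured
#' sequence normalizes by `reference_Lc` (by default the contour length of
#' the unfolded conformation `U` measured in the same summary, if present).
#'
#' @param fragments A `fragment_stats` data.frame.
#' @param force Force at which the fluctuations were measured, pN.
#' @param params [fjc_params()].
#' @param reference_Lc Contour-length increment of the fully unfolded state,
#'   nm, or `NULL` to take the summary's own `U` row.
#' @param weighted Duration-weighted fragment means (default) or unweighted.
#' @param min_fragments Conformations with fewer fragments are flagged
#'   `low_n`.
#' @return data.frame of class `state_summary`: per conformation the mean
#'   and sd of `dz_nm`, `dvar_nm2`, the derived `lc_nm` +/- sd and
#'   `lc_pct` +/- sd, fragment count `n` and `low_n` flag.
#' @export
summarize_state <- function(fragments, force, params = fjc_params(),
                            reference_Lc = NULL, weighted = TRUE,
                            min_fragments = 3) {
  stopifnot(inherits(fragments, "fragment_stats"))
  ref_lab <- attr(fragments, "reference_label")
  sp <- split(seq_len(nrow(fragments)), fragments$label)
  vfac <- fjc_variance_factor(force, params)
  rows <- lapply(names(sp), function(lab) {
    i <- sp[[lab]]
    w <- if (weighted) fragments$duration_s[i] else rep(1, length(i))
    dz <- .wstats(fragments$dz_nm[i], w)
    dv <- .wstats(fragments$dvar_nm2[i], w)
    lc <- max(dv[["mean"]], 0) / vfac
    data.frame(label = lab, n = length(i),
               dz_nm = dz[["mean"]], dz_sd = dz[["sd"]],
               dvar_nm2 = dv[["mean"]], dvar_sd = dv[["sd"]],
               lc_nm = lc, lc_sd = dv[["sd"]] / vfac,
               low_n = length(i) < min_fragments,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (ref_lab %in% out$label) {   # reference row is exactly zero by definition
    i <- out$label == ref_lab
    out[i, c("dz_nm", "dz_sd", "dvar_nm2", "dvar_sd", "lc_nm", "lc_sd")] <- 0
  }
  if (is.null(reference_Lc)) {
    if ("U" %in% out$label) reference_Lc <- out$lc_nm[out$label == "U"]
    else reference_Lc <- NA_real_
  }
  if (is.finite(reference_Lc) && reference_Lc > 0) {
    out$lc_pct <- unstructured_fraction(out$lc_nm, reference_Lc)
    out$lc_pct_sd <- 100 * out$lc_sd / reference_Lc
  } else {
    out$lc_pct <- NA_real_
    out$lc_pct_sd <- NA_real_
  }
  attr(out, "force_pN") <- force
  attr(out, "reference_Lc") <- reference_Lc
  attr(out, "reference_label") <- ref_lab
  class(out) <- c("state_summary", "data.frame")
  out
}

#' Classify a recording stretch into one of the six conformational regions
#'
#' Rule-based assignment of a stretch with stable level structure to a
#' region of the talin R3 conformational space, from the number of levels,
#' their extension offsets relative to the folded level, and (for the
#' two-state regions) the unfolded occupancy. Offsets are compared with the
#' catalog signatures within a tolerance window.
#'
#' Signatures: `i` two levels at 0/18.2 nm with substantial folded
#' occupancy; `ii` the same two levels with the equilibrium shifted to the
#' unfolded side (trans-proline isomer); `iii` a single level near 5.4 nm;
#' `iv` a single level near 15.6 nm; `v` three levels near 3.3/7.6/14.9 nm;
#' `vi` two intermediate levels near 7.45/14.3 nm. Anything else is
#' `"unknown"` (a valid outcome, surfaced rather than forced into the
#' catalog).
#'
#' @param level_offsets Extension levels of the stretch relative to the
#'   folded conformation, nm (sorted internally).
#' @param unfolded_occupancy Fraction of time at the highest level, used to
#'   separate regions `i` and `ii`; `NA` defaults the two-state call to `i`.
#' @param tol Matching tolerance around the catalog offsets, nm.
#' @param trans_cut Unfolded occupancy above which a two-state stretch is
#'   called `ii`.
#' @return One of `"i" ... "vi"` or `"unknown"`.
#' @export
classify_region <- function(level_offsets, unfolded_occupancy = NA,
                            tol = 1.5, trans_cut = 0.8) {
  o <- sort(as.numeric(level_offsets))
  k <- length(o)
  near <- function(x, ref) length(x) == length(ref) && all(abs(x - ref) <= tol)
  if (k == 2 && near(o, c(0, 18.2))) {
    if (is.finite(unfolded_occupancy) && unfolded_occupancy > trans_cut)
      return("ii")
    return("i")
  }
  if (k == 1) {
    if (near(o, 5.4)) return("iii")
    if (near(o, 15.6)) return("iv")
    return("unknown")
  }
  if (k == 3 && near(o, c(3.3, 7.6, 14.9))) return("v")
  if (k == 2 && near(o, c(7.45, 14.3))) return("vi")
  "unknown"
}

#' Classify a trajectory stretch (levels + occupancy + rules)
#'
#' Convenience wrapper: estimates the number of levels and their positions
#' by BIC mixture selection, measures the occupancy of the highest level by
#' idealization (for two-level stretches), and applies [classify_region()].
#'
#' @param traj A [trajectory()] covering one stable region.
#' @param folded_level Absolute extension of the folded conformation, nm
#'   (reference for the offsets).
#' @param max_components Upper bound on the number of levels.
#' @param ... Passed to [classify_region()].
#' @return Region label, with the estimated `thresholds` as attribute.
#' @export
classify_stretch <- function(traj, folded_level = 0, max_components = 3, ...) {
  th <- tryCatch(estimate_levels(traj, k_levels = NULL,
                                 max_components = max_components),
                 error = function(e) NULL)
  if (is.null(th)) return("unknown")
  occ <- NA_real_
  if (length(th$levels) >= 2) {
    ideal <- label_and_excise(traj, th)
    dw <- ideal$segments[ideal$segments$label != "TP", ]
    top <- th$labels[length(th$labels)]
    tot <- sum(dw$duration_s)
    if (tot > 0) occ <- sum(dw$duration_s[dw$label == top]) / tot
  }
  out <- classify_region(th$levels - folded_level, occ, ...)
  attr(out, "thresholds") <- th
  out
}
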