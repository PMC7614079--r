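#' Helix topology of a four-helix bundle
#'
#' Residue spans of the independently folding helices (foldons) of the
#' domain, plus the contour length per residue used to convert unstructured
#' residues into contour length. The talin R3 domain has 110 residues
#' (total contour length about 44 nm at 0.4 nm per residue); the default
#' topology splits them into four equal 24-residue helices separated by
#' short loops, and is meant to be overridden when better boundaries are
#' known.
#'
#' @param spans Two-column matrix or data.frame of 1-based inclusive
#'   residue spans (start, end), one row per helix, ordered and
#'   non-overlapping.
#' @param n_residues Total residues in the domain.
#' @param nm_per_residue Contour length per residue, nm.
#' @param helix_extension_nm Extension contribution of each folded helix
#'   along the pulling axis, nm (scalar or per helix; default 0, the
#'   helix-axis-orthogonal assumption).
#' @return A `helix_topology` object.
#' @export
helix_topology <- function(spans = cbind(start = c(2, 30, 58, 86),
                                         end = c(25, 53, 81, 109)),
                           n_residues = 110, nm_per_residue = 0.4,
                           helix_extension_nm = 0) {
  spans <- as.matrix(spans)
  stopifnot(ncol(spans) == 2, nrow(spans) >= 1,
            nm_per_residue > 0, n_residues >= 1)
  storage.mode(spans) <- "integer"
  if (any(spans[, 1] > spans[, 2]))
    stop("each span needs start <= end")
  if (any(spans < 1) || any(spans > n_residues))
    stop("spans must lie within 1..n_residues")
  o <- order(spans[, 1])
  spans <- spans[o, , drop = FALSE]
  if (nrow(spans) > 1 && any(spans[-1, 1] <= spans[-nrow(spans), 2]))
    stop("helix spans overlap")
  nh <- nrow(spans)
  if (length(helix_extension_nm) == 1L)
    helix_extension_nm <- rep(helix_extension_nm, nh)
  stopifnot(length(helix_extension_nm) == nh)
  structure(list(spans = spans, n_residues = n_residues,
                 nm_per_residue = nm_per_residue,
                 helix_extension_nm = helix_extension_nm,
                 helix_residues = as.integer(spans[, 2] - spans[, 1] + 1L)),
            class = "helix_topology")
}

#' Enumerate foldon configurations and their predicted observables
#'
#' Enumerates every subset of folded helices (2^n configurations) and
#' predicts, for each, the observables that fingerprint a conformation in a
#' constant-force recording:
#' * `unstructured_lc_nm` — absolute unstructured contour length
#'   (residues outside folded helices times nm per residue; loops are always
#'   unstructured),
#' * `delta_lc_nm` — unstructured contour length released relative to the
#'   native all-folded configuration (only unfolded helix residues
#'   contribute, since the loops are unstructured in both),
#' * `unstructured_pct` — `delta_lc_nm` normalized by the all-unfolded
#'   configuration's release (0% all folded, 100% none folded),
#' * `dz_nm` — predicted extension offset relative to the native
#'   configuration: `delta_lc_nm` times the FJC relative extension at the
#'   given force, minus the extension contributions of the unfolded helices.
#'
#' @param topology A [helix_topology()].
#' @param force Force at which extensions are predicted, pN.
#' @param params [fjc_params()].
#' @return data.frame of class `foldon_configs`, 2^n rows: `config`
#'   (e.g. `"1011"`, 1 = folded), `n_folded`, plus the predicted columns.
#' @export
enumerate_configs <- function(topology, force = 8.5, params = fjc_params()) {
  stopifnot(inherits(topology, "helix_topology"))
  nh <- nrow(topology$spans)
  phi <- fjc_relative_extension(force, params)
  n_helix_res <- topology$helix_residues
  loop_res <- topology$n_residues - sum(n_helix_res)
  total_release <- sum(n_helix_res) * topology$nm_per_residue
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), nh))[, nh:1, drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    folded <- as.logical(combos[i, ])
    unf_res <- sum(n_helix_res[!folded])
    delta_lc <- unf_res * topology$nm_per_residue
    abs_lc <- (unf_res + loop_res) * topology$nm_per_residue
    dz <- delta_lc * phi - sum(topology$helix_extension_nm[!folded])
    data.frame(
      config = paste(as.integer(folded), collapse = ""),
      n_folded = sum(folded),
      unstructured_lc_nm = abs_lc,
      delta_lc_nm = delta_lc,
      unstructured_pct = if (total_release > 0) 100 * delta_lc / total_release
                         else 0,
      dz_nm = dz, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "force_pN") <- force
  attr(out, "topology") <- topology
  class(out) <- c("foldon_configs", "data.frame")
  out
}

#' Rank foldon configurations against a measured conformation
#'
#' Scores each enumerated configuration by its weighted squared mismatch to
#' a measured conformation's extension offset and unstructured contour
#' length, and orders them best first; ties are broken in favour of fewer
#' unfolded helices (the more structured hypothesis). These are structural
#' hypotheses compatible with the measurements, not structure
#' determinations.
#'
#' @param configs A `foldon_configs` data.frame.
#' @param measured List or one-row data.frame with `dz_nm` and `lc_nm`
#'   (measured extension offset and unstructured contour length).
#' @param weights Length-2 weights for the `(dz, lc)` squared mismatches.
#' @return The configs data.frame with a `score` column, ordered ascending.
#' @export
rank_against_measurement <- function(configs, measured, weights = c(1, 1)) {
  stopifnot(inherits(configs, "foldon_configs"), length(weights) == 2)
  dz <- measured$dz_nm
  lc <- measured$lc_nm
  if (!is.finite(dz) || !is.finite(lc))
    stop("measurement needs finite `dz_nm` and `lc_nm`")
  score <- weights[1] * (configs$dz_nm - dz)^2 +
    weights[2] * (configs$delta_lc_nm - lc)^2
  out <- configs
  out$score <- score
  n_unfolded <- nrow(attr(configs, "topology")$spans) - configs$n_folded
  out[order(out$score, n_unfolded), , drop = FALSE]
}
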