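#' Conformational level thresholds
#'
#' Ordered extension levels of the conformations visible in a recording,
#' used as the thresholds of the idealization algorithm (the thresholds are
#' the mean extensions of the conformations, not midpoints between them).
#'
#' @param levels Strictly increasing extension levels, nm.
#' @param labels Optional conformation labels, low to high extension.
#'   Defaults to `c("N", "U")` for two levels and `S1..Sk` otherwise.
#' @return A `thresholds` object.
#' @export
thresholds <- function(levels, labels = NULL) {
  stopifnot(is.numeric(levels), length(levels) >= 1)
  if (is.unsorted(levels, strictly = TRUE))
    stop("`levels` must be strictly increasing")
  k <- length(levels)
  if (is.null(labels))
    labels <- if (k == 2) c("N", "U") else paste0("S", seq_len(k))
  stopifnot(length(labels) == k)
  structure(list(levels = as.numeric(levels), labels = as.character(labels)),
            class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat("Thresholds:", paste(sprintf("%s = %.3g nm", x$labels, x$levels),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Estimate conformational extension levels from a recording
#'
#' Fits a Gaussian mixture to the extension histogram and places one level
#' at each component mean. The number of components is either given
#' (`k_levels`) or selected by BIC among `1:max_components`. Long recordings
#' are thinned deterministically (evenly spaced samples) before fitting.
#'
#' Adjacent components must be resolvable: the fit is rejected when the
#' overlap misclassification proxy `pnorm(-gap / (sd_i + sd_j))` of any
#' adjacent pair exceeds `max_overlap`.
#'
#' @param traj A [trajectory()] (or numeric extension vector).
#' @param k_levels Number of levels, or `NULL` for BIC selection.
#' @param max_components Upper bound for BIC selection.
#' @param max_samples Thinning cap for the mixture fit.
#' @param max_overlap Maximal tolerated adjacent-component overlap.
#' @param labels Optional labels passed to [thresholds()].
#' @return A [thresholds()] object with attribute `fit_sd` (component sds).
#' @export
estimate_levels <- function(traj, k_levels = NULL, max_components = 4,
                            max_samples = 1e5, max_overlap = 0.2,
                            labels = NULL) {
  z <- if (is.numeric(traj)) traj else traj$extension_nm
  n <- length(z)
  if (n < 10) stop("too few samples to estimate levels")
  zs <- if (n > max_samples) z[round(seq(1, n, length.out = max_samples))] else z
  uz <- unique(zs)
  if (length(uz) <= (k_levels %||% max_components)) {
    # degenerate noise-free recording: the distinct values are the levels
    lev <- sort(uz)
    if (!is.null(k_levels) && length(lev) != k_levels)
      stop("extension histogram has ", length(lev),
           " distinct values but k_levels = ", k_levels)
    th <- thresholds(lev, labels)
    attr(th, "fit_sd") <- rep(0, length(lev))
    return(th)
  }
  G <- if (is.null(k_levels)) seq_len(max_components) else k_levels
  fit <- mclust::Mclust(zs, G = G, modelNames = "V", verbose = FALSE)
  if (is.null(fit))
    stop("mixture fit failed on the extension histogram")
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1L) sig <- rep(sig, length(mu))
  o <- order(mu)
  mu <- mu[o]; sig <- sig[o]
  if (length(mu) > 1) {
    gap <- diff(mu)
    overlap <- stats::pnorm(-gap / (head(sig, -1) + tail(sig, -1)))
    if (any(overlap > max_overlap))
      stop("fewer resolvable modes than requested in the extension histogram ",
           sprintf("(adjacent-component overlap up to %.2f)", max(overlap)))
  }
  th <- thresholds(mu, labels)
  attr(th, "fit_sd") <- sig
  th
}

# Debounce per-sample labels (0 = transition path): dwells shorter than
# min_dwell samples are absorbed into the neighbouring dwell, and transition
# paths left between equal-label dwells are relabeled to that dwell.
.debounce_labels <- function(lab, min_dwell) {
  if (min_dwell <= 1) return(lab)
  r <- rle(lab)
  v <- r$values; l <- r$lengths
  guard <- 10L * length(v) + 100L
  repeat {
    guard <- guard - 1L
    if (guard < 0L) break
    if (length(v) > 1) {
      g <- cumsum(c(TRUE, v[-1] != v[-length(v)]))
      if (max(g) < length(v)) {
        l <- as.vector(rowsum(l, g))
        v <- v[!duplicated(g)]
      }
    }
    nr <- length(v)
    changed <- FALSE
    if (nr >= 3) {
      mid <- which(v[2:(nr - 1)] == 0 & v[1:(nr - 2)] != 0 &
                     v[1:(nr - 2)] == v[3:nr]) + 1L
      if (length(mid)) {
        v[mid] <- v[mid - 1L]
        changed <- TRUE
      }
    }
    if (!changed) {
      dwell_idx <- which(v != 0)
      short <- dwell_idx[l[dwell_idx] < min_dwell]
      if (!length(short) || length(dwell_idx) <= 1) break
      i <- short[1]
      pos <- match(i, dwell_idx)
      v[i] <- if (pos > 1) v[dwell_idx[pos - 1]] else v[dwell_idx[pos + 1]]
    }
  }
  inverse.rle(list(lengths = l, values = v))
}

#' Idealize a trajectory: label dwells and excise transition paths
#'
#' Applies the threshold algorithm: every sample is assigned to a
#' conformation dwell or to a transition path (TP). A transition is the
#' fragment of trajectory where the signal escapes one conformation's basin
#' (crosses beyond that conformation's mean extension) and directly reaches
#' another conformation's mean; those samples are excised, because their
#' contribution to dwell and fluctuation statistics is spurious (they are
#' diffusive excursions over the barrier). Excursions beyond the home mean
#' that return without reaching another level remain part of the dwell.
#' Dwells shorter than `min_dwell` samples are treated as noise chatter and
#' absorbed into their neighbour (the instrument cannot resolve events below
#' ~1-2 ms at ~1,500 Hz).
#'
#' @param traj A [trajectory()].
#' @param th A [thresholds()] object (from [estimate_levels()] or built
#'   manually).
#' @param min_dwell Minimal dwell length in samples (debouncing), default 3.
#' @return An `idealization`: list with `segments` (data.frame: `label`,
#'   `start`, `end` 1-based inclusive sample indices, `t_start_s`, `t_end_s`,
#'   `duration_s`, `censored`), `labels` (per-sample conformation label,
#'   `"TP"` for transition paths), `thresholds`, `sampling_rate_hz`,
#'   `n_samples`.
#' @export
label_and_excise <- function(traj, th, min_dwell = 3) {
  stopifnot(inherits(th, "thresholds"))
  z <- traj$extension_nm
  fs <- sampling_rate(traj)
  lab <- label_threshold_cpp(z, th$levels)
  lab <- .debounce_labels(lab, min_dwell)
  r <- rle(lab)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  seg_lab <- ifelse(r$values == 0L, "TP", th$labels[pmax(r$values, 1L)])
  segments <- data.frame(
    label = seg_lab, start = start, end = end,
    t_start_s = traj$time_s[start], t_end_s = traj$time_s[end],
    duration_s = r$lengths / fs,
    stringsAsFactors = FALSE
  )
  dw <- which(segments$label != "TP")
  segments$censored <- FALSE
  if (length(dw)) segments$censored[c(dw[1], dw[length(dw)])] <- TRUE
  if (length(dw) <= 1)
    warning("trajectory never crosses between levels: single-dwell idealization")
  out <- list(segments = segments,
              labels = ifelse(lab == 0L, "TP", th$labels[pmax(lab, 1L)]),
              thresholds = th,
              sampling_rate_hz = fs,
              n_samples = length(z))
  class(out) <- "idealization"
  out
}

#' @export
print.idealization <- function(x, ...) {
  dw <- x$segments[x$segments$label != "TP", ]
  cat(sprintf("Idealization: %d samples, %d dwells (%s), %d transition paths\n",
              x$n_samples, nrow(dw),
              paste(sprintf("%s:%d", names(table(dw$label)), table(dw$label)),
                    collapse = ", "),
              sum(x$segments$label == "TP")))
  invisible(x)
}

#' Directed transition events of an idealization
#'
#' One row per observed transition between consecutive dwells: the origin
#' and destination conformations, the dwell time spent in the origin before
#' the transition, and the time of the transition. The first dwell of the
#' recording is start-censored, so the event leaving it carries `dwell_s = NA`
#' and is excluded from mean dwell times (the last dwell precedes no event).
#'
#' @param ideal An `idealization`.
#' @return data.frame with columns `from`, `to`, `dwell_s`, `t_s`.
#' @export
transition_events <- function(ideal) {
  seg <- ideal$segments
  dw <- seg[seg$label != "TP", , drop = FALSE]
  if (nrow(dw) < 2)
    return(data.frame(from = character(), to = character(),
                      dwell_s = numeric(), t_s = numeric()))
  from <- dw$label[-nrow(dw)]
  to <- dw$label[-1]
  dwell <- dw$duration_s[-nrow(dw)]
  dwell[1] <- NA_real_             # start-censored
  keep <- from != to
  data.frame(from = from[keep], to = to[keep], dwell_s = dwell[keep],
             t_s = dw$t_end_s[-nrow(dw)][keep], stringsAsFactors = FALSE)
}

#' Dwell-time statistics per directed transition
#'
#' Mean waiting time preceding each directed transition type, with event
#' counts and standard errors; censored edge dwells are excluded from the
#' means. Also returns the complete (uncensored) dwell-time lists per
#' conformation.
#'
#' @param ideal An `idealization`.
#' @return List with `transitions` (data.frame `from`, `to`, `mean_s`,
#'   `sem_s`, `n`) and `dwells` (named list of complete dwell times per
#'   conformation, s).
#' @export
dwell_statistics <- function(ideal) {
  ev <- transition_events(ideal)
  evc <- ev[!is.na(ev$dwell_s), , drop = FALSE]
  if (nrow(evc)) {
    key <- paste(evc$from, evc$to, sep = "\r")
    sp <- split(evc$dwell_s, key)
    tab <- data.frame(
      from = sub("\r.*", "", names(sp)),
      to = sub(".*\r", "", names(sp)),
      mean_s = vapply(sp, mean, 0),
      sem_s = vapply(sp, function(x)
        if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_, 0),
      n = lengths(sp), stringsAsFactors = FALSE, row.names = NULL
    )
    tab <- tab[order(tab$from, tab$to), , drop = FALSE]
    dwl <- split(evc$dwell_s, evc$from)
  } else {
    tab <- data.frame(from = character(), to = character(), mean_s = numeric(),
                      sem_s = numeric(), n = integer())
    dwl <- list()
  }
  list(transitions = tab, dwells = dwl)
}
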