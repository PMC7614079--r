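#' Estimate the instrument point-spread function from a reference bead
#'
#' The vertical trace of a reference bead firmly attached to the surface
#' measures the instrument noise (image-analysis artifacts) that blurs the
#' molecular extension signal. After removing low-frequency components
#' arising from local drift with a zero-phase Butterworth high-pass filter,
#' the residual spread is Gaussian; its standard deviation is the width of
#' the point-spread function (PSF) used for landscape deconvolution.
#'
#' @param reference_trace A [trajectory()] of the reference bead (or a
#'   numeric vector, in which case `sampling_rate_hz` must be given).
#' @param highpass_cutoff_hz High-pass cutoff, Hz (must be below Nyquist);
#'   default 2 Hz, well above the drift band and far below the sampling
#'   band, so white instrument noise is essentially untouched.
#' @param sampling_rate_hz Required when `reference_trace` is a bare vector.
#' @return List of class `psf_model`: `sd_nm` (the PSF sigma), `sd_robust_nm`
#'   (interquartile-range cross-check, equal to `sd_nm` for Gaussian noise),
#'   `highpass_cutoff_hz`, `sampling_rate_hz`, `valid`.
#' @export
estimate_psf <- function(reference_trace, highpass_cutoff_hz = 2,
                         sampling_rate_hz = NULL) {
  if (is.numeric(reference_trace)) {
    z <- reference_trace
    fs <- sampling_rate_hz %||% stop("`sampling_rate_hz` required for a bare vector")
  } else {
    z <- reference_trace$extension_nm
    fs <- sampling_rate(reference_trace)
  }
  if (length(z) < 1e4)
    stop("reference trace too short (need >= 10,000 samples)")
  if (highpass_cutoff_hz >= fs / 2)
    stop("high-pass cutoff must be below the Nyquist frequency ", fs / 2, " Hz")
  if (highpass_cutoff_hz > 0) {
    bf <- signal::butter(2, highpass_cutoff_hz / (fs / 2), type = "high")
    zf <- signal::filtfilt(bf, z - mean(z))
  } else zf <- z - mean(z)
  s <- sd(zf)
  rob <- stats::IQR(zf) / (2 * stats::qnorm(0.75))
  valid <- is.finite(s) && s > 0
  if (!valid) warning("degenerate reference trace: PSF sd is zero")
  structure(list(sd_nm = s, sd_robust_nm = rob,
                 highpass_cutoff_hz = highpass_cutoff_hz,
                 sampling_rate_hz = fs, valid = valid),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("PSF: sigma = %.4g nm (robust %.4g nm), high-pass %.3g Hz\n",
              x$sd_nm, x$sd_robust_nm, x$highpass_cutoff_hz))
  invisible(x)
}

# Convolution matrix of a Gaussian kernel on a uniform grid with reflecting
# (default) or zero boundary handling.
.psf_matrix <- function(k, step, sd, boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  h <- max(1L, ceiling(6 * sd / step))
  off <- (-h):h
  ker <- exp(-(off * step)^2 / (2 * sd^2))
  ker <- ker / sum(ker)
  S <- matrix(0, k, k)
  for (i in seq_len(k)) {
    j <- i + off
    if (boundary == "reflect") {
      j <- ifelse(j < 1L, 2L - j, j)
      j <- ifelse(j > k, 2L * k - j, j)
    }
    keep <- j >= 1L & j <= k
    for (m in which(keep)) S[i, j[m]] <- S[i, j[m]] + ker[m]
  }
  S
}

#' Jansson iterative deconvolution of a measured density
#'
#' Removes the instrument point-spread blur from a measured extension
#' density by Jansson's relaxation method: starting from the measured
#' density `m`, iterate
#' \deqn{p \leftarrow p + r(p)\,(m - S p), \quad
#'   r(p) = r_0\,\bigl(1 - 2|p - A/2|/A\bigr),}
#' where `S` is the Gaussian PSF convolution operator and `A` is the
#' relaxation ceiling. The weight vanishes at `p = 0`, softly enforcing the
#' non-negativity constraint, and the estimate is additionally clamped at
#' zero and re-normalized every iteration. The ceiling is set to twice the
#' running maximum of `p`, so the weight grows linearly from 0 at empty
#' bins to `r_0` at the modal bin; a ceiling at the current maximum itself
#' would freeze the modal bin, which must grow during deblurring. Iteration
#' stops after `iterations` rounds or when the L1 residual `sum |m - S p|`
#' improves by less than `tol`.
#'
#' @param measured Measured density on a uniform grid (normalized to sum 1;
#'   re-normalized with a warning otherwise).
#' @param grid The uniform extension grid, nm (only the spacing is used;
#'   spacing should be at most about a third of the PSF sigma for the blur
#'   to be well represented — a warning is raised otherwise).
#' @param psf A `psf_model` or a numeric sigma in nm.
#' @param iterations Maximal iterations.
#' @param relaxation Base relaxation constant `r_0`.
#' @param tol Residual-improvement stopping tolerance.
#' @param boundary `"reflect"` (default) or `"zero"` padding.
#' @return List of class `jansson_deconvolution`: `density` (deconvolved,
#'   non-negative, sums to 1), `residual_l1`, `iterations_run`, `converged`,
#'   `reblurred` (S applied to the estimate, for consistency checks).
#' @export
deconvolve_jansson <- function(measured, grid, psf, iterations = 500,
                               relaxation = 1.0, tol = 1e-6,
                               boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  sdv <- if (inherits(psf, "psf_model")) psf$sd_nm else as.numeric(psf)
  stopifnot(length(measured) == length(grid), sdv >= 0)
  step <- grid[2] - grid[1]
  if (any(abs(diff(grid) - step) > 1e-9 * step))
    stop("grid must be uniform")
  if (sdv > 0 && step > sdv / 3)
    warning("grid spacing exceeds psf sd / 3; blur is coarsely represented")
  if (any(measured < 0)) stop("measured density has negative entries")
  tot <- sum(measured)
  if (abs(tot - 1) > 1e-8) {
    warning("measured density not normalized; re-normalizing")
    measured <- measured / tot
  }
  S <- .psf_matrix(length(grid), step, max(sdv, 1e-12), boundary)
  p <- measured
  res_prev <- Inf
  res_best <- Inf
  grow <- 0L
  it <- 0L
  while (it < iterations) {
    it <- it + 1L
    conv <- as.numeric(S %*% p)
    resid <- measured - conv
    res <- sum(abs(resid))
    if (res > 1.1 * res_best) {
      grow <- grow + 1L
      if (grow >= 10L)
        stop("Jansson iteration diverging (residual grew 10 iterations in a row)")
    } else grow <- 0L
    if (res < tol ||
        (is.finite(res_prev) && res_prev - res < tol && res <= res_prev)) {
      it <- it - 1L
      break
    }
    res_prev <- res
    res_best <- min(res_best, res)
    A <- 2 * max(p)
    w <- relaxation * (1 - 2 * abs(p - A / 2) / A)
    p <- p + w * resid
    p[p < 0] <- 0
    p <- p / sum(p)
  }
  conv <- as.numeric(S %*% p)
  structure(list(density = p, grid_nm = grid, psf_sd_nm = sdv,
                 residual_l1 = sum(abs(measured - conv)),
                 iterations_run = it,
                 converged = it < iterations,
                 reblurred = conv),
            class = "jansson_deconvolution")
}

# local minima / maxima of a vector (strict sign change of the slope)
.local_extrema <- function(y) {
  d <- sign(diff(y))
  d <- d[d != 0]
  # with plateaus removed via run-length on the original
  dy <- diff(y)
  idx_min <- integer(); idx_max <- integer()
  prev <- 0
  for (i in seq_along(dy)) {
    s <- sign(dy[i])
    if (s == 0) next
    if (prev > 0 && s < 0) idx_max <- c(idx_max, i)
    if (prev < 0 && s > 0) idx_min <- c(idx_min, i)
    prev <- s
  }
  list(minima = idx_min, maxima = idx_max)
}

#' Free-energy landscape from an extension density
#'
#' Boltzmann inversion `G(z) = -ln p(z)` (in kT units, shifted so the global
#' minimum is zero) of a normalized extension density, with basin and
#' barrier detection: the two deepest free-energy minima separated by at
#' least `min_separation_nm` are the basins, and the barrier is the maximum
#' of `G` on the path between them minus the shallower basin's value. A
#' density floor is applied before the logarithm.
#'
#' @param density Normalized density on `grid`.
#' @param grid Uniform extension grid, nm.
#' @param floor Density floor before the log (default 1e-8).
#' @param min_separation_nm Minimal basin separation, nm.
#' @param smooth_window_nm Width (nm) of an order-2 Savitzky-Golay smoothing
#'   of the free-energy curve applied before locating basins and barrier.
#'   `0` (default) disables it. For densities estimated from finite noisy
#'   histograms, reading the barrier as the raw maximum over the inter-basin
#'   bins is biased upward (the maximum of many noisy values); a local
#'   quadratic fit over a few bins removes most of that selection bias
#'   while leaving a smooth landscape unchanged.
#' @return List of class `landscape_estimate`: `grid_nm`,
#'   `free_energy_kT`, `basins_nm`, `barrier_kT` (`NA` with
#'   `has_barrier = FALSE` for a unimodal density), `barrier_position_nm`.
#' @export
landscape_from_density <- function(density, grid, floor = 1e-8,
                                   min_separation_nm = 2,
                                   smooth_window_nm = 0) {
  stopifnot(length(density) == length(grid))
  tot <- sum(density)
  if (abs(tot - 1) > 1e-8) density <- density / tot
  G <- -log(pmax(density, floor))
  G <- G - min(G)
  if (smooth_window_nm > 0) {
    step <- grid[2] - grid[1]
    w <- max(5L, round(smooth_window_nm / step))
    if (w %% 2L == 0L) w <- w + 1L
    if (w < length(G)) {
      G <- signal::sgolayfilt(G, p = 2, n = w)
      G <- G - min(G)
    }
  }
  supp <- density > floor
  ext <- .local_extrema(G)
  mins <- ext$minima[supp[ext$minima]]
  # include flat global minimum even if not a strict interior extremum
  if (!length(mins)) mins <- which.min(G)
  out <- list(grid_nm = grid, free_energy_kT = G, density = density,
              basins_nm = grid[mins][order(G[mins])][seq_len(min(2, length(mins)))],
              barrier_kT = NA_real_, barrier_position_nm = NA_real_,
              has_barrier = FALSE)
  if (length(mins) >= 2) {
    o <- mins[order(G[mins])]
    # two deepest minima with sufficient spatial separation
    b1 <- o[1]
    b2 <- NA_integer_
    for (m in o[-1]) if (abs(grid[m] - grid[b1]) >= min_separation_nm) {
      b2 <- m; break
    }
    if (!is.na(b2)) {
      lo <- min(b1, b2); hi <- max(b1, b2)
      ridge <- lo - 1L + which.max(G[lo:hi])
      out$barrier_kT <- G[ridge] - max(G[b1], G[b2])
      out$barrier_position_nm <- grid[ridge]
      out$basins_nm <- sort(grid[c(b1, b2)])
      out$has_barrier <- TRUE
    }
  }
  class(out) <- "landscape_estimate"
  out
}

#' @export
print.landscape_estimate <- function(x, ...) {
  if (x$has_barrier)
    cat(sprintf("Landscape: basins at %s nm, barrier %.2f kT at %.2f nm\n",
                paste(sprintf("%.2f", x$basins_nm), collapse = " / "),
                x$barrier_kT, x$barrier_position_nm))
  else cat("Landscape: unimodal density, no barrier\n")
  invisible(x)
}

#' Reconstruct a free-energy landscape from measured extensions
#'
#' End-to-end convenience wrapper: histograms the extension samples on a
#' uniform grid, deconvolves the instrument PSF with
#' [deconvolve_jansson()], and Boltzmann-inverts the intrinsic density with
#' [landscape_from_density()].
#'
#' @param extension Extension samples, nm (dwell and transition samples of
#'   an equilibrium recording, or raw samples).
#' @param psf A `psf_model` or numeric sigma, nm.
#' @param bin_width_nm Histogram bin width (default 0.25 nm).
#' @param range_nm Grid range `c(lo, hi)`; defaults to the data range padded
#'   by 3 sigma.
#' @param iterations,relaxation,tol,boundary Passed to
#'   [deconvolve_jansson()].
#' @param floor,min_separation_nm,smooth_window_nm Passed to
#'   [landscape_from_density()]; the free-energy curve of a histogram-based
#'   density is smoothed over `smooth_window_nm` (default 3 nm) before the
#'   barrier is read off, to suppress the upward selection bias of a raw
#'   maximum over noisy bins.
#' @return A `landscape_estimate` with the deconvolution attached as
#'   attribute `deconvolution` and the measured density as `measured`.
#' @export
reconstruct_landscape <- function(extension, psf, bin_width_nm = 0.25,
                                  range_nm = NULL, iterations = 500,
                                  relaxation = 1.0, tol = 1e-6,
                                  boundary = "reflect", floor = 1e-8,
                                  min_separation_nm = 2,
                                  smooth_window_nm = 3) {
  sdv <- if (inherits(psf, "psf_model")) psf$sd_nm else as.numeric(psf)
  if (is.null(range_nm))
    range_nm <- range(extension) + c(-3, 3) * sdv
  breaks <- seq(range_nm[1], range_nm[2] + bin_width_nm, by = bin_width_nm)
  h <- graphics::hist(extension[extension >= breaks[1] &
                                  extension <= breaks[length(breaks)]],
                      breaks = breaks, plot = FALSE)
  measured <- h$counts / sum(h$counts)
  grid <- h$mids
  dec <- deconvolve_jansson(measured, grid, sdv, iterations = iterations,
                            relaxation = relaxation, tol = tol,
                            boundary = boundary)
  ls <- landscape_from_density(dec$density, grid, floor = floor,
                               min_separation_nm = min_separation_nm,
                               smooth_window_nm = smooth_window_nm)
  attr(ls, "deconvolution") <- dec
  attr(ls, "measured") <- measured
  ls
}
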