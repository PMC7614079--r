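#' Construct an extension-time trajectory
#'
#' The package's core data container: a uniformly sampled recording of
#' molecular end-to-end extension under force, as produced by a magnetic
#' tweezers experiment or by the package's simulator.
#'
#' @param time Sample times in s, uniform grid (length >= 2).
#' @param extension Extension in nm, same length as `time`, finite.
#' @param force Force in pN: scalar (constant-force recording) or per-sample.
#' @param sampling_rate Sampling rate in Hz; inferred from `time` if `NULL`.
#' @param molecule_id Optional identifier carried in metadata.
#' @return A data.frame of class `trajectory` with columns `time_s`,
#'   `extension_nm`, `force_pN` and attributes `sampling_rate_hz`,
#'   `molecule_id`.
#' @export
trajectory <- function(time, extension, force, sampling_rate = NULL,
                       molecule_id = NA_character_) {
  n <- length(time)
  if (n < 2) stop("a trajectory needs at least 2 samples")
  if (length(extension) != n) stop("`extension` length must match `time`")
  if (length(force) == 1L) force <- rep(force, n)
  if (length(force) != n) stop("`force` must be scalar or match `time`")
  if (any(!is.finite(time)) || any(!is.finite(extension)) || any(!is.finite(force)))
    stop("trajectory values must be finite (no NaN/NA/Inf)")
  dt <- diff(time)
  dt_ref <- stats::median(dt)
  if (dt_ref <= 0 || max(abs(dt - dt_ref)) > 1e-6 * dt_ref)
    stop("`time` must be a strictly increasing uniform grid (tolerance 1 ppm)")
  if (is.null(sampling_rate)) sampling_rate <- 1 / dt_ref
  out <- data.frame(time_s = time, extension_nm = extension, force_pN = force)
  attr(out, "sampling_rate_hz") <- sampling_rate
  attr(out, "molecule_id") <- molecule_id
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Sampling rate of a trajectory
#' @param x A `trajectory`.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(x) {
  r <- attr(x, "sampling_rate_hz")
  if (is.null(r)) 1 / stats::median(diff(x$time_s)) else r
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples at %.6g Hz (%.6g s), force %s pN\n",
              nrow(x), sampling_rate(x), nrow(x) / sampling_rate(x),
              if (length(unique(x$force_pN)) == 1L)
                format(x$force_pN[1]) else "variable"))
  invisible(x)
}
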