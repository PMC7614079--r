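#' Read a trajectory from tabular text
#'
#' Reads the canonical interchange format: a delimited text file with a
#' header line and columns `time_s`, `extension_nm`, `force_pN` (UTF-8,
#' `.` decimal). The time grid is validated to be uniform to 1 ppm.
#'
#' @param path File path.
#' @param molecule_id Optional identifier; defaults to the file name.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, molecule_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("time_s", "extension_nm", "force_pN")
  missing <- setdiff(need, names(dt))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  trajectory(dt$time_s, dt$extension_nm, dt$force_pN,
             molecule_id = molecule_id %||% basename(path))
}

#' Write a trajectory (and optional ground-truth sidecar) to tabular text
#'
#' @param traj A [trajectory()].
#' @param path Output file (tab-separated, header line).
#' @param sidecar_path Optional path for the true state path attached to a
#'   simulated trajectory (`label`, `entry_time_s`), for recovery tests.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, sidecar_path = NULL) {
  data.table::fwrite(as.data.frame(traj)[c("time_s", "extension_nm", "force_pN")],
                     path, sep = "\t")
  tp <- attr(traj, "true_path")
  if (!is.null(sidecar_path)) {
    if (is.null(tp)) stop("trajectory carries no true path for a sidecar")
    data.table::fwrite(as.data.frame(tp), sidecar_path, sep = "\t")
  }
  invisible(path)
}

#' Write an idealization as a segment table
#'
#' Writes the dwell/transition-path segments (`label`, `t_start_s`,
#' `t_end_s`, `duration_s`) as tab-separated text.
#'
#' @param ideal An `idealization`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_idealization <- function(ideal, path) {
  data.table::fwrite(ideal$segments[c("label", "t_start_s", "t_end_s",
                                      "duration_s")], path, sep = "\t")
  invisible(path)
}

#' Savitzky-Golay smoothing for display
#'
#' Returns a display copy of the trajectory with the extension smoothed by
#' a Savitzky-Golay filter (default 101 points, order 3). Smoothing is for
#' figures only: every analysis stage in this package consumes the raw
#' recording, never the smoothed one, and the returned object is flagged
#' accordingly.
#'
#' @param traj A [trajectory()].
#' @param window Window length in samples, odd, at least `order + 2`.
#' @param order Polynomial order.
#' @return A `trajectory` with smoothed `extension_nm` and attribute
#'   `smoothed = TRUE`.
#' @export
smooth_for_display <- function(traj, window = 101, order = 3) {
  if (window %% 2 == 0) stop("`window` must be odd")
  if (window < order + 2) stop("`window` must be at least order + 2")
  out <- traj
  out$extension_nm <- signal::sgolayfilt(traj$extension_nm, p = order,
                                         n = window)
  attr(out, "smoothed") <- TRUE
  out
}
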