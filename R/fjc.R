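#' Freely-jointed-chain model parameters
#'
#' Container for the two physical constants of the freely-jointed chain (FJC)
#' model of polymer elasticity used throughout the package: the Kuhn length
#' of the unstructured polypeptide and the thermal energy.
#'
#' @param kuhn_length Kuhn length \eqn{l_K} in nm. Default 1.1 nm, the value
#'   appropriate for an unstructured polypeptide under force in the
#'   single-digit piconewton range.
#' @param thermal_energy Thermal energy \eqn{kT} in pN nm. Default 4.11 pN nm
#'   (room temperature, ~298 K).
#' @return An object of class `fjc_params`.
#' @examples
#' p <- fjc_params()
#' fjc_relative_extension(8.5, p)
#' @export
fjc_params <- function(kuhn_length = 1.1, thermal_energy = 4.11) {
  stopifnot(is.numeric(kuhn_length), length(kuhn_length) == 1L,
            is.numeric(thermal_energy), length(thermal_energy) == 1L)
  if (!is.finite(kuhn_length) || kuhn_length <= 0)
    stop("`kuhn_length` must be strictly positive (nm)")
  if (!is.finite(thermal_energy) || thermal_energy <= 0)
    stop("`thermal_energy` must be strictly positive (pN nm)")
  structure(list(kuhn_length = kuhn_length, thermal_energy = thermal_energy),
            class = "fjc_params")
}

#' @export
print.fjc_params <- function(x, ...) {
  cat(sprintf("FJC parameters: l_K = %g nm, kT = %g pN nm\n",
              x$kuhn_length, x$thermal_energy))
  invisible(x)
}

# reduced force beta = F * l_K / kT
.fjc_beta <- function(force, params) force * params$kuhn_length / params$thermal_energy

# series/closed-form crossover; both branches agree to better than 1e-9 here
.fjc_series_cut <- 0.15

# Langevin function L(b) = coth(b) - 1/b, series branch for small b
.fjc_phi_series <- function(b) b / 3 - b^3 / 45 + 2 * b^5 / 945 - b^7 / 4725

.fjc_phi_closed <- function(b) 1 / tanh(b) - 1 / b

# excess one-axis variance per unit contour length, in units of l_K:
# 1/b^2 - csch^2(b); series branch avoids catastrophic cancellation
.fjc_vfac_series <- function(b) 1 / 3 - b^2 / 15 + 2 * b^4 / 189 - b^6 / 675

.fjc_vfac_closed <- function(b) 1 / b^2 - 1 / sinh(b)^2

#' FJC relative extension under force
#'
#' Mean end-to-end extension per unit contour length of a freely-jointed
#' chain held at constant force: the Langevin function
#' \eqn{\phi(\beta) = \coth\beta - 1/\beta} with reduced force
#' \eqn{\beta = F l_K / kT}. This is the \eqn{z(F)} relationship that
#' converts contour length into measured extension at a given force.
#'
#' A series expansion is used for small \eqn{\beta} to avoid catastrophic
#' cancellation between \eqn{\coth\beta} and \eqn{1/\beta}.
#'
#' @param force Applied force in pN (vectorized, must be non-negative).
#' @param params An [fjc_params()] object.
#' @return Dimensionless fraction in `[0, 1)`, strictly increasing in force.
#' @examples
#' fjc_relative_extension(c(0, 8.5, 17))
#' @export
fjc_relative_extension <- function(force, params = fjc_params()) {
  stopifnot(inherits(params, "fjc_params"), is.numeric(force))
  if (any(!is.finite(force)) || any(force < 0))
    stop("`force` must be finite and non-negative (pN)")
  b <- .fjc_beta(force, params)
  out <- numeric(length(b))
  small <- b < .fjc_series_cut
  out[small] <- .fjc_phi_series(b[small])
  out[!small] <- .fjc_phi_closed(b[!small])
  out
}

#' FJC excess extension variance per unit contour length
#'
#' The one-axis end-to-end variance of a freely-jointed chain per nm of
#' contour length at force \eqn{F}:
#' \deqn{v(F) = l_K \left[\frac{1}{\beta^2} - \mathrm{csch}^2\beta\right],
#'   \quad \beta = F l_K / kT,}
#' equivalently \eqn{l_K[1 - \coth^2\beta + 1/\beta^2]}. Multiplying
#' \eqn{v(F)} by an unstructured contour length gives the excess extension
#' variance that stretch of chain contributes to the recording. \eqn{v} is
#' strictly decreasing in force with analytic zero-force limit \eqn{l_K/3}.
#'
#' @inheritParams fjc_relative_extension
#' @return Variance factor in nm (variance nm^2 per nm of contour length).
#' @examples
#' fjc_variance_factor(0)          # l_K / 3
#' fjc_variance_factor(8.5)
#' @export
fjc_variance_factor <- function(force, params = fjc_params()) {
  stopifnot(inherits(params, "fjc_params"), is.numeric(force))
  if (any(!is.finite(force)) || any(force < 0))
    stop("`force` must be finite and non-negative (pN)")
  b <- .fjc_beta(force, params)
  out <- numeric(length(b))
  small <- b < .fjc_series_cut
  out[small] <- .fjc_vfac_series(b[small])
  out[!small] <- .fjc_vfac_closed(b[!small])
  params$kuhn_length * out
}

#' Unstructured contour length from excess extension variance
#'
#' Inverts the FJC fluctuation model: given the excess end-to-end variance
#' \eqn{\langle\Delta\sigma^2\rangle} of a conformation relative to the
#' native reference, returns the unstructured contour length
#' \deqn{\Delta L_C = \frac{\langle\Delta\sigma^2\rangle}{l_K
#'   [1/\beta^2 - \mathrm{csch}^2\beta]}.}
#' The quotient form is fixed by dimensional analysis (nm^2 divided by nm).
#' This is the exact inverse of `delta_var = delta_Lc * fjc_variance_factor(force)`.
#'
#' @param delta_var Excess extension variance in nm^2 (non-negative).
#' @param force Applied force in pN, strictly positive. The force at which
#'   the fluctuations were measured must be supplied explicitly; the result
#'   is sensitive to it.
#' @param params An [fjc_params()] object.
#' @return Contour length in nm.
#' @examples
#' v <- fjc_variance_factor(8.5)
#' contour_length_from_variance(42.5 * v, 8.5)   # recovers 42.5
#' @export
contour_length_from_variance <- function(delta_var, force, params = fjc_params()) {
  stopifnot(inherits(params, "fjc_params"), is.numeric(delta_var), is.numeric(force))
  if (any(!is.finite(delta_var)) || any(delta_var < 0))
    stop("`delta_var` must be finite and non-negative (nm^2)")
  if (any(!is.finite(force)) || any(force <= 0))
    stop("`force` must be strictly positive (pN): the extension model is degenerate at zero force")
  delta_var / fjc_variance_factor(force, params)
}

#' Fraction of unstructured protein sequence
#'
#' Normalizes an unstructured contour length by the contour-length increment
#' of the fully unfolded conformation, giving the percentage of the sequence
#' that is disordered in a given conformation.
#'
#' @param delta_Lc Unstructured contour length of the conformation, nm.
#' @param reference_Lc Contour-length increment of the unfolded state, nm
#'   (strictly positive; 42.5 nm for talin R3).
#' @return Percentage, `100 * delta_Lc / reference_Lc`.
#' @examples
#' unstructured_fraction(24.9, 42.5)
#' @export
unstructured_fraction <- function(delta_Lc, reference_Lc) {
  stopifnot(is.numeric(delta_Lc), is.numeric(reference_Lc))
  if (any(!is.finite(reference_Lc)) || any(reference_Lc <= 0))
    stop("`reference_Lc` must be strictly positive (nm)")
  100 * delta_Lc / reference_Lc
}
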