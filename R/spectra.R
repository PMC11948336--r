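#' Experimental extinction spectrum
#'
#' @param nu wavenumber grid in cm^-1, strictly increasing.
#' @param eps decadic molar extinction coefficient at each grid point
#'   (M^-1 cm^-1), non-negative.
#' @return object of class `spectrum_uv`: list with `nu`, `eps`.
#' @export
spectrum_uv <- function(nu, eps) {
  nu <- as.numeric(nu); eps <- as.numeric(eps)
  if (length(nu) != length(eps)) stop("`nu` and `eps` must have equal length")
  if (length(nu) < 2) stop("a spectrum needs at least 2 grid points")
  if (any(!is.finite(nu)) || any(diff(nu) <= 0)) {
    stop("UnitError: wavenumber grid must be finite and strictly increasing")
  }
  if (any(!is.finite(eps)) || any(eps < 0)) {
    stop("extinction coefficients must be finite and non-negative")
  }
  structure(list(nu = nu, eps = eps), class = "spectrum_uv")
}

#' @export
print.spectrum_uv <- function(x, ...) {
  cat("UV-vis spectrum:", length(x$nu), "points,",
      format(min(x$nu)), "-", format(max(x$nu)), "cm^-1\n")
  invisible(x)
}

# restrict a spectrum to a wavenumber window, adding interpolated endpoints
window_spectrum <- function(s, limits) {
  limits <- sort(as.numeric(limits))
  if (limits[1] < min(s$nu) - 1e-9 || limits[2] > max(s$nu) + 1e-9) {
    stop("LimitsOutsideGrid: window [", limits[1], ", ", limits[2],
         "] exceeds the grid span [", min(s$nu), ", ", max(s$nu), "]")
  }
  inside <- s$nu > limits[1] & s$nu < limits[2]
  nu <- c(limits[1], s$nu[inside], limits[2])
  eps <- stats::approx(s$nu, s$eps, xout = nu, rule = 2)$y
  if (length(nu) < 2 || limits[1] == limits[2]) stop("EmptyWindow: empty integration window")
  list(nu = nu, eps = eps)
}

#' Experimental oscillator strength from a spectrum band
#'
#' Integrates the decadic molar extinction coefficient over a band window and
#' applies the gas-phase conversion
#' \deqn{f_{exp} = 4.319\times 10^{-9}\ \mathrm{mol\,L^{-1}\,cm^2}
#'   \int \varepsilon(\tilde\nu)\, d\tilde\nu ,}
#' using trapezoidal integration on the native grid (window endpoints are
#' linearly interpolated). For solution data the comparison reference is
#' `n * f_exp` downstream; this function returns the bare `f_exp`.
#'
#' @param s a [spectrum_uv()].
#' @param limits length-2 numeric, band window `(nu_lo, nu_hi)` in cm^-1,
#'   inside the grid span.
#' @return dimensionless oscillator strength.
#' @examples
#' nu <- seq(20000, 40000, by = 20)
#' s <- spectrum_uv(nu, 1e4 * exp(-(nu - 30000)^2 / (2 * 1000^2)))
#' f_exp_from_spectrum(s, c(20000, 40000))   # ~ 4.319e-9 * eps_max * sigma * sqrt(2*pi)
#' @export
f_exp_from_spectrum <- function(s, limits) {
  stopifnot(inherits(s, "spectrum_uv"))
  w <- window_spectrum(s, limits)
  4.319e-9 * pracma::trapz(w$nu, w$eps)
}

#' Mean band energy from a spectrum
#'
#' Extinction-weighted mean wavenumber over a band window,
#' \eqn{\bar{\tilde\nu} = \int \tilde\nu\,\varepsilon\,d\tilde\nu /
#' \int \varepsilon\,d\tilde\nu}, the experimental counterpart of the
#' strength-weighted computed band energy.
#'
#' @inheritParams f_exp_from_spectrum
#' @return mean wavenumber in cm^-1, guaranteed to lie within `limits`.
#' @export
band_mean_energy <- function(s, limits) {
  stopifnot(inherits(s, "spectrum_uv"))
  w <- window_spectrum(s, limits)
  denom <- pracma::trapz(w$nu, w$eps)
  if (denom <= 0) stop("ZeroIntensity: no extinction inside the window")
  pracma::trapz(w$nu, w$nu * w$eps) / denom
}
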