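#' Depolarization factors of an ellipsoid
#'
#' Shape factors controlling the uniform field inside an ellipsoidal cavity.
#' For semiaxes \eqn{(a, b, c)} the factor for axis k with semiaxis
#' \eqn{x_k} is
#' \deqn{A_k = \frac{abc}{2}\int_0^\infty
#'   \frac{ds}{(s + x_k^2)\sqrt{(s+a^2)(s+b^2)(s+c^2)}}.}
#' The three factors are positive, sum to 1, and a longer semiaxis carries a
#' smaller factor; for a sphere each equals 1/3.
#'
#' @param semiaxes three positive lengths (any common unit; the factors are
#'   dimensionless and scale invariant).
#' @param tol target absolute accuracy of the quadrature (default 1e-10).
#' @return numeric 3-vector `(A1, A2, A3)` in the order of `semiaxes`.
#' @examples
#' depolarization_factors(c(1, 1, 1))            # sphere: 1/3 each
#' depolarization_factors(c(2.169, 3.773, 3.694))
#' @export
depolarization_factors <- function(semiaxes, tol = 1e-10) {
  semiaxes <- as.numeric(semiaxes)
  if (length(semiaxes) != 3 || !all(is.finite(semiaxes)) || any(semiaxes <= 0)) {
    stop("NonPositiveAxis: semiaxes must be three positive finite lengths")
  }
  # scale invariance: work with normalized axes for well-conditioned quadrature
  ax <- semiaxes / exp(mean(log(semiaxes)))
  a <- ax[1]; b <- ax[2]; c <- ax[3]
  pref <- a * b * c / 2
  A <- vapply(ax, function(x) {
    f <- function(s) 1 / ((s + x^2) * sqrt((s + a^2) * (s + b^2) * (s + c^2)))
    out <- tryCatch(
      stats::integrate(f, 0, Inf, rel.tol = tol, abs.tol = tol,
                       subdivisions = 500L),
      error = function(e) stop("IntegrationFailure: ", conditionMessage(e)))
    if (out$abs.error > 1e-7) {
      stop("IntegrationFailure: estimated error ", format(out$abs.error),
           " exceeds 1e-7")
    }
    pref * out$value
  }, numeric(1))
  A
}

#' Cavity-field factor along one ellipsoid axis
#'
#' Ratio of the field inside an empty ellipsoidal cavity to the macroscopic
#' field in the surrounding dielectric, for a field along axis k:
#' \deqn{h_k = \frac{\epsilon_1}{\epsilon_1 + (\epsilon_2 - \epsilon_1) A_k}.}
#' With `eps2 = 1` (explicitly treated solute) and `eps1 = n^2` (solvent at
#' optical frequency) this is the correction entering the oscillator-strength
#' model; the sphere limit `A = 1/3` reproduces Onsager's
#' \eqn{3n^2/(2n^2+1)}.
#'
#' @param A depolarization factor(s) in `[0, 1]` (vectorized).
#' @param eps1 dielectric constant of the surrounding medium (solvent),
#'   typically `n^2` with `n` the refractive index at the sodium D line.
#' @param eps2 dielectric constant inside the cavity (default 1).
#' @return field factor(s) `h`, same length as `A`.
#' @export
cavity_field_factor <- function(A, eps1, eps2 = 1) {
  A <- as.numeric(A)
  if (any(!is.finite(A)) || any(A < 0) || any(A > 1)) {
    stop("DomainError: depolarization factor A must lie in [0, 1]")
  }
  stopifnot(eps1 > 0, eps2 > 0)
  eps1 / (eps1 + (eps2 - eps1) * A)
}

#' Depolarization and field factors for an ellipsoid
#'
#' Bundles [depolarization_factors()] and [cavity_field_factor()] for the
#' three axes of an ellipsoidal cavity.
#'
#' @param semiaxes three positive semiaxis lengths (angstrom), or an
#'   `ellipsoid` object.
#' @param n solvent refractive index at the sodium D line; sets
#'   `eps1 = n^2` unless `eps1` is given explicitly.
#' @param eps1,eps2 dielectric constants outside / inside the cavity.
#' @return object of class `cavity_factors`: list with `A`, `h`, `eps1`,
#'   `eps2`, `semiaxes`.
#' @examples
#' cavity_factors(c(2.169, 3.773, 3.694), n = 1.333)
#' @export
cavity_factors <- function(semiaxes, n = NULL, eps1 = if (!is.null(n)) n^2 else
                             stop("supply `n` or `eps1`"), eps2 = 1) {
  if (inherits(semiaxes, "ellipsoid")) semiaxes <- semiaxes$semiaxes
  A <- depolarization_factors(semiaxes)
  h <- cavity_field_factor(A, eps1 = eps1, eps2 = eps2)
  structure(list(A = A, h = h, eps1 = eps1, eps2 = eps2,
                 semiaxes = as.numeric(semiaxes)),
            class = "cavity_factors")
}

#' @export
print.cavity_factors <- function(x, ...) {
  cat("cavity factors (eps1 =", format(x$eps1, digits = 6),
      ", eps2 =", format(x$eps2, digits = 6), ")\n")
  print(data.frame(k = 1:3, semiaxis = x$semiaxes,
                   A = round(x$A, 4), h = round(x$h, 4),
                   h2 = round(x$h^2, 4)), row.names = FALSE)
  invisible(x)
}

#' Orientation-averaged squared correction factors along the lab axes
#'
#' The cavity field along a lab direction d, per unit macroscopic field,
#' depends on the orientation of the field relative to the cavity. Averaging
#' the squared component over all field orientations (uniform on the sphere)
#' and multiplying by 3 — computed oscillator strengths already carry the 1/3
#' isotropic-orientation factor — reduces analytically to
#' \deqn{\mathrm{Corr}_d^2 = \sum_k h_k^2 \, (\hat e_k \cdot \hat d)^2,}
#' where \eqn{\hat e_k} are the ellipsoid axis directions in the lab frame.
#' These are the factors that multiply squared transition dipole moment
#' components.
#'
#' @param rotation 3 x 3 orthonormal matrix mapping lab to body frame (row k
#'   = axis k direction in the lab frame), e.g. `fit_ellipsoid(...)$rotation`.
#' @param h three cavity-field factors from [cavity_field_factor()], ordered
#'   as the rotation rows.
#' @return object of class `correction_factors`: list with `corr2`
#'   (named `(x, y, z)` squared factors), `corr` (their square roots),
#'   `rotation`, `h`.
#' @examples
#' cf <- cavity_factors(c(2.169, 3.773, 3.694), n = 1.333)
#' correction_factors(diag(3), cf$h)$corr2   # aligned axes: h_k^2
#' @export
correction_factors <- function(rotation, h) {
  check_rotation(rotation)
  h <- as.numeric(h)
  stopifnot(length(h) == 3, all(is.finite(h)))
  corr2 <- drop(h^2 %*% rotation^2)    # sum_k h_k^2 R[k, d]^2
  names(corr2) <- c("x", "y", "z")
  structure(list(corr2 = corr2, corr = sqrt(corr2),
                 rotation = unname(as.matrix(rotation)), h = h),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat("orientation-averaged correction factors\n")
  cat("  Corr^2 (x, y, z):",
      paste(format(x$corr2, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Orientation average by explicit quadrature
#'
#' Direct numerical evaluation of the orientation average defining the
#' squared correction factors: the macroscopic field direction is swept over
#' the sphere (polar and azimuthal angles in the body frame) with a product
#' Gauss rule, the cavity field components are scaled by the per-axis factors
#' `h`, and the squared projection onto each lab axis is averaged and tripled.
#' Exists as an independent check of the analytic reduction in
#' [correction_factors()]; that function is the one to use.
#'
#' @inheritParams correction_factors
#' @param degree number of Gauss-Legendre nodes per angle (default 21).
#' @return numeric 3-vector of squared correction factors `(x, y, z)`.
#' @export
correction_factors_quadrature <- function(rotation, h, degree = 21) {
  check_rotation(rotation)
  h <- as.numeric(h)
  gl <- pracma::gaussLegendre(degree, -1, 1)     # cos(theta) nodes
  gp <- pracma::gaussLegendre(degree, 0, 2 * pi) # phi nodes
  corr2 <- numeric(3)
  for (d in 1:3) {
    dhat_body <- rotation[, d]                   # lab axis d in body frame
    acc <- 0
    for (i in seq_len(degree)) {
      ct <- gl$x[i]; st <- sqrt(1 - ct^2)
      ex <- st * cos(gp$x); ey <- st * sin(gp$x); ez <- ct
      proj <- h[1] * ex * dhat_body[1] + h[2] * ey * dhat_body[2] +
        h[3] * ez * dhat_body[3]
      acc <- acc + gl$w[i] * sum(gp$w * proj^2)
    }
    corr2[d] <- 3 * acc / (4 * pi)
  }
  names(corr2) <- c("x", "y", "z")
  corr2
}
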