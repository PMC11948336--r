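#' Surface point cloud
#'
#' Container for molecular-surface sample points (e.g. PCM / van der Waals
#' tesserae centres) in the lab frame, in angstrom.
#'
#' @param points numeric matrix with 3 columns (x, y, z in angstrom) or an
#'   object coercible to one.
#' @param label free-text label carried through to outputs.
#' @return an object of class `point_cloud`: a list with elements `points`
#'   (n x 3 matrix) and `label`.
#' @examples
#' pc <- point_cloud(generate_ellipsoid_cloud(c(1, 2, 3), n_points = 50, seed = 1)$points)
#' nrow(pc$points)
#' @export
point_cloud <- function(points, label = "") {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must have exactly 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) < 9) {
    stop("TooFewPoints: a quadric fit needs at least 9 points, got ", nrow(points))
  }
  if (!all(is.finite(points))) stop("all coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, label = as.character(label)[1]),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", nrow(x$points), "points",
      if (nzchar(x$label)) paste0("(", x$label, ")") else "", "\n")
  invisible(x)
}

as_point_cloud <- function(x) {
  if (inherits(x, "point_cloud")) x else point_cloud(x)
}

#' Fit a general quadric surface to points
#'
#' Least-squares fit of the general quadric
#' \deqn{a x^2 + b y^2 + c z^2 + d xy + e xz + f yz + g x + h y + i z = 1}
#' to a point cloud, i.e. the constant term is fixed to -1 and the nine
#' remaining coefficients solve an ordinary linear least-squares problem.
#' When that system is rank deficient but the homogeneous 10-coefficient
#' problem still has a one-dimensional null space (a surface through the
#' origin), the fit falls back to the unit-norm eigenvector of the
#' homogeneous system.
#'
#' @param cloud a [point_cloud()] (or an n x 3 matrix).
#' @return an object of class `quadric`: list with `Q` (symmetric 3 x 3
#'   quadratic-form matrix), `b` (half the linear coefficients, so the surface
#'   is \eqn{x'Qx + 2b'x + j = 0}), `j` (constant term), `coefficients`
#'   (named a..i vector), `normalization` ("constant-fixed" or "unit-norm"),
#'   and `rms` (root-mean-square algebraic residual).
#' @examples
#' cl <- generate_ellipsoid_cloud(c(2, 3, 4), n_points = 200, seed = 1)
#' q <- fit_quadric(cl)
#' q$rms
#' @export
fit_quadric <- function(cloud) {
  cloud <- as_point_cloud(cloud)
  p <- cloud$points
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  D <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z)
  colnames(D) <- c("a", "b", "c", "d", "e", "f", "g", "h", "i")
  sv <- svd(D, nu = 0, nv = 0)$d
  rank_tol <- max(dim(D)) * .Machine$double.eps * sv[1]
  if (sum(sv > rank_tol) == 9L) {
    beta <- qr.coef(qr(D), rep(1, nrow(D)))
    j <- -1
    normalization <- "constant-fixed"
    resid <- D %*% beta - 1
  } else {
    # surface may pass through the origin: homogeneous fit with unit-norm
    # coefficient vector
    D10 <- cbind(D, 1)
    s10 <- svd(D10)
    if (sum(s10$d > max(dim(D10)) * .Machine$double.eps * s10$d[1]) < 9L) {
      stop("DegenerateConfiguration: design matrix is rank deficient ",
           "(points may be coplanar or otherwise degenerate)")
    }
    v <- s10$v[, 10]
    beta <- v[1:9]
    j <- v[10]
    normalization <- "unit-norm"
    resid <- D10 %*% v
  }
  if (max(abs(beta[1:6])) < 1e-12 * max(1, max(abs(beta)))) {
    stop("DegenerateConfiguration: all second-order coefficients vanish")
  }
  names(beta) <- colnames(D)
  Q <- matrix(c(beta["a"], beta["d"] / 2, beta["e"] / 2,
                beta["d"] / 2, beta["b"], beta["f"] / 2,
                beta["e"] / 2, beta["f"] / 2, beta["c"]), 3, 3)
  structure(list(Q = Q, b = beta[7:9] / 2, j = j,
                 coefficients = beta, normalization = normalization,
                 rms = sqrt(mean(resid^2))),
            class = "quadric")
}

#' @export
print.quadric <- function(x, ...) {
  cat("quadric surface (", x$normalization, " normalization), rms residual ",
      format(x$rms, digits = 4), "\n", sep = "")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Reduce a quadric to a canonical ellipsoid
#'
#' Diagonalizes the quadratic form, translates to the ellipsoid centre, and
#' returns centre, rotation and semiaxes such that in the rotated/translated
#' frame the surface satisfies
#' \eqn{(x''/a'')^2 + (y''/b'')^2 + (z''/c'')^2 = 1}.
#'
#' @param q a `quadric` from [fit_quadric()].
#' @return an object of class `ellipsoid`: list with `center` (3-vector,
#'   angstrom, lab frame), `rotation` (3 x 3 orthonormal, determinant +1;
#'   row k is the direction of semiaxis k in the lab frame, so
#'   `rotation %*% (x - center)` gives body-frame coordinates), `semiaxes`
#'   (ascending, angstrom; semiaxis k pairs with rotation row k) and
#'   `fit_rms` (algebraic residual of the source fit, `NA` for analytic
#'   constructions).
#' @details The quadratic form is first multiplied by the sign that makes the
#'   majority of its eigenvalues positive; the surface is an ellipsoid only if
#'   all eigenvalues are then strictly positive (relative tolerance 1e-10) and
#'   the centred constant is positive.
#' @export
canonicalize <- function(q) {
  stopifnot(inherits(q, "quadric"))
  eg <- eigen(q$Q, symmetric = TRUE)
  s <- if (sum(eg$values > 0) >= 2) 1 else -1
  lam <- s * eg$values
  if (any(lam <= 1e-10 * max(abs(lam)))) {
    stop("NotAnEllipsoid: quadratic form is not positive definite ",
         "(paraboloid, hyperboloid or cylinder)")
  }
  Q <- s * q$Q; b <- s * q$b; j <- s * q$j
  center <- drop(-solve(Q, b))
  c0 <- drop(crossprod(b, solve(Q, b))) - j
  if (c0 <= 0) stop("NotAnEllipsoid: empty or point-like surface")
  semiaxes <- sqrt(c0 / lam)
  o <- order(semiaxes)            # ascending, rotation rows kept in step
  semiaxes <- semiaxes[o]
  R <- t(eg$vectors)[o, , drop = FALSE]
  # deterministic signs: dominant component of each axis direction positive
  for (k in 1:3) {
    m <- which.max(abs(R[k, ]))
    if (R[k, m] < 0) R[k, ] <- -R[k, ]
  }
  if (det(R) < 0) R[3, ] <- -R[3, ]
  structure(list(center = unname(center), rotation = unname(R),
                 semiaxes = unname(semiaxes), fit_rms = q$rms),
            class = "ellipsoid")
}

#' Fit an ellipsoid to surface points
#'
#' Convenience composition of [fit_quadric()] and [canonicalize()], the
#' geometric model used for the molecular cavity: an ellipsoid interpolated
#' through PCM / van der Waals surface points.
#'
#' @inheritParams fit_quadric
#' @return an `ellipsoid` (see [canonicalize()]) with `fit_rms` populated.
#' @examples
#' cl <- generate_ellipsoid_cloud(c(2.169, 3.773, 3.694), n_points = 400, seed = 7)
#' e <- fit_ellipsoid(cl)
#' e$semiaxes
#' @export
fit_ellipsoid <- function(cloud) {
  canonicalize(fit_quadric(cloud))
}

#' Construct an ellipsoid analytically
#'
#' @param semiaxes three positive lengths (angstrom).
#' @param rotation 3 x 3 orthonormal matrix, row k = direction of axis k in
#'   the lab frame (default identity).
#' @param center 3-vector (default origin).
#' @return an `ellipsoid` object (`fit_rms` is `NA`).
#' @export
ellipsoid <- function(semiaxes, rotation = diag(3), center = c(0, 0, 0)) {
  semiaxes <- as.numeric(semiaxes)
  stopifnot(length(semiaxes) == 3, all(semiaxes > 0), all(is.finite(semiaxes)))
  check_rotation(rotation)
  structure(list(center = as.numeric(center), rotation = unname(rotation),
                 semiaxes = semiaxes, fit_rms = NA_real_),
            class = "ellipsoid")
}

check_rotation <- function(R, tol = 1e-8) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3)) ||
      max(abs(crossprod(R) - diag(3))) > tol ||
      abs(det(R) - 1) > tol) {
    stop("NonOrthonormalRotation: rotation must be 3x3 orthonormal with det +1")
  }
  invisible(R)
}

#' Quadric coefficients of an ellipsoid
#'
#' Inverse of [canonicalize()]: the quadric whose solution set is the given
#' ellipsoid, under the constant-fixed normalization (surface equation
#' `x'Qx + 2b'x = 1`).
#'
#' @param e an `ellipsoid`.
#' @return a `quadric` object.
#' @export
ellipsoid_quadric <- function(e) {
  stopifnot(inherits(e, "ellipsoid"))
  R <- e$rotation
  Qb <- t(R) %*% diag(1 / e$semiaxes^2) %*% R   # body-frame form in lab coords
  x0 <- e$center
  # (x-x0)' Qb (x-x0) = 1  ->  x'Qx + 2 b'x + j = 0 with constant scaled to -1
  c0 <- 1 - drop(t(x0) %*% Qb %*% x0)           # j before scaling = -c0
  if (abs(c0) < 1e-12) {
    Q <- Qb; b <- drop(-Qb %*% x0); j <- -c0
    normalization <- "unit-norm"
    nrm <- sqrt(sum(Q^2) + sum((2 * b)^2) + j^2)
    Q <- Q / nrm; b <- b / nrm; j <- j / nrm
  } else {
    Q <- Qb / c0; b <- drop(-Qb %*% x0) / c0; j <- -1
    normalization <- "constant-fixed"
  }
  beta <- c(Q[1, 1], Q[2, 2], Q[3, 3], 2 * Q[1, 2], 2 * Q[1, 3], 2 * Q[2, 3],
            2 * b)
  names(beta) <- c("a", "b", "c", "d", "e", "f", "g", "h", "i")
  structure(list(Q = Q, b = b, j = j, coefficients = beta,
                 normalization = normalization, rms = 0),
            class = "quadric")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat("ellipsoid\n")
  cat("  semiaxes [A]:", paste(format(x$semiaxes, digits = 6), collapse = ", "), "\n")
  cat("  center   [A]:", paste(format(x$center, digits = 6), collapse = ", "), "\n")
  if (is.finite(x$fit_rms)) cat("  fit rms     :", format(x$fit_rms, digits = 4), "\n")
  invisible(x)
}
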