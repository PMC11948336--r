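# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate surface points on an ellipsoid
#'
#' Draws directions uniformly on the sphere (normalized Gaussian vectors),
#' projects each onto the ellipsoid surface along its ray, and optionally
#' perturbs each point radially by Gaussian noise — a stand-in for PCM / van
#' der Waals tesserae. Deterministic for a fixed seed.
#'
#' @param semiaxes three positive semiaxis lengths (angstrom).
#' @param rotation 3 x 3 orthonormal matrix, row k = axis k direction in the
#'   lab frame.
#' @param center ellipsoid centre (angstrom).
#' @param n_points number of points (>= 9).
#' @param noise_sigma standard deviation of the radial noise (angstrom).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [point_cloud()].
#' @examples
#' cl <- generate_ellipsoid_cloud(c(2.169, 3.773, 3.694), n_points = 300, seed = 1)
#' fit_ellipsoid(cl)$semiaxes
#' @export
generate_ellipsoid_cloud <- function(semiaxes, rotation = diag(3),
                                     center = c(0, 0, 0), n_points = 500,
                                     noise_sigma = 0, seed = NULL) {
  semiaxes <- as.numeric(semiaxes)
  stopifnot(length(semiaxes) == 3, all(semiaxes > 0), noise_sigma >= 0)
  if (n_points < 9) stop("TooFewPoints: need at least 9 points")
  check_rotation(rotation)
  with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n_points), n_points, 3)
    u <- u / sqrt(rowSums(u^2))
    # ray-surface intersection in the body frame
    t_hit <- 1 / sqrt(rowSums(sweep(u, 2, semiaxes, "/")^2))
    body <- u * t_hit
    if (noise_sigma > 0) {
      r <- sqrt(rowSums(body^2))
      body <- body * (1 + stats::rnorm(n_points, sd = noise_sigma) / r)
    }
    lab <- body %*% rotation          # t(R) %*% body, row-wise
    lab <- sweep(lab, 2, center, "+")
    point_cloud(lab, label = sprintf("synthetic ellipsoid (%s)",
                                     paste(format(semiaxes), collapse = ", ")))
  })
}

#' Specification of a synthetic benchmark dataset
#'
#' @param n_bands number of disjoint experimental bands (>= 1).
#' @param band_width_cm1 width of each band window (cm^-1).
#' @param s_true true scaling between total computed strength per band and
#'   the reference `n * f_exp` (> 0).
#' @param sigma_f relative Gaussian noise on the per-band total computed
#'   strength (>= 0).
#' @param n solvent refractive index (sodium D line).
#' @param seed integer RNG seed.
#' @param gap_cm1 gap between consecutive band windows (cm^-1).
#' @param nu_start_cm1 lower edge of the first band (cm^-1).
#' @return a validated list of class `synthetic_benchmark_spec`.
#' @export
synthetic_benchmark_spec <- function(n_bands = 20, band_width_cm1 = 4000,
                                     s_true = 1, sigma_f = 0.1, n = 1.333,
                                     seed = 1, gap_cm1 = 1000,
                                     nu_start_cm1 = 20000) {
  stopifnot(n_bands >= 1, band_width_cm1 > 0, s_true > 0, sigma_f >= 0,
            n >= 1, gap_cm1 > 0)
  structure(list(n_bands = n_bands, band_width_cm1 = band_width_cm1,
                 s_true = s_true, sigma_f = sigma_f, n = n, seed = seed,
                 gap_cm1 = gap_cm1, nu_start_cm1 = nu_start_cm1),
            class = "synthetic_benchmark_spec")
}

#' Generate a synthetic benchmark dataset
#'
#' Emulates the structure the benchmark statistics assume: disjoint
#' experimental bands, each carrying a Gaussian extinction spectrum from which
#' `f_exp` and the mean band energy are derived, and 1–3 computed transitions
#' inside each band window whose total (length-gauge) strength is
#' `s_true * n * f_exp * (1 + e)` with `e ~ N(0, sigma_f)`. Momentum-gauge
#' vectors are set to `E_h * mu`, so all gauges agree exactly for every
#' synthetic transition. Deterministic for a fixed seed. It emulates band
#' structure and strength scaling only — not overlapping bands, baseline
#' drift, vibronic shape, or gauge disagreement of approximate wavefunctions.
#'
#' @param spec a [synthetic_benchmark_spec()], or arguments passed to it via
#'   `...`.
#' @param ... used to build the spec when `spec` is missing.
#' @return list with `transitions` (a [transitions()] table), `bands` (data
#'   frame with `band_id, nu_lo_cm1, nu_hi_cm1, f_exp, n_solvent, E_exp_cm1`),
#'   `spectra` (named list of [spectrum_uv()]), `exclusions` (empty), `spec`.
#' @examples
#' ds <- generate_synthetic_benchmark(synthetic_benchmark_spec(
#'   n_bands = 5, s_true = 1.3, sigma_f = 0, seed = 42))
#' scaling_factor(ds$transitions, ds$bands, mode = "ebl")$C   # ~1.3
#' @export
generate_synthetic_benchmark <- function(spec = synthetic_benchmark_spec(...),
                                         ...) {
  stopifnot(inherits(spec, "synthetic_benchmark_spec"))
  with_seed(spec$seed, {
    lo <- spec$nu_start_cm1 +
      (seq_len(spec$n_bands) - 1) * (spec$band_width_cm1 + spec$gap_cm1)
    hi <- lo + spec$band_width_cm1
    bands <- data.frame(band_id = seq_len(spec$n_bands), nu_lo_cm1 = lo,
                        nu_hi_cm1 = hi, f_exp = NA_real_, n_solvent = spec$n,
                        E_exp_cm1 = NA_real_)
    spectra <- list()
    tr_rows <- list()
    next_id <- 1L
    for (k in seq_len(spec$n_bands)) {
      center <- (lo[k] + hi[k]) / 2 +
        stats::runif(1, -0.1, 0.1) * spec$band_width_cm1
      sdv <- spec$band_width_cm1 / 6
      eps_max <- stats::runif(1, 5e3, 3e4)
      nu <- seq(lo[k], hi[k], length.out = 201)
      s <- spectrum_uv(nu, eps_max * exp(-(nu - center)^2 / (2 * sdv^2)))
      spectra[[as.character(k)]] <- s
      bands$f_exp[k] <- f_exp_from_spectrum(s, c(lo[k], hi[k]))
      bands$E_exp_cm1[k] <- band_mean_energy(s, c(lo[k], hi[k]))
      # transitions: total strength s_true * n * f_exp * (1 + e)
      target <- spec$s_true * spec$n * bands$f_exp[k] *
        max(1 + stats::rnorm(1, sd = spec$sigma_f), 0.05)
      m <- sample(1:3, 1)
      share <- stats::runif(m, 0.2, 1)
      share <- share / sum(share)
      e_ev <- sort(cm1_to_ev(stats::runif(
        m, lo[k] + 0.1 * spec$band_width_cm1,
        hi[k] - 0.1 * spec$band_width_cm1)))
      for (i in seq_len(m)) {
        f_i <- target * share[i]
        eh <- e_ev[i] * EV_TO_HARTREE
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        mu <- dir * sqrt(3 * f_i / (2 * eh))
        tr_rows[[next_id]] <- data.frame(
          id = next_id, energy_ev = e_ev[i],
          mu_x = mu[1], mu_y = mu[2], mu_z = mu[3],
          p_x = eh * mu[1], p_y = eh * mu[2], p_z = eh * mu[3])
        next_id <- next_id + 1L
      }
    }
    list(transitions = transitions(do.call(rbind, tr_rows)), bands = bands,
         spectra = spectra, exclusions = integer(), spec = spec)
  })
}
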