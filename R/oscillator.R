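#' Oscillator strength from transition dipole moments
#'
#' Dimensionless absorption strength of an electronic 0 -> i transition, in
#' one of three gauges (all in atomic units, with `E_h` the excitation energy
#' in hartree):
#' \itemize{
#'   \item length:   \eqn{f = (2/3)\, E_h\, |\mu|^2}
#'   \item velocity: \eqn{f = (2/3)\, |p|^2 / E_h}
#'   \item mixed:    \eqn{f = (2/3)\, \mu \cdot p} (energy-independent; the
#'     signed dot product is returned as is, a negative value indicating
#'     inconsistent gauges)
#' }
#'
#' @param mu length-gauge transition dipole moment, 3-vector (a.u.).
#' @param p velocity-gauge (momentum) transition dipole moment, 3-vector
#'   (a.u.); required for the velocity and mixed gauges.
#' @param energy_ev excitation energy in eV (converted internally to hartree).
#' @param gauge one of `"length"`, `"velocity"`, `"mixed"`.
#' @return oscillator strength (dimensionless scalar).
#' @examples
#' oscillator_strength(mu = c(1, 0, 0), energy_ev = 0.1 / 0.0367493)  # E = 0.1 Ha
#' @export
oscillator_strength <- function(mu = NULL, p = NULL, energy_ev,
                                gauge = c("length", "velocity", "mixed")) {
  gauge <- match.arg(gauge)
  if (!is.numeric(energy_ev) || length(energy_ev) != 1 || energy_ev <= 0) {
    stop("NonPositiveEnergy: excitation energy must be a positive scalar (eV)")
  }
  eh <- energy_ev * EV_TO_HARTREE
  need <- switch(gauge, length = "mu", velocity = "p", mixed = c("mu", "p"))
  for (nm in need) {
    v <- get(nm)
    if (is.null(v) || length(v) != 3 || !all(is.finite(v))) {
      stop("MissingVector: gauge '", gauge, "' requires a finite 3-vector `",
           nm, "`")
    }
  }
  switch(gauge,
         length = (2 / 3) * eh * sum(mu^2),
         velocity = (2 / 3) * sum(p^2) / eh,
         mixed = (2 / 3) * sum(mu * p))
}

#' Transition table with per-gauge oscillator strengths
#'
#' Normalizes a table of computed electronic transitions and computes raw
#' oscillator strengths in every gauge the supplied vectors allow.
#'
#' @param df data frame with columns `id`, `energy_ev`, `mu_x`, `mu_y`,
#'   `mu_z` and optionally `p_x`, `p_y`, `p_z` (atomic units).
#' @return data frame of class `transitions` with added columns `f_len` and,
#'   when momentum vectors are present, `f_vel`, `f_mix`.
#' @export
transitions <- function(df) {
  df <- as.data.frame(df)
  req <- c("id", "energy_ev", "mu_x", "mu_y", "mu_z")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("SchemaError: missing column(s) ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$energy_ev)) || any(df$energy_ev <= 0)) {
    stop("NonPositiveEnergy: all transition energies must be positive")
  }
  has_p <- all(c("p_x", "p_y", "p_z") %in% names(df))
  df$f_len <- vapply(seq_len(nrow(df)), function(i) {
    oscillator_strength(mu = c(df$mu_x[i], df$mu_y[i], df$mu_z[i]),
                        energy_ev = df$energy_ev[i], gauge = "length")
  }, numeric(1))
  if (has_p) {
    df$f_vel <- vapply(seq_len(nrow(df)), function(i) {
      oscillator_strength(p = c(df$p_x[i], df$p_y[i], df$p_z[i]),
                          energy_ev = df$energy_ev[i], gauge = "velocity")
    }, numeric(1))
    df$f_mix <- vapply(seq_len(nrow(df)), function(i) {
      oscillator_strength(mu = c(df$mu_x[i], df$mu_y[i], df$mu_z[i]),
                          p = c(df$p_x[i], df$p_y[i], df$p_z[i]),
                          energy_ev = df$energy_ev[i], gauge = "mixed")
    }, numeric(1))
    if (any(df$f_mix < 0)) {
      message("note: ", sum(df$f_mix < 0),
              " transition(s) have negative mixed-gauge strength (mu.p < 0)")
    }
  }
  class(df) <- c("transitions", "data.frame")
  df
}

#' Apply the cavity-field correction to transition dipole moments
#'
#' Multiplies each Cartesian component d of every transition dipole moment by
#' `Corr_d` (the square root of the orientation-averaged squared correction
#' factor along lab axis d) and recomputes the oscillator strengths per gauge
#' from the corrected vectors. The corrected strengths are the "Scholte"
#' strengths `f^S`; raw columns are kept untouched. The same factors are
#' applied to length- and velocity-gauge vectors.
#'
#' @param t a `transitions` table (see [transitions()]), or a data frame with
#'   its columns.
#' @param c a `correction_factors` object from [correction_factors()], built
#'   from the same molecule's ellipsoid.
#' @return the input table with added columns `fS_len` and, when momentum
#'   vectors are present, `fS_vel`, `fS_mix`.
#' @examples
#' tr <- transitions(data.frame(id = 1, energy_ev = 4, mu_x = 1, mu_y = 0, mu_z = 0))
#' cf <- cavity_factors(c(2.169, 3.773, 3.694), n = 1.333)
#' corrected_os(tr, correction_factors(diag(3), cf$h))
#' @export
corrected_os <- function(t, c) {
  if (!inherits(c, "correction_factors")) {
    stop("MissingFactors: `c` must be a correction_factors object")
  }
  if (!inherits(t, "transitions")) t <- transitions(t)
  corr <- c$corr
  has_p <- all(c("p_x", "p_y", "p_z") %in% names(t))
  t$fS_len <- vapply(seq_len(nrow(t)), function(i) {
    oscillator_strength(
      mu = corr * c(t$mu_x[i], t$mu_y[i], t$mu_z[i]),
      energy_ev = t$energy_ev[i], gauge = "length")
  }, numeric(1))
  if (has_p) {
    t$fS_vel <- vapply(seq_len(nrow(t)), function(i) {
      oscillator_strength(
        p = corr * c(t$p_x[i], t$p_y[i], t$p_z[i]),
        energy_ev = t$energy_ev[i], gauge = "velocity")
    }, numeric(1))
    t$fS_mix <- vapply(seq_len(nrow(t)), function(i) {
      oscillator_strength(
        mu = corr * c(t$mu_x[i], t$mu_y[i], t$mu_z[i]),
        p = corr * c(t$p_x[i], t$p_y[i], t$p_z[i]),
        energy_ev = t$energy_ev[i], gauge = "mixed")
    }, numeric(1))
  }
  t
}
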