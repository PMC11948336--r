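# shared fixtures built in code

rot_axis <- function(angle, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  co <- cos(angle); si <- sin(angle)
  switch(axis,
         z = matrix(c(co, -si, 0, si, co, 0, 0, 0, 1), 3, 3, byrow = TRUE),
         y = matrix(c(co, 0, si, 0, 1, 0, -si, 0, co), 3, 3, byrow = TRUE),
         x = matrix(c(1, 0, 0, 0, co, -si, 0, si, co), 3, 3, byrow = TRUE))
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Table 1 inputs: pyridinium cavity ellipsoid, water solvent
pyridinium_semiaxes <- c(2.169, 3.773, 3.694)
water_n <- 1.333

# closed-form depolarization factor along the long axis of a prolate
# spheroid with semiaxes (a, b, b), a > b — independent oracle
prolate_A_long <- function(a, b) {
  e <- sqrt(1 - (b / a)^2)
  (1 - e^2) / e^3 * (0.5 * log((1 + e) / (1 - e)) - e)
}

onsager_h <- function(n) 3 * n^2 / (2 * n^2 + 1)

# simple toy transitions table: strengths realised through mu along x
toy_transitions <- function(energy_ev, f_len) {
  stopifnot(length(energy_ev) == length(f_len))
  eh <- energy_ev * 0.0367493
  mu <- sqrt(3 * f_len / (2 * eh))
  zero <- rep(0, length(energy_ev))
  transitions(data.frame(id = seq_along(energy_ev), energy_ev = energy_ev,
                         mu_x = mu, mu_y = zero, mu_z = zero,
                         p_x = eh * mu, p_y = zero, p_z = zero))
}

# bands from eV windows with directly prescribed references n * f_exp
toy_bands <- function(lo_ev, hi_ev, nf_exp, n_solvent = 1.333) {
  data.frame(band_id = seq_along(lo_ev),
             nu_lo_cm1 = ev_to_cm1(lo_ev), nu_hi_cm1 = ev_to_cm1(hi_ev),
             f_exp = nf_exp / n_solvent, n_solvent = n_solvent)
}
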