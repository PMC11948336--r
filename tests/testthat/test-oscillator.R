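test_that("per-gauge oscillator strength formulas are correct", {
  expect_equal(oscillator_strength(mu = c(0, 0, 0), energy_ev = 4,
                                   gauge = "length"), 0)
  # |mu|^2 = 1 a.u., E = 0.1 hartree -> f = (2/3) * 0.1
  e_ev <- 0.1 / 0.0367493
  expect_equal(oscillator_strength(mu = c(1, 0, 0), energy_ev = e_ev,
                                   gauge = "length"), 2 / 30, tolerance = 1e-12)
  expect_error(oscillator_strength(mu = c(1, 0, 0), energy_ev = -1), "NonPositiveEnergy")
  expect_error(oscillator_strength(energy_ev = 1, gauge = "length"), "MissingVector")
  expect_error(oscillator_strength(mu = c(1, 0, 0), energy_ev = 1,
                                   gauge = "velocity"), "MissingVector")
})

test_that("p = E * mu makes all three gauges agree", {
  set.seed(14)
  for (i in 1:20) {
    mu <- rnorm(3)
    e_ev <- runif(1, 1, 10)
    eh <- e_ev * 0.0367493
    p <- eh * mu
    f <- vapply(c("length", "velocity", "mixed"), function(g) {
      oscillator_strength(mu = mu, p = p, energy_ev = e_ev, gauge = g)
    }, numeric(1))
    expect_equal(unname(f[2]), unname(f[1]), tolerance = 1e-12)
    expect_equal(unname(f[3]), unname(f[1]), tolerance = 1e-12)
  }
})

test_that("cavity-field correction scales strengths componentwise", {
  cf <- cavity_factors(pyridinium_semiaxes, n = water_n)
  co <- correction_factors(diag(3), cf$h)
  # identity correction leaves everything unchanged
  tr <- toy_transitions(c(4, 5), c(0.2, 0.4))
  out <- corrected_os(tr, correction_factors(diag(3), c(1, 1, 1)))
  expect_equal(out$fS_len, out$f_len, tolerance = 1e-12)
  expect_equal(out$fS_vel, out$f_vel, tolerance = 1e-12)
  # TDM along lab x: f^S = Corr_x^2 * f in length gauge
  out <- corrected_os(tr, co)
  expect_equal(out$fS_len / out$f_len, rep(unname(co$corr2["x"]), 2),
               tolerance = 1e-9)
  # mu = (1, 1, 0) / sqrt(2): ratio is the mean of Corr_x^2 and Corr_y^2
  tr2 <- transitions(data.frame(id = 1, energy_ev = 4,
                                mu_x = 1 / sqrt(2), mu_y = 1 / sqrt(2), mu_z = 0))
  out2 <- corrected_os(tr2, co)
  expect_equal(out2$fS_len / out2$f_len,
               unname(co$corr2["x"] + co$corr2["y"]) / 2, tolerance = 1e-9)
  expect_equal(round(unname(co$corr2["x"] + co$corr2["y"]) / 2, 3), 1.438)
  expect_error(corrected_os(tr, list(corr = c(1, 1, 1))), "MissingFactors")
})

test_that("corrected strengths never fall below raw ones when Corr^2 >= 1", {
  set.seed(8)
  cf <- cavity_factors(c(1.5, 2.5, 4), n = 1.45)
  for (i in 1:10) {
    co <- correction_factors(random_rotation(), cf$h)
    df <- data.frame(id = 1:5, energy_ev = runif(5, 2, 8),
                     mu_x = rnorm(5), mu_y = rnorm(5), mu_z = rnorm(5))
    df[c("p_x", "p_y", "p_z")] <- df[c("mu_x", "mu_y", "mu_z")] *
      (df$energy_ev * 0.0367493)
    out <- corrected_os(transitions(df), co)
    expect_true(all(out$fS_len >= out$f_len - 1e-12))
    expect_true(all(out$fS_vel >= out$f_vel - 1e-12))
  }
})

test_that("raw strengths are rotation invariant; corrected ones are frame-consistent", {
  truth_ax <- c(1.8, 2.6, 3.9)
  mu <- c(0.8, -0.3, 0.5)
  e_ev <- 4.2
  mk <- function(mu) transitions(data.frame(id = 1, energy_ev = e_ev,
                                            mu_x = mu[1], mu_y = mu[2],
                                            mu_z = mu[3]))
  cl0 <- generate_ellipsoid_cloud(truth_ax, n_points = 400, seed = 31)
  e0 <- fit_ellipsoid(cl0)
  h0 <- cavity_factors(e0, n = water_n)$h
  co0 <- correction_factors(e0$rotation, h0)
  f0 <- corrected_os(mk(mu), co0)
  # raw strengths do not depend on the molecule's orientation
  R_mol <- rot_axis(0.77) %*% rot_axis(-0.3, "x")
  cl1 <- point_cloud(cl0$points %*% t(R_mol))
  e1 <- fit_ellipsoid(cl1)
  co1 <- correction_factors(e1$rotation, cavity_factors(e1, n = water_n)$h)
  f1 <- corrected_os(mk(drop(R_mol %*% mu)), co1)
  expect_equal(f1$f_len, f0$f_len, tolerance = 1e-10)
  # the lab-component correction is exact in the aligned frame:
  # f^S = (2/3) E sum_k h_k^2 mu_k^2 with mu resolved along the cavity axes
  mu_body <- drop(e0$rotation %*% mu)
  expect_equal(f0$fS_len,
               (2 / 3) * e_ev * 0.0367493 * sum((h0 * mu_body)^2),
               tolerance = 1e-8)
  # and invariant under 90-degree relabelings of the lab axes
  P <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))  # cyclic axis permutation
  clp <- point_cloud(cl0$points %*% t(P))
  ep <- fit_ellipsoid(clp)
  cop <- correction_factors(ep$rotation, cavity_factors(ep, n = water_n)$h)
  fp <- corrected_os(mk(drop(P %*% mu)), cop)
  expect_equal(fp$fS_len, f0$fS_len, tolerance = 1e-8)
})

test_that("negative mixed-gauge strengths pass through with a note", {
  df <- data.frame(id = 1, energy_ev = 4, mu_x = 1, mu_y = 0, mu_z = 0,
                   p_x = -0.2, p_y = 0, p_z = 0)
  expect_message(tr <- transitions(df), "negative mixed-gauge")
  expect_lt(tr$f_mix, 0)
})
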