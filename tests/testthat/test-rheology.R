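test_that("GSER plateau returns the trap stiffness of an OU trap", {
  L <- 1e-8; Tb <- 310.15
  G_trap <- 5e-5; eta <- 0.05
  zeta <- 6 * pi * L * eta
  rate <- G_trap / zeta
  x <- simulate_ou(kB() * Tb / G_trap, rate, 4e5, 1e-4, seed = 11)
  rh <- gser_modulus(compute_psd(x, segment_length = 8192, dt = 1e-4),
                     L = L, T = Tb)
  plateau <- median(rh$G_prime[rh$omega < rate / 10])
  expect_lt(abs(plateau / G_trap - 1), 0.05)
})

test_that("GSER on free diffusion returns a flat milieu viscosity", {
  L <- 1e-8; Tb <- 310.15; D <- 1e-15; dt <- 1e-4
  set.seed(4)
  x <- cumsum(rnorm(4e5, 0, sqrt(2 * D * dt)))
  rh <- gser_modulus(compute_psd(x, segment_length = 4096, dt = dt),
                     L = L, T = Tb)
  eta_true <- kB() * Tb / (6 * pi * L * D)       # zeta/(6 pi L)
  mid <- rh$omega > 100 & rh$omega < 3000
  expect_lt(abs(median(rh$eta_eff[mid]) / eta_true - 1), 0.1)
  ## flat: relative spread across the mid-band is small
  expect_lt(diff(range(rh$eta_eff[mid])) / eta_true, 0.35)
})

test_that("GSER on the bending membrane shows the omega^(2/3) rigidity", {
  bend <- fx_bend_sp()
  rh <- gser_modulus(bend$sp, L = bend$s$L, T = fx_m_bend()$T)
  i <- rh$omega > 100 & rh$omega < 2500
  slope <- coef(lm(log(rh$G_prime[i]) ~ log(rh$omega[i])))[2]
  expect_lt(abs(slope - 2 / 3), 0.1)
  ## fractional fit of the same curve gives the passive bending exponent
  fr <- fit_fractional_rigidity(rh, R = fx_m_bend()$R_bar,
                                T = fx_m_bend()$T, omega_range = c(20, 2500))
  expect_lt(abs(fr$alpha - 1 / 3), 0.07)
})

test_that("GSER round trip recovers the generator tension", {
  ## tension-dominated membrane whose slowest mode relaxes well inside the
  ## spectral band, so the equipartition plateau is resolved
  mt <- membrane_params(gamma = 4e-4, kappa = 2e-19, eta = 1.0)
  s <- suppressWarnings(simulate_passive_contour(mt, N = 128,
                                                 n_frames = 20000, dt = 5e-4,
                                                 n_modes = 64, seed = 23))
  sp <- compute_psd(s, segment_length = 4096)
  rh <- gser_modulus(sp, L = s$L, T = mt$T)
  ## tension fit below the mode-relaxation band (plateau window)
  fr <- fit_fractional_rigidity(rh, R = mt$R_bar, T = mt$T,
                                omega_range = c(3, 80))
  ## invert the analytic mode-sum bijection gamma <-> kBT/Sigma2_pass
  g_hat <- uniroot(function(g)
    kB() * mt$T / passive_variance_sum(
      membrane_params(gamma = g, kappa = mt$kappa, eta = mt$eta), 64) -
      fr$G_gamma, c(mt$gamma / 30, mt$gamma * 30))$root
  expect_lt(abs(g_hat / mt$gamma - 1), 0.2)
})

test_that("effective temperature kernel has the K(0) = 1 normalization", {
  Tb <- 310.15
  expect_equal(effective_temperature_kernel(1:10, 0, 1e-19, 0.02, Tb),
               rep(Tb, 10))
  e_act <- 0.3 * 1.25e-19 / kB()
  expect_equal(effective_temperature_kernel(0, 0.3, 1.25e-19, 0.02, Tb),
               Tb + e_act)
  ## x = pi: K = 4/pi^2
  expect_equal(effective_temperature_kernel(pi / 0.02, 0.3, 1.25e-19, 0.02,
                                            Tb),
               Tb + e_act * 4 / pi^2)
  expect_error(effective_temperature_kernel(1, 0.3, 1e-19, 0), "positive")
})

test_that("fractional rigidity fit is exact on model curves", {
  om <- exp(seq(log(3), log(3000), length.out = 300))
  truth <- c(Gg = 5e-5, Gk = 2e-4, tauD = 1 / 300, al = 0.25)
  r <- list(omega = om,
            G_prime = fractional_rigidity_model(om, truth["Gg"], truth["Gk"],
                                                truth["tauD"], truth["al"]))
  fr <- fit_fractional_rigidity(r, R = 3.6e-6, T = 310.15)
  expect_equal(fr$G_gamma, unname(truth["Gg"]), tolerance = 1e-4)
  expect_equal(fr$G_kappa, unname(truth["Gk"]), tolerance = 1e-4)
  expect_equal(fr$tau_D, unname(truth["tauD"]), tolerance = 1e-4)
  expect_equal(fr$alpha, unname(truth["al"]), tolerance = 1e-4)
  expect_equal(fr$gamma_eff, fr$G_gamma * 3.6e-6 / 4)
  ## deterministic: identical data give identical fits
  fr2 <- fit_fractional_rigidity(r, R = 3.6e-6, T = 310.15)
  expect_identical(coef(fr), coef(fr2))
})

test_that("alpha = 1/4 rigidity branch rises with exponent one half", {
  tauD <- 1 / 300
  om <- exp(seq(log(1e-5 / tauD), log(1e-4 / tauD), length.out = 50))
  g <- fractional_rigidity_model(om, 0, 2e-4, tauD, 0.25)
  slope <- coef(lm(log(g) ~ log(om)))[2]
  expect_lt(abs(slope - 0.5), 0.02)
})

test_that("noisy model curves are recovered within 20 percent", {
  om <- exp(seq(log(3), log(3000), length.out = 300))
  set.seed(5)
  y <- fractional_rigidity_model(om, 5e-5, 2e-4, 1 / 300, 0.25) *
    exp(rnorm(300, 0, 0.1))
  fr <- fit_fractional_rigidity(list(omega = om, G_prime = y),
                                R = 3.6e-6, T = 310.15)
  expect_lt(abs(fr$G_gamma / 5e-5 - 1), 0.2)
  expect_lt(abs(fr$tau_D * 300 - 1), 0.2)
  expect_lt(abs(fr$alpha / 0.25 - 1), 0.2)
})

test_that("fractional viscosity model reduces to Maxwell at alpha = 1", {
  om <- exp(seq(log(1), log(1000), length.out = 100))
  expect_equal(fractional_viscosity_model(om, 0.5, 2.0, 1 / 100, 1),
               0.5 + 2.0 / (1 + (om / 100)^2), tolerance = 1e-12)
  ## low-frequency log-slope of the relaxation term is alpha - 1
  for (al in c(0.25, 1 / 3, 0.6)) {
    oml <- exp(seq(log(1e-4 * 100), log(1e-3 * 100), length.out = 30))
    y <- fractional_viscosity_model(oml, 0, 2.0, 1 / 100, al)
    expect_equal(unname(coef(lm(log(y) ~ log(oml)))[2]), al - 1,
                 tolerance = 0.02)
  }
  ## fit recovery on a noisy viscosity curve
  set.seed(7)
  yv <- fractional_viscosity_model(om, 0.4, 3.0, 1 / 150, 0.3) *
    exp(rnorm(100, 0, 0.05))
  fv <- fit_fractional_viscosity(list(omega = om, eta_eff = yv))
  expect_lt(abs(fv$alpha / 0.3 - 1), 0.2)
  expect_lt(abs(fv$tau_D * 150 - 1), 0.25)
})

test_that("viscoelastic crossovers: Maxwell crossing exact, floor detected", {
  ## pure Maxwell element (G, H): omega_D = G/H exactly
  G <- 5e-5; H <- 2e-7; L <- 1e-8
  om <- exp(seq(log(1), log(5000), length.out = 200))
  rmx <- structure(list(omega = om, G_prime = rep(G, 200),
                        eta_eff = rep(H / (6 * pi * L), 200),
                        alpha_local = rep(-1.5, 200),
                        ratio = rep(G / H, 200), L = L, T = 310.15,
                        psd = NULL),
                   class = "rheo_spectrum")
  vc <- viscoelastic_ratio_and_crossovers(rmx)
  expect_equal(vc$omega_D, G / H, tolerance = 1e-6)
  expect_false(vc$omega_D_bounded)
  ## injected white floor: onset recovered within a factor 1.5
  m <- fx_m()
  omf <- exp(seq(log(3), log(6283), length.out = 400))
  psd <- flickering:::passive_psd_sum(m, 128, omf)
  Fl <- psd[which.min(abs(omf - 1000))]
  rh <- gser_modulus(structure(list(omega = omf, psd = psd + Fl),
                               class = "flicker_spectrum"),
                     L = 1.1e-8, T = m$T)
  vc2 <- viscoelastic_ratio_and_crossovers(rh)
  expect_gt(vc2$omega_C, 1000 / 1.5)
  expect_lt(vc2$omega_C, 1000 * 1.5)
  ## floor-free spectrum reports no omega_C
  rh0 <- gser_modulus(structure(list(omega = omf, psd = psd),
                                class = "flicker_spectrum"),
                      L = 1.1e-8, T = m$T)
  expect_true(is.na(viscoelastic_ratio_and_crossovers(rh0)$omega_C))
})

test_that("kicking activity drops the mean softness ratio", {
  ## active softening: G_eff = kBT/Sigma^2 falls while the membrane
  ## microviscosity is unchanged, so G_eff/eta drops (Delta-eta ~ 0)
  m <- fx_m()
  G_act <- effective_elasticity(mean(local_variance(fx_act_mid())), m$T)
  G_pas <- effective_elasticity(mean(local_variance(fx_pass_mid())), m$T)
  expect_lt(G_act, G_pas)
  expect_lt(G_act / m$eta, G_pas / m$eta)
})
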