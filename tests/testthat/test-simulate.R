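test_that("dispersion rate is the tension/bending viscoelastic ratio", {
  m1 <- membrane_params(gamma = 1e-6, kappa = 1e-30, eta = 1e-3)
  expect_equal(dispersion_rate(m1, 1e6), 250, tolerance = 1e-9)
  m2 <- membrane_params(gamma = 0, kappa = 1e-19, eta = 1e-3)
  expect_equal(dispersion_rate(m2, 1e6), 25)
  m3 <- membrane_params(gamma = 1e-6, kappa = 1e-19, eta = 1e-3)
  expect_equal(dispersion_rate(m3, 1e6), 275, tolerance = 1e-6)
  expect_true(all(diff(dispersion_rate(m3, 10^seq(4, 8, by = 0.1))) > 0))
  expect_error(dispersion_rate(m3, -1), "positive")
  expect_error(dispersion_rate(m3, 0), "positive")
})

test_that("mode variance follows the projected Helfrich line spectrum", {
  ## frozen value from an independent arbitrary-precision evaluation of the
  ## implemented closed form (mpmath, 30 digits):
  ## kBT/(2 gamma q) (1 - x/sqrt(1+x^2)) / (pi R), x = q sqrt(kappa/gamma)
  m <- membrane_params(gamma = 6.4e-6, kappa = 1e-19, eta = 1e-3,
                       R_bar = 3.6e-6, T = 310.15)
  x <- 2e6 * sqrt(1e-19 / 6.4e-6)
  expect_equal(mode_variance(m, 2e6),
               kB() * 310.15 / (2 * 6.4e-6 * 2e6) *
                 (1 - x / sqrt(1 + x^2)) / (pi * 3.6e-6))
  ## zero temperature
  m0 <- membrane_params(T = 0)
  expect_equal(mode_variance(m0, 1e6), 0)
  ## bending-only limit agrees with the explicit gamma -> 0 branch
  mb <- membrane_params(gamma = 0, kappa = 2e-19)
  expect_equal(mode_variance(mb, 5e6),
               kB() * mb$T / (4 * pi * mb$R_bar * 2e-19 * 5e6^3))
  ## decreasing in q, positive
  m <- membrane_params()
  v <- mode_variance(m, 10^seq(5.5, 8, by = 0.1))
  expect_true(all(v > 0))
  expect_true(all(diff(v) < 0))
  expect_error(mode_variance(m, 0), "positive")
  expect_error(membrane_params(gamma = 0, kappa = 0), "strictly positive")
})

test_that("passive simulation is stationary, zero-mean and seed-deterministic", {
  s <- fx_eq_sim()
  m <- fx_m()
  expect_equal(nrow(s$dh), 128)
  expect_equal(s$L * 128, 2 * pi * m$R_bar, tolerance = 1e-12)
  expect_lt(abs(mean(s$dh)), 1e-9 * m$R_bar)
  ## ensemble variance against the analytic mode sum, within 3 SE
  sig2 <- local_variance(s)
  S2_hat <- mean(sig2)
  q <- (1:64) / m$R_bar
  s2 <- mode_variance(m, q)
  wn <- dispersion_rate(m, q)
  ## Sigma2_hat = sum_n (a_n^2 + b_n^2)/2 time-averaged, so its variance is
  ## sum_n s2_n^2 coth(w_n dt) / T
  coth <- ifelse(wn * s$dt > 20, 1, 1 / tanh(wn * s$dt))
  se <- sqrt(sum(s2^2 * coth / ncol(s$dh)))
  expect_lt(abs(S2_hat - sum(s2)), 3 * se)
  ## reproducibility
  s2b <- suppressWarnings(simulate_passive_contour(m, N = 32, n_frames = 50,
                                                   dt = 5e-4, n_modes = 8,
                                                   seed = 99))
  s2c <- suppressWarnings(simulate_passive_contour(m, N = 32, n_frames = 50,
                                                   dt = 5e-4, n_modes = 8,
                                                   seed = 99))
  expect_identical(s2b$dh, s2c$dh)
  ## athermal membrane does not move
  s0 <- simulate_passive_contour(membrane_params(T = 0), N = 16,
                                 n_frames = 20, dt = 5e-4, n_modes = 4)
  expect_true(all(s0$dh == 0))
})

test_that("each simulated mode obeys equipartition within 4 standard errors", {
  s <- fx_eq_sim()
  m <- fx_m()
  ## modes 1..N/2-1: at n = N/2 the sine quadrature vanishes on the grid
  ## and the cosine projection degenerates, so the spatial-Nyquist mode is
  ## not separately resolvable
  N <- 128; nm <- 63
  theta <- 2 * pi * (0:(N - 1)) / N
  q <- (1:nm) / m$R_bar
  s2 <- mode_variance(m, q)
  wn <- dispersion_rate(m, q)
  A <- (2 / N) * cos(outer(1:nm, theta)) %*% s$dh
  B <- (2 / N) * sin(outer(1:nm, theta)) %*% s$dh
  ## exact SE of the variance of a discretely sampled OU process:
  ## Var(s2_hat) = (2 s2^2 / T) * coth(w dt), valid from the slow-mode to
  ## the aliased limit
  Tn <- ncol(s$dh)
  coth <- ifelse(wn * s$dt > 20, 1, 1 / tanh(wn * s$dt))
  se <- s2 * sqrt(2 * coth / Tn)
  expect_true(all(abs(apply(A, 1, var) - s2) < 4 * se))
  expect_true(all(abs(apply(B, 1, var) - s2) < 4 * se))
})

test_that("pooled passive displacements are Gaussian (small excess kurtosis)", {
  x <- as.numeric(fx_eq_sim()$dh)
  k4 <- mean(x^4) / mean(x^2)^2 - 3
  expect_lt(abs(k4), 0.1)
})

test_that("slow sampling of fast modes triggers the aliasing warning", {
  m <- membrane_params()
  expect_warning(simulate_passive_contour(m, N = 32, n_frames = 10, dt = 1,
                                          n_modes = 16),
                 class = "flicker_aliasing")
  expect_error(simulate_passive_contour(m, N = 32, n_frames = 10, dt = 5e-4,
                                        n_modes = 20), "n_modes")
})

test_that("active simulation adds independent kicker power with phi = 0 identity", {
  m <- fx_m()
  a0 <- activity_params(phi = 0)
  sp <- suppressWarnings(simulate_passive_contour(m, N = 64, n_frames = 500,
                                                  dt = 5e-4, n_modes = 32,
                                                  seed = 3))
  sa0 <- suppressWarnings(simulate_active_contour(m, a0, N = 64,
                                                  n_frames = 500, dt = 5e-4,
                                                  n_modes = 32, seed = 3))
  expect_identical(sp$dh, sa0$dh)
  ## positive kicking energy strictly increases the ensemble variance
  a <- activity_params(phi = 0.3)
  sa <- suppressWarnings(simulate_active_contour(m, a, N = 64, n_frames = 500,
                                                 dt = 5e-4, n_modes = 32,
                                                 seed = 3))
  expect_gt(mean(sa$dh^2), mean(sp$dh^2))
  ## unphysical kicking amplitude rejected
  expect_error(simulate_active_contour(
    m, activity_params(Lambda0 = 2e-6), N = 64, n_frames = 10, dt = 5e-4,
    n_modes = 32), "unphysical")
  ## single-rate mode runs and is deterministic
  a1 <- activity_params(phi = 0.2, rate_mode = "single_rate", omega_A = 50)
  x1 <- suppressWarnings(simulate_active_contour(m, a1, N = 64, n_frames = 200,
                                                 dt = 5e-4, n_modes = 32,
                                                 seed = 4))
  x2 <- suppressWarnings(simulate_active_contour(m, a1, N = 64, n_frames = 200,
                                                 dt = 5e-4, n_modes = 32,
                                                 seed = 4))
  expect_identical(x1$dh, x2$dh)
})

test_that("long-run active variance recovers the Gov effective temperature", {
  sa <- fx_act_mid()
  m <- fx_m()
  a <- sa$meta$activity
  S2_pass <- passive_variance_sum(m, 128)
  Teff_ratio <- mean(local_variance(sa)) / S2_pass
  n_active <- length(sa$meta$active$sites)
  expected <- 1 + (n_active / 256) * a$p_on * a$f0 * a$Lambda0 / (kB() * m$T)
  expect_lt(abs(Teff_ratio / expected - 1), 0.1)
})

test_that("activity statistics are monotone in phi, f0 and Lambda0", {
  m <- fx_m()
  run <- function(phi = 0.25, f0 = 2.5e-12, L0 = 5e-8) {
    a <- activity_params(phi = phi, f0 = f0, Lambda0 = L0)
    s <- suppressWarnings(simulate_active_contour(m, a, N = 64,
                                                  n_frames = 4000, dt = 5e-4,
                                                  n_modes = 32, seed = 12))
    mean(local_variance(s))
  }
  expect_true(all(diff(c(run(phi = 0), run(phi = 0.15), run(phi = 0.3))) > 0))
  expect_true(all(diff(c(run(f0 = 5e-13), run(f0 = 1.5e-12),
                         run(f0 = 3e-12))) > 0))
  expect_true(all(diff(c(run(L0 = 1e-8), run(L0 = 3e-8), run(L0 = 6e-8))) > 0))
})
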