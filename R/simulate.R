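#' Passive relaxation rate of a contour mode
#'
#' Diffusive relaxation rate of a membrane contour mode of wavenumber
#' \code{q}, the viscoelastic ratio across the tension and bending regimes:
#' \deqn{\omega(q) = (\gamma q + \kappa q^3) / (4 \eta).}
#'
#' @param m A \code{\link{membrane_params}} object.
#' @param q Wavenumber(s) (1/m), > 0.
#' @return Relaxation rate(s) in rad/s, strictly increasing in q.
#' @export
dispersion_rate <- function(m, q) {
  stopifnot(inherits(m, "membrane_params"))
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be positive")
  (m$gamma * q + m$kappa * q^3) / (4 * m$eta)
}

#' Equilibrium variance of a contour mode
#'
#' Thermal variance carried by one quadrature amplitude of the ring mode of
#' wavenumber \code{q}. The equatorial contour samples a one-dimensional cut
#' through the two-dimensional membrane, so the per-mode variance is the line
#' projection of the Helfrich spectrum,
#' \deqn{s^2(q) = \frac{k_B T}{2\gamma q}\left(1 -
#'   \frac{x}{\sqrt{1+x^2}}\right) \frac{1}{\pi \bar R}, \quad
#'   x = q\sqrt{\kappa/\gamma},}
#' with limits \eqn{k_B T/(2\pi\bar R\,\gamma q)} (tension) and
#' \eqn{k_B T/(4\pi\bar R\,\kappa q^3)} (bending). Summed over the ring modes
#' \eqn{q_n = n/\bar R} this reproduces the ensemble variance
#' \eqn{\Sigma^2}, and combined with \code{\link{dispersion_rate}} it yields
#' the pink (~1/omega) tension spectrum and the omega^(-5/3) bending spectrum
#' of equatorial flickering.
#'
#' @param m A \code{\link{membrane_params}} object.
#' @param q Wavenumber(s) (1/m), > 0.
#' @return Variance(s) in m^2; positive (zero at T = 0), decreasing in q.
#' @export
mode_variance <- function(m, q) {
  stopifnot(inherits(m, "membrane_params"))
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be positive")
  if (m$gamma == 0 && m$kappa == 0) stop("degenerate mode: gamma = kappa = 0")
  if (m$gamma == 0) return(.kB * m$T / (4 * pi * m$R_bar * m$kappa * q^3))
  x <- q * sqrt(m$kappa / m$gamma)
  .kB * m$T / (2 * m$gamma * q) * (1 - x / sqrt(1 + x^2)) / (pi * m$R_bar)
}

#' Analytic ensemble variance of a simulated mode bank
#'
#' Closed-form mode sum \eqn{\Sigma^2 = \sum_n s^2(q_n)} over the ring modes
#' \eqn{q_n = n/\bar R}, n = 1..n_modes: the stationary per-site variance of a
#' passive simulation with that mode bank.
#'
#' @param m A \code{\link{membrane_params}} object.
#' @param n_modes Number of ring modes.
#' @return Variance (m^2).
#' @export
passive_variance_sum <- function(m, n_modes) {
  if (m$T == 0) return(0)
  sum(mode_variance(m, (seq_len(n_modes)) / m$R_bar))
}

## One-sided PSD (integral over omega = variance) of the passive mode bank,
## evaluated on an angular-frequency grid: sum of OU Lorentzians.
passive_psd_sum <- function(m, n_modes, omega) {
  q <- seq_len(n_modes) / m$R_bar
  s2 <- mode_variance(m, q)
  wn <- dispersion_rate(m, q)
  vapply(omega, function(w) sum(s2 * (2 / pi) * wn / (w^2 + wn^2)), 0)
}

new_contour_series <- function(dh, R_bar, dt, meta = list()) {
  N <- nrow(dh)
  structure(list(dh = dh,
                 l = (seq_len(N) - 1) * 2 * pi * R_bar / N,
                 L = 2 * pi * R_bar / N,
                 R_bar = R_bar, dt = dt, meta = meta),
            class = "contour_series")
}

#' @export
print.contour_series <- function(x, ...) {
  cat(sprintf("Contour fluctuation series: N = %d emplacements x %d frames\n",
              nrow(x$dh), ncol(x$dh)))
  cat(sprintf("  R_bar %.3g um, emplacement size L %.3g nm, dt %.3g ms (%.3g s total)\n",
              x$R_bar * 1e6, x$L * 1e9, x$dt * 1e3, x$dt * ncol(x$dh)))
  cat(sprintf("  rms displacement %.3g nm\n", stats::sd(as.numeric(x$dh)) * 1e9))
  invisible(x)
}

check_aliasing <- function(rates, dt) {
  if (length(rates) && dt >= 1 / (2 * max(rates)))
    warning(structure(class = c("flicker_aliasing", "warning", "condition"),
                      list(message = paste0(
                        "fastest mode relaxes above the Nyquist rate (dt >= 1/(2 max rate)); ",
                        "the exact OU update remains unbiased but fast modes appear ",
                        "as a white spectral floor"),
                        call = sys.call(-1))))
}

#' Simulate passive thermal contour fluctuations
#'
#' Ring Fourier mode bank: modes \eqn{q_n = n/\bar R} for n = 1..n_modes, each
#' quadrature amplitude an exactly discretized Ornstein-Uhlenbeck process with
#' rate \code{dispersion_rate(q_n)} and stationary variance
#' \code{mode_variance(q_n)}; the real displacement field is assembled as
#' \eqn{\delta h_i(t) = \sum_n a_n(t)\cos(n\theta_i) + b_n(t)\sin(n\theta_i)}.
#' Amplitudes start in their stationary distribution, so the series is
#' stationary from the first frame at any dt.
#'
#' @param m A \code{\link{membrane_params}} object.
#' @param N Number of contour emplacements.
#' @param n_frames Number of frames.
#' @param dt Frame interval (s).
#' @param n_modes Number of ring modes (<= N/2).
#' @param seed Integer seed; identical inputs + seed give identical output.
#' @return A \code{contour_series}: fields \code{dh} (N x n_frames matrix, m),
#'   \code{l}, \code{L}, \code{R_bar}, \code{dt}, \code{meta}.
#' @export
simulate_passive_contour <- function(m, N = 2048, n_frames = 10000, dt = 5e-4,
                                     n_modes = N %/% 2, seed = 1) {
  stopifnot(inherits(m, "membrane_params"), N > 0, n_frames >= 1, dt > 0)
  if (n_modes > N / 2) stop("n_modes must not exceed N/2")
  q <- seq_len(n_modes) / m$R_bar
  s2 <- if (m$T > 0) mode_variance(m, q) else rep(0, n_modes)
  wn <- dispersion_rate(m, q)
  if (m$T > 0) check_aliasing(wn, dt)
  theta <- 2 * pi * (seq_len(N) - 1) / N
  Ccos <- cos(outer(theta, seq_len(n_modes)))
  Csin <- sin(outer(theta, seq_len(n_modes)))
  e <- exp(-wn * dt)
  sd_inn <- sqrt(pmax(s2 * (1 - e^2), 0))
  sd_st <- sqrt(s2)
  sim_bank <- function() {
    A <- matrix(0, n_modes, n_frames)
    for (i in seq_len(n_modes)) {
      if (s2[i] == 0) next
      a0 <- stats::rnorm(1L, 0, sd_st[i])
      A[i, ] <- stats::filter(stats::rnorm(n_frames, 0, sd_inn[i]),
                              e[i], method = "recursive", init = a0)
    }
    A
  }
  dh <- with_local_seed(seed, {
    A <- sim_bank(); B <- sim_bank()
    Ccos %*% A + Csin %*% B
  })
  new_contour_series(dh, m$R_bar, dt,
                     meta = list(seed = seed, params = m, kind = "passive",
                                 modes = list(q = q, s2 = s2, rates = wn),
                                 Sigma2_passive = sum(s2)))
}

## Exact stationary variance of the discrete AR(1)-filtered telegraph
## u_t = a u_{t-1} + (1-a) Lam s_t with corr(s_t, s_{t+1}) = rho.
filtered_telegraph_var <- function(a, rho, Lam) {
  if (a == 0) return(Lam^2)
  (1 - a)^2 * Lam^2 * (1 + a * rho) / ((1 - a^2) * (1 - a * rho))
}

#' Simulate active contour fluctuations (thermal modes + kickers)
#'
#' Adds the Gov-model active component to \code{\link{simulate_passive_contour}}:
#' a randomly chosen fraction \code{phi} of emplacements carries a dichotomous
#' kicking force that switches between +f0 and -f0 (telegraph process, rate
#' \code{omega_A} or per-site log-uniform over \code{rate_span}) and is relaxed
#' through the local milieu friction \eqn{\zeta_0 = 6\pi L \eta_0} toward
#' excursions of scale \code{Lambda0} (relaxation corner
#' \eqn{\omega_r = f_0/(\zeta_0 \Lambda_0)}). Each active site's added
#' displacement is scaled so its stationary variance equals
#' \eqn{p_{on} f_0 \Lambda_0 / G_0}, with \eqn{G_0 = k_B T/\Sigma^2_{pass}}
#' taken from the run's own passive mode bank (or the explicit \code{G0} of
#' \code{m} for athermal runs), so that the ensemble effective temperature
#' satisfies the Gov relation
#' \eqn{T_{eff}/T = 1 + \phi\, p_{on} f_0 \Lambda_0 / (k_B T)}.
#' Active and passive components are statistically independent; with
#' \code{phi = 0} the output is bitwise identical to the passive run at the
#' same seed.
#'
#' @inheritParams simulate_passive_contour
#' @param a An \code{\link{activity_params}} object.
#' @return A \code{contour_series}; \code{meta$active} records kicker sites,
#'   rates and scales.
#' @export
simulate_active_contour <- function(m, a, N = 2048, n_frames = 10000, dt = 5e-4,
                                    n_modes = N %/% 2, seed = 1) {
  stopifnot(inherits(a, "activity_params"))
  if (a$Lambda0 >= m$R_bar / 2)
    stop("unphysical amplitude: Lambda0 must be below R_bar/2")
  s <- simulate_passive_contour(m, N, n_frames, dt, n_modes, seed)
  n_active <- round(a$phi * N)
  if (n_active == 0 || a$f0 == 0 || a$Lambda0 == 0 || a$p_on == 0) {
    s$meta$kind <- "active"
    s$meta$activity <- a
    s$meta$active <- list(sites = integer(0))
    return(s)
  }
  Sigma2_pass <- s$meta$Sigma2_passive
  G0_cal <- if (m$T > 0) .kB * m$T / Sigma2_pass else m$G0
  if (!is.finite(G0_cal) || G0_cal <= 0)
    stop("athermal active run needs a positive G0 in membrane_params")
  v_target <- a$p_on * a$f0 * a$Lambda0 / G0_cal
  L <- s$L
  zeta0 <- 6 * pi * L * a$eta0
  omega_r <- a$f0 / (zeta0 * a$Lambda0)
  aa <- exp(-omega_r * dt)
  act <- with_local_seed(derive_seed(seed, 104729), {
    sites <- sort(sample.int(N, n_active))
    rates <- switch(a$rate_mode,
      single_rate = rep(a$omega_A, n_active),
      log_uniform_ensemble = 10^stats::runif(n_active,
                                             log10(a$rate_span[1]),
                                             log10(a$rate_span[2])))
    scales <- numeric(n_active)
    U <- matrix(0, n_active, n_frames)
    for (k in seq_len(n_active)) {
      rho <- exp(-2 * rates[k] * dt)
      flips <- stats::runif(n_frames) < (1 - rho) / 2
      sgn <- if (stats::runif(1) < 0.5) 1 else -1
      tele <- sgn * cumprod(ifelse(flips, -1, 1))
      u <- as.numeric(stats::filter((1 - aa) * a$Lambda0 * tele, aa,
                                    method = "recursive",
                                    init = a$Lambda0 * tele[1]))
      v_raw <- filtered_telegraph_var(aa, rho, a$Lambda0)
      scales[k] <- sqrt(v_target / v_raw)
      U[k, ] <- scales[k] * u
    }
    list(sites = sites, rates = rates, scales = scales, U = U)
  })
  s$dh[act$sites, ] <- s$dh[act$sites, ] + act$U
  s$meta$kind <- "active"
  s$meta$activity <- a
  s$meta$active <- list(sites = act$sites, rates = act$rates,
                        scales = act$scales, omega_r = omega_r,
                        var_target = v_target, G0_cal = G0_cal)
  s
}

#' Simulate a single Ornstein-Uhlenbeck trajectory
#'
#' Exactly discretized OU process with stationary variance \code{sigma2} and
#' relaxation rate \code{rate}, started in its stationary distribution. Used
#' as a closed-form reference input for spectral and rheological estimators
#' (its Lorentzian spectrum and trap-plateau modulus are known exactly).
#'
#' @param sigma2 Stationary variance (m^2).
#' @param rate Relaxation rate (rad/s).
#' @param n_frames Number of samples.
#' @param dt Sampling interval (s).
#' @param seed Integer seed.
#' @return Numeric vector of length \code{n_frames}.
#' @export
simulate_ou <- function(sigma2, rate, n_frames, dt, seed = 1) {
  stopifnot(sigma2 >= 0, rate > 0, n_frames >= 1, dt > 0)
  e <- exp(-rate * dt)
  with_local_seed(seed, {
    as.numeric(stats::filter(stats::rnorm(n_frames, 0, sqrt(sigma2 * (1 - e^2))),
                             e, method = "recursive",
                             init = stats::rnorm(1, 0, sqrt(sigma2))))
  })
}
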