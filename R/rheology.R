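#' Generalized Stokes-Einstein viscoelastic modulus from a spectrum
#'
#' Converts a displacement power spectrum into the frequency-dependent
#' complex membrane modulus with the local power-law (Mason) estimator.
#' The mean-square displacement is reconstructed from the one-sided spectrum,
#' \eqn{MSD(\tau) = 2\int S(\omega)(1 - \cos\omega\tau)\,d\omega}, and
#' \deqn{|\tilde G(\omega)| = C_{cal}\, k_B T / (MSD(1/\omega)\,
#'   \Gamma[1 + \beta(\omega)]),}
#' with \eqn{\beta(\omega) = -d\log S/d\log\omega - 1} the local MSD
#' power-law exponent read off the PSD slope, clipped to [0, 1] (equivalent
#' to the log-log slope of the MSD at lag \eqn{1/\omega}). The calibration
#' constant
#' \eqn{C_{cal} = 2} is fixed once by the harmonic-trap identity (an
#' overdamped trap of stiffness G has plateau MSD = 2 kB T / G, so the
#' low-frequency plateau returns the trap stiffness exactly) and is never
#' refit. The elastic/viscous split uses the power-law phase approximation:
#' \eqn{G' = |\tilde G| \cos(\pi\beta/2)} and the effective viscosity
#' \eqn{\eta_{eff} = |\tilde G| \sin(\pi\beta/2) / (6\pi L \omega)}, so free
#' diffusion against friction \eqn{6\pi L \eta} returns \eqn{\eta_{eff} = \eta}.
#'
#' @param sp A \code{flicker_spectrum}.
#' @param L Emplacement size (m) entering the friction 6*pi*L.
#' @param T Temperature (K).
#' @param C_cal Calibration constant; the version-pinned default 2 is the
#'   exact trap-plateau value.
#' @return An object of class \code{rheo_spectrum}: \code{omega},
#'   \code{G_mag}, \code{G_prime} (N/m), \code{eta_eff} (Pa s),
#'   \code{alpha_local} (local log-slope of the PSD), \code{beta} (MSD
#'   exponent), \code{ratio} (viscoelastic ratio G'/(6 pi L eta_eff), 1/s),
#'   \code{msd}, \code{L}, \code{T}.
#' @export
gser_modulus <- function(sp, L, T = 310.15, C_cal = 2) {
  ok <- sp$psd > 0
  om <- sp$omega[ok]; S <- sp$psd[ok]
  if (length(om) < 16) stop("spectrum too short for GSER")
  if (!is.null(sp$msd)) {
    ## measured time-domain MSD (exact at discrete lags): interpolate
    ## log-log at tau = 1/omega, power-law extrapolation beyond the ends
    lt <- log(sp$msd_tau); lm_ <- log(sp$msd)
    sl <- local_slope(lt, lm_)
    msd_f <- stats::approxfun(lt, lm_, rule = 2)
    sl_f <- stats::approxfun(lt, sl, rule = 2)
    tau <- 1 / om
    ltau <- log(tau)
    lv <- msd_f(ltau)
    below <- ltau < lt[1]; above <- ltau > lt[length(lt)]
    lv[below] <- lm_[1] + sl[1] * (ltau[below] - lt[1])
    lv[above] <- lm_[length(lt)] + sl[length(sl)] * (ltau[above] -
                                                       lt[length(lt)])
    msd <- exp(lv)
    beta <- pmin(pmax(sl_f(ltau), 0), 1)
  } else {
    ## model spectrum without a series: MSD by quadrature on the grid
    dw <- diff(om)
    msd <- vapply(om, function(w) {
      f <- 2 * S * (1 - cos(om / w))
      sum(dw * (f[-1] + f[-length(f)]) / 2)
    }, 0)
    beta <- NULL
  }
  alpha_local <- local_slope(log(om), log(S))
  if (is.null(beta)) beta <- pmin(pmax(-alpha_local - 1, 0), 1)
  Gmag <- C_cal * .kB * T / (msd * gamma(1 + beta))
  Gp <- Gmag * cos(pi * beta / 2)
  eta_eff <- Gmag * sin(pi * beta / 2) / (6 * pi * L * om)
  ratio <- ifelse(eta_eff > 0, Gp / (6 * pi * L * eta_eff), Inf)
  structure(list(omega = om, G_mag = Gmag, G_prime = Gp, eta_eff = eta_eff,
                 alpha_local = alpha_local, beta = beta, ratio = ratio,
                 msd = msd, psd = S, L = L, T = T, C_cal = C_cal),
            class = "rheo_spectrum")
}

## Local slope dy/dx on possibly uneven grid, centered differences with a
## 5-point running-mean smoothing.
local_slope <- function(x, y) {
  n <- length(x)
  s <- numeric(n)
  s[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  s[1] <- (y[2] - y[1]) / (x[2] - x[1])
  s[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  as.numeric(stats::filter(s, rep(1 / 5, 5), sides = 2)) ->
    sm
  ifelse(is.na(sm), s, sm)
}

#' @export
print.rheo_spectrum <- function(x, ...) {
  cat(sprintf("Rheological spectrum: %d frequencies in [%.3g, %.3g] rad/s\n",
              length(x$omega), min(x$omega), max(x$omega)))
  cat(sprintf("  G' range [%.3g, %.3g] N/m, eta_eff range [%.3g, %.3g] Pa s\n",
              min(x$G_prime), max(x$G_prime), min(x$eta_eff), max(x$eta_eff)))
  invisible(x)
}

#' Frequency-dependent effective temperature kernel
#'
#' Effective temperature of the actively kicked membrane,
#' \deqn{T_{eff}(\omega) = T + \frac{\phi f_0 \Lambda_0}{k_B}
#'   K(\omega \tau_A), \quad K(x) = \frac{2(1 - \cos x)}{x^2},}
#' with the kernel normalized so K(0) = 1 and hence
#' \eqn{T_{eff}(0) = T + \phi f_0 \Lambda_0 / k_B}.
#'
#' @param omega Angular frequency (rad/s).
#' @param phi Active fraction.
#' @param f0Lambda0 Kicking energy f0*Lambda0 (J).
#' @param tau_A Kicker pulsation time (s), > 0.
#' @param T Bath temperature (K).
#' @return Effective temperature(s) (K).
#' @export
effective_temperature_kernel <- function(omega, phi, f0Lambda0, tau_A,
                                         T = 310.15) {
  if (tau_A <= 0) stop("tau_A must be positive")
  x <- omega * tau_A
  K <- ifelse(x == 0, 1, 2 * (1 - cos(x)) / x^2)
  T + phi * f0Lambda0 / .kB * K
}

#' Fractional Maxwell model of the effective rigidity
#'
#' \deqn{G_{eff}(\omega) = G_\gamma + G_\kappa
#'   \frac{(\omega\tau_D)^{2\alpha}}{1 + (\omega\tau_D)^{2\alpha}},}
#' the tension plateau followed by a fractional (anomalous-diffusion)
#' bending relaxation of exponent 2*alpha; alpha = 1/3 is the passive
#' pure-bending value, alpha < 1/3 signals active confinement.
#'
#' @param omega Angular frequency (rad/s).
#' @param G_gamma Tension plateau (N/m).
#' @param G_kappa Bending relaxation strength (N/m).
#' @param tau_D Diffusive time 1/omega_D (s).
#' @param alpha Fractional exponent in [0, 1].
#' @return Modulus values (N/m).
#' @export
fractional_rigidity_model <- function(omega, G_gamma, G_kappa, tau_D, alpha) {
  x <- (omega * tau_D)^(2 * alpha)
  G_gamma + G_kappa * x / (1 + x)
}

#' Fractional Maxwell model of the effective viscosity
#'
#' \deqn{\eta_{eff}(\omega) = \eta_0 + H_0
#'   \frac{(\omega\tau_D)^{\alpha - 1}}{1 + (\omega\tau_D)^{2\alpha}}
#'   + \eta_{kick},}
#' the conjugate fractional relaxation of the rigidity model: for alpha = 1
#' and eta_kick = 0 it reduces exactly to the Maxwell form
#' eta_0 + H_0 / (1 + (omega tau_D)^2) with H_0 = G0 * tau_D, and an
#' active-kicker dissipation floor eta_kick = phi f0^2/(4 eta_0 L) enters as
#' a frequency-independent offset.
#'
#' @param omega Angular frequency (rad/s).
#' @param eta0 Baseline (milieu) viscosity (Pa s).
#' @param H0 Relaxation strength (Pa s).
#' @param tau_D Diffusive time (s).
#' @param alpha Fractional exponent in [0, 1].
#' @param eta_kick Active dissipation offset (Pa s).
#' @return Viscosity values (Pa s).
#' @export
fractional_viscosity_model <- function(omega, eta0, H0, tau_D, alpha,
                                       eta_kick = 0) {
  x <- omega * tau_D
  eta0 + H0 * x^(alpha - 1) / (1 + x^(2 * alpha)) + eta_kick
}

multistart_nlsLM <- function(formula, data, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(minpack.lm::nlsLM(formula, data = data, start = st,
                                      lower = lower, upper = upper,
                                      control = minpack.lm::nls.lm.control(
                                        maxiter = 400)),
                    error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || stats::deviance(fit) < stats::deviance(best)))
      best <- fit
  }
  if (is.null(best)) stop("all fit starts failed")
  best
}

fit_ci <- function(fit) {
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(cf)))
  list(coef = cf, se = se)
}

#' Fit the fractional rigidity model to a rheological spectrum
#'
#' Weighted log-space least squares of
#' \code{\link{fractional_rigidity_model}} to G'(omega), with a fixed
#' multistart grid over (alpha, tau_D) (deterministic given the data) and
#' bounds 0 <= alpha <= 1. The tension parameter is reported both as the
#' plateau \code{G_gamma} (N/m) and as the equivalent tension
#' \code{gamma_eff = G_gamma * R / 4} of the Laplace term 4 gamma / R.
#'
#' @param r A \code{rheo_spectrum} (or list with omega and G_prime).
#' @param R Mean radius (m) for the gamma_eff conversion.
#' @param T Temperature (K), carried through for reporting.
#' @param omega_range Optional fit window.
#' @return An object of class \code{fractional_fit} with fields
#'   \code{gamma_eff}, \code{G_gamma}, \code{G_kappa}, \code{tau_D},
#'   \code{alpha}, standard errors, \code{goodness} (residual norm) and the
#'   underlying \code{nls} fit.
#' @export
fit_fractional_rigidity <- function(r, R = 3.6e-6, T = 310.15,
                                    omega_range = NULL) {
  om <- r$omega; y <- r$G_prime
  if (!is.null(omega_range)) {
    i <- om >= omega_range[1] & om <= omega_range[2]
    om <- om[i]; y <- y[i]
  }
  ok <- is.finite(y) & y > 0
  om <- om[ok]; y <- y[ok]
  dat <- list(om = om, ly = log(y))
  tauD_grid <- 1 / exp(seq(log(min(om)), log(max(om)), length.out = 5))
  starts <- list()
  for (td in tauD_grid)
    for (al in c(0.15, 1 / 3, 0.6))
      starts[[length(starts) + 1]] <-
        list(Gg = max(min(y), 1e-12), Gk = max(y), td = td, al = al)
  fit <- multistart_nlsLM(
    ly ~ log(fractional_rigidity_model(om, Gg, Gk, td, al)),
    data = dat, starts = starts,
    lower = c(Gg = 0, Gk = 1e-12, td = 1e-12, al = 0),
    upper = c(Gg = Inf, Gk = Inf, td = Inf, al = 1))
  ci <- fit_ci(fit)
  structure(list(gamma_eff = unname(ci$coef[["Gg"]]) * R / 4,
                 G_gamma = unname(ci$coef[["Gg"]]),
                 G_kappa = unname(ci$coef[["Gk"]]),
                 tau_D = unname(ci$coef[["td"]]),
                 alpha = unname(ci$coef[["al"]]),
                 se = ci$se, R = R, T = T,
                 goodness = sqrt(stats::deviance(fit) / length(om)),
                 branch = "rigidity", fit = fit),
            class = "fractional_fit")
}

#' Fit the fractional viscosity model to a rheological spectrum
#'
#' Conjugate fit of \code{\link{fractional_viscosity_model}} to
#' eta_eff(omega), log-space least squares with a fixed multistart grid.
#'
#' @param r A \code{rheo_spectrum} (or list with omega and eta_eff).
#' @param omega_range Optional fit window.
#' @param fit_offset Fit the active dissipation offset eta_kick (else 0).
#' @return A \code{fractional_fit} (viscosity branch): \code{eta0},
#'   \code{H0}, \code{tau_D}, \code{alpha}, \code{eta_kick}.
#' @export
fit_fractional_viscosity <- function(r, omega_range = NULL,
                                     fit_offset = FALSE) {
  om <- r$omega; y <- r$eta_eff
  if (!is.null(omega_range)) {
    i <- om >= omega_range[1] & om <= omega_range[2]
    om <- om[i]; y <- y[i]
  }
  ok <- is.finite(y) & y > 0
  om <- om[ok]; y <- y[ok]
  dat <- list(om = om, ly = log(y))
  tauD_grid <- 1 / exp(seq(log(min(om)), log(max(om)), length.out = 5))
  starts <- list()
  for (td in tauD_grid)
    for (al in c(0.2, 1 / 3, 0.9))
      starts[[length(starts) + 1]] <-
        list(e0 = max(min(y) / 2, 1e-12), H0 = max(y), td = td, al = al)
  if (fit_offset) {
    starts <- lapply(starts, function(s) c(s, list(ek = min(y) / 2)))
    fit <- multistart_nlsLM(
      ly ~ log(fractional_viscosity_model(om, e0, H0, td, al, ek)),
      data = dat, starts = starts,
      lower = c(e0 = 1e-15, H0 = 1e-15, td = 1e-12, al = 0, ek = 0),
      upper = c(e0 = Inf, H0 = Inf, td = Inf, al = 1, ek = Inf))
  } else {
    fit <- multistart_nlsLM(
      ly ~ log(fractional_viscosity_model(om, e0, H0, td, al, 0)),
      data = dat, starts = starts,
      lower = c(e0 = 1e-15, H0 = 1e-15, td = 1e-12, al = 0),
      upper = c(e0 = Inf, H0 = Inf, td = Inf, al = 1))
  }
  ci <- fit_ci(fit)
  cf <- ci$coef
  structure(list(eta0 = unname(cf[["e0"]]), H0 = unname(cf[["H0"]]),
                 tau_D = unname(cf[["td"]]), alpha = unname(cf[["al"]]),
                 eta_kick = if (fit_offset) unname(cf[["ek"]]) else 0,
                 se = ci$se,
                 goodness = sqrt(stats::deviance(fit) / length(om)),
                 branch = "viscosity", fit = fit),
            class = "fractional_fit")
}

#' @export
print.fractional_fit <- function(x, ...) {
  cat(sprintf("Fractional Maxwell fit (%s branch)\n", x$branch))
  if (x$branch == "rigidity")
    cat(sprintf("  G_gamma %.4g N/m (gamma_eff %.4g N/m), G_kappa %.4g N/m\n",
                x$G_gamma, x$gamma_eff, x$G_kappa))
  else
    cat(sprintf("  eta0 %.4g Pa s, H0 %.4g Pa s, eta_kick %.4g Pa s\n",
                x$eta0, x$H0, x$eta_kick))
  cat(sprintf("  tau_D %.4g s (omega_D %.4g rad/s), alpha %.4g, residual %.3g\n",
              x$tau_D, 1 / x$tau_D, x$alpha, x$goodness))
  invisible(x)
}

#' @export
coef.fractional_fit <- function(object, ...) {
  if (object$branch == "rigidity")
    c(G_gamma = object$G_gamma, G_kappa = object$G_kappa,
      tau_D = object$tau_D, alpha = object$alpha)
  else
    c(eta0 = object$eta0, H0 = object$H0, tau_D = object$tau_D,
      alpha = object$alpha, eta_kick = object$eta_kick)
}

#' @export
predict.fractional_fit <- function(object, omega, ...) {
  if (object$branch == "rigidity")
    fractional_rigidity_model(omega, object$G_gamma, object$G_kappa,
                              object$tau_D, object$alpha)
  else
    fractional_viscosity_model(omega, object$eta0, object$H0, object$tau_D,
                               object$alpha, object$eta_kick)
}

#' Viscoelastic ratio and spectral crossovers
#'
#' The viscoelastic ratio \eqn{G'(\omega) / (6\pi L\, \eta_{eff}(\omega))}
#' (units 1/s), the Maxwell crossover omega_D where
#' \eqn{G'(\omega) = \omega\, 6\pi L\, \eta_{eff}(\omega)} (log-interpolated;
#' reported as a band edge with \code{omega_D_bounded = TRUE} when no
#' crossing lies in band), and the noise-floor onset omega_C, the first
#' frequency above which the local PSD slope stays above -0.2.
#'
#' @param r A \code{rheo_spectrum}.
#' @param floor_slope Slope threshold defining the white floor.
#' @return List with \code{ratio} (vector), \code{omega_D},
#'   \code{omega_D_bounded}, \code{omega_C} (NA if no floor in band).
#' @export
viscoelastic_ratio_and_crossovers <- function(r, floor_slope = -0.2) {
  stopifnot(inherits(r, "rheo_spectrum"))
  om <- r$omega
  H <- 6 * pi * r$L * r$eta_eff              # friction spectrum, N s/m
  f <- log(r$G_prime) - log(om * H)          # zero at the Maxwell crossing
  cross <- which(f[-1] * f[-length(f)] < 0)
  if (length(cross)) {
    j <- cross[1]
    t <- f[j] / (f[j] - f[j + 1])
    omega_D <- exp(log(om[j]) + t * (log(om[j + 1]) - log(om[j])))
    bounded <- FALSE
  } else {
    omega_D <- if (mean(f) > 0) max(om) else min(om)
    bounded <- TRUE
  }
  ## noise-floor onset: the top of the band must be flat (local psd slope
  ## above floor_slope); the onset is where the spectrum meets twice the
  ## floor level (the equal-power point of signal and floor)
  omega_C <- NA_real_
  top <- om >= max(om) / sqrt(10)            # top half-decade
  if (sum(top) >= 3 && !is.null(r$psd) &&
      mean(r$alpha_local[top]) > floor_slope) {
    floor_level <- stats::median(r$psd[top])
    hit <- which(r$psd <= 2 * floor_level)
    if (length(hit)) omega_C <- om[hit[1]]
  }
  list(ratio = r$ratio, omega_D = omega_D, omega_D_bounded = bounded,
       omega_C = omega_C)
}
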