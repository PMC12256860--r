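#' Welch power spectral density of a contour series
#'
#' Per-site Welch-averaged one-sided power spectral density (Hann window,
#' 50 percent overlap, per-segment mean removal), and the ensemble mean over
#' sites. The density is expressed on an angular-frequency grid (rad/s) and
#' normalized so the integral over the grid equals the series variance
#' (Parseval): \code{sum(psd * diff(omega))} approximates \code{var(x)}.
#'
#' @param s A \code{contour_series}, or a numeric matrix (sites x frames) or
#'   vector (then \code{dt} is required).
#' @param segment_length Welch segment length in frames (power of 2
#'   recommended); must not exceed half the series length... it must satisfy
#'   \code{n_frames >= 2*segment_length} unless only one segment fits.
#' @param dt Frame interval (s) for bare inputs.
#' @param return_per_site Keep the per-site PSD matrix (sites x frequencies).
#' @param msd_lags Number of log-spaced lags at which the ensemble
#'   mean-square displacement is measured in the time domain (0 or NULL to
#'   skip); the MSD feeds \code{\link{gser_modulus}}.
#' @return An object of class \code{flicker_spectrum}: \code{omega} (rad/s,
#'   increasing, DC excluded), \code{psd} (ensemble mean, m^2 s/rad),
#'   \code{psd_site} (optional), \code{n_segments}, \code{dt},
#'   \code{scope}.
#' @export
compute_psd <- function(s, segment_length = 4096L, dt = NULL,
                        return_per_site = FALSE, msd_lags = 48L) {
  if (inherits(s, "contour_series")) { x <- s$dh; dt <- s$dt }
  else if (is.null(dim(s))) x <- matrix(s, nrow = 1)
  else x <- s
  if (is.null(dt)) stop("dt required for bare matrix input")
  Tn <- ncol(x)
  if (Tn < 2 * segment_length && segment_length > Tn)
    stop("segment longer than series")
  L <- min(segment_length, Tn)
  starts <- seq(1L, Tn - L + 1L, by = max(1L, L %/% 2L))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))   # Hann
  W2 <- sum(w^2)
  nf <- L %/% 2L
  acc <- matrix(0, nrow(x), nf)
  for (st in starts) {
    seg <- x[, st:(st + L - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    Y <- t(stats::mvfft(t(seg * rep(w, each = nrow(seg)))))
    acc <- acc + (Mod(Y[, 2:(nf + 1L), drop = FALSE])^2)
  }
  P_f <- acc / length(starts) * (2 * dt / W2)     # one-sided, per Hz
  omega <- 2 * pi * (seq_len(nf)) / (L * dt)
  psd_site <- P_f / (2 * pi)                      # per rad/s
  psd <- colMeans(psd_site)
  msd <- NULL; msd_tau <- NULL
  if (!is.null(msd_lags) && msd_lags > 0) {
    lags <- unique(round(exp(seq(0, log(min(Tn - 1, 2L * L)),
                                 length.out = msd_lags))))
    ## sites are statistically equivalent: a subsample suffices for the
    ## ensemble MSD
    sub <- if (nrow(x) > 64) round(seq(1, nrow(x), length.out = 64)) else
      seq_len(nrow(x))
    msd <- series_msd(x[sub, , drop = FALSE], lags)
    msd_tau <- lags * dt
  }
  structure(list(omega = omega, psd = psd,
                 psd_site = if (return_per_site) psd_site else NULL,
                 msd_tau = msd_tau, msd = msd,
                 n_segments = length(starts), dt = dt,
                 scope = if (nrow(x) > 1) "ensemble" else "single"),
            class = "flicker_spectrum")
}

## Ensemble mean-square displacement at integer lags, via FFT
## autocovariance (unbiased lag normalization), averaged over sites.
series_msd <- function(x, lags) {
  Tn <- ncol(x); N <- nrow(x)
  nfft <- stats::nextn(2 * Tn, 2)
  msd_acc <- numeric(length(lags))
  blk <- max(1L, min(N, floor(2^24 / nfft)))
  for (i0 in seq(1L, N, by = blk)) {
    idx <- i0:min(i0 + blk - 1L, N)
    Xc <- t(x[idx, , drop = FALSE])
    Xc <- sweep(Xc, 2, colMeans(Xc))
    Z <- rbind(Xc, matrix(0, nfft - Tn, length(idx)))
    F <- stats::mvfft(Z)
    ac <- Re(stats::mvfft(F * Conj(F), inverse = TRUE))[1:Tn, ,
                                                        drop = FALSE] / nfft
    ac <- ac / (Tn - (seq_len(Tn) - 1))           # unbiased C(k)
    msd_acc <- msd_acc + rowSums(2 * (rep(ac[1, ], each = length(lags)) -
                                        ac[lags + 1, , drop = FALSE]))
  }
  msd_acc / N
}

#' @export
print.flicker_spectrum <- function(x, ...) {
  cat(sprintf("Flickering PSD (%s): %d frequencies in [%.3g, %.3g] rad/s, %d Welch segments\n",
              x$scope, length(x$omega), min(x$omega), max(x$omega),
              x$n_segments))
  cat(sprintf("  spectral integral (variance) %.3g m^2\n", spectrum_integral(x)))
  invisible(x)
}

#' Integral of a spectrum over angular frequency
#'
#' Trapezoidal integral of the one-sided PSD over its grid; equals the series
#' variance captured by the estimator (Parseval).
#'
#' @param sp A \code{flicker_spectrum}.
#' @return Variance (m^2).
#' @export
spectrum_integral <- function(sp) {
  sum(diff(sp$omega) * (sp$psd[-1] + sp$psd[-length(sp$psd)]) / 2)
}

#' Log-log power-law fit of a spectrum
#'
#' Least-squares slope of log(psd) vs log(omega) over a frequency window.
#'
#' @param sp A \code{flicker_spectrum} (or list with omega, psd).
#' @param omega_range Window \code{c(lo, hi)} in rad/s.
#' @return List with \code{exponent}, \code{stderr}, \code{n} and
#'   \code{omega_range}.
#' @export
fit_powerlaw <- function(sp, omega_range) {
  i <- sp$omega >= omega_range[1] & sp$omega <= omega_range[2] & sp$psd > 0
  if (sum(i) < 8) stop("need at least 8 grid points in the window")
  fit <- stats::lm(log(sp$psd[i]) ~ log(sp$omega[i]))
  list(exponent = unname(stats::coef(fit)[2]),
       stderr = unname(sqrt(diag(stats::vcov(fit)))[2]),
       n = sum(i), omega_range = omega_range)
}

#' Passive spectral model
#'
#' Bimodal passive flickering spectrum PSD(omega) = kB*T / (omega * G(omega))
#' with the frequency-renormalized flexural stiffness
#' G(omega) = G_gamma + G_kappa_w * omega^(2/3): a pink (1/omega) tension
#' branch crossing over to the omega^(-5/3) bending branch at
#' omega_D = (G_gamma/G_kappa_w)^(3/2).
#'
#' @param omega Angular frequency grid (rad/s).
#' @param G_gamma Tension (static) stiffness (N/m).
#' @param G_kappa_w Bending stiffness coefficient (N s^(2/3)/m).
#' @param T Temperature (K).
#' @return PSD values (m^2 s/rad).
#' @export
psd_passive_model <- function(omega, G_gamma, G_kappa_w, T = 310.15) {
  .kB * T / (omega * (G_gamma + G_kappa_w * omega^(2 / 3)))
}

#' Active spectral model (log-uniform telegraph ensemble)
#'
#' One-sided spectrum of a superposition of equal-power telegraph processes
#' with switching rates log-uniform over \code{c(a, b)}:
#' S(omega) = P_act * (2/pi) * (atan(2b/omega) - atan(2a/omega)) /
#' (omega * log(b/a)), which decays as ~1/omega for a << omega << b (the
#' pink kicking band) and integrates to the total active power P_act.
#'
#' @param omega Angular frequency grid (rad/s).
#' @param P_act Total active displacement power (m^2), proportional to
#'   phi * p_on * f0 * Lambda0.
#' @param span Switching-rate band \code{c(a, b)} (rad/s).
#' @return PSD values (m^2 s/rad).
#' @export
psd_active_model <- function(omega, P_act, span) {
  a <- span[1]; b <- span[2]
  P_act * (2 / pi) * (atan(2 * b / omega) - atan(2 * a / omega)) /
    (omega * log(b / a))
}

#' Bicomponent (passive + active) spectral fit
#'
#' Weighted log-space least-squares fit of the ensemble spectrum to the sum
#' of the passive bimodal model and the active kicking ensemble model, with
#' the active rate-band span ratio fixed (two decades by default, matching
#' the kicker ensemble). Model selection against the passive-only fit uses
#' AIC: if the passive-only model is preferred or the active amplitude is
#' consistent with zero, the fit is flagged passive-only.
#'
#' @param sp A \code{flicker_spectrum}.
#' @param m A \code{membrane_params} (supplies T).
#' @param span_ratio Fixed ratio b/a of the active rate band.
#' @param omega_range Fit window; default the full grid.
#' @return An object of class \code{bicomponent_fit}: passive parameters
#'   (G_gamma, G_kappa_w), active power P_act and rate-band low edge
#'   omega_A, the crossovers omega_A and omega_D, \code{passive_only} flag
#'   and the underlying \code{nls} fits.
#' @export
fit_bicomponent <- function(sp, m, span_ratio = 100, omega_range = NULL) {
  i <- sp$psd > 0
  if (!is.null(omega_range))
    i <- i & sp$omega >= omega_range[1] & sp$omega <= omega_range[2]
  om <- sp$omega[i]; y <- log(sp$psd[i])
  if (diff(range(log10(om))) < 2.5)
    stop("spectrum must span at least 2.5 decades")
  Tb <- m$T
  ## passive-only fit
  g0 <- .kB * Tb / (om[1] * sp$psd[i][1])
  k0 <- .kB * Tb / (max(om)^(5 / 3) * sp$psd[i][length(om)])
  fit_p <- minpack.lm::nlsLM(
    y ~ log(psd_passive_model(om, Gg, Gk, Tb)),
    start = list(Gg = g0, Gk = k0),
    lower = c(1e-12, 1e-14), control = minpack.lm::nls.lm.control(maxiter = 200))
  ## bicomponent fit, multistart over the active band position
  P0 <- spectrum_integral(sp)
  best <- NULL
  for (a_lo in c(min(om), stats::median(om) / 10, stats::median(om) / 3)) {
    for (fr in c(0.1, 0.5, 0.9)) {
      fit_b <- tryCatch(minpack.lm::nlsLM(
        y ~ log(psd_passive_model(om, Gg, Gk, Tb) +
                  psd_active_model(om, Pa, c(alo, alo * span_ratio))),
        start = list(Gg = stats::coef(fit_p)[["Gg"]],
                     Gk = stats::coef(fit_p)[["Gk"]],
                     Pa = fr * P0, alo = a_lo),
        lower = c(1e-12, 1e-14, 0, min(om) / 10),
        upper = c(Inf, Inf, Inf, max(om)),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(fit_b) &&
          (is.null(best) || stats::deviance(fit_b) < stats::deviance(best)))
        best <- fit_b
    }
  }
  passive_only <- TRUE
  cf <- stats::coef(fit_p); Pa <- 0; alo <- NA_real_
  if (!is.null(best)) {
    cb <- stats::coef(best)
    se_Pa <- tryCatch(sqrt(diag(stats::vcov(best)))[["Pa"]],
                      error = function(e) Inf)
    aic_p <- length(om) * log(stats::deviance(fit_p) / length(om)) + 2 * 2
    aic_b <- length(om) * log(stats::deviance(best) / length(om)) + 2 * 4
    if (aic_b < aic_p && is.finite(se_Pa) && cb[["Pa"]] > 2 * se_Pa) {
      passive_only <- FALSE
      cf <- cb[c("Gg", "Gk")]; Pa <- cb[["Pa"]]; alo <- cb[["alo"]]
    }
  }
  structure(list(G_gamma = unname(cf[["Gg"]]), G_kappa_w = unname(cf[["Gk"]]),
                 P_act = unname(Pa),
                 omega_A = if (is.na(alo)) NA_real_
                           else unname(sqrt(alo^2 * span_ratio)),
                 rate_span = if (is.na(alo)) NULL
                             else c(alo, alo * span_ratio),
                 omega_D = (cf[["Gg"]] / cf[["Gk"]])^(3 / 2),
                 passive_only = passive_only, T = Tb,
                 fits = list(passive = fit_p, bicomponent = best)),
            class = "bicomponent_fit")
}

#' @export
print.bicomponent_fit <- function(x, ...) {
  cat("Bicomponent spectral fit\n")
  cat(sprintf("  passive: G_gamma %.3g N/m, G_kappa_w %.3g, omega_D %.3g rad/s\n",
              x$G_gamma, x$G_kappa_w, x$omega_D))
  if (x$passive_only) cat("  active component: not identifiable (passive-only)\n")
  else cat(sprintf("  active: power %.3g m^2 over rates [%.3g, %.3g] rad/s\n",
                   x$P_act, x$rate_span[1], x$rate_span[2]))
  invisible(x)
}

#' Predicted total fitted spectral power
#'
#' Integral over the fitted model (passive + active components) on a grid.
#'
#' @param fit A \code{bicomponent_fit}.
#' @param omega Evaluation grid.
#' @return Power (m^2).
#' @export
fitted_total_power <- function(fit, omega) {
  y <- psd_passive_model(omega, fit$G_gamma, fit$G_kappa_w, fit$T)
  if (!fit$passive_only)
    y <- y + psd_active_model(omega, fit$P_act, fit$rate_span)
  sum(diff(omega) * (y[-1] + y[-length(y)]) / 2)
}
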