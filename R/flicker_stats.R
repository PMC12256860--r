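#' Per-emplacement flickering variance
#'
#' Time-averaged squared displacement per contour site (per-site mean
#' removed): the local flickering amplitude sigma_i^2.
#'
#' @param s A \code{contour_series} or an N x T numeric matrix.
#' @return Numeric vector of N variances (m^2).
#' @export
local_variance <- function(s) {
  dh <- if (inherits(s, "contour_series")) s$dh else s
  if (ncol(dh) < 100) stop("series too short: need at least 100 frames")
  mu <- rowMeans(dh)
  rowMeans(dh^2) - mu^2
}

#' Ensemble flickering variance
#'
#' Ensemble variance Sigma^2 = mean over sites of sigma_i^2, and the
#' characteristic displacement 2*Sigma (the span of ~95 percent of
#' near-Gaussian deformation events).
#'
#' @param sigma2 Vector of per-site variances (m^2).
#' @return List with \code{Sigma2} (m^2) and \code{two_Sigma} (m).
#' @export
ensemble_variance <- function(sigma2) {
  if (length(sigma2) < 1) stop("need at least one site")
  Sigma2 <- mean(sigma2)
  list(Sigma2 = Sigma2, two_Sigma = 2 * sqrt(Sigma2))
}

#' Pooled displacement distribution and Gaussian fit
#'
#' Normalized histogram of displacements pooled over all sites and frames,
#' with a maximum-likelihood Gaussian fit and the fraction of events within
#' +/- 2 Sigma of the fitted mean.
#'
#' @param s A \code{contour_series} or numeric matrix/vector.
#' @param bins Number of histogram bins.
#' @return List with \code{mids}, \code{density}, \code{mean_fit},
#'   \code{Sigma_fit} (ML sd), \code{frac_within_2Sigma} and \code{n}.
#' @export
displacement_pdf <- function(s, bins = 101L) {
  x <- if (inherits(s, "contour_series")) as.numeric(s$dh) else as.numeric(s)
  if (length(x) < 1e4) stop("need at least 1e4 pooled samples")
  sdx <- stats::sd(x)
  if (!is.finite(sdx) || sdx == 0) stop("degenerate (zero-variance) input")
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  mu <- mean(x)
  Sig <- sqrt(mean((x - mu)^2))            # ML estimate
  list(mids = h$mids, density = h$density, mean_fit = mu, Sigma_fit = Sig,
       frac_within_2Sigma = mean(abs(x - mu) <= 2 * Sig), n = length(x))
}

#' Equipartition (effective) elasticity
#'
#' Harmonic stiffness implied by a fluctuation variance at temperature T:
#' G = kB*T / Sigma^2.
#'
#' @param Sigma2 Ensemble variance (m^2), > 0.
#' @param T Temperature (K).
#' @return Elasticity (N/m).
#' @export
effective_elasticity <- function(Sigma2, T = 310.15) {
  if (Sigma2 <= 0) stop("Sigma2 must be positive")
  .kB * T / Sigma2
}

#' Local effective temperature map
#'
#' Maps per-site variances to effective temperatures, Teff_i = G0*sigma_i^2/kB:
#' a site fluctuating at the basal passive variance kB*T/G0 maps to Teff = T,
#' and Teff is linear in sigma_i^2.
#'
#' @param sigma2 Per-site variances (m^2).
#' @param G0 Basal passive rigidity (N/m), > 0.
#' @param T Bath temperature (K) (used only for reference in the result).
#' @return Numeric vector of effective temperatures (K).
#' @export
effective_temperature_map <- function(sigma2, G0, T = 310.15) {
  if (G0 <= 0) stop("G0 must be positive")
  G0 * sigma2 / .kB
}

#' Hot-spot mask and activated fraction
#'
#' A site is "hot" when its standard deviation reaches k times the reference
#' ensemble amplitude, i.e. sigma_i^2 >= k^2 * Sigma2_ref (boundary
#' inclusive). With the default k = 2 the criterion is sigma_i >= 2*Sigma,
#' the kicking displacement scale Lambda0.
#'
#' @param sigma2 Per-site variances (m^2).
#' @param Sigma2_ref Reference (passive) ensemble variance (m^2), > 0.
#' @param k Amplitude multiple defining "hot".
#' @return List with \code{mask} (logical) and \code{phi_est} = N_hot/N.
#' @export
hot_spot_mask <- function(sigma2, Sigma2_ref, k = 2) {
  if (Sigma2_ref <= 0) stop("Sigma2_ref must be positive")
  mask <- sigma2 >= k^2 * Sigma2_ref
  list(mask = mask, phi_est = mean(mask))
}

#' Flickering velocities
#'
#' Finite-difference mobility per site and frame pair:
#' v_i(t) = (dh_i(t+dt) - dh_i(t)) / dt.
#'
#' @param s A \code{contour_series} or N x T matrix.
#' @param dt Frame interval (s); taken from the series if available.
#' @return N x (T-1) matrix of velocities (m/s).
#' @export
flicker_velocity <- function(s, dt = NULL) {
  if (inherits(s, "contour_series")) { dh <- s$dh; dt <- s$dt }
  else dh <- s
  if (is.null(dt)) stop("dt required for a bare matrix")
  if (ncol(dh) < 2) stop("need at least 2 frames")
  (dh[, -1, drop = FALSE] - dh[, -ncol(dh), drop = FALSE]) / dt
}

#' Green-Kubo local diffusivity
#'
#' Phenomenological diffusivity per site from the velocity autocorrelation
#' function: D_i = integral of <v_i(t) v_i(t+t')> dt', computed as the
#' discrete-time trapezoid up to the first zero crossing of the
#' autocorrelation (capped at \code{max_lag} lags; a non-decaying
#' autocorrelation triggers a warning and truncation at the cap). For
#' memoryless (Brownian) input this equals MSD(dt)/(2 dt).
#'
#' @param v N x (T-1) velocity matrix (or vector), from
#'   \code{\link{flicker_velocity}}.
#' @param dt Frame interval (s).
#' @param max_lag Autocorrelation lag cap.
#' @return Numeric vector of diffusivities (m^2/s).
#' @export
greenkubo_diffusivity <- function(v, dt, max_lag = 100L) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  if (ncol(v) < 1000) stop("need at least 1e3 velocity samples")
  n_lag <- min(max_lag, ncol(v) - 1)
  warned <- FALSE
  D <- apply(v, 1, function(x) {
    if (all(x == 0)) return(0)
    ac <- stats::acf(x, lag.max = n_lag, type = "covariance",
                     plot = FALSE, demean = TRUE)$acf[, 1, 1]
    zc <- which(ac[-1] <= 0)
    if (length(zc) == 0) {
      if (!warned) {
        warning("velocity autocorrelation does not decay to zero within the lag cap; truncating")
        warned <<- TRUE
      }
      k <- n_lag + 1
    } else {
      k <- zc[1] + 1
      ac[k] <- 0                       # clip at the crossing
    }
    sum((ac[seq_len(k - 1)] + ac[2:k]) / 2) * dt
  })
  as.numeric(D)
}

#' Mobility-deformability density map
#'
#' Normalized 2D density histogram of (sigma_i, D_i) pooled over sites (and
#' cells); total mass 1.
#'
#' @param Dloc Vector of local diffusivities (m^2/s).
#' @param sigma Vector of local amplitudes sigma_i (m), same length.
#' @param bins Number of bins per axis.
#' @return List with \code{sigma_breaks}, \code{D_breaks} and \code{density}
#'   (bins x bins matrix summing to 1).
#' @export
mobility_deformability_map <- function(Dloc, sigma, bins = 40L) {
  if (length(Dloc) == 0 || length(sigma) == 0) stop("empty input")
  if (length(Dloc) != length(sigma)) stop("inputs must have equal length")
  sb <- seq(min(sigma), max(sigma), length.out = bins + 1)
  db <- seq(min(Dloc), max(Dloc), length.out = bins + 1)
  si <- pmin(pmax(findInterval(sigma, sb, all.inside = TRUE), 1), bins)
  di <- pmin(pmax(findInterval(Dloc, db, all.inside = TRUE), 1), bins)
  M <- matrix(0, bins, bins)
  for (k in seq_along(si)) M[si[k], di[k]] <- M[si[k], di[k]] + 1
  list(sigma_breaks = sb, D_breaks = db, density = M / sum(M))
}

#' Full real-space flickering statistics
#'
#' Aggregates the real-space statistics of a contour series: local and
#' ensemble variances, equipartition elasticity, effective-temperature map,
#' hot-spot mask and activated fraction, and Green-Kubo diffusivities.
#'
#' @param s A \code{contour_series}.
#' @param G0 Basal rigidity (N/m) for the Teff map and hot-spot reference;
#'   default kB*T/Sigma2 of the series itself (so Teff averages T).
#' @param T Bath temperature (K).
#' @param Sigma2_ref Reference passive variance for the hot-spot criterion;
#'   default kB*T/G0.
#' @param k_hot Hot-spot amplitude multiple.
#' @param max_lag Green-Kubo lag cap.
#' @return An object of class \code{flicker_stats}: sigma2, Sigma2, two_Sigma,
#'   G_eff, Teff_map, hot_mask, phi_est, Dloc, D_bar.
#' @export
flicker_stats <- function(s, G0 = NULL, T = 310.15, Sigma2_ref = NULL,
                          k_hot = 2, max_lag = 100L) {
  stopifnot(inherits(s, "contour_series"))
  sigma2 <- local_variance(s)
  ens <- ensemble_variance(sigma2)
  if (is.null(G0)) G0 <- .kB * T / ens$Sigma2
  if (is.null(Sigma2_ref)) Sigma2_ref <- .kB * T / G0
  hs <- hot_spot_mask(sigma2, Sigma2_ref, k = k_hot)
  v <- flicker_velocity(s)
  Dloc <- greenkubo_diffusivity(v, s$dt, max_lag = max_lag)
  structure(list(sigma2 = sigma2, Sigma2 = ens$Sigma2,
                 two_Sigma = ens$two_Sigma,
                 G_eff = effective_elasticity(ens$Sigma2, T),
                 Teff_map = effective_temperature_map(sigma2, G0, T),
                 hot_mask = hs$mask, phi_est = hs$phi_est,
                 Dloc = Dloc, D_bar = mean(Dloc),
                 G0 = G0, T = T, Sigma2_ref = Sigma2_ref, k_hot = k_hot),
            class = "flicker_stats")
}

#' @export
print.flicker_stats <- function(x, ...) {
  cat("Flickering statistics\n")
  cat(sprintf("  Sigma %.3g nm (2*Sigma %.3g nm), G_eff %.3g uN/m\n",
              sqrt(x$Sigma2) * 1e9, x$two_Sigma * 1e9, x$G_eff * 1e6))
  cat(sprintf("  mean Teff %.1f K (bath %.2f K), hot fraction phi_est %.3f\n",
              mean(x$Teff_map), x$T, x$phi_est))
  cat(sprintf("  mean diffusivity %.3g m^2/s over %d sites\n",
              x$D_bar, length(x$sigma2)))
  invisible(x)
}
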