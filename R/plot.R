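#' @export
plot.flicker_spectrum <- function(x, slopes = c(-1, -5 / 3), ...) {
  graphics::plot(x$omega, x$psd, log = "xy", type = "l",
                 xlab = expression(omega ~ "(rad/s)"),
                 ylab = expression(PSD ~ (m^2 * s)),
                 main = "Flickering power spectral density", ...)
  if (length(slopes)) {
    i0 <- which.min(abs(x$omega - stats::median(x$omega)))
    for (sl in slopes)
      graphics::lines(x$omega, x$psd[i0] * (x$omega / x$omega[i0])^sl,
                      lty = 3, col = "grey50")
  }
  invisible(x)
}

#' @export
plot.rheo_spectrum <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$omega, x$G_prime, log = "xy", type = "l",
                 xlab = expression(omega ~ "(rad/s)"),
                 ylab = expression(G * minute ~ "(N/m)"),
                 main = "Effective rigidity", ...)
  graphics::plot(x$omega, x$eta_eff, log = "xy", type = "l",
                 xlab = expression(omega ~ "(rad/s)"),
                 ylab = expression(eta[eff] ~ "(Pa s)"),
                 main = "Effective viscosity", ...)
  invisible(x)
}

#' @export
plot.contour_series <- function(x, frames = NULL, ...) {
  if (is.null(frames)) frames <- seq_len(min(ncol(x$dh), 2000L))
  graphics::image(x = frames * x$dt, y = x$l * 1e6,
                  z = t(x$dh[, frames, drop = FALSE]) * 1e9,
                  xlab = "time (s)", ylab = "contour position (um)",
                  main = "Contour displacements (nm)",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(x)
}

#' @export
plot.flicker_stats <- function(x, ...) {
  n <- length(x$sigma2)
  graphics::plot(seq_len(n), sqrt(x$sigma2) * 1e9, type = "h",
                 col = ifelse(x$hot_mask, "red3", "grey40"),
                 xlab = "emplacement", ylab = expression(sigma[i] ~ "(nm)"),
                 main = sprintf("Local flickering amplitudes (phi_est = %.2f)",
                                x$phi_est), ...)
  graphics::abline(h = 2 * sqrt(x$Sigma2_ref) * 1e9, lty = 2)
  invisible(x)
}

#' @export
plot.fractional_fit <- function(x, r = NULL, ...) {
  if (is.null(r)) stop("supply the fitted rheo_spectrum as `r`")
  y <- if (x$branch == "rigidity") r$G_prime else r$eta_eff
  graphics::plot(r$omega, y, log = "xy", pch = 20, cex = 0.5,
                 xlab = expression(omega ~ "(rad/s)"),
                 ylab = if (x$branch == "rigidity") "G' (N/m)"
                        else expression(eta[eff] ~ "(Pa s)"),
                 main = sprintf("Fractional Maxwell fit (alpha = %.3g)",
                                x$alpha), ...)
  graphics::lines(r$omega, predict(x, r$omega), col = "red3", lwd = 2)
  invisible(x)
}
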