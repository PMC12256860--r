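#' Image stack container
#'
#' Grayscale frame stack emulating phase-contrast equatorial views: a list of
#' identically sized matrices plus acquisition metadata.
#'
#' @param frames List of numeric matrices (equal dimensions).
#' @param pixel_size Pixel size (m/px).
#' @param dt Frame interval (s).
#' @param optics List of rendering/optics metadata (ring sigma, noise sd,
#'   contrast, polarity, ...).
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(frames, pixel_size, dt, optics = list()) {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same shape")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive")
  structure(list(frames = frames, pixel_size = pixel_size, dt = dt,
                 optics = optics),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Image stack: %d frames of %d x %d px, pixel size %.3g nm, dt %.3g ms\n",
              length(x$frames), d[1], d[2], x$pixel_size * 1e9, x$dt * 1e3))
  invisible(x)
}

#' Default rendering optics
#'
#' @param pixel_size Pixel size (m/px).
#' @param ring_sigma_px Gaussian sigma of the ring cross-section (px).
#' @param noise_sd Additive Gaussian noise sd, as a fraction of the contrast.
#' @param contrast Ring depth (intensity units).
#' @param background Background intensity.
#' @param polarity \code{"dark"} (dark ring on bright field) or \code{"bright"}.
#' @param margin_px Margin between the largest contour radius and frame edge.
#' @return List of optics settings.
#' @export
render_optics <- function(pixel_size = 5e-8, ring_sigma_px = 2,
                          noise_sd = 0, contrast = 0.5, background = 0.75,
                          polarity = c("dark", "bright"), margin_px = 12) {
  polarity <- match.arg(polarity)
  list(pixel_size = pixel_size, ring_sigma_px = ring_sigma_px,
       noise_sd = noise_sd, contrast = contrast, background = background,
       polarity = polarity, margin_px = margin_px)
}

## Periodic linear interpolation of a profile given at n equally spaced
## angles starting at 0, evaluated at arbitrary angles.
interp_periodic <- function(profile, at) {
  n <- length(profile)
  pos <- (at %% (2 * pi)) / (2 * pi) * n   # in [0, n)
  i0 <- floor(pos)
  w <- pos - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  profile[i0] * (1 - w) + profile[i1] * w
}

#' Render contour fluctuations as ring-image frames
#'
#' Draws, for each frame, a ring of Gaussian cross-section centered on the
#' instantaneous contour \eqn{R(\theta, t) = \bar R + \delta h(\theta, t)}:
#' the intensity extremum along any ray from the center lies at
#' \eqn{R(\theta, t)} up to interpolation error. Optional additive Gaussian
#' noise emulates camera noise.
#'
#' @param s A \code{contour_series} (or a \code{cell_contour} for a single
#'   static frame).
#' @param optics Settings from \code{\link{render_optics}}.
#' @param frames Which frames to render (default: all).
#' @param center Optional center in px (default: frame center).
#' @param frame_dim Optional frame dimension in px (square); default sized
#'   from the contour plus margin.
#' @param seed Seed for the noise stream.
#' @return An \code{\link{image_stack}}.
#' @export
render_contour_frames <- function(s, optics = render_optics(), frames = NULL,
                                  center = NULL, frame_dim = NULL, seed = 1) {
  if (inherits(s, "cell_contour")) {
    radii_px <- matrix(s$r / optics$pixel_size, ncol = 1)
    dt <- NA_real_
    contrast <- optics$contrast * s$contrast
  } else {
    stopifnot(inherits(s, "contour_series"))
    if (is.null(frames)) frames <- seq_len(ncol(s$dh))
    radii_px <- (s$R_bar + s$dh[, frames, drop = FALSE]) / optics$pixel_size
    dt <- s$dt
    contrast <- optics$contrast
  }
  r_max <- max(radii_px)
  if (min(radii_px) < 10) stop("ring radius must be at least 10 px")
  if (is.null(frame_dim)) frame_dim <- 2 * ceiling(r_max + optics$margin_px)
  if (is.null(center)) center <- c((frame_dim + 1) / 2, (frame_dim + 1) / 2)
  if (r_max + 2 > min(center, frame_dim - center))
    stop("contour exits the frame; enlarge frame_dim or margin")
  xg <- seq_len(frame_dim) - center[1]
  yg <- seq_len(frame_dim) - center[2]
  rho <- sqrt(outer(xg^2, yg^2, `+`))
  tht <- atan2(rep(yg, each = frame_dim), rep(xg, times = frame_dim))
  sgn <- if (optics$polarity == "dark") -1 else 1
  w2 <- 2 * optics$ring_sigma_px^2
  out <- with_local_seed(seed, {
    lapply(seq_len(ncol(radii_px)), function(t) {
      Rt <- interp_periodic(radii_px[, t], tht)
      img <- optics$background +
        sgn * contrast * exp(-(as.numeric(rho) - Rt)^2 / w2)
      if (optics$noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0,
                                  optics$noise_sd * optics$contrast)
      matrix(img, frame_dim, frame_dim)
    })
  })
  image_stack(out, optics$pixel_size, dt,
              optics = c(optics, list(center = center, seed = seed)))
}
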