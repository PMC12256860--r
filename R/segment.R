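#' Denoise and binarize a frame (Gaussian filter + Otsu threshold)
#'
#' Gaussian-filters the frame (sigma 2 px by default) and binarizes it with
#' Otsu's between-class variance maximization, returning the foreground mask
#' of the cell disk: the thresholded region of the cell polarity, hole-filled
#' and reduced to its largest connected component.
#'
#' @param frame Numeric matrix (any intensity scale).
#' @param sigma_px Gaussian filter sigma in pixels.
#' @param polarity \code{"dark"} if the cell is darker than the field.
#' @param levels Number of candidate thresholds for Otsu's scan.
#' @return Logical matrix mask, with attributes \code{threshold} (in the
#'   original intensity units) and \code{centroid} (px).
#' @export
denoise_binarize <- function(frame, sigma_px = 2, polarity = c("dark", "bright"),
                             levels = 65536L) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  lo <- min(frame); hi <- max(frame)
  if (hi - lo <= 0) stop("degenerate threshold: frame is constant")
  nf <- (frame - lo) / (hi - lo)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(nf), sigma = sigma_px))
  if (max(sm) - min(sm) <= .Machine$double.eps)
    stop("degenerate threshold: filtered frame is constant")
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1), levels = levels)
  mask <- if (polarity == "dark") sm < th else sm > th
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- EBImage::bwlabel(filled)
  labs <- as.integer(lab)
  if (any(labs > 0)) {
    keep <- as.integer(names(which.max(table(labs[labs > 0]))))
    mask <- matrix(labs == keep, nrow(frame), ncol(frame))
  }
  ij <- which(mask, arr.ind = TRUE)
  attr(mask, "threshold") <- th * (hi - lo) + lo
  attr(mask, "centroid") <- if (nrow(ij)) colMeans(ij) else c(NA_real_, NA_real_)
  mask
}

## Bilinear interpolation of a matrix at fractional coordinates (x = row
## index, y = column index). Out-of-range points are clamped to the border.
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nr); y <- pmin(pmax(y, 1), nc)
  x0 <- pmin(floor(x), nr - 1); y0 <- pmin(floor(y), nc - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- x0 + (y0 - 1) * nr
  img[i00] * (1 - fx) * (1 - fy) + img[i00 + 1] * fx * (1 - fy) +
    img[i00 + nr] * (1 - fx) * fy + img[i00 + nr + 1] * fx * fy
}

## Catmull-Rom cubic convolution kernel weights for fractional offset f.
cubic_w <- function(f) {
  list(w0 = ((2 - f) * f - 1) * f / 2,
       w1 = ((3 * f - 5) * f * f + 2) / 2,
       w2 = ((4 - 3 * f) * f + 1) * f / 2,
       w3 = (f - 1) * f * f / 2)
}

## Bicubic (cubic convolution) interpolation; coordinates clamped so the
## 4x4 neighbourhood stays in range. Substantially lower positional bias
## than bilinear for smooth (blurred) images.
bicubic <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 2), nr - 2 + 0.999999)
  y <- pmin(pmax(y, 2), nc - 2 + 0.999999)
  x0 <- floor(x); y0 <- floor(y)
  wx <- cubic_w(x - x0); wy <- cubic_w(y - y0)
  row_interp <- function(dy, wyk) {
    i <- x0 + (y0 + dy - 1) * nr
    (img[i - 1] * wx$w0 + img[i] * wx$w1 + img[i + 1] * wx$w2 +
       img[i + 2] * wx$w3) * wyk
  }
  row_interp(-1, wy$w0) + row_interp(0, wy$w1) +
    row_interp(1, wy$w2) + row_interp(2, wy$w3)
}

#' Extract a radial contour profile from one frame
#'
#' Casts \code{N} rays from the center and locates, on each ray, the subpixel
#' position of the ring-intensity extremum: the ray profile is sampled by
#' bilinear interpolation, the neighbourhood of the discrete extremum is
#' upsampled with a cubic spline, and the vertex is refined parabolically.
#' Rays without a detectable extremum give \code{NA}; up to 1 percent of
#' missing rays are filled by periodic linear interpolation, more rejects the
#' frame.
#'
#' @param frame Numeric matrix.
#' @param center Center (row, col) in px.
#' @param N Number of rays (angles).
#' @param r_range Search range of radii in px, \code{c(min, max)}; default
#'   from 5 px to the frame border.
#' @param polarity \code{"dark"} ring minimum or \code{"bright"} maximum.
#' @param step_px Coarse sampling step along the ray.
#' @param min_depth Minimum extremum depth, as a fraction of the profile's
#'   intensity range, below which a ray is flagged missing.
#' @return Numeric vector of N radii (px) at angles \code{2*pi*(0:(N-1))/N},
#'   with attribute \code{n_missing}.
#' @export
extract_contour <- function(frame, center, N = 2048L, r_range = NULL,
                            polarity = c("dark", "bright"), step_px = 0.5,
                            min_depth = 0.1) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(frame), length(center) == 2)
  if (center[1] < 1 || center[1] > nrow(frame) ||
      center[2] < 1 || center[2] > ncol(frame))
    stop("center must lie inside the frame")
  if (is.null(r_range)) {
    r_max <- min(center[1] - 1, nrow(frame) - center[1],
                 center[2] - 1, ncol(frame) - center[2])
    r_range <- c(5, r_max)
  }
  rs <- seq(r_range[1], r_range[2], by = step_px)
  theta <- 2 * pi * (seq_len(N) - 1) / N
  ## sample all rays at once: (length(rs) x N)
  X <- center[1] + outer(rs, cos(theta))
  Y <- center[2] + outer(rs, sin(theta))
  P <- matrix(bicubic(frame, as.numeric(X), as.numeric(Y)), length(rs), N)
  if (polarity == "bright") P <- -P
  radii <- rep(NA_real_, N)
  rng <- apply(P, 2, function(p) diff(range(p)))
  idx <- apply(P, 2, which.min)             # index of the minimum per ray
  depth_ok <- rng > 0
  for (j in seq_len(N)) {
    i <- idx[j]
    if (i <= 2 || i >= length(rs) - 1) next   # extremum at search boundary
    p <- P[, j]
    depth <- stats::median(p) - p[i]
    if (!depth_ok[j] || depth < min_depth * rng[j]) next
    lo <- max(1, i - 3); hi <- min(length(rs), i + 3)
    sp <- stats::splinefun(rs[lo:hi], p[lo:hi])
    fine <- seq(rs[max(lo, i - 1)], rs[min(hi, i + 1)], length.out = 41)
    pf <- sp(fine)
    k <- which.min(pf)
    if (k > 1 && k < length(fine)) {
      ## parabolic vertex through the three finest points
      y1 <- pf[k - 1]; y2 <- pf[k]; y3 <- pf[k + 1]
      den <- y1 - 2 * y2 + y3
      delta <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
      radii[j] <- fine[k] + delta * (fine[2] - fine[1])
    } else radii[j] <- fine[k]
  }
  n_missing <- sum(is.na(radii))
  if (n_missing > 0.01 * N)
    stop(sprintf("frame rejected: %d of %d rays without a detectable extremum",
                 n_missing, N))
  if (n_missing > 0) {
    ok <- which(!is.na(radii))
    ## periodic linear interpolation across missing rays
    th3 <- c(theta[ok] - 2 * pi, theta[ok], theta[ok] + 2 * pi)
    r3 <- rep(radii[ok], 3)
    radii[is.na(radii)] <- stats::approx(th3, r3, xout = theta[is.na(radii)])$y
  }
  attr(radii, "n_missing") <- n_missing
  radii
}

#' Radial profile stack
#'
#' @param radii T x N matrix of contour radii (px or m).
#' @param center Per-frame center used at extraction (T x 2, px), optional.
#' @param angles N angular coordinates (rad), strictly increasing in [0, 2pi).
#' @return An object of class \code{radial_profile_stack}.
#' @export
radial_profile_stack <- function(radii, center = NULL,
                                 angles = 2 * pi * (seq_len(ncol(radii)) - 1) /
                                   ncol(radii)) {
  stopifnot(is.matrix(radii), all(radii > 0), length(angles) == ncol(radii),
            all(diff(angles) > 0), angles[1] >= 0, max(angles) < 2 * pi)
  structure(list(radii = radii, center = center, angles = angles),
            class = "radial_profile_stack")
}

#' @export
print.radial_profile_stack <- function(x, ...) {
  cat(sprintf("Radial profile stack: %d frames x %d angles, mean radius %.3g\n",
              nrow(x$radii), ncol(x$radii), mean(x$radii)))
  invisible(x)
}

## Polygon centroid (area barycenter) of a star-shaped contour given as radii
## over the canonical angles, about the current origin.
polygon_centroid <- function(r, theta) {
  x <- r * cos(theta); y <- r * sin(theta)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  c(sum((x + x2) * cr) / (6 * A), sum((y + y2) * cr) / (6 * A))
}

## Re-express a star-shaped contour (radii about origin) as radii about a
## shifted center, resampled on the canonical angle grid with a periodic
## cubic spline (linear resampling measurably damps per-site variance).
recenter_profile <- function(r, theta, center) {
  x <- r * cos(theta) - center[1]
  y <- r * sin(theta) - center[2]
  th <- atan2(y, x) %% (2 * pi)
  rr <- sqrt(x^2 + y^2)
  o <- order(th)
  sf <- stats::splinefun(c(th[o], th[o][1] + 2 * pi), c(rr[o], rr[o][1]),
                         method = "periodic")
  sf(theta %% (2 * pi) + ifelse(theta %% (2 * pi) < th[o][1], 2 * pi, 0))
}

## Periodic spline evaluation of a profile on the canonical grid at
## arbitrary angles (used for subgrid rotation shifts).
spline_periodic <- function(profile, theta, at) {
  sf <- stats::splinefun(c(theta, theta[1] + 2 * pi),
                         c(profile, profile[1]), method = "periodic")
  sf(at %% (2 * pi) + ifelse(at %% (2 * pi) < theta[1], 2 * pi, 0))
}

#' Drift-correct a radial profile stack
#'
#' Removes rigid motion frame by frame: translation by iterated re-centering
#' on the contour barycenter, and rotation by maximizing the circular
#' cross-correlation of each frame's radius profile against the running mean
#' reference profile (integer shift on the angle grid, parabolically refined
#' and applied by periodic interpolation).
#'
#' @param stack A \code{\link{radial_profile_stack}}.
#' @param rotate Logical; register rotation as well as translation.
#' @param tol_px Convergence tolerance for the barycenter iteration.
#' @param min_corr Frames whose peak profile correlation with the reference
#'   falls below this are flagged (attribute \code{flagged}).
#' @return A corrected \code{radial_profile_stack} with attributes
#'   \code{translations} (applied per-frame barycenter shifts),
#'   \code{rotations} (applied angular shifts, rad) and \code{flagged}.
#' @export
correct_drift <- function(stack, rotate = TRUE, tol_px = 1e-3, min_corr = 0.2) {
  stopifnot(inherits(stack, "radial_profile_stack"))
  R <- stack$radii
  if (nrow(R) < 2) stop("drift correction needs at least 2 frames")
  theta <- stack$angles
  N <- ncol(R); T_ <- nrow(R)
  trans <- matrix(0, T_, 2)
  rots <- numeric(T_)
  flagged <- logical(T_)
  for (t in seq_len(T_)) {
    r <- R[t, ]
    shift_tot <- c(0, 0)
    for (it in 1:8) {
      ctr <- polygon_centroid(r, theta)
      if (sqrt(sum(ctr^2)) < tol_px) break
      r <- recenter_profile(r, theta, ctr)
      shift_tot <- shift_tot + ctr
    }
    R[t, ] <- r
    trans[t, ] <- shift_tot
  }
  if (rotate) {
    ref <- R[1, ] - mean(R[1, ])
    for (t in seq_len(T_)) {
      x <- R[t, ] - mean(R[t, ])
      ## circular cross-correlation via FFT
      cc <- Re(stats::fft(stats::fft(x) * Conj(stats::fft(ref)),
                          inverse = TRUE)) / N
      k <- which.max(cc)
      pk <- cc[k] / (stats::sd(x) * stats::sd(ref) * (N - 1) / N) / N
      if (!is.finite(pk) || pk < min_corr) flagged[t] <- TRUE
      km <- if (k == 1) N else k - 1
      kp <- if (k == N) 1 else k + 1
      den <- cc[km] - 2 * cc[k] + cc[kp]
      frac <- if (abs(den) > 0) 0.5 * (cc[km] - cc[kp]) / den else 0
      shift <- (k - 1 + frac)        # x(theta) ~ ref(theta - shift*dtheta)
      shift <- ((shift + N / 2) %% N) - N / 2
      if (abs(shift) > 1e-9) {
        rots[t] <- shift * 2 * pi / N
        R[t, ] <- spline_periodic(R[t, ], theta, theta + rots[t])
      }
      ## running mean reference reduces reference-noise bias
      ref <- ((t) * ref + (R[t, ] - mean(R[t, ]))) / (t + 1)
    }
  }
  out <- radial_profile_stack(R, center = stack$center, angles = theta)
  attr(out, "translations") <- trans
  attr(out, "rotations") <- rots
  attr(out, "flagged") <- flagged
  out
}

#' Segment an image stack into a radial profile stack
#'
#' Convenience wrapper: per frame, a coarse center from the binarized disk
#' barycenter (first frame; reused subsequently), then subpixel ray
#' segmentation via \code{\link{extract_contour}}.
#'
#' @param stack An \code{\link{image_stack}}.
#' @param N Number of rays.
#' @param polarity Ring polarity for \code{\link{extract_contour}}.
#' @param sigma_px Gaussian sigma for the binarization step.
#' @return A \code{\link{radial_profile_stack}} (radii in px).
#' @export
segment_stack <- function(stack, N = 2048L, polarity = "dark", sigma_px = 2) {
  stopifnot(inherits(stack, "image_stack"))
  ctr <- attr(denoise_binarize(stack$frames[[1]], sigma_px = sigma_px,
                               polarity = polarity), "centroid")
  radii <- t(vapply(stack$frames,
                    function(f) extract_contour(f, ctr, N = N,
                                                polarity = polarity),
                    numeric(N)))
  radial_profile_stack(radii, center = matrix(ctr, nrow(radii), 2,
                                              byrow = TRUE))
}

#' Assemble a contour series from a drift-corrected stack
#'
#' Converts radii to displacements about the global mean radius:
#' \eqn{\bar R} is the mean over all frames and angles (the per-frame mean is
#' not subtracted, so the breathing mode is retained), and
#' \eqn{\delta h_i(t) = R_i(t) - \bar R}, converted to meters.
#'
#' @param stack A \code{\link{radial_profile_stack}} (radii in px).
#' @param dt Frame interval (s).
#' @param pixel_size Pixel size (m/px).
#' @param duration Optional total duration (s); if given, the frame count is
#'   checked against \code{duration/dt}.
#' @return A \code{contour_series}.
#' @export
assemble_series <- function(stack, dt, pixel_size, duration = NULL) {
  stopifnot(inherits(stack, "radial_profile_stack"), dt > 0, pixel_size > 0)
  if (!is.null(duration) && round(duration / dt) != nrow(stack$radii))
    stop(sprintf("frame count %d inconsistent with duration/dt = %g",
                 nrow(stack$radii), duration / dt))
  R_bar_px <- mean(stack$radii)
  dh <- t(stack$radii - R_bar_px) * pixel_size
  new_contour_series(dh, R_bar_px * pixel_size, dt,
                     meta = list(kind = "segmented", pixel_size = pixel_size))
}
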