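#' Shape specification for morphotype fixtures
#'
#' Describes an idealized equatorial cell contour of one of the canonical
#' erythrocyte morphotype geometries: a circle (discocyte rim), an ellipse
#' (elliptocyte), a spiculated contour (echinocyte,
#' \eqn{R(\theta) = R(1 + a\cos m\theta)}) or a low-contrast circle (ghost).
#'
#' @param kind One of \code{"circle"}, \code{"ellipse"}, \code{"spiculated"},
#'   \code{"ghost"}.
#' @param R Reference radius (m).
#' @param axis_ratio Minor/major axis ratio for ellipses, in (0, 1].
#' @param lobes Integer lobe count m for spiculated contours.
#' @param lobe_amplitude Lobe amplitude as a fraction of R, in [0, 1).
#' @param contrast Ring contrast (dimensionless, 1 = full contrast).
#' @return An object of class \code{shape_spec}.
#' @export
shape_spec <- function(kind = c("circle", "ellipse", "spiculated", "ghost"),
                       R = 3.6e-6, axis_ratio = 1, lobes = 0L,
                       lobe_amplitude = 0, contrast = 1) {
  kind <- match.arg(kind)
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  if (!is.finite(axis_ratio) || axis_ratio <= 0 || axis_ratio > 1)
    stop("axis_ratio must be in (0, 1]")
  if (lobes < 0) stop("lobes must be >= 0")
  if (lobe_amplitude < 0 || lobe_amplitude >= 1)
    stop("lobe_amplitude must be in [0, 1)")
  structure(list(kind = kind, R = R, axis_ratio = axis_ratio,
                 lobes = as.integer(lobes), lobe_amplitude = lobe_amplitude,
                 contrast = contrast),
            class = "shape_spec")
}

#' Generate a closed test contour
#'
#' Renders a \code{\link{shape_spec}} as a polygon of radii over \code{n}
#' equally spaced angles. Circles have constant radius; ellipses use the polar
#' radius about the center, \eqn{r(\theta) = ab/\sqrt{(b\cos\theta)^2 +
#' (a\sin\theta)^2}} with a = R and b = axis_ratio * R; spiculated contours
#' use \eqn{R(1 + a\cos m\theta)}; ghosts are circles flagged with their low
#' contrast.
#'
#' @param spec A \code{\link{shape_spec}}.
#' @param n Number of contour vertices (default 2048).
#' @return An object of class \code{cell_contour}: list with \code{theta},
#'   \code{r} (m), \code{contrast} and \code{kind}.
#' @export
generate_shape <- function(spec, n = 2048L) {
  stopifnot(inherits(spec, "shape_spec"))
  theta <- 2 * pi * (seq_len(n) - 1) / n
  r <- switch(spec$kind,
    circle = rep(spec$R, n),
    ghost = rep(spec$R, n),
    ellipse = {
      a <- spec$R; b <- spec$axis_ratio * spec$R
      a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    },
    spiculated = spec$R * (1 + spec$lobe_amplitude * cos(spec$lobes * theta)))
  structure(list(theta = theta, r = r,
                 contrast = if (spec$kind == "ghost") min(spec$contrast, 0.05)
                            else spec$contrast,
                 kind = spec$kind),
            class = "cell_contour")
}

#' @export
print.cell_contour <- function(x, ...) {
  cat(sprintf("Closed contour (%s): %d vertices, mean radius %.3g um, contrast %.2f\n",
              x$kind, length(x$r), mean(x$r) * 1e6, x$contrast))
  invisible(x)
}
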