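#' Principal radii of a closed contour
#'
#' Semi-axes of the second-central-moment-equivalent ellipse of the region
#' enclosed by the contour, computed from exact polygon area moments
#' (Green's theorem). For a solid ellipse with semi-axes (a, b) the
#' eigenvalues of the normalized second-moment tensor are a^2/4 and b^2/4,
#' so the returned radii are \code{2*sqrt(eigenvalues)}, ordered R1 <= R2.
#' The moment estimator is robust to spiculation: lobes of even count cancel
#' in the second moments.
#'
#' @param contour A \code{cell_contour}, or a list/data.frame with fields
#'   \code{theta} and \code{r}, or a 2-column matrix of (x, y) vertices.
#' @return Numeric c(R1, R2), R1 <= R2, in the contour's length units.
#' @export
principal_radii <- function(contour) {
  xy <- contour_xy(contour)
  if (nrow(xy) < 16) stop("contour needs at least 16 points")
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (!is.finite(A) || A <= 0)
    stop("contour is degenerate or self-intersecting (non-positive area)")
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  ## second moments about the origin, then shifted to the centroid
  Ixx <- sum((y^2 + y * y2 + y2^2) * cr) / 12
  Iyy <- sum((x^2 + x * x2 + x2^2) * cr) / 12
  Ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  Cyy <- Ixx / A - cy^2
  Cxx <- Iyy / A - cx^2
  Cxy <- Ixy / A - cx * cy
  ev <- eigen(matrix(c(Cxx, Cxy, Cxy, Cyy), 2, 2), symmetric = TRUE)$values
  if (any(ev < 0)) stop("contour is degenerate or self-intersecting")
  sort(2 * sqrt(ev))
}

contour_xy <- function(contour) {
  if (is.matrix(contour) && ncol(contour) == 2) return(contour)
  if (!is.null(contour$theta) && !is.null(contour$r))
    return(cbind(contour$r * cos(contour$theta),
                 contour$r * sin(contour$theta)))
  stop("contour must be a cell_contour, a theta/r list, or an (x, y) matrix")
}

#' Circularity index
#'
#' Canonical circularity c = R1/R2 of the principal radii; 1 for a circle.
#'
#' @param R1,R2 Principal radii, R1 <= R2, R2 > 0.
#' @return c in (0, 1].
#' @export
circularity_index <- function(R1, R2) {
  if (R2 <= 0) stop("R2 must be positive")
  R1 / R2
}

#' Relative contourness
#'
#' Excess perimeter relative to the equivalent circle:
#' \eqn{\Delta = (D - 2\pi\bar R) / (2\pi\bar R)} where D is the polygonal
#' arc length of the contour. Zero for a circle; spiculated contours have
#' large Delta even when globally circular.
#'
#' @param contour As in \code{\link{principal_radii}}.
#' @param R_bar Mean radius; defaults to the mean of the radial coordinate.
#' @return List with \code{D} (arc length) and \code{Delta} (>= 0 for radial
#'   contours).
#' @export
contourness <- function(contour, R_bar = NULL) {
  xy <- contour_xy(contour)
  if (is.null(R_bar)) {
    if (!is.null(contour$r)) R_bar <- mean(contour$r)
    else R_bar <- mean(sqrt(rowSums(scale(xy, scale = FALSE)^2)))
  }
  D <- sum(sqrt(rowSums((xy[c(2:nrow(xy), 1), ] - xy)^2)))
  list(D = D, Delta = (D - 2 * pi * R_bar) / (2 * pi * R_bar))
}

#' Morphotype record for a contour
#'
#' Computes the shape metrics used by the morphotype classifier.
#'
#' @param contour As in \code{\link{principal_radii}}.
#' @param contrast Measured ring contrast (dimensionless); taken from the
#'   contour if present, else 1.
#' @return A one-row data.frame: R1, R2, c, D, Delta, contrast.
#' @export
morphotype_record <- function(contour, contrast = NULL) {
  if (is.null(contrast))
    contrast <- if (!is.null(contour$contrast)) contour$contrast else 1
  pr <- tryCatch(principal_radii(contour), error = function(e) c(NA, NA))
  cn <- tryCatch(contourness(contour), error = function(e)
    list(D = NA, Delta = NA))
  data.frame(R1 = pr[1], R2 = pr[2],
             c = if (is.na(pr[2])) NA else circularity_index(pr[1], pr[2]),
             D = cn$D, Delta = cn$Delta, contrast = contrast)
}

#' Classify a contour into an erythrocyte morphotype
#'
#' Threshold classifier with precedence ghost -> echinocyte -> elliptocyte ->
#' discocyte: a contrast below \code{contrast_min} marks a ghost (contrast
#' failure invalidates the shape metrics); otherwise contourness Delta > 0.1
#' marks an echinocyte (spiculated cells can still be globally circular);
#' otherwise circularity c <= 0.95 marks an elliptocyte and c > 0.95 a
#' discocyte. Records with missing metrics are debris.
#'
#' @param rec A record from \code{\link{morphotype_record}} (or a list with
#'   fields c, Delta, contrast).
#' @param contrast_min Ghost contrast threshold (fraction of full contrast).
#' @param c_min Circularity threshold (default 0.95).
#' @param Delta_max Contourness threshold (default 0.1).
#' @return Character label: one of \code{"ghost"}, \code{"echinocyte"},
#'   \code{"elliptocyte"}, \code{"discocyte"}, \code{"debris"}.
#' @export
classify_morphotype <- function(rec, contrast_min = 0.2, c_min = 0.95,
                                Delta_max = 0.1) {
  if (is.na(rec$contrast) || is.na(rec$Delta) || is.na(rec$c)) return("debris")
  if (rec$contrast < contrast_min) return("ghost")
  if (rec$Delta > Delta_max) return("echinocyte")
  if (rec$c <= c_min) return("elliptocyte")
  "discocyte"
}

#' Morphotype population distribution
#'
#' Percentage of each morphotype class; debris is excluded from the
#' denominator and reported separately.
#'
#' @param labels Character vector of labels from
#'   \code{\link{classify_morphotype}}.
#' @return List with \code{percent} (named vector over non-debris classes,
#'   summing to 100), \code{counts}, \code{n} and \code{debris_percent}.
#' @export
population_distribution <- function(labels) {
  if (length(labels) == 0) stop("no labels given")
  classes <- c("discocyte", "elliptocyte", "echinocyte", "ghost")
  keep <- labels[labels != "debris"]
  if (length(keep) == 0) stop("all records are debris")
  counts <- table(factor(keep, levels = classes))
  list(percent = stats::setNames(100 * as.numeric(counts) / length(keep),
                                 classes),
       counts = counts, n = length(keep),
       debris_percent = 100 * sum(labels == "debris") / length(labels))
}
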