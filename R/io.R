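#' Write a contour series to disk
#'
#' Text format: header lines \code{# R_bar_m=}, \code{# dt_s=}, \code{# N=},
#' then T rows x N columns of displacements in meters (tab-delimited, written
#' at full round-trip precision). The \code{"rds"} format is the equivalent
#' single-file binary container for large runs.
#'
#' @param s A \code{contour_series}.
#' @param path Output file path.
#' @param format \code{"text"} or \code{"rds"}.
#' @return \code{path}, invisibly.
#' @export
write_contour_series <- function(s, path, format = c("text", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(s, "contour_series"))
  if (format == "rds") { saveRDS(s, path); return(invisible(path)) }
  hdr <- c(sprintf("# R_bar_m=%.17g", s$R_bar),
           sprintf("# dt_s=%.17g", s$dt),
           sprintf("# N=%d", nrow(s$dh)))
  writeLines(hdr, path)
  data.table::fwrite(data.table::as.data.table(t(s$dh)), path, sep = "\t",
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a contour series from disk
#'
#' @param path File written by \code{\link{write_contour_series}}.
#' @param format \code{"text"} or \code{"rds"}.
#' @return A \code{contour_series}.
#' @export
read_contour_series <- function(path, format = c("text", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  hdr <- readLines(path, n = 3L)
  get_field <- function(name) {
    ln <- grep(paste0("^# ", name, "="), hdr, value = TRUE)
    if (length(ln) != 1)
      stop(sprintf("parse error: missing header field '%s' (header lines 1-3)",
                   name))
    as.numeric(sub(paste0("^# ", name, "="), "", ln))
  }
  R_bar <- get_field("R_bar_m")
  dt <- get_field("dt_s")
  N <- as.integer(get_field("N"))
  M <- as.matrix(data.table::fread(path, skip = 3L, sep = "\t", header = FALSE))
  if (ncol(M) != N)
    stop(sprintf("parse error at line 4: expected %d columns, found %d",
                 N, ncol(M)))
  new_contour_series(t(unname(M)), R_bar, dt, meta = list(kind = "file",
                                                          path = path))
}

#' Write an image stack as multi-page TIFF + JSON sidecar
#'
#' Pixel data are scaled to 16-bit over the stored intensity range and
#' written as a multi-page TIFF; pixel size, frame interval, optics and the
#' intensity range go into a JSON sidecar (\code{<path>.json}). Reading
#' recovers the quantized pixel values exactly.
#'
#' @param stack An \code{\link{image_stack}}.
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  lo <- min(vapply(stack$frames, min, 0))
  hi <- max(vapply(stack$frames, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  frames16 <- lapply(stack$frames, function(f)
    round((f - lo) / scale * 65535) / 65535)
  tiff::writeTIFF(frames16, path, bits.per.sample = 16L)
  side <- list(pixel_size_m = stack$pixel_size, dt_s = stack$dt,
               n_frames = length(stack$frames),
               intensity_range = c(lo, hi),
               optics = stack$optics[!vapply(stack$optics, is.null, TRUE)])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack (multi-page TIFF + JSON sidecar)
#'
#' Accepts 8- and 16-bit TIFF stacks; the sidecar \code{<path>.json} is
#' required and its frame count must match the TIFF.
#'
#' @param path TIFF path written by \code{\link{write_image_stack}} (or any
#'   multi-page grayscale TIFF with a conforming sidecar).
#' @return An \code{\link{image_stack}}.
#' @export
read_image_stack <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing sidecar JSON: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]
    f
  })
  if (!is.null(side$n_frames) && side$n_frames != length(frames))
    stop(sprintf("sidecar frame count %d does not match TIFF (%d pages)",
                 side$n_frames, length(frames)))
  rng <- side$intensity_range
  if (is.null(rng)) rng <- c(0, 1)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  frames <- lapply(frames, function(f) f * scale + rng[1])
  image_stack(frames, pixel_size = side$pixel_size_m, dt = side$dt_s,
              optics = if (is.null(side$optics)) list() else side$optics)
}
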