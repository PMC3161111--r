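#' Line-scan (kymograph) image with sampling metadata
#'
#' A line-scan image is built by repeatedly scanning a single line along the
#' length of a microvessel. Rows (axis 1) are positions along the scan line
#' and columns (axis 2) are successive scan times, so unlabelled red blood
#' cells moving through fluorescently labelled plasma appear as slanted dark
#' streaks whose slope encodes their speed.
#'
#' @param intensity Numeric matrix of non-negative intensities; rows are
#'   space (pixels), columns are time (pixels). Both dimensions must be at
#'   least 8 pixels.
#' @param dx_um Spatial sampling interval, micrometres per pixel (> 0).
#' @param dt_ms Temporal sampling interval, milliseconds per pixel (> 0).
#'
#' @return An object of class `linescan_image`: a list with elements
#'   `intensity`, `dx_um`, `dt_ms`.
#'
#' @examples
#' img <- linescan_image(matrix(1, 32, 32), dx_um = 0.2, dt_ms = 1)
#' dim(img$intensity)
#' @export
linescan_image <- function(intensity, dx_um, dt_ms) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("`intensity` must be a numeric matrix (space x time)")
  if (any(dim(intensity) < 8L))
    stop(sprintf(
      "line-scan image must be at least 8 x 8 pixels, got %d x %d",
      nrow(intensity), ncol(intensity)))
  bad <- which(!is.finite(intensity), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "non-finite intensity at [space %d, time %d]", bad[1, 1], bad[1, 2]))
  if (!is.numeric(dx_um) || length(dx_um) != 1L || !is.finite(dx_um) ||
      dx_um <= 0)
    stop("`dx_um` must be a single positive number (um/pixel)")
  if (!is.numeric(dt_ms) || length(dt_ms) != 1L || !is.finite(dt_ms) ||
      dt_ms <= 0)
    stop("`dt_ms` must be a single positive number (ms/pixel)")
  structure(
    list(intensity = intensity, dx_um = dx_um, dt_ms = dt_ms),
    class = "linescan_image")
}

#' @export
print.linescan_image <- function(x, ...) {
  cat(sprintf(
    "<linescan_image> %d px space x %d px time  (dx %.4g um/px, dt %.4g ms/px)\n",
    nrow(x$intensity), ncol(x$intensity), x$dx_um, x$dt_ms))
  cat(sprintf("  window: %.3g um x %.3g ms, intensity range [%.3g, %.3g]\n",
              nrow(x$intensity) * x$dx_um, ncol(x$intensity) * x$dt_ms,
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Transpose a line-scan image, swapping space and time axes
#'
#' Swaps the array axes and exchanges the roles of the sampling intervals:
#' `dx_um` takes the numeric value of `dt_ms` and vice versa. Useful for
#' checking the orientation convention of the estimators.
#'
#' @param x A [linescan_image()].
#' @param ... Ignored.
#' @return A `linescan_image` with axes and sampling metadata swapped.
#' @export
t.linescan_image <- function(x, ...) {
  linescan_image(t(x$intensity), dx_um = x$dt_ms, dt_ms = x$dx_um)
}

#' Read a line-scan image from TIFF or delimited text
#'
#' Single-page grayscale TIFF (8/16-bit or float) or a delimited text matrix
#' (whitespace, comma or tab separated). Sampling metadata can be given
#' directly or through a sidecar JSON file holding `{"dx_um": ..., "dt_ms":
#' ...}`; explicit arguments win over the sidecar.
#'
#' @param path Path to the image file.
#' @param dx_um,dt_ms Sampling intervals; may be omitted when `sidecar`
#'   (or `<path>.json`) provides them.
#' @param sidecar Optional path to a metadata JSON file. Defaults to
#'   `<path>.json` when that file exists.
#' @return A [linescan_image()].
#' @export
read_linescan <- function(path, dx_um = NULL, dt_ms = NULL, sidecar = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read line-scan image: %s", path))
  if (is.null(sidecar) && file.exists(paste0(path, ".json")))
    sidecar <- paste0(path, ".json")
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(dx_um)) dx_um <- meta$dx_um
    if (is.null(dt_ms)) dt_ms <- meta$dt_ms
  }
  if (is.null(dx_um)) stop("missing metadata: dx_um (um/pixel)")
  if (is.null(dt_ms)) stop("missing metadata: dt_ms (ms/pixel)")
  ext <- tolower(tools::file_ext(path))
  intensity <- if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # drop extra channels
    m
  } else {
    as.matrix(utils::read.table(path, header = FALSE, sep = "",
                                colClasses = "numeric"))
  }
  dimnames(intensity) <- NULL
  linescan_image(intensity, dx_um = dx_um, dt_ms = dt_ms)
}

#' Write a line-scan image to TIFF or delimited text
#'
#' TIFF output is normalised to `[0, 1]` over the image range (the scale
#' does not matter to the estimators, which are invariant to affine
#' intensity changes); text output keeps raw values. A sidecar JSON with
#' the sampling metadata is written alongside.
#'
#' @param img A [linescan_image()].
#' @param path Output path; extension `.tif`/`.tiff` selects TIFF,
#'   anything else tab-delimited text.
#' @param sidecar Logical; write `<path>.json` metadata (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_linescan <- function(img, path, sidecar = TRUE) {
  stopifnot(inherits(img, "linescan_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- img$intensity
    rng <- range(m)
    if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng) else m <- m * 0
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  } else {
    utils::write.table(img$intensity, path, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  if (sidecar)
    jsonlite::write_json(list(dx_um = img$dx_um, dt_ms = img$dt_ms),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
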