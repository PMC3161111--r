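#' Read a multi-page grayscale TIFF as a time-lapse stack
#'
#' @param path Multi-page TIFF, one grayscale page per frame.
#' @param frame_rate_hz Frame rate (frames/s).
#' @param baseline_frames Pre-injection frame count.
#' @return A [timelapse_stack()].
#' @export
read_stack <- function(path, frame_rate_hz, baseline_frames) {
  if (!file.exists(path)) stop(sprintf("cannot read stack: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p
  })
  frames <- array(unlist(pages),
                  dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                          length(pages)))
  timelapse_stack(frames, frame_rate_hz = frame_rate_hz,
                  baseline_frames = baseline_frames)
}

#' Write a time-lapse stack to a multi-page TIFF
#'
#' Intensities are normalised to `[0, 1]` over the stack range (16-bit).
#'
#' @param stack A [timelapse_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  rng <- range(stack$frames)
  sc <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(f)
    (stack$frames[, , f] - rng[1]) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a binary mask from a TIFF or delimited text file
#'
#' Any strictly positive pixel counts as in-mask.
#'
#' @param path Image (TIFF) or 0/1 text matrix.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read mask: %s", path))
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    x
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
  dimnames(m) <- NULL
  m > 0
}

#' Write an appearance-time map
#'
#' The authoritative output is a CSV matrix of seconds with empty cells
#' for excluded pixels. Optionally also writes a TIFF visualisation
#' normalised over the valid range (excluded pixels 0).
#'
#' @param map An [appearance_time()] result.
#' @param path Output CSV path.
#' @param tiff_path Optional TIFF visualisation path.
#' @return `path`, invisibly.
#' @export
write_appearance_map <- function(map, path, tiff_path = NULL) {
  stopifnot(inherits(map, "appearance_map"))
  utils::write.table(map$t_appear, path, sep = ",", na = "",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tiff_path)) {
    m <- map$t_appear
    m[!map$valid] <- 0
    mx <- max(m)
    tiff::writeTIFF(if (mx > 0) m / mx else m, tiff_path,
                    bits.per.sample = 16L)
  }
  invisible(path)
}
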