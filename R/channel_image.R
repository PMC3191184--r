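#' Single-channel fluorescence image
#'
#' Container for one channel of a micrograph: an integer-valued intensity
#' matrix together with its camera bit depth and physical pixel size.
#'
#' Pixel coordinates throughout the package are 0-based, with `x` = column
#' and `y` = row, so the pixel stored at `pixels[r, c]` has its center at
#' `(c - 1, r - 1)`. Intensities must lie in `[0, 2^bit_depth - 1]`.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param bit_depth camera bit depth, 8 or 16.
#' @param pixel_size_um physical size of one pixel in micrometres.
#'
#' @return An object of class `channel_image`: a list with elements
#'   `pixels`, `bit_depth` and `pixel_size_um`.
#' @examples
#' img <- channel_image(matrix(0:99, 10, 10), bit_depth = 8)
#' dim(img$pixels)
#' @export
channel_image <- function(pixels, bit_depth = 8L, pixel_size_um = 0.11) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric matrix")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16")
  if (anyNA(pixels))
    stop("`pixels` must not contain NA")
  maxv <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > maxv)
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(
    list(pixels = pixels, bit_depth = bit_depth,
         pixel_size_um = pixel_size_um),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %d x %d px, %d-bit, %.3f um/px, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read grayscale TIFF channels
#'
#' Reads a single- or multi-page 8- or 16-bit grayscale TIFF; each page
#' becomes one [channel_image]. RGB pages are rejected.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_um pixel calibration to attach (TIFF files written by
#'   this package do not embed it).
#' @return A list of `channel_image` objects, one per page.
#' @seealso [write_channel_tiff()], [write_scene()]
#' @export
read_channel_tiff <- function(path, pixel_size_um = 0.11) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) != 2L)
      stop("only single-sample (grayscale) TIFF pages are supported")
    bd <- if (max(p) > 255) 16L else 8L
    bps <- attr(p, "bits.per.sample")
    if (!is.null(bps)) bd <- as.integer(bps)
    channel_image(p, bit_depth = bd, pixel_size_um = pixel_size_um)
  })
}

#' Write channel images to a (multi-page) grayscale TIFF
#'
#' @param channels a `channel_image` or list of them (all the same bit
#'   depth); one page is written per channel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(channels, path) {
  if (inherits(channels, "channel_image")) channels <- list(channels)
  bd <- unique(vapply(channels, `[[`, integer(1), "bit_depth"))
  if (length(bd) != 1L)
    stop("all channels must share one bit depth")
  maxv <- 2^bd - 1
  pages <- lapply(channels, function(ch) ch$pixels / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bd)
  invisible(path)
}

## round-half-up quantization to the integer intensity range of `bit_depth`
.quantize <- function(x, bit_depth) {
  maxv <- 2^bit_depth - 1
  pmin(pmax(floor(x + 0.5), 0), maxv)
}
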