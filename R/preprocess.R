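#' Convert a 16-bit channel to 8-bit
#'
#' Linear min--max rescale to `[0, 255]` with round-half-up, the standard
#' conversion applied before intensity-correlation analysis. A constant
#' image maps to all zeros; 8-bit input passes through unchanged.
#' Preserves the intensity ordering of pixels.
#'
#' @param image a [channel_image()].
#' @return An 8-bit `channel_image`.
#' @export
convert_to_8bit <- function(image) {
  stopifnot(inherits(image, "channel_image"))
  if (image$bit_depth == 8L) return(image)
  p <- image$pixels
  lo <- min(p); hi <- max(p)
  out <- if (hi == lo) {
    matrix(0, nrow(p), ncol(p))
  } else {
    .quantize(255 * (p - lo) / (hi - lo), 8L)
  }
  channel_image(out, bit_depth = 8L, pixel_size_um = image$pixel_size_um)
}

#' ROI-based background subtraction
#'
#' Computes the background threshold `T = mean + k_sd * SD` over the pixels
#' of a user-drawn background polygon (SD is the sample, n-1, standard
#' deviation) and subtracts it from the whole image, clamping at zero and
#' re-quantizing to the image's integer range. `k_sd = 2` is the usual
#' setting for immunofluorescence; `k_sd = 0.5` for in situ hybridization,
#' whose diffuse signal tolerates less aggressive subtraction.
#'
#' Raising `k_sd` never increases any output pixel (monotone).
#'
#' @param image a [channel_image()].
#' @param background_roi an [roi()] polygon covering a signal-free region;
#'   must contain at least 2 pixels and intersect the image.
#' @param k_sd non-negative multiplier on the background SD.
#' @return A background-subtracted `channel_image` (same bit depth).
#' @export
subtract_background_roi <- function(image, background_roi, k_sd = 2) {
  stopifnot(inherits(image, "channel_image"), inherits(background_roi, "roi"))
  if (background_roi$kind != "polygon")
    stop("`background_roi` must be a polygon")
  if (k_sd < 0) stop("`k_sd` must be >= 0")
  pix <- roi_pixels(background_roi, dim(image$pixels))
  if (nrow(pix) < 2L)
    stop("background ROI must cover at least 2 pixels inside the image")
  vals <- image$pixels[pix]
  thr <- mean(vals) + k_sd * stats::sd(vals)
  out <- .quantize(pmax(image$pixels - thr, 0), image$bit_depth)
  channel_image(out, bit_depth = image$bit_depth,
                pixel_size_um = image$pixel_size_um)
}

#' Paired pixel intensities under an ROI
#'
#' Extracts, from two co-registered channels, the intensities of every
#' pixel covered by the ROI — the same positions in both channels, in
#' stable row-major order. These paired samples are the input to all four
#' colocalization coefficients.
#'
#' @param image_a,image_b `channel_image`s with identical dimensions.
#' @param roi an [roi()] (polygon or polyline).
#' @return An object of class `pixel_pairs`: list with `a`, `b` (intensity
#'   vectors), `coords` (matrix with columns `x`, `y`) and `n`.
#' @export
extract_roi_pixels <- function(image_a, image_b, roi) {
  stopifnot(inherits(image_a, "channel_image"),
            inherits(image_b, "channel_image"), inherits(roi, "roi"))
  if (!identical(dim(image_a$pixels), dim(image_b$pixels)))
    stop("channels must have identical dimensions")
  pix <- roi_pixels(roi, dim(image_a$pixels))
  if (nrow(pix) == 0L)
    stop("ROI does not intersect the image")
  structure(
    list(a = as.numeric(image_a$pixels[pix]),
         b = as.numeric(image_b$pixels[pix]),
         coords = cbind(x = attr(pix, "x"), y = attr(pix, "y")),
         n = nrow(pix)),
    class = "pixel_pairs"
  )
}

#' @export
print.pixel_pairs <- function(x, ...) {
  cat(sprintf("<pixel_pairs> n = %d, mean A = %.2f, mean B = %.2f\n",
              x$n, mean(x$a), mean(x$b)))
  invisible(x)
}

#' Intensity profile along a path
#'
#' Samples an image at unit-spaced points along a polyline (nearest-pixel
#' lookup), in path order. Plotting the profiles of two channels on a
#' shared axis displays their covariance along a dendritic segment.
#'
#' @param image a [channel_image()].
#' @param path an [roi()] polyline with total length >= 2 px.
#' @return Numeric vector of intensities; attribute `distance_px` gives
#'   the arc-length position of each sample.
#' @export
intensity_profile <- function(image, path) {
  stopifnot(inherits(image, "channel_image"), inherits(path, "roi"))
  if (path$kind != "polyline") stop("`path` must be a polyline")
  v <- path$vertices
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  total <- sum(seg)
  if (total < 2) stop("path shorter than 2 px")
  s <- seq(0, floor(total))
  pts <- .point_on_path(v, s)
  r <- pmin(pmax(round(pts$xy[, 2]) + 1L, 1L), nrow(image$pixels))
  cc <- pmin(pmax(round(pts$xy[, 1]) + 1L, 1L), ncol(image$pixels))
  out <- image$pixels[cbind(r, cc)]
  attr(out, "distance_px") <- s
  out
}

## Interpolate points (and unit normals) at arc lengths `s` along a
## polyline given by vertex matrix `v`. Used by the profile sampler and
## the scene generator.
.point_on_path <- function(v, s) {
  seg <- cbind(dx = diff(v[, 1]), dy = diff(v[, 2]))
  len <- sqrt(seg[, 1]^2 + seg[, 2]^2)
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(seg))
  t <- (s - cum[idx]) / len[idx]
  xy <- cbind(v[idx, 1] + t * seg[idx, 1], v[idx, 2] + t * seg[idx, 2])
  nrm <- cbind(-seg[idx, 2], seg[idx, 1]) / len[idx]
  list(xy = xy, normal = nrm, total = total)
}
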