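#' Label connected components
#'
#' Labels the foreground of a logical mask into connected components.
#' Default connectivity is 8 (diagonal neighbors connect), the particle
#' convention of ImageJ's Analyze Particles.
#'
#' @param mask logical matrix.
#' @param connectivity 8 or 4.
#' @return Integer matrix of the same dimensions; 0 = background,
#'   components numbered from 1 in order of first (column-major) pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8")
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    stack <- s
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      rr <- r + dr; cc <- cl + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      q <- (cc[ok] - 1L) * nr + rr[ok]
      q <- q[mask[q] & lab[q] == 0L]
      if (length(q)) {
        lab[q] <- cur
        stack <- c(stack, q)
      }
    }
  }
  lab
}

## Build a cluster_set from a label matrix.
.make_cluster_set <- function(lab, source, threshold_used, min_area_px) {
  nr <- nrow(lab)
  fg <- which(lab > 0L)
  parts <- list()
  if (length(fg)) {
    by_lab <- split(fg, lab[fg])
    for (px in by_lab) {
      if (length(px) < min_area_px) next
      x <- ((px - 1L) %/% nr)          # 0-based col
      y <- ((px - 1L) %% nr)           # 0-based row
      parts[[length(parts) + 1L]] <- list(
        pixels = px,
        centroid = c(x = mean(x), y = mean(y)),
        area_px = length(px))
    }
  }
  structure(
    list(particles = parts, dim = dim(lab), source = source,
         threshold_used = threshold_used, min_area_px = min_area_px),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d particles (source: %s, threshold: %s, min area %d px)\n",
              length(x$particles), x$source, format(x$threshold_used),
              x$min_area_px))
  invisible(x)
}

#' @export
as.data.frame.cluster_set <- function(x, ...) {
  if (!length(x$particles))
    return(data.frame(id = integer(0), source = character(0),
                      x = numeric(0), y = numeric(0), area_px = integer(0)))
  data.frame(
    id = seq_along(x$particles),
    source = x$source,
    x = vapply(x$particles, function(p) p$centroid[["x"]], numeric(1)),
    y = vapply(x$particles, function(p) p$centroid[["y"]], numeric(1)),
    area_px = vapply(x$particles, function(p) p$area_px, integer(1)))
}

#' Number of particles in a cluster set
#' @param x a `cluster_set`.
#' @return Integer count.
#' @export
n_clusters <- function(x) {
  stopifnot(inherits(x, "cluster_set"))
  length(x$particles)
}

## Otsu threshold of a set of intensity values, on the integer range of
## the source image. Returns Inf when the values are constant (so that
## "> threshold" selects nothing above a flat background).
.otsu_threshold <- function(vals, bit_depth) {
  if (max(vals) == min(vals)) return(Inf)
  EBImage::otsu(matrix(vals, ncol = 1), range = c(0, 2^bit_depth - 1),
                levels = 256L)
}

#' Detect bright clusters in one channel
#'
#' Thresholds the channel inside an ROI (Otsu's method on the ROI pixels
#' by default, or a fixed value), labels the resulting binary image into
#' 8-connected particles and removes particles smaller than
#' `min_area_px`. The image is expected to be background-subtracted.
#' An image with nothing above threshold yields an empty set, not an
#' error.
#'
#' @param image a [channel_image()].
#' @param roi optional [roi()] restricting the analysis; `NULL` uses the
#'   whole image.
#' @param threshold `"otsu"` or a fixed numeric threshold; pixels strictly
#'   above it are foreground.
#' @param min_area_px minimum particle area in pixels (default 4, to
#'   suppress single-pixel noise).
#' @return A `cluster_set`.
#' @export
detect_clusters <- function(image, roi = NULL, threshold = "otsu",
                            min_area_px = 4L) {
  stopifnot(inherits(image, "channel_image"))
  dm <- dim(image$pixels)
  support <- matrix(TRUE, dm[1], dm[2])
  if (!is.null(roi)) {
    support <- matrix(FALSE, dm[1], dm[2])
    support[roi_pixels(roi, dm)] <- TRUE
  }
  vals <- image$pixels[support]
  if (!length(vals)) stop("ROI does not intersect the image")
  thr <- if (identical(threshold, "otsu")) {
    .otsu_threshold(vals, image$bit_depth)
  } else {
    as.numeric(threshold)
  }
  mask <- support & image$pixels > thr
  .make_cluster_set(label_components(mask, 8), source = "channel",
                    threshold_used = thr, min_area_px = as.integer(min_area_px))
}

#' Particles of the positive-PDM image
#'
#' Converts the positive-PDM mask of a [pdm_image()] (pixels where both
#' channels exceed their ROI means and the PDM is positive) into a binary
#' image, optionally raises the cut with an Otsu threshold on the positive
#' PDM values, then labels and size-filters particles exactly as
#' [detect_clusters()] does. These particles mark where the two signals
#' covary.
#'
#' @param pdm a [pdm_image()].
#' @param min_area_px minimum particle area in pixels.
#' @param threshold `"mask"` (default: the positive mask itself, i.e. a
#'   threshold at 0) or `"otsu"` (Otsu on the positive PDM values).
#' @return A `cluster_set` (possibly empty).
#' @export
positive_pdm_particles <- function(pdm, min_area_px = 4L,
                                   threshold = c("mask", "otsu")) {
  stopifnot(inherits(pdm, "pdm_image"))
  threshold <- match.arg(threshold)
  mask <- pdm$positive_mask
  thr <- 0
  if (threshold == "otsu" && any(mask)) {
    v <- pdm$pdm[mask]
    if (max(v) > min(v)) {
      thr <- EBImage::otsu(matrix(v / max(v), ncol = 1),
                           range = c(0, 1), levels = 256L) * max(v)
      mask <- mask & !is.na(pdm$pdm) & pdm$pdm > thr
    }
  }
  .make_cluster_set(label_components(mask, 8), source = "positive_pdm",
                    threshold_used = thr, min_area_px = as.integer(min_area_px))
}

#' Percentage of clusters containing colocalized signal
#'
#' A cluster counts as colocalized when its pixel set overlaps at least
#' one pixel of any positive-PDM particle; the result is
#' `100 * colocalized / total`. This is the particle-based estimate of
#' the fraction of protein clusters that carry correlated signal from the
#' other channel.
#'
#' @param clusters `cluster_set` of the protein channel (must be
#'   non-empty).
#' @param pdm_particles `cluster_set` from [positive_pdm_particles()].
#' @return A single percentage in `[0, 100]`, with attributes
#'   `n_clusters` and `n_colocalized`.
#' @export
percent_colocalized_clusters <- function(clusters, pdm_particles) {
  stopifnot(inherits(clusters, "cluster_set"),
            inherits(pdm_particles, "cluster_set"))
  total <- length(clusters$particles)
  if (total == 0L)
    stop("cannot compute a percentage over an empty cluster set")
  if (!identical(clusters$dim, pdm_particles$dim))
    stop("cluster sets come from images of different dimensions")
  pdm_px <- unlist(lapply(pdm_particles$particles, `[[`, "pixels"))
  hits <- vapply(clusters$particles, function(p)
    any(p$pixels %in% pdm_px), logical(1))
  out <- 100 * sum(hits) / total
  attr(out, "n_clusters") <- total
  attr(out, "n_colocalized") <- sum(hits)
  out
}
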