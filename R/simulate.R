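#' Parameters for a synthetic two-channel punctate scene
#'
#' Describes the imaging regime emulated by [generate_punctate_pair()]:
#' diffraction-limited puncta scattered along a dendrite-like path in two
#' channels, with a controllable fraction of channel-A clusters carrying
#' a co-positioned channel-B cluster, Gaussian PSF blur, optional Poisson
#' photon noise, Gaussian read noise and integer quantization.
#'
#' @param image_height_px,image_width_px image dimensions (>= 32).
#' @param pixel_size_um micrometres per pixel; the default 0.11 um/px is
#'   typical for a 60x / 1.25 NA oil objective on a spinning-disk system.
#' @param dendrite_path polyline (two-column `(x, y)` matrix) the puncta
#'   are distributed along; default is a horizontal midline with a small
#'   margin.
#' @param cluster_density_per_um expected clusters per micrometre of
#'   path; the default 0.67/um matches observed dendritic cluster
#'   densities for this class of RNA-binding protein.
#' @param cluster_radius_px punctum radius (Gaussian sigma) before PSF
#'   blur.
#' @param amplitude_mean,amplitude_sd peak-intensity distribution
#'   (normal, truncated below at 1).
#' @param coloc_fraction fraction in `[0, 1]` of channel-A clusters that
#'   receive a co-positioned channel-B partner (within 1 px).
#' @param psf_sigma_px Gaussian PSF scale; punctum and PSF sigmas add in
#'   quadrature at render time.
#' @param background_level constant offset added to both channels.
#' @param read_noise_sd Gaussian read-noise SD (0 disables).
#' @param photon_noise apply Poisson resampling of the noiseless render?
#' @param bit_depth 8 or 16; rendered intensities are clipped and
#'   round-half-up quantized to this range.
#' @param lateral_jitter_px SD of the Gaussian offset of cluster centers
#'   perpendicular to the path.
#' @param min_separation_px separation scale keeping the planted ground
#'   truth unambiguous: channel-A centers are redrawn to lie at least
#'   `2 * min_separation_px` apart (a hard-core process; the count stays
#'   Poisson) and non-paired channel-B clusters at least
#'   `min_separation_px` from every channel-A center, so the fraction of
#'   A clusters with a B cluster within 2 px equals `coloc_fraction`
#'   exactly.
#' @param seed RNG seed; scenes are byte-identical for a fixed seed.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(image_height_px = 96L, image_width_px = 512L,
                         pixel_size_um = 0.11, dendrite_path = NULL,
                         cluster_density_per_um = 0.67,
                         cluster_radius_px = 1, amplitude_mean = 150,
                         amplitude_sd = 30, coloc_fraction = 0.7,
                         psf_sigma_px = 1, background_level = 10,
                         read_noise_sd = 2, photon_noise = TRUE,
                         bit_depth = 8L, lateral_jitter_px = 1,
                         min_separation_px = 2, seed = 1L) {
  if (image_height_px < 32 || image_width_px < 32)
    stop("image dimensions must be at least 32 px")
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("`coloc_fraction` must lie in [0, 1]")
  for (nm in c("pixel_size_um", "cluster_density_per_um",
               "cluster_radius_px", "amplitude_mean", "psf_sigma_px")) {
    if (get(nm) <= 0) stop("`", nm, "` must be strictly positive")
  }
  if (amplitude_sd < 0 || read_noise_sd < 0 || background_level < 0)
    stop("noise scales and background must be non-negative")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (is.null(dendrite_path)) {
    m <- 8
    y0 <- (image_height_px - 1) / 2
    dendrite_path <- cbind(c(m, image_width_px - 1 - m), c(y0, y0))
  }
  dendrite_path <- as.matrix(dendrite_path)
  if (nrow(dendrite_path) < 2L)
    stop("`dendrite_path` needs at least 2 vertices")
  if (min(dendrite_path[, 1]) < 0 ||
      max(dendrite_path[, 1]) > image_width_px - 1 ||
      min(dendrite_path[, 2]) < 0 ||
      max(dendrite_path[, 2]) > image_height_px - 1)
    stop("`dendrite_path` vertices must lie inside the image")
  structure(
    list(image_height_px = as.integer(image_height_px),
         image_width_px = as.integer(image_width_px),
         pixel_size_um = pixel_size_um, dendrite_path = dendrite_path,
         cluster_density_per_um = cluster_density_per_um,
         cluster_radius_px = cluster_radius_px,
         amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
         coloc_fraction = coloc_fraction, psf_sigma_px = psf_sigma_px,
         background_level = background_level,
         read_noise_sd = read_noise_sd, photon_noise = photon_noise,
         bit_depth = as.integer(bit_depth),
         lateral_jitter_px = lateral_jitter_px,
         min_separation_px = min_separation_px, seed = as.integer(seed)),
    class = "scene_params"
  )
}

## Render a field of isotropic 2-D Gaussian spots over a constant
## background. `centers` is an (x, y) matrix in 0-based pixel coords.
.render_spots <- function(dm, centers, amps, sigma, background) {
  img <- matrix(background, dm[1], dm[2])
  if (is.null(centers) || nrow(centers) == 0L) return(img)
  ext <- ceiling(4 * sigma)
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    cols <- max(1L, floor(cx) + 1L - ext):min(dm[2], floor(cx) + 1L + ext)
    rows <- max(1L, floor(cy) + 1L - ext):min(dm[1], floor(cy) + 1L + ext)
    gx <- exp(-((cols - 1) - cx)^2 / (2 * sigma^2))
    gy <- exp(-((rows - 1) - cy)^2 / (2 * sigma^2))
    img[rows, cols] <- img[rows, cols] + amps[k] * outer(gy, gx)
  }
  img
}

## Draw cluster centers as a Poisson process along the path with
## Gaussian lateral jitter; returns an (x, y) matrix (possibly 0-row).
.draw_centers <- function(params, n) {
  if (n == 0L)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  path <- params$dendrite_path
  total <- .point_on_path(path, 0)$total
  s <- stats::runif(n, 0, total)
  pp <- .point_on_path(path, s)
  off <- stats::rnorm(n, 0, params$lateral_jitter_px)
  xy <- pp$xy + off * pp$normal
  xy[, 1] <- pmin(pmax(xy[, 1], 0), params$image_width_px - 1)
  xy[, 2] <- pmin(pmax(xy[, 2], 0), params$image_height_px - 1)
  colnames(xy) <- c("x", "y")
  xy
}

#' Generate a synthetic two-channel punctate scene
#'
#' The channel-A cluster count is Poisson (expected count = density x
#' path length); centers are placed along the dendrite path with Gaussian
#' lateral jitter, redrawn on conflict to keep a hard-core separation of
#' `2 * min_separation_px` between A centers. A fraction `coloc_fraction` of them (rounded) receives
#' a channel-B partner offset by a uniform draw from a disc of radius
#' 1 px (a sub-resolution offset); the remaining channel-B clusters are
#' placed independently along the path, rejection-sampled to keep at
#' least `min_separation_px` from every channel-A center so the planted
#' colocalized fraction is exact. Each channel is rendered as a sum of
#' Gaussian spots (sigma = sqrt(cluster_radius^2 + psf_sigma^2)) over the
#' background, then optionally Poisson-resampled, read noise added, and
#' clipped/quantized to the integer range.
#'
#' @param params a [scene_params()].
#' @return An object of class `synthetic_scene`: list with `channel_a`,
#'   `channel_b` ([channel_image()]s), `truth_clusters_a`,
#'   `truth_clusters_b` (`(x, y)` center matrices), `truth_pairs`
#'   (two-column matrix of paired A/B indices) and `params`.
#' @examples
#' sc <- generate_punctate_pair(scene_params(seed = 7))
#' nrow(sc$truth_pairs) / max(1, nrow(sc$truth_clusters_a))
#' @export
generate_punctate_pair <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  dm <- c(params$image_height_px, params$image_width_px)
  path_um <- .point_on_path(params$dendrite_path, 0)$total *
    params$pixel_size_um
  lambda <- params$cluster_density_per_um * path_um

  n_a <- stats::rpois(1, lambda)
  ## hard-core placement: cluster count stays Poisson, but centers are
  ## redrawn to keep >= 2 * min_separation_px apart, so a B partner
  ## (within 1 px of its A) can never sit within 2 px of another A and
  ## the planted colocalized fraction stays exact
  centers_a <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n_a)) {
    cand <- .draw_centers(params, 1L)
    for (try in 1:100) {
      if (nrow(centers_a) == 0L ||
          min(sqrt((centers_a[, 1] - cand[1])^2 +
                   (centers_a[, 2] - cand[2])^2)) >=
          2 * params$min_separation_px) break
      cand <- .draw_centers(params, 1L)
    }
    centers_a <- rbind(centers_a, cand)
  }
  colnames(centers_a) <- c("x", "y")
  amps_a <- pmax(stats::rnorm(n_a, params$amplitude_mean,
                              params$amplitude_sd), 1)

  n_pair <- round(params$coloc_fraction * n_a)
  paired_a <- if (n_pair > 0) sort(sample.int(n_a, n_pair)) else integer(0)
  centers_b <- matrix(numeric(0), 0, 2)
  if (n_pair > 0) {
    r <- sqrt(stats::runif(n_pair))          # uniform over unit disc
    th <- stats::runif(n_pair, 0, 2 * pi)
    centers_b <- centers_a[paired_a, , drop = FALSE] +
      cbind(r * cos(th), r * sin(th))
  }
  n_extra <- stats::rpois(1, lambda * (1 - params$coloc_fraction))
  extras <- matrix(numeric(0), 0, 2)
  if (n_extra > 0) {
    for (k in seq_len(n_extra)) {
      for (try in 1:100) {
        cand <- .draw_centers(params, 1L)
        if (n_a == 0L || min(sqrt((centers_a[, 1] - cand[1])^2 +
                                  (centers_a[, 2] - cand[2])^2)) >=
            params$min_separation_px) {
          extras <- rbind(extras, cand)
          break
        }
      }
    }
  }
  centers_b <- rbind(centers_b, extras)
  colnames(centers_b) <- c("x", "y")
  n_b <- nrow(centers_b)
  amps_b <- pmax(stats::rnorm(n_b, params$amplitude_mean,
                              params$amplitude_sd), 1)

  sigma <- sqrt(params$cluster_radius_px^2 + params$psf_sigma_px^2)
  render <- function(centers, amps) {
    img <- .render_spots(dm, centers, amps, sigma, params$background_level)
    if (params$photon_noise)
      img <- matrix(stats::rpois(length(img), img), dm[1], dm[2])
    if (params$read_noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, params$read_noise_sd)
    channel_image(.quantize(img, params$bit_depth),
                  bit_depth = params$bit_depth,
                  pixel_size_um = params$pixel_size_um)
  }
  structure(
    list(channel_a = render(centers_a, amps_a),
         channel_b = render(centers_b, amps_b),
         truth_clusters_a = centers_a,
         truth_clusters_b = centers_b,
         truth_pairs = cbind(a = paired_a, b = seq_len(n_pair)),
         params = params),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %dx%d px, %d A-clusters, %d B-clusters, %d pairs (f = %g)\n",
              nrow(x$channel_a$pixels), ncol(x$channel_a$pixels),
              nrow(x$truth_clusters_a), nrow(x$truth_clusters_b),
              nrow(x$truth_pairs), x$params$coloc_fraction))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' The two channels go into one multi-page TIFF (page 1 = channel A) and
#' the ground truth into a CSV sidecar with columns `id`, `channel`,
#' `x`, `y`, `paired_with` (the partner's id, or `NA`).
#'
#' @param scene a [generate_punctate_pair()] result.
#' @param tiff_path output TIFF path.
#' @param truth_csv_path output CSV path; `NULL` skips the sidecar.
#' @return `tiff_path`, invisibly.
#' @export
write_scene <- function(scene, tiff_path, truth_csv_path = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  write_channel_tiff(list(scene$channel_a, scene$channel_b), tiff_path)
  if (!is.null(truth_csv_path)) {
    na <- nrow(scene$truth_clusters_a)
    nb <- nrow(scene$truth_clusters_b)
    pa <- rep(NA_integer_, na); pb <- rep(NA_integer_, nb)
    if (nrow(scene$truth_pairs) > 0) {
      pa[scene$truth_pairs[, "a"]] <- scene$truth_pairs[, "b"]
      pb[scene$truth_pairs[, "b"]] <- scene$truth_pairs[, "a"]
    }
    truth <- rbind(
      data.frame(id = seq_len(na), channel = "A",
                 x = scene$truth_clusters_a[, 1],
                 y = scene$truth_clusters_a[, 2], paired_with = pa),
      data.frame(id = seq_len(nb), channel = "B",
                 x = scene$truth_clusters_b[, 1],
                 y = scene$truth_clusters_b[, 2], paired_with = pb))
    utils::write.csv(truth, truth_csv_path, row.names = FALSE)
  }
  invisible(tiff_path)
}

#' End-to-end analysis of a synthetic scene
#'
#' Convenience pipeline mirroring the analysis applied to real
#' micrographs: background subtraction from a signal-free strip, a line
#' ROI along the dendrite path, the four colocalization coefficients,
#' Otsu cluster detection in channel A, positive-PDM particle counting
#' and the percentage of A-clusters containing colocalized signal.
#'
#' @param scene a [generate_punctate_pair()] result.
#' @param k_sd background-subtraction SD multiplier.
#' @param min_area_px minimum particle area.
#' @param line_width_px width of the analysis line ROI; `NULL` chooses
#'   a width wide enough to cover lateral jitter plus the spot extent.
#' @return List with `result` (a `coloc_result`), `percent_colocalized`
#'   (`NA` when channel A has no detected clusters), `n_clusters_a`,
#'   `n_pdm_particles`.
#' @export
analyze_scene <- function(scene, k_sd = 2, min_area_px = 4L,
                          line_width_px = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  p <- scene$params
  sigma <- sqrt(p$cluster_radius_px^2 + p$psf_sigma_px^2)
  if (is.null(line_width_px))
    line_width_px <- 2 * ceiling(3 * p$lateral_jitter_px + 3 * sigma) + 1
  ## background strip: top rows, clear of the path and spot extent
  top <- max(2, floor(min(p$dendrite_path[, 2]) -
                        6 * sigma - 4 * p$lateral_jitter_px))
  if (top < 4) stop("no signal-free strip available for background")
  bg <- roi(cbind(c(1, p$image_width_px - 2, p$image_width_px - 2, 1),
                  c(1, 1, top - 1, top - 1)), "polygon", name = "background")
  line <- roi(p$dendrite_path, "polyline", line_width_px = line_width_px)

  sub_a <- subtract_background_roi(scene$channel_a, bg, k_sd = k_sd)
  sub_b <- subtract_background_roi(scene$channel_b, bg, k_sd = k_sd)
  pairs <- extract_roi_pixels(sub_a, sub_b, line)
  mm <- coloc_manders(pairs)
  rr <- coloc_pearson(pairs)
  res <- structure(
    list(pearson_rr = rr, manders_m1 = unname(mm["m1"]),
         manders_m2 = unname(mm["m2"]), icq = coloc_icq(pairs),
         n_pixels = pairs$n, mean_a = mean(pairs$a), mean_b = mean(pairs$b),
         k_sd = k_sd, colocalized = rr >= 0.5),
    class = "coloc_result")

  clusters_a <- detect_clusters(sub_a, roi = line, min_area_px = min_area_px)
  pdm <- pdm_image(sub_a, sub_b, line)
  pdm_parts <- positive_pdm_particles(pdm, min_area_px = min_area_px)
  pct <- if (n_clusters(clusters_a) > 0)
    as.numeric(percent_colocalized_clusters(clusters_a, pdm_parts))
  else NA_real_
  list(result = res, percent_colocalized = pct,
       n_clusters_a = n_clusters(clusters_a),
       n_pdm_particles = n_clusters(pdm_parts))
}
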