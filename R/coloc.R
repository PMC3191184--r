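#' Colocalization coefficients for paired pixel intensities
#'
#' The four standard intensity-based colocalization measures, computed
#' over the same paired pixel samples (a [extract_roi_pixels()] result or
#' two raw vectors):
#'
#' * `coloc_pearson()` — Pearson's correlation Rr of the paired
#'   intensities; in `[-1, 1]`, with values from 0.5 upward conventionally
#'   read as colocalization.
#' * `coloc_manders()` — Mander's overlap coefficients: `m1` is the
#'   fraction of channel-A intensity found at pixels where B has signal
#'   (`B > 0`), `m2` the converse; both in `[0, 1]`. Intensities are
#'   assumed background-subtracted, so zero means "no signal".
#' * `coloc_icq()` — the intensity correlation quotient: the fraction of
#'   pixels whose mean-centered intensities `(A_i - mean(A))(B_i - mean(B))`
#'   multiply to a strictly positive product, minus 0.5. Ranges from
#'   -0.5 (segregated staining) through ~0 (random) to +0.5 (perfect
#'   covariation). Products exactly zero count in the denominator only.
#'
#' Degenerate inputs are signalled, never silently coerced: a constant
#' channel has no defined Rr or ICQ, and an all-zero channel no defined
#' Mander's coefficient.
#'
#' @param a a `pixel_pairs` object, or a numeric vector of channel-A
#'   intensities.
#' @param b numeric vector of channel-B intensities (ignored when `a` is
#'   a `pixel_pairs`).
#' @return `coloc_pearson()` and `coloc_icq()` return a single number;
#'   `coloc_manders()` a named vector `c(m1 = , m2 = )`.
#' @examples
#' coloc_pearson(c(0, 1, 2, 3), c(1, 3, 2, 4))
#' coloc_manders(c(10, 0, 5), c(0, 7, 3))   # m1 = 5/15, m2 = 3/10
#' coloc_icq(c(1, 2, 3, 4), c(4, 1, 2, 8))
#' @name coloc_coefficients
NULL

.as_ab <- function(a, b) {
  if (inherits(a, "pixel_pairs")) return(list(a = a$a, b = a$b))
  if (is.null(b)) stop("supply either a `pixel_pairs` or two vectors")
  if (length(a) != length(b)) stop("channel vectors must have equal length")
  list(a = as.numeric(a), b = as.numeric(b))
}

#' @rdname coloc_coefficients
#' @export
coloc_pearson <- function(a, b = NULL) {
  p <- .as_ab(a, b)
  if (stats::var(p$a) == 0 || stats::var(p$b) == 0)
    stop("Pearson's Rr is undefined for a constant channel")
  stats::cor(p$a, p$b)
}

#' @rdname coloc_coefficients
#' @export
coloc_manders <- function(a, b = NULL) {
  p <- .as_ab(a, b)
  if (any(p$a < 0) || any(p$b < 0))
    stop("Mander's coefficients require non-negative intensities")
  sa <- sum(p$a); sb <- sum(p$b)
  if (sa == 0 || sb == 0)
    stop("Mander's coefficients are undefined for an all-zero channel")
  c(m1 = sum(p$a[p$b > 0]) / sa,
    m2 = sum(p$b[p$a > 0]) / sb)
}

#' @rdname coloc_coefficients
#' @export
coloc_icq <- function(a, b = NULL) {
  p <- .as_ab(a, b)
  if (stats::var(p$a) == 0 || stats::var(p$b) == 0)
    stop("ICQ is undefined for a constant channel")
  pdm <- (p$a - mean(p$a)) * (p$b - mean(p$b))
  sum(pdm > 0) / length(pdm) - 0.5
}

#' PDM image for an ROI
#'
#' Computes the per-pixel product of the differences from the mean,
#' `PDM_i = (A_i - mean(A)) (B_i - mean(B))`, over the pixels of an ROI
#' (channel means are taken over those same ROI pixels). The positive
#' support localizes covarying signal; the returned mask keeps only the
#' "(+ x +)" pixels, i.e. pixels whose PDM is strictly positive *and*
#' where both channels exceed their means — the "(- x -)" pixels, which
#' in background-subtracted punctate images are mostly 0,0 background,
#' are excluded from the display/particle mask.
#'
#' @param image_a,image_b co-registered `channel_image`s.
#' @param roi an [roi()]; the PDM is only defined on its pixels.
#' @return An object of class `pdm_image`: list with `pdm` (matrix, `NA`
#'   outside the ROI), `positive_mask` (logical matrix), `mean_a`,
#'   `mean_b`, `n` and `dim`.
#' @export
pdm_image <- function(image_a, image_b, roi) {
  pairs <- extract_roi_pixels(image_a, image_b, roi)
  dm <- dim(image_a$pixels)
  ma <- mean(pairs$a); mb <- mean(pairs$b)
  vals <- (pairs$a - ma) * (pairs$b - mb)
  idx <- cbind(pairs$coords[, "y"] + 1L, pairs$coords[, "x"] + 1L)
  pdm <- matrix(NA_real_, dm[1], dm[2])
  pdm[idx] <- vals
  mask <- matrix(FALSE, dm[1], dm[2])
  mask[idx] <- vals > 0 & pairs$a > ma & pairs$b > mb
  structure(
    list(pdm = pdm, positive_mask = mask, mean_a = ma, mean_b = mb,
         n = pairs$n, dim = dm),
    class = "pdm_image"
  )
}

#' @export
print.pdm_image <- function(x, ...) {
  cat(sprintf("<pdm_image> n = %d ROI px, %d positive-mask px, mean A = %.2f, mean B = %.2f\n",
              x$n, sum(x$positive_mask), x$mean_a, x$mean_b))
  invisible(x)
}

#' Export a PDM image as TIFF
#'
#' Writes the signed PDM values rescaled linearly to the 16-bit range
#' (zero maps to mid-gray) and, optionally, the positive-PDM mask as a
#' binary 8-bit TIFF alongside.
#'
#' @param pdm a [pdm_image()].
#' @param path output TIFF path for the scaled PDM values.
#' @param mask_path optional output path for the binary positive mask.
#' @return `path`, invisibly.
#' @export
write_pdm_tiff <- function(pdm, path, mask_path = NULL) {
  stopifnot(inherits(pdm, "pdm_image"))
  v <- pdm$pdm
  v[is.na(v)] <- 0
  lim <- max(abs(v), 1e-12)
  scaled <- (v / lim + 1) / 2
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  if (!is.null(mask_path))
    tiff::writeTIFF(pdm$positive_mask * 1, mask_path, bits.per.sample = 8)
  invisible(path)
}

#' Full per-ROI colocalization summary
#'
#' Runs the fixed preprocessing order — 8-bit conversion (if enabled and
#' needed), then ROI background subtraction — on both channels, extracts
#' the paired pixels of the analysis ROI, and computes all four
#' coefficients on the same pixel set.
#'
#' @param image_a,image_b co-registered `channel_image`s.
#' @param analysis_roi [roi()] over which the coefficients are computed
#'   (typically a line ROI traced along a dendrite).
#' @param background_roi optional [roi()] polygon for background
#'   subtraction; `NULL` skips subtraction (e.g. for already-corrected
#'   images).
#' @param k_sd SD multiplier for background subtraction (2 for
#'   immunostaining, 0.5 for in situ hybridization).
#' @param convert_8bit convert 16-bit input to 8-bit first?
#' @return An object of class `coloc_result`: list with `pearson_rr`,
#'   `manders_m1`, `manders_m2`, `icq`, `n_pixels`, `mean_a`, `mean_b`,
#'   `k_sd` and `colocalized` (logical flag, `pearson_rr >= 0.5`, the
#'   conventional calling threshold).
#' @export
coloc_summary <- function(image_a, image_b, analysis_roi,
                          background_roi = NULL, k_sd = 2,
                          convert_8bit = TRUE) {
  prep <- function(img) {
    if (convert_8bit) img <- convert_to_8bit(img)
    if (!is.null(background_roi))
      img <- subtract_background_roi(img, background_roi, k_sd = k_sd)
    img
  }
  image_a <- prep(image_a); image_b <- prep(image_b)
  pairs <- extract_roi_pixels(image_a, image_b, analysis_roi)
  rr <- coloc_pearson(pairs)
  mm <- coloc_manders(pairs)
  structure(
    list(pearson_rr = rr,
         manders_m1 = unname(mm["m1"]), manders_m2 = unname(mm["m2"]),
         icq = coloc_icq(pairs),
         n_pixels = pairs$n, mean_a = mean(pairs$a), mean_b = mean(pairs$b),
         k_sd = if (is.null(background_roi)) NA_real_ else k_sd,
         colocalized = rr >= 0.5),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> Rr = %.3f%s, M1 = %.3f, M2 = %.3f, ICQ = %.3f (N = %d px)\n",
    x$pearson_rr, if (x$colocalized) " [colocalized]" else "",
    x$manders_m1, x$manders_m2, x$icq, x$n_pixels))
  invisible(x)
}

#' @export
as.data.frame.coloc_result <- function(x, ...) {
  data.frame(pearson_rr = x$pearson_rr, manders_m1 = x$manders_m1,
             manders_m2 = x$manders_m2, icq = x$icq, n_pixels = x$n_pixels,
             mean_a = x$mean_a, mean_b = x$mean_b, k_sd = x$k_sd,
             colocalized = x$colocalized)
}
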