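#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the observations (typically one value per cell) with
#' replacement using [boot::boot()] and takes empirical quantiles of the
#' resampled means as interval bounds. Percentile bounds always lie
#' within the observed value range. Deterministic for a fixed seed.
#'
#' @param values numeric vector of observations (>= 2).
#' @param level confidence level in (0, 1); default 0.95.
#' @param n_reps number of bootstrap resamples.
#' @param seed RNG seed (logged in the result); `NULL` leaves the RNG
#'   state alone.
#' @return An object of class `bootstrap_ci`: list with `estimate` (the
#'   observed mean), `lower`, `upper`, `level`, `n_reps`, `n_obs`, `seed`.
#' @examples
#' bootstrap_ci(c(0.6, 0.7, 0.8), n_reps = 1000, seed = 1)
#' @export
bootstrap_ci <- function(values, level = 0.95, n_reps = 10000L, seed = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  if (anyNA(values)) stop("`values` must not contain NA")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  if (n_reps < 1L) stop("`n_reps` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  bt <- boot::boot(values, function(d, i) mean(d[i]), R = n_reps)
  alpha <- (1 - level) / 2
  qs <- stats::quantile(bt$t[, 1], c(alpha, 1 - alpha), names = FALSE)
  structure(
    list(estimate = mean(values), lower = qs[1], upper = qs[2],
         level = level, n_reps = as.integer(n_reps),
         n_obs = length(values), seed = seed),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> %.4g (%.0f%% CI %.4g-%.4g; n = %d, %d resamples)\n",
              x$estimate, 100 * x$level, x$lower, x$upper, x$n_obs, x$n_reps))
  invisible(x)
}

#' Mean and standard error over independent cultures
#'
#' Per-cell (or per-dendrite) measurements are first averaged within each
#' independent culture; the reported mean is the mean of culture means and
#' the standard error is `SD(culture means) / sqrt(#cultures)` (sample,
#' n-1, SD). With a single culture the SE is undefined and reported as
#' `NA` — shown as "(N/A)" in tabular output, as is conventional.
#'
#' @param values numeric measurements.
#' @param groups culture identifier per value (same length).
#' @return List with `mean`, `se`, `n_groups` and the per-culture
#'   `group_means`.
#' @examples
#' per_culture_se(c(70, 75, 74), c("c1", "c2", "c3"))
#' @export
per_culture_se <- function(values, groups) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no observations")
  if (length(values) != length(groups))
    stop("`values` and `groups` must have equal length")
  gm <- tapply(values, groups, mean)
  k <- length(gm)
  list(mean = mean(gm),
       se = if (k >= 2L) stats::sd(gm) / sqrt(k) else NA_real_,
       n_groups = k,
       group_means = gm)
}

#' Densitometry normalization of a developmental expression profile
#'
#' Normalizes western-blot band intensities of a target protein to a
#' loading control (ratio per timepoint) and expresses each ratio as a
#' percentage of the ratio at a reference timepoint (by convention the
#' earliest), which therefore reads exactly 100. Invariant to rescaling
#' all control intensities by a common positive factor.
#'
#' @param band_intensity target-protein band areas, one per timepoint
#'   (> 0).
#' @param control_intensity loading-control band areas (> 0, same
#'   length).
#' @param timepoints optional labels (e.g. `c("P2", "P5", ...)`).
#' @param reference_index index of the reference timepoint (default 1,
#'   the earliest).
#' @return data.frame with columns `timepoint`, `ratio` and
#'   `percent_of_reference`.
#' @examples
#' densitometry_normalize(c(10, 5), c(2, 2))   # 100, 50
#' @export
densitometry_normalize <- function(band_intensity, control_intensity,
                                   timepoints = NULL, reference_index = 1L) {
  band_intensity <- as.numeric(band_intensity)
  control_intensity <- as.numeric(control_intensity)
  if (length(band_intensity) != length(control_intensity))
    stop("band and control profiles must have equal length")
  if (any(control_intensity <= 0))
    stop("control intensities must be strictly positive")
  if (any(band_intensity <= 0))
    stop("band intensities must be strictly positive")
  if (reference_index < 1L || reference_index > length(band_intensity))
    stop("`reference_index` out of range")
  if (is.null(timepoints))
    timepoints <- paste0("t", seq_along(band_intensity))
  ratio <- band_intensity / control_intensity
  data.frame(timepoint = timepoints, ratio = ratio,
             percent_of_reference = 100 * ratio / ratio[reference_index])
}

#' Coefficient table with bootstrap confidence intervals
#'
#' Aggregates per-dendrite colocalization results to per-cell means (at
#' least two dendrites per cell are typically analyzed), then reports for
#' each coefficient the mean over cells with a percentile-bootstrap
#' confidence interval — the layout used to summarize colocalization
#' across a population of neurons.
#'
#' @param df data.frame with one row per analyzed ROI (dendrite);
#'   see [as.data.frame.coloc_result()].
#' @param cell_col name of the column identifying the cell.
#' @param coef_cols coefficient columns to summarize.
#' @param level,n_reps,seed passed to [bootstrap_ci()] (the seed is
#'   advanced by one per coefficient so intervals are independent).
#' @return data.frame with one row per coefficient: `coefficient`,
#'   `estimate`, `lower`, `upper`, `n_cells`.
#' @export
summarize_coefficients <- function(df, cell_col = "cell_id",
                                   coef_cols = c("pearson_rr", "manders_m1",
                                                 "manders_m2", "icq"),
                                   level = 0.95, n_reps = 10000L, seed = 1L) {
  stopifnot(is.data.frame(df), cell_col %in% names(df),
            all(coef_cols %in% names(df)))
  out <- lapply(seq_along(coef_cols), function(j) {
    per_cell <- tapply(df[[coef_cols[j]]], df[[cell_col]], mean)
    ci <- bootstrap_ci(per_cell, level = level, n_reps = n_reps,
                       seed = if (is.null(seed)) NULL else seed + j - 1L)
    data.frame(coefficient = coef_cols[j], estimate = ci$estimate,
               lower = ci$lower, upper = ci$upper,
               n_cells = length(per_cell))
  })
  do.call(rbind, out)
}
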