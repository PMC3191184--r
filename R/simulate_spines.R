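#' Generate a spine-scoring scenario with planted ground truth
#'
#' Builds a synthetic traced dendritic segment — a straight shaft with
#' `n_spines` spine perimeters attached on alternating sides — and plants
#' cluster centroids realizing `cluster_plan` exactly. Non-stubby spines
#' get a total-perimeter polygon enclosing a smaller head polygon at the
#' tip; stubby spines (a fraction `stubby_fraction`, rounded) get a total
#' perimeter only. Traced segments in tissue typically span 30--70 um and
#' carry 30--80 spines; the generator accepts any `n_spines >= 1`.
#'
#' Planted categories follow the scoring rules of
#' [classify_cluster_location()]: `shaft` centroids go on the shaft
#' midline (outside every spine polygon), `head` inside a head polygon,
#' `base_neck` inside a total perimeter below the head, `all` inside a
#' stubby spine's perimeter.
#'
#' @param n_spines number of spines (>= 1).
#' @param segment_length_um dendritic segment length in micrometres.
#' @param stubby_fraction fraction of spines without a distinct head.
#' @param cluster_plan named counts over `c("shaft", "head", "base_neck",
#'   "all")`; missing names mean 0. Head/base--neck clusters require at
#'   least one non-stubby spine; `all` clusters at least one stubby
#'   spine.
#' @param seed RNG seed.
#' @param pixel_size_um micrometres per pixel of the drawing frame.
#' @return An object of class `spine_scenario`: list with `geometry`
#'   (a [spine_geometry()]), `truth_cluster_centroids` (`(x, y)` matrix)
#'   and `truth_categories` (character vector).
#' @examples
#' sc <- generate_spine_scenario(40, 50, cluster_plan = c(shaft = 20,
#'   head = 2, base_neck = 7, all = 1), seed = 3)
#' table(sc$truth_categories)
#' @export
generate_spine_scenario <- function(n_spines, segment_length_um,
                                    stubby_fraction = 0.2,
                                    cluster_plan = c(shaft = 0, head = 0,
                                                     base_neck = 0, all = 0),
                                    seed = 1L, pixel_size_um = 0.11) {
  if (n_spines < 1) stop("`n_spines` must be >= 1")
  if (segment_length_um <= 0) stop("`segment_length_um` must be > 0")
  if (stubby_fraction < 0 || stubby_fraction > 1)
    stop("`stubby_fraction` must lie in [0, 1]")
  plan <- c(shaft = 0, head = 0, base_neck = 0, all = 0)
  if (!all(names(cluster_plan) %in% names(plan)) || any(cluster_plan < 0))
    stop("`cluster_plan` must give non-negative counts for shaft/head/base_neck/all")
  plan[names(cluster_plan)] <- cluster_plan
  set.seed(seed)

  L_px <- segment_length_um / pixel_size_um
  shaft_y <- 30                     # shaft midline (px)
  shaft_hw <- 5                     # shaft half-width: ~1.1 um diameter
  spine_hw <- 2                     # spine half-width (px)
  len_full <- 12; len_stubby <- 6   # protrusion lengths (px)

  n_stubby <- round(stubby_fraction * n_spines)
  if (plan[["head"]] + plan[["base_neck"]] > 0 && n_stubby == n_spines)
    stop("cluster_plan requests head/base-neck clusters but all spines are stubby")
  if (plan[["all"]] > 0 && n_stubby == 0)
    stop("cluster_plan requests 'all' clusters but no spine is stubby")
  stubby <- rep(FALSE, n_spines)
  if (n_stubby > 0) stubby[sample.int(n_spines, n_stubby)] <- TRUE

  xs <- seq(5, L_px - 5, length.out = n_spines)
  side <- rep(c(-1, 1), length.out = n_spines)   # -1 = up (smaller y)
  spines <- vector("list", n_spines)
  for (j in seq_len(n_spines)) {
    xj <- xs[j]; s <- side[j]
    yb <- shaft_y + s * shaft_hw                  # attachment at shaft edge
    len <- if (stubby[j]) len_stubby else len_full
    yt <- yb + s * len                            # spine tip
    total <- cbind(c(xj - spine_hw, xj + spine_hw, xj + spine_hw, xj - spine_hw),
                   c(yb, yb, yt, yt))
    head <- NULL
    if (!stubby[j]) {
      head <- cbind(c(xj - spine_hw + 0.4, xj + spine_hw - 0.4,
                      xj + spine_hw - 0.4, xj - spine_hw + 0.4),
                    c(yb + s * (len - 4.5), yb + s * (len - 4.5),
                      yb + s * (len - 0.5), yb + s * (len - 0.5)))
    }
    spines[[j]] <- list(total = total, head = head)
  }
  geometry <- suppressWarnings(
    spine_geometry(segment_length_um, spines, pixel_size_um))

  cents <- NULL; cats <- character(0)
  add <- function(xy, cat) {
    cents <<- rbind(cents, xy)
    cats <<- c(cats, cat)
  }
  if (plan[["shaft"]] > 0) {
    x <- stats::runif(plan[["shaft"]], 2, L_px - 2)
    y <- shaft_y + stats::runif(plan[["shaft"]], -2, 2)
    for (i in seq_along(x)) add(c(x[i], y[i]), "shaft")
  }
  pick <- function(ids, k) ids[1 + (seq_len(k) - 1) %% length(ids)]
  full_ids <- which(!stubby); stub_ids <- which(stubby)
  if (plan[["head"]] > 0) {
    for (j in pick(full_ids, plan[["head"]])) {
      add(colMeans(spines[[j]]$head), "head")
    }
  }
  if (plan[["base_neck"]] > 0) {
    for (j in pick(full_ids, plan[["base_neck"]])) {
      ## neck midpoint: inside total, clear of the head polygon
      add(c(xs[j], shaft_y + side[j] * (shaft_hw + 2.5)), "base_neck")
    }
  }
  if (plan[["all"]] > 0) {
    for (j in pick(stub_ids, plan[["all"]])) {
      add(colMeans(spines[[j]]$total), "all")
    }
  }
  if (!is.null(cents)) colnames(cents) <- c("x", "y")
  structure(
    list(geometry = geometry,
         truth_cluster_centroids = cents,
         truth_categories = cats),
    class = "spine_scenario"
  )
}

#' @export
print.spine_scenario <- function(x, ...) {
  cat(sprintf("<spine_scenario> %d spines, %.1f um, %d planted clusters\n",
              length(x$geometry$spines), x$geometry$segment_length_um,
              length(x$truth_categories)))
  if (length(x$truth_categories))
    print(table(x$truth_categories))
  invisible(x)
}
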