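#' Traced dendritic-spine geometry
#'
#' Holds the manually traced geometry of one dendritic segment: its
#' length, and for every spine a total-perimeter polygon plus, for spines
#' with a distinct head, a head-perimeter polygon lying inside it.
#' Stubby spines carry a total perimeter only. The tracing is done on the
#' membrane channel alone, so scoring cluster positions against it is
#' structurally blind to the cluster channel.
#'
#' @param segment_length_um length of the dendritic segment in
#'   micrometres (> 0). Typical traced segments span 30--70 um and carry
#'   30--80 spines; counts far outside that range trigger a warning, not
#'   an error.
#' @param spines list of spines, each a list with `total` (an [roi()]
#'   polygon or vertex matrix) and optional `head` (polygon inside
#'   `total`, or `NULL` for stubby spines).
#' @param pixel_size_um micrometres per pixel of the coordinate system
#'   the polygons are drawn in.
#' @return An object of class `spine_geometry`.
#' @export
spine_geometry <- function(segment_length_um, spines, pixel_size_um = 0.11) {
  if (!is.numeric(segment_length_um) || segment_length_um <= 0)
    stop("`segment_length_um` must be > 0")
  spines <- lapply(spines, function(sp) {
    total <- if (inherits(sp$total, "roi")) sp$total else
      roi(sp$total, "polygon")
    head <- NULL
    if (!is.null(sp$head)) {
      head <- if (inherits(sp$head, "roi")) sp$head else
        roi(sp$head, "polygon")
      if (!all(point_in_polygon(head$vertices[, 1], head$vertices[, 2],
                                total)))
        stop("a head perimeter must lie inside its total perimeter")
    }
    list(total = total, head = head)
  })
  n <- length(spines)
  if (n > 0 && (n < 30 || n > 80))
    warning(sprintf("%d spines is outside the typical traced range (30-80)", n))
  structure(
    list(segment_length_um = segment_length_um, spines = spines,
         pixel_size_um = pixel_size_um),
    class = "spine_geometry"
  )
}

#' @export
print.spine_geometry <- function(x, ...) {
  stubby <- sum(vapply(x$spines, function(s) is.null(s$head), logical(1)))
  cat(sprintf("<spine_geometry> %.1f um segment, %d spines (%d stubby)\n",
              x$segment_length_um, length(x$spines), stubby))
  invisible(x)
}

#' Classify cluster positions against spine perimeters
#'
#' Scores each cluster centroid as:
#' * `"shaft"` — outside every spine's total perimeter;
#' * `"head"` — inside a spine's total perimeter and inside its head
#'   perimeter;
#' * `"base_neck"` — inside a total perimeter but outside the head
#'   perimeter;
#' * `"all"` — inside a stubby spine (no traced head), where head and
#'   base/neck cannot be distinguished.
#'
#' Point-in-polygon is boundary inclusive. A centroid falling inside two
#' overlapping total perimeters is ambiguous: a warning is raised and the
#' spine whose polygon centroid is nearest wins.
#'
#' @param centroids two-column `(x, y)` matrix (or length-2 vector) of
#'   cluster centroid coordinates, in the geometry's pixel frame.
#' @param geometry a [spine_geometry()].
#' @return Character vector of categories, one per centroid, with
#'   attribute `spine_index` (`NA` for shaft clusters).
#' @export
classify_cluster_location <- function(centroids, geometry) {
  stopifnot(inherits(geometry, "spine_geometry"))
  if (is.null(dim(centroids))) centroids <- matrix(centroids, ncol = 2)
  centroids <- as.matrix(centroids)
  nsp <- length(geometry$spines)
  n <- nrow(centroids)
  inside <- matrix(FALSE, n, max(nsp, 1L))
  for (j in seq_len(nsp)) {
    inside[, j] <- point_in_polygon(centroids[, 1], centroids[, 2],
                                    geometry$spines[[j]]$total)
  }
  cats <- character(n)
  spine_idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hits <- which(inside[i, seq_len(nsp)])
    if (length(hits) == 0L) {
      cats[i] <- "shaft"
      next
    }
    if (length(hits) > 1L) {
      warning("cluster centroid falls inside overlapping spine perimeters; ",
              "assigning the nearest")
      d <- vapply(hits, function(j) {
        pc <- colMeans(geometry$spines[[j]]$total$vertices)
        sqrt(sum((centroids[i, ] - pc)^2))
      }, numeric(1))
      hits <- hits[which.min(d)]
    }
    sp <- geometry$spines[[hits]]
    spine_idx[i] <- hits
    cats[i] <- if (is.null(sp$head)) {
      "all"
    } else if (point_in_polygon(centroids[i, 1], centroids[i, 2], sp$head)) {
      "head"
    } else {
      "base_neck"
    }
  }
  attr(cats, "spine_index") <- spine_idx
  cats
}

#' Summarize cluster distribution over a dendritic segment
#'
#' Computes the per-segment quantities used to describe how a punctate
#' protein distributes between dendritic shaft and spines:
#' cluster density per micrometre of dendrite, the percentage of spines
#' containing at least one cluster, the shaft/spine split of clusters
#' and, within spine clusters, the head / base--neck / stubby-("all")
#' split (fractions over spine clusters, summing to 1).
#'
#' @param clusters a `cluster_set` (its centroids are used) or a
#'   two-column `(x, y)` centroid matrix; may be empty.
#' @param geometry a [spine_geometry()].
#' @return An object of class `spine_localization_summary`: list with
#'   `n_clusters`, `cluster_density_per_um`, `pct_spines_with_cluster`,
#'   `fraction_shaft`, `fraction_spine`, `fraction_head`,
#'   `fraction_base_neck`, `fraction_all` and the per-cluster
#'   `categories`.
#' @export
summarize_spine_localization <- function(clusters, geometry) {
  stopifnot(inherits(geometry, "spine_geometry"))
  centroids <- if (inherits(clusters, "cluster_set")) {
    do.call(rbind, lapply(clusters$particles, `[[`, "centroid"))
  } else if (is.null(clusters) || NROW(clusters) == 0L) {
    NULL
  } else {
    as.matrix(clusters)
  }
  n <- if (is.null(centroids)) 0L else nrow(centroids)
  nsp <- length(geometry$spines)
  if (n > 0L) {
    cats <- classify_cluster_location(centroids, geometry)
    spine_idx <- attr(cats, "spine_index")
  } else {
    cats <- character(0)
    spine_idx <- integer(0)
  }
  n_shaft <- sum(cats == "shaft")
  n_spine <- n - n_shaft
  split3 <- c(head = sum(cats == "head"),
              base_neck = sum(cats == "base_neck"),
              all = sum(cats == "all"))
  structure(
    list(
      n_clusters = n,
      n_spines = nsp,
      cluster_density_per_um = n / geometry$segment_length_um,
      pct_spines_with_cluster =
        if (nsp == 0L) NA_real_
        else 100 * length(unique(spine_idx[!is.na(spine_idx)])) / nsp,
      fraction_shaft = if (n > 0L) n_shaft / n else NA_real_,
      fraction_spine = if (n > 0L) n_spine / n else NA_real_,
      fraction_head = if (n_spine > 0L) split3[["head"]] / n_spine else NA_real_,
      fraction_base_neck =
        if (n_spine > 0L) split3[["base_neck"]] / n_spine else NA_real_,
      fraction_all = if (n_spine > 0L) split3[["all"]] / n_spine else NA_real_,
      categories = cats),
    class = "spine_localization_summary"
  )
}

#' @export
print.spine_localization_summary <- function(x, ...) {
  cat(sprintf("<spine_localization_summary> %d clusters over %d spines\n",
              x$n_clusters, x$n_spines))
  cat(sprintf("  density: %.3f clusters/um; spines with cluster: %s%%\n",
              x$cluster_density_per_um,
              format(round(x$pct_spines_with_cluster, 1))))
  cat(sprintf("  shaft %.1f%% / spine %.1f%%; within spines: head %s, base/neck %s, all %s\n",
              100 * x$fraction_shaft, 100 * x$fraction_spine,
              format(round(100 * x$fraction_head, 1)),
              format(round(100 * x$fraction_base_neck, 1)),
              format(round(100 * x$fraction_all, 1))))
  invisible(x)
}

#' @export
as.data.frame.spine_localization_summary <- function(x, ...) {
  data.frame(n_clusters = x$n_clusters, n_spines = x$n_spines,
             cluster_density_per_um = x$cluster_density_per_um,
             pct_spines_with_cluster = x$pct_spines_with_cluster,
             fraction_shaft = x$fraction_shaft,
             fraction_spine = x$fraction_spine,
             fraction_head = x$fraction_head,
             fraction_base_neck = x$fraction_base_neck,
             fraction_all = x$fraction_all)
}

#' Write / read spine geometry as an ROI file
#'
#' Serializes a [spine_geometry()] to the package's plain-text ROI schema
#' (see [write_roi_file()]): records named `spineNN_total` and
#' `spineNN_head`, with `segment_length_um` and `pixel_size_um` stored as
#' metadata comments.
#'
#' @param geometry a [spine_geometry()].
#' @param path file path.
#' @return `write_spine_geometry()` returns `path` invisibly;
#'   `read_spine_geometry()` returns a `spine_geometry`.
#' @export
write_spine_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "spine_geometry"))
  rois <- list()
  for (j in seq_along(geometry$spines)) {
    sp <- geometry$spines[[j]]
    rois[[sprintf("spine%02d_total", j)]] <- sp$total
    if (!is.null(sp$head))
      rois[[sprintf("spine%02d_head", j)]] <- sp$head
  }
  write_roi_file(rois, path,
                 metadata = list(segment_length_um = geometry$segment_length_um,
                                 pixel_size_um = geometry$pixel_size_um))
}

#' @rdname write_spine_geometry
#' @export
read_spine_geometry <- function(path) {
  rois <- read_roi_file(path)
  meta <- attr(rois, "metadata")
  ids <- unique(sub("_(total|head)$", "", names(rois)))
  spines <- lapply(ids, function(id) {
    list(total = rois[[paste0(id, "_total")]],
         head = rois[[paste0(id, "_head")]])
  })
  suppressWarnings(spine_geometry(
    segment_length_um = as.numeric(meta[["segment_length_um"]]),
    spines = spines,
    pixel_size_um = as.numeric(meta[["pixel_size_um"]])))
}
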