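#' Region of interest (polygon or polyline)
#'
#' Analysis regions are either simple polygons (background regions, traced
#' spine perimeters) or polylines with a width (line ROIs traced along a
#' dendrite). Vertices are 0-based pixel coordinates (`x` = column,
#' `y` = row); see [channel_image()].
#'
#' @param vertices two-column numeric matrix (or data.frame) of `(x, y)`
#'   vertices, in order. Polygons are closed implicitly (do not repeat the
#'   first vertex).
#' @param kind `"polygon"` or `"polyline"`.
#' @param line_width_px width of a polyline ROI in pixels (>= 1); ignored
#'   for polygons.
#' @param name optional label used when writing ROI files.
#' @return An object of class `roi`.
#' @examples
#' bg <- roi(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), "polygon", name = "bg")
#' line <- roi(cbind(c(2, 40), c(5, 5)), "polyline", line_width_px = 3)
#' @export
roi <- function(vertices, kind = c("polygon", "polyline"),
                line_width_px = 1, name = NULL) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || !is.numeric(vertices) || anyNA(vertices))
    stop("`vertices` must be a numeric two-column (x, y) matrix")
  colnames(vertices) <- c("x", "y")
  if (kind == "polygon" && nrow(vertices) < 3L)
    stop("a polygon needs at least 3 vertices")
  if (kind == "polyline" && nrow(vertices) < 2L)
    stop("a polyline needs at least 2 vertices")
  if (line_width_px < 1)
    stop("`line_width_px` must be >= 1")
  structure(
    list(kind = kind, vertices = vertices,
         line_width_px = as.numeric(line_width_px), name = name),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s%s, %d vertices%s\n", x$kind,
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$vertices),
              if (x$kind == "polyline")
                sprintf(", width %g px", x$line_width_px) else ""))
  invisible(x)
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd (ray casting) rule; points lying on a polygon edge count as
#' inside. This is the containment rule used everywhere in the package,
#' both for rasterizing polygon ROIs and for scoring cluster centroids
#' against spine perimeters.
#'
#' @param px,py coordinates of the query points (vectors of equal length).
#' @param polygon an `roi` of kind polygon, or a two-column vertex matrix.
#' @param tol distance below which a point is treated as on the boundary.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, polygon, tol = 1e-9) {
  v <- if (inherits(polygon, "roi")) polygon$vertices else as.matrix(polygon)
  n <- nrow(v)
  xs <- v[, 1]; ys <- v[, 2]
  inside <- logical(length(px))
  onedge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    cross <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross)
    onedge <- onedge | (.dist_point_segment(px, py, x1, y1, x2, y2) <= tol)
    j <- i
  }
  inside | onedge
}

## Euclidean distance from points (px, py) to segment (x1,y1)-(x2,y2)
.dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

#' Pixels covered by an ROI
#'
#' Rasterizes an ROI onto an image grid. For polygons, a pixel belongs to
#' the ROI when its center falls inside the polygon (boundary inclusive);
#' for polylines, when its center lies within `line_width_px / 2` of the
#' path. Pixels are returned in row-major order (stable).
#'
#' @param x an `roi`.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return Integer matrix with columns `row`, `col` (1-based matrix
#'   indices) and attributes `x`, `y` (the 0-based pixel coordinates).
#' @export
roi_pixels <- function(x, dim) {
  stopifnot(inherits(x, "roi"), length(dim) == 2L)
  nr <- dim[1]; nc <- dim[2]
  v <- x$vertices
  pad <- if (x$kind == "polyline") x$line_width_px / 2 + 1 else 1
  cmin <- max(1L, floor(min(v[, 1]) - pad) + 1L)
  cmax <- min(nc, ceiling(max(v[, 1]) + pad) + 1L)
  rmin <- max(1L, floor(min(v[, 2]) - pad) + 1L)
  rmax <- min(nr, ceiling(max(v[, 2]) + pad) + 1L)
  if (cmin > cmax || rmin > rmax)
    return(.pixel_table(integer(0), integer(0)))
  ## row-major order: iterate rows outer
  grid <- expand.grid(col = cmin:cmax, row = rmin:rmax)
  px <- grid$col - 1; py <- grid$row - 1
  keep <- if (x$kind == "polygon") {
    point_in_polygon(px, py, v)
  } else {
    d <- rep(Inf, length(px))
    for (i in seq_len(nrow(v) - 1L)) {
      d <- pmin(d, .dist_point_segment(px, py, v[i, 1], v[i, 2],
                                       v[i + 1L, 1], v[i + 1L, 2]))
    }
    d <= x$line_width_px / 2 + 1e-9
  }
  .pixel_table(grid$row[keep], grid$col[keep])
}

.pixel_table <- function(row, col) {
  out <- cbind(row = as.integer(row), col = as.integer(col))
  attr(out, "x") <- out[, "col"] - 1L
  attr(out, "y") <- out[, "row"] - 1L
  out
}

#' Read and write ROI files
#'
#' ROIs are stored in a plain-text, tab-separated schema: comment lines
#' starting with `#` may hold `key: value` metadata; every other line is
#' `name <TAB> kind <TAB> width <TAB> x1,y1;x2,y2;...`.
#'
#' @param path file path.
#' @return `read_roi_file()` returns a named list of [roi] objects with a
#'   `metadata` attribute (named character vector, possibly empty).
#' @examples
#' f <- tempfile(fileext = ".roi.txt")
#' write_roi_file(list(bg = roi(cbind(c(0, 5, 5), c(0, 0, 5)), "polygon")), f)
#' read_roi_file(f)
#' @export
read_roi_file <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- character(0)
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.+)$", ml))[[1]]
    if (length(m) == 3L) meta[trimws(m[2])] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rois <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L)
      stop("malformed ROI record: ", ln)
    pts <- do.call(rbind, lapply(strsplit(f[4], ";", fixed = TRUE)[[1]],
      function(p) as.numeric(strsplit(p, ",", fixed = TRUE)[[1]])))
    rois[[f[1]]] <- roi(pts, kind = f[2],
                        line_width_px = as.numeric(f[3]), name = f[1])
  }
  attr(rois, "metadata") <- meta
  rois
}

#' @param rois named list of [roi] objects.
#' @param metadata optional named list/vector written as `# key: value`
#'   comment lines.
#' @rdname read_roi_file
#' @export
write_roi_file <- function(rois, path, metadata = NULL) {
  if (inherits(rois, "roi")) rois <- list(rois)
  nm <- names(rois)
  if (is.null(nm)) nm <- vapply(rois, function(r)
    if (is.null(r$name)) "" else r$name, character(1))
  nm[!nzchar(nm)] <- paste0("roi", which(!nzchar(nm)))
  lines <- "# icaloc ROI file v1"
  for (k in names(metadata))
    lines <- c(lines, sprintf("# %s: %s", k, format(metadata[[k]])))
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    coords <- paste(apply(r$vertices, 1L, function(p)
      paste0(format(p[1], trim = TRUE), ",", format(p[2], trim = TRUE))),
      collapse = ";")
    lines <- c(lines, paste(nm[i], r$kind,
                            format(r$line_width_px, trim = TRUE),
                            coords, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
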