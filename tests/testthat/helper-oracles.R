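# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals.

ref_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

ref_manders <- function(a, b) {
  m1num <- 0; m2num <- 0
  for (i in seq_along(a)) {
    if (b[i] > 0) m1num <- m1num + a[i]
    if (a[i] > 0) m2num <- m2num + b[i]
  }
  c(m1 = m1num / sum(a), m2 = m2num / sum(b))
}

ref_icq <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  npos <- 0
  for (i in seq_along(a)) {
    if ((a[i] - ma) * (b[i] - mb) > 0) npos <- npos + 1
  }
  npos / length(a) - 0.5
}

# population-covariance identity oracle for the PDM sum
ref_pdm_sum <- function(a, b) {
  n <- length(a)
  n * (sum((a - mean(a)) * (b - mean(b))) / n)
}

# recursive-style flood fill labeling (explicit queue), 8- or 4-connected
ref_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (cc in 1:nc) for (rr in 1:nr) {
    if (!mask[rr, cc] || lab[rr, cc] != 0L) next
    cur <- cur + 1L
    queue <- list(c(rr, cc))
    lab[rr, cc] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        if (connectivity == 4 && abs(dr) + abs(dc) != 1) next
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# brute-force scan: pixel centers within width/2 of any polyline segment
ref_polyline_pixels <- function(verts, width, dim) {
  hits <- NULL
  for (r in 1:dim[1]) for (cc in 1:dim[2]) {
    px <- cc - 1; py <- r - 1
    dmin <- Inf
    for (i in 1:(nrow(verts) - 1)) {
      x1 <- verts[i, 1]; y1 <- verts[i, 2]
      x2 <- verts[i + 1, 1]; y2 <- verts[i + 1, 2]
      dx <- x2 - x1; dy <- y2 - y1
      t <- ((px - x1) * dx + (py - y1) * dy) / (dx^2 + dy^2)
      t <- min(max(t, 0), 1)
      dmin <- min(dmin, sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2))
    }
    if (dmin <= width / 2 + 1e-9) hits <- rbind(hits, c(r, cc))
  }
  hits
}

# random non-constant paired intensity vectors for fuzzing
random_pairs <- function(n, maxval = 255) {
  repeat {
    a <- sample(0:maxval, n, replace = TRUE)
    b <- sample(0:maxval, n, replace = TRUE)
    if (length(unique(a)) > 1 && length(unique(b)) > 1 &&
        sum(a) > 0 && sum(b) > 0)
      return(list(a = as.numeric(a), b = as.numeric(b)))
  }
}

# sparse, well-separated high-SNR scene configuration used for
# parameter-recovery checks (ground truth unambiguous at the analysis
# resolution)
sparse_scene_params <- function(coloc_fraction, seed) {
  scene_params(image_height_px = 64, image_width_px = 448,
               cluster_density_per_um = 0.12, min_separation_px = 5,
               amplitude_mean = 180, amplitude_sd = 20, read_noise_sd = 1,
               background_level = 5, coloc_fraction = coloc_fraction,
               seed = seed)
}
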