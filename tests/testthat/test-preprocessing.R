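test_that("16-bit to 8-bit conversion follows the linear min-max map", {
  p <- matrix(c(100, 612, 1124, 500), 2, 2)
  img <- channel_image(p, bit_depth = 16L)
  out <- convert_to_8bit(img)
  expect_equal(out$bit_depth, 8L)
  # closed-form oracle: round-half-up of 255 * (v - min) / (max - min)
  expect_equal(out$pixels[1, 1], 0)
  expect_equal(out$pixels[1, 2], floor(255 * (1124 - 100) / 1024 + 0.5))
  expect_equal(out$pixels[2, 1], floor(255 * (612 - 100) / 1024 + 0.5))
  expect_equal(out$pixels[2, 1], 128)

  full <- channel_image(matrix(c(0, 65535), 1, 2), bit_depth = 16L)
  expect_equal(convert_to_8bit(full)$pixels[1, 2], 255)

  const <- channel_image(matrix(7, 4, 4), bit_depth = 16L)
  expect_true(all(convert_to_8bit(const)$pixels == 0))

  # 8-bit input passes through untouched
  i8 <- channel_image(matrix(0:3, 2, 2), bit_depth = 8L)
  expect_identical(convert_to_8bit(i8), i8)
})

test_that("8-bit conversion preserves pixel intensity ordering", {
  set.seed(5)
  p <- matrix(sample(0:65535, 200, replace = TRUE), 10, 20)
  out <- convert_to_8bit(channel_image(p, bit_depth = 16L))
  # ordering never inverts under the monotone rescale
  o <- order(p)
  expect_true(all(diff(out$pixels[o]) >= 0))
})

test_that("background subtraction uses mean + k * sample SD of the ROI", {
  p <- matrix(0, 10, 10)
  p[1, 1] <- 8; p[1, 2] <- 10; p[1, 3] <- 12   # ROI pixels
  p[5, 5] <- 20
  img <- channel_image(p, bit_depth = 8L)
  # polygon covering exactly pixels (0,0), (1,0), (2,0)
  bg <- roi(cbind(c(-0.4, 2.4, 2.4, -0.4), c(-0.4, -0.4, 0.4, 0.4)), "polygon")
  out <- subtract_background_roi(img, bg, k_sd = 2)
  expect_equal(out$pixels[5, 5], 20 - (10 + 2 * 2))  # sample SD of {8,10,12} = 2
  expect_equal(out$pixels[1, 1], 0)                  # clamped at zero

  # all-equal ROI: T = mean, pixel at the mean goes to 0
  p2 <- matrix(10, 6, 6)
  img2 <- channel_image(p2, bit_depth = 8L)
  bg2 <- roi(cbind(c(0, 3, 3, 0), c(0, 0, 3, 3)), "polygon")
  out2 <- subtract_background_roi(img2, bg2, k_sd = 2)
  expect_true(all(out2$pixels == 0))
})

test_that("background subtraction is monotone in k_sd", {
  set.seed(9)
  p <- matrix(sample(0:255, 400, TRUE), 20, 20)
  img <- channel_image(p, bit_depth = 8L)
  bg <- roi(cbind(c(0, 6, 6, 0), c(0, 0, 6, 6)), "polygon")
  prev <- subtract_background_roi(img, bg, k_sd = 0)$pixels
  for (k in c(0.5, 1, 2, 4)) {
    cur <- subtract_background_roi(img, bg, k_sd = k)$pixels
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("background ROI errors: off-image and sub-2-pixel regions", {
  img <- channel_image(matrix(1, 10, 10), bit_depth = 8L)
  off <- roi(cbind(c(50, 60, 60), c(50, 50, 60)), "polygon")
  expect_error(subtract_background_roi(img, off, 2), "at least 2 pixels")
  line <- roi(cbind(c(0, 5), c(0, 5)), "polyline")
  expect_error(subtract_background_roi(img, line, 2), "polygon")
})

test_that("ROI pixel extraction pairs identical positions in both channels", {
  set.seed(2)
  a <- channel_image(matrix(sample(0:255, 400, TRUE), 20, 20))
  b <- channel_image(matrix(sample(0:255, 400, TRUE), 20, 20))
  sq <- roi(cbind(c(3, 5, 5, 3), c(4, 4, 6, 6)), "polygon")
  pp <- extract_roi_pixels(a, b, sq)
  expect_s3_class(pp, "pixel_pairs")
  expect_equal(pp$n, 9)  # axis-aligned 3x3 square, boundary inclusive
  idx <- cbind(pp$coords[, "y"] + 1, pp$coords[, "x"] + 1)
  expect_equal(pp$a, as.numeric(a$pixels[idx]))
  expect_equal(pp$b, as.numeric(b$pixels[idx]))
  # row-major stable ordering
  expect_true(all(diff(order(pp$coords[, "y"], pp$coords[, "x"])) == 1))

  expect_error(extract_roi_pixels(a, b,
    roi(cbind(c(100, 110, 110), c(100, 100, 110)), "polygon")),
    "does not intersect")
})

test_that("polyline rasterization matches a brute-force distance scan", {
  dimg <- c(15, 18)
  set.seed(3)
  a <- channel_image(matrix(sample(0:255, prod(dimg), TRUE), dimg[1], dimg[2]))
  for (case in list(
    list(v = cbind(c(2, 11), c(5, 5)), w = 1),     # horizontal, 10 px long
    list(v = cbind(c(2, 12), c(2, 9)), w = 3),      # oblique
    list(v = cbind(c(1, 8, 14), c(10, 3, 10)), w = 2))) {
    r <- roi(case$v, "polyline", line_width_px = case$w)
    got <- roi_pixels(r, dimg)
    want <- ref_polyline_pixels(case$v, case$w, dimg)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE][, 1:2],
                 want[order(want[, 1], want[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
  # the horizontal width-1 line covers exactly its 10 path pixels
  h <- roi_pixels(roi(cbind(c(2, 11), c(5, 5)), "polyline", 1), dimg)
  expect_equal(nrow(h), 10)
})

test_that("intensity profile samples the path in order", {
  p <- matrix(0, 12, 30)
  img <- channel_image(p)
  path <- roi(cbind(c(2, 25), c(6, 6)), "polyline")
  prof <- intensity_profile(img, path)
  expect_true(all(prof == 0))
  expect_equal(length(prof), 24)

  p[7, 12] <- 200  # single bright pixel at (x=11, y=6), on the path
  img2 <- channel_image(p)
  prof2 <- intensity_profile(img2, path)
  expect_equal(sum(prof2 > 0), 1)
  expect_equal(which(prof2 > 0) - 1, 11 - 2)  # arc-length position

  expect_error(intensity_profile(img, roi(cbind(c(1, 1.5), c(1, 1)),
                                          "polyline")), "shorter")
})

test_that("profiles of a fully colocalized noiseless scene peak together", {
  sp <- scene_params(coloc_fraction = 1, read_noise_sd = 0,
                     photon_noise = FALSE, background_level = 0,
                     lateral_jitter_px = 0, seed = 21)
  sc <- generate_punctate_pair(sp)
  path <- roi(sp$dendrite_path, "polyline")
  pa <- intensity_profile(sc$channel_a, path)
  pb <- intensity_profile(sc$channel_b, path)
  # local maxima of A lie within 1 sample of a high B value and vice versa
  peaks <- function(v) which(diff(sign(diff(v))) == -2) + 1
  for (i in peaks(pa)) {
    if (pa[i] < 50) next
    expect_gt(max(pb[max(1, i - 1):min(length(pb), i + 1)]), 25)
  }
})
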