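test_that("coefficient endpoint identities hold", {
  a <- c(10, 10, 10, 200, 200, 200, 200)  # mean not attained by any pixel
  expect_equal(coloc_pearson(a, a), 1)
  expect_equal(coloc_pearson(a, 255 - a), -1)
  expect_equal(coloc_icq(a, a), 0.5)
  expect_equal(coloc_icq(a, 255 - a), -0.5)
  m <- coloc_manders(a, 255 - a)          # both strictly positive
  expect_equal(unname(m), c(1, 1))
})

test_that("hand-computed examples evaluate exactly", {
  expect_equal(coloc_pearson(c(0, 1, 2, 3), c(1, 3, 2, 4)),
               ref_pearson(c(0, 1, 2, 3), c(1, 3, 2, 4)))
  m <- coloc_manders(c(10, 0, 5), c(0, 7, 3))
  expect_equal(unname(m["m1"]), 5 / 15)
  expect_equal(unname(m["m2"]), 3 / 10)
  # enumerate the four signed products: means 2.5 and 3.75
  # (1-2.5)(4-3.75) < 0, (2-2.5)(1-3.75) > 0, (3-2.5)(2-3.75) < 0,
  # (4-2.5)(8-3.75) > 0  ->  2/4 - 0.5 = 0
  expect_equal(coloc_icq(c(1, 2, 3, 4), c(4, 1, 2, 8)), 0)
  # disjoint supports
  m0 <- coloc_manders(c(5, 0, 3, 0), c(0, 2, 0, 9))
  expect_equal(unname(m0), c(0, 0))
})

test_that("degenerate channels are signalled, not silently coerced", {
  expect_error(coloc_pearson(rep(4, 5), 1:5), "constant")
  expect_error(coloc_icq(1:5, rep(4, 5)), "constant")
  expect_error(coloc_manders(rep(0, 5), 1:5), "all-zero")
  expect_error(coloc_manders(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("coefficients match brute-force oracles on random inputs", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(2:64, 1)
    p <- random_pairs(n)
    expect_equal(coloc_pearson(p$a, p$b), ref_pearson(p$a, p$b),
                 tolerance = 1e-12)
    expect_equal(coloc_icq(p$a, p$b), ref_icq(p$a, p$b), tolerance = 1e-12)
    expect_equal(unname(coloc_manders(p$a, p$b)),
                 unname(ref_manders(p$a, p$b)), tolerance = 1e-12)
  }
})

test_that("range, symmetry and affine-invariance properties hold", {
  set.seed(77)
  for (i in 1:100) {
    p <- random_pairs(sample(4:64, 1))
    rr <- coloc_pearson(p$a, p$b)
    ic <- coloc_icq(p$a, p$b)
    mm <- coloc_manders(p$a, p$b)
    expect_true(rr >= -1 && rr <= 1)
    expect_true(ic >= -0.5 && ic <= 0.5)
    expect_true(all(mm >= 0 & mm <= 1))
    # symmetry
    expect_equal(rr, coloc_pearson(p$b, p$a))
    expect_equal(ic, coloc_icq(p$b, p$a))
    expect_equal(unname(mm["m1"]), unname(coloc_manders(p$b, p$a)["m2"]))
    # strictly positive affine rescaling of one channel
    expect_equal(rr, coloc_pearson(3.7 * p$a + 11, p$b))
    expect_equal(ic, coloc_icq(p$a, 0.4 * p$b + 2))
  }
})

test_that("PDM image: values, mask rule and covariance identity", {
  set.seed(31)
  a <- channel_image(matrix(sample(0:255, 144, TRUE), 12, 12))
  b <- channel_image(matrix(sample(0:255, 144, TRUE), 12, 12))
  sq <- roi(cbind(c(2, 9, 9, 2), c(2, 2, 9, 9)), "polygon")
  pdm <- pdm_image(a, b, sq)
  pp <- extract_roi_pixels(a, b, sq)
  # sum of PDM values equals N * population covariance
  expect_equal(sum(pdm$pdm, na.rm = TRUE), ref_pdm_sum(pp$a, pp$b))
  # mask subset of strictly positive PDM and both-above-mean pixels
  in_roi <- !is.na(pdm$pdm)
  expect_true(all(pdm$pdm[pdm$positive_mask] > 0))
  expect_true(all(a$pixels[pdm$positive_mask] > pdm$mean_a))
  expect_true(all(b$pixels[pdm$positive_mask] > pdm$mean_b))
  expect_true(all(!pdm$positive_mask[!in_roi]))

  # identical channels: mask = pixels above the mean
  pdm2 <- pdm_image(a, a, sq)
  above <- in_roi & a$pixels > pdm2$mean_a
  expect_equal(pdm2$positive_mask, above)
})

test_that("mean PDM of independent noise shrinks toward zero", {
  set.seed(55)
  means <- sapply(1:20, function(i) {
    a <- channel_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
    b <- channel_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
    sq <- roi(cbind(c(0, 63, 63, 0), c(0, 0, 63, 63)), "polygon")
    mean(pdm_image(a, b, sq)$pdm, na.rm = TRUE)
  })
  # E|cov| ~ sd_a*sd_b/sqrt(N) ~ 5400/64 = 85; mean over 20 fields smaller
  expect_lt(abs(mean(means)), 40)
})

test_that("coloc_summary runs the fixed preprocessing order and flags Rr >= 0.5", {
  sc <- generate_punctate_pair(scene_params(coloc_fraction = 1,
    amplitude_mean = 200, amplitude_sd = 20, read_noise_sd = 1,
    background_level = 5, seed = 4))
  p <- sc$params
  bg <- roi(cbind(c(1, 100, 100, 1), c(1, 1, 20, 20)), "polygon")
  line <- roi(p$dendrite_path, "polyline", line_width_px = 15)
  res <- coloc_summary(sc$channel_a, sc$channel_b, line, bg, k_sd = 2)
  expect_s3_class(res, "coloc_result")
  expect_gt(res$pearson_rr, 0.9)
  expect_gt(res$icq, 0.3)
  expect_true(res$colocalized)
  expect_equal(res$k_sd, 2)
  df <- as.data.frame(res)
  expect_equal(df$n_pixels, res$n_pixels)

  # uncorrelated channels are not flagged
  sc0 <- generate_punctate_pair(scene_params(coloc_fraction = 0, seed = 4))
  res0 <- coloc_summary(sc0$channel_a, sc0$channel_b, line, bg, k_sd = 2)
  expect_false(res0$colocalized)
})
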