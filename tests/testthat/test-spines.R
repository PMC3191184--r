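test_that("point classification follows the perimeter rules", {
  total <- cbind(c(10, 14, 14, 10), c(5, 5, 17, 17))
  head <- cbind(c(10.5, 13.5, 13.5, 10.5), c(12.5, 12.5, 16.5, 16.5))
  stub <- cbind(c(30, 34, 34, 30), c(5, 5, 11, 11))
  geom <- suppressWarnings(spine_geometry(20, list(
    list(total = total, head = head),
    list(total = stub, head = NULL))))
  expect_equal(unclass(classify_cluster_location(c(2, 2), geom))[1], "shaft")
  expect_equal(unclass(classify_cluster_location(c(12, 14), geom))[1], "head")
  expect_equal(unclass(classify_cluster_location(c(12, 8), geom))[1], "base_neck")
  expect_equal(unclass(classify_cluster_location(c(32, 8), geom))[1], "all")
  # boundary inclusive: a point on the total perimeter is inside the spine
  expect_equal(unclass(classify_cluster_location(c(10, 10), geom))[1],
               "base_neck")
  # classification is invariant to ordering
  pts <- rbind(c(2, 2), c(12, 14), c(32, 8))
  c1 <- classify_cluster_location(pts, geom)
  c2 <- classify_cluster_location(pts[3:1, ], geom)
  expect_equal(unclass(c1)[1:3], rev(unclass(c2)[1:3]))
})

test_that("overlapping perimeters are signalled and tie-broken by distance", {
  g <- suppressWarnings(spine_geometry(10, list(
    list(total = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), head = NULL),
    list(total = cbind(c(8, 20, 20, 8), c(0, 0, 10, 10)), head = NULL))))
  expect_warning(cat1 <- classify_cluster_location(c(9, 5), g), "overlapping")
  expect_equal(unclass(cat1)[1], "all")
  expect_equal(attr(suppressWarnings(
    classify_cluster_location(c(8.2, 5), g)), "spine_index"), 1L)
})

test_that("summary arithmetic: density, spine occupancy, fractions", {
  sc <- generate_spine_scenario(20, 20, stubby_fraction = 0,
                                cluster_plan = c(shaft = 10), seed = 2)
  s <- summarize_spine_localization(sc$truth_cluster_centroids, sc$geometry)
  expect_equal(s$cluster_density_per_um, 0.5)
  expect_equal(s$fraction_shaft, 1)
  expect_equal(s$pct_spines_with_cluster, 0)

  sc2 <- generate_spine_scenario(20, 40, stubby_fraction = 0.25,
    cluster_plan = c(shaft = 20, head = 2, base_neck = 7, all = 1), seed = 5)
  s2 <- summarize_spine_localization(sc2$truth_cluster_centroids, sc2$geometry)
  expect_equal(s2$n_clusters, 30)
  expect_equal(s2$fraction_shaft, 20 / 30)
  expect_equal(s2$fraction_spine, 10 / 30)
  expect_equal(s2$fraction_head, 2 / 10)
  expect_equal(s2$fraction_base_neck, 7 / 10)
  expect_equal(s2$fraction_all, 1 / 10)
  expect_equal(s2$fraction_head + s2$fraction_base_neck + s2$fraction_all, 1)
  # spine clusters cycle through spines: head on full spines 1-2,
  # base/neck on full spines 1-7, "all" on stubby spine 1 -> 8 of 20
  expect_equal(s2$pct_spines_with_cluster, 100 * 8 / 20)
})

test_that("generated scenarios are recovered with 100% agreement", {
  for (seed in 1:5) {
    sc <- generate_spine_scenario(40, 50, stubby_fraction = 0.2,
      cluster_plan = c(shaft = 15, head = 3, base_neck = 6, all = 2),
      seed = seed)
    got <- classify_cluster_location(sc$truth_cluster_centroids, sc$geometry)
    expect_equal(unclass(got)[seq_along(sc$truth_categories)],
                 sc$truth_categories)
  }
})

test_that("scenario generator validates its cluster plan", {
  expect_error(generate_spine_scenario(5, 10, stubby_fraction = 1,
    cluster_plan = c(head = 3)), "all spines are stubby")
  expect_error(generate_spine_scenario(5, 10, stubby_fraction = 0,
    cluster_plan = c(all = 1)), "no spine is stubby")
  expect_error(generate_spine_scenario(0, 10), "n_spines")
  expect_error(generate_spine_scenario(5, 10,
    cluster_plan = c(nucleus = 2)), "cluster_plan")
  # head clusters with zero stubby spines land inside head polygons
  sc <- generate_spine_scenario(10, 12, stubby_fraction = 0,
                                cluster_plan = c(head = 3), seed = 9)
  expect_equal(sc$truth_categories, rep("head", 3))
  got <- classify_cluster_location(sc$truth_cluster_centroids, sc$geometry)
  expect_equal(unclass(got)[1:3], rep("head", 3))
})

test_that("tissue-scale geometry passes the plausibility bounds silently", {
  expect_silent(sc <- generate_spine_scenario(40, 50, stubby_fraction = 0.2,
    cluster_plan = c(shaft = 5), seed = 1))
  expect_equal(length(sc$geometry$spines), 40)
  expect_equal(sc$geometry$segment_length_um, 50)
  # outside the traced range -> warning from the geometry constructor
  expect_warning(spine_geometry(50, sc$geometry$spines[1:5]), "typical")
})

test_that("spine geometry round-trips through the ROI file schema", {
  sc <- generate_spine_scenario(35, 45, stubby_fraction = 0.2,
    cluster_plan = c(shaft = 3, head = 1, base_neck = 1, all = 1), seed = 7)
  f <- tempfile(fileext = ".roi.txt")
  write_spine_geometry(sc$geometry, f)
  back <- read_spine_geometry(f)
  expect_equal(back$segment_length_um, 45)
  expect_equal(length(back$spines), 35)
  got <- classify_cluster_location(sc$truth_cluster_centroids, back)
  expect_equal(unclass(got)[seq_along(sc$truth_categories)],
               sc$truth_categories)
})
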