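lens_dice <- function(r, d) {
  # analytic Dice of two equal circles with center distance d
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  100 * 2 * lens / (2 * pi * r^2)
}

test_that("dice matches identity, disjointness and the analytic lens value", {
  a <- region_circle(r = 20, n = 1024L)
  expect_equal(dice(a, a), 100)
  far <- region_circle(cx = 200, r = 20, n = 1024L)
  expect_equal(dice(a, far), 0)
  b <- region_circle(cx = 105, r = 20, n = 1024L)
  expect_equal(dice(a, b), lens_dice(20, 5), tolerance = 0.2 / 84)
  expect_equal(dice(a, b), dice(b, a))
})

test_that("dice rejects degenerate zero-area regions", {
  flat <- slice_annotation(0L, "ED", list(
    lv_endo = contour_polygon(cbind(c(0, 1, 2), c(0, 0, 0)), "lv_endo")))
  expect_error(dice(build_region(flat, "lv_endo"), region_circle()), "degenerate")
})

test_that("dice decreases monotonically as concentric radii diverge", {
  base <- region_circle(r = 20, n = 512L)
  ratios <- seq(1, 0.5, by = -0.1)
  d <- vapply(ratios, function(f) dice(base, region_circle(r = 20 * f, n = 512L)),
              numeric(1))
  expect_true(all(diff(d) < 0))
  # concentric circles have closed-form Dice 2f^2/(1+f^2)
  expect_equal(d, 100 * 2 * ratios^2 / (1 + ratios^2), tolerance = 1e-3)
})

test_that("hausdorff matches translated-circle and nested-square geometry", {
  a <- region_circle(r = 20, n = 1024L)
  expect_equal(hausdorff(a, a), 0)
  b <- region_circle(cx = 105, r = 20, n = 1024L)
  expect_equal(hausdorff(a, b), 5, tolerance = 0.1 / 5)
  expect_equal(hausdorff(a, b), hausdorff(b, a))

  sq <- function(s) build_region(slice_annotation(0L, "ED", list(
    lv_endo = contour_polygon(cbind(c(0, s, s, 0), c(0, 0, s, s)), "lv_endo"))),
    "lv_endo")
  expect_equal(hausdorff(sq(1), sq(2), max_step_px = 0.05), sqrt(2), tolerance = 0.1)
})

test_that("hausdorff agrees with an independent brute-force oracle", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (k in 1:5) {
    a <- region_circle(cx = runif(1, 80, 120), cy = runif(1, 80, 120),
                       r = runif(1, 10, 25), n = 128L)
    b <- region_circle(cx = runif(1, 80, 120), cy = runif(1, 80, 120),
                       r = runif(1, 10, 25), n = 128L)
    step <- 0.25 * min(a$pixel_spacing_mm)
    pa <- do.call(rbind, lapply(a$rings, cmrqc:::resample_ring, max_step = step))
    pb <- do.call(rbind, lapply(b$rings, cmrqc:::resample_ring, max_step = step))
    expect_equal(hausdorff(a, b), pracma::hausdorff_dist(pa, pb), tolerance = 1e-10)
  }
})

test_that("hausdorff dominates the directed mean surface distance", {
  set.seed(31)
  for (k in 1:5) {
    a <- region_circle(r = runif(1, 10, 25), n = 128L)
    b <- region_circle(cx = runif(1, 90, 110), r = runif(1, 10, 25), n = 128L)
    pa <- do.call(rbind, lapply(a$rings, cmrqc:::resample_ring, max_step = 0.25))
    pb <- do.call(rbind, lapply(b$rings, cmrqc:::resample_ring, max_step = 0.25))
    d2 <- outer(pa[, 1L], pb[, 1L], "-")^2 + outer(pa[, 2L], pb[, 2L], "-")^2
    mean_surf <- mean(sqrt(apply(d2, 1L, min)))
    expect_gte(hausdorff(a, b) + 1e-12, mean_surf)
  }
})

test_that("polygon-clipping dice agrees with the rasterization oracle", {
  set.seed(41)
  for (k in 1:10) {
    a <- region_circle(cx = runif(1, 90, 110), cy = runif(1, 90, 110),
                       r = runif(1, 12, 25), n = 256L)
    b <- region_circle(cx = runif(1, 90, 110), cy = runif(1, 90, 110),
                       r = runif(1, 12, 25), n = 256L)
    expect_equal(dice(a, b), cmrqc:::rasterized_dice(a, b, grid = 512L), tolerance = 0.5 / 50)
  }
})

test_that("slice volume difference follows the area difference", {
  meta <- list(pixel_spacing_mm = c(1, 1), slice_thickness_mm = 7, slice_gap_mm = 0)
  sa <- slice_annotation(0L, "ED", list(lv_endo = circle_poly(r = 20, n = 1024L)))
  sb <- slice_annotation(0L, "ED", list(lv_endo = circle_poly(r = 19.5, n = 1024L)))
  expect_equal(slice_volume_difference(sa, sa, "lv_endo", meta),
               c(signed_ml = 0, abs_ml = 0))
  vd <- slice_volume_difference(sa, sb, "lv_endo", meta)
  expect_equal(unname(vd["abs_ml"]), pi * (400 - 380.25) * 7 / 1000, tolerance = 0.01)
  expect_lt(vd["signed_ml"], 0)

  empty <- slice_annotation(0L, "ED", list())
  vd2 <- slice_volume_difference(empty, sa, "lv_endo", meta)
  expect_equal(unname(vd2["signed_ml"]), pi * 400 * 7 / 1000, tolerance = 0.01)
  expect_equal(vd2["abs_ml"], vd2["signed_ml"], ignore_attr = TRUE)
})

test_that("compare_slice applies the segmentation-decision conventions", {
  meta <- list(pixel_spacing_mm = c(1, 1), slice_thickness_mm = 7, slice_gap_mm = 0)
  empty <- slice_annotation(0L, "ED", list())
  seg <- slice_annotation(0L, "ED", list(lv_endo = circle_poly()))

  neither <- compare_slice(empty, empty, "lv_endo", meta)
  expect_equal(neither$decision, "neither")
  expect_equal(neither$dice_pct, 100)
  expect_true(is.na(neither$hausdorff_mm))

  only_b <- compare_slice(empty, seg, "lv_endo", meta)
  expect_equal(only_b$decision, "only_b")
  expect_equal(only_b$dice_pct, 0)
  expect_true(is.na(only_b$hausdorff_mm))

  only_a <- compare_slice(seg, empty, "lv_endo", meta)
  expect_equal(only_a$decision, "only_a")
  expect_equal(only_a$dice_pct, 0)

  both <- compare_slice(seg, seg, "lv_endo", meta)
  expect_equal(both$decision, "both")
  expect_equal(both$dice_pct, 100)
  expect_equal(both$hausdorff_mm, 0)

  misaligned <- slice_annotation(1L, "ED", list())
  expect_error(compare_slice(seg, misaligned, "lv_endo", meta), "aligned")
})

test_that("anisotropic spacing is honoured in physical-coordinate metrics", {
  # same pixel-space circles; with row spacing 2 the region is an ellipse
  sa <- slice_annotation(0L, "ED", list(lv_endo = circle_poly(r = 20, n = 1024L)))
  ra <- build_region(sa, "lv_endo", spacing = c(2, 1))
  expect_equal(ra$area_mm2, 2 * pi * 400, tolerance = 1e-4)
  # translation along y moves 2 mm per pixel
  sb <- slice_annotation(0L, "ED", list(
    lv_endo = contour_polygon(circle_ring(r = 20, n = 1024L) + cbind(0, rep(2, 1024L)),
                              "lv_endo")))
  rb <- build_region(sb, "lv_endo", spacing = c(2, 1))
  expect_equal(hausdorff(ra, rb), 4, tolerance = 0.02)
})
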