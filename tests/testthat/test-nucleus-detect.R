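test_that("well-separated nuclei are each detected with sub-micron centroids", {
  truth <- fx_grid_truth(n_side = 5, spacing = 25, area = 55, hem = 0.6)
  img <- render_scene(truth, 125, 125, noise_sd = 0)
  det <- detect_nuclei(rgb_to_od(img))
  expect_equal(nrow(det), 25)
  md <- match_truth(det, truth, radius_um = 3)
  expect_true(all(!is.na(md$truth_id)))
  ti <- match(md$truth_id, truth$id)
  err <- sqrt((md$x_um - truth$x_um[ti])^2 + (md$y_um - truth$y_um[ti])^2)
  expect_true(all(err < 1))
})

test_that("nuclei below the minimum area are filtered out", {
  tiny <- fx_grid_truth(n_side = 1, spacing = 30, area = 5, hem = 0.8)
  img <- render_scene(tiny, 30, 30, noise_sd = 0)
  det <- detect_nuclei(rgb_to_od(img))
  expect_equal(nrow(det), 0)
})

test_that("touching nucleus pairs are split by the watershed", {
  r <- sqrt(55 / pi)                       # ~4.18 um
  gap <- 0.8 * 2 * r                       # centres at 0.8 x diameter
  tr <- fx_grid_truth(n_side = 1, spacing = 60, area = 55, hem = 0.6)
  tr2 <- tr; tr2$id <- 2L
  tr2$x_um <- tr$x_um + gap
  tr2$polygon <- lapply(tr2$polygon, function(p) { p[, 1] <- p[, 1] + gap; p })
  pair <- dplyr::bind_rows(tr, tr2)
  img <- render_scene(pair, 60, 60, noise_sd = 0)
  det <- detect_nuclei(rgb_to_od(img))
  expect_equal(nrow(det), 2)
})

test_that("detection has F1 >= 0.90 against ground truth on noisy scenes", {
  s <- fx_scene()
  f <- detection_f1(s$detections, s$truth, radius_um = 3)
  expect_gte(f$f1, 0.90)
  expect_lt(f$mean_centroid_error_um, 1)
})

test_that("all emitted areas honour the configured area window", {
  s <- fx_scene()
  p <- detection_params()
  expect_true(all(s$detections$area_um2 >= p$min_area_um2))
  expect_true(all(s$detections$area_um2 <= p$max_area_um2))
})

test_that("detection count is stable under a 90-degree scene rotation", {
  s <- fx_scene()
  img <- s$image
  rot <- aperm(img, c(2, 1, 3))[, dim(img)[1]:1, , drop = FALSE]
  attr(rot, "pixel_size_um") <- attr(img, "pixel_size_um")
  det_rot <- detect_nuclei(rgb_to_od(rot))
  expect_lte(abs(nrow(det_rot) - nrow(s$detections)), 1)
})

test_that("missing pixel-size metadata is an error and empty input is empty", {
  img <- array(255, dim = c(20, 20, 3))
  od <- rgb_to_od(img)   # no pixel size attribute
  expect_error(detect_nuclei(od), "pixel-size")
  attr(img, "pixel_size_um") <- 0.23
  expect_equal(nrow(detect_nuclei(rgb_to_od(img))), 0)
})

test_that("cell expansion dilates isolated nuclei by the expansion distance", {
  tr <- fx_grid_truth(n_side = 1, spacing = 60, area = 55, hem = 0.6)
  img <- render_scene(tr, 60, 60, noise_sd = 0)
  det <- detect_nuclei(rgb_to_od(img))
  det <- expand_cells(det, 5)
  r_det <- sqrt(det$area_um2[1] / pi)
  expected <- pi * (r_det + 5)^2   # detected disc dilated by 5 um
  expect_equal(det$cell_area_um2[1], expected, tolerance = 0.05)
})

test_that("the cell boundary between close nuclei is the equidistant line", {
  tr <- fx_grid_truth(n_side = 1, spacing = 40, area = 20, hem = 0.6)
  gap <- 2 * sqrt(20 / pi) + 4   # boundaries 4 um apart
  tr2 <- tr; tr2$id <- 2L; tr2$x_um <- tr$x_um + gap
  tr2$polygon <- lapply(tr2$polygon, function(p) { p[, 1] <- p[, 1] + gap; p })
  pair <- dplyr::bind_rows(tr, tr2)
  img <- render_scene(pair, 80, 60, noise_sd = 0)
  det <- detect_nuclei(rgb_to_od(img))
  det <- expand_cells(det, 5)
  expect_equal(nrow(det), 2)
  midline <- mean(det$x_um)
  left <- which.min(det$x_um); right <- which.max(det$x_um)
  expect_lte(max(det$cell_polygon[[left]][, 1]), midline + 0.5)
  expect_gte(min(det$cell_polygon[[right]][, 1]), midline - 0.5)
  # cells are equal-sized by symmetry
  expect_equal(det$cell_area_um2[left], det$cell_area_um2[right],
               tolerance = 0.1)
})

test_that("zero expansion returns the nucleus outline unchanged", {
  s <- fx_scene()
  det <- expand_cells(s$detections[1:5, ], 0)
  expect_identical(det$cell_polygon, det$polygon)
})

test_that("shape and stain features match closed forms on clean nuclei", {
  truth <- fx_grid_truth(n_side = 2, spacing = 40, area = 55,
                         dab = 0.5, hem = 0.03)
  img <- render_scene(truth, 80, 80, noise_sd = 0)
  od <- rgb_to_od(img)
  conc <- deconvolve(od, stain_profile())
  det <- detect_nuclei(od)
  det <- measure_features(det, od, conc)
  expect_equal(nrow(det), 4)
  # rasterized circles: circularity within 5% of 1
  expect_true(all(det$circularity > 0.95))
  expect_true(all(det$eccentricity < 0.35))
  # uniform DAB concentration is recovered by the nucleus mean within 2%
  expect_true(all(abs(det$nucleus_dab_od_mean - 0.5) < 0.01))

  # zero-DAB nuclei measure ~0
  t0 <- fx_grid_truth(n_side = 1, spacing = 40, area = 55, hem = 0.6)
  img0 <- render_scene(t0, 40, 40, noise_sd = 0)
  od0 <- rgb_to_od(img0)
  d0 <- measure_features(detect_nuclei(od0), od0,
                         deconvolve(od0, stain_profile()))
  expect_lt(abs(d0$nucleus_dab_od_mean[1]), 1e-6)
})

test_that("degenerate polygons are flagged invalid", {
  s <- fx_scene()
  det <- s$detections[1:2, ]
  det$polygon[[1]] <- cbind(x = c(1, 1, 1), y = c(1, 1, 1))
  out <- measure_features(det, s$od, s$conc)
  expect_false(out$valid[1])
  expect_true(is.na(out$nucleus_dab_od_mean[1]))
  expect_true(out$valid[2])
})

test_that("feature smoothing is a convex combination with local weights", {
  # single detection: smoothed equals raw at every radius
  one <- tibble::tibble(id = 1L, x_um = 10, y_um = 10, f = 2.5)
  sm1 <- smooth_features(one, features = "f")
  expect_equal(sm1$f_sm25, 2.5)
  expect_equal(sm1$f_sm100, 2.5)

  # constant feature stays constant
  many <- tibble::tibble(id = 1:50, x_um = runif(50, 0, 100),
                         y_um = runif(50, 0, 100), f = 1.7)
  smc <- smooth_features(many, features = "f")
  expect_true(all(abs(smc$f_sm50 - 1.7) < 1e-12))

  # two clusters 500 um apart do not bleed into each other at 50 um
  cl <- tibble::tibble(
    id = 1:40,
    x_um = c(runif(20, 0, 30), runif(20, 500, 530)),
    y_um = runif(40, 0, 30),
    f = rep(c(1, 0), each = 20))
  smx <- smooth_features(cl, features = "f", radii_um = 50)
  expect_true(all(abs(smx$f_sm50[1:20] - 1) < 0.01))
  expect_true(all(abs(smx$f_sm50[21:40] - 0) < 0.01))

  # convexity on real features
  s <- fx_scene()
  det <- s$detections
  expect_true(all(det$area_um2_sm50 >= min(det$area_um2) - 1e-9))
  expect_true(all(det$area_um2_sm50 <= max(det$area_um2) + 1e-9))
})
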