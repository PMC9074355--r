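test_that("an empty scene renders to a uniform white image with empty truth", {
  cfg <- scene_config(width_um = 30, height_um = 30,
                      n_tumour = 0, n_stroma = 0, n_lymph = 0,
                      noise_sd = 0, seed = 1)
  s <- simulate_scene(cfg)
  expect_equal(nrow(s$nuclei), 0)
  expect_true(all(s$image == 255))
})

test_that("ground-truth positive fraction matches the configured field", {
  cfg <- scene_config(width_um = 440, height_um = 440,
                      n_tumour = 1000, n_stroma = 0, n_lymph = 0,
                      base_positivity = 0.3, hotspots = list(), seed = 21)
  nuc <- simulate_nuclei(cfg, polygons = FALSE)
  phat <- mean(nuc$ki67_positive)
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("hotspot tumour nuclei are positive more often than the rest", {
  cfg <- scene_config(width_um = 300, height_um = 300,
                      n_tumour = 450, n_stroma = 0, n_lymph = 0,
                      base_positivity = 0.1,
                      hotspots = list(list(center = c(150, 150), radius = 60,
                                           peak_positivity = 0.9)),
                      seed = 4)
  nuc <- simulate_nuclei(cfg, polygons = FALSE)
  d <- sqrt((nuc$x_um - 150)^2 + (nuc$y_um - 150)^2)
  expect_gt(mean(nuc$ki67_positive[d < 60]), mean(nuc$ki67_positive[d >= 60]))
})

test_that("identical config and seed reproduce the scene bit for bit", {
  cfg <- scene_config(width_um = 90, height_um = 90,
                      n_tumour = 25, n_stroma = 8, n_lymph = 5,
                      noise_sd = 2, seed = 11)
  a <- simulate_scene(cfg)
  b <- simulate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$nuclei, b$nuclei)
})

test_that("an infeasible packing raises an explicit error", {
  cfg <- scene_config(width_um = 40, height_um = 40,
                      n_tumour = 400, n_stroma = 0, n_lymph = 0, seed = 1)
  expect_error(simulate_nuclei(cfg), "hard-core")
})

test_that("scene and hotspot configs are validated", {
  expect_error(scene_config(base_positivity = 1.2), "base_positivity")
  expect_error(scene_config(
    base_positivity = 0.5,
    hotspots = list(list(center = c(1, 1), radius = 10,
                         peak_positivity = 0.3))),
    "peak_positivity")
  expect_error(scene_config(width_um = -5))
})

test_that("rendering follows the transmission model exactly", {
  # zero concentration everywhere: white point in every channel
  blank <- render_scene(ki67flow:::empty_truth(), 10, 10, noise_sd = 0)
  expect_true(all(blank == 255))

  # a single uniform DAB-only nucleus: channel OD equals conc * stain vector
  p <- stain_profile()
  tr <- fx_grid_truth(n_side = 1, spacing = 30, dab = 1, hem = 0)
  tr$hematoxylin <- 0
  img <- render_scene(tr, 30, 30, profile = p, noise_sd = 0)
  centre <- round(c(15, 15) / 0.23)
  od_px <- -log10(img[centre[1], centre[2], ] / 255)
  expect_equal(as.numeric(od_px), as.numeric(p$dab), tolerance = 1e-10)

  # doubling the concentration doubles the OD per channel
  tr2 <- tr; tr2$dab <- 0.5
  img2 <- render_scene(tr2, 30, 30, profile = p, noise_sd = 0)
  od2 <- -log10(img2[centre[1], centre[2], ] / 255)
  expect_equal(as.numeric(od_px), 2 * as.numeric(od2), tolerance = 1e-10)
})

test_that("cohort simulation respects degenerate censoring", {
  co <- simulate_cohort(cohort_config(n_patients = 50,
                                      admin_censor_years = 0, seed = 2))
  expect_true(all(co$event == "censored"))
  expect_true(all(co$time_years == 0))
})

test_that("a null Ki-67 hazard coefficient yields a Cox CI covering 1", {
  cfg <- cohort_config(n_patients = 2000,
                       hazard_bc = list(rate = 0.04, beta = 0),
                       seed = 14)
  co <- simulate_cohort(cfg)
  fit <- tidy(cox_ph(co, "true_ki67"))
  expect_true(fit$conf_low < 1 && fit$conf_high > 1)
})

test_that("a positive Ki-67 hazard coefficient is detected by Gray's test", {
  co <- simulate_cohort(cohort_config(n_patients = 2000, seed = 15))
  med <- stats::median(co$true_ki67)
  co$grp <- ifelse(co$true_ki67 > med, "High", "Low")
  g <- gray_test(co, "grp")
  expect_lt(g$p_value, 0.001)
})

test_that("cohort structure depends on true Ki-67 as configured", {
  co <- simulate_cohort(cohort_config(n_patients = 1500, seed = 6))
  expect_setequal(levels(co$event), c("censored", "bc_death", "other_death"))
  # grade and mitoses increase with true Ki-67
  expect_gt(mean(co$true_ki67[co$grade == 3]),
            mean(co$true_ki67[co$grade == 1]))
  expect_gt(stats::cor(co$true_ki67, co$mitoses_10hpf), 0.3)
})
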