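# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# A small mixed scene with moderate uniform positivity, rendered with noise,
# plus its OD, deconvolution and fully measured detections.
fx_scene <- function() fixture("scene", function() {
  cfg <- scene_config(width_um = 150, height_um = 150,
                      n_tumour = 100, n_stroma = 30, n_lymph = 20,
                      base_positivity = 0.3, hotspots = list(),
                      noise_sd = 2, seed = 3)
  s <- simulate_scene(cfg)
  od <- rgb_to_od(s$image)
  conc <- deconvolve(od, stain_profile())
  det <- detect_nuclei(od)
  det <- expand_cells(det, 5)
  det <- measure_features(det, od, conc)
  det <- smooth_features(det)
  list(config = cfg, truth = s$nuclei, image = s$image, od = od,
       conc = conc, detections = det)
})

# A noise-free scene of well-separated identical round nuclei on a grid.
fx_grid_truth <- function(n_side = 5, spacing = 25, area = 55,
                          dab = 0, hem = 0.6) {
  k <- n_side^2
  r <- sqrt(area / pi)
  centres <- expand.grid(x = spacing * (seq_len(n_side) - 0.5),
                         y = spacing * (seq_len(n_side) - 0.5))
  tibble::tibble(
    id = seq_len(k), class = "tumour",
    x_um = centres$x, y_um = centres$y,
    r_major_um = r, r_minor_um = r, theta = 0, area_um2 = area,
    ki67_positive = dab > 0,
    dab = dab, hematoxylin = hem,
    polygon = lapply(seq_len(k), function(i)
      ki67flow:::ellipse_polygon(centres$x[i], centres$y[i], r, r, 0))
  )
}

# Labeled feature tibble with two linearly separable classes.
fx_separable <- function(n = 300, gap = 3, seed = 1) {
  withr::with_seed(seed, {
    half <- n %/% 2
    tibble::tibble(
      id = seq_len(2 * half),
      x_um = stats::runif(2 * half, 0, 100),
      y_um = stats::runif(2 * half, 0, 100),
      f1 = c(stats::rnorm(half, 0), stats::rnorm(half, gap)),
      f2 = stats::rnorm(2 * half),
      class_label = rep(c("other", "tumour"), each = half)
    )
  })
}
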