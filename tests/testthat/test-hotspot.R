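# Truth tables double as detections: `class` + `dab` columns drive the map.
hotspot_truth <- function(seed = 4, base = 0.1, peak = 0.9,
                          centre = c(150, 150), radius = 60,
                          n_tumour = 700, side = 380) {
  cfg <- scene_config(width_um = side, height_um = side,
                      n_tumour = n_tumour, n_stroma = 0, n_lymph = 0,
                      base_positivity = base,
                      hotspots = list(list(center = centre, radius = radius,
                                           peak_positivity = peak)),
                      seed = seed)
  simulate_nuclei(cfg, polygons = FALSE)
}

test_that("a uniform stain field gives a flat heat map", {
  det <- tibble::tibble(
    id = 1:400, class = "tumour",
    x_um = rep(seq(10, 390, by = 20), 20),
    y_um = rep(seq(10, 390, by = 20), each = 20),
    dab = 0.4)
  hm <- build_heatmap(det, feature = "dab")
  v <- hm$values[!hm$mask]
  expect_lt(max(v) - min(v), 0.01 * mean(v))
})

test_that("the heat-map argmax lands on the true hotspot", {
  nuc <- hotspot_truth(seed = 4)
  hm <- build_heatmap(nuc, feature = "dab")
  hs <- find_hotspot(hm)
  expect_lt(sqrt((hs$x_um - 150)^2 + (hs$y_um - 150)^2), 50)
})

test_that("artefact exclusion masks cells and redirects the hotspot", {
  nuc <- hotspot_truth(seed = 4)
  hm <- build_heatmap(nuc, feature = "dab")
  # empty exclusion: unchanged
  hm0 <- exclude_artefacts(hm, list())
  expect_identical(hm0$values, hm$values)
  expect_identical(hm0$mask, hm$mask)

  box <- cbind(x = c(50, 250, 250, 50), y = c(50, 50, 250, 250))
  hm1 <- exclude_artefacts(hm, list(box))
  hs1 <- find_hotspot(hm1)
  expect_false(hs1$x_um > 50 && hs1$x_um < 250 &&
                 hs1$y_um > 50 && hs1$y_um < 250)

  # idempotent
  hm2 <- exclude_artefacts(hm1, list(box))
  expect_identical(hm2$mask, hm1$mask)

  # excluding everything leaves nothing to seed
  all_box <- cbind(x = c(-1, 400, 400, -1), y = c(-1, -1, 400, 400))
  hm3 <- exclude_artefacts(hm, list(all_box))
  expect_error(find_hotspot(hm3), "no unmasked")
})

test_that("heat-map construction is invariant to detection order", {
  nuc <- hotspot_truth(seed = 6)
  hm1 <- build_heatmap(nuc, feature = "dab")
  perm <- withr::with_seed(1, sample(nrow(nuc)))
  hm2 <- build_heatmap(nuc[perm, ], feature = "dab")
  expect_equal(hm1$values, hm2$values, tolerance = 1e-12)
})

test_that("increments are disjoint 100-cell tumour sets in density order", {
  nuc <- hotspot_truth(seed = 4)
  hm <- build_heatmap(nuc, feature = "dab")
  inc <- select_increments(nuc, hm, rule = NULL)
  expect_equal(inc$rank, 1:5)
  expect_true(all(inc$n == 100))
  ids <- unlist(inc$member_ids)
  expect_equal(length(ids), length(unique(ids)))
  expect_true(all(nuc$class[match(ids, nuc$id)] == "tumour"))
  # a strong hotspot: the first increment has at least as many positives
  expect_gte(inc$n_positive[1], inc$n_positive[5])
  # first seed is near the hotspot
  expect_lt(sqrt((inc$seed_x_um[1] - 150)^2 + (inc$seed_y_um[1] - 150)^2),
            60)
})

test_that("exactly 500 eligible nuclei are partitioned; fewer is an error", {
  cfg <- scene_config(width_um = 320, height_um = 320,
                      n_tumour = 500, n_stroma = 0, n_lymph = 0,
                      base_positivity = 0.2, hotspots = list(), seed = 9)
  nuc <- simulate_nuclei(cfg, polygons = FALSE)
  inc <- select_increments(nuc, rule = NULL)
  expect_setequal(unlist(inc$member_ids), nuc$id)

  short <- nuc[1:450, ]
  expect_error(select_increments(short, rule = NULL), "shortfall of 50")
})

test_that("under a uniform field the five counts stay within the null envelope", {
  # simulation envelope for rank1 - rank5 under the null (no hotspot)
  null_diff <- vapply(1:30, function(s) {
    cfg <- scene_config(width_um = 320, height_um = 320,
                        n_tumour = 550, n_stroma = 0, n_lymph = 0,
                        base_positivity = 0.3, hotspots = list(),
                        seed = 1000 + s)
    nuc <- simulate_nuclei(cfg, polygons = FALSE)
    inc <- select_increments(nuc, rule = NULL)
    inc$n_positive[1] - inc$n_positive[5]
  }, numeric(1))
  cfg <- scene_config(width_um = 320, height_um = 320,
                      n_tumour = 550, n_stroma = 0, n_lymph = 0,
                      base_positivity = 0.3, hotspots = list(), seed = 77)
  nuc <- simulate_nuclei(cfg, polygons = FALSE)
  inc <- select_increments(nuc, rule = NULL)
  obs <- inc$n_positive[1] - inc$n_positive[5]
  expect_gte(obs, min(null_diff) - 1)
  expect_lte(obs, max(null_diff) + 1)
  # every count is a plausible Binomial(100, 0.3) draw given hotspot seeding
  expect_true(all(inc$n_positive >= 10 & inc$n_positive <= 60))
})

test_that("seed jitter emulates visual assessment without changing the design", {
  nuc <- hotspot_truth(seed = 12)
  hm <- build_heatmap(nuc, feature = "dab")
  va <- select_increments(nuc, hm, rule = NULL, jitter_sd_um = 25, seed = 3)
  expect_equal(va$rank, 1:5)
  expect_true(all(va$n == 100))
  va2 <- select_increments(nuc, hm, rule = NULL, jitter_sd_um = 25, seed = 3)
  expect_identical(va$n_positive, va2$n_positive)  # seeded jitter
})

test_that("increment ranks can be written back onto the detections", {
  nuc <- hotspot_truth(seed = 4)
  inc <- select_increments(nuc, rule = NULL)
  out <- apply_increments(nuc, inc)
  expect_equal(sum(!is.na(out$increment_rank)), 500)
  expect_equal(sort(unique(stats::na.omit(out$increment_rank))), 1:5)
})
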