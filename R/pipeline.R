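#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters with a single global seed. The global
#' seed fans out deterministically to per-stage seeds
#' (`(seed + 104729 * stage) mod 2^31 - 1`), so each stage is
#' independently reproducible from the manifest.
#'
#' @param scene A [scene_config()] for the synthetic input scene.
#' @param detection A [detection_params()].
#' @param rule A [positivity_rule()].
#' @param smoothing_radii_um Feature-smoothing radii (default 25/50/100).
#' @param hotspot List with `smoothing_radius_um` and `grid_um`.
#' @param scoring List with `n_sets` and `set_size` (default 5 x 100).
#' @param va_jitter_sd_um Seed perturbation SD for the emulated visual
#'   assessment arm (default 25).
#' @param estimate_stains Re-estimate stain vectors from the image
#'   (default `TRUE`).
#' @param write_image Also write the rendered scene PNG (default `FALSE`).
#' @param seed Global integer seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(scene = scene_config(),
                            detection = detection_params(),
                            rule = positivity_rule(),
                            smoothing_radii_um = c(25, 50, 100),
                            hotspot = list(smoothing_radius_um = 50,
                                           grid_um = 25),
                            scoring = list(n_sets = 5, set_size = 100),
                            va_jitter_sd_um = 25,
                            estimate_stains = TRUE,
                            write_image = FALSE,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 104729 * stage) %% 2147483647)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full digital Ki-67 pipeline on a synthetic scene
#'
#' Simulate -> stain estimation and deconvolution -> watershed detection,
#' cell expansion, feature measurement, smoothing -> classifier training
#' (on ground-truth-labeled detections) and classification -> positivity
#' calling -> heat-map hotspot and 5 x 100 increments -> case scores for
#' the digital arm and an emulated visual-assessment arm counted on the
#' ground truth. Every tabular artifact and a machine-readable manifest
#' are written under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param case_id Case identifier used in the score tables.
#' @return Invisibly, a list with the detections, increments, scores and
#'   file paths.
#' @export
run_pipeline <- function(config, out_dir, case_id = "case1") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[ki67flow] ", ...)

  sc <- config$scene
  sc$seed <- stage_seed(config$seed, 1)
  scene <- run_stage("simulate", simulate_scene(sc))
  log("simulated scene: ", nrow(scene$nuclei), " nuclei (",
      sum(scene$nuclei$class == "tumour"), " tumour)")

  od <- run_stage("stains", rgb_to_od(scene$image))
  profile <- if (config$estimate_stains) {
    run_stage("stains", estimate_stain_vectors(od))
  } else stain_profile()
  conc <- run_stage("stains", deconvolve(od, profile))

  det <- run_stage("detect", {
    d <- detect_nuclei(od, config$detection)
    d <- expand_cells(d, config$detection$cell_expansion_um)
    d <- measure_features(d, od, conc)
    smooth_features(d, radii_um = config$smoothing_radii_um)
  })
  log("detected ", nrow(det), " nuclei")

  det <- run_stage("classify", {
    d <- match_truth(det, scene$nuclei)
    labeled <- d[!is.na(d$truth_class), , drop = FALSE]
    labeled$class_label <- ifelse(labeled$truth_class == "tumour",
                                  "tumour", "other")
    model <- train_classifier(labeled, seed = stage_seed(config$seed, 2))
    d <- classify_nuclei(d, model)
    call_positivity(d, config$rule)
  })
  log(sum(det$class_label == "tumour"), " tumour-classified nuclei, ",
      sum(det$ki67_positive & det$class_label == "tumour"), " positive")

  hm <- run_stage("hotspot", build_heatmap(
    det, smoothing_radius_um = config$hotspot$smoothing_radius_um,
    grid_um = config$hotspot$grid_um))
  inc <- run_stage("hotspot", select_increments(
    det, hm, n_sets = config$scoring$n_sets,
    set_size = config$scoring$set_size, rule = config$rule))
  det <- apply_increments(det, inc)

  scores <- run_stage("score", {
    dia <- score_case(inc, case_id, "DIA", config$scoring$set_size)
    va_inc <- select_increments(
      scene$nuclei, heatmap = build_heatmap(
        scene$nuclei, feature = "dab",
        smoothing_radius_um = config$hotspot$smoothing_radius_um,
        grid_um = config$hotspot$grid_um),
      n_sets = config$scoring$n_sets, set_size = config$scoring$set_size,
      rule = NULL, jitter_sd_um = config$va_jitter_sd_um,
      seed = stage_seed(config$seed, 3))
    va <- score_case(va_inc, case_id, "VA", config$scoring$set_size)
    dplyr::bind_rows(dia, va)
  })

  paths <- list(
    detections_geojson = file.path(out_dir, "detections.geojson"),
    detections_csv = file.path(out_dir, "detections.csv"),
    increments_csv = file.path(out_dir, "increments.csv"),
    scores_csv = file.path(out_dir, "scores.csv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  run_stage("write", {
    write_detections_geojson(det, paths$detections_geojson)
    write_detections_csv(det, paths$detections_csv)
    inc_flat <- inc[setdiff(names(inc), "member_ids")]
    inc_flat <- dplyr::mutate(inc_flat, case_id = case_id, .before = 1)
    utils::write.csv(inc_flat, paths$increments_csv, row.names = FALSE)
    utils::write.csv(scores, paths$scores_csv, row.names = FALSE)
    if (config$write_image) {
      paths$image <- file.path(out_dir, "scene.png")
      write_image(scene$image, paths$image)
    }
    manifest <- list(
      package = "ki67flow",
      version = as.character(utils::packageVersion("ki67flow")),
      seed = config$seed,
      stage_seeds = list(simulate = stage_seed(config$seed, 1),
                         train = stage_seed(config$seed, 2),
                         va_emulation = stage_seed(config$seed, 3)),
      scene = unclass(config$scene),
      detection = unclass(config$detection),
      rule = unclass(config$rule),
      smoothing_radii_um = config$smoothing_radii_um,
      hotspot = config$hotspot,
      scoring = config$scoring,
      va_jitter_sd_um = config$va_jitter_sd_um,
      estimate_stains = config$estimate_stains,
      counts = list(nuclei_truth = nrow(scene$nuclei),
                    detections = nrow(det),
                    tumour = sum(det$class_label == "tumour"))
    )
    yaml::write_yaml(manifest, paths$manifest, precision = 15)
  })
  log("wrote ", length(paths), " artifacts to ", out_dir)
  invisible(list(detections = det, increments = inc, scores = scores,
                 heatmap = hm, profile = profile, truth = scene$nuclei,
                 paths = paths))
}
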