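#' Simulate a cohort of hotspot-scored synthetic cases
#'
#' Generates `n_cases` heterogeneous tumour point patterns (per-case random
#' baseline positivity and one random proliferation hotspot), runs the
#' density-ordered 100-cell increment procedure on the ground truth for
#' two arms, and returns the long case-score table:
#' * `DIA`: increments seeded exactly at the hottest heat-map cell,
#'   positives counted from ground truth (an idealized digital arm without
#'   detection noise);
#' * `VA`: the same procedure with each seed perturbed by isotropic
#'   Gaussian jitter (`va_jitter_sd_um`), emulating a pathologist's
#'   imperfect hotspot localisation under the microscope.
#'
#' Intended for cohort-level experiments on the scoring and statistics
#' stages (reclassification flows, cut-off calibration, method agreement)
#' where rendering and detection would add nothing but runtime; the
#' image-based stages are exercised by [run_pipeline()].
#'
#' @param n_cases Number of cases (default 20).
#' @param width_um,height_um Scene size per case (default 320).
#' @param n_tumour Tumour nuclei per case (default 560).
#' @param base_range Per-case baseline positivity drawn uniformly from
#'   this range (default 0.05-0.45).
#' @param boost_range Hotspot peak is base + uniform draw from this range,
#'   capped at 0.95 (default 0.15-0.5).
#' @param radius_range Hotspot radius range in um (default 40-80).
#' @param va_jitter_sd_um Seed jitter SD for the VA arm (default 25).
#' @param n_sets,set_size Increment design (default 5 x 100).
#' @param seed Integer seed.
#' @return Long tibble of case scores (case x method x increment) as from
#'   [score_case()].
#' @export
simulate_score_cohort <- function(n_cases = 20,
                                  width_um = 320, height_um = 320,
                                  n_tumour = 560,
                                  base_range = c(0.05, 0.45),
                                  boost_range = c(0.15, 0.5),
                                  radius_range = c(40, 80),
                                  va_jitter_sd_um = 25,
                                  n_sets = 5, set_size = 100,
                                  seed = 1L) {
  stopifnot(n_cases >= 1, n_tumour >= n_sets * set_size)
  pars <- with_local_seed(seed, tibble::tibble(
    base = stats::runif(n_cases, base_range[1], base_range[2]),
    boost = stats::runif(n_cases, boost_range[1], boost_range[2]),
    radius = stats::runif(n_cases, radius_range[1], radius_range[2]),
    cx = stats::runif(n_cases, 0.25 * width_um, 0.75 * width_um),
    cy = stats::runif(n_cases, 0.25 * height_um, 0.75 * height_um),
    case_seed = sample.int(2147483646, n_cases)
  ))
  out <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    peak <- min(0.95, pars$base[i] + pars$boost[i])
    cfg <- scene_config(
      width_um = width_um, height_um = height_um,
      n_tumour = n_tumour, n_stroma = 0, n_lymph = 0,
      base_positivity = pars$base[i],
      hotspots = list(list(center = c(pars$cx[i], pars$cy[i]),
                           radius = pars$radius[i],
                           peak_positivity = peak)),
      seed = pars$case_seed[i])
    nuc <- simulate_nuclei(cfg, polygons = FALSE)
    hm <- build_heatmap(nuc, feature = "dab")
    cid <- sprintf("case%03d", i)
    dia <- score_case(
      select_increments(nuc, hm, n_sets = n_sets, set_size = set_size,
                        rule = NULL),
      cid, "DIA", set_size)
    va <- score_case(
      select_increments(nuc, hm, n_sets = n_sets, set_size = set_size,
                        rule = NULL, jitter_sd_um = va_jitter_sd_um,
                        seed = pars$case_seed[i]),
      cid, "VA", set_size)
    out[[i]] <- dplyr::bind_rows(dia, va)
  }
  dplyr::bind_rows(out)
}
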