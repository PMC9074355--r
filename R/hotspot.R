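#' Build a smoothed DAB-OD heat map over the tumour region
#'
#' Lays a regular grid over the region (or the detections' bounding box)
#' and fills each cell with the Gaussian-weighted mean of the per-nucleus
#' `nucleus_dab_od_mean` of tumour-classified nuclei, with weight
#' `exp(-d^2 / (2 * (radius/2)^2))` to the cell centre - the same
#' radius-to-sigma convention as [smooth_features()]. Cells with no
#' contributing nucleus within twice the smoothing radius are masked, as
#' are cells outside the region polygon. The hottest unmasked cell seeds
#' hotspot counting.
#'
#' @param detections Detection tibble with coordinates, a class column
#'   (`class_label` from [classify_nuclei()], or `class` for ground-truth
#'   tables) and the heat feature.
#' @param region_polygon Optional tumour-region polygon (um vertex matrix);
#'   cells and nuclei outside it are excluded.
#' @param smoothing_radius_um Smoothing radius (default 50).
#' @param grid_um Grid spacing (default 25, half the smoothing radius).
#' @param feature Feature visualized (default `nucleus_dab_od_mean`; use
#'   `"dab"` on ground-truth tables).
#' @param classes Classes contributing to the map (default `"tumour"`).
#' @return A `ki67_heatmap` object: cell-centre coordinates, value matrix,
#'   exclusion mask and the construction parameters.
#' @export
build_heatmap <- function(detections, region_polygon = NULL,
                          smoothing_radius_um = 50, grid_um = 25,
                          feature = "nucleus_dab_od_mean",
                          classes = "tumour") {
  cls <- detection_class(detections)
  keep <- cls %in% classes
  if (!is.null(region_polygon))
    keep <- keep & points_in_polygon(detections$x_um, detections$y_um,
                                     region_polygon)
  pts <- detections[keep, , drop = FALSE]
  if (nrow(pts) == 0)
    stop("no ", paste(classes, collapse = "/"),
         "-classified detections inside the region")
  if (!feature %in% names(pts))
    stop("detections lack the heat feature `", feature, "`")

  if (!is.null(region_polygon)) {
    xr <- range(region_polygon[, 1]); yr <- range(region_polygon[, 2])
  } else {
    xr <- range(detections$x_um); yr <- range(detections$y_um)
  }
  xc <- seq(xr[1] + grid_um / 2, xr[2], by = grid_um)
  yc <- seq(yr[1] + grid_um / 2, yr[2], by = grid_um)
  if (length(xc) == 0) xc <- mean(xr)
  if (length(yc) == 0) yc <- mean(yr)

  hv <- heat_values(xc, yc, pts$x_um, pts$y_um, pts[[feature]],
                    smoothing_radius_um)
  mask <- hv$no_coverage
  if (!is.null(region_polygon)) {
    gx <- rep(xc, times = length(yc)); gy <- rep(yc, each = length(xc))
    outside <- !points_in_polygon(gx, gy, region_polygon)
    mask <- mask | matrix(outside, length(xc), length(yc))
  }
  structure(
    list(x_um = xc, y_um = yc, values = hv$values, mask = mask,
         smoothing_radius_um = smoothing_radius_um, grid_um = grid_um,
         feature = feature, classes = classes,
         region = region_polygon, exclusions = list()),
    class = "ki67_heatmap"
  )
}

detection_class <- function(detections) {
  if ("class_label" %in% names(detections)) detections$class_label
  else if ("class" %in% names(detections)) detections$class
  else stop("detections carry neither `class_label` nor `class`")
}

# Gaussian-weighted mean of (px, py, f) at grid cell centres.
heat_values <- function(xc, yc, px, py, f, radius) {
  sigma2 <- (radius / 2)^2
  nx <- length(xc); ny <- length(yc)
  gx <- rep(xc, times = ny); gy <- rep(yc, each = nx)
  d2 <- outer(gx, px, "-")^2 + outer(gy, py, "-")^2
  w <- exp(-d2 / (2 * sigma2))
  num <- as.numeric(w %*% f)
  den <- rowSums(w)
  vals <- ifelse(den > 0, num / pmax(den, 1e-300), 0)
  near <- matrix(apply(d2, 1, min) <= (2 * radius)^2, nx, ny)
  list(values = matrix(vals, nx, ny), no_coverage = !near)
}

#' @export
print.ki67_heatmap <- function(x, ...) {
  cat("Ki-67 heat map: ", length(x$x_um), " x ", length(x$y_um),
      " cells at ", x$grid_um, " um (", x$feature, ", smoothed ",
      x$smoothing_radius_um, " um); ", sum(x$mask), " masked\n", sep = "")
  invisible(x)
}

#' Exclude artefact regions from a heat map
#'
#' Cells whose centre falls inside any exclusion polygon are masked and
#' the polygons are retained, so masked regions neither seed hotspots nor
#' contribute member nuclei during increment selection. Exclusion is
#' idempotent.
#'
#' @param heatmap A `ki67_heatmap`.
#' @param exclusion_polygons List of polygon vertex matrices (um).
#' @return The heat map with updated mask and stored exclusions.
#' @export
exclude_artefacts <- function(heatmap, exclusion_polygons) {
  stopifnot(inherits(heatmap, "ki67_heatmap"))
  if (length(exclusion_polygons) == 0) return(heatmap)
  nx <- length(heatmap$x_um); ny <- length(heatmap$y_um)
  gx <- rep(heatmap$x_um, times = ny); gy <- rep(heatmap$y_um, each = nx)
  for (poly in exclusion_polygons) {
    inside <- points_in_polygon(gx, gy, poly)
    heatmap$mask <- heatmap$mask | matrix(inside, nx, ny)
  }
  heatmap$exclusions <- c(heatmap$exclusions, exclusion_polygons)
  heatmap
}

#' Locate the hotspot (hottest unmasked heat-map cell)
#'
#' @param heatmap A `ki67_heatmap`.
#' @return One-row tibble with `x_um`, `y_um`, `value`.
#' @export
find_hotspot <- function(heatmap) {
  stopifnot(inherits(heatmap, "ki67_heatmap"))
  v <- heatmap$values
  v[heatmap$mask] <- -Inf
  if (all(!is.finite(v))) stop("no unmasked cells in the heat map")
  k <- which.max(v)
  nx <- length(heatmap$x_um)
  i <- ((k - 1) %% nx) + 1
  j <- ((k - 1) %/% nx) + 1
  tibble::tibble(x_um = heatmap$x_um[i], y_um = heatmap$y_um[j],
                 value = heatmap$values[k])
}

# TRUE for nuclei eligible under the heat map's region/exclusions.
nucleus_unmasked <- function(heatmap, x, y) {
  ok <- rep(TRUE, length(x))
  if (!is.null(heatmap$region))
    ok <- ok & points_in_polygon(x, y, heatmap$region)
  for (poly in heatmap$exclusions)
    ok <- ok & !points_in_polygon(x, y, poly)
  ok
}

#' Select density-ordered 100-cell counting increments
#'
#' Greedy emulation of hotspot counting: seed at the hottest unmasked heat
#' cell, take the `set_size` nearest unassigned tumour nuclei to the seed,
#' count the Ki-67-positive members, then rebuild the heat map from the
#' still-unassigned nuclei and repeat, so increments follow decreasing
#' order of local positive-staining density. Set 1 is the hotspot count.
#'
#' For emulating visual assessment on ground-truth tables, `jitter_sd_um`
#' perturbs each seed point with isotropic Gaussian noise (a pathologist's
#' imperfect hotspot localisation) and `rule = NULL` counts the stored
#' `ki67_positive` ground truth instead of thresholding a measurement.
#'
#' @param detections Detection tibble (tumour class column plus the heat
#'   feature and either `nucleus_dab_od_mean` or `ki67_positive`).
#' @param heatmap A `ki67_heatmap`; built with defaults from `detections`
#'   when `NULL`.
#' @param n_sets Number of increments (default 5).
#' @param set_size Tumour nuclei per increment (default 100).
#' @param rule A [positivity_rule()], or `NULL` to use an existing
#'   `ki67_positive` column.
#' @param jitter_sd_um SD of the seed perturbation (default 0 = none).
#' @param seed Seed for the jitter draws.
#' @return A `ki67_increments` tibble: `rank`, `n`, `n_positive`,
#'   `seed_x_um`, `seed_y_um`, `centroid_x_um`, `centroid_y_um` and a
#'   `member_ids` list-column of detection ids.
#' @export
select_increments <- function(detections, heatmap = NULL, n_sets = 5,
                              set_size = 100, rule = positivity_rule(),
                              jitter_sd_um = 0, seed = 1L) {
  if (is.null(heatmap)) {
    feature <- if ("nucleus_dab_od_mean" %in% names(detections))
      "nucleus_dab_od_mean" else "dab"
    heatmap <- build_heatmap(detections, feature = feature)
  }
  stopifnot(inherits(heatmap, "ki67_heatmap"))
  cls <- detection_class(detections)
  elig <- cls %in% heatmap$classes &
    nucleus_unmasked(heatmap, detections$x_um, detections$y_um)
  pool <- detections[elig, , drop = FALSE]
  need <- n_sets * set_size
  if (nrow(pool) < need)
    stop("only ", nrow(pool), " eligible tumour nuclei; ", need,
         " are required (", n_sets, " x ", set_size, "), shortfall of ",
         need - nrow(pool))
  if (is.null(rule)) {
    if (!"ki67_positive" %in% names(pool))
      stop("`rule = NULL` requires a `ki67_positive` column")
    pos <- pool$ki67_positive
  } else {
    pos <- call_positivity(pool, rule)$ki67_positive
  }

  jit <- if (jitter_sd_um > 0) {
    with_local_seed(seed, matrix(stats::rnorm(2 * n_sets, 0, jitter_sd_um),
                                 n_sets, 2))
  } else matrix(0, n_sets, 2)

  unassigned <- rep(TRUE, nrow(pool))
  out <- vector("list", n_sets)
  for (r in seq_len(n_sets)) {
    hv <- heat_values(heatmap$x_um, heatmap$y_um,
                      pool$x_um[unassigned], pool$y_um[unassigned],
                      pool[[heatmap$feature]][unassigned],
                      heatmap$smoothing_radius_um)
    v <- hv$values
    v[heatmap$mask | hv$no_coverage] <- -Inf
    if (all(!is.finite(v)))
      stop("no unmasked heat cells with unassigned nuclei at rank ", r)
    k <- which.max(v)
    nx <- length(heatmap$x_um)
    sx <- heatmap$x_um[((k - 1) %% nx) + 1] + jit[r, 1]
    sy <- heatmap$y_um[((k - 1) %/% nx) + 1] + jit[r, 2]
    cand <- which(unassigned)
    d <- (pool$x_um[cand] - sx)^2 + (pool$y_um[cand] - sy)^2
    take <- cand[order(d)[seq_len(set_size)]]
    unassigned[take] <- FALSE
    out[[r]] <- tibble::tibble(
      rank = r, n = set_size, n_positive = sum(pos[take]),
      seed_x_um = sx, seed_y_um = sy,
      centroid_x_um = mean(pool$x_um[take]),
      centroid_y_um = mean(pool$y_um[take]),
      member_ids = list(pool$id[take])
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("ki67_increments", class(res))
  res
}

#' Write increment ranks back onto the detections
#' @param detections Detection tibble.
#' @param increments A `ki67_increments` tibble.
#' @return The detections with an `increment_rank` column (`NA` outside
#'   the counted sets).
#' @export
apply_increments <- function(detections, increments) {
  detections$increment_rank <- NA_integer_
  for (r in seq_len(nrow(increments))) {
    ids <- increments$member_ids[[r]]
    detections$increment_rank[match(ids, detections$id)] <-
      increments$rank[r]
  }
  detections
}
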