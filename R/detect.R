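#' Watershed nucleus-detection parameters
#'
#' The detection pipeline and its defaults follow the QuPath-style
#' watershed nucleus detection on the optical-density sum channel:
#' resample to the requested pixel size, rolling-ball (morphological
#' opening) background subtraction, exclusion of dense artefacts where the
#' background estimate exceeds `max_background_intensity`, median filter,
#' Gaussian smoothing, global threshold, marker-controlled watershed
#' splitting of touching nuclei, and an area filter.
#'
#' @param requested_pixel_size_um Working resolution (default 0.4).
#' @param background_radius_um Opening (rolling-ball) radius (default 8).
#' @param median_filter_radius_um Median filter radius (default 1.5).
#' @param sigma_um Gaussian smoothing sigma (default 1.5).
#' @param min_area_um2,max_area_um2 Nucleus area bounds in um^2
#'   (defaults 10 and 350).
#' @param threshold Foreground threshold on the background-subtracted,
#'   smoothed OD sum (default 0.02).
#' @param max_background_intensity Pixels whose background estimate exceeds
#'   this OD sum are excluded as artefact (default 3.0).
#' @param cell_expansion_um Cell expansion distance for [expand_cells()]
#'   (default 5).
#' @param marker_separation_um Minimum separation of watershed markers
#'   (local maxima of the smoothed channel; default 4).
#' @return A `detection_params` object.
#' @export
detection_params <- function(requested_pixel_size_um = 0.4,
                             background_radius_um = 8.0,
                             median_filter_radius_um = 1.5,
                             sigma_um = 1.5,
                             min_area_um2 = 10,
                             max_area_um2 = 350,
                             threshold = 0.02,
                             max_background_intensity = 3.0,
                             cell_expansion_um = 5.0,
                             marker_separation_um = 4.0) {
  stopifnot(requested_pixel_size_um > 0, background_radius_um > 0,
            median_filter_radius_um > 0, sigma_um > 0,
            min_area_um2 > 0, max_area_um2 > 0,
            threshold > 0, cell_expansion_um >= 0,
            marker_separation_um > 0)
  if (min_area_um2 >= max_area_um2)
    stop("`min_area_um2` must be smaller than `max_area_um2`")
  structure(as.list(environment()), class = "detection_params")
}

odd_brush <- function(radius_px) {
  size <- 2L * max(1L, round(radius_px)) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

#' Detect cell nuclei by marker-controlled watershed on the OD sum
#'
#' @param od A `ki67_od` object from [rgb_to_od()]; its `pixel_size_um`
#'   must be set.
#' @param params A [detection_params()].
#' @return A tibble of detections: `id`, `x_um`, `y_um` (centroid),
#'   `area_um2` and a `polygon` list-column (vertex matrices in um).
#'   Attribute `"scene"` records the scene extent and working pixel size.
#' @export
detect_nuclei <- function(od, params = detection_params()) {
  stopifnot(inherits(od, "ki67_od"), inherits(params, "detection_params"))
  p0 <- od$pixel_size_um
  if (is.null(p0) || !is.finite(p0) || p0 <= 0)
    stop("the OD image has no pixel-size metadata (`pixel_size_um`)")
  ch <- od$od_sum
  if (length(ch) == 0 || all(ch == 0)) return(empty_detections(od, params))

  psz <- params$requested_pixel_size_um
  nx <- max(1L, round(ncol_safe(ch, 1) * p0 / psz))
  ny <- max(1L, round(ncol_safe(ch, 2) * p0 / psz))
  ch <- EBImage::resize(ch, w = nx, h = ny)
  ch[ch < 0] <- 0

  bg <- EBImage::opening(ch, odd_brush(params$background_radius_um / psz))
  excl <- bg > params$max_background_intensity
  sub <- pmax(ch - bg, 0)
  sub[excl] <- 0

  # medianFilter works in [0,1]; rescale around it
  m <- max(sub)
  if (m > 0) {
    sz <- max(1L, round(params$median_filter_radius_um / psz))
    sub <- EBImage::medianFilter(sub / m, size = sz) * m
  }
  sm <- EBImage::gblur(sub, sigma = params$sigma_um / psz)
  fg <- sm > params$threshold & !excl
  if (!any(fg)) return(empty_detections(od, params))

  # markers: regional maxima of the smoothed channel, thinned so that no
  # kept marker has a stronger kept marker within the minimum separation
  mx <- EBImage::dilate(sm, EBImage::makeBrush(3, "box"))
  cand <- (sm >= mx) & fg
  plat <- EBImage::bwlabel(cand)  # plateau maxima merge to one candidate
  if (max(plat) == 0) return(empty_detections(od, params))
  idx <- which(plat > 0)
  lab <- plat[idx]
  pi_ <- ((idx - 1L) %% nrow(plat)) + 1L
  pj <- ((idx - 1L) %/% nrow(plat)) + 1L
  px <- tapply(pi_, lab, mean); py <- tapply(pj, lab, mean)
  ph <- tapply(sm[idx], lab, max)
  ord <- order(-ph)
  sep2 <- (params$marker_separation_um / psz)^2
  keep <- logical(length(ord))
  kx <- ky <- numeric(0)
  for (o in ord) {
    if (length(kx) == 0 ||
        all((kx - px[o])^2 + (ky - py[o])^2 >= sep2)) {
      keep[o] <- TRUE
      kx <- c(kx, px[o]); ky <- c(ky, py[o])
    }
  }
  remap_pk <- integer(max(plat))
  remap_pk[which(keep)] <- seq_len(sum(keep))
  markers <- matrix(0L, nrow(plat), ncol(plat))
  kept_px <- idx[keep[lab]]
  markers[kept_px] <- remap_pk[lab[keep[lab]]]
  if (max(markers) == 0) return(empty_detections(od, params))

  seg <- EBImage::propagate(sm, seeds = markers, mask = fg)
  seg <- refine_segments(as.matrix(seg), sm, floor_level = params$threshold)

  labels_to_detections(seg, psz, params, scene_extent(od))
}

ncol_safe <- function(m, d) dim(m)[d]

scene_extent <- function(od) {
  list(width_um = dim(od$od_sum)[1] * od$pixel_size_um,
       height_um = dim(od$od_sum)[2] * od$pixel_size_um)
}

empty_detections <- function(od, params) {
  out <- tibble::tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                        area_um2 = numeric(), polygon = list())
  attr(out, "scene") <- c(scene_extent(od),
                          list(pixel_size_um = params$requested_pixel_size_um))
  out
}

# Tighten watershed segments to the half-peak-height level set: Gaussian
# smoothing spreads each nucleus well beyond its edge at a low global
# threshold, while the 50%-of-peak contour of a blurred object lies on the
# true boundary. Keeps, per segment, the largest connected piece.
refine_segments <- function(seg, sm, frac = 0.5, floor_level = 0) {
  idx <- which(seg > 0)
  if (length(idx) == 0) return(seg)
  lab <- seg[idx]
  nlab <- max(lab)
  peak <- tapply(sm[idx], lab, max)
  lvl <- pmax(peak[as.character(seq_len(nlab))] * frac, floor_level)
  lvl[is.na(lvl)] <- Inf
  out <- matrix(0L, nrow(seg), ncol(seg))
  keep_idx <- idx[sm[idx] >= lvl[lab]]
  out[keep_idx] <- seg[keep_idx]
  # retain only the largest connected fragment of each segment
  ii <- ((keep_idx - 1L) %% nrow(seg)) + 1L
  jj <- ((keep_idx - 1L) %/% nrow(seg)) + 1L
  lab2 <- out[keep_idx]
  for (k in unique(lab2)) {
    sel <- lab2 == k
    i0 <- min(ii[sel]); i1 <- max(ii[sel])
    j0 <- min(jj[sel]); j1 <- max(jj[sel])
    sub <- out[i0:i1, j0:j1, drop = FALSE] == k
    cc <- EBImage::bwlabel(sub)
    if (max(cc) > 1) {
      tab <- tabulate(cc)
      drop <- sub & cc != which.max(tab)
      block <- out[i0:i1, j0:j1, drop = FALSE]
      block[drop] <- 0L
      out[i0:i1, j0:j1] <- block
    }
  }
  out
}

# Convert a label raster into the detection tibble (area filter + polygons).
# The canonical nucleus area is the pixel-count (mask) area; the boundary
# polygon traced through pixel centres under-reads it by a half-pixel band.
labels_to_detections <- function(seg, psz, params, extent) {
  tab <- tabulate(seg)
  areas <- tab * psz^2
  keep <- which(areas >= params$min_area_um2 & areas <= params$max_area_um2)
  if (length(keep) == 0) {
    out <- tibble::tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                          area_um2 = numeric(), polygon = list())
    attr(out, "scene") <- c(extent, list(pixel_size_um = psz))
    return(out)
  }
  # relabel kept components 1..k for contour extraction
  remap <- integer(length(tab))
  remap[keep] <- seq_along(keep)
  seg2 <- matrix(0L, nrow(seg), ncol(seg))
  nz <- seg > 0
  seg2[nz] <- remap[seg[nz]]
  cont <- EBImage::ocontour(seg2)

  idx <- which(seg2 > 0)
  lab <- seg2[idx]
  ii <- ((idx - 1L) %% nrow(seg2)) + 1L
  jj <- ((idx - 1L) %/% nrow(seg2)) + 1L
  cx <- (tapply(ii, lab, mean) - 0.5) * psz
  cy <- (tapply(jj, lab, mean) - 0.5) * psz

  poly <- lapply(seq_along(keep), function(k) {
    pc <- cont[[k]]
    # ocontour coordinates are 0-based pixel indices; map to pixel centres
    cbind(x = (pc[, 1] + 0.5) * psz, y = (pc[, 2] + 0.5) * psz)
  })
  out <- tibble::tibble(
    id = seq_along(keep),
    x_um = as.numeric(cx), y_um = as.numeric(cy),
    area_um2 = areas[keep],
    polygon = poly
  )
  attr(out, "scene") <- c(extent, list(pixel_size_um = psz))
  out
}

# Even-odd point-in-polygon, vectorized over points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + (yj == yi) * 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(sqrt((poly[j, 1] - poly[, 1])^2 + (poly[j, 2] - poly[, 2])^2))
}

# Circular moving average of a closed contour: pixel-traced outlines are
# staircase polygons whose raw chain length overestimates the perimeter.
smooth_polygon <- function(poly, window = NULL) {
  n <- nrow(poly)
  if (is.null(window)) window <- max(3L, 2L * (n %/% 16L) + 1L)
  if (n <= window) return(poly)
  half <- window %/% 2
  idx <- function(i) ((i - 1) %% n) + 1
  out <- poly
  for (d in seq_len(half)) {
    out <- out + poly[idx(seq_len(n) + d), , drop = FALSE] +
      poly[idx(seq_len(n) - d), , drop = FALSE]
  }
  out / window
}

# Rasterize polygons in um onto a grid, returning an integer label matrix.
rasterize_polygons <- function(polys, nx, ny, psz) {
  lab <- matrix(0L, nx, ny)
  for (k in seq_along(polys)) {
    poly <- polys[[k]]
    i0 <- max(1L, floor(min(poly[, 1]) / psz))
    i1 <- min(nx, ceiling(max(poly[, 1]) / psz))
    j0 <- max(1L, floor(min(poly[, 2]) / psz))
    j1 <- min(ny, ceiling(max(poly[, 2]) / psz))
    if (i1 < i0 || j1 < j0) next
    is <- seq(i0, i1); js <- seq(j0, j1)
    gx <- rep((is - 0.5) * psz, times = length(js))
    gy <- rep((js - 0.5) * psz, each = length(is))
    inside <- points_in_polygon(gx, gy, poly)
    if (!any(inside)) next
    sub <- lab[i0:i1, j0:j1]
    sub[inside & sub == 0L] <- k
    lab[i0:i1, j0:j1] <- sub
  }
  lab
}

#' Expand nuclei to cell outlines by distance-limited Voronoi growth
#'
#' Each nucleus is grown outward by up to `expansion_um`, and where
#' neighbouring cells meet, the boundary is the equidistant line between
#' their nuclei (nearest-nucleus partition), so cell polygons never
#' overlap.
#'
#' @param detections Detection tibble from [detect_nuclei()] (or any tibble
#'   with `id` and `polygon`).
#' @param expansion_um Expansion distance (default 5).
#' @param pixel_size_um Rasterization grid; defaults to the detections'
#'   working pixel size.
#' @return The detections with added `cell_polygon` list-column and
#'   `cell_area_um2`.
#' @export
expand_cells <- function(detections, expansion_um = 5, pixel_size_um = NULL) {
  if (nrow(detections) == 0) {
    detections$cell_polygon <- list()
    detections$cell_area_um2 <- numeric()
    return(detections)
  }
  if (expansion_um == 0) {
    detections$cell_polygon <- detections$polygon
    detections$cell_area_um2 <- vapply(detections$polygon, polygon_area,
                                       numeric(1))
    return(detections)
  }
  scene <- attr(detections, "scene")
  psz <- pixel_size_um %||% scene$pixel_size_um %||% 0.4
  xmax <- max(vapply(detections$polygon, function(p) max(p[, 1]), numeric(1)))
  ymax <- max(vapply(detections$polygon, function(p) max(p[, 2]), numeric(1)))
  w <- scene$width_um %||% (xmax + expansion_um + 2)
  h <- scene$height_um %||% (ymax + expansion_um + 2)
  nx <- ceiling(w / psz); ny <- ceiling(h / psz)

  lab <- rasterize_polygons(detections$polygon, nx, ny, psz)
  d <- EBImage::distmap(matrix(as.numeric(lab == 0L), nx, ny))
  # half-pixel compensation: distances are between pixel centres
  mask <- lab > 0L | (d * psz) <= expansion_um + psz / 2
  cells <- EBImage::propagate(matrix(0, nx, ny), seeds = lab, mask = mask)
  cells <- as.matrix(cells)
  present <- sort(unique(cells[cells > 0]))
  cont <- EBImage::ocontour(cells)
  cont_by_lab <- stats::setNames(cont[seq_along(present)],
                                 as.character(present))

  tabc <- tabulate(cells, nbins = nrow(detections))
  detections$cell_polygon <- lapply(seq_len(nrow(detections)), function(k) {
    pc <- cont_by_lab[[as.character(k)]]
    # tiny nuclei can rasterize to nothing; fall back to the nucleus outline
    if (is.null(pc) || nrow(pc) < 3) return(detections$polygon[[k]])
    cbind(x = (pc[, 1] + 0.5) * psz, y = (pc[, 2] + 0.5) * psz)
  })
  detections$cell_area_um2 <- ifelse(
    tabc > 0, tabc * psz^2,
    vapply(detections$polygon, polygon_area, numeric(1)))
  detections
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure shape and stain-intensity features per detection
#'
#' Computes shape features (area, perimeter, circularity `4*pi*A/P^2`,
#' eccentricity from mask second moments) and per-stain intensity
#' statistics (mean/max/min/sd) over the nucleus mask, plus mean/sd over
#' the cell ring (cell minus nucleus) when cell polygons are present.
#' `nucleus_dab_od_mean` - the mean deconvolved DAB optical density over
#' the nucleus mask - is the measurement that drives both Ki-67 positivity
#' calling and the hotspot heat map.
#'
#' @param detections Detection tibble with `polygon` (and optionally
#'   `cell_polygon`) columns.
#' @param od A `ki67_od` object (for the OD sum channel).
#' @param concentrations A `ki67_conc` object from [deconvolve()].
#' @return The detections with feature columns added; degenerate polygons
#'   are flagged `valid = FALSE` with `NA` features.
#' @export
measure_features <- function(detections, od, concentrations) {
  stopifnot(inherits(od, "ki67_od"), inherits(concentrations, "ki67_conc"))
  n <- nrow(detections)
  psz <- od$pixel_size_um
  if (is.null(psz)) stop("the OD image has no pixel-size metadata")
  nx <- dim(od$od_sum)[1]; ny <- dim(od$od_sum)[2]
  rasters <- list(dab_od = concentrations$dab,
                  hem_od = concentrations$hematoxylin,
                  od_sum = od$od_sum)
  has_cell <- "cell_polygon" %in% names(detections)

  stat_names <- c("mean", "max", "min", "sd")
  feat <- list()
  for (r in names(rasters)) for (s in stat_names)
    feat[[paste0("nucleus_", r, "_", s)]] <- rep(NA_real_, n)
  if (has_cell) for (r in names(rasters)) for (s in c("mean", "sd"))
    feat[[paste0("ring_", r, "_", s)]] <- rep(NA_real_, n)
  area <- perim <- circ <- ecc <- rep(NA_real_, n)
  valid <- rep(TRUE, n)

  grid_pixels <- function(poly) {
    i0 <- max(1L, floor(min(poly[, 1]) / psz))
    i1 <- min(nx, ceiling(max(poly[, 1]) / psz))
    j0 <- max(1L, floor(min(poly[, 2]) / psz))
    j1 <- min(ny, ceiling(max(poly[, 2]) / psz))
    if (i1 < i0 || j1 < j0) return(NULL)
    is <- seq(i0, i1); js <- seq(j0, j1)
    gx <- rep((is - 0.5) * psz, times = length(js))
    gy <- rep((js - 0.5) * psz, each = length(is))
    inside <- points_in_polygon(gx, gy, poly)
    if (!any(inside)) return(NULL)
    ii <- rep(is, times = length(js))[inside]
    jj <- rep(js, each = length(is))[inside]
    list(idx = (jj - 1L) * nx + ii, gx = gx[inside], gy = gy[inside])
  }

  for (k in seq_len(n)) {
    poly <- detections$polygon[[k]]
    a <- polygon_area(poly)
    if (!is.finite(a) || a <= 0) { valid[k] <- FALSE; next }
    area[k] <- a
    # perimeter and circularity from the smoothed contour (staircase-free)
    sp <- smooth_polygon(poly)
    a_s <- polygon_area(sp)
    p <- polygon_perimeter(sp)
    perim[k] <- p
    circ[k] <- min(1, 4 * pi * a_s / p^2)
    gp <- grid_pixels(poly)
    if (is.null(gp)) { valid[k] <- FALSE; next }
    # eccentricity from the pixel-coordinate covariance
    if (length(gp$gx) >= 3) {
      cv <- stats::cov(cbind(gp$gx, gp$gy))
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      ecc[k] <- if (ev[1] > 0) sqrt(max(0, 1 - ev[2] / ev[1])) else 0
    } else ecc[k] <- 0
    for (r in names(rasters)) {
      v <- rasters[[r]][gp$idx]
      feat[[paste0("nucleus_", r, "_mean")]][k] <- mean(v)
      feat[[paste0("nucleus_", r, "_max")]][k] <- max(v)
      feat[[paste0("nucleus_", r, "_min")]][k] <- min(v)
      feat[[paste0("nucleus_", r, "_sd")]][k] <-
        if (length(v) > 1) stats::sd(v) else 0
    }
    if (has_cell) {
      cp <- detections$cell_polygon[[k]]
      gc <- grid_pixels(cp)
      if (!is.null(gc)) {
        ring <- setdiff(gc$idx, gp$idx)
        if (length(ring)) {
          for (r in names(rasters)) {
            v <- rasters[[r]][ring]
            feat[[paste0("ring_", r, "_mean")]][k] <- mean(v)
            feat[[paste0("ring_", r, "_sd")]][k] <-
              if (length(v) > 1) stats::sd(v) else 0
          }
        }
      }
    }
  }

  # the mask (pixel-count) area from detection is authoritative when present
  if ("area_um2" %in% names(detections)) {
    old <- detections$area_um2
    detections$area_um2 <- ifelse(is.finite(old), old, area)
    detections$area_um2[!valid] <- NA_real_
  } else {
    detections$area_um2 <- area
  }
  detections$perimeter_um <- perim
  detections$circularity <- circ
  detections$eccentricity <- ecc
  detections$valid <- valid
  for (nm in names(feat)) detections[[nm]] <- feat[[nm]]
  detections
}

#' Gaussian spatial smoothing of per-nucleus features
#'
#' For every nucleus and smoothing radius `r`, the smoothed feature is the
#' Gaussian-weighted mean over neighbouring nuclei (self included) with
#' weight `exp(-d^2 / (2 * (r/2)^2))`, the same radius-to-sigma convention
#' used by the hotspot heat map. Smoothed columns are named
#' `<feature>_sm<r>`.
#'
#' @param detections Detection tibble with `x_um`, `y_um` and feature
#'   columns.
#' @param features Character vector of feature columns to smooth; default
#'   is every measured shape/intensity feature present.
#' @param radii_um Smoothing radii in um (default `c(25, 50, 100)`).
#' @return The detections with smoothed feature columns appended.
#' @export
smooth_features <- function(detections, features = NULL,
                            radii_um = c(25, 50, 100)) {
  n <- nrow(detections)
  if (n == 0) return(detections)
  if (is.null(features)) {
    cand <- c("area_um2", "perimeter_um", "circularity", "eccentricity",
              grep("^(nucleus|ring)_", names(detections), value = TRUE))
    features <- intersect(cand, names(detections))
  }
  miss <- setdiff(features, names(detections))
  if (length(miss))
    stop("features not present: ", paste(miss, collapse = ", "))
  fm <- as.matrix(detections[features])
  fm[is.na(fm)] <- 0
  xs <- detections$x_um; ys <- detections$y_um
  block <- 1000L
  for (r in radii_um) {
    sigma2 <- (r / 2)^2
    out <- matrix(0, n, length(features))
    for (s in seq(1L, n, by = block)) {
      e <- min(n, s + block - 1L)
      d2 <- outer(xs[s:e], xs, "-")^2 + outer(ys[s:e], ys, "-")^2
      w <- exp(-d2 / (2 * sigma2))
      out[s:e, ] <- (w %*% fm) / rowSums(w)
    }
    colnames(out) <- paste0(features, "_sm", r)
    for (cn in colnames(out)) detections[[cn]] <- as.numeric(out[, cn])
  }
  detections
}

#' Measure features on ground-truth nuclei as labeled training objects
#'
#' Treats the ground-truth nucleus outlines of a rendered synthetic scene
#' as annotated objects: measures the full shape/stain feature set on the
#' rendered image, applies spatial feature smoothing, and attaches the
#' two-class training label (`"tumour"` vs `"other"`). This mirrors
#' manually annotated training objects in a real workflow and is the
#' standard way to assemble classifier training material from synthetic
#' scenes.
#'
#' @param truth Ground-truth tibble from [simulate_nuclei()].
#' @param od A `ki67_od` of the rendered scene.
#' @param concentrations A `ki67_conc` from [deconvolve()].
#' @param radii_um Smoothing radii (default `c(25, 50, 100)`).
#' @return A labeled detection tibble ready for [train_classifier()].
#' @export
measure_truth_features <- function(truth, od, concentrations,
                                   radii_um = c(25, 50, 100)) {
  det <- tibble::tibble(id = truth$id, x_um = truth$x_um,
                        y_um = truth$y_um, polygon = truth$polygon)
  det <- measure_features(det, od, concentrations)
  det <- smooth_features(det, radii_um = radii_um)
  det$class_label <- ifelse(truth$class == "tumour", "tumour", "other")
  det
}

#' Match detections to ground-truth nuclei and compute detection accuracy
#'
#' Greedy mutual-nearest matching: candidate pairs within `radius_um` are
#' sorted by centroid distance and matched one-to-one.
#'
#' @param detections Detection tibble (`x_um`, `y_um`).
#' @param truth Ground-truth tibble from [simulate_nuclei()].
#' @param radius_um Maximum centroid distance for a match (default 3).
#' @return `match_truth()`: the detections with `truth_id`, `truth_class`,
#'   `truth_positive` columns (`NA` for unmatched). `detection_f1()`: a
#'   one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `mean_centroid_error_um`.
#' @export
match_truth <- function(detections, truth, radius_um = 3) {
  n <- nrow(detections); m <- nrow(truth)
  detections$truth_id <- rep(NA_integer_, n)
  detections$truth_class <- rep(NA_character_, n)
  detections$truth_positive <- rep(NA, n)
  if (n == 0 || m == 0) return(detections)
  pairs <- NULL
  for (i in seq_len(n)) {
    d <- sqrt((truth$x_um - detections$x_um[i])^2 +
                (truth$y_um - detections$y_um[i])^2)
    j <- which(d <= radius_um)
    if (length(j))
      pairs <- rbind(pairs, cbind(i = i, j = j, d = d[j]))
  }
  if (is.null(pairs)) return(detections)
  pairs <- pairs[order(pairs[, "d"]), , drop = FALSE]
  used_i <- logical(n); used_j <- logical(m)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, "i"]; j <- pairs[k, "j"]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    detections$truth_id[i] <- truth$id[j]
    detections$truth_class[i] <- truth$class[j]
    detections$truth_positive[i] <- truth$ki67_positive[j]
  }
  detections
}

#' @rdname match_truth
#' @export
detection_f1 <- function(detections, truth, radius_um = 3) {
  md <- match_truth(detections, truth, radius_um)
  tp <- sum(!is.na(md$truth_id))
  fp <- nrow(md) - tp
  fn <- nrow(truth) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  err <- NA_real_
  if (tp > 0) {
    mi <- which(!is.na(md$truth_id))
    ti <- match(md$truth_id[mi], truth$id)
    err <- mean(sqrt((md$x_um[mi] - truth$x_um[ti])^2 +
                       (md$y_um[mi] - truth$y_um[ti])^2))
  }
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1,
                 mean_centroid_error_um = err)
}
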