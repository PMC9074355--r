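#' Read and write RGB images (PNG or 8-bit TIFF)
#'
#' Images are `(nx, ny, 3)` arrays with intensities in `[0, 255]`, x
#' increasing rightward and y downward from the top-left origin; the file
#' format is chosen from the extension (`.png`, `.tif`, `.tiff`).
#'
#' @param image RGB array as produced by [render_scene()].
#' @param path File path.
#' @param pixel_size_um Pixel size attached to the image on read.
#' @return `write_image` returns `path` invisibly; `read_image` the array.
#' @export
write_image <- function(image, path) {
  stopifnot(is.array(image), length(dim(image)) == 3)
  out <- aperm(image, c(2, 1, 3)) / 255
  out[out < 0] <- 0; out[out > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(out, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(out, path, bits.per.sample = 8)
  } else stop("unsupported image extension `.", ext, "`")
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image extension `.", ext, "`")
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  img <- aperm(raw[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255
  attr(img, "pixel_size_um") <- pixel_size_um
  img
}

#' Write a 32-bit float raster (e.g. heat map or concentration) as TIFF
#' @param raster Numeric matrix indexed (x, y).
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(raster, path) {
  tiff::writeTIFF(t(raster), path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

list_cols <- function(df) names(df)[vapply(df, is.list, logical(1))]

close_ring <- function(poly) {
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  unname(poly)
}

#' Write / read detections as a GeoJSON FeatureCollection
#'
#' One polygon feature per nucleus with every scalar measurement in the
#' feature's `properties` map; coordinates are micrometres with y
#' increasing downward. The layout matches cell-detection exports of
#' digital-pathology tools, so files round-trip through them.
#'
#' @param detections Detection tibble with a `polygon` list-column.
#' @param path Output `.geojson`/`.json` path.
#' @return `write_detections_geojson` returns `path` invisibly;
#'   `read_detections_geojson` the detection tibble.
#' @export
write_detections_geojson <- function(detections, path) {
  lc <- list_cols(detections)
  props <- detections[setdiff(names(detections), lc)]
  features <- lapply(seq_len(nrow(detections)), function(i) {
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = list(close_ring(detections$polygon[[i]]))
      ),
      properties = as.list(props[i, , drop = FALSE])
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_detections_geojson
#' @export
read_detections_geojson <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$type) || x$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- x$features
  if (length(feats) == 0)
    return(tibble::tibble(id = integer(), polygon = list()))
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    if (is.null(f$geometry) || is.null(f$geometry$coordinates))
      stop("feature ", i, " has no polygon geometry")
    pr <- f$properties
    pr[vapply(pr, is.null, logical(1))] <- NA
    tibble::as_tibble(pr)
  })
  out <- dplyr::bind_rows(rows)
  out$polygon <- lapply(seq_along(feats), function(i) {
    ring <- feats[[i]]$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v)
      c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
    colnames(m) <- c("x", "y")
    # drop the closing vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), ]
    m
  })
  out
}

#' Write / read detections as flat CSV (one row per nucleus)
#'
#' Polygon list-columns are dropped; all scalar measurements are kept.
#'
#' @param detections Detection tibble.
#' @param path CSV path.
#' @return `write_detections_csv` returns `path` invisibly;
#'   `read_detections_csv` a tibble.
#' @export
write_detections_csv <- function(detections, path) {
  flat <- detections[setdiff(names(detections), list_cols(detections))]
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

cohort_required_cols <- c("patient_id", "time_years", "event")

#' Write / read a cohort table as CSV
#'
#' Schema: `patient_id, true_ki67, grade, mitoses_10hpf, subtype,
#' time_years, event` with `event` one of censored / bc_death /
#' other_death. Missing required columns raise an error naming them.
#'
#' @param records Cohort tibble from [simulate_cohort()].
#' @param path CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a tibble
#'   with `event` as a factor.
#' @export
write_cohort <- function(records, path) {
  miss <- setdiff(cohort_required_cols, names(records))
  if (length(miss))
    stop("cohort lacks required column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_required_cols, names(df))
  if (length(miss))
    stop("cohort file lacks required column(s): ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$event), c("censored", "bc_death", "other_death"))
  if (length(bad))
    stop("unknown event code(s): ", paste(bad, collapse = ", "))
  df$event <- factor(df$event,
                     levels = c("censored", "bc_death", "other_death"))
  tibble::as_tibble(df)
}

#' Read / write a scene configuration as strict YAML
#'
#' Unknown keys are an error, so typos in config files fail loudly rather
#' than silently falling back to defaults.
#'
#' @param path YAML path.
#' @param config A [scene_config()] (or [cohort_config()]).
#' @return The parsed config object; writers return `path` invisibly.
#' @export
read_scene_config <- function(path) {
  x <- yaml::read_yaml(path)
  allowed <- names(formals(scene_config))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown scene config key(s): ", paste(unknown, collapse = ", "))
  do.call(scene_config, x)
}

#' @rdname read_scene_config
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname read_scene_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  allowed <- names(formals(cohort_config))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown cohort config key(s): ", paste(unknown, collapse = ", "))
  do.call(cohort_config, x)
}

#' @rdname read_scene_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
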