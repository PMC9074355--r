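#' Configuration for a synthetic stained-tissue scene
#'
#' Describes a rectangular H-DAB-stained tissue scene with three nucleus
#' classes (epithelial tumour, stromal, lymphocyte), a spatially varying
#' Ki-67 positivity field (uniform base plus Gaussian hotspot bumps) and
#' the rendering parameters. The defaults emulate a heterogeneous invasive
#' breast-carcinoma field at 0.23 um/pixel scanner resolution: large
#' round-to-oval tumour nuclei, elongated stromal nuclei, small round
#' dense lymphocytes, a modest baseline proliferation fraction and one
#' proliferation hotspot.
#'
#' @param width_um,height_um Physical scene size in micrometres.
#' @param pixel_size_um Rendering resolution (default 0.23 um/pixel).
#' @param n_tumour,n_stroma,n_lymph Nucleus counts per class.
#' @param base_positivity Baseline probability that a tumour nucleus is
#'   Ki-67 positive, in `[0, 1]`.
#' @param hotspots List of hotspots, each a list with `center` (x, y in um),
#'   `radius` (um) and `peak_positivity`. The positivity field is
#'   `base + (peak - base) * exp(-d^2 / (2 * (radius/2)^2))` summed over
#'   hotspots and clipped to `[0, 1]`.
#' @param nucleus_size_params Per-class morphology: list with entries
#'   `tumour`, `stroma`, `lymph`, each a list with `area_mean`, `area_sd`,
#'   `area_min`, `area_max` (um^2), `ratio_range` (major/minor axis ratio)
#'   and `spacing` (hard-core minimum centre distance, um).
#' @param stain_params Per-class stain concentrations: hematoxylin mean/sd
#'   per class and DAB mean/sd for Ki-67-positive tumour nuclei (OD units
#'   along the unit stain vectors).
#' @param noise_sd Additive Gaussian RGB noise (intensity units).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `scene_config` object (validated list).
#' @export
scene_config <- function(width_um = 400, height_um = 400,
                         pixel_size_um = 0.23,
                         n_tumour = 700, n_stroma = 250, n_lymph = 150,
                         base_positivity = 0.15,
                         hotspots = list(list(center = c(110, 110),
                                              radius = 70,
                                              peak_positivity = 0.75)),
                         nucleus_size_params = default_nucleus_size_params(),
                         stain_params = default_stain_params(),
                         noise_sd = 2,
                         seed = 1L) {
  stopifnot(width_um > 0, height_um > 0, pixel_size_um > 0,
            n_tumour >= 0, n_stroma >= 0, n_lymph >= 0,
            noise_sd >= 0)
  if (base_positivity < 0 || base_positivity > 1)
    stop("`base_positivity` must lie in [0, 1]")
  for (h in hotspots) {
    if (!all(c("center", "radius", "peak_positivity") %in% names(h)))
      stop("each hotspot needs fields `center`, `radius`, `peak_positivity`")
    if (h$radius <= 0) stop("hotspot radius must be positive")
    if (h$peak_positivity < base_positivity)
      stop("hotspot `peak_positivity` must be >= `base_positivity`")
    if (h$peak_positivity > 1) stop("`peak_positivity` must be <= 1")
  }
  structure(
    list(width_um = width_um, height_um = height_um,
         pixel_size_um = pixel_size_um,
         n_tumour = n_tumour, n_stroma = n_stroma, n_lymph = n_lymph,
         base_positivity = base_positivity, hotspots = hotspots,
         nucleus_size_params = nucleus_size_params,
         stain_params = stain_params,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' @rdname scene_config
#' @export
default_nucleus_size_params <- function() {
  list(
    tumour = list(area_mean = 55, area_sd = 12, area_min = 28, area_max = 110,
                  ratio_range = c(1.0, 1.6), spacing = 9.5),
    stroma = list(area_mean = 30, area_sd = 7, area_min = 14, area_max = 60,
                  ratio_range = c(2.2, 3.5), spacing = 8.0),
    lymph  = list(area_mean = 16, area_sd = 2.5, area_min = 11, area_max = 24,
                  ratio_range = c(1.0, 1.25), spacing = 6.5)
  )
}

#' @rdname scene_config
#' @export
default_stain_params <- function() {
  list(
    hematoxylin = list(tumour = c(mean = 0.55, sd = 0.08),
                       stroma = c(mean = 0.50, sd = 0.08),
                       lymph  = c(mean = 0.80, sd = 0.10)),
    hematoxylin_min = 0.25,
    dab_positive = c(mean = 0.60, sd = 0.12),
    dab_min = 0.30,
    # DAB chromogen largely displaces the blue counterstain in positive
    # nuclei, which therefore appear brown rather than blue-brown
    dab_displacement = 0.05
  )
}

# Evaluate the positivity field at points (x, y) in um.
positivity_field <- function(x, y, config) {
  p <- rep(config$base_positivity, length(x))
  for (h in config$hotspots) {
    sigma <- h$radius / 2
    d2 <- (x - h$center[1])^2 + (y - h$center[2])^2
    p <- p + (h$peak_positivity - config$base_positivity) *
      exp(-d2 / (2 * sigma^2))
  }
  pmin(1, pmax(0, p))
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0
  while (length(bad) && tries < 100) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    tries <- tries + 1
  }
  pmin(hi, pmax(lo, x))
}

ellipse_polygon <- function(cx, cy, r_major, r_minor, theta, n = 32) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  # counterclockwise in a y-down coordinate frame
  px <- r_major * cos(tt); py <- r_minor * sin(tt)
  cbind(x = cx + px * cos(theta) - py * sin(theta),
        y = cy + px * sin(theta) + py * cos(theta))
}

#' Place ground-truth nuclei for a synthetic scene
#'
#' Places tumour, stromal and lymphocyte nuclei by a hard-core (minimum
#' centre distance) point process, draws per-class elliptical morphology,
#' and draws Ki-67 positivity of tumour nuclei Bernoulli from the scene's
#' positivity field (base + hotspot bumps). Stain concentrations are drawn
#' per nucleus: every nucleus carries hematoxylin; Ki-67-positive tumour
#' nuclei additionally carry DAB.
#'
#' @param config A [scene_config()].
#' @param polygons Build the per-nucleus `polygon` list-column (default
#'   `TRUE`; skip for large point-pattern-only simulations).
#' @return A tibble of ground-truth nuclei with columns `id`, `class`
#'   (tumour/stroma/lymph), `x_um`, `y_um`, `r_major_um`, `r_minor_um`,
#'   `theta`, `area_um2`, `ki67_positive`, `dab`, `hematoxylin` and a
#'   `polygon` list-column (closed counterclockwise vertex matrices, um).
#' @export
simulate_nuclei <- function(config, polygons = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  with_local_seed(config$seed, simulate_nuclei_impl(config, polygons))
}

simulate_nuclei_impl <- function(config, polygons = TRUE) {
  sp <- config$nucleus_size_params
  classes <- c(rep("tumour", config$n_tumour),
               rep("stroma", config$n_stroma),
               rep("lymph", config$n_lymph))
  n <- length(classes)
  if (n == 0) return(empty_truth())

  spacing <- vapply(sp, function(s) s$spacing, numeric(1))[
    c(tumour = "tumour", stroma = "stroma", lymph = "lymph")[classes]]
  # shuffle placement order so no class is systematically squeezed out
  ord <- sample.int(n)
  classes <- classes[ord]; spacing <- spacing[ord]

  # draw morphology first so placement can limit deep overlap
  draw_class <- function(cls) {
    idx <- which(classes == cls)
    m <- sp[[cls]]
    k <- length(idx)
    if (k == 0) return(NULL)
    area <- rtrunc_norm(k, m$area_mean, m$area_sd, m$area_min, m$area_max)
    ratio <- stats::runif(k, m$ratio_range[1], m$ratio_range[2])
    r_minor <- sqrt(area / (pi * ratio))
    r_major <- r_minor * ratio
    theta <- stats::runif(k, 0, pi)
    list(idx = idx, area = area, r_major = r_major, r_minor = r_minor,
         theta = theta)
  }
  area <- r_major <- r_minor <- theta <- numeric(n)
  for (cls in c("tumour", "stroma", "lymph")) {
    d <- draw_class(cls)
    if (is.null(d)) next
    area[d$idx] <- d$area; r_major[d$idx] <- d$r_major
    r_minor[d$idx] <- d$r_minor; theta[d$idx] <- d$theta
  }

  xs <- numeric(n); ys <- numeric(n)
  margin <- 6  # keep nuclei inside the frame
  placed <- 0L
  attempts <- 0L; max_attempts <- 400L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " nuclei at the requested hard-core ",
           "spacing in a ", config$width_um, " x ", config$height_um,
           " um scene (placed ", placed, "); reduce counts or spacing")
    x <- stats::runif(1, margin, config$width_um - margin)
    y <- stats::runif(1, margin, config$height_um - margin)
    if (placed > 0L) {
      i <- seq_len(placed)
      k <- placed + 1L
      # hard-core class spacing; touching pairs allowed, deep merges not
      req <- pmax((spacing[i] + spacing[k]) / 2,
                  0.8 * (r_major[i] + r_major[k]))
      if (any((xs[i] - x)^2 + (ys[i] - y)^2 < req^2)) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }

  st <- config$stain_params
  hem_par <- st$hematoxylin[c(tumour = "tumour", stroma = "stroma",
                              lymph = "lymph")[classes]]
  hem <- vapply(seq_len(n), function(i) {
    p <- hem_par[[i]]
    rtrunc_norm(1, p["mean"], p["sd"], st$hematoxylin_min, 1.5)
  }, numeric(1))

  p_field <- positivity_field(xs, ys, config)
  positive <- classes == "tumour" & stats::runif(n) < p_field
  dab <- numeric(n)
  if (any(positive)) {
    dab[positive] <- rtrunc_norm(sum(positive), st$dab_positive["mean"],
                                 st$dab_positive["sd"], st$dab_min, 1.5)
    hem[positive] <- hem[positive] * (st$dab_displacement %||% 1)
  }

  poly <- if (polygons) {
    lapply(seq_len(n), function(i)
      ellipse_polygon(xs[i], ys[i], r_major[i], r_minor[i], theta[i]))
  } else {
    vector("list", n)
  }

  tibble::tibble(
    id = seq_len(n),
    class = classes,
    x_um = xs, y_um = ys,
    r_major_um = r_major, r_minor_um = r_minor, theta = theta,
    area_um2 = area,
    ki67_positive = positive,
    dab = dab, hematoxylin = hem,
    polygon = poly
  )
}

empty_truth <- function() {
  tibble::tibble(
    id = integer(), class = character(),
    x_um = numeric(), y_um = numeric(),
    r_major_um = numeric(), r_minor_um = numeric(), theta = numeric(),
    area_um2 = numeric(), ki67_positive = logical(),
    dab = numeric(), hematoxylin = numeric(),
    polygon = list()
  )
}

# Rasterize per-nucleus stain concentrations onto the pixel grid.
# Overlapping nuclei combine by per-pixel maximum (opaque chromatin).
concentration_rasters <- function(nuclei, width_um, height_um, pixel_size_um) {
  nx <- ceiling(width_um / pixel_size_um)
  ny <- ceiling(height_um / pixel_size_um)
  hem <- matrix(0, nx, ny)
  dab <- matrix(0, nx, ny)
  for (i in seq_len(nrow(nuclei))) {
    cx <- nuclei$x_um[i]; cy <- nuclei$y_um[i]
    a <- nuclei$r_major_um[i]; b <- nuclei$r_minor_um[i]
    th <- nuclei$theta[i]
    r <- max(a, b)
    i0 <- max(1L, floor((cx - r) / pixel_size_um))
    i1 <- min(nx, ceiling((cx + r) / pixel_size_um))
    j0 <- max(1L, floor((cy - r) / pixel_size_um))
    j1 <- min(ny, ceiling((cy + r) / pixel_size_um))
    if (i1 < i0 || j1 < j0) next
    px <- (seq(i0, i1) - 0.5) * pixel_size_um - cx
    py <- (seq(j0, j1) - 0.5) * pixel_size_um - cy
    gx <- matrix(px, length(px), length(py))
    gy <- matrix(py, length(px), length(py), byrow = TRUE)
    u <- gx * cos(th) + gy * sin(th)
    v <- -gx * sin(th) + gy * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(inside)) next
    sub_h <- hem[i0:i1, j0:j1]
    sub_h[inside] <- pmax(sub_h[inside], nuclei$hematoxylin[i])
    hem[i0:i1, j0:j1] <- sub_h
    if (nuclei$dab[i] > 0) {
      sub_d <- dab[i0:i1, j0:j1]
      sub_d[inside] <- pmax(sub_d[inside], nuclei$dab[i])
      dab[i0:i1, j0:j1] <- sub_d
    }
  }
  list(hematoxylin = hem, dab = dab)
}

#' Render ground-truth nuclei to an RGB brightfield image
#'
#' Renders the Beer-Lambert transmission model: per pixel and channel,
#' `I_c = i0 * 10^(-(c_hem * v_hem,c + c_dab * v_dab,c))`, where the
#' concentration rasters are rasterized nucleus ellipses, plus optional
#' additive Gaussian noise, clipped to `[0, i0]`.
#'
#' @param nuclei Ground-truth nucleus tibble from [simulate_nuclei()].
#' @param width_um,height_um Scene size.
#' @param profile A [stain_profile()].
#' @param pixel_size_um Pixel size in um.
#' @param noise_sd Additive Gaussian RGB noise SD (intensity units); 0 for
#'   a pristine render.
#' @param return_concentrations If `TRUE`, attach the ground-truth
#'   concentration rasters as attribute `"concentrations"`.
#' @return An (nx, ny, 3) numeric array with intensities in `[0, 255]` and
#'   attribute `pixel_size_um`.
#' @export
render_scene <- function(nuclei, width_um, height_um,
                         profile = stain_profile(),
                         pixel_size_um = 0.23, noise_sd = 0,
                         return_concentrations = FALSE) {
  stopifnot(inherits(profile, "stain_profile"))
  conc <- concentration_rasters(nuclei, width_um, height_um, pixel_size_um)
  nx <- nrow(conc$hematoxylin); ny <- ncol(conc$hematoxylin)
  img <- array(0, dim = c(nx, ny, 3))
  for (c in 1:3) {
    od_c <- conc$hematoxylin * profile$hematoxylin[c] +
      conc$dab * profile$dab[c]
    img[, , c] <- profile$i0 * 10^(-od_c)
  }
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sd)
    img[img < 0] <- 0
    img[img > profile$i0] <- profile$i0
  }
  attr(img, "pixel_size_um") <- pixel_size_um
  if (return_concentrations) attr(img, "concentrations") <- conc
  img
}

#' Simulate a full synthetic scene: ground truth plus rendered image
#'
#' Convenience wrapper: [simulate_nuclei()] then [render_scene()] under a
#' single seed, so identical config + seed reproduces the scene bit for bit.
#'
#' @param config A [scene_config()].
#' @param profile A [stain_profile()] used for rendering.
#' @return A list with `image` (RGB array), `nuclei` (ground-truth tibble)
#'   and `config`.
#' @export
simulate_scene <- function(config, profile = stain_profile()) {
  stopifnot(inherits(config, "scene_config"))
  with_local_seed(config$seed, {
    nuclei <- simulate_nuclei_impl(config)
    image <- render_scene(nuclei, config$width_um, config$height_um,
                          profile = profile,
                          pixel_size_um = config$pixel_size_um,
                          noise_sd = config$noise_sd)
    list(image = image, nuclei = nuclei, config = config)
  })
}
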