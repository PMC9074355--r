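#' Stain profile for H-DAB colour deconvolution
#'
#' A stain profile holds the unit optical-density (OD) vectors of
#' hematoxylin, DAB and a residual stain, plus the white point `i0`. It is
#' the linear basis for colour deconvolution: per pixel, the OD vector is
#' modelled as `OD = c_h * v_h + c_dab * v_dab + c_res * v_res` and the
#' concentrations `c` are recovered by inverting the 3x3 stain matrix.
#'
#' The default vectors are the widely used published H-DAB basis
#' (hematoxylin roughly (0.65, 0.70, 0.29), DAB roughly (0.27, 0.57, 0.78));
#' the residual defaults to the normalized cross product of the two, so the
#' matrix is always invertible.
#'
#' @param hematoxylin,dab Numeric length-3 nonnegative per-channel OD
#'   vectors; normalized to unit L2 norm internally.
#' @param residual Optional third stain vector; default is the normalized
#'   cross product of `hematoxylin` and `dab`.
#' @param i0 White point intensity (default 255 for 8-bit images).
#' @return An object of class `stain_profile`: list with unit vectors
#'   `hematoxylin`, `dab`, `residual`, the white point `i0`, and the
#'   condition number `kappa` of the stain matrix.
#' @examples
#' p <- stain_profile()
#' p$kappa
#' @export
stain_profile <- function(hematoxylin = c(0.65, 0.70, 0.29),
                          dab = c(0.27, 0.57, 0.78),
                          residual = NULL,
                          i0 = 255) {
  check_stain_vec <- function(v, name) {
    if (!is.numeric(v) || length(v) != 3 || any(!is.finite(v)))
      stop("stain vector `", name, "` must be a finite numeric 3-vector")
    if (any(v < 0))
      stop("stain vector `", name, "` must be nonnegative")
    n <- sqrt(sum(v^2))
    if (n == 0) stop("stain vector `", name, "` must be nonzero")
    v / n
  }
  h <- check_stain_vec(hematoxylin, "hematoxylin")
  d <- check_stain_vec(dab, "dab")
  if (is.null(residual)) {
    # orthogonal complement of the two chromogens; may carry negative
    # channel weights (it is a mathematical residual, not a dye)
    r <- cross3(h, d)
    if (sqrt(sum(r^2)) < 1e-8)
      stop("hematoxylin and DAB vectors are collinear; cannot derive a residual")
    r <- r / sqrt(sum(r^2))
  } else {
    if (!is.numeric(residual) || length(residual) != 3 ||
        any(!is.finite(residual)))
      stop("stain vector `residual` must be a finite numeric 3-vector")
    n <- sqrt(sum(residual^2))
    if (n == 0) stop("stain vector `residual` must be nonzero")
    r <- residual / n
  }
  m <- stain_matrix_of(h, d, r)
  kap <- kappa(m, exact = TRUE)
  if (!is.finite(kap) || kap > 1e8)
    stop("stain matrix is singular or nearly so (condition number ",
         format(kap), "); check for collinear stain vectors")
  structure(
    list(hematoxylin = h, dab = d, residual = r,
         i0 = i0, kappa = kap),
    class = "stain_profile"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# columns = stains, rows = RGB channels
stain_matrix_of <- function(h, d, r) cbind(hematoxylin = h, dab = d, residual = r)

#' @export
print.stain_profile <- function(x, ...) {
  cat("H-DAB stain profile (white point", x$i0, ")\n")
  m <- rbind(hematoxylin = x$hematoxylin, dab = x$dab, residual = x$residual)
  colnames(m) <- c("R", "G", "B")
  print(round(m, 4))
  cat("condition number:", format(x$kappa, digits = 4), "\n")
  invisible(x)
}

#' Angular distance between two stain vectors, in degrees
#' @param a,b Numeric 3-vectors.
#' @return Angle in degrees between the directions of `a` and `b`.
#' @export
stain_angle <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

#' Convert an RGB brightfield image to optical density
#'
#' Applies the Beer-Lambert transform `OD_c = -log10(I_c / i0)` per channel.
#' Intensities are floored at one intensity unit before the log so a zero
#' pixel maps to a finite OD, and the resulting OD is clipped at 0 (pixels
#' brighter than the white point carry no stain signal).
#'
#' @param rgb A numeric array of dimension (nx, ny, 3) with intensities in
#'   `[0, i0]`, as produced by [render_scene()] or [read_image()]. A
#'   `pixel_size_um` attribute, if present, is carried through.
#' @param i0 White point (default 255).
#' @return An object of class `ki67_od`: list with `od` (nx, ny, 3 array),
#'   `od_sum` (nx, ny matrix, the per-pixel channel sum used as the
#'   detection channel), `pixel_size_um` and `i0`.
#' @examples
#' img <- array(255, dim = c(4, 4, 3))
#' od <- rgb_to_od(img)
#' max(od$od_sum)  # 0 at the white point
#' @export
rgb_to_od <- function(rgb, i0 = 255) {
  if (!is.array(rgb) || length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("`rgb` must be an (nx, ny, 3) RGB array")
  if (any(rgb < 0 | rgb > i0, na.rm = TRUE))
    stop("intensities must lie in [0, i0]")
  eps <- 1  # 8-bit quantization floor; avoids log(0)
  od <- -log10(pmax(rgb, eps) / i0)
  od[od < 0] <- 0
  structure(
    list(od = od,
         od_sum = od[, , 1] + od[, , 2] + od[, , 3],
         pixel_size_um = attr(rgb, "pixel_size_um"),
         i0 = i0),
    class = "ki67_od"
  )
}

#' Colour deconvolution of an OD image into per-stain concentrations
#'
#' Inverts the 3x3 stain matrix of `profile` and applies it per pixel:
#' `concentrations = inv(M) %*% OD`. Negative concentrations (pixels outside
#' the stain simplex, typically noise) are clipped to zero and the clipped
#' fraction is recorded.
#'
#' @param od A `ki67_od` object from [rgb_to_od()].
#' @param profile A [stain_profile()].
#' @return An object of class `ki67_conc`: list with matrices `hematoxylin`,
#'   `dab`, `residual` (concentration in OD units along each unit stain
#'   vector), `clip_fraction` (fraction of concentration values clipped at
#'   0) and `pixel_size_um`.
#' @export
deconvolve <- function(od, profile) {
  stopifnot(inherits(od, "ki67_od"), inherits(profile, "stain_profile"))
  m <- stain_matrix_of(profile$hematoxylin, profile$dab, profile$residual)
  minv <- tryCatch(solve(m), error = function(e) {
    ang_hd <- stain_angle(profile$hematoxylin, profile$dab)
    stop("singular stain profile (hematoxylin/DAB angular distance ",
         round(ang_hd, 2), " degrees); cannot deconvolve")
  })
  d <- dim(od$od)
  flat <- matrix(od$od, nrow = d[1] * d[2], ncol = 3)
  conc <- flat %*% t(minv)
  neg <- conc < 0
  clip_fraction <- mean(neg)
  conc[neg] <- 0
  structure(
    list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
         dab = matrix(conc[, 2], d[1], d[2]),
         residual = matrix(conc[, 3], d[1], d[2]),
         clip_fraction = clip_fraction,
         pixel_size_um = od$pixel_size_um),
    class = "ki67_conc"
  )
}

#' Estimate stain vectors from a stained image
#'
#' Re-estimates the hematoxylin and DAB OD vectors from the image itself,
#' in the spirit of automated stain estimation in digital-pathology
#' software. Foreground pixels (od_sum above `min_od_sum`) are assigned to
#' their dominant stain under the `default` profile (largest deconvolved
#' concentration between hematoxylin and DAB); each stain vector is then
#' re-estimated as the unit-normalized trimmed mean direction of its pixel
#' group, trimming the stated fraction at both tails per channel. The
#' residual is recomputed as the normalized cross product.
#'
#' If either stain group holds fewer than `min_pixels` pixels the default
#' profile is returned with a warning (e.g. a blank image).
#'
#' @param od A `ki67_od` object.
#' @param default Fallback/seed [stain_profile()].
#' @param min_od_sum Foreground threshold on the OD channel sum (default
#'   0.15).
#' @param percentile Fraction trimmed from each tail of each channel's OD
#'   distribution within a stain group (default 0.01).
#' @param min_pixels Minimum pixels per stain group (default 50).
#' @return A [stain_profile()] with re-estimated vectors.
#' @export
estimate_stain_vectors <- function(od, default = stain_profile(),
                                   min_od_sum = 0.15, percentile = 0.01,
                                   min_pixels = 50) {
  stopifnot(inherits(od, "ki67_od"))
  fg <- which(od$od_sum > min_od_sum)
  if (length(fg) < 2 * min_pixels) {
    warning("too few foreground pixels (", length(fg),
            "); returning the default stain profile")
    return(default)
  }
  d <- dim(od$od)
  flat <- matrix(od$od, nrow = d[1] * d[2], ncol = 3)[fg, , drop = FALSE]
  m <- stain_matrix_of(default$hematoxylin, default$dab, default$residual)
  conc <- flat %*% t(solve(m))
  grp <- ifelse(conc[, 1] >= conc[, 2], "hematoxylin", "dab")

  trimmed_dir <- function(rows) {
    # per-channel trimmed mean of unit directions, then renormalize
    dirs <- rows / sqrt(rowSums(rows^2))
    v <- apply(dirs, 2, mean, trim = percentile)
    v[v < 0] <- 0
    v / sqrt(sum(v^2))
  }
  n_h <- sum(grp == "hematoxylin"); n_d <- sum(grp == "dab")
  if (n_h < min_pixels || n_d < min_pixels) {
    warning("too few pixels in a stain group (hematoxylin ", n_h,
            ", DAB ", n_d, "); returning the default stain profile")
    return(default)
  }
  v_h <- trimmed_dir(flat[grp == "hematoxylin", , drop = FALSE])
  v_d <- trimmed_dir(flat[grp == "dab", , drop = FALSE])
  stain_profile(hematoxylin = v_h, dab = v_d, i0 = default$i0)
}

#' Write / read a stain profile as a small YAML text file
#' @param profile A [stain_profile()].
#' @param path File path.
#' @return `write_stain_profile` returns `path` invisibly;
#'   `read_stain_profile` returns a [stain_profile()].
#' @export
write_stain_profile <- function(profile, path) {
  stopifnot(inherits(profile, "stain_profile"))
  yaml::write_yaml(list(
    hematoxylin = as.numeric(profile$hematoxylin),
    dab = as.numeric(profile$dab),
    residual = as.numeric(profile$residual),
    i0 = profile$i0
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_stain_profile
#' @export
read_stain_profile <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("hematoxylin", "dab", "residual", "i0")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("stain profile file missing field(s): ", paste(miss, collapse = ", "))
  stain_profile(x$hematoxylin, x$dab, x$residual, i0 = x$i0)
}
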