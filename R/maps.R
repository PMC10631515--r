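#' RNFLT thickness map
#'
#' Container for a dense peripapillary retinal nerve fiber layer thickness
#' (RNFLT) grid as produced by spectral-domain OCT, together with its physical
#' geometry and acquisition metadata. Values are in micrometers; the default
#' geometry is a 200 x 200 grid covering a 6 x 6 mm region (pixel pitch
#' 0.03 mm/px).
#'
#' @param values numeric matrix of thickness values in um. All values must be
#'   finite and in `[0, 500]`.
#' @param pixel_pitch physical size of one pixel in mm (> 0).
#' @param patient_id,eye_id opaque identifiers.
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param acquisition_date a `Date` (or string coercible to one).
#' @param signal_strength optional device signal strength.
#' @return An object of class `rnflt_map`: the values matrix with geometry and
#'   identity attributes.
#' @examples
#' m <- rnflt_map(matrix(100, 50, 50), pixel_pitch = 0.12)
#' dim(m)
#' @export
rnflt_map <- function(values, pixel_pitch = 0.03,
                      patient_id = NA_character_, eye_id = NA_character_,
                      laterality = c("OD", "OS"),
                      acquisition_date = NA, signal_strength = NA_real_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("thickness values must all be finite", call. = FALSE)
  if (any(values < 0) || any(values > 500))
    stop("thickness values must lie in [0, 500] um", call. = FALSE)
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0)
    stop("`pixel_pitch` must be a single positive number (mm/px)", call. = FALSE)
  laterality <- if (all(is.na(laterality))) NA_character_ else match.arg(laterality)
  if (!is.na(acquisition_date[1L])) acquisition_date <- as.Date(acquisition_date)
  structure(values,
            pixel_pitch = pixel_pitch,
            patient_id = as.character(patient_id),
            eye_id = as.character(eye_id),
            laterality = laterality,
            acquisition_date = acquisition_date,
            signal_strength = as.numeric(signal_strength),
            class = c("rnflt_map", "matrix", "array"))
}

#' @export
print.rnflt_map <- function(x, ...) {
  cat(sprintf("RNFLT map: %d x %d px, pitch %.4g mm/px (%.3g x %.3g mm)\n",
              nrow(x), ncol(x), attr(x, "pixel_pitch"),
              nrow(x) * attr(x, "pixel_pitch"), ncol(x) * attr(x, "pixel_pitch")))
  cat(sprintf("  patient %s, eye %s (%s), acquired %s\n",
              attr(x, "patient_id"), attr(x, "eye_id"),
              attr(x, "laterality"),
              format(attr(x, "acquisition_date"))))
  cat(sprintf("  thickness: mean %.1f um, range [%.1f, %.1f] um\n",
              mean(x), min(x), max(x)))
  invisible(x)
}

#' @export
summary.rnflt_map <- function(object, disc = NULL, floor_um = 50, ...) {
  ar <- if (is.null(disc)) NA_real_ else
    artifact_ratio(artifact_mask(object, disc, floor_um), disc)
  out <- list(dim = dim(object), pixel_pitch = attr(object, "pixel_pitch"),
              mean_um = mean(object), sd_um = stats::sd(object),
              range_um = range(object), artifact_ratio = ar,
              quality = if (is.na(ar)) NA_character_ else classify_quality(ar))
  class(out) <- "summary.rnflt_map"
  out
}

#' @export
print.summary.rnflt_map <- function(x, ...) {
  cat(sprintf("%d x %d RNFLT map, mean %.1f (sd %.1f) um, range [%.1f, %.1f]\n",
              x$dim[1], x$dim[2], x$mean_um, x$sd_um,
              x$range_um[1], x$range_um[2]))
  if (!is.na(x$artifact_ratio))
    cat(sprintf("artifact ratio %.2f%% -> %s quality\n",
                100 * x$artifact_ratio, x$quality))
  invisible(x)
}

#' @export
plot.rnflt_map <- function(x, main = "RNFLT (um)", ...) {
  z <- t(unclass(x))[, nrow(x):1, drop = FALSE]
  graphics::image(z, useRaster = TRUE, axes = FALSE, main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

map_center_mm <- function(map) {
  attr(map, "pixel_pitch") * (dim(map) + 1) / 2
}

#' Optic-disc mask
#'
#' Boolean grid marking pixels belonging to the optic disc region, which is
#' excluded from artifact detection and from the artifact-ratio denominator.
#' The default is a filled circle of radius 0.8 mm at the grid center
#' (disc area ~2 mm^2, matching typical adult disc area); supply `mask` to
#' override with any delineation.
#'
#' @param map an [rnflt_map()] fixing shape and pixel pitch.
#' @param center disc center as `(row, col)` in pixel coordinates
#'   (default: grid center).
#' @param radius_mm disc radius in mm for the default circular mask.
#' @param mask optional logical matrix (same shape as `map`) overriding the
#'   circular default.
#' @return Object of class `disc_mask` (logical matrix).
#' @export
disc_mask <- function(map, center = NULL, radius_mm = 0.8, mask = NULL) {
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(map)))
      stop("`mask` must be a logical matrix with the map's shape", call. = FALSE)
    return(structure(mask, class = c("disc_mask", "matrix", "array")))
  }
  pitch <- attr(map, "pixel_pitch")
  if (is.null(center)) center <- (dim(map) + 1) / 2
  r_px <- radius_mm / pitch
  rr <- row(map) - center[1L]
  cc <- col(map) - center[2L]
  m <- (rr * rr + cc * cc) <= r_px * r_px
  structure(m, center = center, radius_mm = radius_mm,
            class = c("disc_mask", "matrix", "array"))
}

#' Artifact mask: sub-floor thickness outside the disc
#'
#' Flags segmentation-failure artifacts: pixels whose RNFLT value falls below
#' the physiological measurement floor (default 50 um), excluding the optic
#' disc region. The map's values are left untouched -- artifact pixels keep
#' their original (sub-floor) thickness.
#'
#' @param map an [rnflt_map()].
#' @param disc a [disc_mask()] of the same shape.
#' @param floor_um measurement floor in um (> 0); values strictly below it are
#'   artifacts.
#' @return Object of class `artifact_mask` (logical matrix) with attribute
#'   `floor_um`.
#' @examples
#' m <- rnflt_map(matrix(100, 20, 20), pixel_pitch = 0.3)
#' d <- disc_mask(m, radius_mm = 0.9)
#' sum(artifact_mask(m, d))  # 0: nothing below the floor
#' @export
artifact_mask <- function(map, disc, floor_um = 50) {
  if (!identical(dim(map), dim(disc)))
    stop("map and disc mask shapes differ", call. = FALSE)
  if (!is.numeric(floor_um) || length(floor_um) != 1L || floor_um <= 0)
    stop("`floor_um` must be a single positive number", call. = FALSE)
  m <- (unclass(map) < floor_um) & !unclass(disc)
  structure(m, floor_um = floor_um,
            class = c("artifact_mask", "matrix", "array"))
}

#' Artifact ratio (AR)
#'
#' Fraction of the map affected by artifacts: artifact area divided by map
#' area excluding the optic disc region.
#'
#' @param artifact an [artifact_mask()].
#' @param disc the matching [disc_mask()].
#' @return A fraction in `[0, 1]`.
#' @export
artifact_ratio <- function(artifact, disc) {
  if (!identical(dim(artifact), dim(disc)))
    stop("artifact and disc mask shapes differ", call. = FALSE)
  denom <- length(disc) - sum(disc)
  if (denom == 0L)
    stop("disc mask covers the entire grid; artifact ratio undefined",
         call. = FALSE)
  sum(artifact & !disc) / denom
}

#' Map quality class from artifact ratio
#'
#' Maps with AR < 2% are high quality (usable as artifact-free ground truth);
#' maps with AR > 5% are low quality (artifact-pattern donors); the rest are
#' intermediate.
#'
#' @param ar artifact ratio(s) in `[0, 1]`; vectorized.
#' @return Character vector: `"high"`, `"intermediate"` or `"low"`.
#' @export
classify_quality <- function(ar) {
  stopifnot(is.numeric(ar), all(ar >= 0 & ar <= 1))
  ifelse(ar < 0.02, "high", ifelse(ar > 0.05, "low", "intermediate"))
}

#' Artifact-ratio stratum membership
#'
#' Stratifies maps by AR the way correction accuracy is reported: the
#' `<=10%` and `>10%` strata partition the data, while `>20%` is nested inside
#' `>10%`. Boundary values (exactly 10%, exactly 20%) go to the `<=` side.
#'
#' @param ar artifact ratio(s) in `[0, 1]`; vectorized.
#' @return A logical matrix with one row per `ar` and columns
#'   `le10`, `gt10`, `gt20`.
#' @export
ar_stratum <- function(ar) {
  stopifnot(is.numeric(ar), all(ar >= 0 & ar <= 1))
  cbind(le10 = ar <= 0.10, gt10 = ar > 0.10, gt20 = ar > 0.20)
}

#' Circle-scan geometry
#'
#' Sampling geometry of the standard circumpapillary scan circle
#' (3.46 mm diameter) centered on the optic disc. The center defaults to the
#' disc-mask centroid, falling back to the grid center when no disc mask is
#' given. Samples run counter-clockwise from `start_angle` (radians, measured
#' from the +column axis with rows pointing down, i.e. the usual image
#' convention); the default starts at the temporal side for a right eye and
#' yields the TSNIT ordering.
#'
#' @param map an [rnflt_map()].
#' @param disc optional [disc_mask()]; its centroid becomes the circle center.
#' @param diameter_mm scan-circle diameter in mm.
#' @param n_samples number of angular samples (>= 4).
#' @param start_angle first sample angle in radians.
#' @param direction `+1` for counter-clockwise, `-1` for clockwise.
#' @return Object of class `circle_geometry`.
#' @export
circle_geometry <- function(map, disc = NULL, diameter_mm = 3.46,
                            n_samples = 256L, start_angle = pi,
                            direction = 1) {
  stopifnot(n_samples >= 4L, diameter_mm > 0, direction %in% c(-1, 1))
  center <- if (!is.null(disc) && any(disc)) {
    c(mean(row(disc)[disc]), mean(col(disc)[disc]))
  } else {
    (dim(map) + 1) / 2
  }
  pitch <- attr(map, "pixel_pitch")
  r_px <- (diameter_mm / 2) / pitch
  if (center[1L] - r_px < 1 || center[1L] + r_px > nrow(map) ||
      center[2L] - r_px < 1 || center[2L] + r_px > ncol(map))
    stop("scan circle does not fit inside the grid", call. = FALSE)
  structure(list(center = center, diameter_mm = diameter_mm,
                 radius_px = r_px, n_samples = as.integer(n_samples),
                 start_angle = start_angle, direction = direction),
            class = "circle_geometry")
}

#' @export
print.circle_geometry <- function(x, ...) {
  cat(sprintf(
    "circle scan: %.2f mm diameter (%.1f px radius), center (%.1f, %.1f), %d samples\n",
    x$diameter_mm, x$radius_px, x$center[1], x$center[2], x$n_samples))
  invisible(x)
}

# bilinear sampling of matrix `m` at continuous (row, col) positions;
# positions must lie inside [1, nrow] x [1, ncol]. The nested-lerp form is
# exactly constant-preserving, which keeps constant-map extraction exact.
bilinear_sample <- function(m, r, c) {
  r0 <- pmin(floor(r), nrow(m) - 1L); c0 <- pmin(floor(c), ncol(m) - 1L)
  fr <- r - r0; fc <- c - c0
  v0 <- m[cbind(r0, c0)]
  v0 <- v0 + fr * (m[cbind(r0 + 1, c0)] - v0)
  v1 <- m[cbind(r0, c0 + 1)]
  v1 <- v1 + fr * (m[cbind(r0 + 1, c0 + 1)] - v1)
  v0 + fc * (v1 - v0)
}

circle_sample_points <- function(geom) {
  i <- seq_len(geom$n_samples) - 1L
  th <- geom$start_angle + geom$direction * 2 * pi * i / geom$n_samples
  list(angles = th,
       row = geom$center[1L] - geom$radius_px * sin(th),
       col = geom$center[2L] + geom$radius_px * cos(th))
}

#' Extract the circumpapillary circle scan
#'
#' Samples the thickness map on the scan circle by bilinear interpolation,
#' giving the conventional TSNIT profile.
#'
#' @param map an [rnflt_map()].
#' @param geom a [circle_geometry()] (default: geometry derived from the map
#'   with standard parameters).
#' @return Object of class `circle_scan`: list with `thickness` (um) and
#'   `angles` (radians), each of length `n_samples`.
#' @examples
#' m <- rnflt_map(matrix(100, 200, 200))
#' cs <- extract_circle_scan(m)
#' range(cs$thickness)  # all 100
#' @export
extract_circle_scan <- function(map, geom = circle_geometry(map)) {
  stopifnot(inherits(geom, "circle_geometry"))
  p <- circle_sample_points(geom)
  th <- bilinear_sample(unclass(map), p$row, p$col)
  structure(list(thickness = th, angles = p$angles),
            class = "circle_scan")
}

#' @export
print.circle_scan <- function(x, ...) {
  cat(sprintf("circle scan: %d samples, mean %.1f um, range [%.1f, %.1f]\n",
              length(x$thickness), mean(x$thickness),
              min(x$thickness), max(x$thickness)))
  invisible(x)
}

#' @export
plot.circle_scan <- function(x, ...) {
  deg <- seq(0, 360, length.out = length(x$thickness) + 1L)[-1L]
  graphics::plot(deg, x$thickness, type = "l", xlab = "angle (deg, TSNIT)",
                 ylab = "RNFLT (um)", ...)
  invisible(x)
}
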