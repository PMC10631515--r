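#' Simulate a high-quality RNFLT map
#'
#' Generates an artifact-free peripapillary thickness map with the anatomy
#' that matters downstream: a thin background, superior and inferior arcuate
#' nerve-fiber bundles modeled as Gaussian ridges on an annulus around the
#' optic disc (reproducing the double-hump TSNIT profile on the scan circle),
#' a low-valued disc region, and the measurement floor. `severity` scales
#' bundle loss: 0 is a healthy eye, 1 removes the bundles entirely, mimicking
#' advanced glaucomatous thinning. Pixel noise is Gaussian; outside the disc
#' the map is clipped to the floor, so a simulated high-quality map always has
#' artifact ratio 0 (< 2%).
#'
#' @param size grid side in pixels (square map).
#' @param pixel_pitch mm per pixel; the default spans 6 mm regardless of
#'   `size`.
#' @param base_thickness background thickness in um.
#' @param bundle_amplitude peak bundle elevation above background, um.
#' @param bundle_angle_spread angular half-width (sd) of each bundle, radians.
#' @param severity bundle-loss fraction in `[0, 1]`.
#' @param noise_sd pixelwise Gaussian noise sd, um.
#' @param floor_um measurement floor, um.
#' @param disc_radius_mm optic-disc radius, mm.
#' @param seed integer seed; the same seed reproduces the map exactly.
#' @param patient_id,eye_id,laterality,acquisition_date metadata passed to
#'   [rnflt_map()].
#' @return List with elements `map` ([rnflt_map()]) and `disc`
#'   ([disc_mask()]).
#' @examples
#' hq <- simulate_rnflt_map(size = 64, seed = 1)
#' artifact_ratio(artifact_mask(hq$map, hq$disc), hq$disc)  # 0
#' @export
simulate_rnflt_map <- function(size = 200L, pixel_pitch = 6 / size,
                               base_thickness = 62, bundle_amplitude = 55,
                               bundle_angle_spread = 0.55, severity = 0,
                               noise_sd = 3, floor_um = 50,
                               disc_radius_mm = 0.8, seed = NULL,
                               patient_id = NA, eye_id = NA,
                               laterality = "OD", acquisition_date = NA) {
  stopifnot(bundle_amplitude >= 0, severity >= 0, severity <= 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  ctr <- (size + 1) / 2
  rr <- (row(diag(0, size, size)) - ctr) * pixel_pitch
  cc <- (col(diag(0, size, size)) - ctr) * pixel_pitch
  r <- sqrt(rr^2 + cc^2)
  # image convention: rows grow downward, so the superior retina is -row
  theta <- atan2(-rr, cc)
  radial <- exp(-(r - 1.7)^2 / (2 * 0.55^2))
  ang <- function(th0) {
    d <- (theta - th0 + pi) %% (2 * pi) - pi
    exp(-d^2 / (2 * bundle_angle_spread^2))
  }
  bundles <- radial * (ang(pi * 65 / 180) + ang(-pi * 65 / 180))
  vals <- base_thickness + (1 - severity) * bundle_amplitude * bundles
  if (noise_sd > 0) vals <- vals + stats::rnorm(length(vals), sd = noise_sd)
  disc_px <- r <= disc_radius_mm
  vals[!disc_px] <- pmax(vals[!disc_px], floor_um)
  vals[disc_px] <- stats::runif(sum(disc_px), 20, 40)
  vals <- pmin(pmax(vals, 0), 500)
  map <- rnflt_map(matrix(vals, size, size), pixel_pitch = pixel_pitch,
                   patient_id = patient_id, eye_id = eye_id,
                   laterality = laterality,
                   acquisition_date = acquisition_date)
  disc <- disc_mask(map, radius_mm = disc_radius_mm)
  ar <- artifact_ratio(artifact_mask(map, disc, floor_um), disc)
  if (classify_quality(ar) != "high")
    stop("simulated map is not high quality (AR = ", signif(ar, 3), ")",
         call. = FALSE)
  list(map = map, disc = disc)
}

# one filled ellipse mask with center (r0,c0) px, semi-axes (a,b) px, tilt phi
ellipse_mask <- function(size, r0, c0, a, b, phi) {
  dr <- row(diag(0, size, size)) - r0
  dc <- col(diag(0, size, size)) - c0
  u <- dr * cos(phi) + dc * sin(phi)
  v <- -dr * sin(phi) + dc * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Corrupt a map with simulated segmentation failures
#'
#' Overwrites random regions of a thickness map with sub-floor values,
#' emulating the blocked-signal and layer-disruption segmentation failures
#' seen in clinical scans. Artifact shapes are a union of random ellipses
#' plus, optionally, an annular wedge crossing the scan circle (the shape a
#' run of failed B-scans produces). Regions never intrude into the disc.
#' Ellipses are added, with the final one shrunk to size, until the achieved
#' artifact ratio is within +/-20% of `target_ar`.
#'
#' @param map a (typically high-quality) [rnflt_map()].
#' @param disc its [disc_mask()].
#' @param target_ar desired artifact ratio; 0 returns the map unchanged.
#' @param blob_scale characteristic ellipse radius, mm.
#' @param wedge_prob probability that one annular wedge is included.
#' @param fill_range artifact fill values are drawn uniformly from this um
#'   range; the upper end must be below `floor_um`.
#' @param floor_um measurement floor, um.
#' @param seed integer seed.
#' @return An [rnflt_map()] with artifacts written in (metadata preserved).
#' @export
simulate_segmentation_failure <- function(map, disc, target_ar = 0.1,
                                          blob_scale = 0.5, wedge_prob = 0.5,
                                          fill_range = c(0, 45),
                                          floor_um = 50, seed = NULL) {
  stopifnot(target_ar >= 0, target_ar <= 1, length(fill_range) == 2L,
            fill_range[2L] < floor_um, fill_range[1L] >= 0)
  if (target_ar == 0) return(map)
  if (!is.null(seed)) set.seed(seed)
  size <- nrow(map)
  pitch <- attr(map, "pixel_pitch")
  denom <- sum(!disc)
  if (denom == 0L) stop("disc covers grid; cannot place artifacts", call. = FALSE)
  ctr <- (dim(map) + 1) / 2
  sel <- matrix(FALSE, size, ncol(map))
  ar_of <- function(m) sum(m & !disc) / denom

  if (stats::runif(1) < wedge_prob) {
    # annular wedge crossing the 1.73 mm scan circle
    th0 <- stats::runif(1, -pi, pi)
    hw <- stats::runif(1, 0.15, 0.45) * sqrt(max(target_ar, 0.02) / 0.1)
    rr <- (row(sel) - ctr[1L]) * pitch
    cc <- (col(sel) - ctr[2L]) * pitch
    r <- sqrt(rr^2 + cc^2)
    d <- (atan2(-rr, cc) - th0 + pi) %% (2 * pi) - pi
    wedge <- abs(d) <= hw & r >= 1.1 & r <= 2.6
    if (ar_of(sel | wedge) <= 1.1 * target_ar) sel <- sel | wedge
  }

  a_px <- blob_scale / pitch
  for (i in seq_len(200L)) {
    cur <- ar_of(sel)
    if (cur >= 0.9 * target_ar) break
    need_px <- (target_ar - cur) * denom
    scale <- min(1, sqrt(need_px / (pi * a_px * a_px * 0.75)))
    e <- ellipse_mask(size,
                      stats::runif(1, 1, size), stats::runif(1, 1, size),
                      a_px * scale * stats::runif(1, 0.7, 1.3),
                      a_px * scale * stats::runif(1, 0.4, 1.0),
                      stats::runif(1, 0, pi))
    if (ar_of(sel | e) <= 1.15 * target_ar) sel <- sel | e
  }
  sel <- sel & !disc
  ar <- ar_of(sel)
  if (abs(ar - target_ar) > 0.2 * target_ar)
    stop(sprintf("could not reach target AR %.3f (achieved %.3f)",
                 target_ar, ar), call. = FALSE)
  vals <- unclass(map)
  vals[sel] <- stats::runif(sum(sel), fill_range[1L], fill_range[2L])
  out <- map
  out[] <- vals
  out
}

#' Simulate a visual-field exam series
#'
#' Generates a time-ordered series of 24-2 visual-field exams for one eye:
#' exam dates evenly spread over the follow-up span, mean deviation (MD)
#' following a linear trend plus Gaussian noise, 52 pointwise total deviations
#' (TDs) likewise, the visual field index (VFI) as an affine function of MD
#' clipped to `[0, 100]`, and reliability indices (fixation loss,
#' false-positive and false-negative rates) drawn so that roughly 90% of
#' exams pass the standard reliability filter.
#'
#' @param n_exams number of exams (>= 2).
#' @param span_years follow-up span in years (> 0).
#' @param md_intercept baseline MD, dB.
#' @param md_slope MD trend, dB/year.
#' @param td_slopes length-52 vector of TD trends, dB/year (default: all
#'   equal to `md_slope`).
#' @param td_intercepts length-52 vector of baseline TDs, dB.
#' @param noise_sd test-retest noise sd, dB (applied to MD and each TD).
#' @param start_date date of the first exam.
#' @param unreliable_rate target fraction of exams failing the reliability
#'   filter.
#' @param eye_id identifier.
#' @param seed integer seed.
#' @return Object of class `vf_series`: a list with `eye_id` and `exams`, a
#'   data frame with columns `exam_date`, `md`, `vfi`, `td_1` .. `td_52`,
#'   `fixation_loss`, `false_pos`, `false_neg`.
#' @export
simulate_vf_series <- function(n_exams = 8L, span_years = 6,
                               md_intercept = -2, md_slope = 0,
                               td_slopes = rep(md_slope, 52L),
                               td_intercepts = rep(md_intercept, 52L),
                               noise_sd = 0.5,
                               start_date = as.Date("2015-01-01"),
                               unreliable_rate = 0.1,
                               eye_id = NA, seed = NULL) {
  stopifnot(n_exams >= 2L, span_years > 0, noise_sd >= 0,
            length(td_slopes) == 52L, length(td_intercepts) == 52L)
  if (!is.null(seed)) set.seed(seed)
  t_years <- seq(0, span_years, length.out = n_exams)
  md <- md_intercept + md_slope * t_years +
    stats::rnorm(n_exams, sd = noise_sd)
  td <- sapply(seq_len(52L), function(j)
    td_intercepts[j] + td_slopes[j] * t_years +
      stats::rnorm(n_exams, sd = noise_sd))
  td <- matrix(td, nrow = n_exams)
  vfi <- pmin(pmax(100 + 2.1 * md, 0), 100)
  # per-index failure rate chosen so overall pass rate ~ 1 - unreliable_rate
  p_each <- 1 - (1 - unreliable_rate)^(1 / 3)
  draw_rate <- function(thr) {
    bad <- stats::runif(n_exams) < p_each
    ifelse(bad, stats::runif(n_exams, thr + 0.01, min(1, thr + 0.3)),
           stats::runif(n_exams, 0, thr))
  }
  exams <- data.frame(
    exam_date = start_date + round(t_years * 365.25),
    md = md, vfi = vfi)
  exams[paste0("td_", seq_len(52L))] <- as.data.frame(td)
  exams$fixation_loss <- draw_rate(0.33)
  exams$false_pos <- draw_rate(0.20)
  exams$false_neg <- draw_rate(0.20)
  # evenly spread dates are strictly increasing by construction
  vf_series(eye_id = as.character(eye_id), exams = exams)
}

#' Visual-field series container
#'
#' @param eye_id identifier.
#' @param exams data frame with columns `exam_date` (Date, strictly
#'   increasing), `md`, `vfi`, `td_1`..`td_52`, `fixation_loss`, `false_pos`,
#'   `false_neg`.
#' @return Object of class `vf_series`.
#' @export
vf_series <- function(eye_id, exams) {
  need <- c("exam_date", "md", "vfi", paste0("td_", 1:52),
            "fixation_loss", "false_neg", "false_pos")
  miss <- setdiff(need, names(exams))
  if (length(miss))
    stop("exams is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  exams$exam_date <- as.Date(exams$exam_date)
  if (is.unsorted(exams$exam_date, strictly = TRUE))
    stop("exam dates must be strictly increasing", call. = FALSE)
  structure(list(eye_id = as.character(eye_id), exams = exams),
            class = "vf_series")
}

#' @export
print.vf_series <- function(x, ...) {
  n <- nrow(x$exams)
  span <- as.numeric(diff(range(x$exams$exam_date))) / 365.25
  cat(sprintf("VF series, eye %s: %d exams over %.1f years, MD %.1f to %.1f dB\n",
              x$eye_id, n, span, x$exams$md[1L], x$exams$md[n]))
  invisible(x)
}

#' Simulate a linked OCT + VF cohort
#'
#' Builds a full synthetic cohort for exercising the correction and
#' clinical-utility pipeline: each patient contributes 1-2 eyes; each eye gets
#' a high-quality RNFLT map whose bundle loss (severity) varies across the
#' cohort, and a visual-field series whose baseline MD is tied to the map
#' through a structure-function link
#' `MD = a * (mean circle-scan thickness - b) + noise`, so a real
#' structure-function signal exists for predictors to find. A subset of eyes
#' additionally carries a low-quality copy of its map with simulated
#' segmentation failures, usable as artifact-pattern donors.
#'
#' @param n_patients number of patients (>= 1).
#' @param size map side in pixels.
#' @param two_eye_prob probability a patient contributes both eyes.
#' @param donor_prob probability an eye also gets a low-quality donor map.
#' @param donor_ar_range donors' target artifact ratios are drawn uniformly
#'   from this range.
#' @param severity_shape1,severity_shape2 Beta parameters for the severity
#'   distribution across eyes.
#' @param sf_link list with `a` (dB per um), `b` (um) and `noise_sd` (dB)
#'   defining the structure-function link.
#' @param prog_fraction fraction of eyes with fast MD decline
#'   (-1.5 dB/year); the rest are stable (0 dB/year).
#' @param vf_noise_sd VF test-retest noise, dB.
#' @param n_exams,span_years follow-up design passed to
#'   [simulate_vf_series()].
#' @param seed integer seed; regeneration with the same seed reproduces the
#'   cohort exactly.
#' @return Object of class `rnflt_cohort`: list with `eyes` (named list; each
#'   element has `map`, `disc`, optional `donor`, `vf`, `severity`,
#'   `patient_id`, `eye_id`) and `manifest` (data frame, one row per eye).
#' @export
simulate_cohort <- function(n_patients, size = 64L, two_eye_prob = 0.4,
                            donor_prob = 0.2, donor_ar_range = c(0.06, 0.30),
                            severity_shape1 = 1.2, severity_shape2 = 2.2,
                            sf_link = list(a = 0.12, b = 100, noise_sd = 0.7),
                            prog_fraction = 0.3, vf_noise_sd = 0.5,
                            n_exams = 8L, span_years = 6, seed = 1L) {
  stopifnot(n_patients >= 1L)
  set.seed(seed)
  eyes <- list()
  rows <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%04d", p)
    lats <- if (stats::runif(1) < two_eye_prob) c("OD", "OS") else
      sample(c("OD", "OS"), 1L)
    for (lat in lats) {
      eid <- paste0(pid, "_", lat)
      sev <- stats::rbeta(1, severity_shape1, severity_shape2)
      hq <- simulate_rnflt_map(size = size, severity = sev,
                               seed = sample.int(2^31 - 1, 1),
                               patient_id = pid, eye_id = eid,
                               laterality = lat,
                               acquisition_date = as.Date("2015-01-01"))
      donor <- NULL
      donor_ar <- NA_real_
      if (stats::runif(1) < donor_prob) {
        donor_ar <- stats::runif(1, donor_ar_range[1L], donor_ar_range[2L])
        donor <- simulate_segmentation_failure(
          hq$map, hq$disc, target_ar = donor_ar,
          seed = sample.int(2^31 - 1, 1))
      }
      mean_circle <- mean(extract_circle_scan(hq$map,
                                              circle_geometry(hq$map, hq$disc))$thickness)
      md0 <- sf_link$a * (mean_circle - sf_link$b) +
        stats::rnorm(1, sd = sf_link$noise_sd)
      slope <- if (stats::runif(1) < prog_fraction) -1.5 else 0
      vf <- simulate_vf_series(n_exams = n_exams, span_years = span_years,
                               md_intercept = md0, md_slope = slope,
                               td_intercepts = rep(md0, 52L),
                               noise_sd = vf_noise_sd, eye_id = eid,
                               seed = sample.int(2^31 - 1, 1))
      eyes[[eid]] <- list(patient_id = pid, eye_id = eid, laterality = lat,
                          severity = sev, map = hq$map, disc = hq$disc,
                          donor = donor, donor_ar = donor_ar, vf = vf,
                          md_slope = slope, md_intercept = md0)
      rows[[eid]] <- data.frame(patient_id = pid, eye_id = eid,
                                laterality = lat, severity = sev,
                                has_donor = !is.null(donor),
                                donor_target_ar = donor_ar,
                                md_intercept = md0, md_slope = slope)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(eyes = eyes, manifest = manifest, seed = seed, size = size),
            class = "rnflt_cohort")
}

#' @export
print.rnflt_cohort <- function(x, ...) {
  cat(sprintf("synthetic RNFLT cohort: %d eyes of %d patients (%d donor maps), %dx%d px\n",
              nrow(x$manifest), length(unique(x$manifest$patient_id)),
              sum(x$manifest$has_donor), x$size, x$size))
  invisible(x)
}
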