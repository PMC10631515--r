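#' Extract an artifact pattern from a low-quality donor map
#'
#' Harvests the artifact region of a low-quality map (artifact ratio > 5%)
#' together with its sub-floor values, to be transplanted onto high-quality
#' maps as a pseudo-artifact. Values are carried along, not just the mask,
#' because artifact pixels retain real (sub-floor) intensities that the
#' correction model should see as input.
#'
#' @param low_map a low-quality [rnflt_map()] donor.
#' @param disc its [disc_mask()].
#' @param floor_um measurement floor, um.
#' @return Object of class `artifact_pattern`: list with `mask` (logical
#'   matrix), `values` (um values on the masked pixels, in column-major
#'   order), `donor_id`.
#' @export
extract_artifact_pattern <- function(low_map, disc, floor_um = 50) {
  am <- artifact_mask(low_map, disc, floor_um)
  ar <- artifact_ratio(am, disc)
  if (classify_quality(ar) != "low")
    stop(sprintf("donor is not low quality (AR = %.3f, need > 0.05)", ar),
         call. = FALSE)
  structure(list(mask = unclass(am) & TRUE,
                 values = unclass(low_map)[unclass(am)],
                 donor_id = attr(low_map, "eye_id"),
                 floor_um = floor_um),
            class = "artifact_pattern")
}

#' @export
print.artifact_pattern <- function(x, ...) {
  cat(sprintf("artifact pattern from donor %s: %d px, values %.1f-%.1f um\n",
              x$donor_id, sum(x$mask), min(x$values), max(x$values)))
  invisible(x)
}

# rigid transform of pattern pixel coordinates: rotate about grid center,
# then shift; returns in-grid destination indices and the surviving values
transform_pattern <- function(pattern, dim_out, shift = c(0, 0), rot_deg = 0) {
  idx <- which(pattern$mask, arr.ind = TRUE)
  ctr <- (dim(pattern$mask) + 1) / 2
  th <- rot_deg * pi / 180
  dr <- idx[, 1L] - ctr[1L]; dc <- idx[, 2L] - ctr[2L]
  r2 <- round(ctr[1L] + dr * cos(th) - dc * sin(th) + shift[1L])
  c2 <- round(ctr[2L] + dr * sin(th) + dc * cos(th) + shift[2L])
  keep <- r2 >= 1 & r2 <= dim_out[1L] & c2 >= 1 & c2 <= dim_out[2L]
  dest <- cbind(r2[keep], c2[keep])
  dup <- duplicated(dest)
  list(dest = dest[!dup, , drop = FALSE], values = pattern$values[keep][!dup])
}

#' Superimpose an artifact pattern onto a high-quality map
#'
#' Writes a donor artifact pattern (optionally under a random rigid
#' shift/rotation) onto a high-quality map, producing a supervised training
#' pair: the corrupted map as model input and the untouched high-quality map
#' as ground truth. The pattern never overwrites disc pixels.
#'
#' @param high_map a high-quality [rnflt_map()] (artifact ratio < 2%).
#' @param pattern an [extract_artifact_pattern()] result.
#' @param disc the target map's [disc_mask()].
#' @param transform `"rigid"` applies a random shift (<= `max_shift` px) and
#'   rotation (<= `max_rot` degrees); `"identity"` transplants in place.
#' @param max_shift,max_rot rigid-transform bounds.
#' @param floor_um measurement floor, um.
#' @param seed integer seed for the random transform.
#' @return Object of class `training_pair`: list with `input` (corrupted
#'   map), `target` (ground truth), `pseudo_mask` (logical matrix of written
#'   pixels) and `ar` (input's artifact ratio).
#' @export
superimpose_pattern <- function(high_map, pattern, disc,
                                transform = c("rigid", "identity"),
                                max_shift = 20, max_rot = 15,
                                floor_um = 50, seed = NULL) {
  transform <- match.arg(transform)
  ar0 <- artifact_ratio(artifact_mask(high_map, disc, floor_um), disc)
  if (classify_quality(ar0) != "high")
    stop("target map is not high quality", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (transform == "rigid") {
    shift <- round(stats::runif(2, -max_shift, max_shift))
    rot <- stats::runif(1, -max_rot, max_rot)
  } else {
    shift <- c(0, 0); rot <- 0
  }
  tp <- transform_pattern(pattern, dim(high_map), shift, rot)
  if (nrow(tp$dest)) {
    off_disc <- !unclass(disc)[tp$dest]
    tp$dest <- tp$dest[off_disc, , drop = FALSE]
    tp$values <- tp$values[off_disc]
  }
  if (nrow(tp$dest) == 0L)
    stop("pattern is empty after transform; no pixels to transplant",
         call. = FALSE)
  vals <- unclass(high_map)
  vals[tp$dest] <- tp$values
  input <- high_map
  input[] <- vals
  pm <- matrix(FALSE, nrow(high_map), ncol(high_map))
  pm[tp$dest] <- TRUE
  structure(list(input = input, target = high_map, pseudo_mask = pm,
                 ar = artifact_ratio(artifact_mask(input, disc, floor_um), disc),
                 donor_id = pattern$donor_id),
            class = "training_pair")
}

#' @export
print.training_pair <- function(x, ...) {
  cat(sprintf("training pair: %d px pseudo-artifact (AR %.1f%%), donor %s\n",
              sum(x$pseudo_mask), 100 * x$ar, x$donor_id))
  invisible(x)
}

#' Patient-level train/test split
#'
#' Partitions patients (not images) into groups, so all images from one
#' patient land in the same group and no identity leaks across the split.
#'
#' @param patient_ids character vector of patient ids (one per patient, or
#'   per image -- duplicates are collapsed).
#' @param fractions named numeric vector of group fractions summing to 1.
#' @param seed integer seed.
#' @return Named list of patient-id character vectors, one per group.
#' @examples
#' patient_level_split(sprintf("P%02d", 1:10), seed = 1)
#' @export
patient_level_split <- function(patient_ids,
                                fractions = c(train = 0.7, test = 0.3),
                                seed = NULL) {
  ids <- unique(as.character(patient_ids))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1", call. = FALSE)
  k <- length(fractions)
  if (length(ids) < k)
    stop("fewer patients than groups", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- sample(ids)
  # largest-remainder apportionment of patients to groups
  raw <- fractions * length(ids)
  n <- floor(raw)
  rem <- length(ids) - sum(n)
  if (rem > 0) {
    o <- order(raw - n, decreasing = TRUE)
    n[o[seq_len(rem)]] <- n[o[seq_len(rem)]] + 1L
  }
  ends <- cumsum(n)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- lapply(seq_len(k), function(i)
    if (n[i] > 0) sort(ids[starts[i]:ends[i]]) else character())
  names(out) <- names(fractions)
  out
}

#' Build a pseudo-artifact training corpus from a cohort
#'
#' Pairs every high-quality map in a cohort with one donor artifact pattern
#' (donors sampled uniformly with replacement) and returns the corpus split
#' at patient level.
#'
#' @param cohort an [simulate_cohort()] result, or any list with `eyes` and
#'   `manifest` in the same layout.
#' @param fractions train/test fractions (patient level).
#' @param transform,max_shift,max_rot passed to [superimpose_pattern()].
#' @param floor_um measurement floor, um.
#' @param seed integer seed.
#' @return List with `train` and `test`, each a list of `training_pair`
#'   objects (with `$disc` and `$patient_id` attached), and `split`.
#' @export
build_pseudo_corpus <- function(cohort, fractions = c(train = 0.7, test = 0.3),
                                transform = "rigid", max_shift = 20,
                                max_rot = 15, floor_um = 50, seed = 1L) {
  set.seed(seed)
  donors <- Filter(function(e) {
    if (is.null(e$donor)) return(FALSE)
    ar <- artifact_ratio(artifact_mask(e$donor, e$disc, floor_um), e$disc)
    classify_quality(ar) == "low"   # targets near 5% can land just under
  }, cohort$eyes)
  if (!length(donors))
    stop("cohort contains no low-quality donor maps", call. = FALSE)
  patterns <- lapply(donors, function(e)
    extract_artifact_pattern(e$donor, e$disc, floor_um))
  split <- patient_level_split(cohort$manifest$patient_id, fractions,
                               seed = sample.int(2^31 - 1, 1))
  make_pairs <- function(pids) {
    eyes <- Filter(function(e) e$patient_id %in% pids, cohort$eyes)
    lapply(eyes, function(e) {
      pat <- patterns[[sample.int(length(patterns), 1L)]]
      pr <- superimpose_pattern(e$map, pat, e$disc, transform = transform,
                                max_shift = max_shift, max_rot = max_rot,
                                floor_um = floor_um,
                                seed = sample.int(2^31 - 1, 1))
      pr$disc <- e$disc
      pr$patient_id <- e$patient_id
      pr
    })
  }
  list(train = make_pairs(split$train), test = make_pairs(split$test),
       split = split)
}
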