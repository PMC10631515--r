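#' Correction accuracy in a masked region
#'
#' Mean absolute error and Pearson correlation between predicted and true
#' thickness over the pixels of a mask (typically the pseudo-artifact
#' region), with pixels pooled across the supplied grids.
#'
#' @param pred,truth numeric matrices (or lists of matrices to pool).
#' @param mask logical matrix (or list) selecting the evaluated pixels.
#' @return List of class `region_metrics`: `mae` (um), `r`, `r2`,
#'   `n_pixels`. `r` is `NA` (flagged via `r_defined = FALSE`) when either
#'   side has zero variance.
#' @examples
#' region_metrics(matrix(c(90, 85, 60, 110)), matrix(c(100, 80, 60, 120)),
#'                matrix(TRUE, 4, 1))
#' @export
region_metrics <- function(pred, truth, mask) {
  if (!is.list(pred)) { pred <- list(pred); truth <- list(truth); mask <- list(mask) }
  stopifnot(length(pred) == length(truth), length(pred) == length(mask))
  p <- unlist(lapply(seq_along(pred), function(i) {
    stopifnot(all(dim(pred[[i]]) == dim(truth[[i]])))
    pred[[i]][mask[[i]]]
  }))
  t_ <- unlist(lapply(seq_along(truth), function(i) truth[[i]][mask[[i]]]))
  if (!length(p)) stop("mask selects no pixels; metrics undefined", call. = FALSE)
  r_ok <- length(p) >= 2L && stats::sd(p) > 0 && stats::sd(t_) > 0
  r <- if (r_ok) stats::cor(p, t_) else NA_real_
  structure(list(mae = mean(abs(p - t_)), r = r, r2 = r^2,
                 n_pixels = length(p), r_defined = r_ok),
            class = "region_metrics")
}

#' @export
print.region_metrics <- function(x, ...) {
  cat(sprintf("region metrics: MAE %.2f um, R %.3f (R2 %.3f), %d px\n",
              x$mae, x$r, x$r2, x$n_pixels))
  invisible(x)
}

# circle-scan sample indices whose nearest pixel is masked
circle_mask_samples <- function(mask, geom) {
  p <- circle_sample_points(geom)
  idx <- cbind(pmin(pmax(round(p$row), 1L), nrow(mask)),
               pmin(pmax(round(p$col), 1L), ncol(mask)))
  which(mask[idx])
}

#' Correction accuracy on the scan circle
#'
#' Restricts the comparison to circle-scan samples falling on artifact
#' pixels: each angular sample is kept if the mask is true at its nearest
#' pixel, and predicted/true profiles are compared at those samples.
#'
#' @param pred_map,truth_map [rnflt_map()]s (or bare matrices).
#' @param mask logical artifact/pseudo-artifact matrix.
#' @param geom a [circle_geometry()].
#' @return A `region_metrics` object, or `NULL` (flagged empty) when no
#'   artifact touches the circle.
#' @export
circle_region_metrics <- function(pred_map, truth_map, mask, geom) {
  on <- circle_mask_samples(mask, geom)
  if (!length(on)) return(NULL)
  sp <- extract_circle_scan_values(pred_map, geom)[on]
  st <- extract_circle_scan_values(truth_map, geom)[on]
  region_metrics(matrix(sp), matrix(st), matrix(TRUE, length(sp), 1L))
}

extract_circle_scan_values <- function(map, geom) {
  p <- circle_sample_points(geom)
  bilinear_sample(unclass(map), p$row, p$col)
}

#' Stratified correction-accuracy report
#'
#' Applies a trained correction model to held-out pseudo-artifact pairs and
#' reports MAE / Pearson R in the pseudo-artifact region -- pixels pooled
#' within stratum -- overall and within the artifact-ratio strata `<=10%`,
#' `>10%` and `>20%` (the `>20%` stratum is nested inside `>10%`), for the
#' full maps and for the scan circle. Per-map MAE summaries are attached for
#' diagnostics.
#'
#' @param pairs list of held-out `training_pair` objects (each carrying
#'   `$disc`).
#' @param model an [train_correction_model()] fit.
#' @param n_samples circle-scan sample count.
#' @return Object of class `stratified_report`: data frame with columns
#'   `stratum`, `surface` (`map`/`circle`), `n_maps`, `n_pixels`, `mae`,
#'   `r`, `r2`; empty strata are absent. Attribute `per_map` holds the
#'   per-pair diagnostics.
#' @export
stratified_report <- function(pairs, model, n_samples = 256L) {
  stopifnot(length(pairs) >= 1L)
  corrected <- lapply(pairs, function(pr)
    predict(model, pr$input, pr$disc)$map)
  ar <- vapply(pairs, `[[`, numeric(1), "ar")
  strata <- list(overall = rep(TRUE, length(pairs)),
                 ar_le_10 = ar <= 0.10, ar_gt_10 = ar > 0.10,
                 ar_gt_20 = ar > 0.20)
  per_map <- data.frame(
    ar = ar,
    n_pixels = vapply(pairs, function(pr) sum(pr$pseudo_mask), numeric(1)),
    mae = vapply(seq_along(pairs), function(i) {
      m <- pairs[[i]]$pseudo_mask
      mean(abs(corrected[[i]][m] - pairs[[i]]$target[m]))
    }, numeric(1)))
  rows <- list()
  for (s in names(strata)) {
    in_s <- which(strata[[s]])
    if (!length(in_s)) next
    mm <- region_metrics(lapply(corrected[in_s], unclass),
                         lapply(pairs[in_s], function(p) unclass(p$target)),
                         lapply(pairs[in_s], `[[`, "pseudo_mask"))
    rows[[paste0(s, ".map")]] <- data.frame(
      stratum = s, surface = "map", n_maps = length(in_s),
      n_pixels = mm$n_pixels, mae = mm$mae, r = mm$r, r2 = mm$r2)
    cp <- ct <- list()
    nm <- 0L
    for (i in in_s) {
      geom <- circle_geometry(pairs[[i]]$input, pairs[[i]]$disc,
                              n_samples = n_samples)
      on <- circle_mask_samples(pairs[[i]]$pseudo_mask, geom)
      if (!length(on)) next
      cp[[length(cp) + 1L]] <- matrix(
        extract_circle_scan_values(corrected[[i]], geom)[on])
      ct[[length(ct) + 1L]] <- matrix(
        extract_circle_scan_values(pairs[[i]]$target, geom)[on])
      nm <- nm + 1L
    }
    if (length(cp)) {
      cm <- region_metrics(cp, ct, lapply(cp, function(m) m == m))
      rows[[paste0(s, ".circle")]] <- data.frame(
        stratum = s, surface = "circle", n_maps = nm,
        n_pixels = cm$n_pixels, mae = cm$mae, r = cm$r, r2 = cm$r2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_map") <- per_map
  class(out) <- c("stratified_report", "data.frame")
  out
}

#' @export
print.stratified_report <- function(x, ...) {
  cat("artifact-correction accuracy in the pseudo-artifact region\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
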