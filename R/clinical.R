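#' Visual-field reliability filter
#'
#' A 24-2 exam is reliable when fixation loss is <= 33%, the false-positive
#' rate <= 20% and the false-negative rate <= 20%. Missing indices make the
#' exam unreliable by policy.
#'
#' @param fixation_loss,false_pos,false_neg rates in `[0, 1]`; vectorized.
#' @return Logical vector.
#' @examples
#' vf_is_reliable(0.33, 0.20, 0.20)  # TRUE: boundaries are inclusive
#' vf_is_reliable(0.34, 0.10, 0.10)  # FALSE
#' @export
vf_is_reliable <- function(fixation_loss, false_pos, false_neg) {
  ok <- fixation_loss <= 0.33 & false_pos <= 0.20 & false_neg <= 0.20
  ok[is.na(ok)] <- FALSE
  ok
}

reliable_exams <- function(series) {
  e <- series$exams
  e[vf_is_reliable(e$fixation_loss, e$false_pos, e$false_neg), , drop = FALSE]
}

#' Pair OCT maps with visual-field exams
#'
#' Pairs each map with the reliable exam of the same eye acquired within the
#' pairing window (default 30 days), choosing the nearest-dated exam when
#' several qualify. Maps with no qualifying exam are dropped.
#'
#' @param maps data frame with columns `map_id`, `eye_id`, `date`.
#' @param exams data frame with columns `exam_id`, `eye_id`, `date` and the
#'   reliability indices `fixation_loss`, `false_pos`, `false_neg`.
#' @param window_days maximum |date difference| in days.
#' @return Data frame with one row per paired map: `map_id`, `exam_id`,
#'   `eye_id`, `delta_days`. Attribute `n_unpaired` counts dropped maps.
#' @export
pair_oct_vf <- function(maps, exams, window_days = 30) {
  exams <- exams[vf_is_reliable(exams$fixation_loss, exams$false_pos,
                                exams$false_neg), , drop = FALSE]
  maps$date <- as.Date(maps$date); exams$date <- as.Date(exams$date)
  rows <- lapply(seq_len(nrow(maps)), function(i) {
    cand <- exams[exams$eye_id == maps$eye_id[i], , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    dd <- as.numeric(cand$date - maps$date[i])
    ok <- abs(dd) <= window_days
    if (!any(ok)) return(NULL)
    j <- which(ok)[which.min(abs(dd[ok]))]
    data.frame(map_id = maps$map_id[i], exam_id = cand$exam_id[j],
               eye_id = maps$eye_id[i], delta_days = dd[j])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(map_id = character(), exam_id = character(),
                      eye_id = character(), delta_days = numeric())
  attr(out, "n_unpaired") <- nrow(maps) - nrow(out)
  out
}

#' Trend of a visual-field index over time
#'
#' Ordinary least-squares regression of an index (MD, VFI or a pointwise TD)
#' on time in years since the first exam; the p-value is the two-sided t-test
#' on the slope coefficient. The closed form (slope = Sxy/Sxx,
#' t = slope/SE) is evaluated directly so that exactly constructed series
#' give exact slopes -- the progression criteria compare slopes against
#' hard boundaries. A perfect (zero-residual) fit returns p = 0.
#'
#' @param values numeric vector (dB or %).
#' @param dates `Date` vector (or numeric years), strictly increasing,
#'   length >= 3.
#' @return List of class `slope_fit`: `slope` (units/year), `intercept`,
#'   `p_value`, `n`.
#' @export
fit_series_slope <- function(values, dates) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 exams to fit a trend", call. = FALSE)
  t_years <- if (inherits(dates, "Date"))
    as.numeric(dates - dates[1L]) / 365.25 else as.numeric(dates - dates[1L])
  tc <- t_years - mean(t_years)
  yc <- values - mean(values)
  sxx <- sum(tc * tc)
  slope <- sum(tc * yc) / sxx
  intercept <- mean(values) - slope * mean(t_years)
  sse <- sum((yc - slope * tc)^2)
  scale <- max(sum(yc * yc), 1)
  p <- if (sse <= 1e-24 * scale) 0 else {
    se <- sqrt(sse / (n - 2L) / sxx)
    2 * stats::pt(abs(slope / se), df = n - 2L, lower.tail = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, p_value = p, n = n),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("slope %.3f /year (intercept %.2f, p = %.3g, n = %d)\n",
              x$slope, x$intercept, x$p_value, x$n))
  invisible(x)
}

#' Series eligibility for progression analysis
#'
#' An eye's series qualifies when it holds at least `min_exams` reliable
#' exams spanning at least `min_years` years.
#'
#' @param series a [vf_series()].
#' @param min_exams,min_years eligibility thresholds.
#' @return Logical scalar.
#' @export
vf_series_eligible <- function(series, min_exams = 5L, min_years = 4) {
  e <- reliable_exams(series)
  nrow(e) >= min_exams &&
    as.numeric(diff(range(e$exam_date))) / 365.25 >= min_years
}

#' Trend-based progression labels
#'
#' Computes four literature progression criteria from the reliable exams of
#' an eligible series: (1) MD progression -- MD slope < 0 with p < 0.05;
#' (2) TD pointwise progression -- at least three TD locations with slope
#' <= -1 dB/year and p < 0.05; (3) VFI progression -- VFI slope < 0 with
#' p < 0.05; (4) MD fast progression -- MD slope <= -1 dB/year with
#' p < 0.05.
#'
#' @param series a [vf_series()].
#' @param min_exams,min_years eligibility thresholds (see
#'   [vf_series_eligible()]).
#' @return Object of class `progression_labels`: logicals `md_prog`,
#'   `td_pointwise_prog`, `vfi_prog`, `md_fast`, plus `md_fit`, `vfi_fit`,
#'   `td_fits` and `n_td_progressing`.
#' @export
label_progression <- function(series, min_exams = 5L, min_years = 4) {
  if (!vf_series_eligible(series, min_exams, min_years))
    stop("series not eligible: needs >= ", min_exams,
         " reliable exams over >= ", min_years, " years", call. = FALSE)
  e <- reliable_exams(series)
  md_fit <- fit_series_slope(e$md, e$exam_date)
  vfi_fit <- fit_series_slope(e$vfi, e$exam_date)
  td_fits <- lapply(paste0("td_", 1:52), function(cn)
    fit_series_slope(e[[cn]], e$exam_date))
  td_hits <- vapply(td_fits, function(f)
    f$slope <= -1 && f$p_value < 0.05, logical(1))
  structure(list(
    md_prog = md_fit$slope < 0 && md_fit$p_value < 0.05,
    td_pointwise_prog = sum(td_hits) >= 3L,
    vfi_prog = vfi_fit$slope < 0 && vfi_fit$p_value < 0.05,
    md_fast = md_fit$slope <= -1 && md_fit$p_value < 0.05,
    md_fit = md_fit, vfi_fit = vfi_fit, td_fits = td_fits,
    n_td_progressing = sum(td_hits)),
    class = "progression_labels")
}

#' @export
print.progression_labels <- function(x, ...) {
  cat(sprintf(
    "progression: MD %s (slope %.2f, p %.3g) | TD pointwise %s (%d locs) | VFI %s | MD fast %s\n",
    x$md_prog, x$md_fit$slope, x$md_fit$p_value,
    x$td_pointwise_prog, x$n_td_progressing, x$vfi_prog, x$md_fast))
  invisible(x)
}

#' Structure-function predictor
#'
#' Fits the circle-scan linear model: each target (MD, or one of the 52 TDs)
#' is regressed on the circle-scan thickness profile via least squares
#' (with a ridge fallback for rank-deficient designs).
#'
#' @param x numeric feature matrix, one row per eye/visit (e.g. circle-scan
#'   profiles, possibly downsampled).
#' @param y numeric target vector (MD) or matrix (52 TDs, one column each).
#' @return Object of class `vf_predictor` with a `predict` method.
#' @export
fit_vf_predictor <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 2L)
  X <- cbind(1, x)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) XtX <- XtX + diag(1e-8 * mean(diag(XtX)), ncol(X))
  beta <- solve(XtX, crossprod(X, y))
  structure(list(beta = beta, p = ncol(x), targets = ncol(y)),
            class = "vf_predictor")
}

#' @export
predict.vf_predictor <- function(object, x, ...) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == object$p)
  out <- cbind(1, x) %*% object$beta
  if (ncol(out) == 1L) drop(out) else out
}

#' Logistic progression classifier
#'
#' @param x feature matrix (circle-scan profile summaries).
#' @param labels logical/0-1 progression labels; both classes must be
#'   present.
#' @return Object of class `progression_classifier`; `predict()` returns
#'   probabilities.
#' @export
fit_progression_classifier <- function(x, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  df <- data.frame(y = labels, as.data.frame(as.matrix(x)))
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  structure(list(fit = fit, p = ncol(as.matrix(x))),
            class = "progression_classifier")
}

#' @export
predict.progression_classifier <- function(object, x, ...) {
  nd <- as.data.frame(as.matrix(x))
  names(nd) <- names(object$fit$model)[-1L]
  unname(stats::predict(object$fit, newdata = nd, type = "response"))
}

#' Area under the ROC curve
#'
#' Rank-based AUC (equivalent to the Wilcoxon statistic), computed through
#' pROC.
#'
#' @param scores numeric classifier scores.
#' @param labels logical/0-1 outcomes (both classes present).
#' @return AUC in `[0, 1]`, oriented so higher scores indicate the positive
#'   class.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("AUC undefined: single-class labels", call. = FALSE)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Patient-level k-fold comparison of raw vs corrected inputs
#'
#' Splits a cohort into `k` patient-disjoint folds; each fold is evaluated
#' once by a predictor trained on the remaining folds, separately for the
#' raw and the corrected feature set, giving a paired per-fold metric table.
#'
#' @param x_raw,x_corr feature matrices (same rows: one per eye/visit).
#' @param y target vector: numeric for `task = "regression"` (metrics MAE
#'   and R2), logical/0-1 for `task = "classification"` (metric AUC).
#' @param patient_ids patient id per row.
#' @param task `"regression"` or `"classification"`.
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @return Data frame, one row per fold, with paired metrics and attribute
#'   `predictions` (per-row out-of-fold predictions for both inputs).
#' @export
crossval_compare <- function(x_raw, x_corr, y, patient_ids,
                             task = c("regression", "classification"),
                             k = 3L, seed = 1L) {
  task <- match.arg(task)
  ids <- unique(patient_ids)
  if (k > length(ids)) stop("more folds than patients", call. = FALSE)
  fr <- stats::setNames(rep(1 / k, k), paste0("fold", seq_len(k)))
  folds <- patient_level_split(ids, fr, seed = seed)
  x_raw <- as.matrix(x_raw); x_corr <- as.matrix(x_corr)
  pred_raw <- pred_corr <- rep(NA_real_, length(y))
  rows <- list()
  for (f in seq_len(k)) {
    te <- patient_ids %in% folds[[f]]
    tr <- !te
    if (task == "regression") {
      pr <- predict(fit_vf_predictor(x_raw[tr, , drop = FALSE], y[tr]),
                    x_raw[te, , drop = FALSE])
      pc <- predict(fit_vf_predictor(x_corr[tr, , drop = FALSE], y[tr]),
                    x_corr[te, , drop = FALSE])
      pred_raw[te] <- pr; pred_corr[te] <- pc
      sst <- sum((y[te] - mean(y[te]))^2)
      r2 <- function(p) if (sst == 0) 0 else 1 - sum((y[te] - p)^2) / sst
      rows[[f]] <- data.frame(fold = f, n = sum(te),
                              mae_raw = mean(abs(y[te] - pr)),
                              mae_corr = mean(abs(y[te] - pc)),
                              r2_raw = r2(pr), r2_corr = r2(pc))
    } else {
      pr <- predict(fit_progression_classifier(x_raw[tr, , drop = FALSE],
                                               y[tr]),
                    x_raw[te, , drop = FALSE])
      pc <- predict(fit_progression_classifier(x_corr[tr, , drop = FALSE],
                                               y[tr]),
                    x_corr[te, , drop = FALSE])
      pred_raw[te] <- pr; pred_corr[te] <- pc
      rows[[f]] <- data.frame(fold = f, n = sum(te),
                              auc_raw = auc_score(pr, y[te]),
                              auc_corr = auc_score(pc, y[te]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- data.frame(y = as.numeric(y),
                                         pred_raw = pred_raw,
                                         pred_corr = pred_corr,
                                         patient_id = patient_ids)
  out
}

#' Bootstrap comparison of paired prediction accuracy
#'
#' Compares two predictors evaluated on the same units (eyes by default) by
#' resampling units with replacement: reports the observed metric
#' difference (corrected minus raw), a percentile confidence interval and a
#' two-sided bootstrap p-value for the difference being zero.
#'
#' @param y observed targets, one per unit.
#' @param pred_raw,pred_corr paired predictions.
#' @param metric `"mae"`, `"r2"` or `"auc"`.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param conf confidence level for the interval.
#' @param seed integer seed.
#' @return List of class `bootstrap_comparison`: `difference`, `ci`,
#'   `p_value`, `metric_raw`, `metric_corr`, `n_boot`.
#' @export
bootstrap_compare <- function(y, pred_raw, pred_corr,
                              metric = c("mae", "r2", "auc"),
                              n_boot = 1000L, conf = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(length(y) >= 2L, length(pred_raw) == length(y),
            length(pred_corr) == length(y), n_boot >= 100L)
  mfun <- switch(metric,
                 mae = function(y, p) mean(abs(y - p)),
                 r2 = function(y, p) {
                   sst <- sum((y - mean(y))^2)
                   if (sst == 0) 0 else 1 - sum((y - p)^2) / sst
                 },
                 auc = function(y, p) auc_score(p, y))
  set.seed(seed)
  obs <- mfun(y, pred_corr) - mfun(y, pred_raw)
  n <- length(y)
  diffs <- vapply(seq_len(n_boot), function(i) {
    repeat {
      j <- sample.int(n, n, replace = TRUE)
      if (metric != "auc" || length(unique(y[j])) > 1L) break
    }
    mfun(y[j], pred_corr[j]) - mfun(y[j], pred_raw[j])
  }, numeric(1))
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  p <- min(1, max(p, 1 / n_boot))
  a <- (1 - conf) / 2
  structure(list(difference = obs,
                 ci = unname(stats::quantile(diffs, c(a, 1 - a))),
                 p_value = p,
                 metric = metric,
                 metric_raw = mfun(y, pred_raw),
                 metric_corr = mfun(y, pred_corr),
                 n_boot = n_boot),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: raw %.4f vs corrected %.4f; diff %+0.4f [%.4f, %.4f], p = %.3g (%d resamples)\n",
    toupper(x$metric), x$metric_raw, x$metric_corr, x$difference,
    x$ci[1L], x$ci[2L], x$p_value, x$n_boot))
  invisible(x)
}
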