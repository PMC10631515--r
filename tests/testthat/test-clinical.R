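test_that("reliability filter applies the printed thresholds inclusively", {
  expect_true(vf_is_reliable(0.33, 0.20, 0.20))   # boundary passes
  expect_false(vf_is_reliable(0.34, 0.10, 0.10))
  expect_true(vf_is_reliable(0, 0, 0))
  expect_false(vf_is_reliable(0.10, 0.21, 0.10))
  expect_false(vf_is_reliable(0.10, 0.10, 0.21))
  expect_false(vf_is_reliable(NA, 0.1, 0.1))      # missing -> unreliable
  expect_equal(vf_is_reliable(c(0.1, 0.4), c(0.1, 0.1), c(0.1, 0.1)),
               c(TRUE, FALSE))
})

test_that("OCT-VF pairing enforces the 30-day window and nearest-date ties", {
  maps <- data.frame(map_id = c("M1", "M2", "M3"),
                     eye_id = c("E1", "E1", "E2"),
                     date = as.Date(c("2020-01-01", "2020-06-01", "2020-01-01")))
  exams <- data.frame(
    exam_id = c("V1", "V2", "V3", "V4"),
    eye_id = c("E1", "E1", "E1", "E2"),
    date = as.Date(c("2020-01-31", "2020-01-06", "2020-07-02", "2020-02-05")),
    fixation_loss = c(0.1, 0.1, 0.1, 0.1),
    false_pos = c(0.1, 0.1, 0.1, 0.1),
    false_neg = c(0.1, 0.1, 0.1, 0.1))
  p <- pair_oct_vf(maps, exams)
  # M1: V1 at +30 d and V2 at +5 d both qualify; nearest (V2) wins
  expect_identical(p$exam_id[p$map_id == "M1"], "V2")
  # M2: V3 is 31 days out -> unpaired
  expect_false("M2" %in% p$map_id)
  # M3: exam 35 days away -> unpaired; so exactly one pair overall
  expect_false("M3" %in% p$map_id)
  expect_equal(attr(p, "n_unpaired"), 2)

  # an exam exactly 30 days after the map is paired
  p30 <- pair_oct_vf(maps[1, ], exams[1, ])
  expect_identical(p30$exam_id, "V1")

  # unreliable exams never pair
  exams$false_pos[2] <- 0.5
  p2 <- pair_oct_vf(maps, exams)
  expect_identical(p2$exam_id[p2$map_id == "M1"], "V1")
})

test_that("series slopes match closed-form OLS with a slope t-test", {
  # noiseless decline: slope -1, perfect fit -> p = 0
  f <- fit_series_slope(c(0, -1, -2, -3, -4), 0:4)
  expect_equal(f$slope, -1, tolerance = 1e-12)
  expect_identical(f$p_value, 0)
  expect_equal(fit_series_slope(rep(5, 6), 0:5)$slope, 0, tolerance = 1e-12)

  # hand OLS oracle on a noisy series
  y <- c(0.1, -0.8, -2.1, -2.9, -4.1); t_ <- 0:4
  hand <- local({
    sxx <- sum((t_ - mean(t_))^2)
    sxy <- sum((t_ - mean(t_)) * (y - mean(y)))
    b <- sxy / sxx; a <- mean(y) - b * mean(t_)
    res <- y - a - b * t_
    se <- sqrt(sum(res^2) / 3 / sxx)
    list(b = b, a = a, p = 2 * pt(abs(b / se), 3, lower.tail = FALSE))
  })
  f2 <- fit_series_slope(y, t_)
  expect_equal(f2$slope, hand$b, tolerance = 1e-10)
  expect_equal(f2$intercept, hand$a, tolerance = 1e-10)
  expect_equal(f2$p_value, hand$p, tolerance = 1e-10)

  # property: random series agree with lm() as the independent oracle
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    y <- rnorm(n); t_ <- sort(runif(n, 0, 8))
    fit <- lm(y ~ t_)
    f3 <- fit_series_slope(y, t_)
    expect_equal(f3$slope, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(f3$p_value, summary(fit)$coefficients[2, 4],
                 tolerance = 1e-10)
  }
  expect_error(fit_series_slope(c(1, 2), c(0, 1)), "at least 3")
})

test_that("progression labels implement the four criteria and boundaries", {
  # fast decline: MD and fast-MD criteria both fire
  s <- toy_vf_series(md = -1.2 * (0:4), td_value = rep(0, 5))
  l <- label_progression(s)
  expect_true(l$md_prog)
  expect_true(l$md_fast)
  expect_false(l$td_pointwise_prog)

  # slow decline: progression without fast progression
  s2 <- toy_vf_series(md = -0.5 * (0:4), td_value = rep(0, 5))
  l2 <- label_progression(s2)
  expect_true(l2$md_prog)
  expect_false(l2$md_fast)

  # boundary: slope exactly -1 dB/year satisfies the <= -1 fast criterion
  # (build MD from the achieved exam dates so the fitted slope is exact)
  yrs <- round((0:4) * 365.25) / 365.25
  s3 <- toy_vf_series(md = -1 * yrs, years = 0:4, td_value = rep(0, 5))
  expect_true(label_progression(s3)$md_fast)

  # TD pointwise: exactly 2 declining locations is not progression, 3 is
  mk_td <- function(k) {
    ex <- toy_vf_series(md = rep(0, 5))$exams
    for (j in seq_len(k)) ex[[paste0("td_", j)]] <- -1.5 * (0:4)
    vf_series("E1", ex)
  }
  expect_false(label_progression(mk_td(2))$td_pointwise_prog)
  expect_true(label_progression(mk_td(3))$td_pointwise_prog)
  expect_equal(label_progression(mk_td(3))$n_td_progressing, 3)

  # VFI criterion follows the VFI slope
  s4 <- toy_vf_series(md = rep(0, 5), vfi = 100 - 2 * (0:4))
  expect_true(label_progression(s4)$vfi_prog)

  # eligibility: too short a span or too few reliable exams errors
  short <- toy_vf_series(md = rep(0, 5), years = seq(0, 3, length.out = 5))
  expect_error(label_progression(short), "eligible")
  few <- toy_vf_series(md = rep(0, 5), fl = c(0, 0, 0.9, 0.9, 0))
  expect_error(label_progression(few), "eligible")
})

test_that("eligibility and the filter reproduce enumerated toy-cohort logic", {
  # 6 constructed series; truth derived by hand
  specs <- list(
    list(n = 5, span = 4, bad = 0, eligible = TRUE),
    list(n = 5, span = 4, bad = 1, eligible = FALSE),  # 4 reliable left
    list(n = 6, span = 4, bad = 1, eligible = TRUE),
    list(n = 5, span = 3.9, bad = 0, eligible = FALSE),
    list(n = 4, span = 6, bad = 0, eligible = FALSE),
    list(n = 8, span = 5, bad = 3, eligible = TRUE))
  got <- vapply(specs, function(sp) {
    fl <- rep(0, sp$n)
    if (sp$bad > 0) fl[seq(2, 1 + sp$bad)] <- 0.9
    s <- toy_vf_series(md = rep(0, sp$n),
                       years = seq(0, sp$span, length.out = sp$n), fl = fl)
    vf_series_eligible(s)
  }, logical(1))
  expect_identical(got, vapply(specs, `[[`, logical(1), "eligible"))
})

test_that("AUC equals brute-force pairwise concordance", {
  set.seed(8)
  for (i in 1:12) {
    n <- sample(8:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    scores <- rnorm(n)
    brute <- local({
      pos <- scores[labels == 1]; neg <- scores[labels == 0]
      tot <- 0
      for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
      tot / (length(pos) * length(neg))
    })
    expect_equal(auc_score(scores, labels), brute, tolerance = 1e-12)
  }
  # invariant under monotone transforms of the scores
  labels <- c(0, 1, 1, 0, 1, 0, 1, 1)
  scores <- c(-2, 0.5, 3, -1, 2, 0, 1, -0.5)
  expect_equal(auc_score(exp(scores), labels), auc_score(scores, labels))
  expect_error(auc_score(scores, rep(1, 8)), "single-class")
})

test_that("VF predictor recovers a noiseless affine structure-function link", {
  set.seed(9)
  X <- matrix(runif(60 * 16, 50, 150), 60, 16)
  y <- 0.1 * rowMeans(X) - 10
  fit <- fit_vf_predictor(X[1:40, ], y[1:40])
  pred <- predict(fit, X[41:60, ])
  expect_equal(pred, y[41:60], tolerance = 1e-6)

  # 52-target mode emits one column of predictions per TD location
  Y <- sapply(1:52, function(j) 0.1 * X[, 1] + j)
  fitm <- fit_vf_predictor(X[1:40, ], Y[1:40, ])
  pm <- predict(fitm, X[41:60, ])
  expect_equal(dim(pm), c(20L, 52L))
  expect_equal(pm[, 52], Y[41:60, 52], tolerance = 1e-6)

  expect_error(fit_vf_predictor(X[1, , drop = FALSE], y[1]), "nrow")
})

test_that("logistic classifier separates separable labels and nulls at 0.5", {
  set.seed(10)
  x <- matrix(rnorm(200), 100, 2)
  y_sep <- as.integer(x[, 1] > 0)
  fit <- fit_progression_classifier(x, y_sep)
  expect_equal(auc_score(predict(fit, x), y_sep), 1)

  # labels independent of features: AUC near 1/2
  y_null <- rbinom(100, 1, 0.5)
  aucs <- replicate(10, {
    yy <- sample(y_null)
    auc_score(predict(fit_progression_classifier(x, yy), x), yy)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_error(fit_progression_classifier(x, rep(1, 100)), "single class")
})

test_that("cross-validation folds are patient-disjoint and seeded", {
  set.seed(11)
  pid <- rep(sprintf("P%02d", 1:9), each = 2)
  X <- matrix(rnorm(18 * 4), 18, 4)
  y <- rnorm(18)
  cv <- crossval_compare(X, X + 0.01, y, pid, task = "regression", k = 3,
                         seed = 2)
  expect_equal(nrow(cv), 3)
  expect_equal(sum(cv$n), 18)
  pred <- attr(cv, "predictions")
  expect_false(anyNA(pred$pred_raw))  # union of test folds covers the cohort
  cv2 <- crossval_compare(X, X + 0.01, y, pid, task = "regression", k = 3,
                          seed = 2)
  expect_identical(cv, cv2)
  expect_error(crossval_compare(X, X, y, pid, k = 10), "folds")
})

test_that("bootstrap comparison: null behavior, determinism, CI", {
  set.seed(12)
  y <- rnorm(40)
  pred <- y + rnorm(40, sd = 0.3)
  # identical predictions: difference 0, p ~ 1, CI contains 0
  bc <- bootstrap_compare(y, pred, pred, metric = "mae", n_boot = 200,
                          seed = 3)
  expect_identical(bc$difference, 0)
  expect_gte(bc$p_value, 0.9)
  expect_true(bc$ci[1] <= 0 && bc$ci[2] >= 0)

  # same seed, same inputs -> identical p
  bc4 <- bootstrap_compare(y, pred, pred, metric = "mae", n_boot = 200,
                           seed = 3)
  expect_identical(bc$p_value, bc4$p_value)

  # a clearly better predictor is detected
  bc5 <- bootstrap_compare(y, y + rnorm(40, sd = 2), y + rnorm(40, sd = 0.1),
                           metric = "mae", n_boot = 300, seed = 5)
  expect_lt(bc5$p_value, 0.05)
  expect_lt(bc5$difference, 0)
})
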