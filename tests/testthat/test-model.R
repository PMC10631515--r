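test_that("augmentation is seeded, bounded, and identity at zero bounds", {
  set.seed(1)
  v <- matrix(runif(32 * 32, 50, 150), 32, 32)
  expect_identical(augment_map(v, max_shift = 0, max_rot = 0), v)
  a1 <- augment_map(v, seed = 4)
  a2 <- augment_map(v, seed = 4)
  expect_identical(a1, a2)
  expect_false(identical(a1, augment_map(v, seed = 5)))

  # pure shifts restore the interior exactly when undone
  sh <- rnfltcorrect:::warp_map(v, shift = c(5, 0), rot = 0)
  back <- rnfltcorrect:::warp_map(sh, shift = c(-5, 0), rot = 0)
  expect_equal(back[7:26, ], v[7:26, ], tolerance = 1e-12)
})

test_that("correction loss has its closed forms", {
  p <- matrix(1, 8, 8); t_ <- matrix(1, 8, 8)
  m <- matrix(FALSE, 8, 8); m[1:4] <- TRUE
  expect_identical(correction_loss(p, t_, m), 0)
  expect_identical(correction_loss(p + 1, t_, m, lambda_mask = 5), 1 + 5 * 1)
  # empty mask: mask term is 0
  expect_identical(correction_loss(p + 2, t_, matrix(FALSE, 8, 8)), 2)
  set.seed(2)
  for (i in 1:10) {
    p2 <- matrix(rnorm(64), 8, 8)
    expect_gte(correction_loss(p2, t_, m), 0)
  }
})

test_that("contrastive loss matches a brute-force softmax oracle", {
  # two identical pairs with orthogonal cross-pair embeddings, temperature 1
  a <- c(1, 0); b <- c(0, 1)
  emb <- rbind(a, b, a, b)
  # brute force over the 4 anchors
  brute <- local({
    partner <- c(3, 4, 1, 2)
    s <- emb %*% t(emb)
    tot <- 0
    for (i in 1:4) {
      num <- exp(s[i, partner[i]])
      den <- sum(exp(s[i, setdiff(1:4, i)]))
      tot <- tot - log(num / den)
    }
    tot / 4
  })
  expect_equal(contrastive_loss(emb, temperature = 1), brute, tolerance = 1e-12)
  expect_equal(brute, log(2 + exp(1)) - 1, tolerance = 1e-12)

  # identical positives, negatives at similarity -1: loss -> 0 as tau -> 0
  emb2 <- rbind(c(1, 0), c(-1, 0), c(1, 0), c(-1, 0))
  expect_lt(contrastive_loss(emb2, temperature = 0.05), 1e-8)

  # permutation of the pair order leaves the loss unchanged
  set.seed(3)
  e <- matrix(rnorm(12), 6, 2)
  e <- e / sqrt(rowSums(e^2))
  perm <- sample(3)
  ep <- e[c(perm, perm + 3), ]
  expect_equal(contrastive_loss(e, 0.5), contrastive_loss(ep, 0.5),
               tolerance = 1e-12)

  expect_error(contrastive_loss(e[c(1, 4), , drop = FALSE]), "2 .*pairs")
})

test_that("consistency loss is moment matching over the kept region", {
  set.seed(4)
  x <- matrix(runif(100, 60, 120), 10, 10)
  keep <- matrix(runif(100) < 0.6, 10, 10)
  expect_identical(consistency_loss(x, x, keep), 0)
  expect_equal(consistency_loss(x + 7, x, keep), 7, tolerance = 1e-12)
  # permuting pixel positions leaves the statistic unchanged
  perm <- sample(sum(keep))
  y <- x; y[keep] <- y[keep][perm]
  expect_equal(consistency_loss(y, x, keep), 0, tolerance = 1e-12)
})

test_that("total loss is exactly the weighted sum", {
  cfg <- loss_config(w_contrast = 1, w_consistency = 1)
  expect_identical(total_loss(list(correct = 2, contrast = 3, consistency = 4),
                              cfg), 9)
  cfg0 <- loss_config(w_contrast = 0, w_consistency = 0)
  expect_identical(total_loss(list(correct = 2, contrast = 99,
                                   consistency = 99), cfg0), 2)
  set.seed(5)
  for (i in 1:20) {
    w <- runif(2); parts <- as.list(setNames(rnorm(3),
                                             c("correct", "contrast",
                                               "consistency")))
    got <- total_loss(parts, loss_config(w_contrast = w[1],
                                         w_consistency = w[2]))
    expect_equal(got,
                 parts$correct + w[1] * parts$contrast + w[2] * parts$consistency,
                 tolerance = 1e-12)
  }
})

test_that("training returns a reproducible history with decreasing loss", {
  pairs <- tiny_corpus()$train[1:8]
  m1 <- train_correction_model(pairs, epochs = 2, batch_size = 4, seed = 1)
  expect_s3_class(m1, "rnflt_correction")
  expect_equal(nrow(m1$history), 2)
  expect_true(all(is.finite(as.matrix(m1$history))))
  # logged parts recompose to the logged overall loss
  expect_equal(m1$history$l_overall,
               m1$history$l_correct +
                 m1$config$w_contrast * m1$history$l_contrast +
                 m1$config$w_consistency * m1$history$l_consistency,
               tolerance = 1e-12)

  m2 <- train_correction_model(pairs, epochs = 2, batch_size = 4, seed = 1)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$outc$w, m2$params$outc$w)

  m3 <- train_correction_model(pairs, epochs = 6, batch_size = 4, seed = 2)
  expect_lt(m3$history$l_overall[6], m3$history$l_overall[1])
})

test_that("correction blends: off-mask untouched, on-mask >= floor, idempotent", {
  corpus <- tiny_corpus()
  m <- train_correction_model(corpus$train[1:8], epochs = 2, batch_size = 4,
                              seed = 3)
  pr <- corpus$test[[1]]
  res <- predict(m, pr$input, pr$disc)
  am <- artifact_mask(pr$input, pr$disc)
  expect_identical(unclass(res$mask), unclass(am))
  expect_identical(res$map[!am], pr$input[!am])
  expect_true(all(res$map[am] >= 50))

  # no artifacts -> identity
  clean <- predict(m, pr$target, pr$disc)
  expect_identical(unclass(clean$map), unclass(pr$target))
  expect_false(any(clean$mask))

  # idempotence: a corrected map has nothing left below the floor
  res2 <- predict(m, res$map, pr$disc)
  expect_identical(unclass(res2$map), unclass(res$map))
})

test_that("model checkpoints round-trip through JSON", {
  corpus <- tiny_corpus()
  m <- train_correction_model(corpus$train[1:4], epochs = 1, batch_size = 4,
                              seed = 6)
  f <- tempfile(fileext = ".json")
  save_correction_model(m, f)
  m2 <- load_correction_model(f)
  expect_equal(m2$params$enc1$w, m$params$enc1$w, tolerance = 1e-12)
  expect_equal(m2$config$w_contrast, m$config$w_contrast)
  pr <- corpus$test[[1]]
  expect_equal(unclass(predict(m2, pr$input, pr$disc)$map),
               unclass(predict(m, pr$input, pr$disc)$map),
               tolerance = 1e-12)
})
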