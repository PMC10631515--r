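test_that("map construction validates values and geometry", {
  expect_s3_class(flat_map(), "rnflt_map")
  expect_error(rnflt_map(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(rnflt_map(matrix(-1, 2, 2)), "\\[0, 500\\]")
  expect_error(rnflt_map(matrix(501, 2, 2)), "\\[0, 500\\]")
  expect_error(rnflt_map(matrix(1, 2, 2), pixel_pitch = 0), "positive")
  expect_error(rnflt_map(1:4), "matrix")
})

test_that("artifact mask is sub-floor AND off-disc, values untouched", {
  f <- map_with_artifacts(10)
  expect_false(any(artifact_mask(f$map, f$disc)))

  low <- c(3, 17, 55, 70, 99)
  f <- map_with_artifacts(10, low_idx = low, low_value = 30)
  am <- artifact_mask(f$map, f$disc)
  expect_identical(which(unclass(am)), as.integer(low))
  expect_equal(f$map[low], rep(30, 5))  # original values preserved

  # a sub-floor pixel inside the disc is not an artifact
  f2 <- map_with_artifacts(10, low_idx = 45, disc_idx = 45)
  expect_false(artifact_mask(f2$map, f2$disc)[45])

  # boundary: exactly the floor value is not an artifact (strict <)
  f3 <- map_with_artifacts(10, low_idx = 7, low_value = 50)
  expect_false(any(artifact_mask(f3$map, f3$disc)))

  expect_error(
    artifact_mask(f$map, disc_mask(flat_map(n = 5), mask = matrix(FALSE, 5, 5))),
    "shape")
})

test_that("artifact ratio is artifact area over non-disc area", {
  f <- map_with_artifacts(10, low_idx = 1:5)
  am <- artifact_mask(f$map, f$disc)
  expect_equal(artifact_ratio(am, f$disc), 0.05)

  # 20 disc pixels shrink the denominator
  f2 <- map_with_artifacts(10, low_idx = 30 + (1:4), disc_idx = 1:20)
  am2 <- artifact_mask(f2$map, f2$disc)
  expect_equal(artifact_ratio(am2, f2$disc), 4 / 80)

  expect_equal(artifact_ratio(artifact_mask(flat_map(n = 10), f$disc), f$disc), 0)

  all_disc <- disc_mask(flat_map(n = 10), mask = matrix(TRUE, 10, 10))
  expect_error(artifact_ratio(am, all_disc), "undefined")
})

test_that("artifact ratio matches brute-force counting and is monotone", {
  set.seed(101)
  for (rep in 1:20) {
    v <- matrix(runif(400, 20, 150), 20, 20)
    m <- rnflt_map(v, pixel_pitch = 0.3)
    dm <- matrix(runif(400) < 0.15, 20, 20)
    d <- disc_mask(m, mask = dm)
    am <- artifact_mask(m, d)
    brute <- 0L
    for (i in 1:20) for (j in 1:20)
      if (v[i, j] < 50 && !dm[i, j]) brute <- brute + 1L
    expect_identical(artifact_ratio(am, d), brute / (400 - sum(dm)))
  }

  # adding one artifact pixel outside the disc never decreases AR
  f <- map_with_artifacts(10, low_idx = 1:5)
  ar0 <- artifact_ratio(artifact_mask(f$map, f$disc), f$disc)
  f2 <- map_with_artifacts(10, low_idx = 1:6)
  expect_gte(artifact_ratio(artifact_mask(f2$map, f2$disc), f2$disc), ar0)
})

test_that("quality classes split at 2% and 5%", {
  expect_identical(classify_quality(0.01), "high")
  expect_identical(classify_quality(0.06), "low")
  expect_identical(classify_quality(0.03), "intermediate")
  # boundaries: strict inequalities on both cutoffs
  expect_identical(classify_quality(c(0.02, 0.05)),
                   c("intermediate", "intermediate"))
})

test_that("AR strata are nested with boundaries on the <= side", {
  s <- ar_stratum(c(0.25, 0.10, 0.15, 0.20))
  expect_equal(s[1, ], c(le10 = FALSE, gt10 = TRUE, gt20 = TRUE))
  expect_equal(s[2, ], c(le10 = TRUE, gt10 = FALSE, gt20 = FALSE))
  expect_equal(s[3, ], c(le10 = FALSE, gt10 = TRUE, gt20 = FALSE))
  expect_equal(s[4, ], c(le10 = FALSE, gt10 = TRUE, gt20 = FALSE))
  # le10/gt10 partition; gt20 implies gt10
  set.seed(1)
  s2 <- ar_stratum(runif(100))
  expect_true(all(xor(s2[, "le10"], s2[, "gt10"])))
  expect_true(all(!s2[, "gt20"] | s2[, "gt10"]))
})

test_that("circle geometry centers on the disc centroid and checks bounds", {
  m <- flat_map(n = 40, pitch = 0.15)
  g <- circle_geometry(m)
  expect_equal(g$center, c(20.5, 20.5))
  expect_equal(g$radius_px, (3.46 / 2) / 0.15)

  dm <- matrix(FALSE, 40, 40); dm[18:22, 16:20] <- TRUE
  g2 <- circle_geometry(m, disc_mask(m, mask = dm))
  expect_equal(g2$center, c(20, 18))

  expect_error(circle_geometry(flat_map(n = 10, pitch = 0.1)), "fit")
})

test_that("circle scan interpolates correctly", {
  # constant map: every sample equals the constant
  cs <- extract_circle_scan(flat_map(100, n = 41, pitch = 0.15))
  expect_equal(cs$thickness, rep(100, 256))
  expect_length(cs$angles, 256)

  # linear field: mean over a full circle equals the center value
  n <- 41
  v <- matrix(60 + 0.8 * row(diag(0, n, n)) + 0.3 * col(diag(0, n, n)), n, n)
  m <- rnflt_map(v, pixel_pitch = 0.15)
  cs2 <- extract_circle_scan(m)
  ctr_val <- 60 + 0.8 * 21 + 0.3 * 21
  expect_equal(mean(cs2$thickness), ctr_val, tolerance = 1e-10)

  # radially symmetric bump peaking at the scan radius: analytic oracle
  n <- 200
  m3 <- rnflt_map(matrix(0, n, n), pixel_pitch = 0.03)
  ctr <- (n + 1) / 2
  r_mm <- sqrt(((row(diag(0, n, n)) - ctr) * 0.03)^2 +
                 ((col(diag(0, n, n)) - ctr) * 0.03)^2)
  m3[] <- 60 + 40 * exp(-(r_mm - 1.73)^2)
  cs3 <- extract_circle_scan(m3, circle_geometry(m3, n_samples = 256L))
  expect_true(all(abs(cs3$thickness - 100) < 0.5))
})

test_that("circle scan commutes with 90-degree rotation of the map", {
  set.seed(5)
  n <- 41
  v <- matrix(runif(n * n, 60, 140), n, n)
  m <- rnflt_map(v, pixel_pitch = 0.15)
  g <- circle_geometry(m, n_samples = 64L)
  cs <- extract_circle_scan(m, g)
  # rotate the grid 90 deg counter-clockwise about its center
  vr <- t(v)[, n:1]
  vr <- t(apply(v, 2, rev))  # 90 deg CCW in (row, col) convention
  mr <- rnflt_map(vr, pixel_pitch = 0.15)
  csr <- extract_circle_scan(mr, g)
  shift <- 64L / 4L
  expect_equal(csr$thickness,
               cs$thickness[((seq_len(64L) - 1L + shift) %% 64L) + 1L],
               tolerance = 1e-8)
})
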