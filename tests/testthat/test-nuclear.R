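test_that("non-touching nuclei are counted and sized correctly", {
  f <- generate_nuclei_image(c(128L, 128L), n_nuclei = 10,
                             noise = noise_none(seed = 44))
  labs <- segment_nuclei(f$dapi)
  expect_equal(max(labs), 10)
  for (i in 1:10) {
    l <- labs[round(f$truth$cy[i]) + 1, round(f$truth$cx[i]) + 1]
    expect_gt(l, 0)
    truth_area <- pi * f$truth$a[i] * f$truth$b[i]
    expect_lt(abs(sum(labs == l) / truth_area - 1), 0.1)
  }
})

test_that("a blank DAPI image yields zero labels", {
  blank <- raster_image(matrix(0, 64, 64))
  expect_equal(max(segment_nuclei(blank)), 0)
})

test_that("two tangent disks are split by the watershed", {
  x <- matrix(seq_len(96), 96, 96, byrow = TRUE)
  y <- t(x)
  m <- pmax(exp(-((x - 38)^2 + (y - 48)^2) / (2 * 36)),
            exp(-((x - 58)^2 + (y - 48)^2) / (2 * 36)))
  labs <- segment_nuclei(raster_image(m / max(m)), min_area_px = 20)
  expect_equal(max(labs), 2)
})

test_that("marker extremes give fractions of exactly 0 and 1", {
  f <- generate_nuclei_image(c(96L, 96L), n_nuclei = 5, marker_fractions = 0,
                             noise = noise_none(seed = 3))
  labs <- segment_nuclei(f$dapi)
  res0 <- nuclear_marker_metrics(f$marker, labs)
  expect_true(all(res0$nuclei$marker_stained_fraction == 0))
  expect_true(all(res0$nuclei$marker_mean_intensity == 0))

  sat <- raster_image(matrix(1, 96, 96))
  res1 <- nuclear_marker_metrics(sat, labs)
  expect_true(all(res1$nuclei$marker_stained_fraction == 1))
})

test_that("marker fractions are recovered within 0.05 on clean fields", {
  errs <- c()
  for (s in 1:5) {
    f <- generate_nuclei_image(c(128L, 128L), n_nuclei = 8,
                               noise = noise_none(seed = s))
    labs <- segment_nuclei(f$dapi)
    res <- nuclear_marker_metrics(f$marker, labs)
    for (i in 1:8) {
      l <- labs[round(f$truth$cy[i]) + 1, round(f$truth$cx[i]) + 1]
      errs <- c(errs, res$nuclei$marker_stained_fraction[res$nuclei$id == l] -
                  f$truth$marker_fraction[i])
    }
  }
  expect_lte(median(abs(errs)), 0.05)
  expect_true(all(abs(errs) < 0.12))
})

test_that("stained fraction decreases monotonically with the threshold", {
  f <- generate_nuclei_image(c(96L, 96L), n_nuclei = 4,
                             noise = noise_none(seed = 9))
  labs <- segment_nuclei(f$dapi)
  fr <- vapply(c(0.2, 0.4, 0.6, 0.8), function(thr) {
    mean(nuclear_marker_metrics(f$marker, labs,
                                stain_threshold = thr)$nuclei$marker_stained_fraction)
  }, numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("mismatched label shapes are rejected", {
  f <- generate_nuclei_image(c(96L, 96L), n_nuclei = 3,
                             noise = noise_none(seed = 2))
  labs <- segment_nuclei(f$dapi)
  expect_error(nuclear_marker_metrics(raster_image(matrix(0, 32, 32)), labs),
               "shape")
})

test_that("group-minimum normalization follows its contract", {
  expect_equal(normalize_to_group_min(c(2, 4, 8), rep("a", 3)), c(1, 2, 4))
  v <- c(2, 4, 3, 6)
  g <- c("ref", "ref", "trt", "trt")
  expect_equal(normalize_to_group_min(v, g, "ref"), c(1, 2, 1.5, 3))
  # scale invariance and idempotence
  expect_equal(normalize_to_group_min(7 * v, g, "ref"),
               normalize_to_group_min(v, g, "ref"))
  once <- normalize_to_group_min(v, g, "ref")
  expect_equal(normalize_to_group_min(once, g, "ref"), once)
  expect_error(normalize_to_group_min(c(0, 1), c("a", "a")), "positive")
  expect_error(normalize_to_group_min(c(1, 2), c("a", "a"), "b"), "empty")
})
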