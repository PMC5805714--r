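test_that("histogram equalization follows the CDF mapping", {
  const <- raster_image(matrix(0.3, 8, 8))
  expect_equal(equalize_histogram(const)$pixels, const$pixels)

  # 90% at 10/255, 10% at 200/255 -> outputs at the CDF values 0.9 and 1.0
  v <- c(rep(10 / 255, 90), rep(200 / 255, 10))
  img <- raster_image(matrix(v, 10, 10))
  out <- equalize_histogram(img)$pixels
  expect_equal(sort(unique(as.vector(round(out, 6)))), c(0.9, 1.0))

  # monotonicity: rank order of distinct values is preserved
  set.seed(8)
  m <- matrix(runif(400), 20, 20)
  eq <- equalize_histogram(raster_image(m))$pixels
  o <- order(m)
  expect_true(all(diff(eq[o]) >= 0))
})

test_that("Otsu matches the exhaustive-search oracle on 30 seeded images", {
  for (s in 1:30) {
    set.seed(s)
    px <- matrix(runif(64 * 64)^sample(c(1, 2, 3), 1), 64, 64)
    got <- otsu_threshold(raster_image(px))
    want <- oracle_otsu_threshold(px)
    expect_equal(attr(got, "threshold"), want$threshold)
    expect_identical(unclass(as.logical(got)), as.logical(want$mask))
  }
})

test_that("Otsu separates a bimodal image and rejects constants", {
  px <- matrix(c(rep(10 / 255, 70), rep(200 / 255, 30)), 10, 10)
  m <- otsu_threshold(raster_image(px))
  thr <- attr(m, "threshold")
  expect_gt(thr, 10 / 255)
  expect_lt(thr, 200 / 255)
  expect_equal(sum(m), 30)
  expect_error(otsu_threshold(raster_image(matrix(0.5, 4, 4))), "constant")
})

test_that("Otsu mask is exactly invariant to constant offsets", {
  set.seed(99)
  px <- matrix(runif(32 * 32), 32, 32)
  m1 <- otsu_threshold(px)
  m2 <- otsu_threshold(px + 0.173)
  expect_identical(as.logical(m1), as.logical(m2))
})

test_that("Frangi vesselness highlights ridges and suppresses blobs", {
  expect_equal(max(frangi_vesselness(matrix(0.4, 48, 48))), 0)

  # Gaussian ridge of width 2 px along x
  y <- matrix(seq_len(64), 64, 64)
  ridge <- exp(-(y - 32)^2 / (2 * 2^2))
  v <- frangi_vesselness(ridge, frangi_params(scales_px = c(1, 2, 3)))
  expect_true(all(v >= 0 & v <= 1))
  expect_gt(v[32, 32], v[27, 32])          # centerline beats flank
  expect_gt(v[32, 32], 0.5)

  # isotropic blob of the same contrast: R_b = 1 at the center
  x <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  blob <- exp(-((y - 32)^2 + (x - 32)^2) / (2 * 2^2))
  vb <- frangi_vesselness(blob, frangi_params(scales_px = c(1, 2, 3)))
  expect_lt(vb[32, 32], v[32, 32] / 2)
  expect_error(frangi_params(scales_px = numeric(0)), "scale")
})

test_that("hysteresis thresholding keeps weak pixels connected to strong ones", {
  ramp <- matrix(0, 5, 256)
  ramp[3, ] <- seq(0, 255) / 255
  m <- hysteresis_threshold(ramp, low = 100 / 255, high = 200 / 255)
  expect_true(all(m[3, 101:256]))          # all >= low joined to the high tail
  expect_false(any(m[3, 1:100]))

  # low == high reduces to the simple threshold
  set.seed(4)
  px <- matrix(runif(100), 10, 10)
  expect_identical(as.logical(hysteresis_threshold(px, 0.6, 0.6)),
                   as.logical(matrix(px >= 0.6, 10, 10)))

  # isolated intermediate pixel with no strong pixel in its component
  iso <- matrix(0, 9, 9)
  iso[5, 5] <- 0.5
  iso[1, 1] <- 0.9
  m2 <- hysteresis_threshold(iso, low = 0.3, high = 0.8)
  expect_false(m2[5, 5])
  expect_true(m2[1, 1])
  expect_error(hysteresis_threshold(iso, 0.9, 0.2), "low <= high")
})

test_that("hysteresis mask is bracketed by the simple-threshold masks", {
  set.seed(12)
  px <- matrix(runif(900), 30, 30)
  m <- as.logical(hysteresis_threshold(px, 0.4, 0.8))
  expect_true(all(m[px >= 0.8]))
  expect_true(!any(m[px < 0.4]))
})
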