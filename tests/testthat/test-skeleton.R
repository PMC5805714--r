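test_that("a wide band thins to a single straight chain", {
  m <- matrix(FALSE, 32, 96)
  m[13:20, 5:90] <- TRUE
  sk <- skeletonize(binary_mask(m))
  expect_equal(length(sk$segments), 1)
  expect_equal(nrow(sk$branch_points), 0)
  ys <- sk$segments[[1]][, "y"]
  expect_lte(diff(range(ys)), 1)   # essentially horizontal
})

test_that("a Y-mask yields one branch point and three segments", {
  truth <- make_y_vessel()
  imgs <- render_vessels(truth, noise_none())
  sk <- skeletonize(otsu_threshold(imgs$cd31))
  expect_equal(nrow(sk$branch_points), 1)
  long_segs <- Filter(function(sg) nrow(sg) >= 5, sk$segments)
  expect_equal(length(long_segs), 3)
})

test_that("a disk collapses to a tiny central cluster", {
  x <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  y <- t(x)
  m <- (x - 32)^2 + (y - 32)^2 <= 20^2
  sk <- skeletonize(binary_mask(m))
  expect_lt(sum(sk$pixels), 25)
  lens <- vapply(sk$segments, function(sg)
    vessel_length(sg, 1, method = "chord"), numeric(1))
  expect_true(all(lens <= 20))     # no segment longer than the radius
})

test_that("skeletonization preserves connected-component count", {
  set.seed(7)
  for (i in 1:5) {
    f <- generate_vessel_image(c(96L, 96L), n_vessels = 2, branching_prob = 0,
                               noise = noise_none(seed = i))
    mask <- otsu_threshold(f$cd31)
    sk <- skeletonize(mask)
    n_mask <- max(EBImage::bwlabel(EBImage::fillHull(
      matrix(as.numeric(as.logical(mask)), 96, 96))))
    n_skel <- max(EBImage::bwlabel(matrix(as.numeric(sk$pixels), 96, 96)))
    expect_gte(n_skel, n_mask)     # 4-connected labeling can only over-split
    expect_equal(nrow(f$truth$vessels), 2)
  }
})

test_that("empty masks give empty skeletons", {
  sk <- skeletonize(binary_mask(matrix(FALSE, 16, 16)))
  expect_equal(sum(sk$pixels), 0)
  expect_equal(length(sk$segments), 0)
})

test_that("chain length follows the step rule and its chord refinement", {
  horiz <- cbind(x = 0:100, y = rep(0, 101))
  expect_equal(vessel_length(horiz, 1), 100)
  diag <- cbind(x = 0:10, y = 0:10)
  expect_equal(vessel_length(diag, 1), 10 * sqrt(2))
  expect_equal(vessel_length(diag, 1, method = "chord"), 10 * sqrt(2))
  expect_equal(vessel_length(horiz, 0.31), 31)
  bad <- cbind(x = c(0, 5), y = c(0, 0))
  expect_error(vessel_length(bad, 1), "non-adjacent")
})

test_that("the thinned ring of a circle has close to its true circumference", {
  x <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  y <- t(x)
  r2 <- (x - 64)^2 + (y - 64)^2
  ring <- r2 <= 53^2 & r2 >= 47^2      # annulus centred on radius 50
  sk <- skeletonize(binary_mask(ring))
  total <- sum(vapply(sk$segments, function(sg)
    vessel_length(sg, 1, method = "chord"), numeric(1)))
  expect_lt(abs(total / (2 * pi * 50) - 1), 0.05)
})

test_that("EDT diameters match the band geometry and the brute-force oracle", {
  m <- matrix(FALSE, 32, 80)
  m[12:19, 5:75] <- TRUE               # half-width 4 band
  mask <- binary_mask(m)
  sk <- skeletonize(mask)
  d <- vessel_diameter(mask, sk, 1)
  expect_lt(abs(d[1] - 8), 1)

  # EDT equals brute force on small masks, including border-touching ones
  set.seed(13)
  for (i in 1:4) {
    mm <- matrix(runif(24 * 24) > 0.4, 24, 24)
    got <- EBImage::distmap(matrix(as.numeric(mm), 24, 24))
    expect_equal(matrix(as.numeric(got), 24, 24), oracle_edt(mm), tolerance = 1e-10)
  }

  expect_error(vessel_diameter(binary_mask(matrix(FALSE, 32, 80)), sk, 1),
               "outside the mask")
})

test_that("a tapered vessel reports the mean of its radius profile", {
  pl <- cbind(x = seq(5, 90, length.out = 30), y = seq(18, 30, length.out = 30))
  rad <- seq(3, 6, length.out = 30)
  truth <- vessel_truth(list(list(pl)), list(list(rad)), TRUE, c(48L, 96L))
  imgs <- render_vessels(truth, noise_none())
  mask <- otsu_threshold(imgs$cd31)
  sk <- skeletonize(mask)
  d <- vessel_diameter(mask, sk, 1)
  longest <- which.max(vapply(sk$segments, nrow, integer(1)))
  expect_lt(abs(d[longest] - 9) / 9, 0.1)
})

test_that("spur pruning removes twigs but keeps real branches", {
  truth <- make_y_vessel()
  imgs <- render_vessels(truth, noise_none())
  mask <- otsu_threshold(imgs$cd31)
  sk <- prune_skeleton(skeletonize(mask), mask)
  expect_equal(nrow(sk$branch_points), 1)
  total <- sum(vapply(sk$segments, function(sg)
    vessel_length(sg, 1, method = "chord"), numeric(1)))
  expect_gt(total, 0.75 * truth$total_length_px)
})
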