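test_that("a straight horizontal tube rasterizes to a band of twice the radius", {
  truth <- make_straight_vessel(shape = c(64L, 128L), y = 32.5, radius = 4)
  imgs <- render_vessels(truth, noise_none())
  mask <- imgs$cd31$pixels >= 0.5
  widths <- colSums(mask[, 20:100])
  expect_true(all(widths == 8))
  expect_equal(truth$total_length_px, 127)
})

test_that("zero perfused fraction leaves the lectin channel blank", {
  f <- generate_vessel_image(c(96L, 96L), n_vessels = 3, perfused_fraction = 0,
                             noise = noise_none(seed = 11))
  expect_true(all(f$lectin$pixels == 0))
  expect_false(any(f$truth$vessels$perfused))
})

test_that("a Y-shaped tree yields exactly one branch point", {
  truth <- make_y_vessel()
  imgs <- render_vessels(truth, noise_none())
  sk <- skeletonize(otsu_threshold(imgs$cd31))
  expect_equal(nrow(sk$branch_points), 1)
  # brute-force oracle: the thinned grid carries >=3-neighbour pixels at the
  # junction, and the reported branch point sits there
  nb <- oracle_neighbor_count(sk$pixels)
  hubs <- which(sk$pixels & nb >= 3, arr.ind = TRUE)
  expect_gte(nrow(hubs), 1)
  hub_xy <- cbind(hubs[, 2] - 1, hubs[, 1] - 1)
  # homotopic thinning migrates an acute-angle junction into the fork by up
  # to r / tan(theta / 2); allow that bound plus discretization
  d_true <- sqrt((hub_xy[, 1] - 47.5)^2 + (hub_xy[, 2] - 48)^2)
  expect_lt(min(d_true), 12)
  bp <- sk$branch_points
  expect_lt(sqrt((bp[1, "x"] - 47.5)^2 + (bp[1, "y"] - 48)^2), 12)
})

test_that("degenerate zero-length polylines are rejected", {
  pl <- cbind(x = c(10, 10), y = c(20, 20))
  expect_error(
    render_vessels(vessel_truth(list(list(pl)), list(list(3)), TRUE, c(64L, 64L))),
    "zero-length")
})

test_that("vessel generation is deterministic and non-overlapping", {
  a <- generate_vessel_image(c(96L, 96L), n_vessels = 3, noise = noise_model(seed = 5))
  b <- generate_vessel_image(c(96L, 96L), n_vessels = 3, noise = noise_model(seed = 5))
  expect_identical(a$cd31$pixels, b$cd31$pixels)
  expect_identical(a$truth$vessels, b$truth$vessels)
  expect_error(generate_vessel_image(c(32L, 32L)), "64x64")
  expect_error(generate_vessel_image(c(96L, 96L), radius_range_px = c(3, 50)),
               "radius_range")
})

test_that("nuclei: full and empty marker fractions are exact", {
  f1 <- generate_nuclei_image(c(96L, 96L), n_nuclei = 4, marker_fractions = 1,
                              noise = noise_none(seed = 2))
  # marker-positive area equals the DAPI nucleus area
  expect_equal(f1$marker$pixels > 0.5, f1$dapi$pixels > 0.5)
  f0 <- generate_nuclei_image(c(96L, 96L), n_nuclei = 4, marker_fractions = 0,
                              noise = noise_none(seed = 2))
  expect_true(all(f0$marker$pixels == 0))
})

test_that("nucleus marker fractions are recovered within 0.05 on clean fields", {
  f <- generate_nuclei_image(c(128L, 128L), n_nuclei = 10,
                             noise = noise_none(seed = 31))
  # pixel-counting oracle on the noise-free masks, restricted to each
  # nucleus via its own truth ellipse
  dapi_mask <- f$dapi$pixels > 0.5
  marker_mask <- f$marker$pixels > 0.5
  X <- matrix(seq_len(128) - 1, 128, 128, byrow = TRUE)
  Y <- matrix(seq_len(128) - 1, 128, 128)
  for (i in seq_len(10)) {
    dx <- X - f$truth$cx[i]; dy <- Y - f$truth$cy[i]
    th <- f$truth$theta[i]
    xr <- dx * cos(th) + dy * sin(th)
    yr <- -dx * sin(th) + dy * cos(th)
    inside <- (xr / f$truth$a[i])^2 + (yr / f$truth$b[i])^2 <= 1.2
    frac <- sum(marker_mask & inside) / sum(dapi_mask & inside)
    expect_lt(abs(frac - f$truth$marker_fraction[i]), 0.05)
  }
})

test_that("nucleus placement failure names the constraint", {
  expect_error(
    generate_nuclei_image(c(64L, 64L), n_nuclei = 60, axes_range_px = c(6, 8),
                          noise = noise_none(seed = 1)),
    "non-overlapping nuclei")
})

test_that("junction coverage extremes behave as stated", {
  f1 <- generate_junction_image(c(96L, 96L), n_cells = 4, stained_coverage = 1,
                                noise = noise_none(seed = 3))
  expect_equal(f1$truth$gap_count, 0L)
  expect_equal(f1$truth$stained_length_px, sum(f1$truth$interface_length_px))
  f0 <- generate_junction_image(c(96L, 96L), n_cells = 4, stained_coverage = 0,
                                noise = noise_none(seed = 3))
  expect_equal(f0$truth$stained_length_px, 0)
  expect_true(all(f0$vec$pixels == 0))
})

test_that("junction truth intervals are disjoint and within their interface", {
  f <- generate_junction_image(c(128L, 128L), n_cells = 9, stained_coverage = 0.5,
                               noise = noise_none(seed = 9))
  for (e in seq_along(f$truth$interfaces)) {
    runs <- f$truth$stained_runs[[e]]
    if (nrow(runs) < 1) next
    expect_true(all(runs[, 2] > runs[, 1]))
    expect_lte(max(runs), f$truth$interface_length_px[e] + 1e-9)
    if (nrow(runs) > 1) {
      expect_true(all(runs[-1, 1] >= runs[-nrow(runs), 2] - 1e-9))
    }
    expect_equal(f$truth$gap_count_per_interface[e], nrow(runs) - 1L)
  }
})

test_that("rendered junction run lengths match truth within 10%", {
  f <- generate_junction_image(c(128L, 128L), n_cells = 9, stained_coverage = 0.5,
                               noise = noise_none(seed = 21))
  jr <- junction_pipeline(f$vec, f$cd31)
  expect_lt(abs(jr$totals$stained_um / f$truth$stained_length_px - 1), 0.1)
})
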