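test_that("a fully stained straight interface yields one run of its length", {
  # 30 um interface at 0.5 um/px = 60 px band in the middle of the field
  pl <- cbind(x = c(20, 80), y = c(48, 48))
  cd31 <- rasterize_for_test <- matrix(0, 96, 96)
  vec <- matrix(0, 96, 96)
  for (xx in 20:80) {
    cd31[(48 - 3):(48 + 3) + 1, xx + 1] <- 1
    vec[(48 - 1):(48 + 1) + 1, xx + 1] <- 1
  }
  runs <- junction_length(raster_image(vec, 0.5), binary_mask(cd31 > 0, 0.5))
  expect_equal(nrow(runs), 1)
  expect_lt(abs(runs$length_um - 30), 1.5)
})

test_that("an unstained image yields zero runs", {
  cd31 <- matrix(FALSE, 64, 64); cd31[30:36, 5:60] <- TRUE
  runs <- junction_length(raster_image(matrix(0, 64, 64)), binary_mask(cd31))
  expect_equal(nrow(runs), 0)
  expect_error(junction_length(raster_image(matrix(0, 64, 64)),
                               binary_mask(matrix(FALSE, 64, 64))), "empty")
})

test_that("three stained runs on one interface are recovered within 10%", {
  # runs of 5 / 10 / 15 um at 0.5 um/px on a straight interface
  pl <- cbind(x = c(5, 120), y = c(40, 40))
  intervals <- rbind(c(10, 20), c(40, 60), c(80, 110))   # px
  cd31 <- matrix(0, 80, 128)
  for (xx in 5:120) cd31[(40 - 3):(40 + 3) + 1, xx + 1] <- 1
  vec <- vasquant:::rasterize_runs(c(80L, 128L), pl, intervals, radius = 1.5)
  runs <- junction_length(raster_image(vec, 0.5), binary_mask(cd31 > 0, 0.5))
  expect_equal(nrow(runs), 3)
  got <- sort(runs$length_um)
  want <- c(5, 10, 15)
  expect_true(all(abs(got / want - 1) < 0.1))
})

test_that("junction continuity splits runs and counts gaps per the contract", {
  # one run covering the whole interface
  full <- junction_continuity(matrix(c(0, 50), 1, 2), 50)
  expect_equal(full$continuous_percent, 100)
  expect_equal(full$gap_count, 0L)
  expect_equal(full$gap_index, 0)

  # no runs: missing percentages, one whole-interface gap
  none <- junction_continuity(NULL, 50)
  expect_true(is.na(none$continuous_percent))
  expect_equal(none$gap_count, 1L)
  expect_equal(none$gap_index, 2)

  # known layout: runs 1.5 / 10 / 20 um with two 5-um gaps
  runs <- rbind(c(0, 1.5), c(6.5, 16.5), c(21.5, 41.5))
  cc <- junction_continuity(runs, 41.5, min_run_um = 2, min_gap_um = 0.5)
  expect_equal(cc$n_runs, 3L)
  expect_equal(cc$gap_count, 2L)
  expect_equal(cc$stained_um, 31.5)
  expect_equal(cc$continuous_percent, 100 * 30 / 31.5)
  expect_equal(cc$discontinuous_percent, 100 * 1.5 / 31.5)

  expect_error(junction_continuity(runs, 0), "positive")
  expect_error(junction_continuity(rbind(c(0, 5), c(3, 8)), 10), "disjoint")
})

test_that("generator gap counts are recovered exactly on clean fields", {
  for (s in 1:4) {
    f <- generate_junction_image(c(128L, 128L), n_cells = 9,
                                 stained_coverage = 0.7,
                                 noise = noise_none(seed = s))
    jr <- junction_pipeline(f$vec, f$cd31)
    expect_equal(jr$totals$gap_count, f$truth$gap_count)
    expect_lt(abs(jr$totals$stained_um / f$truth$stained_length_px - 1), 0.1)
  }
})

test_that("run lengths never exceed their interface lengths", {
  f <- generate_junction_image(c(128L, 128L), n_cells = 9, stained_coverage = 0.8,
                               noise = noise_none(seed = 17))
  jr <- junction_pipeline(f$vec, f$cd31)
  expect_true(all(jr$interfaces$stained_um <=
                  jr$interfaces$interface_length_um + 1e-9))
})

test_that("the gap index falls as stained coverage rises", {
  gi <- vapply(c(0.3, 0.5, 0.7, 0.9), function(cv) {
    f <- generate_junction_image(c(128L, 128L), n_cells = 9,
                                 stained_coverage = cv,
                                 noise = noise_none(seed = 55))
    junction_pipeline(f$vec, f$cd31)$totals$gap_index
  }, numeric(1))
  expect_true(all(diff(gi) <= 1e-9))
})
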