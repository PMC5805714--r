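test_that("tumor volume follows the caliper formula", {
  expect_equal(tumor_volume(0, 5), 0)
  expect_equal(tumor_volume(10, 10), 500)
  expect_equal(tumor_volume(4, 6), 48)
  expect_equal(tumor_volume(c(2, 4), c(3, 6)), c(6, 48))
  expect_error(tumor_volume(-1, 5), "non-negative")
})

test_that("2^-ddCt is anchored at the lowest-expression sample", {
  expect_equal(rq_ddct(25, 20), 1)
  # dCt of 20 and 23: the 23 sample is the calibrator, the other is 8-fold
  expect_equal(rq_ddct(c(30, 33), c(10, 10)), c(8, 1))
  rq <- rq_ddct(c(24, 26, 28), c(20, 20, 20))
  expect_equal(min(rq), 1)
  expect_true(all(rq > 0))
  # shifting every reference Ct leaves Rq unchanged
  expect_equal(rq_ddct(c(24, 26, 28), c(20, 20, 20) + 3.7),
               rq)
  expect_error(rq_ddct(numeric(0), numeric(0)), "no samples")
  expect_error(rq_ddct(c(20, NA), c(1, 1)), "finite")
})

test_that("H-score is the percent x intensity product on [0, 300]", {
  expect_equal(h_score(0, 1), 0)
  expect_equal(h_score(100, 3), 300)
  expect_equal(h_score(55, 2), 110)
  expect_error(h_score(55, 4), "grade")
  expect_error(h_score(120, 2), "\\[0, 100\\]")
})

test_that("standard curves fit, interpolate and round-trip", {
  lin <- fit_standard_curve(c(1, 2), c(10, 20))
  expect_equal(as.numeric(interpolate_curve(lin, 15)), 1.5)

  # qPCR-style: dilutions 1..8, Ct falling one cycle per doubling
  chip <- fit_standard_curve(c(1, 2, 4, 8), c(30, 29, 28, 27), log_base = 2)
  expect_equal(chip$slope, -1)
  expect_equal(as.numeric(interpolate_curve(chip, 26.5)), 2^3.5)
  ex <- attr(interpolate_curve(chip, c(28, 26.5)), "extrapolated")
  expect_identical(ex, c(FALSE, TRUE))

  # round trip on its own fit points
  back <- interpolate_curve(chip, c(30, 29, 28, 27))
  expect_equal(as.numeric(back), c(1, 2, 4, 8), tolerance = 1e-9)

  expect_error(fit_standard_curve(c(1, 1), c(2, 3)), "monotone|singular")
  expect_error(fit_standard_curve(c(-1, 2), c(1, 2), log_base = 2), "positive")
})

test_that("ChIP signal relative to input subtracts the IgG background", {
  curve <- fit_standard_curve(c(1, 2, 4, 8), c(30, 29, 28, 27), log_base = 2)
  expect_equal(chip_relative_to_input(33, 30, 33, curve, 0.01), 0)
  # hand-computed: quantities 2^-3 and 2^-6 of the 1% input scaled 100x
  q_chip <- 2^-3; q_igg <- 2^-6
  want <- (q_chip - q_igg) / (1 / 0.01)
  got <- chip_relative_to_input(33, 30, 36, curve, 0.01)
  expect_equal(got, want, tolerance = 1e-12)
  # chip equal to the scaled input with no IgG signal gives 1
  lowq <- interpolate_curve(curve, 60)   # vanishing IgG quantity
  expect_equal(chip_relative_to_input(30 - log2(100), 30, 60, curve, 0.01), 1,
               tolerance = 1e-6)
  expect_error(chip_relative_to_input(30, 30, 30, curve, 0), "input_fraction")
})

test_that("the 2x2 chi-square matches its summation form and chisq.test", {
  expect_equal(pearson_chi2_2x2(table2x2(10, 10, 10, 10))$chi2, 0)
  expect_equal(pearson_chi2_2x2(table2x2(10, 10, 10, 10))$p, 1)

  set.seed(77)
  for (i in 1:20) {
    v <- rpois(4, 15) + 1
    t <- table2x2(v[1], v[2], v[3], v[4])
    got <- pearson_chi2_2x2(t)
    expect_equal(got$chi2, oracle_chi2_sum(v[1], v[2], v[3], v[4]),
                 tolerance = 1e-12)
    ref <- suppressWarnings(
      chisq.test(matrix(v, 2, byrow = TRUE), correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    # symmetry under swapping rows and under swapping columns
    expect_equal(pearson_chi2_2x2(table2x2(v[3], v[4], v[1], v[2]))$chi2, got$chi2)
    expect_equal(pearson_chi2_2x2(table2x2(v[2], v[1], v[4], v[3]))$chi2, got$chi2)
  }
  expect_error(pearson_chi2_2x2(table2x2(0, 0, 5, 5)), "margin")
  expect_error(table2x2(-1, 2, 3, 4), "non-negative")
})

test_that("the DAR-1 vessel classification table gives p = 0.016 uncorrected", {
  res <- pearson_chi2_2x2(table2x2(35, 11, 17, 17))
  expect_equal(round(res$p, 3), 0.016)
  # Yates' correction moves it to ~0.029, hence the uncorrected default
  expect_equal(round(pearson_chi2_2x2(table2x2(35, 11, 17, 17),
                                      correct = TRUE)$p, 3), 0.029)
})

test_that("Spearman correlation handles monotone data and exact p-values", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_correlation(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)

  set.seed(3)
  for (i in 1:3) {
    y <- rnorm(6)
    got <- spearman_correlation(x, y)
    expect_equal(got$p, oracle_spearman_p(x, y), tolerance = 1e-12)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  }
  # ties handled by midranks
  tied <- spearman_correlation(c(1, 2, 2, 3, 4, 5), c(2, 3, 3, 4, 6, 6))
  expect_equal(tied$rho,
               cor(rank(c(1, 2, 2, 3, 4, 5)), rank(c(2, 3, 3, 4, 6, 6))))
  # large-n path uses the t approximation
  set.seed(5)
  xx <- rnorm(40); yy <- xx + rnorm(40)
  big <- spearman_correlation(xx, yy)
  expect_equal(big$method, "t approximation")
  expect_lt(big$p, 0.001)
  expect_error(spearman_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})
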