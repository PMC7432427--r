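test_that("Shannon and maximum entropy behave on canonical vectors", {
  expect_equal(shannon_entropy(rep(1 / 9, 9)), log2(9))
  expect_equal(shannon_entropy(c(1, rep(0, 8))), 0)
  expect_equal(max_entropy(9), log2(9))
  expect_equal(max_entropy(2), 1)
  expect_equal(max_entropy(8), 3)
  expect_error(max_entropy(1), class = "gazeflow_param_error")
  expect_error(shannon_entropy(c(0.5, 0.6)), class = "gazeflow_data_error")
  expect_error(shannon_entropy(c(-0.1, 1.1)), class = "gazeflow_data_error")
})

test_that("entropy matches a term-by-term oracle on a published occupancy row", {
  # driver 5's regional shares (%), renormalized
  shares <- c(17.18, 2.86, 0.02, 8.91, 68.41, 1.91, 0.50, 0.17, 0.02)
  p <- shares / sum(shares)
  oracle <- 0
  for (pi in p) if (pi > 0) oracle <- oracle - pi * log2(pi)
  expect_equal(shannon_entropy(p), oracle)
  expect_equal(oracle, 1.44, tolerance = 0.005)
})

test_that("shannon_entropy is permutation-invariant and maximized by uniform", {
  withr::with_seed(5, {
    for (i in 1:10) {
      p <- stats::runif(9); p <- p / sum(p)
      expect_equal(shannon_entropy(sample(p)), shannon_entropy(p))
      expect_lte(shannon_entropy(p), log2(9) + 1e-12)
    }
  })
  # exhaustive small-grid search over 3-area distributions on a 0.05 grid:
  # no grid point beats the uniform vector
  grid <- expand.grid(a = seq(0, 1, 0.05), b = seq(0, 1, 0.05))
  grid <- grid[grid$a + grid$b <= 1, ]
  vals <- apply(grid, 1, function(r) {
    shannon_entropy(c(r[1], r[2], max(0, 1 - r[1] - r[2])), tol = 1e-6)
  })
  expect_lte(max(vals), log2(3) + 1e-12)
})

test_that("the entropy rate reproduces the representative driver and closed forms", {
  stats5 <- dplyr::filter(driver_gaze_stats(), driver == 5)
  s <- fixation_summary(stats5$area, stats5$gaze_share_pct, stats5$mean_duration_ms)
  e <- fixation_entropy(s)
  # frozen from an independent spreadsheet-style summation over the nine
  # printed (share, duration) pairs
  expect_equal(e$E_n, 3.0132, tolerance = 1e-4)
  expect_equal(e$D, 9)
  expect_equal(e$E_max, log2(9))

  # uniform shares with all mean durations of 1 s: each of the D terms is
  # 1/D, so E_n is exactly 1
  u <- fixation_summary(LETTERS[1:9], rep(1, 9), rep(1000, 9))
  expect_equal(fixation_entropy_rate(u), 1)

  # degenerate occupancy has zero entropy and zero rate (one retained area
  # would be degenerate, so spread the zero mass over several)
  d <- fixation_summary(LETTERS[1:3], c(1, 1, 1) * 1e-12 + c(1, 0, 0),
                        c(200, 150, 100))
  expect_equal(fixation_entropy(d, tol = 1e-6)$E, 0, tolerance = 1e-9)
  expect_equal(fixation_entropy(d)$E_n, 0, tolerance = 1e-7)
})

test_that("entropy rate scales inversely with a uniform duration rescaling", {
  withr::with_seed(6, {
    p <- stats::runif(9); p <- p / sum(p)
    T_ms <- stats::runif(9, 80, 260)
    s1 <- fixation_summary(LETTERS[1:9], p, T_ms)
    s2 <- fixation_summary(LETTERS[1:9], p, 3 * T_ms)
    expect_equal(fixation_entropy_rate(s1) / 3, fixation_entropy_rate(s2))
  })
})

test_that("excluding an area renormalizes shares and adapts the area count", {
  stats8 <- dplyr::filter(driver_gaze_stats(), driver == 8)
  s <- fixation_summary(stats8$area, stats8$gaze_share_pct, stats8$mean_duration_ms)
  e <- fixation_entropy(s, exclude = "A")
  expect_equal(e$D, 8)
  expect_equal(e$E_max, 3)
  expect_equal(sum(e$areas$p_renormalized, na.rm = TRUE), 1)
  expect_true(e$areas$excluded[e$areas$area == "A"])
  # threshold-based exclusion finds the same artefact cell
  e2 <- fixation_entropy(s, min_duration_ms = 1)
  expect_equal(e2$E_n, e$E_n)
  # a sub-millisecond duration kept in the sum explodes the statistic
  expect_gt(fixation_entropy(s)$E_n, 100)
})

test_that("only the validated formula variant lands in the plausible range", {
  stats5 <- dplyr::filter(driver_gaze_stats(), driver == 5)
  s <- fixation_summary(stats5$area, stats5$gaze_share_pct, stats5$mean_duration_ms)
  validated <- fixation_entropy_rate(s, variant = "validated")
  others <- vapply(c("summed_product", "per_area", "mean_duration"),
                   function(v) fixation_entropy_rate(s, variant = v), numeric(1))
  expect_equal(validated, 3.0132, tolerance = 1e-4)
  expect_true(all(abs(others - 3.0132) > 0.5))
})

test_that("group percent difference matches its definition", {
  expect_equal(group_percent_difference(3.2, 2.6), 23.08, tolerance = 1e-3)
  expect_equal(group_percent_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(group_percent_difference(2, 1), 100)
  expect_error(group_percent_difference(numeric(), 1), class = "gazeflow_data_error")
  expect_error(group_percent_difference(1, 0), class = "gazeflow_data_error")
})
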