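test_that("sequence simulation is reproducible and respects the chain", {
  P <- diag(2)
  dimnames(P) <- list(c("D", "E"), c("D", "E"))
  s <- simulate_aoi_sequence(10, P, start = "D", seed = 1)
  expect_equal(s$aoi, rep("D", 10))  # absorbing start state

  P2 <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE,
               dimnames = list(c("D", "E"), c("D", "E")))
  a <- simulate_aoi_sequence(200, P2, seed = 42)
  b <- simulate_aoi_sequence(200, P2, seed = 42)
  expect_identical(a$aoi, b$aoi)
  expect_identical(a$duration_ms, b$duration_ms)
  c2 <- simulate_aoi_sequence(200, P2, seed = 43)
  expect_false(identical(a$aoi, c2$aoi))

  expect_error(simulate_aoi_sequence(10, P2), class = "gazeflow_config_error")
  expect_error(simulate_aoi_sequence(10, matrix(c(0.5, 0.4, 0.5, 0.5), 2),
                                     states = c("D", "E"), seed = 1),
               class = "gazeflow_data_error")
})

test_that("long simulations hit the closed-form stationary occupancy", {
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE,
              dimnames = list(c("D", "E"), c("D", "E")))
  s <- simulate_aoi_sequence(50000, P, seed = 7)
  freq <- table(s$aoi) / nrow(s)
  expect_equal(unname(freq[["D"]]), 5 / 6, tolerance = 0.012)
  expect_equal(unname(freq[["E"]]), 1 / 6, tolerance = 0.06)
})

test_that("one-step estimation recovers the generating matrix", {
  states <- c("A+B", "C", "D+E", "F", "G+H", "I")
  P_true <- matrix(0.02, 6, 6) + diag(6) * 0.5
  P_true <- P_true / rowSums(P_true)
  dimnames(P_true) <- list(states, states)
  seq6 <- simulate_aoi_sequence(10001, P_true, duration_means = 180, seed = 22)
  m <- fit_transition_model(seq6, states = states)
  expect_lt(max(abs(m$P1 - P_true)), 0.02)
})

test_that("Chapman-Kolmogorov holds for Markov sequences and fails for lag-2 designs", {
  states <- c("A+B", "C", "D+E", "F", "G+H", "I")
  P_true <- matrix(0.03, 6, 6) + diag(6) * 0.4
  P_true <- P_true / rowSums(P_true)
  dimnames(P_true) <- list(states, states)
  seq6 <- simulate_aoi_sequence(10001, P_true, duration_means = 180, seed = 23)
  m <- fit_transition_model(seq6, states = states)
  expect_lt(max(abs(m$P2_emp - k_step_power(m$P1, 2))), 0.02)

  # AABB block repetition: every one-step move is a fair coin between
  # staying and switching, but two steps ahead the state always switches,
  # so the empirical lag-2 matrix sits far from the one-step square
  n <- 3000
  lab <- rep(c("D", "D", "E", "E"), length.out = n)
  withr::with_seed(3, {
    flip <- stats::runif(n) < 0.02
    lab[flip] <- sample(c("D", "E"), sum(flip), replace = TRUE)
  })
  m2 <- fit_transition_model(lab, states = c("D", "E"))
  dep <- max(abs(m2$P2_emp - k_step_power(m2$P1, 2)))
  expect_gt(dep, 0.2)
})

test_that("rendered gaze streams replay their AOI sequence through the pipeline", {
  sch <- aoi_scheme_grid()
  seq0 <- aoi_sequence(c("D", "E", "D"), c(400, 400, 400))
  stream <- simulate_gaze_stream(seq0, sch, jitter_sd = 0.002, seed = 31)
  fx <- detect_fixations(stream, velocity_threshold = 2)
  coded <- code_fixations(fx, sch)
  expect_equal(coded$aoi, c("D", "E", "D"))
  truth <- attr(stream, "ground_truth")
  expect_equal(truth$aoi, c("D", "E", "D"))

  # sub-75 ms blink gaps split fixations; glance merging heals them
  seqb <- aoi_sequence(rep(c("D", "E"), 5), rep(500, 10))
  blinky <- simulate_gaze_stream(seqb, sch, jitter_sd = 0.002, blink_prob = 1,
                                 blink_ms = 50, seed = 32)
  fxb <- code_fixations(detect_fixations(blinky, velocity_threshold = 2), sch)
  expect_gt(nrow(fxb), 10)
  healed <- merge_glances(fxb, same_aoi_required = TRUE)
  expect_equal(nrow(healed), 10)
  expect_equal(healed$aoi, seqb$aoi)

  # 100 ms gaps must survive merging as genuine splits
  gappy <- simulate_gaze_stream(seqb, sch, jitter_sd = 0.002, blink_prob = 1,
                                blink_ms = 100, seed = 33)
  fxg <- merge_glances(
    code_fixations(detect_fixations(gappy, velocity_threshold = 2), sch),
    same_aoi_required = TRUE)
  expect_gt(nrow(fxg), 10)

  expect_error(simulate_gaze_stream(seq0, sch, jitter_sd = 0.2, seed = 1),
               class = "gazeflow_config_error")
})

test_that("noisy end-to-end replay keeps at least 99 percent label agreement", {
  preset <- workload_preset("normal")
  seq0 <- simulate_aoi_sequence(150, preset$P, seed = 41)
  truth <- collapse_runs(seq0$aoi)
  stream <- simulate_gaze_stream(seq0, aoi_scheme_grid(), seed = 42)
  out <- run_gaze_pipeline(stream)
  got <- out$sequence$aoi
  expect_equal(length(got), length(truth))
  expect_gte(mean(got == truth), 0.99)
})

test_that("workload presets produce front-dominant merged stationary structure", {
  for (cond in c("mild", "moderate", "deep", "normal")) {
    preset <- workload_preset(cond)
    x <- stationary_distribution(preset$P)
    expect_equal(sum(x), 1, tolerance = 1e-9)
    expect_equal(as.numeric(x), unname(preset$pi), tolerance = 1e-9)
    merged_front <- sum(x[c("D", "E")])
    expect_gt(merged_front, 0.85)
    expect_gt(sum(x[c("G", "H")]), sum(x[c("A", "B")]))  # right is secondary
  }
})

test_that("entropy of simulated table-like sequences lies in the plausible band", {
  preset <- workload_preset("normal")
  seq0 <- simulate_aoi_sequence(800, preset$P, seed = 51)
  sm <- summarize_fixations(seq0)
  e <- fixation_entropy_rate(sm)
  expect_gt(e, 1.5)
  expect_lt(e, 5)
})
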