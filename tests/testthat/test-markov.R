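test_that("one-step estimates match hand counts", {
  m <- fit_transition_model(c("D", "D", "D"), states = c("D", "E"))
  expect_equal(m$P1["D", "D"], 1)
  expect_equal(m$zero_rows, "E")

  m2 <- fit_transition_model(c("D", "E", "D", "E"), states = c("D", "E"))
  expect_equal(m2$P1["D", "E"], 1)
  expect_equal(m2$P1["E", "D"], 1)
  expect_equal(sum(m2$counts1), 3)

  m3 <- fit_transition_model(c("D", "E", "D", "D"), states = c("D", "E"))
  expect_equal(m3$P1["D", "E"], 0.5)
  expect_equal(m3$P1["D", "D"], 0.5)
  expect_equal(m3$P1["E", "D"], 1)

  expect_error(fit_transition_model("D"), class = "gazeflow_data_error")
})

test_that("two-step estimates are empirical lag-2 frequencies, not a matrix square", {
  p2 <- estimate_two_step_empirical(c("D", "E", "D", "E", "D"),
                                    states = c("D", "E"))
  expect_equal(p2["D", "D"], 1)
  expect_equal(p2["E", "E"], 1)

  single <- estimate_two_step_empirical(c("A", "B", "C"),
                                        states = c("A", "B", "C"))
  expect_equal(single["A", "C"], 1)
  expect_error(estimate_two_step_empirical(c("A", "B")),
               class = "gazeflow_data_error")

  # a deterministic alternation: P1^2 is the identity, and here the
  # empirical lag-2 matrix coincides; a lag-2-dependent sequence must not
  m <- fit_transition_model(c("D", "E", "D", "E", "D"), states = c("D", "E"))
  expect_equal(m$P2_emp, k_step_power(m$P1, 2))
})

test_that("k-step powers match hand multiplication and keep stochasticity", {
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(k_step_power(P, 1), P)
  P2 <- k_step_power(P, 2)
  expect_equal(unname(P2), matrix(c(0.86, 0.14, 0.70, 0.30), 2, byrow = TRUE))
  expect_equal(rowSums(k_step_power(P, 7)), c(a = 1, b = 1))
  I4 <- diag(4)
  expect_equal(k_step_power(I4, 5), I4)
  expect_error(k_step_power(matrix(c(0.5, 0.1, 0.5, 0.5), 2), 2),
               class = "gazeflow_data_error")
  expect_error(k_step_power(P, 0), class = "gazeflow_param_error")
})

test_that("stationary distributions solve XP = X and agree with power iteration", {
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  x <- stationary_distribution(P)
  expect_equal(as.numeric(x), c(5 / 6, 1 / 6))  # closed form p21/(p12+p21)
  expect_equal(as.numeric(x %*% P), as.numeric(x), tolerance = 1e-9)
  expect_true(attr(x, "unique"))
  expect_equal(as.numeric(x), unname(power_iter_stationary(P)), tolerance = 1e-10)

  # doubly stochastic: uniform
  Q <- matrix(c(0.2, 0.3, 0.5, 0.5, 0.2, 0.3, 0.3, 0.5, 0.2), 3, byrow = TRUE)
  expect_equal(as.numeric(stationary_distribution(Q)), rep(1 / 3, 3))

  # identity: every distribution is stationary; flagged, uniform by convention
  xi <- stationary_distribution(diag(3))
  expect_false(attr(xi, "unique"))
  expect_equal(as.numeric(xi), rep(1 / 3, 3))

  expect_error(stationary_distribution(matrix(c(NaN, 1, 0.5, 0.5), 2)),
               class = "gazeflow_data_error")
})

test_that("random irreducible chains satisfy the stationary identity to 1e-9", {
  withr::with_seed(8, {
    for (i in 1:10) {
      n <- sample(3:9, 1)
      P <- matrix(stats::rgamma(n * n, 1) + 0.01, n)
      P <- P / rowSums(P)
      x <- stationary_distribution(P)
      expect_equal(sum(x), 1, tolerance = 1e-12)
      expect_equal(as.numeric(x %*% P), as.numeric(x), tolerance = 1e-9)
      expect_equal(as.numeric(x), unname(power_iter_stationary(P, 5000)),
                   tolerance = 1e-8)
    }
  })
})

test_that("state merging conserves counts and reproduces aggregate structure", {
  withr::with_seed(9, {
    labels <- sample(LETTERS[1:9], 400, replace = TRUE,
                     prob = c(2, 3, 1, 30, 40, 3, 4, 15, 2))
    m <- fit_transition_model(labels, states = aoi_labels())
    merged <- merge_states(m)
    expect_equal(sum(merged$counts1), sum(m$counts1))
    expect_equal(sum(merged$counts2), sum(m$counts2))
    expect_equal(merged$states, c("A+B", "C", "D+E", "F", "G+H", "I"))
    # block sums of the 9-state counts equal merged counts
    g <- aoi_grouping_default6()
    expect_equal(merged$counts1["D+E", "G+H"],
                 sum(m$counts1[c("D", "E"), c("G", "H")]))
    rs <- rowSums(merged$P1)
    expect_true(all(abs(rs[rowSums(merged$counts1) > 0] - 1) < 1e-9))
  })

  # a sequence confined to D and E merges to a single absorbing front state
  seq_de <- aoi_sequence(rep(c("D", "E"), 10), rep(150, 20))
  merged_de <- merge_states(fit_transition_model(seq_de, states = aoi_labels()))
  expect_equal(merged_de$P1["D+E", "D+E"], 1)
  x <- stationary_distribution(merged_de)
  expect_equal(unname(x["D+E"]), 1)
  expect_equal(sum(x), 1)

  m <- fit_transition_model(c("D", "E"), states = aoi_labels())
  expect_error(merge_states(m, grouping = c(D = "front")),
               class = "gazeflow_config_error")
})

test_that("published merged stationary vectors are valid distributions with front dominance", {
  X <- list(mild = c(0, 0, 0.8947, 0, 0.1053, 0),
            moderate = c(0, 0, 0.8966, 0, 0.1034, 0),
            deep = c(0.0035, 0, 0.9031, 0, 0.0934, 0),
            normal = c(0.011, 0.0004, 0.9193, 0.0019, 0.0655, 0.0019))
  for (x in X) {
    expect_equal(sum(x), 1, tolerance = 1e-3)
    expect_gt(x[3], 0.85)          # front mass dominates
    expect_equal(which.max(x[-3]), 4)  # right side is the secondary area
  }
})

test_that("change proportions reproduce published one-/two-step comparisons", {
  expect_equal(transition_change_proportion(0.1539, 0.2308, "increase"), 49.97,
               tolerance = 1e-4)
  expect_equal(transition_change_proportion(0.3846, 0.1538, "reduce"), 60.01,
               tolerance = 1e-4)
  expect_equal(transition_change_proportion(0.4, 0.4, "increase"), 0)
  expect_equal(transition_change_proportion(0.4, 0.4, "reduce"), 0)
  expect_error(transition_change_proportion(0, 0.5, "increase"),
               class = "gazeflow_data_error")
})

test_that("tidy and glance expose the model in long and summary form", {
  m <- fit_transition_model(c("D", "E", "D", "D", "E"), states = c("D", "E"))
  td <- tidy(m)
  expect_setequal(unique(td$step), c("one", "two"))
  expect_equal(sum(td$count[td$step == "one"]), 4)
  expect_equal(td$probability[td$step == "one" & td$from == "D" & td$to == "E"],
               2 / 3)
  g <- glance(m)
  expect_equal(g$n_states, 2)
  expect_equal(g$n_fixations, 5)
})
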