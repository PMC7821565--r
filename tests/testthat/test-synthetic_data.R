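test_that("empty ground-truth graph gives identity precision and zero partial r", {
  gt <- make_ground_truth(3, edges = matrix(integer(0), ncol = 2))
  expect_equal(gt$precision, diag(3))
  p <- population_partial_cor(gt$precision)
  expect_equal(p[upper.tri(p)], rep(0, 3))
})

test_that("single-edge truth yields the requested partial correlation exactly", {
  gt <- make_ground_truth(3, edges = rbind(c(1, 2)), strength = 0.5)
  p <- population_partial_cor(gt$precision)
  expect_equal(p[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(p[1, 3], 0, tolerance = 1e-12)
  expect_equal(p[2, 3], 0, tolerance = 1e-12)
  expect_equal(gt$partial_strength, 0.5)
  expect_equal(gt$ridge, 0)
})

test_that("ground-truth construction is deterministic and positive definite", {
  a <- make_ground_truth(15, n_edges = 20, strength = 0.4, seed = 7)
  b <- make_ground_truth(15, n_edges = 20, strength = 0.4, seed = 7)
  expect_identical(a$precision, b$precision)
  expect_identical(a$edges, b$edges)
  for (s in 1:20) {
    m <- sample(0:30, 1)
    gt <- make_ground_truth(15, n_edges = m, strength = stats::runif(1, .2, .7),
                            seed = s)
    ev <- eigen(gt$precision, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    # implied covariance has unit channel variances
    expect_equal(diag(solve(gt$precision)), rep(1, 15), tolerance = 1e-10)
    # population partial correlations match the reported realized strength
    p <- population_partial_cor(gt$precision)
    on_e <- p[gt$adjacency == 1]
    off_e <- p[gt$adjacency == 0 & upper.tri(p)]
    if (length(on_e) > 0)
      expect_equal(unname(on_e), rep(gt$partial_strength, length(on_e)),
                   tolerance = 1e-10)
    expect_equal(max(abs(off_e)), 0, tolerance = 1e-10)
  }
})

test_that("infeasible strength/edge combinations are rejected", {
  all_edges <- t(utils::combn(15, 2))
  expect_error(make_ground_truth(15, edges = all_edges, strength = 0.9),
               "infeasible network")
  expect_error(make_ground_truth(5, edges = rbind(c(1, 2)), strength = 1.2),
               "strictly in \\(0, 1\\)")
  expect_error(make_ground_truth(5, edges = rbind(c(1, 7)), strength = 0.5),
               "out of range")
})

test_that("simulated hemodynamics are bit-identical under a fixed seed", {
  gt <- make_ground_truth(15, n_edges = 12, strength = 0.5, seed = 4)
  sc <- scenario_spec(watch_duration_s = 30, decision_duration_s = 15, seed = 9)
  h1 <- simulate_hemodynamics(gt, noise_spec(), sc)
  h2 <- simulate_hemodynamics(gt, noise_spec(), sc)
  expect_identical(h1$hbo, h2$hbo)
  expect_identical(h1$hbb, h2$hbb)
  expect_identical(h1$events, h2$events)
})

test_that("noise-free sample partial correlations converge to the population truth", {
  gt <- make_ground_truth(15, n_edges = 12, strength = 0.5, seed = 21)
  # ~10,050 samples at 8.9 Hz
  hemo <- simulate_hemodynamics(gt, noise_spec_silent(),
                                scenario_spec(watch_duration_s = 900,
                                              decision_duration_s = 230,
                                              seed = 5))
  expect_gt(nrow(hemo$hbo), 10000)
  est <- partial_correlation(hemo$hbo)$partial_r
  pop <- population_partial_cor(gt$precision)
  expect_lt(max(abs(est - pop)), 0.05)
})

test_that("event markers land at the phase boundaries", {
  gt <- make_ground_truth(15, n_edges = 6, strength = 0.5, seed = 2)
  sc <- scenario_spec(watch_duration_s = 100, decision_duration_s = 50, seed = 1)
  hemo <- simulate_hemodynamics(gt, noise_spec(), sc)
  expect_equal(hemo$events$label, c("target_spotted", "course_change"))
  expect_equal(hemo$events$time_s[1], round(100 * 8.9) / 8.9, tolerance = 1e-9)
  expect_equal(nrow(hemo$hbo), round(100 * 8.9) + round(50 * 8.9))
})

test_that("cardiac oscillation appears as a spectral peak before filtering", {
  gt <- make_ground_truth(15, n_edges = 12, strength = 0.5, seed = 3)
  hemo <- simulate_hemodynamics(gt, noise_spec(),
                                scenario_spec(watch_duration_s = 292.5,
                                              decision_duration_s = 142,
                                              seed = 2))
  for (ch in c(1, 8)) {
    sp <- stats::spec.pgram(stats::ts(hemo$hbo[, ch], frequency = 8.9),
                            spans = 9, plot = FALSE, detrend = TRUE)
    band <- sp$freq > 0.6 & sp$freq < 2
    peak <- sp$freq[band][which.max(sp$spec[band])]
    expect_lt(abs(peak - 1.2), 0.1)
  }
})

test_that("noise frequencies at or above Nyquist are rejected", {
  gt <- make_ground_truth(15, n_edges = 6, strength = 0.5, seed = 2)
  expect_error(
    simulate_hemodynamics(gt, noise_spec(cardiac_hz = 4.5),
                          scenario_spec(watch_duration_s = 10,
                                        decision_duration_s = 5, seed = 1)),
    "Nyquist")
})

test_that("per-period truth override drives period-specific dependence", {
  dense <- make_ground_truth(15, n_edges = 14, strength = 0.5, seed = 31)
  sparse <- make_ground_truth(15, edges = matrix(integer(0), ncol = 2))
  sc <- scenario_spec(watch_duration_s = 500, decision_duration_s = 250,
                      period_truth = list(watch = dense, decision = sparse),
                      seed = 6)
  hemo <- simulate_hemodynamics(dense, noise_spec_silent(), sc)
  seg <- segment_periods(hemo$events, hemo$fs, nrow(hemo$hbo))
  w1 <- seg$periods[seg$periods$period == "watch1", ]
  d1 <- seg$periods[seg$periods$period == "decision1", ]
  p_w <- partial_correlation(hemo$hbo[w1$start:(w1$end - 1), ])$partial_r
  p_d <- partial_correlation(hemo$hbo[d1$start:(d1$end - 1), ])$partial_r
  strong_w <- abs(p_w[dense$adjacency == 1])
  strong_d <- abs(p_d[dense$adjacency == 1])
  expect_gt(mean(strong_w), 0.25)  # edges present during watch
  expect_lt(mean(strong_d), 0.1)   # absent during decision
})

test_that("simulated behavior is linear, seed-stable, and sign-faithful", {
  set.seed(40)
  metrics <- data.frame(participant_id = sprintf("p%02d", 1:36),
                        density = stats::runif(36, 0.1, 0.5),
                        clustering = stats::runif(36, 0, 0.6))
  co <- list(intercept = 4, beta_d = 3, beta_c = -1, sd = 0)
  beh <- simulate_behavior(metrics, co, seed = 5)
  expect_equal(beh$distance_nm,
               4 + 3 * metrics$density - metrics$clustering, tolerance = 1e-12)
  co$sd <- 0.3
  b1 <- simulate_behavior(metrics, co, seed = 5)
  b2 <- simulate_behavior(metrics, co, seed = 5)
  expect_identical(b1, b2)
  expect_gt(stats::cor(metrics$density, b1$distance_nm), 0)
})

test_that("ground truth JSON round trips", {
  gt <- make_ground_truth(15, n_edges = 9, strength = 0.45, seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, path)
  back <- read_ground_truth(path)
  expect_equal(back$precision, gt$precision, tolerance = 1e-12)
  expect_identical(back$adjacency, gt$adjacency)
  expect_equal(back$partial_strength, gt$partial_strength)
})
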