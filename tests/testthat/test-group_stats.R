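six_periods <- c("watch1", "watch2", "watch3", "watch4",
                 "decision1", "decision2")

test_that("frequency maps count participants per connection", {
  n <- 15
  complete <- matrix(1L, n, n); diag(complete) <- 0L
  nets <- unlist(lapply(sprintf("p%02d", 1:36), function(pid)
    lapply(six_periods, function(per) adj_obj(complete, pid, per))),
    recursive = FALSE)
  fm <- frequency_map(nets)
  expect_named(fm, six_periods)
  off <- upper.tri(complete)
  expect_true(all(fm$watch1$counts[off] == 36))
  expect_true(all(fm$watch1$bin[off] == "red"))
  expect_equal(fm$watch1$n_participants, 36)

  one_edge <- matrix(0L, n, n); one_edge[2, 9] <- one_edge[9, 2] <- 1L
  empty <- matrix(0L, n, n)
  nets2 <- c(list(adj_obj(one_edge, "p01", "watch1")),
             lapply(sprintf("p%02d", 2:36), function(pid)
               adj_obj(empty, pid, "watch1")))
  fm2 <- frequency_map(nets2)
  expect_equal(fm2$watch1$counts[2, 9], 1)
  expect_equal(fm2$watch1$bin[2, 9], "blue")
  expect_equal(sum(fm2$watch1$counts), 2)
})

test_that("frequency counts equal an independent tally and conserve edges", {
  set.seed(61)
  nets <- unlist(lapply(sprintf("p%02d", 1:10), function(pid)
    lapply(six_periods, function(per)
      adj_obj(rand_adjacency(15, 0.3), pid, per))), recursive = FALSE)
  fm <- frequency_map(nets)
  for (per in six_periods) {
    tally <- matrix(0L, 15, 15)
    total_edges <- 0
    for (x in nets) {
      if (x$period != per) next
      for (i in 1:15) for (j in 1:15) tally[i, j] <- tally[i, j] + x$a[i, j]
      total_edges <- total_edges + sum(x$a)
    }
    expect_identical(fm[[per]]$counts, tally)
    expect_equal(sum(fm[[per]]$counts), total_edges)
  }
})

test_that("frequency bins partition the participant counts as published", {
  lab <- connection_bins(0:36)
  expect_true(all(lab[0:12 + 1] == "blue"))
  expect_true(all(lab[13:16 + 1] == "green"))
  expect_true(all(lab[17:21 + 1] == "orange"))
  expect_true(all(lab[22:36 + 1] == "red"))
})

test_that("mixed cohort sizes across periods are rejected unless allowed", {
  a <- rand_adjacency(15, 0.2)
  nets <- list(adj_obj(a, "p01", "watch1"), adj_obj(a, "p02", "watch1"),
               adj_obj(a, "p01", "watch2"))
  expect_error(frequency_map(nets), "cohort sizes differ")
  fm <- frequency_map(nets, allow_unequal = TRUE)
  expect_equal(fm$watch2$n_participants, 1)
})

test_that("arc diagrams emit counts and legend metadata that match the map", {
  set.seed(62)
  n <- 15
  one_red <- matrix(0L, n, n); one_red[3, 11] <- one_red[11, 3] <- 1L
  nets <- unlist(lapply(sprintf("p%02d", 1:25), function(pid)
    lapply(six_periods, function(per) adj_obj(one_red, pid, per))),
    recursive = FALSE)
  fm <- frequency_map(nets)
  d1 <- file.path(withr::local_tempdir(), "a")
  files <- arc_diagram(fm, out_dir = d1, periods = "watch1")
  expect_true(file.exists(files$image))
  counts <- as.matrix(data.table::fread(files$counts))
  dimnames(counts) <- NULL
  expect_equal(counts, fm$watch1$counts)
  legend <- data.table::fread(files$legend)
  expect_equal(legend$n_arcs[legend$bin == "red"], 1L)
  expect_equal(sum(legend$n_arcs), 1L)

  d2 <- file.path(withr::local_tempdir(), "b")
  files2 <- arc_diagram(fm, out_dir = d2, periods = "watch1")
  expect_identical(readLines(files$counts), readLines(files2$counts))

  empty_nets <- unlist(lapply(sprintf("p%02d", 1:5), function(pid)
    lapply(six_periods, function(per)
      adj_obj(matrix(0L, n, n), pid, per))), recursive = FALSE)
  d3 <- file.path(withr::local_tempdir(), "c")
  files3 <- arc_diagram(frequency_map(empty_nets), out_dir = d3,
                        periods = "decision2")
  expect_true(file.exists(files3$image))
  expect_equal(sum(data.table::fread(files3$legend)$n_arcs), 0L)
})

make_metrics <- function(n = 36, seed = 63) {
  set.seed(seed)
  do.call(rbind, lapply(six_periods, function(per)
    data.frame(participant_id = sprintf("p%02d", 1:n), period = per,
               density = stats::rnorm(n, 0.4, 0.08),
               clustering = stats::rnorm(n, 0.5, 0.1))))
}

test_that("noise-free distances are recovered exactly by the regression", {
  metrics <- make_metrics()
  slice <- metrics[metrics$period == "watch4", ]
  beh <- data.frame(participant_id = slice$participant_id,
                    distance_spotted_nm =
                      4 + 3 * slice$density - 2 * slice$clustering)
  res <- suppressWarnings(behavior_regression(metrics, beh, period = "watch4"))
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  est <- res$coefficients$estimate
  expect_equal(est[res$coefficients$term == "(Intercept)"], 4,
               tolerance = 1e-9)
  expect_equal(est[res$coefficients$term == "density"], 3, tolerance = 1e-9)
  expect_equal(est[res$coefficients$term == "clustering"], -2,
               tolerance = 1e-9)
})

test_that("standardized betas and partial r satisfy their algebraic identities", {
  set.seed(64)
  metrics <- make_metrics(seed = 64)
  slice <- metrics[metrics$period == "decision2", ]
  beh <- data.frame(participant_id = slice$participant_id,
                    distance_maneuver_nm =
                      pmax(0, 2 - 4 * slice$density + slice$clustering +
                             stats::rnorm(36, 0, 0.3)))
  res <- behavior_regression(metrics, beh, period = "decision2")
  co <- res$coefficients
  y <- merge(slice, beh, by = "participant_id")$distance_maneuver_nm
  for (term in c("density", "clustering")) {
    raw <- co$estimate[co$term == term]
    expect_equal(co$std_beta[co$term == term],
                 raw * stats::sd(slice[[term]]) / stats::sd(y),
                 tolerance = 1e-10)
    # partial r from the t statistic: r = t / sqrt(t^2 + df)
    t_val <- co$t[co$term == term]
    expect_equal(co$partial_r[co$term == term],
                 t_val / sqrt(t_val^2 + res$n - 3), tolerance = 1e-10)
  }
})

test_that("orthogonal predictors reproduce simple correlations as std betas", {
  set.seed(65)
  raw <- scale(matrix(stats::rnorm(36 * 2), 36, 2), scale = FALSE)
  q <- qr.Q(qr(raw))  # centered, exactly uncorrelated columns
  metrics <- do.call(rbind, lapply(six_periods, function(per)
    data.frame(participant_id = sprintf("p%02d", 1:36), period = per,
               density = q[, 1], clustering = q[, 2])))
  slice <- metrics[metrics$period == "watch4", ]
  y <- 3 * q[, 1] - 1 * q[, 2] + stats::rnorm(36, 0, 0.5)
  beh <- data.frame(participant_id = slice$participant_id,
                    distance_spotted_nm = y)
  res <- behavior_regression(metrics, beh, period = "watch4")
  co <- res$coefficients
  expect_equal(co$std_beta[co$term == "density"],
               stats::cor(y, q[, 1]), tolerance = 1e-10)
  expect_equal(co$std_beta[co$term == "clustering"],
               stats::cor(y, q[, 2]), tolerance = 1e-10)
})

test_that("estimated R-squared concentrates around the generative value", {
  set.seed(66)
  hits <- 0
  for (i in 1:100) {
    d <- stats::rnorm(37, 0.4, 0.08)
    cl <- stats::rnorm(37, 0.5, 0.1)
    metrics <- data.frame(participant_id = sprintf("p%02d", 1:37),
                          period = "watch4", density = d, clustering = cl)
    sd_eps <- noise_sd_for_r2(metrics, 5, 2, 0.3)
    y <- 4 + 5 * d + 2 * cl + stats::rnorm(37, 0, sd_eps)
    beh <- data.frame(participant_id = metrics$participant_id,
                      distance_spotted_nm = y)
    res <- behavior_regression(metrics, beh, period = "watch4")
    if (res$r_squared >= 0.05 && res$r_squared <= 0.6) hits <- hits + 1
  }
  # R-squared sampling sd at n = 37 is ~0.13 around ~0.34, so this band
  # holds with high probability while a materially biased fit would fail
  expect_gte(hits, 90)
})

test_that("collinear or insufficient inputs are rejected", {
  metrics <- make_metrics()
  metrics$clustering <- 2 * metrics$density
  slice <- metrics[metrics$period == "watch4", ]
  beh <- data.frame(participant_id = slice$participant_id,
                    distance_spotted_nm = stats::runif(36, 3, 6))
  expect_error(behavior_regression(metrics, beh, "watch4"), "collinear")
  beh3 <- beh[1:3, ]
  expect_error(behavior_regression(make_metrics(), beh3, "watch4"),
               "at least 4")
})

test_that("recovery reports are reproducible and well-formed", {
  r1 <- recovery_experiment(seeds = 1:2, n_participants = 3)
  r2 <- recovery_experiment(seeds = 1:2, n_participants = 3)
  expect_identical(r1$per_seed, r2$per_seed)
  expect_true(all(r1$per_seed$sensitivity >= 0 & r1$per_seed$sensitivity <= 1))
  expect_true(all(r1$per_seed$fpr >= 0 & r1$per_seed$fpr <= 1))
  expect_true(all(c("mean_sensitivity", "mean_fpr",
                    "prop_density_lower_in_decision") %in%
                    names(r1$summary)))
})
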