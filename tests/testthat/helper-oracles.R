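# Independent brute-force oracles. These deliberately use naive loops and
# the residual-regression definition so they share no code path with the
# package implementations they check.

oracle_density <- function(a) {
  n <- nrow(a)
  s <- 0
  for (i in 1:n) for (j in 1:n) s <- s + a[i, j]
  s / (n * (n - 1))
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  vals <- numeric(n)
  for (i in 1:n) {
    k <- sum(a[i, ])
    if (k < 2) next
    tri <- 0
    for (j in 1:n) for (h in 1:n) tri <- tri + a[i, j] * a[i, h] * a[j, h]
    vals[i] <- tri / (k * (k - 1))
  }
  mean(vals)
}

# Partial correlation via explicit residual regressions.
oracle_partial_cor <- function(x) {
  k <- ncol(x)
  p <- diag(1, k)
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      others <- setdiff(1:k, c(i, j))
      if (length(others) > 0) {
        ri <- stats::resid(stats::lm(x[, i] ~ x[, others, drop = FALSE]))
        rj <- stats::resid(stats::lm(x[, j] ~ x[, others, drop = FALSE]))
      } else {
        ri <- x[, i]; rj <- x[, j]
      }
      p[i, j] <- p[j, i] <- stats::cor(ri, rj)
    }
  }
  p
}

oracle_roi_average <- function(cbsi, periods, roi_channel_list) {
  out <- list()
  for (pi in seq_len(nrow(periods))) {
    rows <- periods$start[pi]:(periods$end[pi] - 1)
    for (roi in names(roi_channel_list)) {
      chans <- roi_channel_list[[roi]]
      acc <- 0
      for (ch in chans) {
        m <- 0
        for (r in rows) m <- m + cbsi[r, ch]
        acc <- acc + m / length(rows)
      }
      out[[length(out) + 1]] <- data.frame(
        period = periods$period[pi], roi = roi,
        value = acc / length(chans))
    }
  }
  do.call(rbind, out)
}

rand_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

adj_obj <- function(a, participant, period) {
  structure(list(a = a, threshold_used = 0.28, participant = participant,
                 period = period),
            class = "adjacency_matrix")
}

# Small noiseless hemo fixture from a planted network.
silent_hemo <- function(truth, watch_s = 60, decision_s = 30, seed = 1) {
  simulate_hemodynamics(truth, noise_spec_silent(),
                        scenario_spec(watch_duration_s = watch_s,
                                      decision_duration_s = decision_s,
                                      seed = seed))
}
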