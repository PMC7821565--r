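#' Connection-frequency map across a cohort
#'
#' For each task period, counts in how many participants each channel pair
#' passed the connectivity threshold (elementwise sum of the binary
#' adjacency matrices) and labels each pair with a frequency bin. Default
#' bins: red for 22 or more participants, orange for 17-21, green for
#' 13-16, blue for 12 or fewer (the blue upper edge closes the partition).
#'
#' @param networks list of `adjacency_matrix` objects with `participant`
#'   and `period` labels.
#' @param bins named numeric vector of lower bin bounds,
#'   `c(red = 22, orange = 17, green = 13)`; counts below the smallest
#'   bound are blue.
#' @param allow_unequal allow different cohort sizes across periods.
#' @return A `connection_frequency_map`: named list (by period) of lists
#'   with `counts` (integer matrix), `bin` (character matrix),
#'   `n_participants`; attribute `bins` stores the bounds.
#' @export
frequency_map <- function(networks, bins = c(red = 22, orange = 17, green = 13),
                          allow_unequal = FALSE) {
  stopifnot(length(networks) > 0)
  periods <- vapply(networks, function(x) x$period, character(1))
  sizes <- vapply(networks, function(x) nrow(x$a), integer(1))
  if (length(unique(sizes)) != 1)
    stop("all adjacency matrices must share the same node set")
  by_period <- split(networks, periods)
  cohort_sizes <- vapply(by_period, length, integer(1))
  if (!allow_unequal && length(unique(cohort_sizes)) != 1)
    stop("cohort sizes differ across periods (",
         paste(cohort_sizes, collapse = ", "),
         "); pass allow_unequal = TRUE to permit this")
  out <- lapply(by_period, function(grp) {
    counts <- Reduce(`+`, lapply(grp, function(x) x$a))
    list(counts = counts, bin = connection_bins(counts, bins),
         n_participants = length(grp))
  })
  structure(out[intersect(period_names(), names(out))],
            bins = bins, class = "connection_frequency_map")
}

#' Frequency-bin labels for connection counts
#'
#' @param counts integer matrix (or vector) of participant counts.
#' @param bins named lower bounds as in [frequency_map()].
#' @return Character matrix/vector of bin labels (`"blue"` below the
#'   smallest bound).
#' @export
connection_bins <- function(counts, bins = c(red = 22, orange = 17, green = 13)) {
  bins <- sort(bins, decreasing = TRUE)
  lab <- array("blue", dim = dim(counts) %||% length(counts))
  for (b in rev(seq_along(bins)))  # apply loosest bound first
    lab[counts >= bins[b]] <- names(bins)[b]
  if (!is.null(dim(counts))) dim(lab) <- dim(counts)
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Arc-diagram connectome visualization
#'
#' Draws one arc diagram per requested period: the 15 channels on a
#' horizontal axis in montage order, labeled with channel number and
#' Brodmann area, and an arc for each channel pair whose connection count
#' is positive, colored by frequency bin. Alongside the image, the
#' underlying counts are written as a TSV (the testable surface) together
#' with a legend metadata TSV giving, per bin, its color and the number of
#' arcs drawn.
#'
#' @param fmap a [frequency_map()] result.
#' @param montage montage for node labels.
#' @param out_dir output directory.
#' @param periods which periods to render (default all present).
#' @param device `"pdf"` or `"png"`.
#' @param min_count smallest count drawn as an arc (default 1).
#' @return Invisibly, data.frame of written file paths.
#' @export
arc_diagram <- function(fmap, montage = default_montage(), out_dir,
                        periods = names(fmap), device = c("pdf", "png"),
                        min_count = 1) {
  stopifnot(inherits(fmap, "connection_frequency_map"))
  device <- match.arg(device)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  bin_cols <- c(red = "#d73027", orange = "#fc8d59", green = "#1a9850",
                blue = "#4575b4")
  files <- list()
  for (p in periods) {
    entry <- fmap[[p]]
    counts <- entry$counts
    n <- nrow(counts)
    labels <- sprintf("%d\n(%s)", montage$channels$channel,
                      montage$channels$brodmann)
    img_path <- file.path(out_dir, paste0("arcs_", p, ".", device))
    if (device == "pdf") grDevices::pdf(img_path, width = 10, height = 5)
    else grDevices::png(img_path, width = 1000, height = 500)
    graphics::par(mar = c(4, 1, 2, 1))
    graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(0, n / 2 + 1),
                   axes = FALSE, xlab = "", ylab = "",
                   main = sprintf("%s (n = %d)", p, entry$n_participants))
    idx <- which(upper.tri(counts) & counts >= min_count, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      ord <- order(counts[idx])  # frequent arcs drawn last, on top
      idx <- idx[ord, , drop = FALSE]
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        bin <- entry$bin[i, j]
        theta <- seq(0, pi, length.out = 60)
        cx <- (i + j) / 2; rad <- abs(j - i) / 2
        graphics::lines(cx + rad * cos(theta), rad * sin(theta),
                        col = bin_cols[bin],
                        lwd = if (bin == "blue") 0.6 else 2)
      }
    }
    graphics::points(seq_len(n), rep(0, n), pch = 21, bg = "grey80")
    graphics::mtext(labels, side = 1, at = seq_len(n), line = 1.5,
                    cex = 0.65)
    grDevices::dev.off()

    counts_path <- file.path(out_dir, paste0("arcs_", p, "_counts.tsv"))
    cm <- counts
    colnames(cm) <- sprintf("ch%02d", seq_len(n))
    data.table::fwrite(data.table::as.data.table(cm), counts_path, sep = "\t")
    legend_path <- file.path(out_dir, paste0("arcs_", p, "_legend.tsv"))
    drawn_bins <- if (nrow(idx) > 0) entry$bin[idx] else character(0)
    legend <- data.frame(bin = names(bin_cols),
                         color = unname(bin_cols),
                         n_arcs = vapply(names(bin_cols), function(b)
                           sum(drawn_bins == b), integer(1)))
    data.table::fwrite(legend, legend_path, sep = "\t")
    files[[p]] <- data.frame(period = p, image = img_path,
                             counts = counts_path, legend = legend_path)
  }
  invisible(do.call(rbind, files))
}

#' Regress behavioral distance on network metrics
#'
#' Ordinary least squares of distance on connection density and clustering
#' with intercept, for a single task period. Reports, per predictor, the
#' raw coefficient, standardized beta (`b * sd(x) / sd(y)`), t, two-sided
#' p, and the partial correlation (correlation between response residuals
#' and predictor residuals, each controlling the other predictor), plus
#' R-squared, adjusted R-squared, F and degrees of freedom.
#'
#' @param metrics [metrics_table()] output (or any data.frame with
#'   `participant_id`, `period`, `density`, `clustering`).
#' @param behavior behavioral data.frame as from [load_behavior()], or any
#'   data.frame with `participant_id` and the response column.
#' @param period task period, `"watch4"` (response: spotting distance) or
#'   `"decision2"` (response: maneuver distance).
#' @param response response column in `behavior`; defaults to
#'   `distance_spotted_nm` for watch4 and `distance_maneuver_nm` for
#'   decision2.
#' @return A `regression_result`: list with `period`, `response`, `n`,
#'   `coefficients` (data.frame), `r_squared`, `adj_r_squared`,
#'   `f_statistic`, `df`, and the underlying `lm` fit.
#' @export
behavior_regression <- function(metrics, behavior,
                                period = c("watch4", "decision2"),
                                response = NULL) {
  period <- match.arg(period)
  if (is.null(response))
    response <- switch(period, watch4 = "distance_spotted_nm",
                       decision2 = "distance_maneuver_nm")
  if (!response %in% names(behavior))
    stop("response column '", response, "' not found in behavior table")
  slice <- metrics[metrics$period == period,
                   c("participant_id", "density", "clustering")]
  dat <- merge(slice, behavior[, c("participant_id", response)],
               by = "participant_id")
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 4) stop("need at least 4 complete cases, got ", nrow(dat))
  if (stats::sd(dat$density) == 0 || stats::sd(dat$clustering) == 0 ||
      abs(stats::cor(dat$density, dat$clustering)) > 1 - 1e-8)
    stop("density and clustering are collinear or constant; model is unidentifiable")
  y <- dat[[response]]
  fit <- stats::lm(y ~ density + clustering, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  sd_y <- stats::sd(y)
  partial_r <- c(
    density = partial_cor_xy(y, dat$density, dat$clustering),
    clustering = partial_cor_xy(y, dat$clustering, dat$density)
  )
  coefs <- data.frame(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_beta = c(NA,
                 co["density", "Estimate"] * stats::sd(dat$density) / sd_y,
                 co["clustering", "Estimate"] * stats::sd(dat$clustering) / sd_y),
    t = co[, "t value"],
    partial_r = c(NA, partial_r),
    p = co[, "Pr(>|t|)"],
    row.names = NULL
  )
  structure(list(period = period, response = response, n = nrow(dat),
                 coefficients = coefs,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 f_statistic = unname(sm$fstatistic["value"]),
                 df = unname(sm$fstatistic[c("numdf", "dendf")]),
                 fit = fit),
            class = "regression_result")
}

# Partial correlation of y with x controlling z (residual definition).
partial_cor_xy <- function(y, x, z) {
  ry <- stats::resid(stats::lm(y ~ z))
  rx <- stats::resid(stats::lm(x ~ z))
  stats::cor(ry, rx)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("distance ~ density + clustering [%s, response %s, n = %d]\n",
              x$period, x$response, x$n))
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4), std_beta = signif(std_beta, 3),
                  t = signif(t, 3), partial_r = signif(partial_r, 3),
                  p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("R2 = %.3f (adj %.3f), F(%d, %d) = %.2f\n", x$r_squared,
              x$adj_r_squared, x$df[1], x$df[2], x$f_statistic))
  invisible(x)
}

# i.i.d. draws from the Gaussian graphical model of a ground truth.
draw_network_series <- function(truth, n) {
  l_chol <- chol(solve(truth$precision))
  matrix(stats::rnorm(n * truth$n_channels), n, truth$n_channels) %*% l_chol
}

# Edge sensitivity and false-positive rate of an estimated adjacency
# against a ground truth (upper triangle only).
edge_recovery_rates <- function(adj, truth) {
  est <- adj$a[upper.tri(adj$a)]
  ref <- truth$adjacency[upper.tri(truth$adjacency)]
  list(sensitivity = if (sum(ref) > 0) sum(est & ref) / sum(ref) else NA_real_,
       fpr = if (sum(!ref) > 0) sum(est & !ref) / sum(!ref) else NA_real_)
}

#' End-to-end network and behavior recovery experiment
#'
#' For each seed, builds per-participant ground-truth networks (a denser
#' watch-phase truth and a sparser decision-phase truth, participant edge
#' counts jittered to create cohort variance), draws period-length
#' network-driven series, estimates and thresholds partial-correlation
#' networks, and summarizes: edge sensitivity and false-positive rate,
#' density/clustering bias against truth, the watch-versus-decision density
#' contrast, and the signs recovered by the two brain-behavior regressions
#' (positive density effect generated for watch4 spotting distance,
#' negative for decision2 maneuver distance, at the target population
#' R-squared).
#'
#' @param seeds integer vector of seeds (one cohort per seed).
#' @param n_participants cohort size (default 36, the analyzable sample).
#' @param n_channels nodes per network.
#' @param edge_strength requested partial-correlation strength.
#' @param n_edges_watch,n_edges_decision mean edge counts of the two
#'   truths; per-participant counts are jittered by `edge_jitter`.
#' @param edge_jitter max absolute jitter on per-participant edge counts.
#' @param n_watch_samples,n_decision_samples samples per watch / decision
#'   period (defaults 2600 and 1264: 292.5 s and 142 s at 8.9 Hz).
#' @param threshold connectivity criterion.
#' @param behavior list with `beta_d_watch4` (> 0), `beta_d_decision2`
#'   (< 0), `beta_c`, `r2`, `intercept`.
#' @param run_regressions fit the two behavior models per seed.
#' @return A `recovery_report`: list with `per_seed` (data.frame) and
#'   `summary` (named list of aggregate rates).
#' @export
recovery_experiment <- function(seeds = 1:20, n_participants = 36,
                                n_channels = 15, edge_strength = 0.5,
                                n_edges_watch = 12, n_edges_decision = 5,
                                edge_jitter = 3,
                                n_watch_samples = 2600,
                                n_decision_samples = 1264,
                                threshold = 0.28,
                                behavior = list(beta_d_watch4 = 8,
                                                beta_d_decision2 = -8,
                                                beta_c = 2, r2 = 0.3,
                                                intercept = 4.7),
                                run_regressions = TRUE) {
  per_seed <- vector("list", length(seeds))
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    set.seed(seed)
    sens <- fpr <- d_bias <- c_bias <- numeric(0)
    metrics_rows <- list()
    for (pp in seq_len(n_participants)) {
      jit <- if (edge_jitter > 0) sample(-edge_jitter:edge_jitter, 2, TRUE)
             else c(0L, 0L)
      m_w <- max(0, n_edges_watch + jit[1])
      m_d <- max(0, n_edges_decision + jit[2])
      edge_seed_w <- (seed * 1000L + pp * 2L) %% .Machine$integer.max
      edge_seed_d <- (seed * 1000L + pp * 2L + 1L) %% .Machine$integer.max
      truth_w <- make_ground_truth(n_channels, strength = edge_strength,
                                   n_edges = m_w, seed = edge_seed_w)
      truth_d <- make_ground_truth(n_channels, strength = edge_strength,
                                   n_edges = m_d, seed = edge_seed_d)
      for (p in period_names()) {
        is_watch <- grepl("^watch", p)
        truth <- if (is_watch) truth_w else truth_d
        n_p <- if (is_watch) n_watch_samples else n_decision_samples
        x <- draw_network_series(truth, n_p)
        adj <- threshold_network(partial_correlation(x), threshold)
        rates <- edge_recovery_rates(adj, truth)
        sens <- c(sens, rates$sensitivity)
        fpr <- c(fpr, rates$fpr)
        d_bias <- c(d_bias,
                    network_density(adj) - network_density(truth$adjacency))
        c_bias <- c(c_bias,
                    clustering_coef(adj) - clustering_coef(truth$adjacency))
        metrics_rows[[length(metrics_rows) + 1]] <- data.frame(
          participant_id = sprintf("p%02d", pp), period = p,
          density = network_density(adj), clustering = clustering_coef(adj),
          stringsAsFactors = FALSE)
      }
    }
    metrics <- do.call(rbind, metrics_rows)
    watch_mask <- grepl("^watch", metrics$period)
    row <- data.frame(
      seed = seed,
      sensitivity = mean(sens, na.rm = TRUE),
      fpr = mean(fpr, na.rm = TRUE),
      density_bias = mean(d_bias),
      clustering_bias = mean(c_bias),
      mean_density_watch = mean(metrics$density[watch_mask]),
      mean_density_decision = mean(metrics$density[!watch_mask]),
      watch4_beta_d_positive = NA,
      decision2_beta_d_negative = NA
    )
    if (run_regressions) {
      row$watch4_beta_d_positive <- regression_beta_sign(
        metrics, "watch4", behavior$beta_d_watch4, behavior$beta_c,
        behavior$r2, behavior$intercept, seed) > 0
      row$decision2_beta_d_negative <- regression_beta_sign(
        metrics, "decision2", behavior$beta_d_decision2, behavior$beta_c,
        behavior$r2, behavior$intercept, seed + 500000L) < 0
    }
    per_seed[[si]] <- row
  }
  per_seed <- do.call(rbind, per_seed)
  structure(list(
    per_seed = per_seed,
    summary = list(
      mean_sensitivity = mean(per_seed$sensitivity, na.rm = TRUE),
      mean_fpr = mean(per_seed$fpr, na.rm = TRUE),
      mean_density_bias = mean(per_seed$density_bias),
      mean_clustering_bias = mean(per_seed$clustering_bias),
      prop_density_lower_in_decision =
        mean(per_seed$mean_density_decision < per_seed$mean_density_watch),
      prop_watch4_sign_recovered = mean(per_seed$watch4_beta_d_positive),
      prop_decision2_sign_recovered = mean(per_seed$decision2_beta_d_negative),
      n_seeds = nrow(per_seed), n_participants = n_participants
    )), class = "recovery_report")
}

# Simulate distances for one period slice and return the fitted density
# coefficient's sign (+1/-1). Falls back to a density-only model when the
# cohort's clustering values carry no variance (sparse truths rarely form
# triangles), in which case the two-predictor model is unidentifiable.
regression_beta_sign <- function(metrics, period, beta_d, beta_c, r2,
                                 intercept, seed) {
  slice <- metrics[metrics$period == period, ]
  sd_eps <- noise_sd_for_r2(slice, beta_d, beta_c, r2)
  beh <- simulate_behavior(slice,
                           list(intercept = intercept, beta_d = beta_d,
                                beta_c = beta_c, sd = sd_eps), seed = seed)
  response <- switch(period, watch4 = "distance_spotted_nm",
                     decision2 = "distance_maneuver_nm")
  names(beh)[names(beh) == "distance_nm"] <- response
  beh[[response]] <- pmax(beh[[response]], 0)
  est <- tryCatch({
    res <- behavior_regression(metrics, beh, period = period)
    res$coefficients$estimate[res$coefficients$term == "density"]
  }, error = function(e) {
    dat <- merge(slice, beh, by = "participant_id")
    stats::coef(stats::lm(dat[[response]] ~ dat$density))[2]
  })
  sign(est)
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("recovery_report: %d seeds x %d participants\n", s$n_seeds,
              s$n_participants))
  cat(sprintf("  edge sensitivity %.3f, FPR %.4f\n", s$mean_sensitivity,
              s$mean_fpr))
  cat(sprintf("  density bias %+.4f, clustering bias %+.4f\n",
              s$mean_density_bias, s$mean_clustering_bias))
  cat(sprintf("  density lower in decision periods: %.0f%% of seeds\n",
              100 * s$prop_density_lower_in_decision))
  if (!is.na(s$prop_watch4_sign_recovered))
    cat(sprintf("  regression sign recovery: watch4 %.0f%%, decision2 %.0f%%\n",
                100 * s$prop_watch4_sign_recovered,
                100 * s$prop_decision2_sign_recovered))
  invisible(x)
}
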