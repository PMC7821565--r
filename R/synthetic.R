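#' Construct a ground-truth connectivity network
#'
#' Builds a Gaussian graphical model whose population partial correlations
#' are known exactly, to serve as ground truth for validating the
#' partial-correlation estimator and the thresholding step. The precision
#' matrix starts from the identity; each requested edge (i, j) receives
#' off-diagonal entries `-strength`; if the resulting matrix is not safely
#' positive definite, a common ridge is added to the diagonal (closed form,
#' since the eigenvalues of `I + S` are `1 + eig(S)`) until the smallest
#' eigenvalue reaches `min_eigen`. The ridge weakens the realized partial
#' correlations to `strength / (1 + ridge)`; the realized value is reported
#' as the truth (`partial_strength`).
#'
#' @param n_channels number of channels (nodes), default 15.
#' @param edges two-column matrix (or NULL) of channel index pairs. If NULL,
#'   `n_edges` edges are sampled uniformly without replacement using `seed`.
#' @param strength requested partial-correlation magnitude, in (0, 1).
#' @param n_edges number of random edges when `edges` is NULL.
#' @param seed integer seed for random edge selection (required when edges
#'   are sampled); the construction is deterministic given it.
#' @param min_eigen floor on the smallest eigenvalue of the precision matrix.
#' @param max_ridge largest acceptable diagonal ridge; beyond this the
#'   requested strength/edge combination is rejected as infeasible.
#' @return A `ground_truth_network`: list with `n_channels`, `adjacency`
#'   (binary symmetric, zero diagonal), `precision`, `partial_strength`
#'   (realized edge partial correlation), `strength_requested`, `ridge`,
#'   `edges`.
#' @examples
#' gt <- make_ground_truth(3, edges = rbind(c(1, 2)), strength = 0.5)
#' population_partial_cor(gt$precision)[1, 2]  # 0.5
#' @export
make_ground_truth <- function(n_channels = 15, edges = NULL, strength = 0.4,
                              n_edges = NULL, seed = NULL,
                              min_eigen = 1e-3, max_ridge = 10) {
  stopifnot(n_channels >= 2)
  if (!(strength > 0 && strength < 1))
    stop("strength must lie strictly in (0, 1)")
  if (is.null(edges)) {
    if (is.null(n_edges)) stop("provide edges or n_edges")
    if (n_edges == 0) {
      edges <- matrix(integer(0), ncol = 2)
    } else {
      if (is.null(seed)) stop("seed required for random edge selection")
      edges <- random_edges(n_channels, n_edges, seed)
    }
  } else {
    edges <- matrix(as.integer(edges), ncol = 2)
  }
  if (nrow(edges) > 0) {
    if (any(edges < 1 | edges > n_channels))
      stop("edge indices out of range 1..", n_channels)
    if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
  }
  s_mat <- matrix(0, n_channels, n_channels)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    s_mat[i, j] <- s_mat[j, i] <- -strength
  }
  adjacency <- (s_mat != 0) * 1L
  lam_min <- if (nrow(edges) > 0)
    min(eigen(s_mat, symmetric = TRUE, only.values = TRUE)$values) else 0
  ridge <- max(0, min_eigen - (1 + lam_min))
  if (ridge > max_ridge)
    stop("infeasible network: strength/edge combination needs ridge ",
         signif(ridge, 3), " > max_ridge")
  precision <- s_mat
  diag(precision) <- 1 + ridge
  # Rescale so the implied covariance has unit diagonal: a diagonal
  # congruence D O D leaves the zero pattern and all partial correlations
  # unchanged but gives every channel unit marginal variance (otherwise a
  # ridged precision with a small least eigenvalue implies huge marginal
  # variances along one direction).
  sigma <- solve(precision)
  d <- sqrt(diag(sigma))
  precision <- precision * outer(d, d)
  precision <- (precision + t(precision)) / 2
  structure(
    list(n_channels = n_channels, adjacency = adjacency,
         precision = precision,
         partial_strength = strength / (1 + ridge),
         strength_requested = strength, ridge = ridge, edges = edges),
    class = "ground_truth_network"
  )
}

#' Sample a deterministic set of random edges
#'
#' @param n number of nodes.
#' @param m number of edges (at most `choose(n, 2)`).
#' @param seed integer seed.
#' @return Two-column integer matrix of node pairs (i < j).
#' @export
random_edges <- function(n, m, seed) {
  all_pairs <- t(utils::combn(n, 2))
  if (m > nrow(all_pairs)) stop("more edges requested than pairs available")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  all_pairs[sample(nrow(all_pairs), m), , drop = FALSE]
}

# Save/restore the global RNG state so helpers with their own seed do not
# perturb an enclosing simulation stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Population partial correlations of a precision matrix
#'
#' For precision matrix `O`, the partial correlation between variables i and
#' j given all others is `-O[i,j] / sqrt(O[i,i] * O[j,j])`; the diagonal is
#' set to 1 by convention.
#'
#' @param precision symmetric positive-definite matrix.
#' @return Matrix of population partial correlations.
#' @export
population_partial_cor <- function(precision) {
  d <- sqrt(diag(precision))
  p <- -precision / outer(d, d)
  diag(p) <- 1
  p
}

#' Physiological and instrument noise specification
#'
#' Parameters of the additive noise superposed on the network-driven
#' hemodynamic component: sinusoidal cardiac, Mayer-wave and respiratory
#' oscillations (random phase per channel), slow polynomial drift,
#' exponential-decay motion spikes at Poisson times (injected common-mode
#' into both HbO and Hbb, the artifact class CBSI targets), and white
#' measurement noise. Amplitudes are in the concentration units of the
#' simulated series (micromolar); frequencies must stay below the Nyquist
#' frequency of the scenario (4.45 Hz at fs = 8.9).
#'
#' @param cardiac_hz,cardiac_amp heartbeat oscillation (default 1.2 Hz).
#' @param mayer_hz,mayer_amp Mayer waves (default 0.1 Hz).
#' @param resp_hz,resp_amp respiration (default 0.3 Hz).
#' @param drift_order,drift_amp polynomial drift order and coefficient scale.
#' @param spike_rate motion spikes per minute.
#' @param spike_amp spike amplitude scale.
#' @param spike_tau_s spike exponential decay constant in seconds.
#' @param measurement_sd white measurement noise sd.
#' @param hbb_ratio Hbb is simulated as `-hbb_ratio * HbO` plus noise.
#' @param hbb_noise_sd sd of the independent noise on Hbb.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(cardiac_hz = 1.2, cardiac_amp = 0.3,
                       mayer_hz = 0.1, mayer_amp = 0.2,
                       resp_hz = 0.3, resp_amp = 0.2,
                       drift_order = 3, drift_amp = 0.3,
                       spike_rate = 0.5, spike_amp = 8, spike_tau_s = 1,
                       measurement_sd = 0.2,
                       hbb_ratio = 0.6, hbb_noise_sd = 0.2) {
  spec <- list(cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
               mayer_hz = mayer_hz, mayer_amp = mayer_amp,
               resp_hz = resp_hz, resp_amp = resp_amp,
               drift_order = drift_order, drift_amp = drift_amp,
               spike_rate = spike_rate, spike_amp = spike_amp,
               spike_tau_s = spike_tau_s,
               measurement_sd = measurement_sd,
               hbb_ratio = hbb_ratio, hbb_noise_sd = hbb_noise_sd)
  amps <- c(cardiac_amp, mayer_amp, resp_amp, drift_amp, spike_amp,
            measurement_sd, hbb_noise_sd)
  if (any(amps < 0)) stop("noise amplitudes must be non-negative")
  structure(spec, class = "noise_spec")
}

#' A noise specification with every amplitude zero
#'
#' Convenience for estimator-level experiments where only the
#' network-driven component is of interest.
#' @return A `noise_spec` with all amplitudes 0.
#' @export
noise_spec_silent <- function() {
  noise_spec(cardiac_amp = 0, mayer_amp = 0, resp_amp = 0, drift_amp = 0,
             spike_rate = 0, spike_amp = 0, measurement_sd = 0,
             hbb_noise_sd = 0)
}

#' Task scenario specification
#'
#' Defines the temporal layout of a simulated recording: the watchkeeping
#' phase (default 1170 s, i.e. the study-average 19 min 42 s) followed by
#' the decision phase (default 284 s, two periods of 142 s), sampled at
#' 8.9 Hz. `period_truth` optionally maps task phases to different
#' ground-truth networks (entries `watch` and `decision`, or all six period
#' names) so that the decision phase can be generated from a sparser truth.
#'
#' @param fs sampling rate in Hz.
#' @param watch_duration_s duration of the watch phase in seconds.
#' @param decision_duration_s duration of the decision phase in seconds.
#' @param network_amp standard-deviation scale (micromolar) of the
#'   network-driven hemodynamic component.
#' @param period_truth NULL or a named list of `ground_truth_network`s.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(fs = 8.9, watch_duration_s = 1170,
                          decision_duration_s = 284, network_amp = 1,
                          period_truth = NULL, seed = 1) {
  if (fs <= 0 || watch_duration_s <= 0 || decision_duration_s <= 0)
    stop("fs and durations must be positive")
  structure(list(fs = fs, watch_duration_s = watch_duration_s,
                 decision_duration_s = decision_duration_s,
                 network_amp = network_amp, period_truth = period_truth,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

period_names <- function() {
  c("watch1", "watch2", "watch3", "watch4", "decision1", "decision2")
}

# Resolve the truth used for each of the six periods.
resolve_period_truth <- function(truth, period_truth) {
  out <- stats::setNames(vector("list", 6), period_names())
  for (p in period_names()) out[[p]] <- truth
  if (!is.null(period_truth)) {
    nm <- names(period_truth)
    if ("watch" %in% nm)
      for (p in paste0("watch", 1:4)) out[[p]] <- period_truth$watch
    if ("decision" %in% nm)
      for (p in paste0("decision", 1:2)) out[[p]] <- period_truth$decision
    for (p in intersect(nm, period_names())) out[[p]] <- period_truth[[p]]
  }
  out
}

#' Simulate hemoglobin concentration-change series with known connectivity
#'
#' Generates a 15-channel HbO series as the sum of (i) a network-driven
#' multivariate Gaussian component drawn i.i.d. over samples with covariance
#' equal to the inverse of the ground-truth precision matrix (so its
#' population partial correlations equal the realized truth), (ii)
#' sinusoidal cardiac/Mayer/respiratory oscillations with uniform random
#' phase per channel, (iii) polynomial drift, (iv) common-mode motion
#' spikes, and (v) white measurement noise. Hbb is `-hbb_ratio * HbO(clean)`
#' plus the same motion spikes and independent noise, producing the
#' imperfect HbO/Hbb anticorrelation that CBSI is designed to repair. Event
#' markers are placed at the watch-phase end (`target_spotted`) and the
#' recording end (`course_change`).
#'
#' @param truth a `ground_truth_network` (used for all periods unless
#'   `scenario$period_truth` overrides specific phases).
#' @param noise a [noise_spec()].
#' @param scenario a [scenario_spec()].
#' @return A [hemo_series()] with events; attribute `network_component`
#'   holds the noise-free network-driven HbO matrix and attribute
#'   `period_truth` the per-period ground truth actually used.
#' @export
simulate_hemodynamics <- function(truth, noise = noise_spec(),
                                  scenario = scenario_spec()) {
  stopifnot(inherits(truth, "ground_truth_network"))
  fs <- scenario$fs
  nyquist <- fs / 2
  freqs <- c(noise$cardiac_hz, noise$mayer_hz, noise$resp_hz)
  if (any(freqs >= nyquist))
    stop("noise frequencies must be below the Nyquist frequency ", nyquist)
  n_w <- round(scenario$watch_duration_s * fs)
  n_d <- round(scenario$decision_duration_s * fs)
  n <- n_w + n_d
  k <- truth$n_channels
  seg <- segment_boundaries(n_w, n_d)
  truth_by_period <- resolve_period_truth(truth, scenario$period_truth)

  set.seed(scenario$seed)
  network <- matrix(0, n, k)
  for (p in period_names()) {
    rows <- seg$start[seg$period == p]:(seg$end[seg$period == p] - 1)
    om <- truth_by_period[[p]]$precision
    l_chol <- chol(solve(om))
    z <- matrix(stats::rnorm(length(rows) * k), length(rows), k)
    network[rows, ] <- (z %*% l_chol) * scenario$network_amp
  }

  t_s <- (seq_len(n) - 1) / fs
  phys <- matrix(0, n, k)
  for (comp in list(c(noise$cardiac_hz, noise$cardiac_amp),
                    c(noise$mayer_hz, noise$mayer_amp),
                    c(noise$resp_hz, noise$resp_amp))) {
    phase <- stats::runif(k, 0, 2 * pi)
    if (comp[2] > 0)
      phys <- phys + comp[2] *
        sin(outer(2 * pi * comp[1] * t_s, phase, `+`))
  }
  if (noise$drift_amp > 0 && noise$drift_order > 0) {
    basis <- outer(t_s / max(t_s), seq_len(noise$drift_order), `^`)
    coefs <- matrix(stats::runif(noise$drift_order * k, -1, 1) *
                      noise$drift_amp, noise$drift_order, k)
    phys <- phys + basis %*% coefs
  }

  motion <- matrix(0, n, k)
  if (noise$spike_rate > 0 && noise$spike_amp > 0) {
    n_spikes <- stats::rpois(1, noise$spike_rate * n / fs / 60)
    if (n_spikes > 0) {
      onsets <- sort(stats::runif(n_spikes, 0, n / fs))
      gains <- matrix(stats::runif(n_spikes * k, 0.5, 1.5), n_spikes, k)
      signs <- sample(c(-1, 1), n_spikes, replace = TRUE)
      for (s in seq_len(n_spikes)) {
        idx <- which(t_s >= onsets[s])
        shape <- exp(-(t_s[idx] - onsets[s]) / noise$spike_tau_s)
        motion[idx, ] <- motion[idx, ] +
          noise$spike_amp * signs[s] * outer(shape, gains[s, ])
      }
    }
  }

  hbo_clean <- network + phys
  hbo <- hbo_clean + motion +
    matrix(stats::rnorm(n * k, 0, noise$measurement_sd), n, k)
  hbb <- -noise$hbb_ratio * hbo_clean + motion +
    matrix(stats::rnorm(n * k, 0, noise$hbb_noise_sd), n, k)

  events <- data.frame(time_s = c(n_w, n) / fs,
                       label = c("target_spotted", "course_change"))
  hs <- hemo_series(hbo = hbo, hbb = hbb, fs = fs, events = events)
  attr(hs, "network_component") <- network
  attr(hs, "period_truth") <- truth_by_period
  hs
}

#' Tabulated hemoglobin extinction coefficients
#'
#' Standard molar extinction coefficients of oxy- and deoxyhemoglobin at the
#' two device wavelengths, in cm^-1 M^-1 (compiled tabulated values as
#' packaged in `inst/extdata/extinction_hb.csv`, which cites the source).
#' All exactness guarantees in the package are round-trip based and
#' therefore independent of the particular table.
#'
#' @return data.frame with columns `wavelength_nm`, `hbo`, `hbb`.
#' @export
default_extinction <- function() {
  path <- system.file("extdata", "extinction_hb.csv", package = "fnirsconn")
  if (!nzchar(path)) stop("packaged extinction_hb.csv not found")
  as.data.frame(data.table::fread(path))
}

#' Forward model: hemoglobin series to raw optical intensities
#'
#' Applies the modified Beer-Lambert law forward: for each wavelength,
#' `dOD(t) = (eps_HbO * HbO(t) + eps_Hbb * Hbb(t)) * DPF * d`, with
#' concentrations in micromolar, extinction coefficients in cm^-1 M^-1 and
#' the source-detector distance converted to cm; intensities are then
#' `I(t) = i0 * 10^(-dOD(t))`. This is the exact inverse of [apply_mbll()]
#' composed with [to_optical_density()] for zero-mean concentration input.
#'
#' @param hemo a [hemo_series()] with `hbo` and `hbb`.
#' @param montage montage supplying the source-detector distance.
#' @param dpf_760,dpf_850 differential pathlength factors (defaults 7.25 and
#'   6.38, the values used for this device).
#' @param distance_mm source-detector separation in mm.
#' @param extinction extinction table as from [default_extinction()].
#' @param i0 baseline intensity (arbitrary units, must be positive).
#' @param participant participant metadata for the resulting recording.
#' @return An [optical_recording()].
#' @export
simulate_optics <- function(hemo, montage = default_montage(),
                            dpf_760 = 7.25, dpf_850 = 6.38,
                            distance_mm = montage$source_detector_distance_mm,
                            extinction = default_extinction(),
                            i0 = 1,
                            participant = list(id = "sim01",
                                               experience = "inexperienced",
                                               distraction = "no_distraction")) {
  stopifnot(inherits(hemo, "hemo_series"))
  if (dpf_760 <= 0 || dpf_850 <= 0 || distance_mm <= 0)
    stop("DPFs and distance must be positive")
  if (any(i0 <= 0)) stop("non-physical baseline intensity (must be > 0)")
  e_mat <- extinction_matrix(extinction)
  d_cm <- distance_mm / 10
  n <- nrow(hemo$hbo); k <- ncol(hemo$hbo)
  intens <- array(NA_real_, c(n, k, 2))
  dpf <- c(dpf_760, dpf_850)
  for (w in 1:2) {
    dod <- (hemo$hbo * e_mat[w, 1] + hemo$hbb * e_mat[w, 2]) * 1e-6 *
      dpf[w] * d_cm
    intens[, , w] <- i0 * 10^(-dod)
  }
  optical_recording(intens, fs = hemo$fs, events = hemo$events,
                    participant = participant, montage = montage)
}

# 2x2 extinction system, rows = wavelengths (ascending), cols = (hbo, hbb).
extinction_matrix <- function(extinction) {
  stopifnot(all(c("wavelength_nm", "hbo", "hbb") %in% names(extinction)))
  ext <- extinction[order(extinction$wavelength_nm), ]
  if (nrow(ext) != 2) stop("extinction table must have exactly two wavelengths")
  e_mat <- as.matrix(ext[, c("hbo", "hbb")])
  if (abs(det(e_mat)) < 1e-12) stop("singular extinction matrix")
  e_mat
}

#' Simulate behavioral distances from network metrics
#'
#' Distances are generated as a linear function of connection density and
#' clustering, `distance = intercept + beta_d * D + beta_c * C + noise`,
#' mirroring the structure of the study's brain-behavior regressions (with a
#' positive density effect for target spotting during the last watch period
#' and a negative one for the evasive maneuver in the last decision period).
#'
#' @param metrics data.frame with columns `participant_id`, `density`,
#'   `clustering` (one row per participant, e.g. a single-period slice of
#'   [metrics_table()] output).
#' @param coeffs list with `intercept`, `beta_d`, `beta_c`, `sd` (noise sd).
#' @param seed integer seed.
#' @return data.frame with `participant_id` and `distance_nm`.
#' @export
simulate_behavior <- function(metrics, coeffs, seed = 1) {
  stopifnot(all(c("participant_id", "density", "clustering") %in%
                  names(metrics)))
  stopifnot(all(c("intercept", "beta_d", "beta_c", "sd") %in% names(coeffs)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu <- coeffs$intercept + coeffs$beta_d * metrics$density +
    coeffs$beta_c * metrics$clustering
  data.frame(participant_id = metrics$participant_id,
             distance_nm = mu + stats::rnorm(nrow(metrics), 0, coeffs$sd))
}

#' Noise sd that yields a target population R-squared
#'
#' Given cohort metric values and regression coefficients, returns the
#' residual standard deviation for which the linear predictor explains
#' `r2` of the response variance in this cohort.
#'
#' @inheritParams simulate_behavior
#' @param beta_d,beta_c regression coefficients on density and clustering.
#' @param r2 target proportion of variance explained, in (0, 1).
#' @return Residual sd.
#' @export
noise_sd_for_r2 <- function(metrics, beta_d, beta_c, r2) {
  stopifnot(r2 > 0, r2 < 1)
  signal <- beta_d * metrics$density + beta_c * metrics$clustering
  v <- stats::var(signal)
  if (v == 0) stop("metrics have zero variance; R-squared target unattainable")
  sqrt(v * (1 - r2) / r2)
}

#' Write / read a ground-truth network as JSON
#'
#' @param gt a `ground_truth_network`.
#' @param path JSON file path.
#' @return `write_ground_truth` invisibly returns `path`;
#'   `read_ground_truth` returns the reconstructed object.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth_network"))
  jsonlite::write_json(
    list(n_channels = gt$n_channels,
         edges = if (nrow(gt$edges)) unname(apply(gt$edges, 1, as.list)) else list(),
         strength_requested = gt$strength_requested,
         partial_strength = gt$partial_strength,
         ridge = gt$ridge,
         precision = gt$precision),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::fromJSON(path)
  edges <- raw$edges
  edges <- if (is.matrix(edges)) {
    matrix(as.integer(edges), ncol = 2)
  } else if (length(edges)) {
    matrix(as.integer(unlist(edges)), ncol = 2, byrow = TRUE)
  } else matrix(integer(0), ncol = 2)
  precision <- as.matrix(raw$precision)
  adjacency <- matrix(0L, raw$n_channels, raw$n_channels)
  for (k in seq_len(nrow(edges))) {
    adjacency[edges[k, 1], edges[k, 2]] <- 1L
    adjacency[edges[k, 2], edges[k, 1]] <- 1L
  }
  structure(
    list(n_channels = raw$n_channels, adjacency = adjacency,
         precision = precision, partial_strength = raw$partial_strength,
         strength_requested = raw$strength_requested, ridge = raw$ridge,
         edges = edges),
    class = "ground_truth_network"
  )
}
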