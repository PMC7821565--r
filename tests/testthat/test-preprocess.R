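make_rec <- function(intens, fs = 8.9, events = NULL) {
  optical_recording(intens, fs = fs, events = events)
}

test_that("constant intensities give identically zero optical density", {
  od <- to_optical_density(make_rec(array(2.5, c(100, 15, 2))))
  expect_equal(max(abs(od$od)), 0)
})

test_that("a tenfold intensity drop reads as ~1 OD against the record baseline", {
  n <- 1000
  intens <- array(1, c(n, 15, 2))
  intens[500, 3, 1] <- 0.1
  od <- to_optical_density(make_rec(intens))
  # baseline absorbs 1/n of the dip (log-mean reference)
  expect_equal(od$od[500, 3, 1], 1 - 1 / n, tolerance = 1e-12)
  expect_equal(od$od[10, 3, 1], -1 / n, tolerance = 1e-12)
})

test_that("artifact repair leaves clean signals untouched", {
  fs <- 8.9
  t_s <- (0:999) / fs
  clean <- matrix(sin(2 * pi * 0.2 * t_s), ncol = 1)
  out <- repair_artifacts(clean, fs = fs)
  expect_equal(out[, 1], clean[, 1])
  expect_false(any(attr(out, "interp_mask")))
  const <- matrix(3, 500, 2)
  out2 <- repair_artifacts(const, fs = fs)
  expect_false(any(attr(out2, "interp_mask")))
})

test_that("an isolated large spike is flagged and replaced by the neighbor midpoint", {
  set.seed(21)
  v <- stats::rnorm(1000)
  v[500] <- 20 * stats::sd(v)
  out <- repair_artifacts(matrix(v, ncol = 1), fs = 8.9)
  mask <- attr(out, "interp_mask")[, 1]
  expect_identical(which(mask), 500L)
  expect_equal(out[500, 1], (v[499] + v[501]) / 2, tolerance = 1e-12)
  expect_equal(out[-500, 1], v[-500])
})

test_that("a channel failing the quality gate raises an error", {
  set.seed(22)
  v <- matrix(stats::rnorm(400), ncol = 1)
  expect_error(repair_artifacts(v, spike_z = 0.1, fs = 8.9),
               "signal quality unacceptable")
})

test_that("low-pass filter meets its passband and stopband contracts", {
  fs <- 8.9
  t_s <- seq(0, 600, by = 1 / fs)
  mid <- 2000:3500
  slow <- matrix(sin(2 * pi * 0.05 * t_s), ncol = 1)
  y_slow <- lowpass(slow, filter_spec(), fs = fs)
  expect_gt(max(abs(y_slow[mid, 1])), 0.99)
  fast <- matrix(sin(2 * pi * 1.2 * t_s), ncol = 1)
  y_fast <- lowpass(fast, filter_spec(), fs = fs)
  expect_lt(max(abs(y_fast[mid, 1])), 0.01)
  const <- matrix(1.7, 500, 1)
  expect_equal(lowpass(const, filter_spec(), fs = fs)[, 1], const[, 1],
               tolerance = 1e-9)
  expect_error(lowpass(const, filter_spec(cutoff_hz = 5), fs = fs), "Nyquist")
})

test_that("zero-phase filtering introduces no group delay", {
  fs <- 8.9
  x <- matrix(0, 1001, 1)
  x[501, 1] <- 1
  y <- lowpass(x, filter_spec(), fs = fs)[, 1]
  # impulse response symmetric about the impulse => zero phase
  expect_equal(y[501 + 1:100], y[501 - 1:100], tolerance = 1e-10)
})

test_that("mBLL inversion recovers zero from zero OD and is linear", {
  set.seed(23)
  gt <- make_ground_truth(15, n_edges = 8, strength = 0.5, seed = 3)
  hemo <- silent_hemo(gt, seed = 7)
  od <- to_optical_density(simulate_optics(hemo))
  zero_od <- od
  zero_od$od[] <- 0
  h0 <- apply_mbll(zero_od)
  expect_equal(max(abs(h0$hbo)), 0)
  expect_equal(max(abs(h0$hbb)), 0)

  od2 <- to_optical_density(simulate_optics(silent_hemo(gt, seed = 8)))
  comb <- od
  comb$od <- 2 * od$od - 0.5 * od2$od
  h_comb <- apply_mbll(comb)
  h1 <- apply_mbll(od); h2 <- apply_mbll(od2)
  expect_equal(h_comb$hbo, 2 * h1$hbo - 0.5 * h2$hbo, tolerance = 1e-9)
})

test_that("scaling both DPFs by two halves the recovered concentrations", {
  gt <- make_ground_truth(15, n_edges = 8, strength = 0.5, seed = 5)
  od <- to_optical_density(simulate_optics(silent_hemo(gt, seed = 9)))
  h1 <- apply_mbll(od)
  h2 <- apply_mbll(od, dpf_760 = 2 * 7.25, dpf_850 = 2 * 6.38)
  expect_equal(h2$hbo, h1$hbo / 2, tolerance = 1e-9)
  expect_equal(h2$hbb, h1$hbb / 2, tolerance = 1e-9)
})

test_that("an HbO impulse produces the predicted cross-wavelength OD ratio", {
  ext <- default_extinction()
  n <- 50
  hbo <- matrix(0, n, 15); hbo[25, 4] <- 1
  hemo <- hemo_series(hbo = hbo, hbb = matrix(0, n, 15), fs = 8.9)
  rec <- simulate_optics(hemo)
  od <- -log10(rec$intensities[25, 4, ] / 1)  # i0 = 1
  e760 <- ext$hbo[ext$wavelength_nm == 760]
  e850 <- ext$hbo[ext$wavelength_nm == 850]
  expect_equal(od[[1]] / od[[2]], (e760 * 7.25) / (e850 * 6.38),
               tolerance = 1e-9)
})

test_that("CBSI is the identity when Hbb is the exact inverse of HbO", {
  set.seed(24)
  hbo <- matrix(stats::rnorm(600 * 3), 600, 3)
  hemo <- hemo_series(hbo = hbo, hbb = -hbo, fs = 8.9)
  out <- apply_cbsi(hemo, scope = "global")
  expect_equal(unname(out$cbsi_alpha[1, ]), rep(1, 3), tolerance = 1e-12)
  expect_equal(out$cbsi_hbo, hbo, tolerance = 1e-12)
})

test_that("CBSI forces exact anticorrelation within every scope window", {
  set.seed(25)
  hemo <- hemo_series(hbo = matrix(stats::rnorm(900 * 4), 900, 4),
                      hbb = matrix(stats::rnorm(900 * 4), 900, 4),
                      fs = 8.9,
                      events = data.frame(time_s = c(60, 900 / 8.9),
                                          label = c("target_spotted",
                                                    "course_change")))
  out <- apply_cbsi(hemo, scope = "per_period")
  hbb_c <- cbsi_hbb(out)
  w <- out$cbsi_windows
  for (wi in seq_len(nrow(w))) {
    rows <- w$start[wi]:(w$end[wi] - 1)
    for (ch in 1:4)
      expect_equal(stats::cor(out$cbsi_hbo[rows, ch], hbb_c[rows, ch]), -1,
                   tolerance = 1e-10)
  }
  # alphas differ across windows, so the whole-record correlation is
  # imperfect (strictly between -1 and 0), as seen in real recordings
  whole <- stats::cor(out$cbsi_hbo[, 1], hbb_c[, 1])
  expect_gt(whole, -1)
  expect_lt(whole, -0.5)
})

test_that("CBSI is invariant to positive rescaling of Hbb", {
  set.seed(26)
  hemo <- hemo_series(hbo = matrix(stats::rnorm(500 * 3), 500, 3),
                      hbb = matrix(stats::rnorm(500 * 3), 500, 3), fs = 8.9)
  a <- apply_cbsi(hemo, scope = "global")
  hemo$hbb <- hemo$hbb * 7.3
  b <- apply_cbsi(hemo, scope = "global")
  expect_equal(a$cbsi_hbo, b$cbsi_hbo, tolerance = 1e-9)
})

test_that("CBSI rejects dead channels", {
  hemo <- hemo_series(hbo = matrix(stats::rnorm(100 * 2), 100, 2),
                      hbb = cbind(stats::rnorm(100), rep(0, 100)), fs = 8.9)
  expect_error(apply_cbsi(hemo, scope = "global"), "dead channel")
})

test_that("CBSI recovers the network component better than raw HbO under motion", {
  gt <- make_ground_truth(15, n_edges = 12, strength = 0.5, seed = 3)
  hemo <- simulate_hemodynamics(gt, noise_spec(spike_rate = 6, spike_amp = 10),
                                scenario_spec(watch_duration_s = 292.5,
                                              decision_duration_s = 142,
                                              seed = 9))
  net <- attr(hemo, "network_component")
  out <- apply_cbsi(hemo, scope = "global")
  raw_c <- vapply(1:15, function(ch) stats::cor(hemo$hbo[, ch], net[, ch]),
                  numeric(1))
  cbsi_c <- vapply(1:15, function(ch) stats::cor(out$cbsi_hbo[, ch], net[, ch]),
                   numeric(1))
  expect_gt(mean(cbsi_c), mean(raw_c))
  expect_gt(sum(cbsi_c > raw_c), 12)
})

test_that("the full preprocessing chain runs and attenuates cardiac noise", {
  gt <- make_ground_truth(15, n_edges = 10, strength = 0.5, seed = 6)
  hemo <- simulate_hemodynamics(gt, noise_spec(),
                                scenario_spec(watch_duration_s = 120,
                                              decision_duration_s = 60,
                                              seed = 4))
  rec <- simulate_optics(hemo)
  pp <- preprocess_recording(rec)
  expect_s3_class(pp, "hemo_series")
  expect_false(is.null(pp$cbsi_hbo))
  expect_identical(dim(pp$cbsi_hbo), dim(pp$hbo))
  # cardiac band energy must be strongly suppressed relative to input
  pg <- function(v) {
    sp <- stats::spec.pgram(stats::ts(v, frequency = 8.9), spans = 9,
                            plot = FALSE, detrend = TRUE)
    sum(sp$spec[sp$freq > 1.1 & sp$freq < 1.3])
  }
  raw_hemo <- apply_mbll(to_optical_density(rec))
  expect_lt(pg(pp$hbo[, 1]) / pg(raw_hemo$hbo[, 1]), 1e-3)
})
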