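#' Construct a hemoglobin concentration-change series
#'
#' Holds per-channel oxy- (`hbo`) and deoxyhemoglobin (`hbb`)
#' concentration-change series in micromolar, the CBSI-corrected HbO once
#' [apply_cbsi()] has run, and a per-sample interpolation mask from artifact
#' repair.
#'
#' @param hbo,hbb numeric matrices, time x channel, same shape.
#' @param fs sampling rate in Hz.
#' @param events optional event data.frame (`time_s`, `label`).
#' @param cbsi_hbo optional CBSI-corrected HbO matrix.
#' @param interp_mask optional logical matrix marking interpolated samples.
#' @param units unit label, default micromolar.
#' @return A `hemo_series` object.
#' @export
hemo_series <- function(hbo, hbb, fs, events = NULL, cbsi_hbo = NULL,
                        interp_mask = NULL, units = "uM") {
  stopifnot(is.matrix(hbo), is.matrix(hbb), identical(dim(hbo), dim(hbb)))
  if (!is.null(cbsi_hbo)) stopifnot(identical(dim(cbsi_hbo), dim(hbo)))
  if (!is.null(interp_mask)) stopifnot(identical(dim(interp_mask), dim(hbo)))
  if (fs <= 0) stop("fs must be positive")
  if (!is.null(events)) events <- validate_events(events, nrow(hbo) / fs)
  structure(list(hbo = hbo, hbb = hbb, cbsi_hbo = cbsi_hbo,
                 interp_mask = interp_mask, fs = fs, events = events,
                 units = units),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("hemo_series: %d samples x %d channels @ %.3g Hz [%s]%s\n",
              nrow(x$hbo), ncol(x$hbo), x$fs, x$units,
              if (is.null(x$cbsi_hbo)) "" else " + CBSI"))
  invisible(x)
}

#' Filter specification for the low-pass stage
#'
#' @param cutoff_hz low-pass cutoff in Hz (default 0.4, which suppresses
#'   cardiac oscillations around 1-1.5 Hz while passing the slow
#'   hemodynamics).
#' @param order Butterworth order (default 4).
#' @param zero_phase apply forward-backward for zero group delay.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(cutoff_hz = 0.4, order = 4, zero_phase = TRUE) {
  stopifnot(cutoff_hz > 0, order >= 1)
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Convert raw intensities to optical-density changes
#'
#' `OD(t) = -log10(I(t) / I0)` per channel and wavelength. The baseline
#' `I0` is the geometric mean intensity of the recording (equivalently, the
#' mean log-intensity is subtracted), so OD changes are exactly zero-mean
#' and concentration changes downstream are deviations from the recording
#' mean; for the small fluctuations typical of these data the geometric and
#' arithmetic means agree to second order.
#'
#' @param rec an [optical_recording()] (strictly positive intensities).
#' @return An `od_series`: list with `od` (time x channel x wavelength
#'   array), `fs`, `events`, `montage`, `participant`.
#' @export
to_optical_density <- function(rec) {
  stopifnot(inherits(rec, "optical_recording"))
  if (any(rec$intensities <= 0)) stop("non-positive intensity")
  log_i <- log10(rec$intensities)
  od <- array(NA_real_, dim(rec$intensities),
              dimnames = dimnames(rec$intensities))
  for (w in seq_len(dim(od)[3])) {
    lw <- log_i[, , w]
    od[, , w] <- -(lw - matrix(colMeans(lw), nrow(lw), ncol(lw), byrow = TRUE))
  }
  structure(list(od = od, fs = rec$fs, events = rec$events,
                 montage = rec$montage, participant = rec$participant),
            class = "od_series")
}

#' Detect and repair spikes and discontinuities
#'
#' Computes a robust z-score per series: residual about a moving-window
#' median, scaled by a moving-window MAD (median absolute residual times
#' 1.4826) with a small floor so that constant channels produce no flags.
#' Samples with |z| above `spike_z` are replaced by linear interpolation
#' between the nearest clean neighbors (nearest clean value at the record
#' edges). Clean input is returned unchanged.
#'
#' @param x an `od_series`, a `hemo_series`, or a numeric matrix
#'   (time x channel).
#' @param spike_z robust z threshold (default 5).
#' @param window_s moving-window length in seconds (default 10).
#' @param mad_floor lower bound on the MAD scale (default 1e-12).
#' @param fs sampling rate; taken from the object when `x` is not a bare
#'   matrix.
#' @return The same type as `x` with repaired values and an interpolation
#'   mask (`interp_mask` element for objects; attribute for matrices).
#'   Errors if more than half of any channel is flagged (unacceptable
#'   signal quality).
#' @export
repair_artifacts <- function(x, spike_z = 5, window_s = 10,
                             mad_floor = 1e-12, fs = NULL) {
  if (inherits(x, "od_series")) {
    mask_any <- matrix(FALSE, dim(x$od)[1], dim(x$od)[2])
    for (w in seq_len(dim(x$od)[3])) {
      r <- repair_matrix(x$od[, , w], x$fs, spike_z, window_s, mad_floor)
      x$od[, , w] <- r$x
      mask_any <- mask_any | r$mask
    }
    x$interp_mask <- mask_any
    return(x)
  }
  if (inherits(x, "hemo_series")) {
    r1 <- repair_matrix(x$hbo, x$fs, spike_z, window_s, mad_floor)
    r2 <- repair_matrix(x$hbb, x$fs, spike_z, window_s, mad_floor)
    x$hbo <- r1$x; x$hbb <- r2$x
    x$interp_mask <- r1$mask | r2$mask
    return(x)
  }
  stopifnot(is.matrix(x), !is.null(fs))
  r <- repair_matrix(x, fs, spike_z, window_s, mad_floor)
  out <- r$x
  attr(out, "interp_mask") <- r$mask
  out
}

repair_matrix <- function(mat, fs, spike_z, window_s, mad_floor) {
  if (any(!is.finite(mat))) stop("input must be finite")
  n <- nrow(mat)
  win <- max(3, round(window_s * fs))
  if (win %% 2 == 0) win <- win + 1
  win <- min(win, if (n %% 2 == 1) n else n - 1)
  mask <- matrix(FALSE, n, ncol(mat))
  for (ch in seq_len(ncol(mat))) {
    v <- mat[, ch]
    med <- stats::runmed(v, win, endrule = "median")
    resid <- v - med
    scale <- pmax(1.4826 * stats::runmed(abs(resid), win, endrule = "median"),
                  mad_floor)
    flagged <- abs(resid) / scale > spike_z
    if (sum(flagged) > n / 2)
      stop("channel ", ch, ": more than half the samples flagged; ",
           "signal quality unacceptable")
    if (any(flagged)) {
      clean_idx <- which(!flagged)
      mat[flagged, ch] <- stats::approx(clean_idx, v[clean_idx],
                                        xout = which(flagged),
                                        rule = 2)$y
      mask[flagged, ch] <- TRUE
    }
  }
  list(x = mat, mask = mask)
}

#' Low-pass filter a series
#'
#' Butterworth low-pass (default order 4), applied forward-backward when
#' `zero_phase` so the net response has zero group delay and squared
#' magnitude; with the default design the attenuation at 1.2 Hz (cardiac
#' band) exceeds 40 dB while frequencies at or below 0.05 Hz pass within
#' 1%. DC gain is exactly 1, so a constant series is unchanged.
#'
#' @param x an `od_series`, `hemo_series`, or numeric matrix.
#' @param spec a [filter_spec()].
#' @param fs sampling rate (bare matrices only).
#' @return Filtered object of the same type.
#' @export
lowpass <- function(x, spec = filter_spec(), fs = NULL) {
  if (inherits(x, "od_series")) {
    for (w in seq_len(dim(x$od)[3]))
      x$od[, , w] <- lowpass_matrix(x$od[, , w], x$fs, spec)
    return(x)
  }
  if (inherits(x, "hemo_series")) {
    x$hbo <- lowpass_matrix(x$hbo, x$fs, spec)
    x$hbb <- lowpass_matrix(x$hbb, x$fs, spec)
    return(x)
  }
  stopifnot(is.matrix(x), !is.null(fs))
  lowpass_matrix(x, fs, spec)
}

lowpass_matrix <- function(mat, fs, spec) {
  nyq <- fs / 2
  if (spec$cutoff_hz >= nyq)
    stop("cutoff must be below the Nyquist frequency ", nyq)
  bf <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")
  out <- mat
  for (ch in seq_len(ncol(mat))) {
    # remove the mean before filtering so the DC component passes exactly
    # and start-up transients are not excited by the offset
    mu <- mean(mat[, ch])
    v <- mat[, ch] - mu
    out[, ch] <- mu + if (spec$zero_phase) {
      signal::filtfilt(bf, v)
    } else {
      as.numeric(signal::filter(bf, v))
    }
  }
  out
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per channel and sample, the two-wavelength system
#' `dOD(lambda) = (eps_HbO(lambda) * dHbO + eps_Hbb(lambda) * dHbb) *
#' DPF(lambda) * d` for the concentration changes (micromolar). The solve
#' is linear, so scaling both DPFs by a constant scales the recovered
#' concentrations by its inverse.
#'
#' @param od an `od_series` from [to_optical_density()].
#' @param montage montage supplying the default source-detector distance.
#' @param dpf_760,dpf_850 differential pathlength factors (7.25 and 6.38 by
#'   default, the values appropriate for this device's wavelengths).
#' @param distance_mm source-detector separation in mm.
#' @param extinction extinction table as from [default_extinction()].
#' @return A [hemo_series()] with `hbo` and `hbb` (no CBSI yet).
#' @export
apply_mbll <- function(od, montage = od$montage,
                       dpf_760 = 7.25, dpf_850 = 6.38,
                       distance_mm = montage$source_detector_distance_mm,
                       extinction = default_extinction()) {
  stopifnot(inherits(od, "od_series"))
  if (dpf_760 <= 0 || dpf_850 <= 0 || distance_mm <= 0)
    stop("DPFs and distance must be positive")
  e_mat <- extinction_matrix(extinction)
  inv_e <- solve(e_mat)
  d_cm <- distance_mm / 10
  dpf <- c(dpf_760, dpf_850)
  od760 <- od$od[, , 1] / (dpf[1] * d_cm)
  od850 <- od$od[, , 2] / (dpf[2] * d_cm)
  hbo <- (inv_e[1, 1] * od760 + inv_e[1, 2] * od850) / 1e-6
  hbb <- (inv_e[2, 1] * od760 + inv_e[2, 2] * od850) / 1e-6
  hemo_series(hbo = hbo, hbb = hbb, fs = od$fs, events = od$events,
              interp_mask = NULL)
}

#' Correlation-based signal improvement (CBSI)
#'
#' Forces HbO and Hbb into perfect anticorrelation to suppress common-mode
#' (motion) artifacts: per channel and scope window, the amplitude ratio
#' `alpha = sd(hbo) / sd(hbb)` is estimated and the corrected signal is
#' `cbsi_hbo = (hbo - alpha * hbb) / 2`, with
#' the implied `cbsi_hbb = -cbsi_hbo / alpha`. Within each window the
#' corrected pair is exactly anticorrelated by construction; when applied
#' per task period, the whole-record correlation of the concatenated
#' corrected series remains above -1 in magnitude because `alpha` varies
#' between windows.
#'
#' @param hemo a [hemo_series()].
#' @param scope `"global"` (one window covering the record) or
#'   `"per_period"` (one window per task period; needs a segmentation or
#'   events on the series).
#' @param segmentation optional [segment_periods()] result for
#'   `"per_period"` scope; derived from `hemo$events` when absent.
#' @return The series with `cbsi_hbo` filled in, plus elements
#'   `cbsi_alpha` (window x channel matrix of alphas) and `cbsi_windows`
#'   (data.frame of half-open sample windows).
#' @export
apply_cbsi <- function(hemo, scope = c("per_period", "global"),
                       segmentation = NULL) {
  stopifnot(inherits(hemo, "hemo_series"))
  scope <- match.arg(scope)
  n <- nrow(hemo$hbo)
  if (scope == "global") {
    windows <- data.frame(window = "global", start = 1L, end = n + 1L)
  } else {
    if (is.null(segmentation)) {
      if (is.null(hemo$events))
        stop("per-period CBSI needs a segmentation or events on the series")
      segmentation <- segment_periods(hemo$events, hemo$fs, n)
    }
    windows <- data.frame(window = segmentation$periods$period,
                          start = segmentation$periods$start,
                          end = segmentation$periods$end)
    # Samples after the last event (if any) form a trailing window so the
    # whole record is covered.
    if (max(windows$end) < n + 1)
      windows <- rbind(windows,
                       data.frame(window = "post", start = max(windows$end),
                                  end = n + 1L))
  }
  k <- ncol(hemo$hbo)
  cbsi <- matrix(NA_real_, n, k)
  alphas <- matrix(NA_real_, nrow(windows), k,
                   dimnames = list(windows$window, NULL))
  for (wi in seq_len(nrow(windows))) {
    rows <- windows$start[wi]:(windows$end[wi] - 1)
    for (ch in seq_len(k)) {
      x <- hemo$hbo[rows, ch]; y <- hemo$hbb[rows, ch]
      sx <- stats::sd(x); sy <- stats::sd(y)
      if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
        stop("dead channel: zero-variance window (channel ", ch,
             ", window ", windows$window[wi], ")")
      alpha <- sx / sy
      cbsi[rows, ch] <- (x - alpha * y) / 2
      alphas[wi, ch] <- alpha
    }
  }
  hemo$cbsi_hbo <- cbsi
  hemo$cbsi_alpha <- alphas
  hemo$cbsi_windows <- windows
  hemo
}

#' Implied CBSI-corrected Hbb
#'
#' Materializes `cbsi_hbb = -cbsi_hbo / alpha` per scope window, exactly
#' anticorrelated with `cbsi_hbo` within each window.
#'
#' @param hemo a `hemo_series` after [apply_cbsi()].
#' @return Matrix of corrected Hbb values.
#' @export
cbsi_hbb <- function(hemo) {
  if (is.null(hemo$cbsi_hbo)) stop("run apply_cbsi() first")
  out <- hemo$cbsi_hbo
  w <- hemo$cbsi_windows
  for (wi in seq_len(nrow(w))) {
    rows <- w$start[wi]:(w$end[wi] - 1)
    out[rows, ] <- -sweep(hemo$cbsi_hbo[rows, , drop = FALSE], 2,
                          hemo$cbsi_alpha[wi, ], `/`)
  }
  out
}

#' Full preprocessing pipeline for one recording
#'
#' Fixed stage order: optical density, artifact repair, low-pass filter,
#' modified Beer-Lambert inversion, CBSI. The order is not configurable.
#'
#' @param rec an [optical_recording()].
#' @param filter a [filter_spec()].
#' @param spike_z robust z threshold for artifact repair.
#' @param dpf_760,dpf_850,distance_mm,extinction see [apply_mbll()].
#' @param cbsi_scope `"per_period"` or `"global"`.
#' @return A [hemo_series()] with `cbsi_hbo` and `interp_mask`.
#' @export
preprocess_recording <- function(rec, filter = filter_spec(), spike_z = 5,
                                 dpf_760 = 7.25, dpf_850 = 6.38,
                                 distance_mm = rec$montage$source_detector_distance_mm,
                                 extinction = default_extinction(),
                                 cbsi_scope = "per_period") {
  od <- to_optical_density(rec)
  od <- repair_artifacts(od, spike_z = spike_z)
  mask <- od$interp_mask
  od <- lowpass(od, filter)
  hemo <- apply_mbll(od, montage = rec$montage, dpf_760 = dpf_760,
                     dpf_850 = dpf_850, distance_mm = distance_mm,
                     extinction = extinction)
  hemo$interp_mask <- mask
  apply_cbsi(hemo, scope = cbsi_scope)
}
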