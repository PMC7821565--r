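#' Split a sample count into near-equal contiguous blocks
#'
#' Used to divide the watch phase into four periods and the decision phase
#' into two. When the count is not divisible, the remainder `r` is assigned
#' one extra sample to each of the first `r` blocks, so block lengths
#' differ by at most one and the allocation is deterministic.
#'
#' @param n total number of samples.
#' @param k number of blocks.
#' @return Integer vector of `k` block lengths summing to `n`.
#' @export
split_even <- function(n, k) {
  stopifnot(n >= k, k >= 1)
  base <- n %/% k
  r <- n %% k
  base + c(rep(1L, r), rep(0L, k - r))
}

# Six half-open sample intervals over a record of n_w watch samples
# followed by n_d decision samples (1-based, [start, end)).
segment_boundaries <- function(n_w, n_d) {
  lens <- c(split_even(n_w, 4), split_even(n_d, 2))
  ends <- cumsum(lens)
  data.frame(period = period_names(),
             start = as.integer(c(1, ends[-6] + 1)),
             end = as.integer(ends + 1),
             n_samples = as.integer(lens),
             stringsAsFactors = FALSE)
}

#' Segment a recording into the six task periods
#'
#' The watch phase `[0, target_spotted)` is divided into four contiguous
#' periods of equal duration (watch1-watch4) and the decision phase
#' `[target_spotted, course_change)` into two (decision1, decision2).
#' Intervals are half-open in time, so boundary samples are never counted
#' twice; remainder samples go to the earliest periods.
#'
#' @param events data.frame with `time_s`, `label` containing one
#'   `target_spotted` and one `course_change` event, in that order.
#' @param fs sampling rate in Hz.
#' @param n_samples total samples in the recording.
#' @return A `period_segmentation`: list with `periods` (data.frame of
#'   period, start, end, n_samples; half-open 1-based sample intervals) and
#'   `events` (the two source event times).
#' @examples
#' ev <- data.frame(time_s = c(40, 60), label = c("target_spotted", "course_change"))
#' segment_periods(ev, fs = 10, n_samples = 600)$periods
#' @export
segment_periods <- function(events, fs, n_samples) {
  stopifnot(is.data.frame(events), fs > 0, n_samples >= 6)
  t_target <- events$time_s[events$label == "target_spotted"]
  t_course <- events$time_s[events$label == "course_change"]
  if (length(t_target) != 1 || length(t_course) != 1)
    stop("need exactly one target_spotted and one course_change event")
  if (!(t_target > 0 && t_target < t_course))
    stop("events out of order: need 0 < target_spotted < course_change")
  if (t_course > n_samples / fs + 1e-9)
    stop("course_change lies beyond the record duration")
  n_w <- round(t_target * fs)
  n_end <- min(round(t_course * fs), n_samples)
  n_d <- n_end - n_w
  if (n_w < 4 || n_d < 2)
    stop("phases too short to divide into periods")
  structure(list(periods = segment_boundaries(n_w, n_d),
                 events = c(target_spotted_s = t_target,
                            course_change_s = t_course),
                 fs = fs),
            class = "period_segmentation")
}

#' @export
print.period_segmentation <- function(x, ...) {
  cat("period_segmentation (fs =", x$fs, "Hz):\n")
  print(x$periods, row.names = FALSE)
  invisible(x)
}

#' Region-of-interest averages of CBSI-corrected HbO
#'
#' For every task period and ROI, the arithmetic mean over the five ROI
#' channels of each channel's mean CBSI_HbO over the period's samples
#' (equivalently, the grand mean over the 5-channel x period block).
#' Interpolated samples are included; their count is reported alongside.
#'
#' @param hemo a [hemo_series()] after [apply_cbsi()].
#' @param seg a [segment_periods()] result.
#' @param montage the montage defining ROI membership.
#' @param participant_id id stamped on the output rows.
#' @return data.frame with columns `participant_id`, `period`, `roi`,
#'   `mean_cbsi_hbo`, `n_samples`, `n_interpolated`.
#' @export
roi_average <- function(hemo, seg, montage = default_montage(),
                        participant_id = "p01") {
  stopifnot(inherits(hemo, "hemo_series"),
            inherits(seg, "period_segmentation"))
  if (is.null(hemo$cbsi_hbo)) stop("run apply_cbsi() first")
  rois <- c("left", "central", "right")
  out <- expand.grid(period = seg$periods$period, roi = rois,
                     stringsAsFactors = FALSE)
  out$participant_id <- participant_id
  out$mean_cbsi_hbo <- NA_real_
  out$n_samples <- NA_integer_
  out$n_interpolated <- 0L
  for (r in seq_len(nrow(out))) {
    p <- seg$periods[seg$periods$period == out$period[r], ]
    rows <- p$start:(p$end - 1)
    chans <- roi_channels(montage, out$roi[r])
    block <- hemo$cbsi_hbo[rows, chans, drop = FALSE]
    out$mean_cbsi_hbo[r] <- mean(colMeans(block))
    out$n_samples[r] <- length(rows)
    if (!is.null(hemo$interp_mask))
      out$n_interpolated[r] <- sum(hemo$interp_mask[rows, chans])
  }
  out[, c("participant_id", "period", "roi", "mean_cbsi_hbo",
          "n_samples", "n_interpolated")]
}

#' Flag outliers by design cell
#'
#' Applies the 3-standard-deviation rule: within each design cell, a value
#' is flagged when its absolute deviation from the cell mean exceeds
#' `sd_mult` sample standard deviations (n-1 denominator, computed with the
#' candidate included, single pass). Degenerate cells (zero SD) produce no
#' flags.
#'
#' @param df data.frame of observations.
#' @param value name of the numeric value column.
#' @param cells character vector of columns defining the design cells.
#' @param sd_mult SD multiplier (default 3).
#' @return List with `table` (the input plus logical column `outlier`) and
#'   `excluded` (the flagged rows).
#' @export
screen_outliers <- function(df, value, cells, sd_mult = 3) {
  stopifnot(value %in% names(df), all(cells %in% names(df)))
  key <- interaction(df[cells], drop = TRUE)
  if (any(table(key) < 2))
    stop("every design cell needs at least 2 observations")
  x <- df[[value]]
  flag <- logical(nrow(df))
  for (lev in levels(key)) {
    idx <- which(key == lev)
    m <- mean(x[idx]); s <- stats::sd(x[idx])
    if (is.finite(s) && s > 0)
      flag[idx] <- abs(x[idx] - m) > sd_mult * s
  }
  df$outlier <- flag
  list(table = df, excluded = df[flag, , drop = FALSE])
}
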