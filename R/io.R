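#' Construct an optical recording
#'
#' Container for raw two-wavelength fNIRS intensity data. Intensities are in
#' arbitrary units but must be strictly positive (optical density is a log
#' ratio). Events mark the two task transitions: `target_spotted` ends the
#' watchkeeping phase, `course_change` ends the decision phase (and the
#' recording).
#'
#' @param intensities numeric array `time x channel x wavelength`
#'   (channels in montage order; wavelength slices named by nm).
#' @param fs sampling rate in Hz (the device used here samples at 8.9 Hz).
#' @param events data.frame with columns `time_s`, `label`; labels must be
#'   among `"target_spotted"`, `"course_change"`.
#' @param participant list with `id`, `experience`
#'   (`"experienced"`/`"inexperienced"`) and `distraction`
#'   (`"distraction"`/`"no_distraction"`).
#' @param montage the montage the channels refer to.
#' @return An `optical_recording` object.
#' @export
optical_recording <- function(intensities, fs, events,
                              participant = list(id = "p01",
                                                 experience = "inexperienced",
                                                 distraction = "no_distraction"),
                              montage = default_montage()) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (dim(intensities)[2] != nrow(montage$channels))
    stop("incomplete montage: expected ", nrow(montage$channels),
         " channels, got ", dim(intensities)[2])
  if (dim(intensities)[3] != 2)
    stop("expected two wavelength slices")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("intensities must be finite and strictly positive")
  if (is.null(events))
    events <- data.frame(time_s = numeric(0), label = character(0))
  events <- validate_events(events, duration_s = dim(intensities)[1] / fs)
  participant <- validate_participant(participant)
  dimnames(intensities) <- list(
    NULL,
    sprintf("ch%02d", montage$channels$channel),
    as.character(montage$wavelengths_nm)
  )
  structure(
    list(intensities = intensities, fs = fs, events = events,
         participant = participant, montage = montage),
    class = "optical_recording"
  )
}

# Write a table with doubles rendered at 17 significant digits, which
# uniquely identify an IEEE double, so read-back is bit-exact.
fwrite_exact <- function(df, path, sep = ",") {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
}

validate_events <- function(events, duration_s) {
  stopifnot(is.data.frame(events))
  if (!all(c("time_s", "label") %in% names(events)))
    stop("events need columns time_s and label")
  allowed <- c("target_spotted", "course_change")
  bad <- setdiff(events$label, allowed)
  if (length(bad) > 0)
    stop("unknown event label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  if (any(events$time_s < 0) || any(events$time_s > duration_s + 1e-9))
    stop("event times must lie within the record duration")
  events <- events[order(events$time_s), c("time_s", "label")]
  events$time_s <- as.numeric(events$time_s)
  events$label <- as.character(events$label)
  rownames(events) <- NULL
  events
}

validate_participant <- function(p) {
  stopifnot(is.list(p), !is.null(p$id))
  exp_levels <- c("experienced", "inexperienced")
  dis_levels <- c("distraction", "no_distraction")
  if (!p$experience %in% exp_levels)
    stop("unknown experience label '", p$experience,
         "' (allowed: ", paste(exp_levels, collapse = ", "), ")")
  if (!p$distraction %in% dis_levels)
    stop("unknown distraction label '", p$distraction,
         "' (allowed: ", paste(dis_levels, collapse = ", "), ")")
  list(id = as.character(p$id), experience = p$experience,
       distraction = p$distraction)
}

#' @export
print.optical_recording <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("optical_recording: %d samples x %d channels x %d wavelengths @ %.3g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$fs, d[1] / x$fs))
  cat("participant:", x$participant$id, "|", x$participant$experience, "|",
      x$participant$distraction, "\n")
  if (nrow(x$events)) {
    cat("events:\n")
    print(x$events, row.names = FALSE)
  }
  invisible(x)
}

#' Write a recording to disk (wide CSV + events TSV + metadata JSON)
#'
#' The on-disk dialect is a UTF-8 comma-separated file with a mandatory
#' header `time, ch01_760, ch01_850, ..., ch15_850`, an events TSV with
#' columns `time_s`, `label`, and a small JSON sidecar holding the sampling
#' rate and participant metadata. Numeric values are written with full
#' round-trip precision so that write/load is lossless.
#'
#' @param rec an `optical_recording`.
#' @param dir output directory (created if missing).
#' @param stem file-name stem; defaults to the participant id.
#' @return Invisibly, a named list of the three file paths.
#' @export
write_recording <- function(rec, dir, stem = rec$participant$id) {
  stopifnot(inherits(rec, "optical_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- dim(rec$intensities)[1]
  wl <- dimnames(rec$intensities)[[3]]
  cols <- list(time = (seq_len(n) - 1) / rec$fs)
  for (ch in seq_len(dim(rec$intensities)[2])) {
    for (w in wl) {
      cols[[sprintf("ch%02d_%s", ch, w)]] <- rec$intensities[, ch, w]
    }
  }
  paths <- list(
    intensities = file.path(dir, paste0(stem, "_intensities.csv")),
    events = file.path(dir, paste0(stem, "_events.tsv")),
    meta = file.path(dir, paste0(stem, "_meta.json"))
  )
  fwrite_exact(data.table::as.data.table(cols), paths$intensities)
  fwrite_exact(rec$events, paths$events, sep = "\t")
  jsonlite::write_json(
    list(fs = rec$fs, participant = rec$participant,
         wavelengths_nm = rec$montage$wavelengths_nm,
         source_detector_distance_mm = rec$montage$source_detector_distance_mm),
    paths$meta, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Load a recording from the wide-CSV dialect
#'
#' Reads the three files written by [write_recording()] and returns a
#' validated [optical_recording()]. Channel columns may appear in any order
#' on disk; they are normalized to montage order. A missing channel column
#' is an error (participants with incomplete montages are excluded from
#' analysis rather than silently padded).
#'
#' @param stem path stem, i.e. `file.path(dir, participant_id)`; the function
#'   appends `_intensities.csv`, `_events.tsv`, `_meta.json`.
#' @param montage montage to validate against.
#' @return An `optical_recording`.
#' @export
load_recording <- function(stem, montage = default_montage()) {
  paths <- paste0(stem, c("_intensities.csv", "_events.tsv", "_meta.json"))
  for (p in paths) if (!file.exists(p)) stop("unknown format or missing file: ", p)
  meta <- jsonlite::fromJSON(paths[3])
  dt <- data.table::fread(paths[1])
  if (!"time" %in% names(dt)) stop("intensity CSV lacks a 'time' column")
  wl <- as.integer(meta$wavelengths_nm)
  chans <- montage$channels$channel
  n <- nrow(dt)
  intens <- array(NA_real_, dim = c(n, length(chans), 2))
  for (ci in seq_along(chans)) {
    for (wi in seq_along(wl)) {
      col <- sprintf("ch%02d_%d", chans[ci], wl[wi])
      if (!col %in% names(dt))
        stop("incomplete montage: missing channel column ", col)
      intens[, ci, wi] <- dt[[col]]
    }
  }
  events <- as.data.frame(data.table::fread(paths[2]))
  meta$participant$distraction <- as.character(meta$participant$distraction)
  optical_recording(
    intensities = intens, fs = meta$fs, events = events,
    participant = meta$participant,
    montage = montage(
      channels = montage$channels, wavelengths_nm = wl,
      source_detector_distance_mm = meta$source_detector_distance_mm
    )
  )
}

#' Read a behavioral table
#'
#' Behavioral records hold, per participant, the distance (nautical miles)
#' between own ship and the target vessel when it was spotted and when the
#' evasive maneuver was made, the index of the target's spawn position
#' (1-10), and the two between-participant group labels.
#'
#' @param path TSV file with header columns `participant_id`, `experience`,
#'   `distraction`, `target_position_index`, `distance_spotted_nm`,
#'   `distance_maneuver_nm`.
#' @return data.frame of validated records.
#' @export
load_behavior <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  validate_behavior(df)
}

#' Validate a behavioral table held in memory
#'
#' @param df data.frame as described in [load_behavior()].
#' @return The validated data.frame (column order normalized).
#' @export
validate_behavior <- function(df) {
  required <- c("participant_id", "experience", "distraction",
                "target_position_index", "distance_spotted_nm",
                "distance_maneuver_nm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("behavior table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, required]
  df$participant_id <- as.character(df$participant_id)
  df$target_position_index <- as.integer(df$target_position_index)
  df$distance_spotted_nm <- as.numeric(df$distance_spotted_nm)
  df$distance_maneuver_nm <- as.numeric(df$distance_maneuver_nm)
  if (anyDuplicated(df$participant_id))
    stop("duplicated participant ids: ",
         paste(unique(df$participant_id[duplicated(df$participant_id)]),
               collapse = ", "))
  bad_exp <- setdiff(df$experience, c("experienced", "inexperienced"))
  if (length(bad_exp) > 0)
    stop("unknown experience label(s): ", paste(bad_exp, collapse = ", "),
         " (allowed: experienced, inexperienced)")
  bad_dis <- setdiff(df$distraction, c("distraction", "no_distraction"))
  if (length(bad_dis) > 0)
    stop("unknown distraction label(s): ", paste(bad_dis, collapse = ", "),
         " (allowed: distraction, no_distraction)")
  if (any(df$distance_spotted_nm < 0) || any(df$distance_maneuver_nm < 0))
    stop("distances must be non-negative")
  if (any(df$distance_maneuver_nm > df$distance_spotted_nm + 1e-12))
    stop("maneuver distance cannot exceed spotted distance (vessels approach monotonically)")
  if (any(df$target_position_index < 1 | df$target_position_index > 10))
    stop("target_position_index must be in 1..10")
  df
}

#' Write a behavioral table
#'
#' @param df validated behavioral data.frame.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_behavior <- function(df, path) {
  df <- validate_behavior(df)
  fwrite_exact(df, path, sep = "\t")
  invisible(path)
}
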