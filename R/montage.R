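#' The standard 15-channel prefrontal montage
#'
#' Returns the montage used throughout the package: 15 source-detector
#' channels over the prefrontal cortex, measured at 760 and 850 nm, grouped
#' into three regions of interest of five channels each (channels 1-5 left
#' lateral, 6-10 central, 11-15 right lateral). Each channel carries its
#' optode-pair label in the 10/20 system and the underlying Brodmann area(s).
#'
#' The montage ships with the package as a JSON file
#' (`system.file("extdata", "montage.json", package = "fnirsconn")`).
#'
#' @return An object of class `fnirs_montage`: a list with elements
#'   `channels` (data.frame with columns `channel`, `optodes`, `brodmann`,
#'   `roi`), `wavelengths_nm` (integer vector, `c(760, 850)`) and
#'   `source_detector_distance_mm` (default 30).
#' @examples
#' m <- default_montage()
#' subset(m$channels, roi == "right")
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage.json", package = "fnirsconn")
  if (!nzchar(path)) stop("packaged montage.json not found")
  raw <- jsonlite::fromJSON(path)
  montage(
    channels = raw$channels,
    wavelengths_nm = as.integer(raw$wavelengths_nm),
    source_detector_distance_mm = raw$source_detector_distance_mm
  )
}

#' Construct and validate a montage object
#'
#' @param channels data.frame with columns `channel` (1..n), `optodes`,
#'   `brodmann`, `roi` (one of `"left"`, `"central"`, `"right"`).
#' @param wavelengths_nm integer vector of exactly two wavelengths.
#' @param source_detector_distance_mm positive optode separation in mm.
#' @return A validated `fnirs_montage` object.
#' @export
montage <- function(channels, wavelengths_nm = c(760L, 850L),
                    source_detector_distance_mm = 30) {
  stopifnot(is.data.frame(channels))
  required <- c("channel", "optodes", "brodmann", "roi")
  missing_cols <- setdiff(required, names(channels))
  if (length(missing_cols) > 0)
    stop("montage channels table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  channels <- channels[order(channels$channel), required]
  if (nrow(channels) != 15)
    stop("montage must have exactly 15 channels, got ", nrow(channels))
  if (!identical(as.integer(channels$channel), 1:15))
    stop("channel ids must be exactly 1..15")
  expected_roi <- rep(c("left", "central", "right"), each = 5)
  if (!identical(as.character(channels$roi), expected_roi))
    stop("ROI partition must be channels 1-5 left, 6-10 central, 11-15 right")
  if (length(wavelengths_nm) != 2 || anyDuplicated(wavelengths_nm))
    stop("exactly two distinct wavelengths required")
  if (!is.numeric(source_detector_distance_mm) ||
      source_detector_distance_mm <= 0)
    stop("source_detector_distance_mm must be positive")
  structure(
    list(channels = channels,
         wavelengths_nm = sort(as.integer(wavelengths_nm)),
         source_detector_distance_mm = source_detector_distance_mm),
    class = "fnirs_montage"
  )
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat("fNIRS montage:", nrow(x$channels), "channels,",
      paste(x$wavelengths_nm, collapse = "/"), "nm,",
      x$source_detector_distance_mm, "mm separation\n")
  print(x$channels, row.names = FALSE)
  invisible(x)
}

#' Channels belonging to a region of interest
#'
#' @param montage an `fnirs_montage`.
#' @param roi one of `"left"`, `"central"`, `"right"`.
#' @return Integer vector of channel ids.
#' @export
roi_channels <- function(montage, roi) {
  roi <- match.arg(roi, c("left", "central", "right"))
  montage$channels$channel[montage$channels$roi == roi]
}
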