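#' Partial-correlation matrix of a multichannel series
#'
#' Estimates, for every channel pair, the correlation remaining after
#' linearly controlling for all other channels. Computed from the inverse
#' of the sample correlation matrix: with `O = R^-1`,
#' `partial_r[i, j] = -O[i, j] / sqrt(O[i, i] * O[j, j])`; this equals the
#' correlation between the residuals of each channel regressed on all the
#' others. The estimate is invariant to per-channel location and positive
#' scale changes.
#'
#' When the correlation matrix is numerically near-singular and no ridge
#' was requested, a small ridge (1e-4) is added to the diagonal and
#' recorded in the result (`ridge_used`); with `auto_ridge = FALSE` a
#' rank-deficient input is an error.
#'
#' @param x numeric matrix, time x channel (a period-restricted slice of
#'   CBSI-corrected HbO in the standard pipeline).
#' @param ridge explicit ridge added to the correlation diagonal
#'   (default 0).
#' @param auto_ridge raise the ridge automatically on near-singularity.
#' @param participant,period labels carried on the result.
#' @return A `connectivity_matrix`: list with `partial_r` (symmetric, unit
#'   diagonal), `n_samples`, `n_channels`, `ridge_used`, `participant`,
#'   `period`.
#' @export
partial_correlation <- function(x, ridge = 0, auto_ridge = TRUE,
                                participant = NA_character_,
                                period = NA_character_) {
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x); k <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("zero-variance channel(s): ",
         paste(which(sds == 0), collapse = ", "),
         "; partial correlation over the full montage is undefined")
  if (n <= k && ridge == 0 && !auto_ridge)
    stop("need more samples than channels, or a ridge")
  r_mat <- stats::cor(x)
  r_mat <- r_mat + diag(ridge, k)
  ridge_used <- ridge
  omega <- tryCatch(chol2inv(chol(r_mat)), error = function(e) NULL)
  near_singular <- is.null(omega) || rcond(r_mat) < 1e-10
  if (near_singular) {
    if (!auto_ridge)
      stop("singular correlation matrix; supply a ridge or allow auto_ridge")
    ridge_used <- max(ridge, 1e-4)
    omega <- chol2inv(chol(stats::cor(x) + diag(ridge_used, k)))
    message("partial_correlation: near-singular correlation matrix, ",
            "ridge raised to ", ridge_used)
  }
  d <- sqrt(diag(omega))
  p <- -omega / outer(d, d)
  p <- (p + t(p)) / 2
  diag(p) <- 1
  structure(list(partial_r = p, n_samples = n, n_channels = k,
                 ridge_used = ridge_used, participant = participant,
                 period = period),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d channels, n = %d%s%s\n",
              x$n_channels, x$n_samples,
              if (!is.na(x$participant)) paste0(", ", x$participant) else "",
              if (!is.na(x$period)) paste0("/", x$period) else ""))
  invisible(x)
}

#' Threshold a partial-correlation matrix into a binary network
#'
#' Negative partial correlations are discarded (only positive association
#' counts as a connection) and an edge is kept where the partial
#' correlation is at or above the criterion. The default criterion 0.28 is
#' the fixed value used in the study; [critical_r()] offers a
#' sample-size-based alternative. Values exactly equal to the criterion
#' produce an edge.
#'
#' @param cm a `connectivity_matrix` (or bare symmetric matrix).
#' @param criterion threshold in (0, 1); default 0.28.
#' @return An `adjacency_matrix`: list with `a` (binary symmetric, zero
#'   diagonal), `threshold_used`, and the labels of `cm`.
#' @export
threshold_network <- function(cm, criterion = 0.28) {
  if (!(criterion > 0 && criterion < 1))
    stop("criterion must lie in (0, 1)")
  p <- if (inherits(cm, "connectivity_matrix")) cm$partial_r else cm
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  a <- (p >= criterion) * 1L
  diag(a) <- 0L
  structure(list(a = a, threshold_used = criterion,
                 participant = if (inherits(cm, "connectivity_matrix"))
                   cm$participant else NA_character_,
                 period = if (inherits(cm, "connectivity_matrix"))
                   cm$period else NA_character_),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("adjacency_matrix: %d nodes, %d edges (threshold %.3g)\n",
              nrow(x$a), sum(x$a) / 2, x$threshold_used))
  invisible(x)
}

#' Critical value of the correlation coefficient
#'
#' Closed form from the t distribution: `r* = t* / sqrt(t*^2 + df)` with
#' `df = n - 2 - n_controlled` and `t*` the critical t value at the
#' requested alpha and tails. With `n_controlled = 0` this is the usual
#' Pearson critical value; with 13 controlled channels it is the
#' partial-correlation analogue. Offered as an alternative to the fixed
#' 0.28 criterion.
#'
#' @param n number of observations.
#' @param alpha significance level (default 0.05).
#' @param tails 1 or 2.
#' @param n_controlled number of variables partialled out (default 0).
#' @return The critical correlation value.
#' @examples
#' critical_r(40)                     # ~0.264
#' critical_r(40, n_controlled = 13)  # ~0.323
#' @export
critical_r <- function(n, alpha = 0.05, tails = 1, n_controlled = 0) {
  stopifnot(tails %in% c(1, 2), alpha > 0, alpha < 1)
  df <- n - 2 - n_controlled
  if (df < 1) stop("infeasible degrees of freedom: ", df)
  t_star <- stats::qt(1 - alpha / tails, df)
  if (!is.finite(t_star)) return(1)
  t_star / sqrt(t_star^2 + df)
}

#' Per-period connectivity networks for one participant
#'
#' Slices the CBSI-corrected HbO series by task period, estimates a
#' partial-correlation matrix per period, and thresholds each into a
#' binary network.
#'
#' @param hemo a [hemo_series()] after [apply_cbsi()].
#' @param seg a [segment_periods()] result.
#' @param criterion threshold passed to [threshold_network()].
#' @param participant id stamped on the results.
#' @param use_cbsi use `cbsi_hbo` (default) or raw `hbo`.
#' @return Named list (by period) of `adjacency_matrix` objects; each
#'   carries its `connectivity_matrix` in attribute `connectivity`.
#' @export
period_networks <- function(hemo, seg, criterion = 0.28,
                            participant = "p01", use_cbsi = TRUE) {
  stopifnot(inherits(hemo, "hemo_series"),
            inherits(seg, "period_segmentation"))
  series <- if (use_cbsi) {
    if (is.null(hemo$cbsi_hbo)) stop("run apply_cbsi() first")
    hemo$cbsi_hbo
  } else hemo$hbo
  out <- list()
  for (r in seq_len(nrow(seg$periods))) {
    p <- seg$periods[r, ]
    cm <- partial_correlation(series[p$start:(p$end - 1), , drop = FALSE],
                              participant = participant, period = p$period)
    adj <- threshold_network(cm, criterion)
    attr(adj, "connectivity") <- cm
    out[[p$period]] <- adj
  }
  out
}

#' Write a connectivity or adjacency matrix as CSV / edge list
#'
#' @param x a `connectivity_matrix` or `adjacency_matrix`.
#' @param path output CSV path (15 x 15 with channel-id header).
#' @param edge_list_path optional TSV path for the edge list of an
#'   adjacency matrix (columns `from`, `to`).
#' @return Invisibly, `path`.
#' @export
write_network <- function(x, path, edge_list_path = NULL) {
  m <- if (inherits(x, "connectivity_matrix")) x$partial_r else x$a
  colnames(m) <- sprintf("ch%02d", seq_len(ncol(m)))
  data.table::fwrite(data.table::as.data.table(m), path)
  if (!is.null(edge_list_path) && inherits(x, "adjacency_matrix")) {
    idx <- which(upper.tri(x$a) & x$a == 1, arr.ind = TRUE)
    data.table::fwrite(data.frame(from = idx[, 1], to = idx[, 2]),
                       edge_list_path, sep = "\t")
  }
  invisible(path)
}
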