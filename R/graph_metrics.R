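#' Connection density of a binary network
#'
#' The fraction of existing connections among all possible ones:
#' `D = sum_ij a_ij / (n (n - 1))` over ordered pairs, identical to
#' (number of edges) / C(n, 2).
#'
#' @param a an `adjacency_matrix` or bare binary symmetric matrix with zero
#'   diagonal.
#' @return Density in `[0, 1]`.
#' @examples
#' network_density(matrix(c(0, 1, 1, 0), 2))  # single edge on 2 nodes: 1
#' @export
network_density <- function(a) {
  m <- as_adjacency(a)
  n <- nrow(m)
  if (n < 2) stop("density needs at least 2 nodes")
  sum(m) / (n * (n - 1))
}

#' Local clustering coefficients of a binary network
#'
#' For node i with degree `k_i`, the proportion of its neighbor pairs that
#' are themselves connected:
#' `C_i = sum_jh a_ij a_ih a_jh / (k_i (k_i - 1))`, where the numerator is
#' the i-th diagonal entry of `A^3` (twice the triangle count at i). Nodes
#' with fewer than two neighbors have an undefined ratio and contribute 0,
#' matching the convention of the standard brain-connectivity tooling.
#'
#' @inheritParams network_density
#' @return Numeric vector of per-node coefficients.
#' @export
local_clustering <- function(a) {
  m <- as_adjacency(a)
  k <- rowSums(m)
  paths2 <- diag(m %*% m %*% m)
  out <- numeric(nrow(m))
  ok <- k >= 2
  out[ok] <- paths2[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Mean local clustering coefficient
#'
#' `C = mean(local_clustering(a))` over all nodes (k < 2 nodes count 0).
#'
#' @inheritParams network_density
#' @return Clustering coefficient in `[0, 1]`.
#' @export
clustering_coef <- function(a) {
  m <- as_adjacency(a)
  if (nrow(m) < 1) stop("clustering needs at least 1 node")
  mean(local_clustering(m))
}

as_adjacency <- function(a) {
  m <- if (inherits(a, "adjacency_matrix")) a$a else a
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(m != 0 & m != 1)) stop("adjacency must be binary")
  if (any(diag(m) != 0)) stop("adjacency diagonal must be zero")
  if (any(m != t(m))) stop("adjacency must be symmetric")
  m
}

#' Tidy metrics table over a cohort of networks
#'
#' One row per participant x period with connection density, mean local
#' clustering, and the degree sequence.
#'
#' @param networks list of `adjacency_matrix` objects carrying
#'   `participant` and `period` labels (e.g. flattened output of
#'   [period_networks()] over participants).
#' @param require_complete require all six periods for every participant.
#' @return data.frame with columns `participant_id`, `period`, `density`,
#'   `clustering`, and list column `degrees`.
#' @export
metrics_table <- function(networks, require_complete = TRUE) {
  stopifnot(length(networks) > 0)
  rows <- lapply(networks, function(adj) {
    stopifnot(inherits(adj, "adjacency_matrix"))
    data.frame(participant_id = adj$participant, period = adj$period,
               density = network_density(adj),
               clustering = clustering_coef(adj),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out[, c("participant_id", "period")]))
    stop("duplicate (participant, period) entries")
  if (require_complete) {
    counts <- table(out$participant_id)
    bad <- names(counts)[counts != length(period_names())]
    if (length(bad) > 0)
      stop("incomplete period set for participant(s): ",
           paste(bad, collapse = ", "))
  }
  out$degrees <- I(lapply(networks, function(adj) rowSums(adj$a)))
  out$period <- factor(out$period, levels = period_names())
  out[order(out$participant_id, out$period), ]
}

#' Per-period summary of network metrics
#'
#' Mean and standard error of density and clustering per task period
#' (the quantities behind per-period metric plots).
#'
#' @param metrics output of [metrics_table()].
#' @return data.frame with `period`, `n`, `mean_density`, `se_density`,
#'   `mean_clustering`, `se_clustering`.
#' @export
metrics_summary <- function(metrics) {
  out <- do.call(rbind, lapply(split(metrics, metrics$period), function(g) {
    data.frame(period = g$period[1], n = nrow(g),
               mean_density = mean(g$density),
               se_density = stats::sd(g$density) / sqrt(nrow(g)),
               mean_clustering = mean(g$clustering),
               se_clustering = stats::sd(g$clustering) / sqrt(nrow(g)))
  }))
  rownames(out) <- NULL
  out
}
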