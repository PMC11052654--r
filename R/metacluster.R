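#' Consensus metaclustering parameters
#'
#' Metaclustering merges the SOM nodes into `k` groups (typically cell
#' types) by consensus hierarchical clustering: the node codes are repeatedly
#' subsampled and cut into `k` agglomerative clusters, co-clustering
#' frequencies are accumulated into a consensus matrix, and the final
#' partition is an agglomerative cut of the consensus dissimilarity.
#' Subsampling is over nodes (the at-most-few-hundred cluster centers),
#' never over events.
#'
#' @param k number of metaclusters (>= 2).
#' @param n_resamples number of subsampling rounds H (default 100).
#' @param resample_fraction fraction p of nodes drawn per round, in (0, 1]
#'   (default 0.9).
#' @param linkage agglomeration rule: `"average"` (default), `"complete"`,
#'   or `"ward"` (Ward's criterion on Euclidean distances, ward.D2).
#' @param seed RNG seed for the subsampling.
#' @return a `consensus_params` object.
#' @export
consensus_params <- function(k, n_resamples = 100, resample_fraction = 0.9,
                             linkage = c("average", "complete", "ward"),
                             seed = NULL) {
  linkage <- match.arg(linkage)
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2")
  if (!(resample_fraction > 0 && resample_fraction <= 1))
    stop("resample_fraction must be in (0, 1]")
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  structure(list(k = k, n_resamples = as.integer(n_resamples),
                 resample_fraction = resample_fraction, linkage = linkage,
                 seed = seed),
            class = "consensus_params")
}

hclust_method <- function(linkage) {
  switch(linkage, average = "average", complete = "complete",
         ward = "ward.D2")
}

#' Consensus (co-clustering) matrix of the node codes
#'
#' For each of H rounds, `ceiling(p * n)` nodes are sampled without
#' replacement, hierarchically clustered (Euclidean distance, the chosen
#' linkage) and cut into k groups. `M[i, j]` is the fraction of rounds in
#' which i and j were co-clustered among those in which both were sampled
#' (0 if never co-sampled); the diagonal is fixed at 1.
#'
#' @param codes numeric matrix of node codes (`n_nodes` x d), finite.
#' @param params a [consensus_params()].
#' @return symmetric `n_nodes` x `n_nodes` matrix with entries in [0, 1].
#' @export
consensus_matrix <- function(codes, params) {
  codes <- as.matrix(codes)
  if (!all(is.finite(codes))) stop("codes must be finite")
  n <- nrow(codes)
  if (params$k > n) stop("k (", params$k, ") exceeds the number of nodes (", n, ")")
  ssize <- ceiling(params$resample_fraction * n)
  if (params$k > ssize)
    stop("k (", params$k, ") exceeds the subsample size (", ssize, ")")
  if (!is.null(params$seed)) set.seed(params$seed)
  indic <- matrix(0, n, n)
  coclust <- matrix(0, n, n)
  method <- hclust_method(params$linkage)
  for (h in seq_len(params$n_resamples)) {
    idx <- sort(sample.int(n, ssize))
    hc <- stats::hclust(stats::dist(codes[idx, , drop = FALSE]),
                        method = method)
    cl <- stats::cutree(hc, k = params$k)
    indic[idx, idx] <- indic[idx, idx] + 1
    coclust[idx, idx] <- coclust[idx, idx] + outer(cl, cl, `==`)
  }
  M <- ifelse(indic > 0, coclust / pmax(indic, 1), 0)
  diag(M) <- 1
  M
}

relabel_first_appearance <- function(labels) {
  match(labels, unique(labels))
}

#' Metacluster the SOM codes by consensus hierarchical clustering
#'
#' Builds the consensus matrix (see [consensus_matrix()]) and cuts an
#' agglomerative clustering of the consensus dissimilarity `1 - M` (same
#' linkage) into k metaclusters. Labels are relabeled to consecutive
#' integers `1..k` ordered by first appearance over the node index, so
#' seeded runs are comparable across platforms.
#'
#' @inheritParams consensus_matrix
#' @return a `metacluster_result`: `labels` (integer in `1..k` per node),
#'   `consensus` (the matrix M), `params`.
#' @export
metacluster <- function(codes, params) {
  M <- consensus_matrix(codes, params)
  hc <- stats::hclust(stats::as.dist(1 - M),
                      method = hclust_method(params$linkage))
  labels <- relabel_first_appearance(stats::cutree(hc, k = params$k))
  structure(list(labels = as.integer(labels), consensus = M, params = params),
            class = "metacluster_result")
}

#' Propagate node metacluster labels to events
#'
#' @param cells a [cell_frame()] with `cluster_id` assigned.
#' @param labels integer metacluster label per node (length `n_nodes`).
#' @return the frame with `metacluster_id[e] = labels[cluster_id[e]]`.
#' @export
apply_metaclusters <- function(cells, labels) {
  if (is.null(cells$cluster_id))
    stop("cells have no cluster assignment; run assign_bmu first")
  if (any(cells$cluster_id > length(labels)))
    stop("cluster_id references nodes beyond the label vector")
  cells$metacluster_id <- as.integer(labels[cells$cluster_id])
  cells
}

#' Export a consensus matrix as CSV
#'
#' @param meta a `metacluster_result`.
#' @param path output path.
#' @export
export_consensus_matrix <- function(meta, path) {
  utils::write.csv(meta$consensus, path, row.names = FALSE)
  invisible(path)
}
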