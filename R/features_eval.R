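#' Per-node summary statistics
#'
#' Counts, percentages and per-channel marker medians for each SOM node.
#' Medians are computed on the (possibly transformed) scale stored in the
#' frame — the space the SOM was trained in — across all channels, not just
#' the clustering channels. Empty nodes get `NA` medians, never 0.
#'
#' @param cells a [cell_frame()] with `cluster_id` assigned.
#' @param n_nodes total number of SOM nodes.
#' @return list with `counts` (integer per node), `percentages` (sum 100),
#'   and `medians` (`n_nodes` x `n_channels`, `NA` for empty nodes).
#' @export
cluster_stats <- function(cells, n_nodes) {
  if (is.null(cells$cluster_id)) stop("cells have no cluster assignment")
  counts <- tabulate(cells$cluster_id, nbins = n_nodes)
  percentages <- 100 * counts / sum(counts)
  medians <- matrix(NA_real_, n_nodes, ncol(cells$X),
                    dimnames = list(NULL, cells$channel_names))
  groups <- split(seq_len(nrow(cells$X)),
                  factor(cells$cluster_id, levels = seq_len(n_nodes)))
  for (j in seq_len(n_nodes)) {
    idx <- groups[[j]]
    if (length(idx))
      medians[j, ] <- apply(cells$X[idx, , drop = FALSE], 2, stats::median)
  }
  list(counts = as.integer(counts), percentages = percentages,
       medians = medians)
}

#' Map a new sample onto a trained model
#'
#' Resolves the model's clustering channels in the new frame by channel name
#' (falling back to marker name), replays the recorded preprocessing
#' transforms, assigns every event to its best matching unit, and propagates
#' metacluster labels. The model itself is not modified.
#'
#' @param result a `flowsom_result`.
#' @param frame a new [cell_frame()] containing the model's clustering
#'   channels.
#' @return the frame with `cluster_id`, `metacluster_id` and
#'   `distance_to_bmu` filled in.
#' @export
map_new_data <- function(result, frame) {
  validate_cell_frame(frame)
  used <- colnames(result$clusters$codes)
  idx <- tryCatch(resolve_channels(frame, used),
                  error = function(e)
                    stop("new data lacks model channel(s): ",
                         paste(setdiff(used, c(frame$channel_names,
                                               frame$marker_names)),
                               collapse = ", ")))
  frame$cols_used <- idx
  for (tr in result$params$transforms)
    frame <- apply_transform(frame, transform_spec(tr$kind, tr$cofactor))
  codebook <- list(codes = result$clusters$codes,
                   params = result$params$som)
  class(codebook) <- "codebook"
  asg <- assign_bmu(codebook, frame$X[, idx, drop = FALSE])
  frame$cluster_id <- asg$cluster_id
  frame$distance_to_bmu <- asg$distance
  apply_metaclusters(frame, result$clusters$metacluster)
}

contingency <- function(truth, predicted, unassigned_token) {
  if (length(truth) != length(predicted))
    stop("truth and predicted label vectors differ in length")
  keep <- !(truth %in% unassigned_token) & !is.na(truth)
  if (!any(keep))
    stop("no events remain after dropping unassigned truth labels")
  table(truth = as.character(truth[keep]),
        predicted = as.character(predicted[keep]))
}

#' Mean matched F1 score
#'
#' The cluster-evaluation convention used with manually gated benchmark
#' data: events whose reference label equals the unassigned token are
#' dropped; for every (true population, predicted group) pair, precision,
#' recall and F1 are computed from the contingency table; populations are
#' matched one-to-one to predicted groups by the assignment maximizing total
#' F1 (optimal bipartite matching, not greedy, so no group is reused); the
#' score is the unweighted mean F1 over true populations, with unmatched
#' populations contributing 0.
#'
#' @param truth reference label per event (character/factor).
#' @param predicted predicted group per event (cluster or metacluster ids).
#' @param unassigned_token truth value(s) marking events excluded from
#'   scoring (default `"unassigned"`; `NA` is always excluded).
#' @return list with `mean` (the mean matched F1) and `per_population`
#'   (data.frame: population, matched_group, precision, recall, f1).
#' @export
mean_f1 <- function(truth, predicted, unassigned_token = "unassigned") {
  tab <- contingency(truth, predicted, unassigned_token)
  f1 <- f1_matrix(tab)
  match_idx <- match_populations(f1)

  per <- data.frame(population = rownames(tab),
                    matched_group = NA_character_,
                    precision = 0, recall = 0, f1 = 0,
                    stringsAsFactors = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  for (i in seq_len(nrow(tab))) {
    j <- match_idx[i]
    if (!is.na(j)) {
      per$matched_group[i] <- colnames(tab)[j]
      per$precision[i] <- tab[i, j] / cs[j]
      per$recall[i] <- tab[i, j] / rs[i]
      per$f1[i] <- f1[i, j]
    }
  }
  list(mean = mean(per$f1), per_population = per)
}

f1_matrix <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  prec <- sweep(tab, 2, pmax(cs, 1), "/")
  rec <- sweep(tab, 1, pmax(rs, 1), "/")
  denom <- prec + rec
  f1 <- ifelse(denom > 0, 2 * prec * rec / denom, 0)
  matrix(f1, nrow(tab), ncol(tab), dimnames = dimnames(tab))
}

# optimal one-to-one assignment of rows (populations) to columns (groups)
# maximizing total F1, via maximum-weight bipartite matching
match_populations <- function(f1) {
  nr <- nrow(f1); nc <- ncol(f1)
  pairs <- which(f1 > 0, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(rep(NA_integer_, nr))
  g <- igraph::make_empty_graph(n = nr + nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(pairs[, 1], nr + pairs[, 2]))
  igraph::V(g)$type <- c(rep(FALSE, nr), rep(TRUE, nc))
  mt <- igraph::max_bipartite_match(g, weights = f1[pairs])
  idx <- mt$matching[seq_len(nr)]
  ifelse(is.na(idx), NA_integer_, as.integer(idx) - nr)
}

#' Cluster purity
#'
#' The weighted fraction of scored events that carry the dominant reference
#' label of their predicted group: `(1/n) * sum over groups of the largest
#' single-label count within the group`. 1 means every group is
#' label-homogeneous.
#'
#' @inheritParams mean_f1
#' @return a number in [0, 1].
#' @export
purity <- function(truth, predicted, unassigned_token = "unassigned") {
  tab <- contingency(truth, predicted, unassigned_token)
  sum(apply(tab, 2, max)) / sum(tab)
}

#' Evaluate a result against reference labels
#'
#' Convenience wrapper computing mean matched F1 and purity at either the
#' cluster (SOM node) or metacluster level.
#'
#' @param result a `flowsom_result`.
#' @param truth reference label per event.
#' @param level `"meta"` (default) or `"cluster"`.
#' @inheritParams mean_f1
#' @return list with `mean_f1`, `purity`, `per_population`, `level`.
#' @export
evaluate_result <- function(result, truth,
                            level = c("meta", "cluster"),
                            unassigned_token = "unassigned") {
  level <- match.arg(level)
  predicted <- if (level == "meta") result$cells$metacluster_id
               else result$cells$cluster_id
  f1 <- mean_f1(truth, predicted, unassigned_token)
  list(mean_f1 = f1$mean,
       purity = purity(truth, predicted, unassigned_token),
       per_population = f1$per_population,
       level = level)
}

#' Export the per-population F1 table as CSV
#'
#' @param eval result of [evaluate_result()] or [mean_f1()].
#' @param path output path.
#' @export
export_f1_table <- function(eval, path) {
  utils::write.csv(eval$per_population, path, row.names = FALSE)
  invisible(path)
}
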