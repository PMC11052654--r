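#' Assemble the two-modality result
#'
#' Bundles the cell-level and cluster-level views of a run into a
#' `flowsom_result`. The cluster modality is populated here: per-node
#' counts, percentages and marker medians, the node metacluster labels
#' (relabeled to consecutive integers `1..k` by first appearance over the
#' node index), the MST edge list and the 2D layout. Event metacluster
#' labels are recomputed from the relabeled node labels so that
#' `clusters$metacluster[cells$cluster_id] == cells$metacluster_id` holds
#' for every event.
#'
#' @param cells a [cell_frame()] with `cluster_id` assigned from `codebook`.
#' @param codebook the trained `codebook`.
#' @param meta a `metacluster_result` with one label per node.
#' @param mst an `mst_layout` with a computed layout (see
#'   [layout_kamada_kawai()]); `NULL` falls back to the grid layout.
#' @return a `flowsom_result`: list with `cells`, `clusters`, `params`,
#'   `version`.
#' @export
build_result <- function(cells, codebook, meta, mst = NULL) {
  validate_cell_frame(cells)
  m <- nrow(codebook$codes)
  if (length(meta$labels) != m)
    stop("metacluster labels have length ", length(meta$labels),
         " but the codebook has ", m, " nodes")
  if (is.null(cells$cluster_id))
    stop("cells have no cluster assignment")

  labels <- relabel_first_appearance(meta$labels)
  cells <- apply_metaclusters(cells, labels)
  stats <- cluster_stats(cells, m)

  if (is.null(mst)) {
    edges <- NULL
    layout_xy <- layout_grid(codebook$params)
    layout_kind <- "grid"
  } else {
    edges <- mst$edges
    layout_xy <- if (is.null(mst$layout_xy))
      layout_grid(codebook$params) else mst$layout_xy
    layout_kind <- if (is.null(mst$layout_xy)) "grid" else mst$layout_kind
  }

  clusters <- structure(
    list(codes = codebook$codes,
         grid_xy = codebook$grid_xy,
         counts = stats$counts,
         percentages = stats$percentages,
         medians = stats$medians,
         metacluster = as.integer(labels),
         mst_edges = edges,
         layout_xy = layout_xy,
         layout_kind = layout_kind,
         channel_names = cells$channel_names,
         marker_names = cells$marker_names),
    class = "cluster_frame")

  result <- structure(
    list(cells = cells,
         clusters = clusters,
         params = list(som = codebook$params,
                       consensus = meta$params,
                       transforms = cells$transform_log,
                       seed = codebook$params$seed),
         version = "cytosom-1"),
    class = "flowsom_result")
  validate_result(result)
  result
}

#' Validate the invariants of a result
#'
#' Checks the cross-modality contracts: label lengths, count conservation,
#' percentages summing to 100, a connected acyclic MST edge set with
#' `n_nodes - 1` edges, metacluster labels covering `1..k`, and
#' `clusters$metacluster[cells$cluster_id] == cells$metacluster_id` for
#' every event.
#'
#' @param result a `flowsom_result`.
#' @return the result, invisibly; stops on violation.
#' @export
validate_result <- function(result) {
  cells <- result$cells; cl <- result$clusters
  m <- nrow(cl$codes)
  validate_cell_frame(cells)
  if (length(cl$metacluster) != m)
    stop("invariant violated: metacluster labels do not match node count")
  if (any(cells$cluster_id < 1L) || any(cells$cluster_id > m))
    stop("invariant violated: cluster_id outside 1..n_nodes")
  if (sum(cl$counts) != nrow(cells$X))
    stop("invariant violated: counts do not sum to the number of events")
  if (abs(sum(cl$percentages) - 100) > 1e-9)
    stop("invariant violated: percentages do not sum to 100")
  k <- max(cl$metacluster)
  if (!setequal(unique(cl$metacluster), seq_len(k)))
    stop("invariant violated: metacluster labels must cover 1..k")
  if (!identical(as.integer(cl$metacluster[cells$cluster_id]),
                 as.integer(cells$metacluster_id)))
    stop("invariant violated: event metacluster labels disagree with ",
         "node metacluster labels")
  if (!is.null(cl$mst_edges)) {
    if (nrow(cl$mst_edges) != m - 1)
      stop("invariant violated: MST must have n_nodes - 1 edges")
    g <- edges_to_graph(cl$mst_edges, m)
    if (igraph::components(g)$no != 1)
      stop("invariant violated: MST edge set is not connected")
    if (any(cl$mst_edges$weight < 0))
      stop("invariant violated: negative MST edge weight")
  }
  invisible(result)
}

#' @export
print.flowsom_result <- function(x, ...) {
  cat(sprintf(
    "flowsom_result: %d events, %dx%d SOM (%d nodes), %d metaclusters\n",
    nrow(x$cells$X), x$params$som$xdim, x$params$som$ydim,
    nrow(x$clusters$codes), max(x$clusters$metacluster)))
  invisible(x)
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

params_to_json <- function(params) {
  as.character(jsonlite::toJSON(strip_classes(params), auto_unbox = TRUE,
                                null = "null", digits = NA))
}

#' Save a result as a two-modality HDF5 file
#'
#' Writes a single HDF5 file with one group per modality — `cell` (the
#' events x channels matrix, per-event labels and distances, channel and
#' marker names) and `cluster` (codes, grid coordinates, counts,
#' percentages, medians, node metacluster labels, MST edges, layout) —
#' mirroring the multi-modality single-cell container convention of one
#' group per modality with observation annotations as named arrays. The
#' full parameter record is serialized as a JSON attribute. The file opens
#' with any generic HDF5 reader.
#'
#' @param result a `flowsom_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_result <- function(result, path) {
  validate_result(result)
  cells <- result$cells; cl <- result$clusters
  medians <- cl$medians
  medians[is.na(medians)] <- NA_real_  # NaN in HDF5; restored as NA on load

  obj <- list(
    cell = list(
      X = unname(cells$X),
      channel_names = cells$channel_names,
      marker_names = cells$marker_names,
      cols_used = as.integer(cells$cols_used),
      cluster_id = as.integer(cells$cluster_id),
      metacluster_id = as.integer(cells$metacluster_id),
      distance_to_bmu = if (is.null(cells$distance_to_bmu)) NULL
                        else as.numeric(cells$distance_to_bmu)
    ),
    cluster = list(
      codes = unname(cl$codes),
      grid_xy = matrix(as.integer(cl$grid_xy), nrow(cl$grid_xy)),
      counts = as.integer(cl$counts),
      percentages = as.numeric(cl$percentages),
      medians = unname(medians),
      metacluster = as.integer(cl$metacluster),
      layout_xy = unname(cl$layout_xy),
      "_attrs" = list(layout_kind = cl$layout_kind)
    ),
    "_attrs" = list(version = result$version,
                    params_json = params_to_json(result$params),
                    n_events = nrow(cells$X))
  )
  if (!is.null(cl$mst_edges)) {
    obj$cluster$mst_from <- as.integer(cl$mst_edges$from)
    obj$cluster$mst_to <- as.integer(cl$mst_edges$to)
    obj$cluster$mst_weight <- as.numeric(cl$mst_edges$weight)
  }
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop("cannot write to '", path, "': directory missing or not writable")
  .cpp_h5_write(path, obj)
  invisible(path)
}

#' Load a result saved by [save_result()]
#'
#' Reconstructs the `flowsom_result` and re-validates every invariant; a
#' file with missing groups or arrays, or with inconsistent labels, raises
#' a format error naming the missing or offending element.
#'
#' @param path path to an HDF5 file written by [save_result()].
#' @return a `flowsom_result`.
#' @export
load_result <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- .cpp_h5_read(path)
  for (grp in c("cell", "cluster"))
    if (is.null(obj[[grp]]))
      stop("format error: missing group '", grp, "'")
  ce <- obj$cell; cg <- obj$cluster
  for (nm in c("X", "channel_names", "marker_names", "cols_used",
               "cluster_id", "metacluster_id"))
    if (is.null(ce[[nm]])) stop("format error: missing array 'cell/", nm, "'")
  for (nm in c("codes", "grid_xy", "counts", "percentages", "medians",
               "metacluster", "layout_xy"))
    if (is.null(cg[[nm]]))
      stop("format error: missing array 'cluster/", nm, "'")

  params <- tryCatch(
    jsonlite::fromJSON(obj[["_attrs"]]$params_json, simplifyVector = TRUE),
    error = function(e) stop("format error: unreadable params_json"))

  cells <- cell_frame(ce$X, channel_names = ce$channel_names,
                      marker_names = ce$marker_names,
                      cols_used = as.integer(ce$cols_used))
  cells$cluster_id <- as.integer(ce$cluster_id)
  cells$metacluster_id <- as.integer(ce$metacluster_id)
  if (!is.null(ce$distance_to_bmu))
    cells$distance_to_bmu <- as.numeric(ce$distance_to_bmu)
  cells$transform_log <- if (is.null(params$transforms)) list() else
    lapply(seq_len(NROW(params$transforms)), function(i)
      as.list(params$transforms[i, , drop = FALSE]))
  validate_cell_frame(cells)

  codes <- cg$codes
  colnames(codes) <- cells$channel_names[cells$cols_used]
  medians <- cg$medians
  medians[is.nan(medians)] <- NA_real_
  colnames(medians) <- cells$channel_names

  edges <- NULL
  if (!is.null(cg$mst_from))
    edges <- data.frame(from = as.integer(cg$mst_from),
                        to = as.integer(cg$mst_to),
                        weight = as.numeric(cg$mst_weight))

  som <- params$som
  somp <- som_params(xdim = som$xdim, ydim = som$ydim, rlen = som$rlen,
                     alpha_start = som$alpha_start, alpha_end = som$alpha_end,
                     radius_start = som$radius_start,
                     radius_end = som$radius_end,
                     distance = som$distance,
                     seed = if (is.null(som$seed)) NULL else som$seed)
  cons <- params$consensus
  consp <- if (is.null(cons)) NULL else
    consensus_params(k = cons$k, n_resamples = cons$n_resamples,
                     resample_fraction = cons$resample_fraction,
                     linkage = cons$linkage,
                     seed = if (is.null(cons$seed)) NULL else cons$seed)

  clusters <- structure(
    list(codes = codes,
         grid_xy = matrix(as.integer(cg$grid_xy), nrow(cg$grid_xy),
                          dimnames = list(NULL, c("x", "y"))),
         counts = as.integer(cg$counts),
         percentages = as.numeric(cg$percentages),
         medians = medians,
         metacluster = as.integer(cg$metacluster),
         mst_edges = edges,
         layout_xy = cg$layout_xy,
         layout_kind = cg[["_attrs"]]$layout_kind,
         channel_names = cells$channel_names,
         marker_names = cells$marker_names),
    class = "cluster_frame")

  result <- structure(
    list(cells = cells, clusters = clusters,
         params = list(som = somp, consensus = consp,
                       transforms = cells$transform_log,
                       seed = somp$seed),
         version = obj[["_attrs"]]$version),
    class = "flowsom_result")
  validate_result(result)
  result
}

#' Export per-node statistics as CSV
#'
#' One row per node: node index, grid coordinates, count, percentage,
#' metacluster, and one column per marker median.
#'
#' @param result a `flowsom_result`.
#' @param path output path.
#' @export
export_cluster_stats <- function(result, path) {
  cl <- result$clusters
  med <- cl$medians
  colnames(med) <- paste0("median_", cl$marker_names)
  df <- data.frame(node = seq_len(nrow(cl$codes)),
                   x = cl$grid_xy[, 1], y = cl$grid_xy[, 2],
                   count = cl$counts, percentage = cl$percentages,
                   metacluster = cl$metacluster)
  utils::write.csv(cbind(df, med), path, row.names = FALSE)
  invisible(path)
}
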