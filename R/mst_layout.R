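#' Minimum spanning tree over SOM node codes
#'
#' Builds the MST of the complete graph on nodes with Euclidean distances in
#' code space as edge weights — the backbone on which the clustered model is
#' drawn. Edge weights use Euclidean distance regardless of the SOM training
#' metric, since the tree is a visualization of code geometry. Edges are
#' returned ordered by (smaller index, larger index) for stable output under
#' weight ties.
#'
#' @param codebook a trained `codebook` with at least 2 nodes.
#' @return an `mst_layout` object: `edges` (data.frame `from`, `to`,
#'   `weight`; `n_nodes - 1` rows), `layout_xy` (NULL until a layout is
#'   computed), `layout_kind`, `n_nodes`.
#' @export
build_mst <- function(codebook) {
  codes <- codebook$codes
  m <- nrow(codes)
  if (m < 2) stop("need at least 2 nodes to build a spanning tree")
  D <- as.matrix(stats::dist(codes))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  t_ig <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(t_ig, names = FALSE)
  from <- pmin(el[, 1], el[, 2])
  to <- pmax(el[, 1], el[, 2])
  ord <- order(from, to)
  edges <- data.frame(from = as.integer(from[ord]), to = as.integer(to[ord]),
                      weight = D[cbind(from[ord], to[ord])])
  stopifnot(nrow(edges) == m - 1)
  structure(list(edges = edges, layout_xy = NULL, layout_kind = NULL,
                 n_nodes = m),
            class = "mst_layout")
}

edges_to_graph <- function(edges, n_nodes) {
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, t(as.matrix(edges[, c("from", "to")])))
  igraph::E(g)$weight <- edges$weight
  g
}

rescale_unit <- function(xy) {
  apply(xy, 2, function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  })
}

#' Kamada-Kawai layout of the MST
#'
#' Stress-minimizing 2D embedding in which geometric distances approximate
#' the tree's weighted path distances. Initialization is a deterministic
#' circular layout ordered by node index, so the layout is reproducible.
#' Positions are rescaled to the unit square.
#'
#' @param mst an `mst_layout` from [build_mst()] (edge set must be connected).
#' @return the `mst_layout` with `layout_xy` filled in and
#'   `layout_kind = "mst"`.
#' @export
layout_kamada_kawai <- function(mst) {
  m <- mst$n_nodes
  g <- edges_to_graph(mst$edges, m)
  if (igraph::components(g)$no != 1) stop("edge set is not connected")
  theta <- 2 * pi * (seq_len(m) - 1) / m
  init <- cbind(cos(theta), sin(theta))
  xy <- igraph::layout_with_kk(g, coords = init, dim = 2,
                               weights = igraph::E(g)$weight)
  mst$layout_xy <- rescale_unit(xy)
  mst$layout_kind <- "mst"
  mst
}

#' Regular-grid layout
#'
#' The classic SOM-grid view: node positions are the grid coordinates scaled
#' to the unit square (a single-row or single-column grid is centered at 0.5
#' on the degenerate axis).
#'
#' @param params a [som_params()].
#' @return matrix `n_nodes` x 2 of positions in the unit square.
#' @export
layout_grid <- function(params) {
  g <- grid_coords(params$xdim, params$ydim)
  sc <- function(v, k) if (k > 1) v / (k - 1) else rep(0.5, length(v))
  unname(cbind(sc(g[, 1], params$xdim), sc(g[, 2], params$ydim)))
}

#' Export MST edges as CSV
#'
#' One row per tree edge: `from`, `to` (1-based node indices), `weight`.
#'
#' @param mst an `mst_layout`.
#' @param path output path.
#' @export
export_mst_edges <- function(mst, path) {
  utils::write.csv(mst$edges, path, row.names = FALSE)
  invisible(path)
}
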