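#' Star-plot specification
#'
#' Geometry and scaling parameters for the star glyphs: which markers are
#' drawn as wedges (in order), how node size encodes cell percentage, and
#' the wedge orientation. Wedge 0 starts at 90 degrees (top) and wedges
#' proceed clockwise by default; orientation is fixed so figures reproduce.
#'
#' @param markers_shown ordered channel/marker subset drawn as wedges
#'   (default: the clustering channels).
#' @param node_scale maximum node radius in layout units (default 0.05 of
#'   the unit square).
#' @param size_mode `"area"` (default; radius proportional to sqrt of the
#'   percentage, so glyph area tracks cell count) or `"radius"`.
#' @param wedge_start_angle start angle of the first wedge, degrees
#'   (default 90, the top).
#' @param wedge_direction `"cw"` (default) or `"ccw"`.
#' @param edge_drawing draw the MST edges beneath the glyphs (default TRUE).
#' @return a `star_spec` object.
#' @export
star_spec <- function(markers_shown = NULL, node_scale = 0.05,
                      size_mode = c("area", "radius"),
                      wedge_start_angle = 90,
                      wedge_direction = c("cw", "ccw"),
                      edge_drawing = TRUE) {
  size_mode <- match.arg(size_mode)
  wedge_direction <- match.arg(wedge_direction)
  if (!is.null(markers_shown) && length(markers_shown) == 0)
    stop("markers_shown must be non-empty")
  if (node_scale <= 0) stop("node_scale must be positive")
  structure(list(markers_shown = markers_shown, node_scale = node_scale,
                 size_mode = size_mode,
                 wedge_start_angle = wedge_start_angle,
                 wedge_direction = wedge_direction,
                 edge_drawing = edge_drawing),
            class = "star_spec")
}

resolve_markers <- function(clusters, markers) {
  idx <- match(markers, clusters$channel_names)
  miss <- is.na(idx)
  idx[miss] <- match(markers[miss], clusters$marker_names)
  if (anyNA(idx))
    stop("unknown marker(s): ", paste(markers[is.na(idx)], collapse = ", "),
         "; available: ",
         paste(unique(c(clusters$channel_names, clusters$marker_names)),
               collapse = ", "))
  as.integer(idx)
}

#' Scaled star-wedge values
#'
#' Per-marker min-max scaling of the node medians across nodes, so each
#' wedge's radial extent is comparable within its marker:
#' `v = (median - min) / (max - min)`. A marker constant across nodes maps
#' to 0.5 everywhere; an empty node (missing median) maps to 0.
#'
#' @param clusters the `cluster_frame` of a result.
#' @param markers channel or marker names (default: clustering channels).
#' @return matrix `n_nodes` x `length(markers)` with values in [0, 1].
#' @export
star_values <- function(clusters, markers = NULL) {
  if (is.null(markers)) markers <- colnames(clusters$codes)
  idx <- resolve_markers(clusters, markers)
  med <- clusters$medians[, idx, drop = FALSE]
  out <- apply(med, 2, function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(rep(0, length(v)))
    r <- range(v[ok])
    s <- if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1]) / diff(r)
    s[!ok] <- 0
    s
  })
  out <- matrix(out, nrow = nrow(med), dimnames = list(NULL, markers))
  out
}

#' Node radii from cell percentages
#'
#' In the default area mode the radius is
#' `node_scale * sqrt(pct / max_pct)`, so glyph area is proportional to the
#' node's share of cells. Radii are strictly increasing in percentage;
#' empty nodes get a small fixed minimum radius (5% of `node_scale`) so
#' they remain visible.
#'
#' @param clusters the `cluster_frame` of a result.
#' @param spec a [star_spec()].
#' @return numeric radius per node.
#' @export
node_radii <- function(clusters, spec = star_spec()) {
  pct <- clusters$percentages
  mx <- max(pct)
  if (mx == 0) return(rep(0.05 * spec$node_scale, length(pct)))
  r <- if (spec$size_mode == "area") spec$node_scale * sqrt(pct / mx)
       else spec$node_scale * pct / mx
  r[pct == 0] <- 0.05 * spec$node_scale
  r
}

# fixed categorical palette, cycled deterministically by metacluster index
meta_palette <- function(k) {
  base <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
            "#FFFF33", "#A65628", "#F781BF", "#999999", "#66C2A5",
            "#FC8D62", "#8DA0CB")
  rep_len(base, k)
}

wedge_polygon <- function(cx, cy, r, a0, a1, n = 24) {
  ang <- seq(a0, a1, length.out = n)
  data.frame(px = c(cx, cx + r * cos(ang)), py = c(cy, cy + r * sin(ang)))
}

circle_polygon <- function(cx, cy, r, n = 64) {
  ang <- seq(0, 2 * pi, length.out = n + 1)
  data.frame(px = cx + r * cos(ang), py = cy + r * sin(ang))
}

#' Star-glyph geometry of a result
#'
#' The polygon data behind [plot_stars()]: one background disc per node
#' (colored by metacluster) and one wedge per (node, marker) whose radial
#' extent is the scaled median. Exposed so the glyph geometry can be
#' inspected and tested independently of the rendering backend.
#'
#' @param result a `flowsom_result`.
#' @param spec a [star_spec()].
#' @param layout `"mst"` (stored layout) or `"grid"`.
#' @return list with `wedges` and `discs` polygon data.frames, `values`,
#'   `radii`, `positions`, `markers`.
#' @export
star_glyph_data <- function(result, spec = star_spec(),
                            layout = c("mst", "grid")) {
  layout <- match.arg(layout)
  cl <- result$clusters
  markers <- spec$markers_shown
  if (is.null(markers)) markers <- colnames(cl$codes)
  vals <- star_values(cl, markers)
  radii <- node_radii(cl, spec)
  pos <- if (layout == "grid") layout_grid(result$params$som) else {
    if (is.null(cl$layout_xy)) stop("result has no stored layout")
    cl$layout_xy
  }
  m <- length(markers)
  a0 <- spec$wedge_start_angle * pi / 180
  dir <- if (spec$wedge_direction == "cw") -1 else 1
  wedges <- do.call(rbind, lapply(seq_len(nrow(pos)), function(j) {
    do.call(rbind, lapply(seq_len(m), function(w) {
      b0 <- a0 + dir * (w - 1) * 2 * pi / m
      b1 <- a0 + dir * w * 2 * pi / m
      poly <- wedge_polygon(pos[j, 1], pos[j, 2], radii[j] * vals[j, w],
                            b0, b1)
      poly$node <- j; poly$marker <- markers[w]
      poly$id <- paste0("n", j, "_w", w)
      poly
    }))
  }))
  discs <- do.call(rbind, lapply(seq_len(nrow(pos)), function(j) {
    poly <- circle_polygon(pos[j, 1], pos[j, 2], radii[j])
    poly$node <- j
    poly$metacluster <- factor(cl$metacluster[j],
                               levels = sort(unique(cl$metacluster)))
    poly
  }))
  list(wedges = wedges, discs = discs, values = vals, radii = radii,
       positions = pos, markers = markers)
}

save_figure <- function(plot, file, width = 8, height = 7) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         svg = grDevices::svg(file, width = width, height = height),
         pdf = grDevices::pdf(file, width = width, height = height),
         png = grDevices::png(file, width = width * 100, height = height * 100),
         stop("unsupported figure format '", ext, "' (use svg, pdf or png)"))
  print(plot)
  grDevices::dev.off()
  invisible(file)
}

theme_glyph <- function() {
  ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
}

#' Star plot of a clustered model
#'
#' One radial glyph per SOM node at its layout position: a background disc
#' colored by metacluster, and one wedge per marker (equal angular width
#' `2*pi/m`) whose radial extent encodes the min-max-scaled marker median
#' of the node. Node size encodes the node's share of cells; the MST edges
#' are drawn beneath the glyphs.
#'
#' @param result a `flowsom_result`.
#' @param file output figure path (`.svg`, `.pdf` or `.png`); `NULL`
#'   returns the ggplot object without writing a file.
#' @param spec a [star_spec()].
#' @param layout `"mst"` (default) or `"grid"`.
#' @return the ggplot object, invisibly (with the glyph data attached as
#'   attribute `"glyphs"`).
#' @export
plot_stars <- function(result, file = NULL, spec = star_spec(),
                       layout = c("mst", "grid")) {
  layout <- match.arg(layout)
  gd <- star_glyph_data(result, spec, layout)
  cl <- result$clusters
  k <- max(cl$metacluster)

  p <- ggplot2::ggplot()
  if (spec$edge_drawing && layout == "mst" && !is.null(cl$mst_edges)) {
    ed <- cl$mst_edges
    seg <- data.frame(x = gd$positions[ed$from, 1],
                      y = gd$positions[ed$from, 2],
                      xend = gd$positions[ed$to, 1],
                      yend = gd$positions[ed$to, 2])
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      color = "grey60", linewidth = 0.3)
  }
  p <- p +
    ggplot2::geom_polygon(
      data = gd$discs,
      ggplot2::aes(x = .data$px, y = .data$py, group = .data$node,
                   fill = .data$metacluster),
      alpha = 0.35, color = "grey40", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = meta_palette(k),
                               name = "metacluster") +
    ggplot2::geom_polygon(
      data = gd$wedges,
      ggplot2::aes(x = .data$px, y = .data$py, group = .data$id,
                   color = .data$marker),
      fill = NA, linewidth = 0.35) +
    ggplot2::scale_color_manual(
      values = stats::setNames(grDevices::hcl.colors(length(gd$markers),
                                                     "Dark 3"),
                               gd$markers),
      name = "marker") +
    ggplot2::coord_fixed() +
    theme_glyph()
  attr(p, "glyphs") <- gd
  if (!is.null(file)) save_figure(p, file)
  invisible(p)
}

#' Per-node label-composition pies
#'
#' Pie fractions per node over node membership: colored wedges with
#' fractions per external label summing to 1 per node, drawn at the stored
#' layout positions. Used to compare the clustering with reference labels.
#'
#' @param result a `flowsom_result`.
#' @param external_labels one label per event (length `n_events`).
#' @param file output figure path or `NULL`.
#' @param spec a [star_spec()] (node sizing and layout options).
#' @param layout `"mst"` or `"grid"`.
#' @return the ggplot object, invisibly, with attribute `"fractions"` (the
#'   per-node label-fraction matrix).
#' @export
plot_pies <- function(result, external_labels, file = NULL,
                      spec = star_spec(), layout = c("mst", "grid")) {
  layout <- match.arg(layout)
  cells <- result$cells
  if (length(external_labels) != nrow(cells$X))
    stop("external_labels has length ", length(external_labels),
         " but the result holds ", nrow(cells$X), " events")
  cl <- result$clusters
  m <- nrow(cl$codes)
  labs <- sort(unique(as.character(external_labels)))
  tab <- table(factor(cells$cluster_id, levels = seq_len(m)),
               factor(as.character(external_labels), levels = labs))
  frac <- sweep(tab, 1, pmax(rowSums(tab), 1), "/")
  frac <- matrix(frac, m, length(labs), dimnames = list(NULL, labs))

  pos <- if (layout == "grid") layout_grid(result$params$som) else cl$layout_xy
  radii <- node_radii(cl, spec)
  pies <- do.call(rbind, lapply(seq_len(m), function(j) {
    f <- frac[j, ]
    f <- f[f > 0]
    if (length(f) == 0) return(NULL)
    start <- pi / 2
    out <- NULL
    for (lb in names(f)) {
      end <- start - 2 * pi * f[[lb]]
      poly <- wedge_polygon(pos[j, 1], pos[j, 2], radii[j], start, end)
      poly$node <- j; poly$label <- lb
      poly$id <- paste0("n", j, "_", lb)
      out <- rbind(out, poly)
      start <- end
    }
    out
  }))

  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = pies,
      ggplot2::aes(x = .data$px, y = .data$py, group = .data$id,
                   fill = .data$label),
      color = "grey30", linewidth = 0.15) +
    ggplot2::scale_fill_manual(values = stats::setNames(
      meta_palette(length(labs)), labs), name = "label") +
    ggplot2::coord_fixed() +
    theme_glyph()
  attr(p, "fractions") <- frac
  if (!is.null(file)) save_figure(p, file)
  invisible(p)
}

#' Nodes colored by one marker's median
#'
#' Continuous-scale companion view: each node is drawn as a disc colored by
#' its median intensity of `marker`, with a colorbar.
#'
#' @param result a `flowsom_result`.
#' @param marker a channel or marker name.
#' @param file output figure path or `NULL`.
#' @param spec a [star_spec()].
#' @param layout `"mst"` or `"grid"`.
#' @return the ggplot object, invisibly.
#' @export
plot_marker <- function(result, marker, file = NULL, spec = star_spec(),
                        layout = c("mst", "grid")) {
  layout <- match.arg(layout)
  cl <- result$clusters
  idx <- resolve_markers(cl, marker)
  pos <- if (layout == "grid") layout_grid(result$params$som) else cl$layout_xy
  radii <- node_radii(cl, spec)
  discs <- do.call(rbind, lapply(seq_len(nrow(cl$codes)), function(j) {
    poly <- circle_polygon(pos[j, 1], pos[j, 2], radii[j])
    poly$node <- j
    poly$value <- cl$medians[j, idx]
    poly
  }))
  p <- ggplot2::ggplot(discs,
                       ggplot2::aes(x = .data$px, y = .data$py,
                                    group = .data$node, fill = .data$value)) +
    ggplot2::geom_polygon(color = "grey40", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = marker) +
    ggplot2::coord_fixed() +
    theme_glyph()
  if (!is.null(file)) save_figure(p, file)
  invisible(p)
}
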