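#' Run the full clustering pipeline
#'
#' The four classic steps in one call: (i) read the input (FCS or CSV path,
#' or an in-memory [cell_frame()]), with optional arcsinh / z-score
#' preprocessing; (ii) train the self-organizing map; (iii) build the
#' minimum spanning tree over the node codes and its Kamada-Kawai layout;
#' (iv) metacluster the codes by consensus hierarchical clustering and
#' propagate labels to the events. Returns the two-modality result, ready
#' for [save_result()], the plot functions and [evaluate_result()].
#'
#' All randomness derives from `seed`: the SOM uses `seed` and the
#' consensus resampling uses `seed + 1`.
#'
#' @param input path to an FCS/CSV file, or a [cell_frame()].
#' @param n_meta number of metaclusters k.
#' @param cols_to_use channel subset used for clustering (indices or names;
#'   default: all channels).
#' @param xdim,ydim,rlen,distance,alpha_start,alpha_end SOM controls, see
#'   [som_params()].
#' @param n_resamples,resample_fraction,linkage consensus controls, see
#'   [consensus_params()].
#' @param arcsinh_cofactor if non-`NULL`, apply `asinh(x / cofactor)` to the
#'   clustering channels before training.
#' @param scale if `TRUE`, z-score the clustering channels (after arcsinh,
#'   if both are requested).
#' @param seed integer seed (default 1).
#' @return a `flowsom_result`.
#' @export
flowsom <- function(input, n_meta,
                    cols_to_use = NULL,
                    xdim = 10, ydim = 10, rlen = 10,
                    distance = "euclidean",
                    alpha_start = 0.05, alpha_end = 0.01,
                    n_resamples = 100, resample_fraction = 0.9,
                    linkage = "average",
                    arcsinh_cofactor = NULL, scale = FALSE,
                    seed = 1) {
  frame <- if (inherits(input, "cell_frame")) {
    if (!is.null(cols_to_use)) input$cols_used <- resolve_channels(input, cols_to_use)
    input
  } else if (grepl("\\.csv$", input, ignore.case = TRUE)) {
    read_csv_frame(input, cols_to_use)
  } else {
    read_fcs(input, cols_to_use)
  }
  if (!is.null(arcsinh_cofactor))
    frame <- apply_transform(frame, transform_spec("arcsinh",
                                                   arcsinh_cofactor))
  if (scale)
    frame <- apply_transform(frame, transform_spec("zscore"))

  sp <- som_params(xdim = xdim, ydim = ydim, rlen = rlen,
                   alpha_start = alpha_start, alpha_end = alpha_end,
                   distance = distance, seed = seed)
  codebook <- train_som(frame, sp)
  asg <- assign_bmu(codebook, frame$X[, frame$cols_used, drop = FALSE])
  frame$cluster_id <- asg$cluster_id
  frame$distance_to_bmu <- asg$distance

  mst <- layout_kamada_kawai(build_mst(codebook))

  cp <- consensus_params(k = n_meta, n_resamples = n_resamples,
                         resample_fraction = resample_fraction,
                         linkage = linkage, seed = seed + 1L)
  meta <- metacluster(codebook$codes, cp)

  build_result(frame, codebook, meta, mst)
}
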