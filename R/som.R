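#' Self-organizing map training parameters
#'
#' The SOM over-clusters events onto an `xdim` x `ydim` rectangular grid of
#' prototype vectors ("codes"). Training is online: events are presented one
#' at a time (uniformly at random, `rlen` passes in total), the best matching
#' unit (BMU) is found under `distance`, and every node within the current
#' neighbourhood radius of the BMU on the grid is pulled toward the event by
#' the current learning rate. Both the learning rate and the radius decay
#' linearly over the run. Grid distance is the squared Euclidean distance on
#' grid coordinates; the neighbourhood is a step ("bubble") kernel, so all
#' in-radius nodes receive the full learning rate.
#'
#' @param xdim,ydim grid dimensions (default 10 x 10, i.e. 100 nodes).
#' @param rlen number of passes over the data (default 10).
#' @param alpha_start,alpha_end learning-rate bounds (defaults 0.05, 0.01).
#' @param radius_start starting neighbourhood radius, in squared-grid-distance
#'   units. Default: the 67th percentile of the grid's squared pairwise
#'   distance distribution.
#' @param radius_end final radius (default 0: only the BMU updates at the end).
#' @param distance metric on marker space: `"euclidean"` (default),
#'   `"manhattan"`, `"chebyshev"` or `"cosine"` (1 - cosine similarity, with
#'   zero vectors given similarity 0).
#' @param seed RNG seed controlling code initialization and the presentation
#'   order; runs with the same data, parameters and seed are bit-identical.
#' @return a `som_params` object.
#' @export
som_params <- function(xdim = 10, ydim = 10, rlen = 10,
                       alpha_start = 0.05, alpha_end = 0.01,
                       radius_start = NULL, radius_end = 0,
                       distance = c("euclidean", "manhattan", "chebyshev",
                                    "cosine"),
                       seed = NULL) {
  distance <- match.arg(distance)
  xdim <- as.integer(xdim); ydim <- as.integer(ydim); rlen <- as.integer(rlen)
  stopifnot(xdim >= 1, ydim >= 1, xdim * ydim >= 2, rlen >= 1)
  if (!(alpha_end > 0 && alpha_end <= alpha_start && alpha_start < 1))
    stop("need 0 < alpha_end <= alpha_start < 1")
  if (is.null(radius_start)) {
    nd <- grid_sqdist(xdim, ydim)
    radius_start <- unname(stats::quantile(nd, 0.67))
  }
  if (radius_end > radius_start) stop("radius_end must be <= radius_start")
  structure(list(xdim = xdim, ydim = ydim, rlen = rlen,
                 alpha_start = alpha_start, alpha_end = alpha_end,
                 radius_start = radius_start, radius_end = radius_end,
                 distance = distance, seed = seed),
            class = "som_params")
}

# row-major grid coordinates: node n sits at ((n-1) %% xdim, (n-1) %/% xdim)
grid_coords <- function(xdim, ydim) {
  n <- seq_len(xdim * ydim) - 1L
  cbind(x = n %% xdim, y = n %/% xdim)
}

grid_sqdist <- function(xdim, ydim) {
  g <- grid_coords(xdim, ydim)
  as.matrix(stats::dist(g))^2
}

metric_code <- function(distance) {
  match(distance, c("manhattan", "euclidean", "chebyshev", "cosine")) - 1L
}

.sample_codes <- function(X, m) {
  n <- nrow(X)
  if (n < m)
    stop("fewer events (", n, ") than SOM nodes (", m,
         "); use a smaller grid")
  X[sample.int(n, m), , drop = FALSE]
}

#' Initialize a codebook by sampling events
#'
#' Codes are initialized to `n_nodes` distinct events drawn without
#' replacement (seeded), so every initial code is an observed event.
#'
#' @param frame a [cell_frame()]; only `cols_used` channels enter the codes.
#' @param params a [som_params()].
#' @return an untrained `codebook`.
#' @export
initialize_codes <- function(frame, params) {
  validate_cell_frame(frame)
  X <- frame$X[, frame$cols_used, drop = FALSE]
  if (!is.null(params$seed)) set.seed(params$seed)
  new_codebook(.sample_codes(X, params$xdim * params$ydim), params,
               trained = FALSE)
}

new_codebook <- function(codes, params, trained) {
  structure(list(codes = codes,
                 grid_xy = grid_coords(params$xdim, params$ydim),
                 params = params, trained = trained),
            class = "codebook")
}

#' Train the self-organizing map
#'
#' Runs `rlen * n_events` online update steps (see [som_params()] for the
#' update rule). All randomness — code initialization and the event
#' presentation order — is drawn from R's seeded Mersenne-Twister stream, so
#' results reproduce exactly across platforms and are unaffected by thread
#' count.
#'
#' @param frame a [cell_frame()] with finite values in its `cols_used`
#'   channels.
#' @param params a [som_params()].
#' @param codes_init optional initial codes matrix (`n_nodes` x `d`);
#'   default: sampled events as in [initialize_codes()].
#' @return a trained `codebook`: `codes` (`n_nodes` x `d`, columns named
#'   after the clustering channels), `grid_xy`, `params`, `trained`.
#' @export
train_som <- function(frame, params, codes_init = NULL) {
  validate_cell_frame(frame)
  X <- frame$X[, frame$cols_used, drop = FALSE]
  if (!all(is.finite(X)))
    stop("input contains NaN/Inf in the clustering channels; ",
         "clean or transform the data before training")
  m <- params$xdim * params$ydim
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(codes_init)) {
    codes_init <- .sample_codes(X, m)
  } else {
    codes_init <- as.matrix(codes_init)
    if (!all(dim(codes_init) == c(m, ncol(X))))
      stop("codes_init must be ", m, " x ", ncol(X))
  }
  ord <- sample.int(nrow(X), params$rlen * nrow(X), replace = TRUE) - 1L
  codes <- .cpp_train_som(X, codes_init, grid_sqdist(params$xdim, params$ydim),
                          params$alpha_start, params$alpha_end,
                          params$radius_start, params$radius_end,
                          ord, metric_code(params$distance))
  colnames(codes) <- frame$channel_names[frame$cols_used]
  new_codebook(codes, params, trained = TRUE)
}

#' Assign events to their best matching unit
#'
#' @param codebook a `codebook`.
#' @param X numeric matrix with `d = ncol(codebook$codes)` columns.
#' @return list with `cluster_id` (1-based node index per row; ties broken
#'   toward the lowest node index) and `distance` (the minimized distance).
#' @export
assign_bmu <- function(codebook, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(codebook$codes))
    stop("X has ", ncol(X), " columns but the codebook expects ",
         ncol(codebook$codes))
  .cpp_assign_bmu(X, codebook$codes, metric_code(codebook$params$distance))
}

#' Quantization error
#'
#' Mean distance from events to their best matching unit; the standard SOM
#' fit diagnostic (lower is better, 0 means every event sits on a code).
#'
#' @inheritParams assign_bmu
#' @return a single number.
#' @export
quantization_error <- function(codebook, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("cannot compute quantization error of zero events")
  mean(assign_bmu(codebook, X)$distance)
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: %dx%d grid (%d nodes), %d markers, %s distance%s\n",
              x$params$xdim, x$params$ydim, nrow(x$codes), ncol(x$codes),
              x$params$distance, if (x$trained) "" else " [untrained]"))
  invisible(x)
}
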