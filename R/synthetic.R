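#' Synthetic cytometry-sample specification
#'
#' A diagonal-covariance Gaussian mixture over `d` markers with `k`
#' populations, emulating the marker-intensity structure of a (transformed)
#' cytometry sample. When `means` is not given, population means are placed
#' at the vertices of a regular simplex scaled so every pair of means sits
#' at distance `separation * mean(sds)` — `separation` is therefore the
#' between-population distance in units of within-population spread.
#'
#' @param k number of populations.
#' @param d number of markers (requires `k <= d` for the automatic simplex
#'   placement).
#' @param n number of events.
#' @param weights population weights on the simplex (default uniform).
#' @param means optional `k` x `d` matrix of population means.
#' @param sds `k` x `d` positive matrix of per-marker standard deviations,
#'   or a scalar (default 1).
#' @param separation pairwise mean distance in units of the average sd
#'   (default 6; ignored when `means` is supplied).
#' @param seed RNG seed.
#' @return a `mixture_spec` object.
#' @export
mixture_spec <- function(k, d, n, weights = NULL, means = NULL, sds = 1,
                         separation = 6, seed = NULL) {
  k <- as.integer(k); d <- as.integer(d); n <- as.integer(n)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("weights must be a length-k vector summing to 1")
  if (length(sds) == 1) sds <- matrix(sds, k, d)
  sds <- as.matrix(sds)
  if (!all(dim(sds) == c(k, d)) || any(sds <= 0))
    stop("sds must be a positive k x d matrix (or scalar)")
  if (is.null(means)) {
    if (k > d)
      stop("automatic mean placement needs k <= d; supply means explicitly")
    # regular simplex: unit vectors e_1..e_k have pairwise distance sqrt(2);
    # center and scale to the requested separation
    E <- diag(1, k, d)
    E <- sweep(E, 2, colMeans(E))
    means <- E * separation * mean(sds) / sqrt(2)
  }
  means <- as.matrix(means)
  if (!all(dim(means) == c(k, d))) stop("means must be k x d")
  structure(list(k = k, d = d, n = n, weights = weights, means = means,
                 sds = sds, separation = separation, seed = seed),
            class = "mixture_spec")
}

#' Draw a synthetic cytometry sample
#'
#' Events are drawn population-wise from diagonal Gaussians; channel names
#' are `M1..Md` and the ground-truth population of each event is returned
#' alongside. Deterministic given the spec's seed.
#'
#' @param spec a [mixture_spec()].
#' @return list with `frame` (a [cell_frame()]) and `truth` (character
#'   label `"Pop1".."Popk"` per event).
#' @export
gen_mixture <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  z <- sample.int(spec$k, spec$n, replace = TRUE, prob = spec$weights)
  noise <- matrix(stats::rnorm(spec$n * spec$d), spec$n, spec$d)
  X <- spec$means[z, , drop = FALSE] + noise * spec$sds[z, , drop = FALSE]
  colnames(X) <- paste0("M", seq_len(spec$d))
  list(frame = cell_frame(X), truth = paste0("Pop", z))
}

#' Oversample a frame to a target event count
#'
#' Rows are drawn with replacement until `n_target` events are reached —
#' the protocol used to scale a sample up for throughput studies. The
#' selected source rows are recorded in attribute `"source_rows"` so
#' event-aligned label vectors can be oversampled consistently.
#'
#' @param frame a [cell_frame()] with at least one event.
#' @param n_target target number of events (>= 1).
#' @param seed RNG seed.
#' @return a [cell_frame()] with `n_target` events.
#' @export
oversample <- function(frame, n_target, seed = NULL) {
  validate_cell_frame(frame)
  n <- nrow(frame$X)
  if (n < 1) stop("cannot oversample an empty frame")
  if (n_target < 1) stop("n_target must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, n_target, replace = TRUE)
  out <- cell_frame(frame$X[idx, , drop = FALSE],
                    channel_names = frame$channel_names,
                    marker_names = frame$marker_names,
                    cols_used = frame$cols_used)
  out$transform_log <- frame$transform_log
  attr(out, "source_rows") <- idx
  out
}

#' Write the demo FCS fixture
#'
#' A 7-channel, 5-population, 50 000-event Gaussian-mixture sample written
#' as FCS 3.1 — the shape of the classic 7-color demo input. Ground-truth
#' population labels can be written alongside as a one-column CSV.
#'
#' @param path output FCS path.
#' @param seed RNG seed.
#' @param labels_path optional path for the truth-label CSV.
#' @param n number of events (default 50 000).
#' @return invisibly, the truth label vector.
#' @export
make_demo_fcs <- function(path, seed = 1, labels_path = NULL, n = 50000) {
  spec <- mixture_spec(k = 5, d = 7, n = n, separation = 6, seed = seed)
  sim <- gen_mixture(spec)
  write_fcs(sim$frame, path)
  if (!is.null(labels_path))
    utils::write.csv(data.frame(label = sim$truth), labels_path,
                     row.names = FALSE)
  invisible(sim$truth)
}
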