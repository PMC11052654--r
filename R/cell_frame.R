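#' Cell-level data container
#'
#' A `cell_frame` holds the events x channels intensity matrix of one
#' cytometry sample together with channel names (unique identifiers, FCS
#' $PnN), marker names (display names, FCS $PnS), the subset of channels used
#' for clustering, optional per-event cluster and metacluster labels, and an
#' ordered log of the transforms that have been applied to `X`.
#'
#' @param X numeric matrix, events in rows, channels in columns.
#' @param channel_names character vector of unique channel identifiers, one
#'   per column of `X`. Defaults to `colnames(X)` or `"M1"`, `"M2"`, ...
#' @param marker_names character vector of display names, same length; falls
#'   back to `channel_names` where missing or empty.
#' @param cols_used integer or character vector selecting the channels used
#'   for clustering (default: all channels). Character entries are resolved
#'   against channel names first, then marker names.
#'
#' @return An object of class `cell_frame`: a list with elements `X`,
#'   `channel_names`, `marker_names`, `cols_used` (integer indices),
#'   `cluster_id`, `metacluster_id`, `distance_to_bmu`, `transform_log`.
#' @export
cell_frame <- function(X, channel_names = NULL, marker_names = NULL,
                       cols_used = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(channel_names)) {
    channel_names <- colnames(X)
    if (is.null(channel_names)) channel_names <- paste0("M", seq_len(ncol(X)))
  }
  channel_names <- as.character(channel_names)
  if (is.null(marker_names)) marker_names <- channel_names
  marker_names <- as.character(marker_names)
  empty <- is.na(marker_names) | marker_names == ""
  marker_names[empty] <- channel_names[empty]
  colnames(X) <- channel_names

  frame <- structure(
    list(X = X,
         channel_names = channel_names,
         marker_names = marker_names,
         cols_used = seq_len(ncol(X)),
         cluster_id = NULL,
         metacluster_id = NULL,
         distance_to_bmu = NULL,
         transform_log = list()),
    class = "cell_frame")
  if (!is.null(cols_used)) frame$cols_used <- resolve_channels(frame, cols_used)
  validate_cell_frame(frame)
  frame
}

validate_cell_frame <- function(frame) {
  stopifnot(inherits(frame, "cell_frame"))
  n <- nrow(frame$X); p <- ncol(frame$X)
  if (length(frame$channel_names) != p || length(frame$marker_names) != p)
    stop("channel/marker names must have one entry per channel")
  if (anyDuplicated(frame$channel_names))
    stop("channel names must be unique")
  if (length(frame$cols_used) < 1 ||
      any(frame$cols_used < 1L) || any(frame$cols_used > p))
    stop("cols_used must index channels of X")
  if (!is.null(frame$cluster_id) && length(frame$cluster_id) != n)
    stop("cluster_id must have one entry per event")
  if (!is.null(frame$metacluster_id)) {
    if (is.null(frame$cluster_id))
      stop("metacluster_id requires cluster_id to be assigned")
    if (length(frame$metacluster_id) != n)
      stop("metacluster_id must have one entry per event")
  }
  invisible(frame)
}

#' Resolve channel references to column indices
#'
#' @param frame a [cell_frame()].
#' @param cols integer indices, channel names, or marker names.
#' @return integer column indices into `frame$X`.
#' @export
resolve_channels <- function(frame, cols) {
  if (is.numeric(cols)) {
    cols <- as.integer(cols)
    if (any(cols < 1L | cols > ncol(frame$X)))
      stop("channel index out of range (1..", ncol(frame$X), ")")
    return(cols)
  }
  idx <- match(cols, frame$channel_names)
  miss <- is.na(idx)
  idx[miss] <- match(cols[miss], frame$marker_names)
  if (anyNA(idx))
    stop("unknown channel(s): ", paste(cols[is.na(idx)], collapse = ", "),
         "; available: ",
         paste(unique(c(frame$channel_names, frame$marker_names)),
               collapse = ", "))
  as.integer(idx)
}

#' @export
print.cell_frame <- function(x, ...) {
  cat(sprintf("cell_frame: %d events x %d channels (%d used for clustering)\n",
              nrow(x$X), ncol(x$X), length(x$cols_used)))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (!is.null(x$cluster_id))
    cat(sprintf("clustered into %d nodes", length(unique(x$cluster_id))),
        if (!is.null(x$metacluster_id))
          sprintf(", %d metaclusters", length(unique(x$metacluster_id))),
        "\n", sep = "")
  if (length(x$transform_log))
    cat("transforms:",
        paste(vapply(x$transform_log, `[[`, "", "kind"), collapse = " -> "),
        "\n")
  invisible(x)
}

#' @export
dim.cell_frame <- function(x) dim(x$X)
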