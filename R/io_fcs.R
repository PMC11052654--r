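#' Read an FCS 3.0/3.1 file
#'
#' Parses the header, TEXT segment and DATA segment of a list-mode FCS file.
#' Channel names are taken from the $PnN keywords and marker names from $PnS,
#' falling back to $PnN for channels without a marker annotation. Supported
#' data types: `F` (float32), `D` (float64) and `I` (16- or 32-bit unsigned
#' integers), in either byte order. No transform is applied on read.
#'
#' @param path path to an FCS file.
#' @param cols_to_use optional channel subset (indices, channel names, or
#'   marker names) recorded as the clustering channels of the result.
#' @return a [cell_frame()].
#' @export
read_fcs <- function(path, cols_to_use = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  header <- rawToChar(readBin(con, "raw", 58L))
  if (nchar(header) < 58 || substr(header, 1, 3) != "FCS")
    stop("not an FCS file: ", path)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version, "' (need FCS 3.0 or 3.1)")
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(header, a, b))))
  text_begin <- off(11, 18); text_end <- off(19, 26)
  data_begin <- off(27, 34); data_end <- off(35, 42)

  seek(con, text_begin)
  text <- rawToChar(readBin(con, "raw", text_end - text_begin + 1L))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(as.list(vals), keys)

  need <- function(k) {
    if (is.null(kw[[k]])) stop("FCS file lacks required keyword ", k)
    kw[[k]]
  }
  n <- as.integer(need("$TOT"))
  p <- as.integer(need("$PAR"))
  dtype <- toupper(need("$DATATYPE"))
  mode <- toupper(need("$MODE"))
  if (mode != "L") stop("only list-mode ($MODE L) FCS files are supported")
  endian <- if (grepl("^4", need("$BYTEORD"))) "big" else "little"
  if (is.na(data_begin) || data_begin == 0) data_begin <- as.numeric(need("$BEGINDATA"))

  seek(con, data_begin)
  total <- n * p
  if (dtype == "F") {
    values <- readBin(con, "numeric", total, size = 4L, endian = endian)
  } else if (dtype == "D") {
    values <- readBin(con, "numeric", total, size = 8L, endian = endian)
  } else if (dtype == "I") {
    bits <- unique(vapply(seq_len(p), function(i)
      as.integer(need(paste0("$P", i, "B"))), integer(1)))
    if (length(bits) != 1 || !bits %in% c(16L, 32L))
      stop("integer FCS data requires a uniform $PnB of 16 or 32 bits")
    if (bits == 16L) {
      values <- readBin(con, "integer", total, size = 2L, signed = FALSE,
                        endian = endian)
    } else {
      values <- readBin(con, "integer", total, size = 4L, endian = endian)
    }
    values <- as.numeric(values)
  } else {
    stop("unsupported $DATATYPE '", dtype, "'")
  }
  if (length(values) != total)
    stop("truncated DATA segment: expected ", total, " values, got ",
         length(values))
  X <- matrix(values, nrow = n, ncol = p, byrow = TRUE)

  channels <- vapply(seq_len(p), function(i) {
    v <- kw[[paste0("$P", i, "N")]]
    if (is.null(v) || v == "") paste0("P", i) else v
  }, character(1))
  markers <- vapply(seq_len(p), function(i) {
    v <- kw[[paste0("$P", i, "S")]]
    if (is.null(v) || v == "") channels[i] else v
  }, character(1))

  cell_frame(X, channel_names = channels, marker_names = markers,
             cols_used = cols_to_use)
}

#' Write a cell frame as a minimal FCS 3.1 file
#'
#' Emits a single-dataset, list-mode FCS 3.1 file with float32 data
#' ($DATATYPE F, little-endian), readable by [read_fcs()] and by standard
#' cytometry software. Intensities are stored at float32 precision.
#'
#' @param frame a [cell_frame()] with at least one event.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(frame, path) {
  validate_cell_frame(frame)
  n <- nrow(frame$X); p <- ncol(frame$X)
  if (n < 1) stop("cannot write an FCS file with zero events")

  d <- "/"
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BEGIN%", "$ENDDATA", "%END%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n))
  for (i in seq_len(p)) {
    rng <- max(1, ceiling(max(frame$X[, i], 0, na.rm = TRUE)) + 1)
    kv <- c(kv,
            paste0("$P", i, "B"), "32",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "N"), frame$channel_names[i],
            paste0("$P", i, "S"), frame$marker_names[i],
            paste0("$P", i, "R"), as.character(rng))
  }
  if (any(grepl(d, kv, fixed = TRUE)))
    stop("channel or marker names may not contain the delimiter '", d, "'")
  # offsets are zero-padded to fixed width so the TEXT length is known up front
  text <- paste0(d, paste(kv, collapse = d), d)
  text_begin <- 58L
  text_end <- text_begin + nchar(text) +
    (10L - nchar("%BEGIN%")) + (10L - nchar("%END%")) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n * p - 1L
  text <- sub("%BEGIN%", sprintf("%010d", data_begin), text, fixed = TRUE)
  text <- sub("%END%", sprintf("%010d", data_end), text, fixed = TRUE)
  stopifnot(nchar(text) == text_end - text_begin + 1L)

  fmt8 <- function(x) if (x <= 99999999) sprintf("%8d", x) else sprintf("%8d", 0L)
  header <- paste0("FCS3.1    ", fmt8(text_begin), fmt8(text_end),
                   fmt8(data_begin), fmt8(data_end), fmt8(0L), fmt8(0L))
  stopifnot(nchar(header) == 58L)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(frame$X)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a CSV matrix as a cell frame
#'
#' Alternative input path for event data already exported as CSV: the header
#' row supplies the channel names.
#'
#' @inheritParams read_fcs
#' @return a [cell_frame()].
#' @export
read_csv_frame <- function(path, cols_to_use = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  cell_frame(as.matrix(df), channel_names = colnames(df),
             cols_used = cols_to_use)
}

#' Preprocessing transform specification
#'
#' @param kind `"arcsinh"` (x -> asinh(x / cofactor), the standard
#'   variance-stabilizing transform for fluorescence and mass intensities),
#'   `"zscore"` (per-channel standardization), or `"none"`.
#' @param cofactor positive arcsinh cofactor; 5 is the usual mass-cytometry
#'   default (fluorescence data typically uses 150).
#' @return a `transform_spec` object.
#' @export
transform_spec <- function(kind = c("none", "arcsinh", "zscore"), cofactor = 5) {
  kind <- match.arg(kind)
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    stop("cofactor must be a positive number")
  structure(list(kind = kind, cofactor = cofactor), class = "transform_spec")
}

#' Apply a preprocessing transform to the clustering channels
#'
#' Transforms act on the `cols_used` channels of the frame and are appended
#' to the frame's transform log so they can be replayed when new samples are
#' mapped onto a trained model. For `zscore`, a channel with zero standard
#' deviation is set to all zeros rather than NaN.
#'
#' @param frame a [cell_frame()].
#' @param spec a [transform_spec()].
#' @return the transformed frame.
#' @export
apply_transform <- function(frame, spec) {
  validate_cell_frame(frame)
  if (!inherits(spec, "transform_spec")) stop("spec must be a transform_spec")
  cols <- frame$cols_used
  if (spec$kind == "arcsinh") {
    frame$X[, cols] <- asinh(frame$X[, cols] / spec$cofactor)
  } else if (spec$kind == "zscore") {
    for (j in cols) {
      v <- frame$X[, j]
      mu <- mean(v); s <- stats::sd(v)
      frame$X[, j] <- if (is.na(s) || s == 0) 0 else (v - mu) / s
    }
  }
  frame$transform_log <- c(frame$transform_log,
                           list(list(kind = spec$kind, cofactor = spec$cofactor)))
  frame
}
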