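#' Write / read a trace table with its sidecar
#'
#' The trace table is a CSV whose first column is \code{cell_id} followed by
#' one column per frame (\code{f0001, f0002, ...}); numeric values are
#' written with 17 significant digits so a write/read round trip is
#' bit-identical. The sidecar JSON carries \code{sampling_rate} and the
#' per-cell coordinates (origin at the field's top-left, x rightward,
#' y downward, um).
#'
#' @param ts a [trace_set()].
#' @param path CSV file path; the sidecar defaults to
#'   \code{<path>.json}.
#' @param sidecar sidecar JSON path.
#' @return \code{path}, invisibly.
#' @export
write_trace_table <- function(ts, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(ts, "ca_trace_set"))
  n_frames <- ncol(ts$f)
  df <- data.frame(cell_id = ts$cell_ids, stringsAsFactors = FALSE)
  vals <- apply(ts$f, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  colnames(vals) <- sprintf("f%04d", seq_len(n_frames))
  df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate = ts$sampling_rate)
  if (!is.null(ts$positions))
    meta$positions <- ts$positions[, c("cell_id", "x", "y")]
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace_table
#' @param require_positions error when the sidecar lacks coordinates.
#' @return for the reader: a validated [trace_set()].
#' @export
read_trace_table <- function(path, sidecar = paste0(path, ".json"),
                             require_positions = FALSE) {
  if (!file.exists(sidecar))
    stop("sidecar JSON not found: ", sidecar, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"cell_id" %in% names(df))
    stop("trace table must have a leading cell_id column", call. = FALSE)
  cell_ids <- as.character(df$cell_id)
  fmat <- as.matrix(df[, setdiff(names(df), "cell_id"), drop = FALSE])
  if (!is.numeric(fmat))
    stop("non-numeric values in trace columns", call. = FALSE)
  if (anyNA(fmat)) {
    bad <- which(is.na(fmat), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at cell '%s', frame column '%s'",
                 cell_ids[bad[1]], colnames(fmat)[bad[2]]), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate))
    stop("sidecar is missing 'sampling_rate'", call. = FALSE)
  positions <- NULL
  if (!is.null(meta$positions)) {
    positions <- as.data.frame(meta$positions)
    if (!all(c("cell_id", "x", "y") %in% names(positions)))
      stop("sidecar positions need cell_id, x, y", call. = FALSE)
    m <- match(cell_ids, positions$cell_id)
    if (anyNA(m))
      stop("sidecar positions missing for cell(s): ",
           paste(cell_ids[is.na(m)], collapse = ", "), call. = FALSE)
    positions <- positions[m, , drop = FALSE]
    rownames(positions) <- NULL
  } else if (require_positions) {
    stop("sidecar has no positions but they are required", call. = FALSE)
  }
  dimnames(fmat) <- list(cell_ids, NULL)
  trace_set(fmat, as.numeric(meta$sampling_rate), positions = positions,
            cell_ids = cell_ids)
}

#' Write / read a ground-truth edge list
#'
#' CSV with columns src, dst, delay_s, distance_um; full precision.
#' @param edges data.frame from [generate_ground_truth_graph()].
#' @param path CSV file path.
#' @return \code{path} invisibly (writer); the edges data.frame (reader).
#' @export
write_ground_truth <- function(edges, path) {
  df <- data.frame(src = edges$src, dst = edges$dst,
                   delay_s = sprintf("%.17g", edges$delay_s),
                   distance_um = sprintf("%.17g", edges$distance_um),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$delay_s <- as.numeric(df$delay_s)
  df$distance_um <- as.numeric(df$distance_um)
  df
}

#' Export an inferred graph
#'
#' Writes GraphML (via igraph) and/or an edge-list CSV with columns
#' src, dst, rho, lag_s, distance_um, speed_um_s.
#'
#' @param graph a [build_graph()] result.
#' @param graphml,csv output paths (NULL skips that format).
#' @return invisible NULL.
#' @export
export_graph <- function(graph, graphml = NULL, csv = NULL) {
  stopifnot(inherits(graph, "ca_graph"))
  if (!is.null(csv))
    utils::write.csv(graph$edges, csv, row.names = FALSE, quote = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      graph$edges, directed = TRUE,
      vertices = graph$nodes
    )
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(NULL)
}

#' Export network metrics as JSON and/or one-row CSV
#' @param metrics a [compute_metrics()] result.
#' @param json,csv output paths (NULL skips).
#' @return invisible NULL.
#' @export
export_metrics <- function(metrics, json = NULL, csv = NULL) {
  stopifnot(inherits(metrics, "ca_network_metrics"))
  vals <- metrics[c("mean_corr_all", "mean_corr_adjacent",
                    "mean_connections_per_cell",
                    "percent_possible_connections", "mean_delay_rate",
                    "n_nodes", "n_edges")]
  if (!is.null(json))
    jsonlite::write_json(vals, json, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (!is.null(csv))
    utils::write.csv(as.data.frame(vals), csv, row.names = FALSE)
  invisible(NULL)
}

#' Define a set of circular regions of interest
#'
#' @param x,y centre coordinates, um.
#' @param radius ROI radius (um), recycled.
#' @param cell_id labels.
#' @param field_size field side, um; centres must lie inside.
#' @return data.frame of class \code{"ca_roi_set"}.
#' @export
roi_set <- function(x, y, radius = 10, cell_id = NULL, field_size = 420) {
  radius <- rep_len(radius, length(x))
  if (any(radius <= 0)) stop("ROI radii must be positive", call. = FALSE)
  bad <- which(x < 0 | x > field_size | y < 0 | y > field_size)
  if (length(bad))
    stop("ROI centre(s) outside the field: index ",
         paste(bad, collapse = ", "), call. = FALSE)
  df <- data.frame(
    cell_id = cell_id %||% paste0("cell_", seq_along(x)),
    x = x, y = y, radius = radius, stringsAsFactors = FALSE)
  class(df) <- c("ca_roi_set", "data.frame")
  df
}

#' Extract mean-intensity traces from an image stack
#'
#' Per frame, the mean pixel value over each circular ROI; a pixel belongs
#' to an ROI when its centre falls inside the circle. The um-to-pixel scale
#' is \code{field_size / resolution} (420/512 for the standard acquisition
#' geometry).
#'
#' @param stack 3-d array \code{[frame, row, col]} (as from
#'   [render_movie()]), a list of matrices, or a path to a single-channel
#'   multi-page TIFF.
#' @param rois a [roi_set()].
#' @param field_size field side, um.
#' @param sampling_rate frame rate of the resulting [trace_set()], Hz.
#' @return a [trace_set()] (one row per ROI) with the ROI centres as
#'   positions.
#' @export
extract_roi_traces <- function(stack, rois, field_size = 420,
                               sampling_rate = 2) {
  if (is.character(stack)) stack <- read_image_stack(stack)
  if (is.list(stack))
    stack <- simplify2array_frames(stack)
  stopifnot(length(dim(stack)) == 3)
  n_frames <- dim(stack)[1]
  res_r <- dim(stack)[2]; res_c <- dim(stack)[3]
  if (res_r != res_c)
    stop("only square frames are supported", call. = FALSE)
  px <- field_size / res_c
  centres <- (seq_len(res_c) - 0.5) * px
  f <- matrix(0, nrow = nrow(rois), ncol = n_frames)
  for (k in seq_len(nrow(rois))) {
    dx2 <- (centres - rois$x[k])^2
    dy2 <- (centres - rois$y[k])^2
    inside <- outer(dy2, dx2, `+`) <= rois$radius[k]^2   # rows=y, cols=x
    idx <- which(inside, arr.ind = TRUE)
    if (nrow(idx) == 0)
      stop("ROI ", k, " covers no pixel centre (radius too small ",
           "or outside the frame)", call. = FALSE)
    if (any(idx[, 1] < 1 | idx[, 1] > res_r | idx[, 2] < 1 |
            idx[, 2] > res_c))
      stop("ROI ", k, " extends outside the frame", call. = FALSE)
    for (fr in seq_len(n_frames))
      f[k, fr] <- mean(stack[cbind(fr, idx)])
  }
  trace_set(f, sampling_rate,
            positions = data.frame(cell_id = rois$cell_id, x = rois$x,
                                   y = rois$y, stringsAsFactors = FALSE),
            cell_ids = rois$cell_id)
}

simplify2array_frames <- function(frames) {
  arr <- array(0, dim = c(length(frames), nrow(frames[[1]]),
                          ncol(frames[[1]])))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  arr
}

#' Write / read a multi-page grayscale TIFF image stack
#'
#' Values are stored as 32-bit floats rescaled to [0, 1] by the stack
#' maximum (the TIFF writer's expected range); relative intensities, which
#' are what ROI extraction uses, are preserved. Multi-channel TIFFs are
#' rejected on read.
#'
#' @param stack 3-d array \code{[frame, row, col]}.
#' @param path TIFF file path.
#' @return \code{path} invisibly (writer); a 3-d array (reader).
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  mx <- max(stack)
  if (mx > 1) stack <- stack / mx
  stack <- pmin(pmax(stack, 0), 1)
  frames <- lapply(seq_len(dim(stack)[1]), function(i) stack[i, , ])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(dim(frames[[1]])) > 2)
    stop("multi-channel TIFF stacks are not supported; ",
         "supply a single-channel stack", call. = FALSE)
  simplify2array_frames(frames)
}
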