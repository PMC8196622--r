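#' Construct a trace set
#'
#' The pipeline's universal currency: a cells x frames fluorescence matrix
#' with its sampling rate and per-cell spatial coordinates.
#'
#' @param f numeric matrix, one row per cell, one column per frame.
#' @param sampling_rate frame rate, Hz.
#' @param positions optional data.frame with columns \code{cell_id},
#'   \code{x}, \code{y} (um); row order must match \code{f}.
#' @param cell_ids character labels; defaults to rownames of \code{f} or
#'   \code{cell_1 ... cell_n}.
#' @return object of class \code{"ca_trace_set"}.
#' @export
trace_set <- function(f, sampling_rate, positions = NULL, cell_ids = NULL) {
  f <- as.matrix(f)
  storage.mode(f) <- "double"
  if (ncol(f) < 2) stop("a trace set needs at least 2 frames",
                        call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar", call. = FALSE)
  if (anyNA(f)) {
    bad <- which(is.na(f), arr.ind = TRUE)[1, ]
    stop(sprintf("trace matrix contains missing values (first at cell %d, frame %d); gapped recordings are rejected rather than imputed",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (is.null(cell_ids))
    cell_ids <- rownames(f) %||% paste0("cell_", seq_len(nrow(f)))
  if (length(cell_ids) != nrow(f))
    stop("cell_ids length must match the number of trace rows",
         call. = FALSE)
  rownames(f) <- cell_ids
  if (!is.null(positions)) {
    if (nrow(positions) != nrow(f))
      stop("positions must have one row per cell", call. = FALSE)
    if (is.null(positions$cell_id)) positions$cell_id <- cell_ids
  }
  structure(list(f = f, sampling_rate = sampling_rate,
                 positions = positions, cell_ids = cell_ids),
            class = "ca_trace_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ca_trace_set <- function(x, ...) {
  cat(sprintf("ca_trace_set: %d cells x %d frames at %g Hz (%.1f s)%s\n",
              nrow(x$f), ncol(x$f), x$sampling_rate,
              ncol(x$f) / x$sampling_rate,
              if (is.null(x$positions)) ", no positions" else ""))
  invisible(x)
}

#' Frame times of a trace set
#' @param ts a [trace_set()].
#' @return numeric vector of frame times, s, starting at 0.
#' @export
frame_times <- function(ts) {
  (seq_len(ncol(ts$f)) - 1) / ts$sampling_rate
}

#' Recording duration of a trace set, in seconds
#' @param ts a [trace_set()].
#' @return duration, s (frames / sampling rate).
#' @export
recording_duration <- function(ts) ncol(ts$f) / ts$sampling_rate
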