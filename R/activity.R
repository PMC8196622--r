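#' Normalize fluorescence traces to dF/F
#'
#' The baseline F0 of each cell is a rolling 10th percentile over a sliding
#' window (60 s by default), clamped from below at the cell's global 5th
#' percentile so that oscillation-dense stretches cannot drag the baseline
#' up into the transients. dF/F = (F - F0) / F0.
#'
#' @param ts a [trace_set()] of raw fluorescence.
#' @param window baseline window length, s.
#' @param baseline_quantile rolling quantile defining F0.
#' @param floor_quantile global quantile used as the lower clamp on F0.
#' @return a [trace_set()] of the same shape holding dF/F values.
#' @export
compute_dff <- function(ts, window = 60, baseline_quantile = 0.10,
                        floor_quantile = 0.05) {
  stopifnot(inherits(ts, "ca_trace_set"))
  w <- max(2L, round(window * ts$sampling_rate))
  half <- w %/% 2
  n <- ncol(ts$f)
  dff <- ts$f
  for (i in seq_len(nrow(ts$f))) {
    x <- ts$f[i, ]
    f0 <- rolling_quantile(x, half, baseline_quantile)
    f0 <- pmax(f0, stats::quantile(x, floor_quantile, names = FALSE))
    if (any(f0 <= 0))
      stop(sprintf("degenerate baseline (F0 <= 0) for cell '%s'; dF/F is undefined",
                   ts$cell_ids[i]), call. = FALSE)
    dff[i, ] <- (x - f0) / f0
  }
  trace_set(dff, ts$sampling_rate, positions = ts$positions,
            cell_ids = ts$cell_ids)
}

# centred rolling quantile with partial windows at the edges
rolling_quantile <- function(x, half, p) {
  n <- length(x)
  vapply(seq_len(n), function(t) {
    stats::quantile(x[max(1, t - half):min(n, t + half)], p, names = FALSE)
  }, numeric(1))
}

#' Detect calcium oscillations in a normalized trace set
#'
#' Hysteresis thresholding on dF/F: an event opens when the trace crosses
#' the onset threshold upward and closes when it falls below the offset
#' threshold; events shorter than \code{min_duration} are discarded. When
#' thresholds are not supplied they are derived per cell from the noise
#' scale: onset = 4x and offset = 2x the median absolute deviation of the
#' differentiated trace (a robust estimate of the frame-to-frame noise that
#' is insensitive to the slow transients themselves).
#'
#' @param ts a [trace_set()] of dF/F values (see [compute_dff()]).
#' @param onset_threshold,offset_threshold dF/F thresholds; either both
#'   given (onset > offset required) or both NULL for the MAD-based default.
#' @param min_duration minimum event duration, s.
#' @return data.frame with columns \code{cell_id}, \code{onset},
#'   \code{offset}, \code{duration} (s), time-ordered within each cell.
#' @export
detect_oscillations <- function(ts, onset_threshold = NULL,
                                offset_threshold = NULL,
                                min_duration = 1) {
  stopifnot(inherits(ts, "ca_trace_set"))
  fixed <- !is.null(onset_threshold) || !is.null(offset_threshold)
  if (fixed) {
    if (is.null(onset_threshold) || is.null(offset_threshold))
      stop("supply both onset_threshold and offset_threshold, or neither",
           call. = FALSE)
    if (onset_threshold <= offset_threshold)
      stop("onset_threshold must exceed offset_threshold", call. = FALSE)
  }
  out <- vector("list", nrow(ts$f))
  tt <- frame_times(ts)
  for (i in seq_len(nrow(ts$f))) {
    x <- ts$f[i, ]
    if (fixed) {
      on_th <- onset_threshold; off_th <- offset_threshold
    } else {
      s <- stats::mad(diff(x))
      if (s == 0) s <- 1e-9         # flat trace: any excursion is an event
      on_th <- 4 * s; off_th <- 2 * s
    }
    ev <- hysteresis_events(x, tt, on_th, off_th)
    if (nrow(ev)) {
      ev <- ev[ev$duration >= min_duration, , drop = FALSE]
      if (nrow(ev)) ev$cell_id <- ts$cell_ids[i]
    }
    out[[i]] <- ev
  }
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out))
    return(data.frame(cell_id = character(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("cell_id", "onset", "offset", "duration")]
}

hysteresis_events <- function(x, tt, on_th, off_th) {
  onsets <- numeric(0); offsets <- numeric(0)
  open <- FALSE; t_on <- NA_real_
  for (k in seq_along(x)) {
    if (!open && x[k] > on_th) {
      open <- TRUE; t_on <- tt[k]
    } else if (open && x[k] < off_th) {
      onsets <- c(onsets, t_on); offsets <- c(offsets, tt[k])
      open <- FALSE
    }
  }
  if (open) {                        # event still open at recording end
    onsets <- c(onsets, t_on); offsets <- c(offsets, tt[length(tt)])
  }
  data.frame(onset = onsets, offset = offsets,
             duration = offsets - onsets)
}

#' Summarize calcium activity per cell and per culture
#'
#' A cell is active iff it has at least one detected event. Frequency is
#' events per minute of recording; culture-level mean duration and mean
#' frequency are averaged over active cells only (the convention when these
#' statistics are reported alongside the percentage of active cells).
#'
#' @param events event table from [detect_oscillations()].
#' @param ts the [trace_set()] the events were detected on (supplies the
#'   cell roster and recording duration).
#' @return object of class \code{"ca_activity_summary"}: list with
#'   \code{per_cell} (data.frame: cell_id, n_events, frequency,
#'   mean_duration, active), \code{percent_active},
#'   \code{mean_duration}, \code{mean_frequency} (the last two NA when no
#'   cell is active), \code{n_cells}, \code{recording_duration}.
#' @export
summarize_activity <- function(events, ts) {
  stopifnot(inherits(ts, "ca_trace_set"))
  dur_min <- recording_duration(ts) / 60
  if (dur_min <= 0) stop("zero-length recording", call. = FALSE)
  per <- data.frame(cell_id = ts$cell_ids, n_events = 0L,
                    frequency = 0, mean_duration = NA_real_,
                    active = FALSE, stringsAsFactors = FALSE)
  if (nrow(events)) {
    tab <- table(factor(events$cell_id, levels = ts$cell_ids))
    per$n_events <- as.integer(tab)
    per$frequency <- per$n_events / dur_min
    md <- tapply(events$duration, factor(events$cell_id,
                                         levels = ts$cell_ids), mean)
    per$mean_duration <- as.numeric(md)
    per$active <- per$n_events >= 1
  }
  act <- per[per$active, , drop = FALSE]
  structure(list(
    per_cell = per,
    percent_active = 100 * nrow(act) / nrow(per),
    mean_duration = if (nrow(act)) mean(act$mean_duration) else NA_real_,
    mean_frequency = if (nrow(act)) mean(act$frequency) else NA_real_,
    n_cells = nrow(per),
    recording_duration = recording_duration(ts)
  ), class = "ca_activity_summary")
}

#' @export
print.ca_activity_summary <- function(x, ...) {
  cat(sprintf("calcium activity: %d cells over %.0f s\n", x$n_cells,
              x$recording_duration))
  cat(sprintf("  %% active cells:   %.1f\n", x$percent_active))
  cat(sprintf("  mean duration:    %s s\n",
              if (is.na(x$mean_duration)) "-" else
                sprintf("%.2f", x$mean_duration)))
  cat(sprintf("  mean frequency:   %s osc/min\n",
              if (is.na(x$mean_frequency)) "-" else
                sprintf("%.2f", x$mean_frequency)))
  invisible(x)
}
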