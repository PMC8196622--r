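#' Scatter cells uniformly on the field of view
#'
#' @param scn a [scenario()].
#' @return data.frame with columns \code{cell_id}, \code{x}, \code{y} (um),
#'   coordinates uniform on \code{[0, field_size]^2}. Origin at the top-left
#'   of the field, x rightward, y downward.
#' @export
generate_positions <- function(scn) {
  scn <- validate_scenario(scn)
  old <- set_local_seed(stage_seed(scn$seed, "positions"))
  on.exit(restore_seed(old))
  n <- scn$n_cells
  data.frame(
    cell_id = paste0("cell_", seq_len(n)),
    x = stats::runif(n, 0, scn$field_size),
    y = stats::runif(n, 0, scn$field_size),
    stringsAsFactors = FALSE
  )
}

# Seed handling: save/restore the global RNG state so simulator stages are
# deterministic without clobbering the caller's stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Plant the ground-truth coupling graph
#'
#' Every ordered pair of cells closer than the connectivity radius becomes a
#' directed edge with probability \code{coupling_probability}. The edge's
#' true signal delay is distance / propagation_speed plus Gaussian jitter,
#' truncated at zero.
#'
#' @param positions data.frame from [generate_positions()].
#' @param scn a [scenario()].
#' @return data.frame with columns \code{src}, \code{dst} (cell ids),
#'   \code{distance_um}, \code{delay_s}.
#' @export
generate_ground_truth_graph <- function(positions, scn) {
  scn <- validate_scenario(scn)
  if (nrow(positions) < 2)
    stop("need at least 2 cells to build a coupling graph", call. = FALSE)
  old <- set_local_seed(stage_seed(scn$seed, "graph"))
  on.exit(restore_seed(old))

  n <- nrow(positions)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$i != idx$j, , drop = FALSE]
  idx <- idx[order(idx$i, idx$j), , drop = FALSE]  # fixed RNG consumption order
  d <- sqrt((positions$x[idx$i] - positions$x[idx$j])^2 +
            (positions$y[idx$i] - positions$y[idx$j])^2)
  near <- d <= scn$connectivity_radius
  keep <- near & (stats::runif(nrow(idx)) < scn$coupling_probability)
  idx <- idx[keep, , drop = FALSE]
  d <- d[keep]
  jitter <- if (scn$delay_jitter_sd > 0)
    stats::rnorm(length(d), 0, scn$delay_jitter_sd) else rep(0, length(d))
  delay <- pmax(0, d / scn$effective$propagation_speed + jitter)
  data.frame(
    src = positions$cell_id[idx$i],
    dst = positions$cell_id[idx$j],
    distance_um = d,
    delay_s = delay,
    stringsAsFactors = FALSE
  )
}

#' Simulate spontaneous and propagated calcium events
#'
#' Non-silenced cells fire spontaneously as independent homogeneous Poisson
#' processes at the condition-scaled event rate. Each accepted event then
#' propagates along every outgoing ground-truth edge with the (scaled)
#' transmit probability, arriving after the edge's true delay. A per-cell
#' refractory period bounds transitive cascades; events arriving inside it
#' are dropped. Silenced cells neither fire nor relay.
#'
#' @param ground_truth list with \code{positions} and \code{edges} (as
#'   returned by the generators), or just the edges data.frame together with
#'   a \code{positions} argument.
#' @param scn a [scenario()].
#' @return named list (one element per cell id) of sorted event-time
#'   vectors, with attribute \code{"silenced"} naming the silenced cells.
#' @export
simulate_events <- function(ground_truth, scn) {
  scn <- validate_scenario(scn)
  positions <- ground_truth$positions
  edges <- ground_truth$edges
  old <- set_local_seed(stage_seed(scn$seed, "events"))
  on.exit(restore_seed(old))

  ids <- positions$cell_id
  n <- length(ids)
  n_silenced <- round(scn$effective$silenced_fraction * n)
  silenced <- if (n_silenced > 0) sample(ids, n_silenced) else character(0)
  active <- setdiff(ids, silenced)

  rate_s <- scn$effective$event_rate / 60    # events per second
  lambda <- rate_s * scn$duration

  # spontaneous seeds, fixed per-cell RNG order
  ev_cell <- character(0)
  ev_time <- numeric(0)
  for (id in ids) {
    if (!(id %in% active)) next
    k <- stats::rpois(1, lambda)
    if (k > 0) {
      ev_cell <- c(ev_cell, rep(id, k))
      ev_time <- c(ev_time, sort(stats::runif(k, 0, scn$duration)))
    }
  }

  out_edges <- split(edges[, c("dst", "delay_s")], edges$src)
  accepted <- stats::setNames(vector("list", n), ids)
  p_tx <- scn$effective$transmit_probability

  # process pending events strictly in (time, cell-index) order
  pend_cell <- ev_cell
  pend_time <- ev_time
  cell_rank <- stats::setNames(seq_along(ids), ids)
  n_accepted <- 0L
  max_events <- 250000L
  while (length(pend_time) > 0) {
    ord <- order(pend_time, cell_rank[pend_cell])
    i <- ord[1]
    cl <- pend_cell[i]; tm <- pend_time[i]
    pend_cell <- pend_cell[-i]; pend_time <- pend_time[-i]
    if (tm > scn$duration) next
    if (cl %in% silenced) next
    prev <- accepted[[cl]]
    if (length(prev) && tm - prev[length(prev)] < scn$refractory_period)
      next
    accepted[[cl]] <- c(prev, tm)
    n_accepted <- n_accepted + 1L
    if (n_accepted > max_events)
      stop("event cascade exceeded ", max_events,
           " events; scenario is unstable", call. = FALSE)
    oe <- out_edges[[cl]]
    if (!is.null(oe) && nrow(oe) > 0) {
      go <- stats::runif(nrow(oe)) < p_tx
      if (any(go)) {
        pend_cell <- c(pend_cell, oe$dst[go])
        pend_time <- c(pend_time, tm + oe$delay_s[go])
      }
    }
  }
  accepted <- lapply(accepted, function(v) if (is.null(v)) numeric(0) else v)
  attr(accepted, "silenced") <- silenced
  accepted
}

#' Calcium transient kernel
#'
#' Difference-of-exponentials impulse response
#' \code{(1 - exp(-t/rise_tau)) * exp(-t/decay_tau)}, normalized to unit
#' peak, so an event of amplitude a produces a transient peaking at a.
#'
#' @param t times since event onset, s (negative times give 0).
#' @param rise_tau,decay_tau time constants, s.
#' @return kernel values, unit peak.
#' @export
transient_kernel <- function(t, rise_tau, decay_tau) {
  t_peak <- rise_tau * log1p(decay_tau / rise_tau)
  peak <- (1 - exp(-t_peak / rise_tau)) * exp(-t_peak / decay_tau)
  k <- ifelse(t >= 0, (1 - exp(-t / rise_tau)) * exp(-t / decay_tau), 0)
  k / peak
}

#' Render fluorescence traces from event times
#'
#' Each cell's trace is
#' \code{baseline_f0 * (1 + amplitude * sum_k K(t - t_k))} plus Gaussian
#' imaging noise of sd \code{noise_sd * baseline_f0}; K is the unit-peak
#' [transient_kernel()]. Optional linear photobleaching multiplies the
#' baseline by \code{max(0, 1 - bleach_rate * t)}.
#'
#' @param event_times named list of event-time vectors (see
#'   [simulate_events()]).
#' @param scn a [scenario()].
#' @param positions data.frame of cell coordinates carried into the result.
#' @return A [trace_set()] with one row per cell.
#' @export
render_traces <- function(event_times, scn, positions = NULL) {
  scn <- validate_scenario(scn)
  n_frames <- floor(scn$duration * scn$sampling_rate)
  if (n_frames < 2) stop("recording must span at least 2 frames",
                         call. = FALSE)
  t_grid <- (seq_len(n_frames) - 1) / scn$sampling_rate
  ids <- names(event_times)
  f <- matrix(0, nrow = length(ids), ncol = n_frames,
              dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    y <- numeric(n_frames)
    for (te in event_times[[i]]) {
      from <- max(1L, ceiling(te * scn$sampling_rate) + 1L)
      if (from > n_frames) next
      seg <- from:n_frames
      y[seg] <- y[seg] + scn$amplitude *
        transient_kernel(t_grid[seg] - te, scn$rise_tau, scn$decay_tau)
    }
    base <- scn$baseline_f0 * pmax(0, 1 - scn$bleach_rate * t_grid)
    f[i, ] <- base * (1 + y)
  }
  if (scn$noise_sd > 0) {
    old <- set_local_seed(stage_seed(scn$seed, "noise"))
    on.exit(restore_seed(old))
    for (i in seq_along(ids))
      f[i, ] <- f[i, ] + stats::rnorm(n_frames, 0,
                                      scn$noise_sd * scn$baseline_f0)
  }
  trace_set(f, sampling_rate = scn$sampling_rate, positions = positions,
            cell_ids = ids)
}

#' Simulate a full synthetic recording
#'
#' Runs positions -> ground-truth graph -> events -> traces and returns both
#' the recording and its ground truth, so downstream inference can be scored
#' against what was planted.
#'
#' @param scn a [scenario()].
#' @return list with elements \code{traces} (a [trace_set()]) and
#'   \code{ground_truth} (list: \code{positions}, \code{edges},
#'   \code{event_times}, \code{silenced}).
#' @export
#' @examples
#' rec <- simulate_recording(scenario(n_cells = 5, duration = 60, seed = 1))
#' dim(rec$traces$f)
simulate_recording <- function(scn) {
  scn <- validate_scenario(scn)
  positions <- generate_positions(scn)
  edges <- if (scn$n_cells >= 2)
    generate_ground_truth_graph(positions, scn)
  else
    data.frame(src = character(0), dst = character(0),
               distance_um = numeric(0), delay_s = numeric(0))
  gt <- list(positions = positions, edges = edges)
  ev <- simulate_events(gt, scn)
  traces <- render_traces(ev, scn, positions = positions)
  list(
    traces = traces,
    ground_truth = list(positions = positions, edges = edges,
                        event_times = ev,
                        silenced = attr(ev, "silenced"))
  )
}

#' Render an image stack from traces
#'
#' Places a Gaussian intensity blob at each cell position, scaled per frame
#' by the cell's instantaneous fluorescence, on a square pixel grid mapping
#' the field of view (512 x 512 by default, matching typical confocal
#' acquisition of a 420 um field). Additive Gaussian pixel noise optional.
#'
#' @param traces a [trace_set()] with positions.
#' @param scn a [scenario()].
#' @param resolution pixels per side.
#' @param cell_sigma_um Gaussian blob sd, um.
#' @param pixel_noise_sd additive pixel noise sd (image units); 0 disables.
#' @return 3-d array \code{[frame, row, col]}; rows map y, columns map x.
#' @export
render_movie <- function(traces, scn, resolution = 512, cell_sigma_um = 8,
                         pixel_noise_sd = 0) {
  scn <- validate_scenario(scn)
  stopifnot(inherits(traces, "ca_trace_set"))
  n_frames <- ncol(traces$f)
  n <- nrow(traces$f)
  px <- scn$field_size / resolution   # um per pixel
  stack <- array(0, dim = c(n_frames, resolution, resolution))
  if (n > 0) {
    pos <- traces$positions
    # pixel-centre coordinates in um
    centres <- (seq_len(resolution) - 0.5) * px
    for (i in seq_len(n)) {
      gx <- exp(-(centres - pos$x[i])^2 / (2 * cell_sigma_um^2))
      gy <- exp(-(centres - pos$y[i])^2 / (2 * cell_sigma_um^2))
      blob <- outer(gy, gx)            # rows = y, cols = x
      nz <- which(blob > 1e-6, arr.ind = TRUE)
      if (nrow(nz) == 0) next
      vals <- blob[nz]
      for (fr in seq_len(n_frames)) {
        stack[cbind(fr, nz)] <- stack[cbind(fr, nz)] +
          vals * traces$f[i, fr]
      }
    }
  }
  if (pixel_noise_sd > 0) {
    old <- set_local_seed(stage_seed(scn$seed, "movie"))
    on.exit(restore_seed(old))
    stack <- stack + stats::rnorm(length(stack), 0, pixel_noise_sd)
  }
  stack
}
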