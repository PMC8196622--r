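#' Maximum lagged correlation between two traces
#'
#' Computes the Pearson (or Spearman) correlation between two equal-length
#' traces at every integer-frame shift in \code{[-max_lag, +max_lag]},
#' each on the overlapping segment, and returns the shift that maximizes
#' the correlation. A positive lag means the second trace follows the
#' first. Ties are broken toward the smallest absolute lag, then toward the
#' negative lag.
#'
#' @param a,b numeric traces of equal length (normalized dF/F recommended;
#'   Pearson is invariant to per-trace affine scaling).
#' @param max_lag maximum shift considered, s.
#' @param sampling_rate frame rate, Hz.
#' @param method "pearson" (default) or "spearman".
#' @return list with \code{rho} (max correlation), \code{lag_s},
#'   \code{lag_frames}, and \code{rho_zero} (the zero-lag correlation,
#'   used by [build_graph()]'s lag-significance rule). If either trace has
#'   zero variance on some evaluated overlap the pair is flagged
#'   non-correlatable: \code{rho} is NA.
#' @export
lagged_correlation <- function(a, b, max_lag = 10, sampling_rate,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b))
    stop("traces must have equal length", call. = FALSE)
  n <- length(a)
  L <- round(max_lag * sampling_rate)
  if (n <= 2 * L)
    stop("traces must be longer than twice max_lag in frames",
         call. = FALSE)
  # evaluate lag 0 first, then +-1, +-2, ... with negative first, and keep
  # the first strict maximum: this realizes the tie-break order directly
  lag_order <- c(0L, as.vector(rbind(-seq_len(L), seq_len(L))))
  best_rho <- -Inf; best_lag <- 0L; rho_zero <- NA_real_
  for (k in lag_order) {
    if (k >= 0) {
      av <- a[seq_len(n - k)]; bv <- b[seq_len(n - k) + k]
    } else {
      av <- a[seq_len(n + k) - k]; bv <- b[seq_len(n + k)]
    }
    if (stats::sd(av) == 0 || stats::sd(bv) == 0)
      return(list(rho = NA_real_, lag_s = NA_real_,
                  lag_frames = NA_integer_, rho_zero = NA_real_))
    r <- stats::cor(av, bv, method = method)
    if (k == 0L) rho_zero <- r
    if (r > best_rho) { best_rho <- r; best_lag <- k }
  }
  list(rho = best_rho, lag_s = best_lag / sampling_rate,
       lag_frames = best_lag, rho_zero = rho_zero)
}

#' Emphasize calcium-concentration increases in a trace set
#'
#' Signal propagation shows up as consistent delays between the *rises* of
#' calcium concentration in coupled cells, while the slow transient decays
#' contribute long autocorrelation tails that inflate spurious lagged
#' correlations between unrelated cells. This transform takes the rectified
#' first difference of each trace (the instantaneous increase) and smooths
#' it with a short centred boxcar so that sub-frame propagation jitter
#' still aligns.
#'
#' @param ts a [trace_set()] (normalized dF/F recommended).
#' @param smooth_window boxcar width, s.
#' @return a [trace_set()] of the same shape.
#' @export
rise_signal <- function(ts, smooth_window = 1) {
  stopifnot(inherits(ts, "ca_trace_set"))
  w <- max(1L, round(smooth_window * ts$sampling_rate))
  r <- t(apply(ts$f, 1, function(x) {
    v <- pmax(c(0, diff(x)), 0)
    if (w > 1) {
      v <- stats::filter(v, rep(1 / w, w), sides = 2)
      v[is.na(v)] <- 0
    }
    as.numeric(v)
  }))
  trace_set(r, ts$sampling_rate, positions = ts$positions,
            cell_ids = ts$cell_ids)
}

#' Infer the directed functional-connectivity graph
#'
#' For every unordered pair of cells the maximum lagged correlation is
#' computed once. Pairs with rho above \code{edge_threshold} become edges,
#' oriented from the leading cell to the lagging cell. A lag counts as
#' significant only when the maximum rho exceeds the zero-lag rho by at
#' least \code{lag_significance}; otherwise the pair is treated as
#' synchronous (lag 0) and represented as a reciprocal pair of zero-lag
#' edges. Each edge carries rho, lag, the Euclidean distance between the
#' cells, and the implied propagation speed distance/lag (absent for
#' zero-lag edges).
#'
#' By default correlation is computed on the [rise_signal()] of the traces
#' (delays live in the *increases* of calcium concentration); set
#' \code{signal = "raw"} to correlate the supplied traces as they are.
#'
#' @param ts a [trace_set()] of normalized traces with positions.
#' @param edge_threshold correlation threshold for an edge (default 0.3).
#' @param max_lag maximum lag searched, s.
#' @param lag_significance minimum rho gain over the zero-lag correlation
#'   for a lag to be trusted as a real delay.
#' @param method correlation method, see [lagged_correlation()].
#' @param signal "rise" (default) correlates the rectified smoothed
#'   derivative; "raw" correlates the traces unchanged.
#' @return object of class \code{"ca_graph"}: list with \code{nodes}
#'   (cell_id, x, y), \code{edges} (src, dst, rho, lag_s, distance_um,
#'   speed_um_s), \code{pairs} (the full pairwise table incl. sub-threshold
#'   pairs: a, b, rho, lag_s, distance_um), and \code{params}.
#' @export
build_graph <- function(ts, edge_threshold = 0.3, max_lag = 10,
                        lag_significance = 0.05,
                        method = c("pearson", "spearman"),
                        signal = c("rise", "raw")) {
  method <- match.arg(method)
  signal <- match.arg(signal)
  stopifnot(inherits(ts, "ca_trace_set"))
  if (is.null(ts$positions))
    stop("trace set has no cell positions; the graph needs them",
         call. = FALSE)
  if (signal == "rise") ts <- rise_signal(ts)
  n <- nrow(ts$f)
  ids <- ts$cell_ids
  variances <- apply(ts$f, 1, stats::var)
  if (sum(variances > 0) < 2) {
    warning("fewer than 2 correlatable cells; returning an empty graph")
    return(empty_graph(ts, edge_threshold, max_lag, method))
  }
  pa <- pb <- character(0)
  prho <- plag <- pdist <- numeric(0)
  e_src <- e_dst <- character(0)
  e_rho <- e_lag <- e_dist <- numeric(0)
  skipped <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((ts$positions$x[i] - ts$positions$x[j])^2 +
                (ts$positions$y[i] - ts$positions$y[j])^2)
      lc <- lagged_correlation(ts$f[i, ], ts$f[j, ], max_lag,
                               ts$sampling_rate, method)
      if (is.na(lc$rho)) {
        skipped <- c(skipped, paste0(ids[i], "~", ids[j]))
        next
      }
      lag <- lc$lag_s
      if (lag != 0 && (lc$rho - lc$rho_zero) < lag_significance)
        lag <- 0                       # shift not significant: synchronous
      pa <- c(pa, ids[i]); pb <- c(pb, ids[j])
      prho <- c(prho, lc$rho); plag <- c(plag, lag); pdist <- c(pdist, d)
      if (lc$rho > edge_threshold) {
        if (lag > 0) {                 # j follows i
          e_src <- c(e_src, ids[i]); e_dst <- c(e_dst, ids[j])
          e_rho <- c(e_rho, lc$rho); e_lag <- c(e_lag, lag)
          e_dist <- c(e_dist, d)
        } else if (lag < 0) {          # i follows j
          e_src <- c(e_src, ids[j]); e_dst <- c(e_dst, ids[i])
          e_rho <- c(e_rho, lc$rho); e_lag <- c(e_lag, -lag)
          e_dist <- c(e_dist, d)
        } else {                       # synchronous: reciprocal pair
          e_src <- c(e_src, ids[i], ids[j])
          e_dst <- c(e_dst, ids[j], ids[i])
          e_rho <- c(e_rho, lc$rho, lc$rho)
          e_lag <- c(e_lag, 0, 0)
          e_dist <- c(e_dist, d, d)
        }
      }
    }
  }
  if (length(skipped))
    message(length(skipped), " zero-variance pair(s) skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  edges <- data.frame(src = e_src, dst = e_dst, rho = e_rho, lag_s = e_lag,
                      distance_um = e_dist, stringsAsFactors = FALSE)
  edges$speed_um_s <- ifelse(edges$lag_s > 0,
                             edges$distance_um / edges$lag_s, NA_real_)
  structure(list(
    nodes = data.frame(cell_id = ids, x = ts$positions$x,
                       y = ts$positions$y, stringsAsFactors = FALSE),
    edges = edges,
    pairs = data.frame(a = pa, b = pb, rho = prho, lag_s = plag,
                       distance_um = pdist, stringsAsFactors = FALSE),
    params = list(edge_threshold = edge_threshold, max_lag = max_lag,
                  lag_significance = lag_significance, method = method,
                  signal = signal, sampling_rate = ts$sampling_rate)
  ), class = "ca_graph")
}

empty_graph <- function(ts, edge_threshold, max_lag, method) {
  structure(list(
    nodes = data.frame(cell_id = ts$cell_ids, x = ts$positions$x,
                       y = ts$positions$y, stringsAsFactors = FALSE),
    edges = data.frame(src = character(0), dst = character(0),
                       rho = numeric(0), lag_s = numeric(0),
                       distance_um = numeric(0), speed_um_s = numeric(0)),
    pairs = data.frame(a = character(0), b = character(0),
                       rho = numeric(0), lag_s = numeric(0),
                       distance_um = numeric(0)),
    params = list(edge_threshold = edge_threshold, max_lag = max_lag,
                  method = method, sampling_rate = ts$sampling_rate)
  ), class = "ca_graph")
}

#' @export
print.ca_graph <- function(x, ...) {
  cat(sprintf("ca_graph: %d nodes, %d directed edges (rho > %g)\n",
              nrow(x$nodes), nrow(x$edges), x$params$edge_threshold))
  invisible(x)
}

#' The five network parameters
#'
#' Computed from an inferred connectivity graph and its full pairwise
#' correlation table: (1) mean correlation over all cell pairs, (2) mean
#' correlation over adjacent pairs (within \code{adjacency_radius}),
#' (3) mean number of connections per cell (in-degree + out-degree),
#' (4) percent of existing connections out of all N(N-1) possible ordered
#' connections, and (5) mean propagation speed distance/lag over edges with
#' a positive lag.
#'
#' @param graph a [build_graph()] result.
#' @param adjacency_radius distance (um) below which a pair counts as
#'   adjacent.
#' @return object of class \code{"ca_network_metrics"}: named list
#'   \code{mean_corr_all}, \code{mean_corr_adjacent},
#'   \code{mean_connections_per_cell}, \code{percent_possible_connections},
#'   \code{mean_delay_rate} (um/s; NA when no positive-lag edges exist).
#'   Correlation means over an empty pair set are NA.
#' @export
compute_metrics <- function(graph, adjacency_radius = 100) {
  stopifnot(inherits(graph, "ca_graph"))
  n <- nrow(graph$nodes)
  pairs <- graph$pairs
  edges <- graph$edges
  adj <- pairs[pairs$distance_um <= adjacency_radius, , drop = FALSE]
  speeds <- edges$speed_um_s[edges$lag_s > 0]
  structure(list(
    mean_corr_all = if (nrow(pairs)) mean(pairs$rho) else NA_real_,
    mean_corr_adjacent = if (nrow(adj)) mean(adj$rho) else NA_real_,
    mean_connections_per_cell = if (n > 0) 2 * nrow(edges) / n else NA_real_,
    percent_possible_connections =
      if (n > 1) 100 * nrow(edges) / (n * (n - 1)) else NA_real_,
    mean_delay_rate = if (length(speeds)) mean(speeds) else NA_real_,
    n_nodes = n, n_edges = nrow(edges),
    adjacency_radius = adjacency_radius
  ), class = "ca_network_metrics")
}

#' @export
print.ca_network_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.3f", v)
  cat("network metrics (", x$n_nodes, " nodes, ", x$n_edges, " edges)\n",
      sep = "")
  cat("  mean correlation, all pairs:      ", fmt(x$mean_corr_all), "\n")
  cat("  mean correlation, adjacent pairs: ", fmt(x$mean_corr_adjacent),
      sprintf(" (<= %g um)\n", x$adjacency_radius))
  cat("  mean connections per cell:        ",
      fmt(x$mean_connections_per_cell), "\n")
  cat("  % of possible connections:        ",
      fmt(x$percent_possible_connections), "\n")
  cat("  mean propagation speed (um/s):    ", fmt(x$mean_delay_rate), "\n")
  invisible(x)
}

#' Correlation as a function of inter-cell distance
#'
#' One point per unordered cell pair (distance, rho), plus a binned summary
#' (median rho per distance bin). Co-located pairs (distance 0) are kept.
#'
#' @param graph a [build_graph()] result (its \code{pairs} table is used).
#' @param bin_width distance bin width, um.
#' @return list with \code{points} (data.frame a, b, distance_um, rho) and
#'   \code{binned} (data.frame bin_lo, bin_hi, bin_mid, median_rho,
#'   n_pairs).
#' @export
correlation_vs_distance <- function(graph, bin_width = 50) {
  stopifnot(inherits(graph, "ca_graph"))
  pts <- graph$pairs[, c("a", "b", "distance_um", "rho")]
  if (!nrow(pts))
    return(list(points = pts,
                binned = data.frame(bin_lo = numeric(0),
                                    bin_hi = numeric(0),
                                    bin_mid = numeric(0),
                                    median_rho = numeric(0),
                                    n_pairs = integer(0))))
  bin <- floor(pts$distance_um / bin_width)
  agg <- tapply(pts$rho, bin, stats::median)
  cnt <- tapply(pts$rho, bin, length)
  lo <- as.numeric(names(agg)) * bin_width
  list(points = pts,
       binned = data.frame(bin_lo = lo, bin_hi = lo + bin_width,
                           bin_mid = lo + bin_width / 2,
                           median_rho = as.numeric(agg),
                           n_pairs = as.integer(cnt)))
}

#' Score an inferred graph against the planted ground truth
#'
#' Edge-set precision, recall and F1 on ordered cell pairs, plus the mean
#' absolute delay error over true-positive edges (inferred lag vs. planted
#' delay). Precision is undefined (NA) for an empty inferred edge set, and
#' recall undefined for an empty truth, rather than coerced to zero.
#'
#' @param graph a [build_graph()] result.
#' @param ground_truth list with \code{positions} and \code{edges}
#'   (src, dst, delay_s), as produced by [simulate_recording()].
#' @return list: \code{precision}, \code{recall}, \code{f1},
#'   \code{delay_error} (s; NA when there are no true positives),
#'   \code{n_true}, \code{n_inferred}, \code{n_tp}.
#' @export
evaluate_recovery <- function(graph, ground_truth) {
  stopifnot(inherits(graph, "ca_graph"))
  truth <- ground_truth$edges
  if (!setequal(graph$nodes$cell_id, ground_truth$positions$cell_id))
    stop("inferred graph and ground truth refer to different cell sets",
         call. = FALSE)
  inf_keys <- paste(graph$edges$src, graph$edges$dst, sep = "->")
  true_keys <- paste(truth$src, truth$dst, sep = "->")
  tp_keys <- intersect(inf_keys, true_keys)
  n_tp <- length(tp_keys)
  precision <- if (length(inf_keys)) n_tp / length(inf_keys) else NA_real_
  recall <- if (length(true_keys)) n_tp / length(true_keys) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall)
  else if (isTRUE(precision == 0) && isTRUE(recall == 0)) 0
  else NA_real_
  delay_error <- NA_real_
  if (n_tp) {
    inferred_lag <- graph$edges$lag_s[match(tp_keys, inf_keys)]
    true_delay <- truth$delay_s[match(tp_keys, true_keys)]
    delay_error <- mean(abs(inferred_lag - true_delay))
  }
  list(precision = precision, recall = recall, f1 = f1,
       delay_error = delay_error, n_true = length(true_keys),
       n_inferred = length(inf_keys), n_tp = n_tp)
}
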