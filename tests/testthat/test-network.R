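make_ts <- function(fmat, fs = 2, field = 420, seed = 1) {
  set.seed(seed)
  n <- nrow(fmat)
  pos <- data.frame(cell_id = paste0("cell_", seq_len(n)),
                    x = runif(n, 0, field), y = runif(n, 0, field))
  trace_set(fmat, fs, positions = pos)
}

test_that("a trace correlates perfectly with itself at lag zero", {
  set.seed(1)
  x <- as.numeric(stats::filter(rnorm(200), rep(0.5, 3), sides = 1))
  x[is.na(x)] <- 0
  lc <- lagged_correlation(x, x, max_lag = 10, sampling_rate = 2)
  expect_equal(lc$rho, 1)
  expect_equal(lc$lag_s, 0)
})

test_that("a pure shift is recovered with the right sign and magnitude", {
  set.seed(2)
  x <- as.numeric(stats::filter(rnorm(400), rep(0.5, 3), sides = 1))
  x[is.na(x)] <- 0
  k <- 3
  y <- c(rep(0, k), x[1:(400 - k)])  # y follows x by 3 frames
  lc <- lagged_correlation(x, y, max_lag = 10, sampling_rate = 2)
  expect_equal(lc$lag_s, 1.5)
  expect_gt(lc$rho, 1 - 1e-6)
  # antisymmetry: swapping the pair negates the lag, keeps rho
  lc2 <- lagged_correlation(y, x, max_lag = 10, sampling_rate = 2)
  expect_equal(lc2$lag_s, -1.5)
  expect_equal(lc2$rho, lc$rho, tolerance = 1e-12)
})

test_that("lagged correlation matches the brute-force oracle to 1e-10", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(c(120, 200), 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- lagged_correlation(a, b, max_lag = 10, sampling_rate = 2)
    ref <- bf_lagged_correlation(a, b, max_lag = 10, sampling_rate = 2)
    expect_equal(got$rho, ref$rho, tolerance = 1e-10)
    expect_equal(got$lag_frames, ref$lag_frames)
    expect_equal(got$rho_zero, ref$rho_zero, tolerance = 1e-10)
  }
})

test_that("degenerate inputs are flagged, not fatal", {
  const <- rep(1, 100)
  x <- rnorm(100)
  lc <- lagged_correlation(const, x, max_lag = 5, sampling_rate = 2)
  expect_true(is.na(lc$rho))
  expect_error(lagged_correlation(x, x[-1], max_lag = 5,
                                  sampling_rate = 2), "equal length")
  expect_error(lagged_correlation(x[1:10], x[1:10], max_lag = 5,
                                  sampling_rate = 2), "max_lag")
})

test_that("identical traces give the degenerate fully-synchronous graph", {
  x <- as.numeric(stats::filter(rnorm(300), rep(0.5, 4), sides = 1))
  x[is.na(x)] <- 0
  ts <- make_ts(rbind(x, x, x))
  g <- build_graph(ts, signal = "raw")
  expect_equal(nrow(g$edges), 6)       # reciprocal pairs on 3 nodes
  expect_true(all(g$edges$lag_s == 0))
  expect_true(all(abs(g$edges$rho - 1) < 1e-12))
  expect_true(all(is.na(g$edges$speed_um_s)))
})

test_that("graph construction on raw traces equals the brute-force oracle", {
  set.seed(4)
  fmat <- matrix(rnorm(10 * 300), nrow = 10)
  # plant a few lagged copies so edges exist
  fmat[2, ] <- c(rep(0, 4), fmat[1, 1:296]) + 0.1 * rnorm(300)
  fmat[5, ] <- c(rep(0, 2), fmat[4, 1:298]) + 0.1 * rnorm(300)
  ts <- make_ts(fmat)
  g <- build_graph(ts, signal = "raw")
  ref <- bf_build_edges(fmat, ts$cell_ids, max_lag = 10, sampling_rate = 2)
  key <- function(d) sort(paste(d$src, d$dst, d$lag_s))
  expect_equal(key(g$edges), key(ref))
  m <- match(paste(g$edges$src, g$edges$dst), paste(ref$src, ref$dst))
  expect_equal(g$edges$rho, ref$rho[m], tolerance = 1e-10)
})

test_that("the rise-signal path equals the oracle applied to the same transform", {
  scn <- scenario(n_cells = 8, duration = 240, seed = 6)
  dff <- compute_dff(simulate_recording(scn)$traces)
  g <- build_graph(dff)   # default signal = "rise"
  r <- rise_signal(dff)
  ref <- bf_build_edges(r$f, dff$cell_ids, max_lag = 10,
                        sampling_rate = 2)
  key <- function(d) sort(paste(d$src, d$dst, round(d$lag_s, 9)))
  expect_equal(key(g$edges), key(ref))
})

test_that("a simulated two-cell chain is recovered with the right lag", {
  scn <- scenario(n_cells = 2, duration = 600, base_event_rate = 1,
                  transmit_probability = 1, delay_jitter_sd = 0,
                  noise_sd = 0.02, silenced_fraction = 0, seed = 8)
  pos <- data.frame(cell_id = c("A", "B"), x = c(100, 140), y = c(100, 100))
  edges <- data.frame(src = "A", dst = "B", distance_um = 40, delay_s = 2)
  ev <- simulate_events(list(positions = pos, edges = edges), scn)
  tr <- render_traces(ev, scn, positions = pos)
  g <- build_graph(compute_dff(tr))
  ab <- g$edges[g$edges$src == "A" & g$edges$dst == "B", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$lag_s, 2, tolerance = 0.5 + 1e-9)   # within one frame
  expect_equal(ab$speed_um_s, 40 / ab$lag_s)
})

test_that("threshold monotonicity: raising the threshold never adds edges", {
  scn <- scenario(n_cells = 10, duration = 300, seed = 10)
  dff <- compute_dff(simulate_recording(scn)$traces)
  thresholds <- c(0.1, 0.3, 0.5, 0.7)
  graphs <- lapply(thresholds, function(th)
    build_graph(dff, edge_threshold = th))
  sizes <- vapply(graphs, function(g) nrow(g$edges), integer(1))
  expect_true(all(diff(sizes) <= 0))
  for (i in 2:length(graphs)) {
    k_hi <- paste(graphs[[i]]$edges$src, graphs[[i]]$edges$dst)
    k_lo <- paste(graphs[[i - 1]]$edges$src, graphs[[i - 1]]$edges$dst)
    expect_true(all(k_hi %in% k_lo))
  }
  # edge-dependent metrics are non-increasing in the threshold
  ms <- lapply(graphs, compute_metrics)
  for (fld in c("mean_connections_per_cell",
                "percent_possible_connections")) {
    vals <- vapply(ms, function(m) m[[fld]], numeric(1))
    expect_true(all(diff(vals) <= 0))
  }
})

test_that("relabeling cells permutes the graph and leaves metrics invariant", {
  scn <- scenario(n_cells = 8, duration = 300, seed = 12)
  dff <- compute_dff(simulate_recording(scn)$traces)
  g <- build_graph(dff)
  perm <- sample(8)
  f2 <- dff$f[perm, , drop = FALSE]
  pos2 <- dff$positions[perm, ]
  ts2 <- trace_set(f2, dff$sampling_rate, positions = pos2,
                   cell_ids = dff$cell_ids[perm])
  g2 <- build_graph(ts2)
  expect_equal(sort(paste(g2$edges$src, g2$edges$dst)),
               sort(paste(g$edges$src, g$edges$dst)))
  m1 <- compute_metrics(g); m2 <- compute_metrics(g2)
  for (fld in c("mean_corr_all", "mean_corr_adjacent",
                "mean_connections_per_cell",
                "percent_possible_connections", "mean_delay_rate"))
    expect_equal(m1[[fld]], m2[[fld]], tolerance = 1e-12)
})

test_that("time reversal flips every edge and preserves rho", {
  # property of the correlation engine itself, so checked on the raw
  # signal: the rise transform is intentionally time-asymmetric (reversal
  # turns concentration increases into decreases)
  scn <- scenario(n_cells = 8, duration = 300, seed = 14,
                  transmit_probability = 0.9)
  dff <- compute_dff(simulate_recording(scn)$traces)
  g <- build_graph(dff, signal = "raw")
  rev_ts <- trace_set(dff$f[, ncol(dff$f):1], dff$sampling_rate,
                      positions = dff$positions, cell_ids = dff$cell_ids)
  g_rev <- build_graph(rev_ts, signal = "raw")
  fwd <- g$edges[g$edges$lag_s > 0, ]
  bwd <- g_rev$edges[g_rev$edges$lag_s > 0, ]
  expect_equal(sort(paste(fwd$src, fwd$dst)),
               sort(paste(bwd$dst, bwd$src)))
  m <- match(paste(fwd$src, fwd$dst), paste(bwd$dst, bwd$src))
  expect_equal(fwd$rho, bwd$rho[m], tolerance = 1e-10)
  expect_equal(fwd$lag_s, bwd$lag_s[m], tolerance = 1e-12)
})

test_that("the five metrics match closed forms on hand-built graphs", {
  # complete zero-lag graph on 4 nodes, rho 0.5 everywhere
  pos <- data.frame(cell_id = paste0("c", 1:4),
                    x = c(0, 50, 0, 50), y = c(0, 0, 50, 50))
  pairs <- t(utils::combn(4, 2))
  g <- structure(list(
    nodes = pos,
    edges = data.frame(
      src = pos$cell_id[c(pairs[, 1], pairs[, 2])],
      dst = pos$cell_id[c(pairs[, 2], pairs[, 1])],
      rho = 0.5, lag_s = 0,
      distance_um = rep(sqrt((pos$x[pairs[, 1]] - pos$x[pairs[, 2]])^2 +
                             (pos$y[pairs[, 1]] - pos$y[pairs[, 2]])^2), 2),
      speed_um_s = NA_real_),
    pairs = data.frame(
      a = pos$cell_id[pairs[, 1]], b = pos$cell_id[pairs[, 2]],
      rho = 0.5, lag_s = 0,
      distance_um = sqrt((pos$x[pairs[, 1]] - pos$x[pairs[, 2]])^2 +
                         (pos$y[pairs[, 1]] - pos$y[pairs[, 2]])^2)),
    params = list(edge_threshold = 0.3)), class = "ca_graph")
  m <- compute_metrics(g, adjacency_radius = 100)
  expect_equal(m$mean_corr_all, 0.5)
  expect_equal(m$mean_corr_adjacent, 0.5)
  expect_equal(m$mean_connections_per_cell, 6)   # 12 directed edges / 4 * 2
  expect_equal(m$percent_possible_connections, 100)
  expect_true(is.na(m$mean_delay_rate))

  # empty graph
  g0 <- g
  g0$edges <- g$edges[0, ]
  g0$pairs <- g$pairs[0, ]
  m0 <- compute_metrics(g0)
  expect_equal(m0$mean_connections_per_cell, 0)
  expect_equal(m0$percent_possible_connections, 0)
  expect_true(is.na(m0$mean_corr_all))

  # 5-node graph, 2 tabulated edges
  pos5 <- data.frame(cell_id = paste0("c", 1:5),
                     x = c(0, 30, 200, 0, 300), y = c(0, 40, 0, 90, 300))
  dist_12 <- 50; dist_35 <- sqrt(100^2 + 300^2)
  gh <- structure(list(
    nodes = pos5,
    edges = data.frame(src = c("c1", "c3"), dst = c("c2", "c5"),
                       rho = c(0.8, 0.4), lag_s = c(2.5, 0),
                       distance_um = c(dist_12, dist_35),
                       speed_um_s = c(dist_12 / 2.5, NA)),
    pairs = data.frame(a = c("c1", "c3", "c1"), b = c("c2", "c5", "c4"),
                       rho = c(0.8, 0.4, 0.1), lag_s = c(2.5, 0, 1),
                       distance_um = c(dist_12, dist_35, 90)),
    params = list(edge_threshold = 0.3)), class = "ca_graph")
  mh <- compute_metrics(gh, adjacency_radius = 100)
  expect_equal(mh$mean_corr_all, mean(c(0.8, 0.4, 0.1)))
  expect_equal(mh$mean_corr_adjacent, mean(c(0.8, 0.1)))
  expect_equal(mh$mean_connections_per_cell, 2 * 2 / 5)
  expect_equal(mh$percent_possible_connections, 100 * 2 / 20)
  expect_equal(mh$mean_delay_rate, 50 / 2.5)
})

test_that("correlation-vs-distance keeps every pair including colocated ones", {
  f <- matrix(rnorm(2 * 100), nrow = 2)
  ts <- trace_set(f, 2, positions = data.frame(
    cell_id = c("a", "b"), x = c(10, 10), y = c(20, 20)))
  g <- build_graph(ts, signal = "raw")
  dc <- correlation_vs_distance(g)
  expect_equal(nrow(dc$points), 1)
  expect_equal(dc$points$distance_um, 0)
  expect_equal(dc$binned$n_pairs, 1L)
})

test_that("recovery scoring follows the stated conventions", {
  pos <- data.frame(cell_id = c("a", "b", "c"), x = 1:3, y = 1:3)
  truth <- list(positions = pos,
                edges = data.frame(src = c("a", "b"), dst = c("b", "c"),
                                   delay_s = c(2, 3),
                                   distance_um = c(10, 10)))
  g_perfect <- structure(list(
    nodes = pos,
    edges = data.frame(src = c("a", "b"), dst = c("b", "c"),
                       rho = 0.9, lag_s = c(2, 3), distance_um = 10,
                       speed_um_s = 5),
    pairs = data.frame(), params = list()), class = "ca_graph")
  r <- evaluate_recovery(g_perfect, truth)
  expect_equal(r$precision, 1); expect_equal(r$recall, 1)
  expect_equal(r$f1, 1); expect_equal(r$delay_error, 0)

  g_empty <- g_perfect
  g_empty$edges <- g_perfect$edges[0, ]
  r0 <- evaluate_recovery(g_empty, truth)
  expect_equal(r0$recall, 0)
  expect_true(is.na(r0$precision))

  # random graphs vs brute-force set arithmetic
  set.seed(20)
  ids <- letters[1:6]
  pos6 <- data.frame(cell_id = ids, x = 1:6, y = 1:6)
  for (rep in 1:5) {
    pick <- function(k) {
      pr <- expand.grid(src = ids, dst = ids,
                        stringsAsFactors = FALSE)
      pr <- pr[pr$src != pr$dst, ]
      pr[sample(nrow(pr), k), ]
    }
    te <- pick(8); te$delay_s <- runif(8, 1, 5); te$distance_um <- 10
    ie <- pick(6); ie$rho <- 0.5
    ie$lag_s <- runif(6, 1, 5); ie$distance_um <- 10; ie$speed_um_s <- 1
    gg <- structure(list(nodes = pos6, edges = ie, pairs = data.frame(),
                         params = list()), class = "ca_graph")
    r <- evaluate_recovery(gg, list(positions = pos6, edges = te))
    tp <- length(intersect(paste(ie$src, ie$dst), paste(te$src, te$dst)))
    expect_equal(r$n_tp, tp)
    expect_equal(r$precision, tp / 6)
    expect_equal(r$recall, tp / 8)
    if (tp > 0)
      expect_equal(r$f1, 2 * (tp / 6) * (tp / 8) / (tp / 6 + tp / 8))
  }

  # mismatched cell sets are an error
  pos_bad <- data.frame(cell_id = c("x", "y", "z"), x = 1:3, y = 1:3)
  expect_error(evaluate_recovery(g_perfect,
                                 list(positions = pos_bad,
                                      edges = truth$edges)),
               "different cell sets")
})
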