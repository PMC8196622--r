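# Independent reference implementations used to cross-check the package.
# These are deliberately naive (double loops, explicit sums) and share no
# code with the implementation under test.

# Pearson correlation from explicit sums
bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# max lagged correlation by brute force; same tie-break contract as the
# package (smallest |lag| first, then negative lag), realized by explicit
# candidate sorting rather than search order
bf_lagged_correlation <- function(a, b, max_lag, sampling_rate) {
  L <- round(max_lag * sampling_rate)
  n <- length(a)
  lags <- -L:L
  rhos <- sapply(lags, function(k) {
    if (k >= 0) {
      bf_pearson(a[1:(n - k)], b[(1 + k):n])
    } else {
      bf_pearson(a[(1 - k):n], b[1:(n + k)])
    }
  })
  ord <- order(-rhos, abs(lags), lags)
  best <- ord[1]
  list(rho = rhos[best], lag_frames = lags[best],
       lag_s = lags[best] / sampling_rate,
       rho_zero = rhos[lags == 0])
}

# naive graph builder mirroring the published construction rule: edge when
# max lagged rho > threshold, oriented by lag; zero-lag pairs reciprocal.
# Applies the same lag-significance margin as the package.
bf_build_edges <- function(fmat, ids, max_lag, sampling_rate,
                           threshold = 0.3, lag_significance = 0.05) {
  n <- nrow(fmat)
  edges <- data.frame(src = character(0), dst = character(0),
                      rho = numeric(0), lag_s = numeric(0))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      lc <- bf_lagged_correlation(fmat[i, ], fmat[j, ], max_lag,
                                  sampling_rate)
      lag <- lc$lag_s
      if (lag != 0 && (lc$rho - lc$rho_zero) < lag_significance) lag <- 0
      if (lc$rho > threshold) {
        if (lag > 0) {
          edges <- rbind(edges, data.frame(src = ids[i], dst = ids[j],
                                           rho = lc$rho, lag_s = lag))
        } else if (lag < 0) {
          edges <- rbind(edges, data.frame(src = ids[j], dst = ids[i],
                                           rho = lc$rho, lag_s = -lag))
        } else {
          edges <- rbind(edges,
                         data.frame(src = c(ids[i], ids[j]),
                                    dst = c(ids[j], ids[i]),
                                    rho = lc$rho, lag_s = 0))
        }
      }
    }
  }
  edges
}

# exact two-sided Mann-Whitney p-value by full rank enumeration (small n)
bf_mann_whitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  obs_u <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ranks <- rank(pooled)
  us <- apply(combos, 2, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(obs_u - mu) - 1e-12)
}

# tiny deterministic trace builders
boxcar_trace <- function(n_frames, from_s, to_s, sampling_rate, height) {
  tt <- (seq_len(n_frames) - 1) / sampling_rate
  ifelse(tt >= from_s & tt < to_s, height, 0)
}

# unique temp path helper
tmp_path <- function(name) {
  file.path(tempdir(), paste0(basename(tempfile("t")), "-", name))
}
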