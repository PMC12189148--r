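# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# Causal windowed percentile: k-th smallest of the trailing window
# (k = ceiling(p * n)), clamped to the current value.
oracle_slow_envelope <- function(x, window, p) {
  if (is.matrix(x)) return(apply(x, 2, oracle_slow_envelope, window, p))
  out <- numeric(length(x))
  for (t in seq_along(x)) {
    win <- x[max(1, t - window + 1):t]
    q <- sort(win)[ceiling(p * length(win))]
    out[t] <- min(q, x[t])
  }
  out
}

# 2D histogram binning by explicit edge scan; last bin closed.
oracle_climate_bins <- function(p, e, n_bins) {
  edges <- seq(-1, 1, length.out = n_bins + 1)
  locate <- function(v) {
    for (i in seq_len(n_bins)) {
      hi_ok <- if (i == n_bins) v <= edges[i + 1] else v < edges[i + 1]
      if (v >= edges[i] && hi_ok) return(i)
    }
    NA_integer_
  }
  counts <- matrix(0, n_bins, n_bins)
  for (s in seq_along(p)) {
    i <- locate(p[s]); j <- locate(e[s])
    counts[i, j] <- counts[i, j] + 1
  }
  counts / length(p)
}

# Exceedance by explicit counting (strict inequality).
oracle_exceedance <- function(aud, thresholds) {
  vapply(thresholds, function(x) {
    n <- 0
    for (a in aud) if (a > x) n <- n + 1
    n / length(aud)
  }, numeric(1))
}

# Pooled band audibility straight from the cell matrix.
oracle_band_audibility <- function(m, cf, band, t, scope, frame_rate) {
  chans <- which(cf >= band[1] & cf < band[2])
  f1 <- max(1, (t - scope) * frame_rate + 1)
  f2 <- min(nrow(m), t * frame_rate)
  per_frame <- apply(m[f1:f2, chans, drop = FALSE], 1, max)
  act <- per_frame[per_frame > 0]
  if (!length(act)) return(0)
  unname(quantile(act, 0.9, type = 7))
}
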