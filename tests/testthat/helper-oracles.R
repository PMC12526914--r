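# Oracles and fixture builders shared across the suite. All fixtures are
# generated in code; nothing is read from disk.

# Noise-free series whose per-replicate fractions lie exactly on the
# n-step curve (counts are kept real-valued so fractions are exact).
exact_series <- function(n_steps, k, c_max,
                         timepoints = c(0, 5, 10, 30, 60, 90, 120, 150, 180),
                         n_reps = 3, n_dna = 3000) {
  f <- assembly_curve(timepoints, n_steps, k, c_max)
  as_assembly_series(data.frame(
    time_min = rep(timepoints, n_reps),
    replicate = rep(seq_len(n_reps), each = length(timepoints)),
    n_dna = n_dna,
    n_colocalized = rep(f, n_reps) * n_dna
  ))
}

# Rate constant such that the n-step curve with plateau c_max crosses
# `threshold` at t = t30. Uses the Erlang/gamma quantile as an
# independent closed form.
calibrate_k <- function(n_steps, c_max, t30, threshold = 0.30) {
  stats::qgamma(threshold / c_max, shape = n_steps) / t30
}

# Exhaustive-search changepoint oracle: all placements of 0, 1, or 2
# changepoints, minimizing RSS + m * penalty * sigma2 * log(n) with the
# same robust noise estimate as the implementation under test. Ties are
# broken toward fewer steps (search order), then lexicographically.
oracle_steps <- function(x, penalty = 3) {
  n <- length(x)
  sigma2 <- (stats::mad(diff(x)) / sqrt(2))^2
  pen <- penalty * sigma2 * log(n)
  rss_seg <- function(a, b) {
    v <- x[a:b]
    sum((v - mean(v))^2)
  }
  best <- list(m = 0L, cost = rss_seg(1, n), frames = integer(0))
  for (c1 in 2:n) {
    cost <- rss_seg(1, c1 - 1) + rss_seg(c1, n) + pen
    if (cost < best$cost - 1e-9) {
      best <- list(m = 1L, cost = cost, frames = c1)
    }
  }
  for (c1 in 2:(n - 1)) {
    for (c2 in (c1 + 1):n) {
      cost <- rss_seg(1, c1 - 1) + rss_seg(c1, c2 - 1) + rss_seg(c2, n) +
        2 * pen
      if (cost < best$cost - 1e-9) {
        best <- list(m = 2L, cost = cost, frames = c(c1, c2))
      }
    }
  }
  best
}

# Precision/recall of detected spots against simulator ground truth,
# restricted to the detectable region (outside the border exclusion).
detection_scores <- function(truth, detected, field_size_px, psf_sigma_px,
                             match_radius = 1) {
  b <- ceiling(3 * psf_sigma_px)
  lim <- field_size_px - 1 - b
  inb <- truth$x_px >= b & truth$x_px <= lim &
    truth$y_px >= b & truth$y_px <= lim
  tr <- truth[inb, , drop = FALSE]
  m <- match_spots(tr, detected, match_radius)
  list(
    precision = if (nrow(detected)) nrow(m) / nrow(detected) else NA_real_,
    recall = if (nrow(tr)) nrow(m) / nrow(tr) else NA_real_,
    rms = if (nrow(m)) sqrt(mean(m$distance_px^2)) else NA_real_
  )
}
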