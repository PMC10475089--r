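# Shared fixtures and independent oracles used across the suite.

# Brute-force O(n^2) TAMSD: explicit double loop over all pairs.
tamsd_bruteforce <- function(track, frame_interval = 0.1) {
  x <- track$x_nm / 1000
  y <- track$y_nm / 1000
  n <- length(x)
  lags <- seq_len(n - 1)
  vals <- numeric(n - 1)
  for (k in lags) {
    sq <- numeric(n - k)
    for (i in 1:(n - k)) {
      sq[i] <- (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    }
    vals[k] <- mean(sq)
  }
  data.frame(lag_s = lags * frame_interval, tamsd_um2 = vals, n_pairs = n - lags)
}

# Brute-force gated assignment: enumerate every one-to-one matching of
# rows to columns, keep those using only gated pairs, and pick the one
# with (most links, then least total distance). Feasible for n, m <= 6.
assignment_bruteforce <- function(d, gate) {
  nr <- nrow(d); nc <- ncol(d)
  best <- list(nlink = -1L, total = Inf, pairs = cbind(integer(0), integer(0)))
  cols <- seq_len(nc)
  # enumerate subsets of rows and injective maps to columns
  rec <- function(i, used, pairs, total) {
    if (i > nr) {
      nl <- nrow(pairs)
      if (nl > best$nlink || (nl == best$nlink && total < best$total)) {
        best <<- list(nlink = nl, total = total, pairs = pairs)
      }
      return(invisible())
    }
    rec(i + 1L, used, pairs, total) # leave row i unmatched
    for (j in setdiff(cols, used)) {
      if (d[i, j] <= gate) {
        rec(i + 1L, c(used, j), rbind(pairs, c(i, j)), total + d[i, j])
      }
    }
  }
  rec(1L, integer(0), cbind(integer(0), integer(0)), 0)
  best$pairs
}

# Geometric track lengths with the configured mean, conditioned on a
# retention window (same law as the simulator's on-times).
sample_track_lengths <- function(n, mean_frames = 8, range = c(4, 12)) {
  out <- integer(0)
  while (length(out) < n) {
    l <- rgeom(2 * n, prob = 1 / mean_frames) + 1L
    l <- l[l >= range[1] & l <= range[2]]
    out <- c(out, l)
  }
  out[seq_len(n)]
}

# Monte-Carlo oracle for the bounding-box immobility statistic: the
# probability that a planar random walk (per-axis step SD from D) plus
# localization noise stays inside a box_size x box_size bounding box,
# under a given track-length law.
bbox_immobile_rate_mc <- function(D, sigma_loc, lengths, box_size = 160,
                                  frame_interval = 0.1) {
  s <- sqrt(2 * D * frame_interval) * 1000
  hits <- vapply(lengths, function(n) {
    x <- cumsum(c(0, rnorm(n - 1, 0, s))) + rnorm(n, 0, sigma_loc)
    y <- cumsum(c(0, rnorm(n - 1, 0, s))) + rnorm(n, 0, sigma_loc)
    diff(range(x)) < box_size && diff(range(y)) < box_size
  }, logical(1))
  mean(hits)
}

# One rendered frame with emitters at known positions, returned with
# the ground truth (used by detection/fitting tests).
render_test_frame <- function(positions_nm, dim = c(32, 32), photons = 5000,
                              background = 10, psf_sigma = 130, seed = 1) {
  loc <- data.frame(frame = 1L,
                    x_nm = positions_nm[, 1], y_nm = positions_nm[, 2])
  render_movie(loc, n_frames = 1, dim = dim, psf_sigma = psf_sigma,
               photons = photons, background = background, seed = seed)[[1]]
}
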