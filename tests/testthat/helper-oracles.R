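# Independent oracles used across test files.  These deliberately avoid the
# package's own code paths wherever the quantity can be recomputed from
# first principles.

# Brute-force raster line: for each step along the major axis, place the
# minor coordinate at the nearest raster row/column (ties rounded half up),
# endpoints excluded.  Endpoints are canonicalized lexicographically first.
brute_line <- function(m, n) {
  if (m[1] > n[1] || (m[1] == n[1] && m[2] > n[2])) { tmp <- m; m <- n; n <- tmp }
  d <- n - m
  steps <- max(abs(d))
  if (steps <= 1) return(matrix(integer(0), 0, 2))
  major <- which.max(abs(d))
  minor <- 3 - major
  out <- matrix(0L, steps - 1L, 2L)
  for (i in seq_len(steps - 1L)) {
    out[i, major] <- m[major] + sign(d[major]) * i
    out[i, minor] <- as.integer(floor(m[minor] + i * d[minor] / steps + 0.5))
  }
  out
}

# Scalar transcription of the coupling weight: product over intermediate
# raster points of the edge attenuation, divided by the Euclidean distance.
oracle_coupling <- function(m, n, edges, grad, t_b) {
  pts <- brute_line(m, n)
  g <- 1
  if (nrow(pts) > 0) {
    for (i in seq_len(nrow(pts))) {
      if (edges[pts[i, 1], pts[i, 2]])
        g <- g * (1 - t_b) * (1 - grad[pts[i, 1], pts[i, 2]])
    }
  }
  g / sqrt(sum((m - n)^2))
}

# Scalar transcription of the per-pixel loss: exponential fidelity plus the
# mean-field smoothness sum, written out loop by loop.
oracle_loss <- function(qw, curves, tvals, observed, nb_spectra, gweights) {
  C <- ncol(curves)
  fid <- 0
  for (ch in seq_len(C)) {
    pred <- 0
    for (i in seq_along(tvals)) pred <- pred + qw[i] * curves[i, ch] * tvals[i]
    fid <- fid + exp(abs(pred - observed[ch]))
  }
  fid <- fid - C
  sm <- 0
  N <- length(gweights)
  if (N > 0) {
    for (j in seq_len(N)) {
      acc <- 0
      for (i in seq_along(tvals)) acc <- acc + (tvals[i] - nb_spectra[[j]][i])^2
      sm <- sm + gweights[j] * acc
    }
    sm <- sm / N
  }
  fid + sm
}

# small shared fixtures
tiny_grid <- function(w = 9, a = 450, b = 775) {
  wavelength_grid(seq(a, b, length.out = w))
}

tiny_light <- function(grid = tiny_grid(), white = 0.75) {
  rgb_light(grid, white = white)
}

# boundary pixels of a label map (any 4-neighbour with a different label)
boundary_mask <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
          labels[rr, cc] != labels[r, c]) out[r, c] <- TRUE
    }
  }
  out
}
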