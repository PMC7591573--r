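#' Grayscale projection on the first principal component
#'
#' Canny edge detection needs a single-channel image.  Rather than a fixed
#' luminance formula, the channel vectors of all pixels are projected onto
#' the first principal axis of their covariance, which retains the maximal
#' variance (information) of the multi-channel data, and the projection is
#' shifted/scaled to `[0, 1]`.
#'
#' @param image a [channel_image()] with at least 2 channels.
#' @return Numeric `h x w` matrix in `[0, 1]`.
#' @export
grayscale_first_pc <- function(image) {
  stopifnot(inherits(image, "channel_image"))
  d <- dim(image$values)
  if (d[3] < 2) stop("PCA grayscale needs at least 2 channels")
  X <- matrix(image$values, d[1] * d[2], d[3])
  if (all(apply(X, 2, function(v) diff(range(v))) < 1e-12)) {
    warning("constant image: zero covariance, returning a zero image")
    return(matrix(0, d[1], d[2]))
  }
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  proj <- p$x[, 1]
  # orient so that "brighter" pixels score higher (skip when overall
  # brightness is constant and the correlation is undefined)
  ori <- suppressWarnings(stats::cor(proj, rowMeans(X)))
  if (!is.na(ori) && ori < 0) proj <- -proj
  rng <- range(proj)
  matrix((proj - rng[1]) / max(rng[2] - rng[1], 1e-300), d[1], d[2])
}

#' Central-difference gradient magnitude
#'
#' Per-axis central differences (one-sided at the borders), merged by the
#' Euclidean norm and max-normalized to `[0, 1]`.
#'
#' @param gray numeric `h x w` matrix.
#' @param normalize max-normalize the result (default `TRUE`).
#' @return Numeric `h x w` matrix (a gradient field).
#' @export
image_gradient <- function(gray, normalize = TRUE) {
  stopifnot(is.matrix(gray))
  gx <- axis_diff(gray, 2L)
  gy <- axis_diff(gray, 1L)
  g <- sqrt(gx^2 + gy^2)
  if (normalize && max(g) > 0) g <- g / max(g)
  g
}

# central differences along an axis with one-sided borders; unit pixel pitch
axis_diff <- function(m, axis) {
  n <- dim(m)[axis]
  if (n < 2) return(m * 0)
  idx_lo <- c(1L, seq_len(n - 1L))
  idx_hi <- c(seq(2L, n), n)
  denom <- (idx_hi - idx_lo)
  if (axis == 1L) {
    (m[idx_hi, , drop = FALSE] - m[idx_lo, , drop = FALSE]) / denom
  } else {
    sweep(m[, idx_hi, drop = FALSE] - m[, idx_lo, drop = FALSE], 2, denom, `/`)
  }
}

#' Spectral dissimilarity gradient
#'
#' From the second mean-field iteration on, the edge evidence comes from the
#' evolving spectral field itself rather than from the raw image.  For each
#' pixel the two flanking spectra along an axis are compared by their
#' zero-lag normalized cross-correlation `rho` (a cosine similarity); the
#' per-axis dissimilarity is `(1 - rho)/2 in [0, 1]` so that larger values
#' mean "more discontinuous", making it a drop-in replacement for the image
#' gradient.  Axes are merged by the Euclidean norm and the result is
#' max-normalized.  Setting `complement = FALSE` returns the raw correlation
#' (clamped to `[0, 1]`) instead of its complement.
#'
#' @param field a [transparency_field()].
#' @param complement use `(1 - rho)/2` (default) rather than `rho`.
#' @return Numeric `h x w` gradient field in `[0, 1]`.
#' @export
spectral_gradient <- function(field, complement = TRUE) {
  stopifnot(inherits(field, "transparency_field"))
  d <- dim(field$values)
  flat <- matrix(field$values, d[1] * d[2], d[3])
  norms <- sqrt(rowSums(flat^2))
  rho_axis <- function(axis) {
    n <- d[axis]
    lo <- c(1L, seq_len(n - 1L)) # replicate at the borders
    hi <- c(seq_len(n)[-1L], n)
    if (axis == 1L) {
      ia <- as.vector(outer(lo, (seq_len(d[2]) - 1L) * d[1], `+`))
      ib <- as.vector(outer(hi, (seq_len(d[2]) - 1L) * d[1], `+`))
    } else {
      ia <- as.vector(outer(seq_len(d[1]), (lo - 1L) * d[1], `+`))
      ib <- as.vector(outer(seq_len(d[1]), (hi - 1L) * d[1], `+`))
    }
    num <- rowSums(flat[ia, , drop = FALSE] * flat[ib, , drop = FALSE])
    den <- norms[ia] * norms[ib]
    rho <- ifelse(den > 0, num / pmax(den, 1e-300), 1) # no spectrum: no edge
    matrix(pmin(pmax(rho, -1), 1), d[1], d[2])
  }
  rho_y <- rho_axis(1L)
  rho_x <- rho_axis(2L)
  if (complement) {
    g <- sqrt(((1 - rho_y) / 2)^2 + ((1 - rho_x) / 2)^2)
  } else {
    g <- sqrt(pmax(rho_y, 0)^2 + pmax(rho_x, 0)^2)
  }
  g[g < 1e-10] <- 0 # floating-point noise must not survive max-normalization
  if (max(g) > 0) g <- g / max(g)
  g
}

#' Canny edge detection on a gradient field
#'
#' The gradient matrix is smoothed by a 2-D Gaussian (`sigma = 0.5` by
#' default), then passed through the Canny chain: Sobel derivatives,
#' non-maximum suppression along the quantized gradient direction, and
#' double-threshold hysteresis.  The hysteresis thresholds are derived from
#' the data: the high threshold is the `high_quantile` quantile of the
#' non-zero suppressed magnitudes and the low threshold is
#' `low_ratio * high`.
#'
#' @param grad numeric `h x w` gradient field.
#' @param sigma Gaussian pre-smoothing standard deviation in pixels.
#' @param high_quantile quantile defining the strong-edge threshold.
#' @param low_ratio low/high threshold ratio.
#' @return An object of class `edge_state`: list with the binary `edges`
#'   matrix, the input `grad`, and the thresholds used.
#' @export
detect_edges <- function(grad, sigma = 0.5, high_quantile = 0.9,
                         low_ratio = 0.4) {
  stopifnot(is.matrix(grad))
  sm <- gauss_smooth(grad, sigma)
  gx <- conv_sep(sm, c(-1, 0, 1) / 2, c(1, 2, 1) / 4) # Sobel-like
  gy <- conv_sep(sm, c(1, 2, 1) / 4, c(-1, 0, 1) / 2)
  mag <- sqrt(gx^2 + gy^2)
  nms <- nonmax_suppress(mag, gx, gy)
  nz <- nms[nms > 0]
  if (length(nz) == 0) {
    edges <- matrix(FALSE, nrow(grad), ncol(grad))
    return(structure(list(edges = edges, grad = grad,
                          high = NA_real_, low = NA_real_),
                     class = "edge_state"))
  }
  high <- as.numeric(quantile(nz, high_quantile, names = FALSE))
  low <- low_ratio * high
  strong <- nms >= high & nms > 0
  weak <- nms >= low & nms > 0
  edges <- hysteresis(strong, weak)
  structure(list(edges = edges, grad = grad, high = high, low = low),
            class = "edge_state")
}

gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_sep(m, k, k)
}

# separable correlation with replicate padding; kx along columns, ky along rows
conv_sep <- function(m, kx, ky) {
  conv1 <- function(mm, k, axis) {
    r <- (length(k) - 1L) %/% 2L
    n <- dim(mm)[axis]
    out <- mm * 0
    for (j in seq_along(k)) {
      off <- j - 1L - r
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[j] * (if (axis == 1L) mm[idx, , drop = FALSE]
                           else mm[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(m, kx, 2L), ky, 1L)
}

nonmax_suppress <- function(mag, gx, gy) {
  h <- nrow(mag); w <- ncol(mag)
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4 # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mag
  out <- matrix(0, h, w)
  rows <- 2:(h + 1L); cols <- 2:(w + 1L)
  for (s in 0:3) {
    o <- offs[[s + 1L]]
    n1 <- pad[rows + o[1], cols + o[2], drop = FALSE]
    n2 <- pad[rows - o[1], cols - o[2], drop = FALSE]
    keep <- sector == s & mag >= n1 & mag >= n2
    out[keep] <- mag[keep]
  }
  out
}

hysteresis <- function(strong, weak) {
  cur <- strong
  repeat {
    grown <- dilate8(cur) & weak
    new <- grown | cur
    if (all(new == cur)) break
    cur <- new
  }
  cur
}

dilate8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  out <- matrix(FALSE, h, w)
  for (dy in -1:1) for (dx in -1:1)
    out <- out | pad[2:(h + 1L) + dy, 2:(w + 1L) + dx, drop = FALSE]
  out
}

#' Bresenham raster line between two pixels
#'
#' Returns the intermediate raster points strictly between `m` and `n`
#' (endpoints excluded) on the Bresenham rasterization of the segment.
#' Endpoints are canonicalized (lexicographic order) before rasterizing so
#' the set is symmetric under endpoint swap.  Ties between the two nearest
#' raster rows/columns are broken upward (round half up along the minor
#' axis, in canonical orientation).
#'
#' @param m,n integer `(row, col)` coordinates, `m != n`.
#' @return Integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
bresenham_line <- function(m, n) {
  m <- as.integer(m); n <- as.integer(n)
  stopifnot(length(m) == 2, length(n) == 2)
  if (all(m == n)) stop("endpoints must differ")
  # canonical order: smaller (row, col) first
  if (m[1] > n[1] || (m[1] == n[1] && m[2] > n[2])) { tmp <- m; m <- n; n <- tmp }
  d <- n - m
  steps <- max(abs(d))
  if (steps <= 1) return(matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("row", "col"))))
  major <- which.max(abs(d))
  minor <- 3L - major
  s_major <- sign(d[major])
  pts <- matrix(0L, steps - 1L, 2L, dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(steps - 1L)) {
    a <- m[major] + s_major * i
    # exact rational rounding, half up: floor(x + 1/2) with x = m_minor + i*d_minor/steps
    num <- 2L * (m[minor] * steps + i * d[minor]) + steps
    b <- num %/% (2L * steps)
    pts[i, major] <- a
    pts[i, minor] <- b
  }
  pts
}

#' Pairwise discontinuousness weight
#'
#' The coupling weight between two neighbouring pixels, damping the spectral
#' smoothness penalty across detected edges:
#' `G_mn = (1 / L_mn) * prod_k [ 1 if not edge(k); (1 - T_b) (1 - D_k) if edge(k) ]`
#' where the product runs over the Bresenham points strictly between `m` and
#' `n`, `L_mn` is their Euclidean distance, `D_k` the normalized gradient
#' magnitude, and `T_b` the edge bias (default 0.9).  Immediate 4- or
#' 8-neighbours have no intermediate points, so the product is empty and
#' `G_mn = 1 / L_mn`.
#'
#' @param m,n integer `(row, col)` coordinates.
#' @param edges an `edge_state` (or a logical matrix).
#' @param grad numeric gradient field matrix in `[0, 1]`.
#' @param t_b edge bias parameter in `[0, 1)`.
#' @return Scalar weight in `[0, 1 / L_mn]`.
#' @export
coupling_weight <- function(m, n, edges, grad, t_b = 0.9) {
  e <- if (inherits(edges, "edge_state")) edges$edges else edges
  L <- sqrt(sum((as.numeric(m) - as.numeric(n))^2))
  pts <- bresenham_line(m, n)
  g <- 1
  if (nrow(pts) > 0) {
    for (i in seq_len(nrow(pts))) {
      r <- pts[i, 1]; c <- pts[i, 2]
      if (e[r, c]) g <- g * (1 - t_b) * (1 - grad[r, c])
    }
  }
  g / L
}

#' Neighbourhood coupling weights for a whole image
#'
#' Builds, for every pixel, the set of neighbours within Euclidean distance
#' `t_ed` and the coupling weight to each.  Weights are stored per relative
#' offset as full matrices (`NA` where the neighbour falls outside the
#' image), and are symmetric by construction: the weight between a pixel and
#' its neighbour does not depend on which one is taken as origin.
#'
#' @param dims integer `(h, w)` image size.
#' @param edges an `edge_state` (or logical matrix), same size.
#' @param grad gradient field matrix, same size.
#' @param t_ed neighbourhood radius in pixels (default 1).
#' @param t_b edge bias (default 0.9).
#' @return An object of class `coupling_weights`: list with `offsets`
#'   (`K x 2` integer matrix of `(drow, dcol)`), `weights` (list of `K`
#'   `h x w` matrices), and the parameters.
#' @export
build_couplings <- function(dims, edges, grad, t_ed = 1, t_b = 0.9) {
  e <- if (inherits(edges, "edge_state")) edges$edges else edges
  h <- dims[1]; w <- dims[2]
  r <- floor(t_ed)
  offs <- expand.grid(drow = -r:r, dcol = -r:r)
  dist <- sqrt(offs$drow^2 + offs$dcol^2)
  keep <- dist > 0 & dist <= t_ed + 1e-12
  offs <- as.matrix(offs[keep, , drop = FALSE])
  dist <- dist[keep]
  weights <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    # Bresenham intermediate points, as offsets from the origin pixel, are
    # translation invariant for a fixed neighbour offset (the internal
    # endpoint canonicalization keeps them consistent under sign flips), so
    # they are computed once per offset
    rel <- bresenham_line(c(0L, 0L), o)
    gmat <- matrix(1, h, w)
    if (nrow(rel) > 0) {
      att <- ifelse(e, (1 - t_b) * (1 - grad), 1)
      for (i in seq_len(nrow(rel)))
        gmat <- gmat * shift_matrix(att, rel[i, 1], rel[i, 2])
    }
    gmat <- gmat / dist[k]
    # invalidate out-of-bounds neighbours
    rows <- seq_len(h) + o[1]
    cols <- seq_len(w) + o[2]
    gmat[rows < 1 | rows > h, ] <- NA
    gmat[, cols < 1 | cols > w] <- NA
    weights[[k]] <- gmat
  }
  structure(list(offsets = offs, weights = weights, t_ed = t_ed, t_b = t_b,
                 dims = c(h, w)),
            class = "coupling_weights")
}

# value at (r + dr, c + dc), replicate 1 outside (unused entries are masked)
shift_matrix <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  rows <- pmin(pmax(seq_len(h) + dr, 1L), h)
  cols <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[rows, cols, drop = FALSE]
}

#' @rdname build_couplings
#' @param couplings a `coupling_weights` object.
#' @param m integer `(row, col)` pixel.
#' @return `pixel_neighbors()` returns, for one pixel, a list with integer
#'   matrix `coords` (neighbours inside the image) and numeric `weights`.
#' @export
pixel_neighbors <- function(couplings, m) {
  h <- couplings$dims[1]; w <- couplings$dims[2]
  offs <- couplings$offsets
  rows <- m[1] + offs[, 1]
  cols <- m[2] + offs[, 2]
  ok <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  gw <- vapply(which(ok), function(k) couplings$weights[[k]][m[1], m[2]],
               numeric(1))
  list(coords = cbind(row = rows[ok], col = cols[ok]), weights = gw)
}
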