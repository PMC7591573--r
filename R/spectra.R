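#' Wavelength grid
#'
#' The ordered set of discrete wavelengths shared by every spectrum in a
#' reconstruction.  The default grid has 48 points spanning 450--775 nm,
#' matching the passband of a bright-field system fitted with a 450 nm
#' UV long-pass and a 775 nm IR short-pass filter.
#'
#' @param wavelengths strictly increasing numeric vector of wavelengths (nm),
#'   length at least 3.
#' @return An object of class `wavelength_grid` (a numeric vector).
#' @export
wavelength_grid <- function(wavelengths) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 3)
    stop("a wavelength grid needs at least 3 points")
  if (any(!is.finite(wavelengths)))
    stop("wavelengths must be finite")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(wavelengths, class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @param w number of grid points.
#' @param lambda_min,lambda_max span of the grid in nm.
#' @export
default_grid <- function(w = 48, lambda_min = 450, lambda_max = 775) {
  wavelength_grid(seq(lambda_min, lambda_max, length.out = w))
}

grid_equal <- function(a, b) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) < 1e-9)
}

#' Quadrature weights on a wavelength grid
#'
#' Composite-Simpson weights for the spectral integrals of the forward model.
#' With an even number of intervals the weights are pure composite Simpson
#' (exact for cubics).  With an odd interval count -- as for the default
#' 48-point grid -- Simpson covers the first even block of intervals and the
#' last interval is closed with a trapezoid.  A pure trapezoid rule is
#' available as a fallback.
#'
#' @param grid a [wavelength_grid()].
#' @param method `"simpson"` (default) or `"trapezoid"`.
#' @return Numeric vector of weights `q` such that `sum(q * f)` approximates
#'   the integral of `f` over the grid.
#' @export
quad_weights <- function(grid, method = c("simpson", "trapezoid")) {
  method <- match.arg(method)
  x <- as.numeric(grid)
  n <- length(x)
  h <- diff(x)
  trap <- function(idx_from, idx_to) {
    w <- numeric(n)
    for (i in seq(idx_from, idx_to - 1L)) {
      w[i] <- w[i] + h[i] / 2
      w[i + 1L] <- w[i + 1L] + h[i] / 2
    }
    w
  }
  if (method == "trapezoid") return(trap(1L, n))
  uniform <- diff(range(h)) < 1e-9 * mean(h)
  if (!uniform) return(trap(1L, n)) # Simpson assumes even spacing
  w <- numeric(n)
  n_int <- n - 1L
  simpson_end <- if (n_int %% 2L == 0L) n else n - 1L
  if (simpson_end >= 3L) {
    hh <- h[1L]
    for (i in seq(1L, simpson_end - 2L, by = 2L)) {
      w[i] <- w[i] + hh / 3
      w[i + 1L] <- w[i + 1L] + 4 * hh / 3
      w[i + 2L] <- w[i + 2L] + hh / 3
    }
  }
  if (simpson_end < n) # odd interval count: close with one trapezoid
    w[(n - 1L):n] <- w[(n - 1L):n] + h[n - 1L] / 2
  w
}

#' Spectral curves
#'
#' `spectrum()` holds a single curve on a wavelength grid (a source spectrum,
#' a quantum-efficiency curve, a class mean, ...).  `pixel_spectrum()` is the
#' same with the physical transparency bound `0 <= t <= 1` enforced.
#'
#' @param grid a [wavelength_grid()].
#' @param values numeric vector, one value per grid wavelength.
#' @return An object of class `spectrum` / `pixel_spectrum`.
#' @export
spectrum <- function(grid, values) {
  stopifnot(inherits(grid, "wavelength_grid"))
  values <- as.numeric(values)
  if (length(values) != length(grid))
    stop("spectrum length does not match the wavelength grid")
  if (any(!is.finite(values)))
    stop("spectrum values must be finite")
  structure(list(grid = grid, values = values), class = "spectrum")
}

#' @rdname spectrum
#' @export
pixel_spectrum <- function(grid, values) {
  s <- spectrum(grid, values)
  if (any(s$values < -1e-12) || any(s$values > 1 + 1e-12))
    stop("transparency values must lie in [0, 1]")
  s$values <- pmin(pmax(s$values, 0), 1)
  class(s) <- c("pixel_spectrum", "spectrum")
  s
}

#' Effective incoming light
#'
#' The per-channel kernel of the forward model, `L_c(lambda) =
#' S(lambda) * F_c(lambda)`: the source spectrum already multiplied by each
#' camera channel's quantum-efficiency curve.
#'
#' @param grid a [wavelength_grid()].
#' @param curves numeric matrix, `length(grid)` rows, one column per channel;
#'   all values non-negative.
#' @param channels channel labels (defaults to column names or `ch1..chC`).
#' @return An object of class `effective_light`.
#' @export
effective_light <- function(grid, curves, channels = NULL) {
  stopifnot(inherits(grid, "wavelength_grid"))
  curves <- as.matrix(curves)
  if (nrow(curves) != length(grid))
    stop("curves must have one row per grid wavelength")
  if (ncol(curves) < 1) stop("at least one channel is required")
  if (any(!is.finite(curves)) || any(curves < 0))
    stop("effective light curves must be finite and non-negative")
  if (is.null(channels)) channels <- colnames(curves)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(curves)))
  colnames(curves) <- channels
  structure(list(grid = grid, curves = curves, channels = channels),
            class = "effective_light")
}

#' @rdname effective_light
#' @param light an `effective_light`.
#' @return `light_integrals()` returns the per-channel integral of
#'   `L_c(lambda)` over the grid (Simpson quadrature), i.e. the intensity of
#'   a fully transparent (white background) pixel.
#' @export
light_integrals <- function(light) {
  stopifnot(inherits(light, "effective_light"))
  q <- quad_weights(light$grid)
  drop(crossprod(light$curves, q))
}

#' @rdname effective_light
#' @param white per-channel white-background intensity on the normalized
#'   `[0, 1]` intensity scale (recycled to the channel count).
#' @return `normalize_light()` rescales each channel so that its integral
#'   equals `white`, fixing the intensity convention of the loss: a pixel
#'   with unit transparency then predicts exactly the background intensity.
#' @export
normalize_light <- function(light, white) {
  ints <- light_integrals(light)
  if (any(ints <= 0)) stop("cannot normalize a channel with zero integral")
  white <- rep_len(white, length(ints))
  effective_light(light$grid,
                  sweep(light$curves, 2, white / ints, `*`),
                  light$channels)
}

#' Multi-channel intensity image
#'
#' Raw per-pixel, per-channel sensor intensities, together with the bit depth
#' that fixes the normalization to `[0, 1]` and a per-pixel saturation flag.
#' Pixel coordinates are 0-free: everything is addressed `[row, col]`,
#' 1-based, row-major, as is native in R.
#'
#' @param values numeric array `h x w x C` (a matrix is promoted to one
#'   channel); all values non-negative.
#' @param bit_depth integer bits per sample (8--16).
#' @param channels channel labels.
#' @param saturated logical `h x w` matrix flagging unusable pixels.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(values, bit_depth = 16, channels = NULL,
                          saturated = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (any(!is.finite(values)) || any(values < 0))
    stop("intensities must be finite and non-negative")
  d <- dim(values)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[3]))
  if (is.null(saturated)) saturated <- matrix(FALSE, d[1], d[2])
  stopifnot(identical(dim(saturated), d[1:2]))
  structure(list(values = values, bit_depth = as.integer(bit_depth),
                 channels = channels, saturated = saturated),
            class = "channel_image")
}

#' @export
dim.channel_image <- function(x) dim(x$values)

#' Per-pixel transparency field
#'
#' The unknown of the inverse problem: one transparency spectrum
#' `t(lambda) in [0,1]` per pixel, stored as an `h x w x w_lambda` array.
#' The `valid` mask marks pixels whose spectra are trustworthy (saturated or
#' masked pixels are carried along but flagged invalid).
#'
#' @param values numeric array `h x w x length(grid)` with entries in `[0,1]`.
#' @param grid a [wavelength_grid()].
#' @param valid logical `h x w` matrix.
#' @return An object of class `transparency_field`.
#' @export
transparency_field <- function(values, grid, valid = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            inherits(grid, "wavelength_grid"))
  if (dim(values)[3] != length(grid))
    stop("third array dimension must match the wavelength grid")
  if (any(!is.finite(values)) || any(values < -1e-9) || any(values > 1 + 1e-9))
    stop("transparency values must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  d <- dim(values)
  if (is.null(valid)) valid <- matrix(TRUE, d[1], d[2])
  stopifnot(identical(dim(valid), d[1:2]))
  structure(list(values = values, grid = grid, valid = valid),
            class = "transparency_field")
}

#' @export
dim.transparency_field <- function(x) dim(x$values)

#' Forward measurement model
#'
#' The linear measurement model of bright-field acquisition: the intensity
#' recorded in channel `c` is the integral of the effective incoming light
#' times the medium's transparency,
#' `I_c = integral L_c(lambda) * t(lambda) d lambda`,
#' evaluated by Simpson quadrature on the working grid.
#'
#' @param t a [pixel_spectrum()] (or plain `spectrum` with values in `[0,1]`).
#' @param light an [effective_light()] on the same grid.
#' @param channel channel index or label.
#' @return The predicted intensity (scalar).
#' @export
forward_integrate <- function(t, light, channel) {
  stopifnot(inherits(t, "spectrum"), inherits(light, "effective_light"))
  if (!grid_equal(t$grid, light$grid))
    stop("spectrum and light are on different wavelength grids")
  if (is.character(channel)) channel <- match(channel, light$channels)
  if (is.na(channel) || channel < 1 || channel > ncol(light$curves))
    stop("unknown channel")
  q <- quad_weights(light$grid)
  sum(q * light$curves[, channel] * t$values)
}

#' @rdname forward_integrate
#' @param field a [transparency_field()].
#' @return `forward_image()` returns a [channel_image()] of predicted
#'   intensities on the normalized `[0, 1]` scale (`bit_depth` 0 marks the
#'   image as already normalized).
#' @export
forward_image <- function(field, light) {
  stopifnot(inherits(field, "transparency_field"),
            inherits(light, "effective_light"))
  if (!grid_equal(field$grid, light$grid))
    stop("field and light are on different wavelength grids")
  d <- dim(field$values)
  q <- quad_weights(field$grid)
  flat <- matrix(field$values, d[1] * d[2], d[3])
  out <- flat %*% (q * light$curves) # (npix x w) %*% (w x C)
  channel_image(array(out, c(d[1], d[2], ncol(light$curves))),
                bit_depth = 0L, channels = light$channels)
}

#' Fidelity part of the per-pixel loss
#'
#' Exponential penalty on the per-channel residual between the forward model
#' and the observed intensities:
#' `sum_c exp(|I_hat_c - I_c|) - C`.
#' It is zero exactly when every channel is matched and grows monotonically
#' (and harshly) with the residual magnitude.
#'
#' @inheritParams forward_integrate
#' @param observed numeric vector of observed intensities, one per channel,
#'   on the same normalized scale as `light` (see [normalize_light()]).
#' @return Non-negative scalar.
#' @export
fidelity_term <- function(t, light, observed) {
  C <- ncol(light$curves)
  if (length(observed) != C)
    stop("observed intensities must have one entry per channel")
  pred <- vapply(seq_len(C), function(ch) forward_integrate(t, light, ch),
                 numeric(1))
  sum(exp(abs(pred - observed))) - C
}
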