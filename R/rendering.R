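#' Planck black-body illuminant
#'
#' Spectral radiance shape of a black body at temperature `T`, sampled on a
#' wavelength grid and normalized to unit maximum.  The default 5800 K is a
#' daylight-like re-illumination temperature (close to the solar surface).
#'
#' @param T temperature in kelvin (> 0).
#' @param grid a [wavelength_grid()].
#' @return An object of class `illuminant`: a [spectrum()] with a
#'   `provenance` attribute such as `"planck_5800K"`.
#' @export
planck_spectrum <- function(T, grid) {
  if (!is.numeric(T) || T <= 0) stop("temperature must be positive")
  h <- 6.62607015e-34; c0 <- 299792458; kB <- 1.380649e-23
  lam <- as.numeric(grid) * 1e-9
  B <- (2 * h * c0^2 / lam^5) / (expm1(h * c0 / (lam * kB * T)))
  s <- spectrum(grid, B / max(B))
  attr(s, "provenance") <- sprintf("planck_%gK", T)
  class(s) <- c("illuminant", class(s))
  s
}

#' CIE 1931 2-degree colour matching functions
#'
#' Analytic multi-lobe Gaussian fit to the CIE 1931 2-degree standard
#' observer (Wyman, Sloan & Shirley 2013), evaluated on an arbitrary grid.
#' The fit reproduces the tabulated observer closely; in particular the
#' equal-energy white computed from it lands within about 3e-4 of
#' `x = y = 1/3`.
#'
#' @param grid a [wavelength_grid()].
#' @return Numeric matrix `length(grid) x 3` with columns `xbar`, `ybar`,
#'   `zbar`.
#' @export
cie_cmf <- function(grid) {
  l <- as.numeric(grid)
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  xbar <- 1.056 * g(l, 599.8, 37.9, 31.0) + 0.362 * g(l, 442.0, 16.0, 26.7) -
    0.065 * g(l, 501.1, 20.4, 26.2)
  ybar <- 0.821 * g(l, 568.8, 46.9, 40.5) + 0.286 * g(l, 530.9, 16.3, 31.1)
  zbar <- 1.217 * g(l, 437.0, 11.8, 36.0) + 0.681 * g(l, 459.0, 26.0, 13.8)
  cbind(xbar = pmax(xbar, 0), ybar = pmax(ybar, 0), zbar = pmax(zbar, 0))
}

xyz_to_linear_srgb <- function(xyz) {
  M <- matrix(c(3.2406, -1.5372, -0.4986,
                -0.9689, 1.8758, 0.0415,
                0.0557, -0.2040, 1.0570), 3, 3, byrow = TRUE)
  xyz %*% t(M)
}

srgb_gamma <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Render a spectral cube under an arbitrary illuminant
#'
#' Artificial re-illumination: every pixel's transparency spectrum is
#' multiplied by the illuminant and the CIE 1931 matching curves, and the
#' integrals (Simpson) give the pixel's XYZ tristimulus coordinates.  XYZ is
#' normalized so that a fully transparent pixel has `Y = 1`, converted to
#' linear sRGB by the standard matrix, clipped to `[0, 1]`, and
#' gamma-encoded for display.
#'
#' @param field a [transparency_field()].
#' @param illuminant an [illuminant()]/[spectrum()] on the same grid.
#' @return An object of class `color_image`: list with `xyz`
#'   (`h x w x 3` array), `rgb` (display sRGB in `[0, 1]`), and the
#'   illuminant provenance.
#' @export
render <- function(field, illuminant) {
  stopifnot(inherits(field, "transparency_field"),
            inherits(illuminant, "spectrum"))
  if (!grid_equal(field$grid, illuminant$grid))
    stop("field and illuminant are on different wavelength grids")
  q <- quad_weights(field$grid)
  cmf <- cie_cmf(field$grid)
  kern <- q * illuminant$values * cmf # w x 3
  d <- dim(field$values)
  flat <- matrix(field$values, d[1] * d[2], d[3])
  xyz <- flat %*% kern
  Ywhite <- sum(q * illuminant$values * cmf[, "ybar"])
  if (Ywhite > 0) xyz <- xyz / Ywhite
  rgb_lin <- pmin(pmax(xyz_to_linear_srgb(xyz), 0), 1)
  structure(list(xyz = array(xyz, c(d[1], d[2], 3)),
                 rgb = array(srgb_gamma(rgb_lin), c(d[1], d[2], 3)),
                 illuminant = attr(illuminant, "provenance")),
            class = "color_image")
}

#' @rdname render
#' @param image a `color_image`.
#' @return `chromaticity()` returns an `h x w x 2` array of CIE `(x, y)`
#'   chromaticities (`NA` where `X + Y + Z = 0`).
#' @export
chromaticity <- function(image) {
  s <- image$xyz[, , 1] + image$xyz[, , 2] + image$xyz[, , 3]
  s[s <= 0] <- NA
  d <- dim(image$xyz)
  out <- array(NA_real_, c(d[1], d[2], 2))
  out[, , 1] <- image$xyz[, , 1] / s
  out[, , 2] <- image$xyz[, , 2] / s
  out
}

#' Flag and rescale very bright pixels
#'
#' Light-condensing objects (bubbles, vacuoles acting as micro-lenses)
#' violate the transparency bound and show up as abnormally bright pixels.
#' For visualization they are detected as intensities above the given
#' percentile (over all channels jointly), treated as saturated, and the
#' remaining intensities are linearly rescaled to the original range.
#'
#' @param image a [channel_image()].
#' @param percentile percentile threshold (default 99).
#' @return A [channel_image()] with the bright pixels flagged in
#'   `$saturated` and the rest rescaled.
#' @export
rescale_bright <- function(image, percentile = 99) {
  stopifnot(inherits(image, "channel_image"))
  v <- image$values
  thr <- as.numeric(quantile(v, percentile / 100, names = FALSE))
  bright <- apply(v > thr, c(1, 2), any)
  keep <- v[rep(!bright, dim(v)[3])]
  out <- v
  if (any(bright) && length(keep) > 0 && diff(range(keep)) > 0) {
    lo <- min(keep); hi <- max(keep)
    scaled <- (pmin(v, hi) - lo) / (hi - lo) * diff(range(v)) + min(v)
    out <- pmax(scaled, 0)
  }
  channel_image(out, bit_depth = image$bit_depth, channels = image$channels,
                saturated = image$saturated | bright)
}
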