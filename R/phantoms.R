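#' Phantom specification
#'
#' Parameters of the synthetic ground-truth generator.  The defaults emulate
#' the acquisition conditions the reconstruction assumes: piecewise-smooth
#' regions with localized gradients at their borders, spectra well inside
#' `[0, 1]`, a linear camera, and a few percent of intensity noise.
#'
#' @param size `(h, w)` image size in pixels.
#' @param n_regions number of regions (2 = disc on background; more =
#'   seeded Voronoi cells).
#' @param grid working [wavelength_grid()].
#' @param modulation within-region smooth spatial modulation amplitude
#'   (relative).
#' @param noise_sigma additive Gaussian intensity noise, as a fraction of
#'   the white-background intensity.
#' @param gain_cv per-pixel sensor gain dispersion (coefficient of
#'   variation).
#' @param offset sensor offset on the normalized intensity scale.
#' @param bit_depth camera bit depth (12 matches a typical scientific RGB
#'   camera).
#' @param bayer simulate a Bayer mosaic readout.
#' @param white white-background intensity on the normalized `[0, 1]` scale;
#'   kept below 1 so that model-violating bright objects stay unsaturated.
#' @param region_mix mixes every region's spectrum toward region 1
#'   (`0` = full contrast, larger = lower contrast variant).
#' @param seed integer seed for all randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(24, 24), n_regions = 2,
                         grid = default_grid(), modulation = 0.03,
                         noise_sigma = 0.05, gain_cv = 0, offset = 0,
                         bit_depth = 12, bayer = FALSE, white = 0.75,
                         region_mix = 0, seed = 1L) {
  stopifnot(length(size) == 2, n_regions >= 1, modulation >= 0,
            noise_sigma >= 0, gain_cv >= 0, white > 0, white <= 1,
            region_mix >= 0, region_mix < 1)
  structure(list(size = as.integer(size), n_regions = as.integer(n_regions),
                 grid = grid, modulation = modulation,
                 noise_sigma = noise_sigma, gain_cv = gain_cv,
                 offset = offset, bit_depth = as.integer(bit_depth),
                 bayer = bayer, white = white, region_mix = region_mix,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Gaussian-band RGB effective light
#'
#' A synthetic effective incoming light for tests and phantoms: one Gaussian
#' band per channel (R 610 nm, G 540 nm, B 470 nm, sd 35 nm), each scaled so
#' that its integral equals `white` -- i.e. a fully transparent pixel reads
#' `white` on the normalized intensity scale in every channel.
#'
#' @param grid a [wavelength_grid()].
#' @param white per-channel white-background intensity.
#' @return An [effective_light()] with channels `R`, `G`, `B`.
#' @export
rgb_light <- function(grid, white = 0.75) {
  l <- as.numeric(grid)
  curves <- cbind(R = dnorm(l, 610, 35), G = dnorm(l, 540, 35),
                  B = dnorm(l, 470, 35))
  normalize_light(effective_light(grid, curves), white)
}

# smooth unimodal bump spectrum over the grid, values in [0, 1]
bump_spectrum <- function(grid, center, width, amplitude = 0.8,
                          baseline = 0.05) {
  l <- as.numeric(grid)
  baseline + amplitude * exp(-0.5 * ((l - center) / width)^2)
}

#' Generate a ground-truth phantom field
#'
#' Builds a [transparency_field()] that is smooth inside regions and
#' discontinuous across region borders.  Each region gets a Gaussian-bump
#' base spectrum with bump centres spread across the wavelength span (so
#' that different regions have nearly orthogonal deviations from baseline),
#' modulated within the region by a low-frequency spatial sinusoid of
#' relative amplitude `modulation`.
#'
#' @param spec a [phantom_spec()].
#' @return List with `field` (the ground truth [transparency_field()]),
#'   `labels` (integer `h x w` region map), and `spectra` (list of the
#'   unmodulated per-region base [spectrum()]s).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  grid <- spec$grid
  l <- as.numeric(grid)
  span <- range(l)
  labels <- with_seed(spec$seed, {
    if (spec$n_regions == 1) {
      matrix(1L, h, w)
    } else if (spec$n_regions == 2) {
      rc <- (h + 1) / 2; cc <- (w + 1) / 2
      radius <- min(h, w) / 3
      dist <- outer(seq_len(h), seq_len(w),
                    function(r, c) sqrt((r - rc)^2 + (c - cc)^2))
      ifelse(dist <= radius, 2L, 1L)
    } else {
      ctr <- cbind(runif(spec$n_regions, 1, h), runif(spec$n_regions, 1, w))
      m <- matrix(0L, h, w)
      for (r in seq_len(h)) for (c in seq_len(w))
        m[r, c] <- which.min((ctr[, 1] - r)^2 + (ctr[, 2] - c)^2)
      m
    }
  })
  centers <- seq(span[1] + 0.12 * diff(span), span[2] - 0.12 * diff(span),
                 length.out = max(spec$n_regions, 2))[seq_len(spec$n_regions)]
  width <- diff(span) / (2.5 * max(spec$n_regions, 2))
  base <- lapply(centers, function(ctr) bump_spectrum(grid, ctr, width))
  if (spec$region_mix > 0 && spec$n_regions > 1) {
    for (j in seq(2, spec$n_regions))
      base[[j]] <- (1 - spec$region_mix) * base[[j]] +
        spec$region_mix * base[[1]]
  }
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  modul <- 1 + spec$modulation * sin(2 * pi * rr / h) * sin(2 * pi * cc / w)
  vals <- array(0, c(h, w, length(grid)))
  for (j in seq_len(spec$n_regions)) {
    mask <- labels == j
    for (i in seq_along(grid)) {
      plane <- vals[, , i]
      plane[mask] <- base[[j]][i] * modul[mask]
      vals[, , i] <- plane
    }
  }
  vals <- pmin(pmax(vals, 0), 1)
  list(field = transparency_field(vals, grid), labels = labels,
       spectra = lapply(base, function(b) spectrum(grid, b)))
}

#' Simulate a camera exposure of a phantom
#'
#' Applies the forward model pixel-wise, then the camera chain: per-pixel
#' gain (normal, CV `gain_cv`), offset, additive Gaussian noise
#' (`noise_sigma` as a fraction of the white level), quantization to
#' `bit_depth`, and -- optionally -- Bayer subsampling.  Pixels that hit the
#' top code value are flagged saturated.
#'
#' @param field a [transparency_field()] (ground truth).
#' @param light an [effective_light()].
#' @param spec a [phantom_spec()] carrying the camera model and seed.
#' @param microlens optional `(row, col)` of one model-violating
#'   "micro-lens" pixel whose intensity is raised above the background.
#' @param microlens_factor intensity multiple of the white level for that
#'   pixel (default 1.25; must keep the pixel below saturation).
#' @return A [channel_image()] (quantized counts).  When `spec$bayer` is
#'   `TRUE`, the result additionally carries the mosaic as attribute
#'   `"mosaic"` and the pattern as `"bayer"`.
#' @export
simulate_camera <- function(field, light, spec, microlens = NULL,
                            microlens_factor = 1.25) {
  stopifnot(inherits(field, "transparency_field"),
            inherits(light, "effective_light"),
            inherits(spec, "phantom_spec"))
  ideal <- forward_image(field, light)
  I <- ideal$values
  d <- dim(I)
  white <- light_integrals(light)
  if (!is.null(microlens))
    for (ch in seq_len(d[3]))
      I[microlens[1], microlens[2], ch] <- microlens_factor * white[ch]
  I <- with_seed(spec$seed + 1L, {
    gains <- matrix(1, d[1], d[2])
    if (spec$gain_cv > 0)
      gains <- matrix(rnorm(d[1] * d[2], 1, spec$gain_cv), d[1], d[2])
    out <- I
    for (ch in seq_len(d[3])) {
      plane <- I[, , ch] * gains + spec$offset
      if (spec$noise_sigma > 0)
        plane <- plane +
          rnorm(d[1] * d[2], 0, spec$noise_sigma * mean(white))
      out[, , ch] <- plane
    }
    out
  })
  maxdn <- 2^spec$bit_depth - 1
  dn <- pmin(pmax(round(I * maxdn), 0), maxdn)
  saturated <- apply(dn >= maxdn, c(1, 2), any)
  img <- channel_image(dn, bit_depth = spec$bit_depth,
                       channels = light$channels, saturated = saturated)
  if (isTRUE(spec$bayer)) {
    chmap <- bayer_channel_map(d[1:2], "RGGB")
    mosaic <- matrix(0, d[1], d[2])
    for (ch in 1:3) {
      plane <- dn[, , ch]
      mosaic[chmap == ch] <- plane[chmap == ch]
    }
    attr(img, "mosaic") <- mosaic
    attr(img, "bayer") <- "RGGB"
  }
  img
}

#' Simulate an ND-filter calibration stack
#'
#' A linear sensor with per-pixel gain dispersion photographs a uniform
#' background through `n_filters` neutral-density layers of transmittance
#' `tau_i`; the spectrometer records `tau_i * source(lambda)` for each.
#' Together with per-channel quantum-efficiency curves this forms a
#' [calibration_input()] that [build_calibration()] can invert exactly
#' (the sensor is linear, so two knots already determine the response).
#'
#' @param grid working [wavelength_grid()].
#' @param n_filters number of gray layers (>= 2, default 4).
#' @param size sensor size `(h, w)`.
#' @param gain_cv per-pixel gain coefficient of variation.
#' @param transmittances filter transmittances (defaults to an even ladder).
#' @param bayer Bayer pattern of the simulated sensor.
#' @param seed integer seed.
#' @return List with `input` (the [calibration_input()]), `gains` (the true
#'   per-pixel gain map), `S_true` (`h x w x n_filters` noiseless spectral
#'   integrals seen by each pixel), and `source` (the unfiltered source
#'   [spectrum()]).
#' @export
simulate_calibration_stack <- function(grid, n_filters = 4, size = c(8, 8),
                                       gain_cv = 0.05,
                                       transmittances = NULL,
                                       bayer = "RGGB", seed = 1L) {
  stopifnot(n_filters >= 2)
  l <- as.numeric(grid)
  span <- range(l)
  if (is.null(transmittances))
    transmittances <- seq(0.25, 1, length.out = n_filters)
  source_vals <- 0.5 + 0.5 * exp(-0.5 * ((l - mean(span)) / (diff(span) / 3))^2)
  qe <- cbind(R = 0.85 * exp(-0.5 * ((l - 610) / 40)^2),
              G = 0.9 * exp(-0.5 * ((l - 540) / 40)^2),
              B = 0.8 * exp(-0.5 * ((l - 470) / 40)^2))
  q <- quad_weights(grid)
  chmap <- bayer_channel_map(size, bayer)
  gains <- with_seed(seed, matrix(rnorm(prod(size), 1, gain_cv),
                                  size[1], size[2]))
  gains <- pmax(gains, 0.05)
  spectra <- lapply(transmittances, function(tau)
    spectrum(grid, tau * source_vals))
  S_true <- array(0, c(size[1], size[2], n_filters))
  images <- vector("list", n_filters)
  for (i in seq_len(n_filters)) {
    S_c <- vapply(1:3, function(ch) sum(q * spectra[[i]]$values * qe[, ch]),
                  numeric(1))
    Sp <- matrix(S_c[chmap], size[1], size[2])
    S_true[, , i] <- Sp
    images[[i]] <- gains * Sp
  }
  list(input = calibration_input(images, spectra, qe, grid, bayer = bayer),
       gains = gains, S_true = S_true,
       source = spectrum(grid, source_vals))
}
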