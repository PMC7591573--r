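#' Calibration input bundle
#'
#' Everything needed to build a per-pixel sensor response curve: for each of
#' `n >= 2` neutral-density filters, one raw image of the uniform background
#' taken through the filter plus the light spectrum measured behind the same
#' filter with a fibre spectrometer; per-channel quantum-efficiency curves;
#' and the Bayer pattern that assigns each mosaic pixel its channel (or
#' `"demosaiced"` when each pixel already carries all channels).
#'
#' @param images list of `h x w` numeric matrices (mosaic intensities), one
#'   per filter.
#' @param spectra list of [spectrum()] objects, one per filter (any grid;
#'   resampled to `grid`).
#' @param qe numeric matrix of quantum efficiencies, one column per channel,
#'   on `qe_grid`.
#' @param grid working [wavelength_grid()].
#' @param qe_grid grid of the `qe` rows (defaults to `grid`).
#' @param bayer Bayer descriptor: one of `"RGGB"`, `"BGGR"`, `"GRBG"`,
#'   `"GBRG"`, or `"demosaiced"`.
#' @return An object of class `calibration_input`.
#' @export
calibration_input <- function(images, spectra, qe, grid, qe_grid = grid,
                              bayer = "RGGB") {
  stopifnot(length(images) >= 2, length(images) == length(spectra),
            inherits(grid, "wavelength_grid"))
  qe <- as.matrix(qe)
  d <- dim(images[[1]])
  for (im in images) stopifnot(identical(dim(im), d))
  structure(list(images = images, spectra = spectra, qe = qe, grid = grid,
                 qe_grid = qe_grid, bayer = toupper(bayer)),
            class = "calibration_input")
}

#' Channel map of a Bayer mosaic
#'
#' @param dims `(h, w)` image size.
#' @param bayer pattern string, e.g. `"RGGB"` (top-left 2x2 block, row-major).
#' @return Integer `h x w` matrix of channel indices (1 = R, 2 = G, 3 = B).
#' @export
bayer_channel_map <- function(dims, bayer = "RGGB") {
  bayer <- toupper(bayer)
  if (!bayer %in% c("RGGB", "BGGR", "GRBG", "GBRG"))
    stop("unsupported Bayer pattern: ", bayer)
  code <- match(strsplit(bayer, "")[[1]], c("R", "G", "B"))
  blk <- matrix(code, 2, 2, byrow = TRUE)
  blk[((seq_len(dims[1]) - 1L) %% 2L) + 1L,
      ((seq_len(dims[2]) - 1L) %% 2L) + 1L, drop = FALSE]
}

resample_to_grid <- function(x_wl, x_val, grid) {
  out <- approx(x_wl, x_val, xout = as.numeric(grid), rule = 1)$y
  if (anyNA(out)) {
    warning("grid extends past the tabulated range; filled with 0")
    out[is.na(out)] <- 0
  }
  out
}

#' Build a per-pixel calibration table
#'
#' For filter `i` and a pixel of channel `c`, the calibration pairs the
#' recorded intensity `M_i` of that pixel with the QE-weighted integral of
#' the spectrometer spectrum, `S_i = integral spec_i(lambda) F_c(lambda)
#' d lambda` (Simpson on the working grid).  Knots are sorted by `M` per
#' pixel; a non-monotone `S` ordering after the sort (a noisy sensor) is
#' kept but reported with a warning.
#'
#' @param input a [calibration_input()].
#' @return An object of class `calibration_table`: list with `M` and `S`
#'   arrays (`h x w x n_filters`, knots sorted by `M` per pixel), the
#'   channel map, and the working grid.
#' @export
build_calibration <- function(input) {
  stopifnot(inherits(input, "calibration_input"))
  grid <- input$grid
  q <- quad_weights(grid)
  nf <- length(input$images)
  C <- ncol(input$qe)
  qe_rs <- vapply(seq_len(C), function(ch)
    resample_to_grid(as.numeric(input$qe_grid), input$qe[, ch], grid),
    numeric(length(grid)))
  # S integral per (filter, channel)
  S_fc <- matrix(0, nf, C)
  for (i in seq_len(nf)) {
    sp <- input$spectra[[i]]
    sv <- resample_to_grid(as.numeric(sp$grid), sp$values, grid)
    for (ch in seq_len(C)) S_fc[i, ch] <- sum(q * sv * qe_rs[, ch])
  }
  d <- dim(input$images[[1]])
  chmap <- if (identical(input$bayer, "DEMOSAICED")) {
    matrix(1L, d[1], d[2]) # single effective channel per pixel plane caller-side
  } else {
    bayer_channel_map(d, input$bayer)
  }
  M <- array(0, c(d[1], d[2], nf))
  S <- array(0, c(d[1], d[2], nf))
  for (i in seq_len(nf)) {
    M[, , i] <- input$images[[i]]
    S[, , i] <- matrix(S_fc[i, ][chmap], d[1], d[2])
  }
  # sort knots by M per pixel
  nonmono <- 0L
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    o <- order(M[r, cc, ])
    ms <- M[r, cc, o]; ss <- S[r, cc, o]
    if (is.unsorted(ss)) nonmono <- nonmono + 1L
    M[r, cc, ] <- ms; S[r, cc, ] <- ss
  }
  if (nonmono > 0)
    warning(nonmono, " pixel(s) have a non-monotone S(M) after sorting by M")
  structure(list(M = M, S = S, channel_map = chmap, grid = grid,
                 bayer = input$bayer),
            class = "calibration_table")
}

#' Apply a calibration table to a raw image
#'
#' Maps every pixel's recorded intensity `M` to integrated spectral energy
#' `S(M)` by piecewise-linear interpolation between that pixel's own knots.
#' Outside the measured knot range the nearest segment is continued
#' linearly and the pixel is flagged as extrapolated.
#'
#' @param raw numeric `h x w` matrix (mosaic) or a [channel_image()] with a
#'   single channel.
#' @param table a [calibration_table()].
#' @return List with `values` (corrected `h x w` matrix) and `extrapolated`
#'   (logical matrix).
#' @export
apply_calibration <- function(raw, table) {
  if (inherits(raw, "channel_image")) {
    stopifnot(dim(raw$values)[3] == 1)
    raw <- raw$values[, , 1]
  }
  stopifnot(is.matrix(raw),
            identical(dim(raw), dim(table$M)[1:2]))
  d <- dim(raw)
  nf <- dim(table$M)[3]
  out <- matrix(NA_real_, d[1], d[2])
  extra <- matrix(FALSE, d[1], d[2])
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    m <- table$M[r, cc, ]; s <- table$S[r, cc, ]
    x <- raw[r, cc]
    dup <- duplicated(m)
    m2 <- m[!dup]; s2 <- s[!dup]
    if (length(m2) < 2) { # degenerate: pass through, flagged
      out[r, cc] <- x
      extra[r, cc] <- TRUE
      next
    }
    k <- findInterval(x, m2, all.inside = TRUE)
    slope <- (s2[k + 1] - s2[k]) / (m2[k + 1] - m2[k])
    out[r, cc] <- s2[k] + slope * (x - m2[k])
    extra[r, cc] <- x < m2[1] || x > m2[length(m2)]
  }
  list(values = out, extrapolated = extra)
}

#' Bilinear demosaicing of a Bayer mosaic
#'
#' Fills each pixel's missing channels by averaging the nearest mosaic
#' neighbours that carry the channel (plain bilinear interpolation).
#' Calibration, when used, is applied on the mosaic before demosaicing.
#'
#' @param mosaic numeric `h x w` matrix.
#' @param bayer Bayer pattern string.
#' @return Numeric array `h x w x 3` (R, G, B).
#' @export
demosaic_bilinear <- function(mosaic, bayer = "RGGB") {
  d <- dim(mosaic)
  chmap <- bayer_channel_map(d, bayer)
  out <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) {
    num <- matrix(0, d[1], d[2]); den <- matrix(0, d[1], d[2])
    for (dr in -1:1) for (dc in -1:1) {
      vals <- shift_matrix(mosaic, dr, dc)
      mask <- shift_matrix((chmap == ch) * 1, dr, dc)
      wgt <- if (dr == 0 && dc == 0) 4 else if (dr == 0 || dc == 0) 2 else 1
      num <- num + wgt * vals * mask
      den <- den + wgt * mask
    }
    out[, , ch] <- num / pmax(den, 1e-300)
  }
  out
}
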