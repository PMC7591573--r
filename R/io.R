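#' Read a raw intensity image
#'
#' Reads a TIFF or PNG image into a [channel_image()] with intensities
#' preserved as integer counts -- no rescaling, no gamma.  An 8-bit white
#' pixel reads as 255, not 1.0.
#'
#' @param path file path (`.tif`, `.tiff`, `.png`).
#' @return A [channel_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(v, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
    # as.is only yields raw counts for grayscale data; multi-channel images
    # come back normalized and must be mapped back to counts
    if (!is.integer(c(v))) v <- round(v * (2^bits - 1))
    channel_image(v, bit_depth = bits)
  } else if (ext == "png") {
    v <- png::readPNG(path, info = TRUE)
    info <- attr(v, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    if (length(dim(v)) == 3 && dim(v)[3] == 4) v <- v[, , 1:3] # drop alpha
    channel_image(round(v * (2^bits - 1)), bit_depth = bits)
  } else {
    stop("unsupported image format '", ext, "' (expected TIFF or PNG)")
  }
}

#' @rdname read_image
#' @param image a [channel_image()] (integer counts) for `write_image()`.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "channel_image"))
  bits <- if (image$bit_depth > 8) 16L else 8L
  v <- image$values / (2^bits - 1)
  v <- pmin(pmax(v, 0), 1)
  if (dim(v)[3] == 1) v <- v[, , 1]
  tiff::writeTIFF(v, path, bits.per.sample = bits)
  invisible(path)
}

#' Spectral cube I/O
#'
#' A reconstructed [transparency_field()] is stored as a multi-page 32-bit
#' float TIFF (one page per wavelength) plus a sidecar CSV listing the grid
#' wavelengths and the per-pixel validity mask.
#'
#' @param field a [transparency_field()].
#' @param path output TIFF path; the sidecar is `<path>.grid.csv`.
#' @export
write_cube <- function(field, path) {
  stopifnot(inherits(field, "transparency_field"))
  d <- dim(field$values)
  pages <- lapply(seq_len(d[3]), function(i) field$values[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  sidecar <- data.frame(wavelength_nm = as.numeric(field$grid))
  write.csv(sidecar, paste0(path, ".grid.csv"), row.names = FALSE)
  write.csv(data.frame(valid = as.integer(field$valid)),
            paste0(path, ".valid.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  grid_df <- read.csv(paste0(path, ".grid.csv"))
  grid <- wavelength_grid(grid_df$wavelength_nm)
  d <- dim(pages[[1]])
  vals <- array(0, c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) vals[, , i] <- pages[[i]]
  valid <- NULL
  vpath <- paste0(path, ".valid.csv")
  if (file.exists(vpath))
    valid <- matrix(read.csv(vpath)$valid == 1, d[1], d[2])
  transparency_field(pmin(pmax(vals, 0), 1), grid, valid = valid)
}

#' Read a tabulated spectrum (CSV)
#'
#' Reads a CSV whose first column is the wavelength in nm and whose
#' remaining column(s) hold spectral values, and resamples linearly onto
#' the working grid.  Grid points outside the tabulated range are filled
#' with 0 (with a warning).  One value column yields a [spectrum()];
#' several yield an [effective_light()].
#'
#' @param path CSV path with a header row.
#' @param grid target [wavelength_grid()].
#' @return A [spectrum()] or [effective_light()].
#' @export
read_spectrum_csv <- function(path, grid) {
  df <- read.csv(path)
  if (ncol(df) < 2) stop("expected wavelength column plus value column(s)")
  wl <- df[[1]]
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  vals <- vapply(seq(2, ncol(df)), function(j)
    resample_to_grid(wl, df[[j]], grid), numeric(length(grid)))
  if (ncol(vals) == 1) spectrum(grid, vals[, 1])
  else effective_light(grid, vals, channels = names(df)[-1])
}

#' @rdname read_spectrum_csv
#' @param light an [effective_light()] for `write_light_csv()`.
#' @export
write_light_csv <- function(light, path) {
  df <- data.frame(wavelength_nm = as.numeric(light$grid))
  df <- cbind(df, as.data.frame(light$curves))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname run_reconstruction
#' @param trace an iteration trace data frame.
#' @param path CSV output path.
#' @export
write_trace <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Calibration table serialization
#'
#' The `.qcal` container is a JSON document holding a header (geometry,
#' Bayer pattern, grid) and the flattened knot arrays, readable anywhere.
#'
#' @param table a [calibration_table()].
#' @param path output path (conventionally `.qcal`).
#' @export
write_calibration <- function(table, path) {
  d <- dim(table$M)
  obj <- list(format = "qcal", version = 1L,
              height = d[1], width = d[2], n_knots = d[3],
              bayer = table$bayer,
              grid = as.numeric(table$grid),
              channel_map = as.integer(table$channel_map),
              M = as.numeric(table$M), S = as.numeric(table$S))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "qcal")) stop("not a qcal container: ", path)
  d <- c(obj$height, obj$width, obj$n_knots)
  structure(list(M = array(obj$M, d), S = array(obj$S, d),
                 channel_map = matrix(obj$channel_map, d[1], d[2]),
                 grid = wavelength_grid(obj$grid), bayer = obj$bayer),
            class = "calibration_table")
}

#' Solver configuration I/O
#'
#' Reads a YAML (or JSON) file whose keys mirror [solver_config()]
#' field-for-field; missing keys take the defaults.
#'
#' @param path YAML/JSON config path.
#' @return A [solver_config()].
#' @export
read_solver_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(solver_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(solver_config, cfg)
}
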