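#' Solver configuration
#'
#' All tunables of the mean-field reconstruction loop in one validated
#' object.
#'
#' The per-pixel loss tolerance follows a linear schedule: it starts at
#' `tol_initial` and decreases linearly to `tol_final` at iteration
#' `tol_horizon` (default 10), after which it is held constant.  The outer
#' loop stops when the relative change of the mean per-pixel cost between
#' consecutive iterations falls below `change_threshold` (default 0.01), or
#' after `max_iterations`.
#'
#' @param max_iterations cap on outer mean-field iterations.
#' @param tol_final final per-pixel loss tolerance (> 0), in loss units on
#'   the `intensity_scale` convention.
#' @param tol_initial initial tolerance; default ten times `tol_final`.
#' @param tol_horizon iteration at which the schedule reaches `tol_final`.
#' @param change_threshold relative mean-cost change that stops the loop.
#' @param sigma0 initial CMA-ES step size in `[0, 1]` transparency units.
#' @param population CMA-ES population size; `0` selects the standard
#'   `4 + floor(3 log w)` for dimension `w`.
#' @param budget maximum loss evaluations per pixel per iteration.
#' @param t_ed neighbourhood radius (pixels, Euclidean).
#' @param t_b edge bias of the coupling weights.
#' @param intensity_scale internal unit of the fidelity residual: observed
#'   intensities and effective light are multiplied by this factor before
#'   entering the loss.  The default 100 expresses residuals in percent of
#'   full scale, which turns the exponential fidelity term into a soft
#'   barrier (strongly dominant until the forward model matches the data to
#'   a few percent) while keeping `exp()` finite; spectra themselves stay
#'   in `[0, 1]`.
#' @param seed integer seed; every per-pixel search is seeded
#'   deterministically from `(seed, iteration, pixel)`.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(max_iterations = 40,
                          tol_final = 3,
                          tol_initial = 10 * tol_final,
                          tol_horizon = 10,
                          change_threshold = 0.01,
                          sigma0 = 0.15,
                          population = 0,
                          budget = 400,
                          intensity_scale = 100,
                          t_ed = 1,
                          t_b = 0.9,
                          seed = 1L) {
  stopifnot(tol_final > 0, tol_initial >= tol_final, tol_horizon >= 1,
            change_threshold > 0, sigma0 > 0, budget >= 1,
            intensity_scale > 0, t_ed > 0, t_b >= 0, t_b < 1,
            max_iterations >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 tol_final = tol_final, tol_initial = tol_initial,
                 tol_horizon = as.integer(tol_horizon),
                 change_threshold = change_threshold,
                 sigma0 = sigma0, population = as.integer(population),
                 budget = as.integer(budget),
                 intensity_scale = intensity_scale,
                 t_ed = t_ed, t_b = t_b, seed = as.integer(seed)),
            class = "solver_config")
}

#' @rdname solver_config
#' @param config a `solver_config`.
#' @param iteration outer iteration number (1-based).
#' @return `tolerance_at()` gives the scheduled tolerance for an iteration.
#' @export
tolerance_at <- function(config, iteration) {
  h <- config$tol_horizon
  if (iteration >= h) return(config$tol_final)
  frac <- (iteration - 1) / (h - 1)
  config$tol_initial + frac * (config$tol_final - config$tol_initial)
}

#' Per-pixel loss
#'
#' The quantity minimized for each pixel: the exponential fidelity term plus
#' the edge-attenuated mean-field smoothness penalty,
#' `F_m = sum_c exp(|I_hat_c - I_c|) - C +
#'   (1/N) sum_{n in Nb(m)} G_mn sum_i (t_i - T_n,i)^2`,
#' with `N` the number of neighbours of `m` actually inside the image.
#' Neighbour spectra are read from `field` (the previous sweep's state).
#'
#' @param m integer `(row, col)` pixel.
#' @param t candidate [pixel_spectrum()] for pixel `m`.
#' @param field [transparency_field()] holding all current spectra.
#' @param light [effective_light()].
#' @param observed per-channel observed intensities at `m` (normalized).
#' @param couplings a [build_couplings()] result.
#' @return Non-negative scalar.
#' @export
pixel_loss <- function(m, t, field, light, observed, couplings) {
  fid <- fidelity_term(t, light, observed)
  nb <- pixel_neighbors(couplings, m)
  keep <- field$valid[nb$coords]
  coords <- nb$coords[keep, , drop = FALSE]
  gw <- nb$weights[keep]
  if (nrow(coords) == 0) return(fid)
  sm <- 0
  for (j in seq_len(nrow(coords))) {
    tn <- field$values[coords[j, 1], coords[j, 2], ]
    sm <- sm + gw[[j]] * sum((t$values - tn)^2)
  }
  unname(fid + sm / nrow(coords))
}

# deterministic 31-bit sub-seed from (seed, iteration, pixel index)
derive_seed <- function(seed, iteration, pixel) {
  x <- (as.numeric(seed) * 2654435761 + as.numeric(iteration) * 40503 +
          as.numeric(pixel) * 69069) %% 2147483647
  x + 1
}

#' Solve one pixel's spectrum by CMA-ES
#'
#' Minimizes [pixel_loss()] over `t in [0,1]^w` with a covariance matrix
#' adaptation evolution strategy, stopping as soon as the loss drops below
#' `tolerance` or the evaluation budget is spent (in which case the best
#' spectrum found is returned, flagged as not having reached tolerance).
#' Candidates are clipped to the physical `[0, 1]` box.  The result never
#' has higher loss than `init`.  An infinite tolerance returns `init`
#' untouched with zero evaluations.
#'
#' @inheritParams pixel_loss
#' @param init starting [pixel_spectrum()].
#' @param tolerance loss value that counts as solved.
#' @param config a [solver_config()] (step size, population, budget, seed).
#' @param iteration outer iteration index used for seed derivation.
#' @return List with `spectrum` ([pixel_spectrum()]), `loss`, `evals`,
#'   `reached`.
#' @export
solve_pixel <- function(m, init, field, light, observed, couplings,
                        tolerance, config = solver_config(),
                        iteration = 1L) {
  if (is.infinite(tolerance))
    return(list(spectrum = init, loss = NA_real_, evals = 0L, reached = TRUE))
  q <- quad_weights(light$grid)
  Lq <- t(q * light$curves) # C x w
  nb <- pixel_neighbors(couplings, m)
  keep <- field$valid[nb$coords]
  coords <- nb$coords[keep, , drop = FALSE]
  gw <- nb$weights[keep]
  nbmat <- matrix(0, length(light$grid), nrow(coords))
  for (j in seq_len(nrow(coords)))
    nbmat[, j] <- field$values[coords[j, 1], coords[j, 2], ]
  pix_index <- (m[2] - 1) * dim(field$values)[1] + m[1]
  res <- .cma_solve(init$values, Lq, as.numeric(observed), nbmat,
                    as.numeric(gw), tolerance, config$budget, config$sigma0,
                    config$population,
                    derive_seed(config$seed, iteration, pix_index))
  list(spectrum = pixel_spectrum(light$grid, res$par),
       loss = res$value, evals = res$evals, reached = res$reached)
}

#' Initial transparency field from the image
#'
#' Flat starting spectra: each pixel gets the constant spectrum
#' `t_i = alpha` with `alpha` the mean over channels of
#' `I_c / integral(L_c)`, clipped to `[0, 1]` -- i.e. the gray level of the
#' pixel relative to the white background.
#'
#' @param image a [channel_image()] (raw counts, or already normalized when
#'   `bit_depth` is 0).
#' @param light an [effective_light()], normalized intensity convention.
#' @return A [transparency_field()] with saturated pixels marked invalid.
#' @export
initialize_field <- function(image, light) {
  ints <- light_integrals(light)
  obs <- normalized_intensities(image)
  alpha <- 0
  for (ch in seq_along(ints)) alpha <- alpha + obs[, , ch] / ints[ch]
  alpha <- pmin(pmax(alpha / length(ints), 0), 1)
  d <- dim(obs)
  vals <- array(rep(as.vector(alpha), length(light$grid)),
                c(d[1], d[2], length(light$grid)))
  transparency_field(vals, light$grid, valid = !image$saturated)
}

normalized_intensities <- function(image) {
  if (image$bit_depth > 0) image$values / (2^image$bit_depth - 1)
  else image$values
}

#' Run the full mean-field reconstruction
#'
#' The outer loop of the method.  Each iteration: (1) obtain edge evidence
#' -- from the PCA grayscale of the raw image at iteration 1, from the
#' zero-lag spectral cross-correlation of the current field afterwards;
#' (2) detect edges (Canny on the Gaussian-smoothed gradient) and rebuild
#' the coupling weights; (3) sweep all valid pixels, re-optimizing each
#' spectrum by CMA-ES at the scheduled tolerance against the neighbours'
#' spectra frozen from the previous sweep (Jacobi-style mean field, so the
#' result does not depend on sweep order); (4) record the mean per-pixel
#' cost and its variation coefficient.  The loop stops when the relative
#' change of mean cost drops below the configured threshold.
#'
#' Saturated pixels are excluded from optimization, keep their initial
#' spectrum, and are flagged invalid in the returned field.
#'
#' @param image a [channel_image()].
#' @param light an [effective_light()] whose per-channel integrals equal the
#'   white-background intensities on the normalized scale (see
#'   [normalize_light()]).
#' @param config a [solver_config()].
#' @param verbose print one line per iteration.
#' @return An object of class `quasispec_result`: list with `field`
#'   (the [transparency_field()]), `trace` (data frame: iteration,
#'   mean_cost, variation_coefficient, tolerance), `cost` (final per-pixel
#'   cost matrix, `NA` at invalid pixels), `converged`, `iterations`,
#'   and `config`.
#' @export
run_reconstruction <- function(image, light, config = solver_config(),
                               verbose = FALSE) {
  stopifnot(inherits(image, "channel_image"),
            inherits(light, "effective_light"))
  d <- dim(image$values)
  w <- length(light$grid)
  field <- initialize_field(image, light)
  valid <- field$valid
  # the loss is evaluated on the intensity_scale convention (percent of
  # full scale by default) so that the exponential fidelity term acts as a
  # soft barrier; see solver_config()
  obs <- normalized_intensities(image) * config$intensity_scale
  q <- quad_weights(light$grid)
  Lq <- t(q * light$curves) * config$intensity_scale

  trace <- data.frame(iteration = integer(0), mean_cost = numeric(0),
                      variation_coefficient = numeric(0),
                      tolerance = numeric(0))
  cost <- matrix(NA_real_, d[1], d[2])
  prev_mean <- NA_real_
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(config$max_iterations)) {
    grad <- if (iter == 1L) {
      if (d[3] >= 2) image_gradient(grayscale_first_pc(image))
      else image_gradient(normalized_intensities(image)[, , 1])
    } else {
      spectral_gradient(field)
    }
    edges <- detect_edges(grad)
    coup <- build_couplings(d[1:2], edges, grad,
                            t_ed = config$t_ed, t_b = config$t_b)
    tol <- tolerance_at(config, iter)

    new_vals <- field$values
    for (cc in seq_len(d[2])) for (rr in seq_len(d[1])) {
      if (!valid[rr, cc]) next
      nb <- pixel_neighbors(coup, c(rr, cc))
      keep <- valid[nb$coords]
      coords <- nb$coords[keep, , drop = FALSE]
      gw <- nb$weights[keep]
      nbmat <- matrix(0, w, nrow(coords))
      for (j in seq_len(nrow(coords)))
        nbmat[, j] <- field$values[coords[j, 1], coords[j, 2], ]
      pix <- (cc - 1L) * d[1] + rr
      res <- .cma_solve(field$values[rr, cc, ], Lq, obs[rr, cc, ], nbmat,
                        as.numeric(gw), tol, config$budget, config$sigma0,
                        config$population,
                        derive_seed(config$seed, iter, pix))
      new_vals[rr, cc, ] <- res$par
      cost[rr, cc] <- res$value
    }
    field$values <- new_vals

    costs <- cost[valid]
    mean_cost <- mean(costs)
    cv <- if (mean_cost > 0) sd(costs) / mean_cost else 0
    trace <- rbind(trace, data.frame(iteration = iter, mean_cost = mean_cost,
                                     variation_coefficient = cv,
                                     tolerance = tol))
    if (verbose)
      message(sprintf("iter %2d  tol %.4f  mean cost %.5f  cv %.3f",
                      iter, tol, mean_cost, cv))
    # the change test is only meaningful once the tolerance has stopped
    # moving: while the schedule still decreases, the cost tracks it
    if (iter > config$tol_horizon && !is.na(prev_mean) &&
        abs(mean_cost - prev_mean) / max(prev_mean, 1e-300) <
          config$change_threshold) {
      converged <- TRUE
      break
    }
    prev_mean <- mean_cost
  }

  structure(list(field = field, trace = trace, cost = cost,
                 converged = converged, iterations = iter, config = config),
            class = "quasispec_result")
}

#' @export
print.quasispec_result <- function(x, ...) {
  d <- dim(x$field$values)
  cat(sprintf(paste0("quasispec reconstruction: %d x %d pixels, %d ",
                     "wavelengths\n  %d iteration(s), %s, final mean cost ",
                     "%.5f\n"),
              d[1], d[2], d[3], x$iterations,
              if (x$converged) "converged" else "not converged",
              x$trace$mean_cost[nrow(x$trace)]))
  invisible(x)
}
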