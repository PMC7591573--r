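test_that("tolerance schedule decreases linearly and then holds", {
  cfg <- solver_config(tol_final = 2, tol_initial = 20, tol_horizon = 10)
  tols <- vapply(1:15, function(i) tolerance_at(cfg, i), numeric(1))
  expect_equal(tols[1], 20)
  expect_equal(tols[10], 2)
  expect_equal(diff(tols[1:10]), rep(-2, 9), tolerance = 1e-12)
  expect_equal(tols[11:15], rep(2, 5))
})

test_that("pixel loss matches an independent scalar transcription", {
  g <- tiny_grid()
  light <- tiny_light(g)
  qw <- quad_weights(g)
  set.seed(11)
  n_cases <- 0
  for (rep in 1:25) {
    h <- sample(3:5, 1); w <- sample(3:5, 1)
    edges <- matrix(runif(h * w) < 0.3, h, w)
    grad <- matrix(runif(h * w), h, w)
    t_ed <- sample(c(1, 1.5, 2), 1)
    cp <- build_couplings(c(h, w), edges, grad, t_ed = t_ed, t_b = 0.9)
    field <- transparency_field(array(runif(h * w * length(g)),
                                      c(h, w, length(g))), g)
    for (k in 1:4) {
      m <- c(sample(h, 1), sample(w, 1))
      tv <- runif(length(g))
      obs <- runif(3, 0, 0.8)
      got <- pixel_loss(m, pixel_spectrum(g, tv), field, light, obs, cp)
      nb <- pixel_neighbors(cp, m)
      nbs <- lapply(seq_len(nrow(nb$coords)), function(j)
        field$values[nb$coords[j, 1], nb$coords[j, 2], ])
      gw <- vapply(seq_len(nrow(nb$coords)), function(j)
        oracle_coupling(m, nb$coords[j, ], edges, grad, 0.9), numeric(1))
      want <- oracle_loss(qw, light$curves, tv, obs, nbs, gw)
      expect_equal(unname(got), unname(want), tolerance = 1e-10)
      n_cases <- n_cases + 1
    }
  }
  expect_gte(n_cases, 100)
})

test_that("solve_pixel reaches a reachable optimum on a small problem", {
  g <- wavelength_grid(c(500, 550, 600, 650))
  light <- effective_light(g, cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)) * 0.01)
  tstar <- pixel_spectrum(g, c(0.2, 0.4, 0.6, 0.8))
  obs <- vapply(1:2, function(ch) forward_integrate(tstar, light, ch),
                numeric(1))
  edges <- matrix(FALSE, 3, 3); grad <- matrix(0, 3, 3)
  cp <- build_couplings(c(3, 3), edges, grad)
  field <- transparency_field(array(rep(tstar$values, each = 9), c(3, 3, 4)), g)
  init <- pixel_spectrum(g, rep(0.5, 4))
  cfg <- solver_config(budget = 2000, seed = 9)
  res <- solve_pixel(c(2, 2), init, field, light, obs, cp,
                     tolerance = 0.01, config = cfg)
  expect_true(res$reached)
  expect_lte(res$loss,
             pixel_loss(c(2, 2), tstar, field, light, obs, cp) + 0.01)
  expect_true(all(res$spectrum$values >= 0 & res$spectrum$values <= 1))
})

test_that("solve_pixel honours the infinite-tolerance and determinism contracts", {
  g <- tiny_grid()
  light <- tiny_light(g)
  edges <- matrix(FALSE, 3, 3); grad <- matrix(0, 3, 3)
  cp <- build_couplings(c(3, 3), edges, grad)
  field <- transparency_field(array(0.5, c(3, 3, length(g))), g)
  init <- pixel_spectrum(g, rep(0.3, length(g)))
  obs <- rep(0.4, 3)
  res_inf <- solve_pixel(c(2, 2), init, field, light, obs, cp, Inf)
  expect_identical(res_inf$spectrum$values, init$values)
  expect_identical(res_inf$evals, 0L)
  cfg <- solver_config(budget = 300, seed = 77)
  r1 <- solve_pixel(c(2, 2), init, field, light, obs, cp, 1e-6, cfg)
  r2 <- solve_pixel(c(2, 2), init, field, light, obs, cp, 1e-6, cfg)
  expect_identical(r1$spectrum$values, r2$spectrum$values)
  expect_identical(r1$loss, r2$loss)
  # the result never degrades the initial loss
  expect_lte(r1$loss, pixel_loss(c(2, 2), init, field, light, obs, cp) + 1e-12)
})

test_that("field initialization reproduces gray levels", {
  g <- tiny_grid()
  light <- tiny_light(g)
  ints <- light_integrals(light)
  vals <- array(0, c(1, 3, 3))
  vals[1, 1, ] <- ints          # white background pixel
  vals[1, 2, ] <- 0             # black pixel
  vals[1, 3, ] <- ints / 2      # half-gray pixel
  img <- channel_image(vals, bit_depth = 0)
  f <- initialize_field(img, light)
  expect_equal(unname(f$values[1, 1, ]), rep(1, length(g)), tolerance = 1e-9)
  expect_equal(unname(f$values[1, 2, ]), rep(0, length(g)))
  expect_equal(unname(f$values[1, 3, ]), rep(0.5, length(g)),
               tolerance = 1e-9)
})

test_that("a uniform background converges almost immediately to a uniform field", {
  g <- tiny_grid()
  light <- tiny_light(g)
  spec <- phantom_spec(size = c(8, 8), n_regions = 1, grid = g,
                       modulation = 0, noise_sigma = 0, seed = 3)
  ph <- make_phantom(spec)
  img <- simulate_camera(ph$field, light, spec)
  # constant schedule so the change rule applies from iteration 2 on
  cfg <- solver_config(tol_horizon = 1, tol_final = 3, budget = 400,
                       seed = 4)
  res <- run_reconstruction(img, light, cfg)
  expect_true(res$converged)
  expect_lte(res$iterations, 3)
  # all pixels face identical subproblems: the field is spatially uniform
  # up to the spread the loss tolerance allows (the smoothness term caps
  # the per-band deviation from the neighbours at sqrt(tol / w))
  per_band_sd <- apply(res$field$values, 3, sd)
  expect_lt(max(per_band_sd), 1.5 * sqrt(cfg$tol_final / 48))
})

test_that("trace bookkeeping honours the configuration contract", {
  g <- tiny_grid()
  light <- tiny_light(g)
  spec <- phantom_spec(size = c(6, 6), grid = g, seed = 8)
  ph <- make_phantom(spec)
  img <- simulate_camera(ph$field, light, spec)
  cfg <- solver_config(max_iterations = 3, budget = 120, seed = 2)
  res <- run_reconstruction(img, light, cfg)
  expect_lte(nrow(res$trace), cfg$max_iterations)
  expect_identical(res$iterations, nrow(res$trace))
  expect_false(res$converged) # cannot converge before the schedule flattens
  expect_true(all(res$trace$mean_cost >= 0))
  expect_equal(res$trace$tolerance,
               vapply(seq_len(nrow(res$trace)),
                      function(i) tolerance_at(cfg, i), numeric(1)))
})

test_that("saturated pixels are excluded and flagged invalid", {
  g <- tiny_grid()
  light <- tiny_light(g)
  spec <- phantom_spec(size = c(6, 6), n_regions = 1, grid = g,
                       modulation = 0, noise_sigma = 0, seed = 5)
  ph <- make_phantom(spec)
  img <- simulate_camera(ph$field, light, spec)
  img$saturated[2, 3] <- TRUE
  cfg <- solver_config(max_iterations = 2, budget = 100, seed = 2)
  res <- run_reconstruction(img, light, cfg)
  expect_false(res$field$valid[2, 3])
  expect_true(is.na(res$cost[2, 3]))
  expect_true(all(!is.na(res$cost[res$field$valid])))
})
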