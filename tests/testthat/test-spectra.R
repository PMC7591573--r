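test_that("grid and spectrum constructors enforce their invariants", {
  expect_error(wavelength_grid(c(500, 450, 600)), "increasing")
  expect_error(wavelength_grid(c(450, 500)), "3 points")
  g <- default_grid()
  expect_length(g, 48)
  expect_equal(range(as.numeric(g)), c(450, 775))
  expect_error(spectrum(g, rep(1, 10)), "match")
  expect_error(pixel_spectrum(g, rep(1.5, 48)), "\\[0, 1\\]")
  expect_error(effective_light(g, matrix(-1, 48, 3)), "non-negative")
})

test_that("Simpson quadrature integrates cubics exactly on even-interval grids", {
  # odd point count -> even interval count -> pure composite Simpson,
  # exact for polynomials up to degree 3 (closed-form integral as oracle)
  g <- wavelength_grid(seq(0, 6, length.out = 7))
  q <- quad_weights(g)
  for (coef in list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(2, -1, 3, 0.5))) {
    f <- function(x) coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3
    Fint <- function(x) coef[1] * x + coef[2] * x^2 / 2 +
      coef[3] * x^3 / 3 + coef[4] * x^4 / 4
    expect_equal(sum(q * f(as.numeric(g))), Fint(6) - Fint(0),
                 tolerance = 1e-12)
  }
})

test_that("the default 48-point grid closes its odd interval with a trapezoid", {
  g <- default_grid()
  q <- quad_weights(g)
  # exact for constants and linears regardless of the parity patch
  expect_equal(sum(q), 775 - 450, tolerance = 1e-9)
  x <- as.numeric(g)
  expect_equal(sum(q * x), (775^2 - 450^2) / 2, tolerance = 1e-6)
  qt <- quad_weights(g, method = "trapezoid")
  expect_equal(sum(qt), 775 - 450, tolerance = 1e-9)
})

test_that("forward_integrate handles the degenerate and constant cases", {
  g <- tiny_grid()
  L <- effective_light(g, matrix(2, length(g), 1))
  expect_equal(forward_integrate(pixel_spectrum(g, rep(0, length(g))), L, 1), 0)
  # t == 1, constant light k: integral k * (b - a)
  expect_equal(forward_integrate(pixel_spectrum(g, rep(1, length(g))), L, 1),
               2 * (775 - 450), tolerance = 1e-9)
  bad <- spectrum(tiny_grid(9, 400, 700), rep(1, 9))
  expect_error(forward_integrate(bad, L, 1), "grids")
})

test_that("forward_integrate is linear and agrees with a dense trapezoid oracle", {
  g <- default_grid()
  light <- tiny_light(g)
  set.seed(42)
  for (rep in 1:5) {
    t1 <- pixel_spectrum(g, runif(48))
    t2 <- pixel_spectrum(g, runif(48))
    a <- runif(1, 0, 0.6); b <- runif(1, 0, 1 - 0.6)
    mix <- pixel_spectrum(g, a * t1$values + b * t2$values)
    for (ch in 1:3) {
      expect_equal(forward_integrate(mix, light, ch),
                   a * forward_integrate(t1, light, ch) +
                     b * forward_integrate(t2, light, ch),
                   tolerance = 1e-10)
    }
  }
  # smooth band-limited integrand: Simpson on the working grid vs a dense
  # trapezoid oracle at 10x resolution of the same analytic curves
  Lfun <- function(l) 0.005 + 0.003 * sin(2 * pi * (l - 450) / 325)
  tfun <- function(l) 0.5 + 0.4 * cos(2 * pi * (l - 450) / 650)
  La <- effective_light(g, matrix(Lfun(as.numeric(g)), ncol = 1))
  ta <- pixel_spectrum(g, tfun(as.numeric(g)))
  fine <- seq(450, 775, length.out = 471)
  dense <- sum(diff(fine) *
                 (head(Lfun(fine) * tfun(fine), -1) +
                    tail(Lfun(fine) * tfun(fine), -1)) / 2)
  expect_lt(abs(forward_integrate(ta, La, 1) - dense) / abs(dense), 1e-3)
})

test_that("forward_image equals pixel-wise forward_integrate and scales linearly", {
  g <- tiny_grid()
  light <- tiny_light(g)
  spec <- phantom_spec(size = c(6, 6), grid = g, modulation = 0, seed = 2)
  ph <- make_phantom(spec)
  img <- forward_image(ph$field, light)
  # two regions with zero modulation -> exactly two intensity levels per channel
  for (ch in 1:3) {
    lev <- sort(unique(round(as.vector(img$values[, , ch]), 12)))
    expect_length(lev, 2)
    for (j in 1:2) {
      px <- which(ph$labels == j, arr.ind = TRUE)[1, ]
      tpix <- pixel_spectrum(g, ph$field$values[px[1], px[2], ])
      expect_equal(img$values[px[1], px[2], ch],
                   forward_integrate(tpix, light, ch), tolerance = 1e-12)
    }
  }
  # uniform field t == 1 -> constant image at the light integrals
  ones <- transparency_field(array(1, c(3, 3, length(g))), g)
  imo <- forward_image(ones, light)
  ints <- light_integrals(light)
  for (ch in 1:3)
    expect_equal(as.vector(imo$values[, , ch]), rep(unname(ints[ch]), 9))
  # scaling the field scales every intensity
  half <- transparency_field(ph$field$values * 0.5, g)
  expect_equal(forward_image(half, light)$values, img$values * 0.5,
               tolerance = 1e-12)
})

test_that("fidelity term is zero at a perfect match and exp-shaped in the residual", {
  g <- tiny_grid()
  light <- tiny_light(g)
  t <- pixel_spectrum(g, rep(0.5, length(g)))
  pred <- vapply(1:3, function(ch) forward_integrate(t, light, ch), numeric(1))
  expect_equal(fidelity_term(t, light, pred), 0)
  # single channel, residual ln 2 -> exactly 1
  L1 <- effective_light(g, matrix(1, length(g), 1))
  p1 <- forward_integrate(t, L1, 1)
  expect_equal(fidelity_term(t, L1, p1 + log(2)), 1, tolerance = 1e-12)
  expect_error(fidelity_term(t, light, c(0, 0)), "channel")
})

test_that("fidelity term is non-negative and monotone in the residual", {
  g <- tiny_grid()
  light <- tiny_light(g)
  set.seed(7)
  for (rep in 1:20) {
    t <- pixel_spectrum(g, runif(length(g)))
    pred <- vapply(1:3, function(ch) forward_integrate(t, light, ch),
                   numeric(1))
    deltas <- sort(abs(rnorm(4)))
    vals <- vapply(deltas, function(d) fidelity_term(t, light, pred + d),
                   numeric(1))
    expect_true(all(vals >= 0))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("normalize_light fixes the per-channel white level", {
  g <- default_grid()
  light <- normalize_light(tiny_light(g), c(0.9, 0.8, 0.7))
  expect_equal(unname(light_integrals(light)), c(0.9, 0.8, 0.7),
               tolerance = 1e-12)
})
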