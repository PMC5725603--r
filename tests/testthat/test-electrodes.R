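test_that("electrode geometry is validated against the design ranges", {
  s <- electrode_spec("bipolar", r = 5)
  expect_equal(s$outer_radius, 10)
  expect_error(electrode_spec("bipolar", r = 2), "6-26")
  expect_error(electrode_spec("bipolar", r = 14), "6-26")
  expect_error(electrode_spec("bipolar", r = 5, disc_radius = 6), "disc_radius")
  expect_error(electrode_spec("bipolar", r = 5, n_samples = 4), "n_samples")
})

test_that("ring averages reproduce closed-form circle integrals", {
  expect_equal(ring_average(make_analytic_field("constant", value = 3),
                            radius = 7), 3)
  # odd terms cancel: linear field averages to the centre value
  lin <- make_analytic_field("linear", a0 = 2, ax = 1.5, ay = -0.7)
  expect_equal(ring_average(lin, center = c(1, 2), radius = 5),
               lin$surface(1, 2))
  # quadratic: mean of x^2 + y^2 on a circle of radius rho is rho^2
  quad <- make_analytic_field("quadratic")
  expect_equal(ring_average(quad, radius = 6), 36, tolerance = 1e-12)
  # annulus of width w around r: r^2 + (w/2)^2
  expect_equal(ring_average(quad, radius = 6, ring_width = 2), 36 + 1,
               tolerance = 1e-12)
  expect_error(ring_average(quad, radius = 0), "positive")
})

test_that("ring quadrature converges at second order on smooth fields", {
  f <- make_analytic_field("dipole", depth = 4, moment = 1, sigma = 0.35)
  ref <- ring_average(f, center = c(1, 0), radius = 6, n_samples = 4096)
  errs <- vapply(c(8, 16, 32), function(n)
    abs(ring_average(f, center = c(1, 0), radius = 6, n_samples = n) - ref),
    numeric(1))
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("monopolar disc averaging is exact on polynomial fields", {
  quad <- make_analytic_field("quadratic")
  spec <- electrode_spec("monopolar", r = 4)   # disc radius 8
  expect_equal(read_monopolar(quad, spec), 8^2 / 2, tolerance = 1e-12)
  expect_equal(read_monopolar(make_analytic_field("constant", value = -2), spec), -2)
  # a shrunk disc approaches the centre value
  tiny <- electrode_spec("monopolar", r = 3)
  f <- make_analytic_field("dipole", depth = 30)
  expect_equal(read_monopolar(f, tiny, center = c(2, 1)),
               f$surface(2, 1), tolerance = 1e-3)
})

test_that("Laplacian estimators are exact on low-degree polynomials", {
  # ring estimators (ideal geometry) and point stencils against the exact
  # in-plane Laplacian, at an off-origin centre so most terms are nonzero
  ctr <- c(0.7, -0.4)
  for (r in c(4, 9)) {
    bip <- ideal_spec("bipolar", r)
    tri <- ideal_spec("tripolar", r)
    for (m in monomial_grid(3)) {
      f <- make_analytic_field("monomial", px = m[1], py = m[2])
      lap <- f$laplacian(ctr[1], ctr[2])
      scale <- max(1, abs(lap))
      expect_lt(abs(laplacian_bipolar(f, bip, ctr) - lap) / scale, 1e-6)
      expect_lt(abs(laplacian_tripolar(f, tri, ctr) - lap) / scale, 1e-6)
      expect_lt(abs(laplacian_five_point(f, ctr, r) - lap) / scale, 1e-6)
      expect_lt(abs(laplacian_nine_point(f, ctr, r) - lap) / scale, 1e-6)
    }
    # fourth-order cancellation: tripolar and nine-point exact to degree 5
    for (m in monomial_grid(5)) {
      f <- make_analytic_field("monomial", px = m[1], py = m[2])
      lap <- f$laplacian(ctr[1], ctr[2])
      scale <- max(1, abs(lap))
      expect_lt(abs(laplacian_tripolar(f, tri, ctr) - lap) / scale, 1e-6)
      expect_lt(abs(laplacian_nine_point(f, ctr, r) - lap) / scale, 1e-6)
    }
  }
})

test_that("five- and nine-point stencils behave as the printed arrangements", {
  r <- 5
  xy <- make_analytic_field("monomial", px = 1, py = 1)
  expect_equal(laplacian_five_point(xy, c(0, 0), r), 0)
  x4 <- make_analytic_field("monomial", px = 4, py = 0)
  # five-point retains a 4th-order error 2 r^2 at the origin ...
  expect_equal(laplacian_five_point(x4, c(0, 0), r), 2 * r^2)
  # ... which the nine-point arrangement cancels
  expect_equal(laplacian_nine_point(x4, c(0, 0), r), 0)
  cst <- make_analytic_field("constant")
  expect_equal(laplacian_nine_point(cst, c(0, 0), r), 0)
})

test_that("bipolar truncation error exceeds tripolar on quartic fields", {
  f <- make_analytic_field("monomial", px = 4, py = 0)
  for (r in c(4, 6, 9)) {
    e_bi <- abs(laplacian_bipolar(f, ideal_spec("bipolar", r), c(0, 0)) - 0)
    e_tri <- abs(laplacian_tripolar(f, ideal_spec("tripolar", r), c(0, 0)) - 0)
    expect_gt(e_bi, e_tri)
  }
})

test_that("the quasi-bipolar reading is the printed unnormalized difference", {
  quad <- make_analytic_field("quadratic")
  for (r in c(4, 8)) {
    spec <- ideal_spec("quasi_bipolar", r)
    # ((2r)^2 + 0)/2 - r^2 = r^2, with no 4/r^2 normalization
    expect_equal(laplacian_quasi_bipolar(quad, spec), r^2, tolerance = 1e-10)
  }
  expect_equal(laplacian_quasi_bipolar(make_analytic_field("constant"),
                                       ideal_spec("quasi_bipolar", 5)), 0)
})

test_that("all estimators are linear in the field", {
  f1 <- make_analytic_field("monomial", px = 3, py = 1)
  f2 <- make_analytic_field("dipole", depth = 12)
  mix <- structure(list(surface = function(x, y)
    2.5 * f1$surface(x, y) - 1.25 * f2$surface(x, y)),
    class = "analytic_field")
  ctr <- c(1, 1)
  readers <- list(
    function(f) read_monopolar(f, electrode_spec("monopolar", r = 5), ctr),
    function(f) laplacian_bipolar(f, ideal_spec("bipolar", 5), ctr),
    function(f) laplacian_quasi_bipolar(f, ideal_spec("quasi_bipolar", 5), ctr),
    function(f) laplacian_tripolar(f, ideal_spec("tripolar", 5), ctr),
    function(f) laplacian_five_point(f, ctr, 5),
    function(f) laplacian_nine_point(f, ctr, 5))
  for (rd in readers) {
    expect_equal(rd(mix), 2.5 * rd(f1) - 1.25 * rd(f2), tolerance = 1e-12)
  }
})

test_that("disc-averaged central element shifts the bipolar estimate by O(a^2)", {
  quad <- make_analytic_field("quadratic")
  r <- 5; a <- 2
  spec <- electrode_spec("bipolar", r = r, disc_radius = a, ring_width = 0,
                         v0_mode = "disc")
  # v0 = a^2/2 exactly, so the estimate is 4 - 2 a^2 / r^2
  expect_equal(laplacian_bipolar(quad, spec), 4 - 2 * a^2 / r^2,
               tolerance = 1e-10)
})

test_that("read_electrode dispatches to the kind-specific reading", {
  f <- make_analytic_field("dipole", depth = 15)
  ctr <- c(0.5, -1)
  pairs <- list(
    list(electrode_spec("monopolar", r = 5), read_monopolar),
    list(electrode_spec("bipolar", r = 5), laplacian_bipolar),
    list(electrode_spec("quasi_bipolar", r = 5), laplacian_quasi_bipolar),
    list(electrode_spec("tripolar", r = 5), laplacian_tripolar))
  for (p in pairs) {
    expect_identical(read_electrode(f, p[[1]], ctr), p[[2]](f, p[[1]], ctr))
  }
})

test_that("surface queries on solved fields project onto the dome", {
  um <- coarse_model()
  band <- default_band()
  f <- solve_forward(um, sensitivity_probe(um, band))
  sf <- surface_fun(f)
  # the local origin is the electrode centre on the skin
  expect_equal(sf(0, 0), field_at(f, c(0, 100, 0)))
  # ring points stay on the sphere of radius 100
  p <- c(10, 100, 0) * 100 / sqrt(10^2 + 100^2)
  expect_equal(sf(10, 0), field_at(f, p))
})
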