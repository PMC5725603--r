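test_that("model constructors validate geometry", {
  expect_error(tissue_layer("skin", -1, 0.1), "non-negative")
  expect_error(tissue_layer("skin", 1, 0), "positive")
  expect_error(abdomen_model(hemisphere_radius = 20), "smaller than the hemisphere")
  expect_error(abdomen_model(box_half_width = 90), "strictly contain")
  expect_error(abdomen_model(box_half_width = 123), "integer multiple")
  expect_error(point_dipole(c(0, 0), c(1, 0, 0)), "length-3")
  expect_error(point_dipole(c(0, 0, Inf), c(1, 0, 0)), "finite")
})

test_that("homogeneous dipole potential has the closed-form structure", {
  d <- point_dipole(c(0, 0, 0), c(0, 0, 2))
  # moment perpendicular to r
  expect_equal(dipole_potential_homogeneous(d, c(5, 0, 0), 0.35), 0)
  # antisymmetric under moment sign flip
  dm <- point_dipole(c(0, 0, 0), c(0, 0, -2))
  x <- c(3, 4, 5)
  expect_equal(dipole_potential_homogeneous(dm, x, 0.35),
               -dipole_potential_homogeneous(d, x, 0.35))
  # 1/r^2 decay on axis
  v1 <- dipole_potential_homogeneous(d, c(0, 0, 10), 0.35)
  v2 <- dipole_potential_homogeneous(d, c(0, 0, 20), 0.35)
  expect_equal(v1 / v2, 4)
  expect_error(dipole_potential_homogeneous(d, c(0, 0, 0), 0.35), "singular")
})

test_that("band discretization conserves the total moment", {
  p <- default_band()
  for (n in c(1, 8, 36)) {
    dips <- discretize_band(p, 11, n_segments = n)
    expect_length(dips, n)
    mags <- vapply(dips, function(d) sqrt(sum(d$moment^2)), numeric(1))
    expect_equal(sum(mags), p$p0)
  }
  # positions lie on the band circle
  dips <- discretize_band(p, 11, n_segments = 16)
  th <- p$theta * pi / 180
  rho <- abs(band_radius(p, 11)) * sin(th)
  rr <- vapply(dips, function(d) sqrt(sum(d$position[1:2]^2)), numeric(1))
  expect_equal(rr, rep(rho, 16))
  # at the apex the circle degenerates to one axial dipole
  apex <- discretize_band(p, p$Ros / p$c, n_segments = 36)
  expect_length(apex, 1)
  expect_equal(abs(apex[[1]]$moment[3]), p$p0)
})

test_that("band discretization converges in the segment count", {
  um <- tiny_uniform(h = 10, half = 120)
  p <- default_band()
  reading <- function(n) {
    f <- solve_forward(um, discretize_band(p, 11, n_segments = n))
    field_at(f, c(0, 100, 0))
  }
  v72 <- reading(72)
  v144 <- reading(144)
  expect_lt(abs(v144 / v72 - 1), 1e-3)
})

test_that("noise dipoles are reproducible and confined to the +x muscle shell", {
  m <- coarse_model()
  cfg <- noise_config(n_dipoles = 6, seed = 42)
  nd1 <- place_noise_dipoles(cfg, m, 2.2e-13)
  nd2 <- place_noise_dipoles(cfg, m, 2.2e-13)
  expect_identical(nd1, nd2)
  expect_length(nd1, 6)
  r <- vapply(nd1, function(d) sqrt(sum(d$position^2)), numeric(1))
  expect_true(all(r >= 75 & r <= 83))
  expect_true(all(vapply(nd1, function(d) d$position[1], numeric(1)) > 0))
  expect_true(all(vapply(nd1, function(d) d$position[2], numeric(1)) >= 0))
  mags <- vapply(nd1, function(d) sqrt(sum(d$moment^2)), numeric(1))
  expect_equal(mags, rep(0.1 * 2.2e-13, 6))
  expect_identical(place_noise_dipoles(noise_config(n_dipoles = 0), m), list())
  # a different seed moves the dipoles
  nd3 <- place_noise_dipoles(noise_config(seed = 43), m, 2.2e-13)
  expect_false(identical(nd1, nd3))
})

test_that("zero sources give an identically zero field", {
  um <- tiny_uniform()
  f <- solve_forward(um, list())
  expect_true(all(f$phi == 0))
})

test_that("the discrete solve is exactly linear in the sources", {
  um <- tiny_uniform()   # direct factorization path
  d1 <- point_dipole(c(0, 0, 0), c(0, 1e-13, 0))
  d2 <- point_dipole(c(10, -5, 5), c(5e-14, 0, 1e-13))
  f1 <- solve_forward(um, d1)
  f2 <- solve_forward(um, d2)
  f12 <- solve_forward(um, list(d1, d2))
  pts <- rbind(c(20, 10, 0), c(0, -25, 10), c(-15, 15, 15))
  s <- field_at(f1, pts) + field_at(f2, pts)
  expect_equal(field_at(f12, pts), s, tolerance = 1e-12)
})

test_that("the uniform-box solve matches the analytic dipole oracle", {
  um <- tiny_uniform(h = 5, half = 80)
  d <- point_dipole(c(0, 0, 0), c(0, 2.2e-13, 0))
  f <- solve_forward(um, d)
  set.seed(3)
  u <- matrix(rnorm(120), ncol = 3); u <- u / sqrt(rowSums(u^2))
  # coarse-grid sanity bound; the production-resolution 2% bound is part
  # of the acceptance suite
  for (rc in c(25, 30)) {   # 5-6 cells from source, >= 10 cells from boundary
    pts <- u * rc
    ana <- dipole_potential_homogeneous(d, pts, 0.35)
    num <- field_at(f, pts)
    expect_lt(mean(abs(num - ana)) / max(abs(ana)), 0.03)
  }
})

test_that("equal-conductivity layers reduce to the homogeneous medium", {
  sg <- 0.2
  m <- abdomen_model(layers = list(tissue_layer("skin", 2, sg),
                                   tissue_layer("fat", 15, sg),
                                   tissue_layer("muscle", 8, sg)),
                     interior_conductivity = sg, air_conductivity = sg,
                     myometrium_grounded = FALSE,
                     grid_spacing = 5, box_half_width = 120)
  d <- point_dipole(c(0, 30, 0), c(0, 2.2e-13, 0))
  f <- solve_forward(m, d)
  pts <- rbind(c(0, 60, 0), c(25, 45, 10), c(0, 40, -30), c(-20, 0, 20))
  # degenerate layers are indistinguishable from the uniform medium on the
  # same grid ...
  um <- uniform_box_model(sigma = sg, grid_spacing = 5, box_half_width = 120)
  fu <- solve_forward(um, d)
  num <- field_at(f, pts)
  expect_equal(num, field_at(fu, pts), tolerance = 1e-8)
  # ... and track the unbounded-medium closed form up to the grounded-box
  # truncation of this domain
  ana <- dipole_potential_homogeneous(d, pts, sg)
  expect_lt(max(abs(num - ana)) / max(abs(ana)), 0.05)
})

test_that("halving the grid spacing converges at first order or better", {
  # self-convergence: successive-solution differences are free of the
  # (h-independent) domain-truncation error
  d <- point_dipole(c(0, 0, 0), c(0, 2.2e-13, 0))
  pts <- rbind(c(0, 40, 0), c(28, 28, 0), c(0, 30, 30))
  sol <- lapply(c(20, 10, 5), function(h)
    field_at(solve_forward(tiny_uniform(h = h, half = 80), d), pts))
  d1 <- max(abs(sol[[1]] - sol[[2]]))
  d2 <- max(abs(sol[[2]] - sol[[3]]))
  expect_lt(d2, d1)
  expect_gt(log2(d1 / d2), 1)
})

test_that("interior extrema sit at the source (discrete maximum principle)", {
  um <- tiny_uniform()
  d <- point_dipole(c(0, 0, 0), c(0, 1e-13, 0))
  f <- solve_forward(um, d)
  idx <- which(abs(f$phi) == max(abs(f$phi)), arr.ind = TRUE)[1, ]
  src_idx <- (c(0, 0, 0) + 60) / 5 + 1
  expect_true(all(abs(idx - src_idx) <= 2))
})

test_that("field queries outside the solved box are refused", {
  um <- tiny_uniform()
  f <- solve_forward(um, point_dipole(c(0, 0, 0), c(0, 1e-13, 0)))
  expect_error(field_at(f, c(0, 0, 61)), "outside")
  expect_error(field_at(f, c(-70, 0, 0)), "outside")
})

test_that("sources adjacent to the grounded box are rejected", {
  um <- tiny_uniform()
  expect_error(solve_forward(um, point_dipole(c(0, 0, 58), c(0, 0, 1e-13))),
               "placement")
})

test_that("the grounded myometrium screens the uterine interior", {
  m <- coarse_model()
  band <- default_band()
  f <- solve_forward(m, sensitivity_probe(m, band))
  # grounded nodes carry exactly zero potential
  expect_identical(field_at(f, c(0, 0, 0)), 0)
  expect_identical(field_at(f, c(0, 50, 0)), 0)
  # while the abdominal wall above the source does not
  expect_gt(abs(field_at(f, c(0, 90, 0))), 0)
})
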