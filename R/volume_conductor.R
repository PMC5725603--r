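#' A tissue layer of the abdominal wall
#'
#' @param name Layer name (`"skin"`, `"fat"` or `"muscle"`).
#' @param thickness Layer thickness, mm (>= 0).
#' @param conductivity Electrical conductivity, S/m (> 0).
#' @param relative_permittivity Relative permittivity (dimensionless).  Not
#'   used by the quasi-static forward solve (EHG is sub-Hz); retained for
#'   completeness and frequency-dependent extensions.
#' @return An object of class `tissue_layer`.
#' @export
tissue_layer <- function(name, thickness, conductivity, relative_permittivity = NA_real_) {
  if (thickness < 0) stop("layer thickness must be non-negative")
  if (conductivity <= 0) stop("layer conductivity must be positive")
  structure(list(name = name, thickness = thickness,
                 conductivity = conductivity,
                 relative_permittivity = relative_permittivity),
            class = "tissue_layer")
}

#' Default three-layer abdominal wall
#'
#' Skin (2 mm), fat (15 mm) and muscle (8 mm), ordered outer to inner.
#' Thicknesses and relative permittivities are the standard abdomen values;
#' low-frequency conductivities (skin 2e-4, fat 0.04, muscle 0.35 S/m) are
#' standard literature values for sub-kHz bioelectric modelling.
#'
#' @return A list of three [tissue_layer()] objects.
#' @export
default_layers <- function() {
  list(tissue_layer("skin",   2, 2e-4, 40.01),
       tissue_layer("fat",   15, 0.04, 12.79),
       tissue_layer("muscle", 8, 0.35, 66.21))
}

#' Layered hemispherical abdomen volume-conductor model
#'
#' The abdomen of a pregnant woman is modelled as a hemispherical dome of
#' radius `hemisphere_radius` (the `y >= 0` half of a sphere centred on the
#' uterus centre, the coordinate origin).  The outermost shells of the dome
#' are the skin, fat and muscle layers; the remaining interior is the
#' uterine region, dominated by amniotic fluid.  The model is immersed in
#' air inside a grounded bounding box (potential 0 on the box faces).
#'
#' Axes: z is the longitudinal (fundus-cervix) axis along which the dipole
#' band travels, +y points anteriorly towards the recording electrode at
#' `(0, hemisphere_radius, 0)`, and x is lateral.
#'
#' @param hemisphere_radius Dome radius, mm.
#' @param layers Tissue layers ordered outer to inner; see [default_layers()].
#' @param interior_conductivity Conductivity of the uterine interior, S/m.
#'   The default 1.6 S/m is an amniotic-fluid-dominated value (only used
#'   when the myometrium is not grounded).
#' @param myometrium_grounded The myometrium (the surface of the innermost
#'   region) is held at potential 0, the model's reference: the default,
#'   matching the electrically quiet, highly conductive uterine contents
#'   acting as the return path.  The dipole band rides just outside this
#'   grounded surface.
#' @param air_conductivity Small positive regularization conductivity for
#'   the air region, S/m.
#' @param grid_spacing Finite-difference grid spacing, mm.
#' @param box_half_width Half-width of the grounded bounding box, mm; must
#'   exceed `hemisphere_radius` and be an integer multiple of `grid_spacing`.
#' @param solver_tol Relative-residual tolerance of the iterative solve.
#' @param solver_maxit Iteration cap of the iterative solve.
#' @return An object of class `abdomen_model`.
#' @export
abdomen_model <- function(hemisphere_radius = 100,
                          layers = default_layers(),
                          interior_conductivity = 1.6,
                          myometrium_grounded = TRUE,
                          air_conductivity = 1e-8,
                          grid_spacing = 5,
                          box_half_width = 120,
                          solver_tol = 1e-10,
                          solver_maxit = 20000) {
  thick <- vapply(layers, `[[`, numeric(1), "thickness")
  if (sum(thick) >= hemisphere_radius)
    stop("sum of layer thicknesses must be smaller than the hemisphere radius")
  if (box_half_width <= hemisphere_radius)
    stop("bounding box must strictly contain the hemisphere")
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  if (abs(box_half_width / grid_spacing - round(box_half_width / grid_spacing)) > 1e-9)
    stop("box_half_width must be an integer multiple of grid_spacing")
  if (air_conductivity <= 0) stop("air_conductivity must be positive")
  m <- structure(list(hemisphere_radius = hemisphere_radius, layers = layers,
                      interior_conductivity = interior_conductivity,
                      myometrium_grounded = isTRUE(myometrium_grounded),
                      air_conductivity = air_conductivity,
                      grid_spacing = grid_spacing,
                      box_half_width = box_half_width,
                      solver_tol = solver_tol, solver_maxit = solver_maxit,
                      uniform_sigma = NULL,
                      cache = new.env(parent = emptyenv())),
                 class = "abdomen_model")
  m
}

#' Uniform-conductivity box model
#'
#' A homogeneous medium filling the whole bounding box, used as the analytic
#' oracle geometry for solver verification (a point dipole in an unbounded
#' uniform conductor has the closed-form potential
#' [dipole_potential_homogeneous()]).
#'
#' @param sigma Conductivity of the medium, S/m.
#' @inheritParams abdomen_model
#' @return An object of class `abdomen_model` with a uniform medium.
#' @export
uniform_box_model <- function(sigma = 0.35, grid_spacing = 5, box_half_width = 120,
                              solver_tol = 1e-10, solver_maxit = 20000) {
  m <- abdomen_model(hemisphere_radius = box_half_width / 2,
                     myometrium_grounded = FALSE,
                     grid_spacing = grid_spacing,
                     box_half_width = box_half_width,
                     solver_tol = solver_tol, solver_maxit = solver_maxit)
  m$uniform_sigma <- sigma
  m
}

#' Point on the skin surface where the electrode is centred
#'
#' @param model An [abdomen_model()].
#' @return A length-3 position, mm.
#' @export
surface_center <- function(model) c(0, model$hemisphere_radius, 0)

#' A point current dipole
#'
#' @param position Length-3 position, mm.
#' @param moment Length-3 dipole moment vector (model units of C·mm).
#' @return An object of class `point_dipole`.
#' @export
point_dipole <- function(position, moment) {
  if (length(position) != 3 || length(moment) != 3 ||
      !all(is.finite(position)) || !all(is.finite(moment)))
    stop("position and moment must be finite length-3 vectors")
  structure(list(position = as.numeric(position), moment = as.numeric(moment)),
            class = "point_dipole")
}

#' Potential of a point dipole in an unbounded homogeneous conductor
#'
#' The quasi-static closed form `m . r / (4 pi sigma |r|^3)` with
#' `r = x - position`.  Serves as the analytic oracle for the
#' finite-difference solver.
#'
#' @param d A [point_dipole()].
#' @param x A length-3 point or an `n x 3` matrix of points, mm.
#' @param sigma Medium conductivity, S/m.
#' @return Potential(s), model units.
#' @export
dipole_potential_homogeneous <- function(d, x, sigma) {
  stopifnot(inherits(d, "point_dipole"))
  x <- if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
  r <- sweep(x, 2, d$position)
  rn <- sqrt(rowSums(r^2))
  if (any(rn == 0)) stop("singular evaluation: point coincides with the dipole position")
  as.numeric((r %*% d$moment) / (4 * pi * sigma * rn^3))
}

#' Discretize the dipole band into point dipoles
#'
#' Places `n_segments` point dipoles uniformly around the band circle of
#' radius `|R(t)| sin(theta)` at the band's axial position, each carrying
#' moment `p0 / n_segments` directed along the local wall (slant) direction,
#' so the summed moment magnitude equals `p0`.  A band at the cone apex
#' degenerates to a single axial dipole.
#'
#' @param params A [dipole_band_params()].
#' @param t Time, s.
#' @param n_segments Number of segments (>= 1; >= 8 recommended, and >= 72
#'   for sub-0.1% surface-potential convergence).
#' @param center Offset added to all positions (the band axis passes through
#'   `center` parallel to z), mm.
#' @return A list of [point_dipole()] objects.
#' @export
discretize_band <- function(params, t, n_segments = 72, center = c(0, 0, 0)) {
  stopifnot(inherits(params, "dipole_band_params"), n_segments >= 1)
  th <- theta_rad(params)
  R <- band_radius(params, t)
  rho <- abs(R) * sin(th)
  zc <- R * cos(th)
  if (rho < 1e-9) {
    return(list(point_dipole(center + c(0, 0, zc), c(0, 0, -params$p0))))
  }
  phi <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  m1 <- params$p0 / n_segments
  lapply(seq_len(n_segments), function(k) {
    pos <- center + c(rho * cos(phi[k]), rho * sin(phi[k]), zc)
    dirn <- -c(sin(th) * cos(phi[k]), sin(th) * sin(phi[k]), cos(th))
    point_dipole(pos, m1 * dirn)
  })
}

#' Noise-dipole configuration
#'
#' @param n_dipoles Number of noise dipoles (>= 0).
#' @param moment_scale Moment magnitude as a fraction of the band moment p0.
#' @param seed Integer seed making the placement reproducible.
#' @param max_angle_deg Angular half-width of the placement region about the
#'   +x axis, degrees: dipoles are placed in the muscle shell toward the
#'   positive x direction, within this angle of the x axis, in the dome
#'   (`y >= 0`).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(n_dipoles = 6, moment_scale = 0.1, seed = 1L,
                         max_angle_deg = 60) {
  if (n_dipoles < 0) stop("n_dipoles must be non-negative")
  if (moment_scale < 0) stop("moment_scale must be non-negative")
  structure(list(n_dipoles = as.integer(n_dipoles), moment_scale = moment_scale,
                 seed = as.integer(seed), max_angle_deg = max_angle_deg),
            class = "noise_config")
}

with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Place random noise dipoles in the muscle shell
#'
#' Positions are sampled uniformly in the part of the muscle shell lying in
#' the dome (`y >= 0`) within `max_angle_deg` of the +x axis; moments have
#' magnitude `moment_scale * p0` and uniformly random orientation.  The
#' result is reproducible for a fixed seed.
#'
#' @param cfg A [noise_config()].
#' @param model An [abdomen_model()].
#' @param p0 Reference dipole moment (the band moment), C·mm.
#' @return A list of [point_dipole()] objects (empty when `n_dipoles = 0`).
#' @export
place_noise_dipoles <- function(cfg, model, p0 = 2.2e-13) {
  stopifnot(inherits(cfg, "noise_config"), inherits(model, "abdomen_model"))
  if (cfg$n_dipoles == 0) return(list())
  thick <- vapply(model$layers, `[[`, numeric(1), "thickness")
  r_out <- model$hemisphere_radius - sum(thick[seq_len(length(thick) - 1)])
  r_in <- model$hemisphere_radius - sum(thick)
  cos_max <- cos(cfg$max_angle_deg * pi / 180)
  with_local_seed(cfg$seed, {
    out <- vector("list", cfg$n_dipoles)
    k <- 0
    while (k < cfg$n_dipoles) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      if (u[1] < cos_max || u[2] < 0) next
      r <- (stats::runif(1) * (r_out^3 - r_in^3) + r_in^3)^(1 / 3)
      m <- stats::rnorm(3)
      m <- m / sqrt(sum(m^2)) * cfg$moment_scale * p0
      k <- k + 1
      out[[k]] <- point_dipole(r * u, m)
    }
    out
  })
}

# ---- finite-difference machinery ------------------------------------------

# Radially sub-grid-averaged conductivity at the grid nodes.  Within each
# cell the tissue shells crossed by the radial interval [r-h/2, r+h/2] act
# as series resistors, so the cell conductivity is the thickness-weighted
# harmonic mean; this represents shells thinner than the grid spacing
# (notably the 2 mm skin) on coarse grids.
sigma_field <- function(model) {
  h <- model$grid_spacing
  xc <- seq(-model$box_half_width, model$box_half_width, by = h)
  n <- length(xc)
  if (!is.null(model$uniform_sigma)) {
    return(list(xc = xc, n = n, h = h,
                sig = array(model$uniform_sigma, dim = c(n, n, n))))
  }
  thick <- vapply(model$layers, `[[`, numeric(1), "thickness")
  cond <- vapply(model$layers, `[[`, numeric(1), "conductivity")
  Rh <- model$hemisphere_radius
  # radial bands from the centre out: interior | inner..outer layers | air
  # (zero-thickness layers give empty bands and contribute nothing)
  brk <- c(0, Rh - rev(cumsum(thick)), Rh, Inf)
  sig_bands <- c(model$interior_conductivity, rev(cond), model$air_conductivity)
  g <- expand.grid(x = xc, y = xc, z = xc)
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  lo <- pmax(r - h / 2, 0); hi <- r + h / 2
  inv <- numeric(length(r))
  for (i in seq_along(sig_bands)) {
    ov <- pmax(0, pmin(hi, brk[i + 1]) - pmax(lo, brk[i]))
    inv <- inv + ov / sig_bands[i]
  }
  s <- (hi - lo) / inv
  s[g$y < 0] <- model$air_conductivity
  list(xc = xc, n = n, h = h, sig = array(s, dim = c(n, n, n)))
}

# Assemble the 7-point variable-coefficient operator over interior unknowns
# with harmonic-mean face conductances and Dirichlet phi = 0 on the box
# faces.  Cached on the model object.
model_grid <- function(model) {
  stopifnot(inherits(model, "abdomen_model"))
  cache <- model$cache
  if (!is.null(cache$grid)) return(cache$grid)
  sf <- sigma_field(model)
  n <- sf$n; h <- sf$h; sig <- sf$sig
  active <- array(FALSE, dim = c(n, n, n))
  active[2:(n - 1), 2:(n - 1), 2:(n - 1)] <- TRUE
  if (model$myometrium_grounded && is.null(model$uniform_sigma)) {
    # Dirichlet phi = 0 on the myometrium: ground every node whose cell
    # lies fully inside the innermost tissue boundary (r < r_in - h/2),
    # so interface-straddling nodes stay active and near-wall sources are
    # deposited intact
    thick <- sum(vapply(model$layers, `[[`, numeric(1), "thickness"))
    r_in <- model$hemisphere_radius - thick
    g <- expand.grid(x = sf$xc, y = sf$xc, z = sf$xc)
    inside <- array(g$x^2 + g$y^2 + g$z^2 < (r_in - h / 2)^2 & g$y >= 0,
                    dim = c(n, n, n))
    active[inside] <- FALSE
  }
  unk <- array(0L, dim = c(n, n, n))
  unk[active] <- seq_len(sum(active))
  nunk <- sum(active)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (d in 1:3) {
    if (d == 1) { a <- unk[1:(n - 1), , ]; b <- unk[2:n, , ]
                  g <- 2 * sig[1:(n - 1), , ] * sig[2:n, , ] /
                       (sig[1:(n - 1), , ] + sig[2:n, , ]) * h }
    if (d == 2) { a <- unk[, 1:(n - 1), ]; b <- unk[, 2:n, ]
                  g <- 2 * sig[, 1:(n - 1), ] * sig[, 2:n, ] /
                       (sig[, 1:(n - 1), ] + sig[, 2:n, ]) * h }
    if (d == 3) { a <- unk[, , 1:(n - 1)]; b <- unk[, , 2:n]
                  g <- 2 * sig[, , 1:(n - 1)] * sig[, , 2:n] /
                       (sig[, , 1:(n - 1)] + sig[, , 2:n]) * h }
    a <- as.integer(a); b <- as.integer(b); g <- as.numeric(g)
    both <- a > 0L & b > 0L
    ii <- c(ii, a[both], b[both], a[a > 0L], b[b > 0L])
    jj <- c(jj, b[both], a[both], a[a > 0L], b[b > 0L])
    xx <- c(xx, -g[both], -g[both], g[a > 0L], g[b > 0L])
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nunk, nunk))
  grid <- list(xc = sf$xc, n = n, nunk = nunk, h = h, sig = sig, unk = unk,
               active = active, A = A, dinv = 1 / Matrix::diag(A))
  cache$grid <- grid
  grid
}

# Trilinear (cloud-in-cell) deposition of a point charge onto the unknown
# vector; boundary corners are grounded and must not receive charge.
deposit_charge <- function(grid, b, p, q) {
  half <- -grid$xc[1]; h <- grid$h; n <- grid$n
  if (any(p <= grid$xc[2] - h / 2) || any(p >= grid$xc[n - 1] + h / 2))
    stop("source placement error: dipole too close to the bounding box")
  f <- (p + half) / h
  i0 <- pmin(pmax(floor(f), 0), n - 2)
  t <- f - i0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[1] else 1 - t[1]) *
         (if (dy) t[2] else 1 - t[2]) *
         (if (dz) t[3] else 1 - t[3])
    if (w == 0) next
    ix <- i0[1] + 1 + dx; iy <- i0[2] + 1 + dy; iz <- i0[3] + 1 + dz
    u <- grid$unk[ix, iy, iz]
    if (u == 0L) {
      n <- grid$n
      if (any(c(ix, iy, iz) %in% c(1L, n)))
        stop("source placement error: dipole adjacent to the grounded bounding box")
      next   # charge sunk into the grounded myometrium
    }
    b[u] <- b[u] + q * w
  }
  b
}

# TRUE when every node of the trilinear support of `p` is an unknown
charges_clear <- function(grid, p) {
  half <- -grid$xc[1]; h <- grid$h; n <- grid$n
  if (any(p <= grid$xc[2] - h / 2) || any(p >= grid$xc[n - 1] + h / 2))
    return(FALSE)
  f <- (p + half) / h
  i0 <- pmin(pmax(floor(f), 0), n - 2)
  t <- f - i0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[1] else 1 - t[1]) *
         (if (dy) t[2] else 1 - t[2]) *
         (if (dz) t[3] else 1 - t[3])
    if (w == 0) next
    if (grid$unk[i0[1] + 1 + dx, i0[2] + 1 + dy, i0[3] + 1 + dz] == 0L)
      return(FALSE)
  }
  TRUE
}

# Right-hand side for a list of point dipoles.  Each dipole component is
# represented by two nested +/- monopole pairs along its axis (separations
# 2h and 4h, moments 4m/3 and -m/3): the Richardson combination cancels
# the O((h/r)^2) finite-separation bias of a single pair.  Where the wide
# stencil would overlap a grounded region it falls back to the compact
# +/- pair at separation h, which keeps near-wall sources intact.
build_rhs <- function(grid, sources) {
  if (inherits(sources, "point_dipole")) sources <- list(sources)
  b <- numeric(grid$nunk)
  h <- grid$h
  wide <- list(c(h, 4 / 3), c(2 * h, -1 / 3))
  narrow <- list(c(h / 2, 1))
  for (d in sources) {
    for (k in 1:3) {
      if (d$moment[k] == 0) next
      e <- c(0, 0, 0); e[k] <- 1
      ok <- all(vapply(wide, function(pair)
        charges_clear(grid, d$position + pair[1] * e) &&
        charges_clear(grid, d$position - pair[1] * e), logical(1)))
      for (pair in if (ok) wide else narrow) {
        q <- pair[2] * d$moment[k] / (2 * pair[1])
        b <- deposit_charge(grid, b, d$position + pair[1] * e, q)
        b <- deposit_charge(grid, b, d$position - pair[1] * e, -q)
      }
    }
  }
  b
}

cg_solve <- function(A, dinv, b, tol, maxit) {
  x <- numeric(length(b))
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = x, iterations = 0L, relres = 0))
  r <- b
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  for (k in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rn <- sqrt(sum(r^2))
    if (rn < tol * nb) return(list(x = x, iterations = k, relres = rn / nb))
    z <- dinv * r
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  stop(sprintf(
    "solver failure: CG did not reach tol %.1e in %d iterations (relres %.2e, %d unknowns)",
    tol, maxit, rn / nb, length(b)))
}

solve_system <- function(model, grid, B) {
  direct <- grid$nunk <= 15000
  if (direct) {
    if (is.null(model$cache$chol))
      model$cache$chol <- Matrix::Cholesky(Matrix::forceSymmetric(grid$A),
                                           LDL = FALSE, perm = TRUE)
    X <- as.matrix(Matrix::solve(model$cache$chol, B, system = "A"))
    list(X = X, iterations = 0L, method = "direct")
  } else {
    B <- as.matrix(B)
    X <- matrix(0, nrow(B), ncol(B))
    it <- 0L
    for (j in seq_len(ncol(B))) {
      s <- cg_solve(grid$A, grid$dinv, B[, j], model$solver_tol, model$solver_maxit)
      X[, j] <- s$x
      it <- max(it, s$iterations)
    }
    list(X = X, iterations = it, method = "cg")
  }
}

make_field <- function(model, grid, x) {
  n <- grid$n
  phi <- array(0, dim = c(n, n, n))
  phi[grid$active] <- x
  structure(list(phi = phi, xc = grid$xc, h = grid$h, n = n,
                 center = surface_center(model),
                 radius = model$hemisphere_radius,
                 model = model),
            class = "potential_field")
}

#' Solve the quasi-static forward problem
#'
#' Solves `div(sigma grad phi) = -div(source)` on a regular grid over the
#' grounded bounding box (Dirichlet `phi = 0` on the box faces, the
#' infinite-air far field), with the piecewise tissue conductivity of the
#' model and harmonic-mean face conductances.  Small systems are solved by
#' sparse Cholesky, larger ones by Jacobi-preconditioned conjugate
#' gradients to the model's `solver_tol`.
#'
#' @param model An [abdomen_model()] (or [uniform_box_model()]).
#' @param sources A [point_dipole()] or list of them; all strictly inside
#'   the solved domain.
#' @return A `potential_field` object; query it with [field_at()] or
#'   [surface_fun()].  Attributes `iterations` and `method` carry solver
#'   diagnostics.
#' @export
solve_forward <- function(model, sources) {
  grid <- model_grid(model)
  b <- build_rhs(grid, sources)
  s <- solve_system(model, grid, matrix(b, ncol = 1))
  f <- make_field(model, grid, s$X[, 1])
  attr(f, "iterations") <- s$iterations
  attr(f, "method") <- s$method
  f
}

#' Solve the forward problem for several source sets at once
#'
#' Shares the operator assembly/factorization across right-hand sides; much
#' faster than repeated [solve_forward()] calls for sweeps over source
#' positions.
#'
#' @inheritParams solve_forward
#' @param source_sets A list; each element a list of [point_dipole()]s.
#' @return A list of `potential_field` objects.
#' @export
solve_forward_many <- function(model, source_sets) {
  grid <- model_grid(model)
  B <- vapply(source_sets, function(s) build_rhs(grid, s), numeric(grid$nunk))
  s <- solve_system(model, grid, B)
  lapply(seq_along(source_sets), function(j) make_field(model, grid, s$X[, j]))
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("Potential field on a %d^3 grid (h = %g mm, box half-width %g mm)\n",
              x$n, x$h, -x$xc[1]))
  invisible(x)
}

#' Query a solved potential field at arbitrary points
#'
#' Trilinear interpolation on the solved grid.  Points outside the solved
#' box raise an error (no extrapolation).
#'
#' @param field A `potential_field` from [solve_forward()].
#' @param points A length-3 point or `n x 3` matrix, mm.
#' @return Potential(s), model units.
#' @export
field_at <- function(field, points) {
  stopifnot(inherits(field, "potential_field"))
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  half <- -field$xc[1]; h <- field$h; n <- field$n
  if (any(p < -half) || any(p > half))
    stop("query outside the solved domain")
  f <- (p + half) / h
  i0 <- pmin(pmax(floor(f), 0), n - 2)
  t <- f - i0
  v <- numeric(nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[, 1] else 1 - t[, 1]) *
         (if (dy) t[, 2] else 1 - t[, 2]) *
         (if (dz) t[, 3] else 1 - t[, 3])
    lin <- (i0[, 1] + 1 + dx) + (i0[, 2] + dy) * n + (i0[, 3] + dz) * n^2
    v <- v + w * field$phi[lin]
  }
  v
}

#' Surface-restricted field query in local electrode-plane coordinates
#'
#' Returns a function `f(x, y)` giving the surface potential at local
#' tangent-plane coordinates `(x, y)` (mm) around the electrode centre.
#' Sample points are generated in the tangent plane at the centre and
#' projected radially onto the spherical skin surface before querying the
#' volume field; the projection error is second order in (ring radius /
#' dome radius).
#'
#' @param field A `potential_field` or an `analytic_field`
#'   (see [make_analytic_field()]).
#' @param ... Unused.
#' @return A vectorized function of two local coordinates.
#' @export
surface_fun <- function(field, ...) UseMethod("surface_fun")

#' @export
surface_fun.potential_field <- function(field, ...) {
  c0 <- field$center
  rad <- sqrt(sum(c0^2))
  nrm <- c0 / rad
  e1 <- c(nrm[2] * 1 - nrm[3] * 0, nrm[3] * 0 - nrm[1] * 1, nrm[1] * 0 - nrm[2] * 0)
  if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0) else e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e1[2] * nrm[3] - e1[3] * nrm[2],
          e1[3] * nrm[1] - e1[1] * nrm[3],
          e1[1] * nrm[2] - e1[2] * nrm[1])
  function(x, y) {
    p <- cbind(c0[1] + x * e1[1] + y * e2[1],
               c0[2] + x * e1[2] + y * e2[2],
               c0[3] + x * e1[3] + y * e2[3])
    pn <- sqrt(rowSums(p^2))
    field_at(field, p * (rad / pn))
  }
}
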