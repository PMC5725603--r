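#' Surface-electrode specification
#'
#' Four read-out designs share the concentric geometry of a central disc, a
#' middle ring at radius `r` and an outer ring at radius `2r`:
#' \describe{
#'   \item{monopolar}{a disc of radius `2r` reading the area-averaged
#'     surface potential;}
#'   \item{bipolar}{disc + outer ring, estimating the surface Laplacian as
#'     `(4 / r^2) (ring(r) - v0)`;}
#'   \item{quasi_bipolar}{disc shorted to the outer ring, reading
#'     `(v_or + v0) / 2 - v_mr` (an unnormalized potential difference);}
#'   \item{tripolar}{three independent elements, estimating
#'     `(1 / 3r^2) (16 (ring(r) - v0) - (ring(2r) - v0))`, which cancels
#'     the fourth-order truncation term.}
#' }
#'
#' @param kind One of `"monopolar"`, `"bipolar"`, `"quasi_bipolar"`,
#'   `"tripolar"`.
#' @param r Middle-ring radius, mm.  The outer ring radius is `2r` (fixed
#'   geometry ratio); `2r` must lie in the 6-26 mm design range.
#' @param disc_radius Central disc radius, mm (design range 1.7-3.6 mm,
#'   must be smaller than `r`).
#' @param ring_width Physical ring width, mm, identical across the
#'   Laplacian kinds; `0` gives ideal line rings.
#' @param n_samples Angular quadrature samples per ring.
#' @param v0_mode `"disc"` averages the central element over its disc (the
#'   physical electrode), `"point"` uses the centre point value (the ideal
#'   stencil of the estimator equations).
#' @return An object of class `electrode_spec`.
#' @export
electrode_spec <- function(kind = c("monopolar", "bipolar", "quasi_bipolar", "tripolar"),
                           r = 5, disc_radius = 2.5, ring_width = 1,
                           n_samples = 360, v0_mode = c("disc", "point")) {
  kind <- match.arg(kind)
  v0_mode <- match.arg(v0_mode)
  if (r <= 0) stop("ring radius `r` must be positive")
  outer_radius <- 2 * r
  if (outer_radius < 6 - 1e-9 || outer_radius > 26 + 1e-9)
    stop("outer ring radius 2r must lie within the 6-26 mm design range")
  if (disc_radius <= 0 || disc_radius >= r)
    stop("disc_radius must be positive and smaller than r")
  if (ring_width < 0) stop("ring_width must be non-negative")
  if (n_samples < 8) stop("n_samples must be at least 8")
  structure(list(kind = kind, r = r, outer_radius = outer_radius,
                 disc_radius = disc_radius, ring_width = ring_width,
                 n_samples = as.integer(n_samples), v0_mode = v0_mode),
            class = "electrode_spec")
}

#' @export
print.electrode_spec <- function(x, ...) {
  cat(sprintf("%s electrode: r = %g mm, 2r = %g mm, disc %g mm, ring width %g mm (v0: %s)\n",
              x$kind, x$r, x$outer_radius, x$disc_radius, x$ring_width, x$v0_mode))
  invisible(x)
}

#' Average potential on a ring
#'
#' Trapezoidal (periodic, spectrally accurate) approximation of
#' `(1/2pi) integral v(radius, theta) dtheta` on the electrode plane.  A
#' positive `ring_width` averages over the annulus
#' `[radius - w/2, radius + w/2]` with area weighting (3-point
#' Gauss-Legendre radially).
#'
#' @param field A `potential_field` or `analytic_field`.
#' @param center Electrode-plane coordinates of the ring centre, mm.
#' @param radius Ring radius, mm (> 0).
#' @param n_samples Angular samples (>= 8).
#' @param ring_width Annulus width, mm (0 for a line ring).
#' @return The ring-averaged potential.
#' @export
ring_average <- function(field, center = c(0, 0), radius, n_samples = 360,
                         ring_width = 0) {
  if (radius <= 0) stop("ring radius must be positive")
  if (n_samples < 8) stop("n_samples must be at least 8")
  sf <- surface_fun(field)
  ang <- 2 * pi * (seq_len(n_samples) - 1) / n_samples
  one_ring <- function(rho) mean(sf(center[1] + rho * cos(ang),
                                    center[2] + rho * sin(ang)))
  if (ring_width <= 0) return(one_ring(radius))
  gl <- pracma::gaussLegendre(3, radius - ring_width / 2, radius + ring_width / 2)
  # area-weighted annulus average: (int rho v(rho) drho) / (int rho drho)
  num <- sum(gl$w * gl$x * vapply(gl$x, one_ring, numeric(1)))
  num / sum(gl$w * gl$x)
}

# Area average over a disc of radius a: (2/a^2) int_0^a rho ringavg(rho) drho
disc_average <- function(field, center, a, n_samples) {
  sf <- surface_fun(field)
  ang <- 2 * pi * (seq_len(n_samples) - 1) / n_samples
  gl <- pracma::gaussLegendre(8, 0, a)
  ring_vals <- vapply(gl$x, function(rho)
    mean(sf(center[1] + rho * cos(ang), center[2] + rho * sin(ang))),
    numeric(1))
  2 / a^2 * sum(gl$w * gl$x * ring_vals)
}

v0_value <- function(field, spec, center) {
  if (spec$v0_mode == "point") {
    sf <- surface_fun(field)
    sf(center[1], center[2])
  } else {
    disc_average(field, center, spec$disc_radius, spec$n_samples)
  }
}

#' Monopolar disc reading
#'
#' Area-averaged surface potential over the disc of radius `2r`.
#'
#' @param field A `potential_field` or `analytic_field`.
#' @param spec An [electrode_spec()] with `kind = "monopolar"`.
#' @param center Electrode-plane coordinates of the electrode centre, mm.
#' @return The disc-averaged potential.
#' @export
read_monopolar <- function(field, spec, center = c(0, 0)) {
  stopifnot(inherits(spec, "electrode_spec"), spec$kind == "monopolar")
  disc_average(field, center, spec$outer_radius, spec$n_samples)
}

#' Bipolar concentric-ring Laplacian estimate
#'
#' `(4 / r^2) * (ring(r) - v0)` with `v0` the central-disc potential.
#'
#' @inheritParams read_monopolar
#' @export
laplacian_bipolar <- function(field, spec, center = c(0, 0)) {
  stopifnot(inherits(spec, "electrode_spec"), spec$kind == "bipolar")
  vr <- ring_average(field, center, spec$r, spec$n_samples, spec$ring_width)
  v0 <- v0_value(field, spec, center)
  4 / spec$r^2 * (vr - v0)
}

#' Quasi-bipolar concentric-ring reading
#'
#' `(v_or + v0) / 2 - v_mr` with the disc shorted to the outer ring.  The
#' reading is an unnormalized potential difference (no `4 / r^2` scaling);
#' attenuation ratios are unaffected by any fixed scaling.
#'
#' @inheritParams read_monopolar
#' @export
laplacian_quasi_bipolar <- function(field, spec, center = c(0, 0)) {
  stopifnot(inherits(spec, "electrode_spec"), spec$kind == "quasi_bipolar")
  vmr <- ring_average(field, center, spec$r, spec$n_samples, spec$ring_width)
  vor <- ring_average(field, center, spec$outer_radius, spec$n_samples, spec$ring_width)
  v0 <- v0_value(field, spec, center)
  (vor + v0) / 2 - vmr
}

#' Tri-polar concentric-ring Laplacian estimate
#'
#' `(1 / 3r^2) * (16 (ring(r) - v0) - (ring(2r) - v0))`; the 16:-1
#' weighting cancels the fourth-order truncation term, making the estimate
#' exact through degree-5 polynomial surface potentials.
#'
#' @inheritParams read_monopolar
#' @export
laplacian_tripolar <- function(field, spec, center = c(0, 0)) {
  stopifnot(inherits(spec, "electrode_spec"), spec$kind == "tripolar")
  vmr <- ring_average(field, center, spec$r, spec$n_samples, spec$ring_width)
  vor <- ring_average(field, center, spec$outer_radius, spec$n_samples, spec$ring_width)
  v0 <- v0_value(field, spec, center)
  (16 * (vmr - v0) - (vor - v0)) / (3 * spec$r^2)
}

#' Five-point finite-difference Laplacian (stencil oracle)
#'
#' `(4 / r^2) * (mean(v1..v4) - v0)` with the four compass points at
#' spacing `r`; the point-stencil counterpart of the bipolar ring
#' estimator.
#'
#' @param field A `potential_field` or `analytic_field`.
#' @param center Electrode-plane coordinates of the stencil centre, mm.
#' @param r Stencil spacing, mm.
#' @export
laplacian_five_point <- function(field, center = c(0, 0), r) {
  sf <- surface_fun(field)
  v0 <- sf(center[1], center[2])
  vs <- sf(center[1] + c(r, -r, 0, 0), center[2] + c(0, 0, r, -r))
  4 / r^2 * (mean(vs) - v0)
}

#' Nine-point finite-difference Laplacian (stencil oracle)
#'
#' `(1 / 12 r^2) * (16 sum(v1..v4) - 60 v0 - sum(v5..v8))` with compass
#' points at spacings `r` and `2r`; the point-stencil counterpart of the
#' tri-polar ring estimator.
#'
#' @inheritParams laplacian_five_point
#' @export
laplacian_nine_point <- function(field, center = c(0, 0), r) {
  sf <- surface_fun(field)
  v0 <- sf(center[1], center[2])
  v14 <- sf(center[1] + c(r, -r, 0, 0), center[2] + c(0, 0, r, -r))
  v58 <- sf(center[1] + c(2 * r, -2 * r, 0, 0), center[2] + c(0, 0, 2 * r, -2 * r))
  (16 * sum(v14) - 60 * v0 - sum(v58)) / (12 * r^2)
}

#' Read an electrode of any kind
#'
#' Dispatches to the kind-appropriate reading: [read_monopolar()],
#' [laplacian_bipolar()], [laplacian_quasi_bipolar()] or
#' [laplacian_tripolar()].
#'
#' @inheritParams read_monopolar
#' @param spec An [electrode_spec()].
#' @return The scalar electrode reading.
#' @export
read_electrode <- function(field, spec, center = c(0, 0)) {
  stopifnot(inherits(spec, "electrode_spec"))
  switch(spec$kind,
         monopolar = read_monopolar(field, spec, center),
         bipolar = laplacian_bipolar(field, spec, center),
         quasi_bipolar = laplacian_quasi_bipolar(field, spec, center),
         tripolar = laplacian_tripolar(field, spec, center),
         stop("unknown electrode kind: ", spec$kind))
}
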