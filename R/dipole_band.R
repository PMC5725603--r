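#' Parameters of the moving dipole-band source model
#'
#' The uterine depolarization front is idealized as an annular band of
#' electric dipoles travelling along the wall of a conical uterus.  The band
#' starts at the fundus, travels to the cervix end and returns, at constant
#' speed along the longitudinal (z) axis.
#'
#' @param c Band propagation speed along the z axis, mm/s.
#' @param Ros Initial axial position of the band, mm.  The band's round trip
#'   covers the axial range `[-Ros, Ros]`.
#' @param theta Cone half-angle of the uterus wall, degrees (0 < theta < 90).
#' @param delta Width of the dipole band measured along the wall, mm.
#' @param p0 Total dipole moment of the band, C·mm.
#' @param eps0 Medium constant appearing in the source-potential denominator
#'   (dimensionless model units).
#'
#' @return An object of class `dipole_band_params`.
#' @examples
#' p <- dipole_band_params()
#' band_displacement(p, 1)   # 30 mm after one second
#' @export
dipole_band_params <- function(c = 30, Ros = 400, theta = 10, delta = 6,
                               p0 = 2.2e-13, eps0 = 0.36) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c))
  if (c <= 0) stop("band speed `c` must be positive")
  if (Ros <= 0) stop("initial position `Ros` must be positive")
  if (theta <= 0 || theta >= 90) stop("`theta` must lie strictly between 0 and 90 degrees")
  if (delta <= 0) stop("band width `delta` must be positive")
  if (p0 <= 0) stop("band moment `p0` must be positive")
  if (eps0 <= 0) stop("`eps0` must be positive")
  structure(list(c = c, Ros = Ros, theta = theta, delta = delta,
                 p0 = p0, eps0 = eps0),
            class = "dipole_band_params")
}

#' @export
print.dipole_band_params <- function(x, ...) {
  cat("Dipole band parameters\n")
  cat(sprintf("  speed c        : %g mm/s\n", x$c))
  cat(sprintf("  start Ros      : %g mm\n", x$Ros))
  cat(sprintf("  cone angle     : %g deg\n", x$theta))
  cat(sprintf("  band width     : %g mm\n", x$delta))
  cat(sprintf("  band moment p0 : %g C.mm\n", x$p0))
  cat(sprintf("  eps0           : %g\n", x$eps0))
  invisible(x)
}

theta_rad <- function(params) params$theta * pi / 180

#' Axial displacement of the dipole band
#'
#' Distance travelled along the band's path after time `t`, i.e. `c * t`.
#'
#' @param params A [dipole_band_params()] object.
#' @param t Time(s) since the start of the traversal, s (non-negative).
#' @return Displacement in mm, vectorized over `t`.
#' @export
band_displacement <- function(params, t) {
  stopifnot(inherits(params, "dipole_band_params"))
  if (any(t < 0)) stop("time `t` must be non-negative")
  params$c * t
}

#' Time for the band to traverse its full axial range one way
#'
#' The outbound leg covers the axial interval `[-Ros, Ros]`, i.e. a path of
#' length `2 * Ros` at speed `c`.
#'
#' @inheritParams band_displacement
#' @return One-way traversal time in seconds.
#' @export
band_traversal_time <- function(params) {
  stopifnot(inherits(params, "dipole_band_params"))
  2 * params$Ros / params$c
}

# Signed axial source coordinate u(t) = Ros - c*t, reflected at the far end
# so that a round trip (period 4*Ros/c) retraces itself.  The band's display
# coordinate along the traversal axis is band_z = -u.
band_axial_u <- function(params, t) {
  if (any(t < 0)) stop("time `t` must be non-negative")
  Tout <- band_traversal_time(params)
  tt <- t %% (2 * Tout)
  ifelse(tt <= Tout, params$Ros - params$c * tt, params$c * tt - 3 * params$Ros)
}

#' Band position along the traversal axis
#'
#' Position of the band on the z axis during the fundus-to-cervix-and-back
#' round trip: `-Ros` at `t = 0`, `+Ros` at the turnaround instant
#' `2 * Ros / c`, and back.
#'
#' @inheritParams band_displacement
#' @return Axial position in mm, vectorized over `t`.
#' @export
band_z_position <- function(params, t) {
  stopifnot(inherits(params, "dipole_band_params"))
  -band_axial_u(params, t)
}

#' Radial position of the band on the cone wall
#'
#' Slant (wall) coordinate of the band, `(Ros - c*t) / cos(theta)`.  After
#' the band passes the cone apex the coordinate continues with its sign,
#' describing the band re-expanding on the opposite traversal leg; the
#' reflection at the far end (`t > 2 * Ros / c`) retraces the trip.
#'
#' @inheritParams band_displacement
#' @return Radial (slant) position in mm, vectorized over `t`.
#' @export
band_radius <- function(params, t) {
  stopifnot(inherits(params, "dipole_band_params"))
  if (params$theta >= 90) stop("cos(theta) vanishes: theta = 90 degrees is degenerate")
  band_axial_u(params, t) / cos(theta_rad(params))
}

#' Dipole surface density of the band
#'
#' The band of total moment `p0` is spread over the annular strip of the cone
#' wall between slant radii `R` and `R + delta`, of area
#' `pi * sin(theta) * ((R + delta)^2 - R^2)`.
#'
#' @inheritParams band_displacement
#' @param R Radial (slant) position of the band's inner edge, mm (>= 0).
#' @return Dipole density in C·mm per mm^2, strictly decreasing in `R`.
#' @export
band_density <- function(params, R) {
  stopifnot(inherits(params, "dipole_band_params"))
  if (any(R < 0)) stop("radial position `R` must be non-negative")
  th <- theta_rad(params)
  if (sin(th) == 0) stop("sin(theta) vanishes: theta = 0 is a degenerate cylinder")
  params$p0 / (pi * sin(th) * ((R + params$delta)^2 - R^2))
}

# Generalized (signed) band area: pi*sin(theta)*(a2|a2| - a1|a1|) with
# a1 = R, a2 = R + delta.  Equals the printed annulus area for R >= 0 and
# remains positive when the band straddles the cone apex (a1 < 0 < a2).
band_area_signed <- function(params, a1) {
  th <- theta_rad(params)
  a2 <- a1 + params$delta
  pi * sin(th) * (a2 * abs(a2) - a1 * abs(a1))
}

#' Axial source potential of the dipole band
#'
#' Potential generated on the cone (z) axis by the dipole band at time `t`,
#' evaluated at the axial coordinate `zeta`.  The expression is the
#' difference of the two edge-ring terms
#' `(zeta - a cos(theta)) / sqrt(zeta^2 - 2 a zeta cos(theta) + a^2)`
#' for `a = R + delta` and `a = R`, scaled by `-D / (2 eps0)` where `D` is
#' the band density.  Potentials are in uncalibrated model units; all
#' derived quantities (delays, attenuation ratios) are unit-invariant.
#'
#' @inheritParams band_displacement
#' @param zeta Axial observation coordinate(s), mm.
#' @param t A single time, s.
#' @return Potential (model units), vectorized over `zeta`.
#' @export
source_potential <- function(params, zeta, t) {
  stopifnot(inherits(params, "dipole_band_params"), length(t) == 1L)
  th <- theta_rad(params)
  a1 <- band_radius(params, t)
  a2 <- a1 + params$delta
  S <- band_area_signed(params, a1)
  D <- params$p0 / S
  term <- function(a, label) {
    den2 <- zeta^2 - 2 * a * zeta * cos(th) + a^2
    if (any(den2 <= .Machine$double.eps * pmax(zeta^2, a^2, 1))) {
      stop(sprintf(
        "singular configuration: observation point lies on the band edge circle (%s term)",
        label))
    }
    (zeta - a * cos(th)) / sqrt(den2)
  }
  -D / (2 * params$eps0) * (term(a2, "outer-edge") - term(a1, "inner-edge"))
}

#' Simulate source waveforms over a full band round trip
#'
#' Moves the band from `-Ros` to `+Ros` and back (axial coordinate of
#' [band_z_position()]) and evaluates the axial source potential at each
#' observation coordinate for every time step.
#'
#' @inheritParams band_displacement
#' @param zetas Observation coordinates on the z axis, mm (non-empty).
#' @param dt Time step, s (> 0).  The default 0.1 s resolves sub-second
#'   peak timing.
#' @param t_end End of the simulated interval, s; defaults to the full
#'   round trip `4 Ros / c`.  Use [band_traversal_time()] to stop at the
#'   turnaround.
#' @return A list of `source_waveform` objects, one per element of `zetas`.
#'   Each holds `times`, `band_z`, `values` and `zeta`.
#' @export
simulate_round_trip <- function(params, zetas, dt = 0.1, t_end = NULL) {
  stopifnot(inherits(params, "dipole_band_params"))
  if (dt <= 0) stop("`dt` must be positive")
  if (length(zetas) == 0) stop("`zetas` must be non-empty")
  if (is.null(t_end)) t_end <- 2 * band_traversal_time(params)
  times <- seq(0, t_end, by = dt)
  bz <- band_z_position(params, times)
  vals <- vapply(times, function(t) source_potential(params, zetas, t),
                 numeric(length(zetas)))
  vals <- matrix(vals, nrow = length(zetas))
  lapply(seq_along(zetas), function(i) {
    structure(list(times = times, band_z = bz, values = vals[i, ],
                   zeta = zetas[i]),
              class = "source_waveform")
  })
}

#' @export
print.source_waveform <- function(x, ...) {
  cat(sprintf("Source waveform at zeta = %g mm: %d samples over [%g, %g] s, peak |v| = %.3g\n",
              x$zeta, length(x$times), min(x$times), max(x$times),
              max(abs(x$values))))
  invisible(x)
}

#' @export
as.data.frame.source_waveform <- function(x, ...) {
  data.frame(time_s = x$times, band_z_mm = x$band_z,
             zeta_mm = x$zeta, potential = x$values)
}
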