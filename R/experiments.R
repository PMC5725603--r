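#' Local-sensitivity probe source
#'
#' The spatial-sensitivity experiments displace a compact dipole source
#' representing the depolarized band segment nearest the recording site.
#' The probe is a point dipole of magnitude `p0` placed on the +y axis just
#' outside the grounded myometrium surface (close to the myometrium, on the
#' abdominal-wall side), oriented towards the electrode (+y): the standard
#' local-sensitivity probe for surface-electrode resolution studies, and
#' the orientation for which the displaced-source response is symmetric in
#' +/- z.
#'
#' @param model An [abdomen_model()].
#' @param band_params A [dipole_band_params()] (supplies the moment `p0`).
#' @param depth_offset Distance of the probe above the innermost tissue
#'   boundary (the myometrium surface), mm.
#' @param position Optional explicit probe position overriding the default
#'   placement, mm.
#' @param orientation Unit moment direction (default +y, towards the
#'   electrode).
#' @return A [point_dipole()].
#' @export
sensitivity_probe <- function(model, band_params, depth_offset = 5,
                              position = NULL, orientation = c(0, 1, 0)) {
  stopifnot(inherits(model, "abdomen_model"), inherits(band_params, "dipole_band_params"))
  if (is.null(position)) {
    thick <- sum(vapply(model$layers, `[[`, numeric(1), "thickness"))
    position <- c(0, model$hemisphere_radius - thick + depth_offset, 0)
  }
  orientation <- orientation / sqrt(sum(orientation^2))
  point_dipole(position, band_params$p0 * orientation)
}

displaced_sources <- function(probe, displacements, axis = c("z", "y"), noise = list()) {
  axis <- match.arg(axis)
  k <- if (axis == "z") 3L else 2L
  lapply(displacements, function(d) {
    p <- probe$position
    p[k] <- p[k] + d
    c(list(point_dipole(p, probe$moment)), noise)
  })
}

electrode_label <- function(spec) sprintf("%s_2r%g", spec$kind, spec$outer_radius)

#' Attenuation of the electrode reading versus source displacement
#'
#' Displaces the probe source along the chosen axis, solves the forward
#' problem at every displacement (sharing the operator across solves), and
#' reads each electrode.  Attenuation is
#' `20 log10(|reading at 0| / |reading at d|)` relative to the undisplaced
#' source, in dB.
#'
#' @param model An [abdomen_model()].
#' @param band_params A [dipole_band_params()].
#' @param specs An [electrode_spec()] or a list of them.
#' @param displacements Displacements along the sweep axis, mm; must
#'   include 0 (the reference).
#' @param axis `"z"` (default, the longitudinal sweep) or `"y"`.
#' @param noise Optional [noise_config()]; its dipoles are added to every
#'   solve.
#' @param probe Optional probe override; default [sensitivity_probe()].
#' @return An `attenuation_curve` (or a list of them, one per spec):
#'   displacements, attenuation_db, readings, electrode label, noise flag.
#' @export
attenuation_sweep <- function(model, band_params, specs,
                              displacements = seq(-30, 30, by = 5),
                              axis = "z", noise = NULL, probe = NULL) {
  single <- inherits(specs, "electrode_spec")
  if (single) specs <- list(specs)
  if (!any(displacements == 0))
    stop("the displacement grid must include 0 (the attenuation reference)")
  displacements <- sort(displacements)
  if (is.null(probe)) probe <- sensitivity_probe(model, band_params)
  noise_dipoles <- if (is.null(noise)) list()
                   else place_noise_dipoles(noise, model, band_params$p0)
  sets <- displaced_sources(probe, displacements, axis, noise_dipoles)
  fields <- solve_forward_many(model, sets)
  curves <- lapply(specs, function(spec) {
    readings <- vapply(fields, read_electrode, numeric(1), spec = spec)
    ref <- readings[displacements == 0]
    if (ref == 0) stop("reference error: zero reading at displacement 0")
    structure(list(displacements = displacements,
                   attenuation_db = 20 * log10(abs(ref) / abs(readings)),
                   readings = readings,
                   electrode = electrode_label(spec), spec = spec,
                   noise = !is.null(noise), axis = axis),
              class = "attenuation_curve")
  })
  if (single) curves[[1]] else curves
}

#' @export
print.attenuation_curve <- function(x, ...) {
  cat(sprintf("Attenuation curve (%s, axis %s, noise: %s)\n",
              x$electrode, x$axis, x$noise))
  print(data.frame(displacement_mm = x$displacements,
                   attenuation_db = round(x$attenuation_db, 3)))
  invisible(x)
}

#' Source displacement at which a given attenuation is reached
#'
#' Walks the non-negative branch of the curve and linearly interpolates the
#' first crossing of `threshold_db`.  If the threshold is not reached
#' within the sweep range the range bound is returned with attribute
#' `censored = TRUE`; a crossing on a non-monotone curve carries attribute
#' `warning = TRUE`.
#'
#' @param curve An `attenuation_curve` from [attenuation_sweep()].
#' @param threshold_db Attenuation threshold, dB (default the 20 dB
#'   sensitivity distance).
#' @return Distance in mm with attributes `censored` and `warning`.
#' @export
distance_at_attenuation <- function(curve, threshold_db = 20) {
  stopifnot(inherits(curve, "attenuation_curve"))
  pos <- curve$displacements >= 0
  d <- curve$displacements[pos]
  a <- curve$attenuation_db[pos]
  o <- order(d); d <- d[o]; a <- a[o]
  if (threshold_db <= 0)
    return(structure(0, censored = FALSE, warning = FALSE))
  cross <- which(a >= threshold_db)
  if (length(cross) == 0)
    return(structure(max(d), censored = TRUE, warning = FALSE))
  i <- cross[1]
  non_monotone <- any(diff(a) < 0)
  if (i == 1)
    return(structure(d[1], censored = FALSE, warning = non_monotone))
  x <- d[i - 1] + (threshold_db - a[i - 1]) / (a[i] - a[i - 1]) * (d[i] - d[i - 1])
  structure(x, censored = FALSE, warning = non_monotone)
}

#' Attenuation versus added tissue thickness
#'
#' Varies the thickness of one tissue layer while holding the others fixed,
#' re-solving the forward problem for each geometry with the probe source
#' held at a fixed position, and reports the attenuation of each
#' electrode's reading relative to the zero-thickness baseline.
#'
#' @param model Template [abdomen_model()]; its other layers and grid
#'   settings are reused.
#' @param band_params A [dipole_band_params()].
#' @param specs An [electrode_spec()] or list of them (the paper's
#'   thickness study uses the bipolar and tri-polar designs).
#' @param which `"fat"` (range 0-30 mm) or `"muscle"` (range 0-16 mm).
#' @param thicknesses Thickness grid, mm; must include 0 (the baseline)
#'   and stay within the stated range.
#' @param noise Optional [noise_config()] added to every solve.
#' @param depth_offset Probe height above the myometrium surface, mm.  The
#'   probe follows the myometrium as the layers thicken (the band rides on
#'   the uterus wall), so added thickness increases the source-electrode
#'   distance.
#' @return A `tissue_sweep_result`: thickness grid, per-electrode
#'   attenuation table (dB, relative to thickness 0), labels, noise flag.
#' @export
tissue_sweep <- function(model, band_params, specs,
                         which = c("fat", "muscle"),
                         thicknesses = NULL, noise = NULL,
                         depth_offset = 5) {
  which <- match.arg(which)
  rng <- if (which == "fat") c(0, 30) else c(0, 16)
  if (is.null(thicknesses))
    thicknesses <- seq(rng[1], rng[2], length.out = 5)
  if (any(thicknesses < rng[1] - 1e-9 | thicknesses > rng[2] + 1e-9))
    stop(sprintf("%s thickness must lie within [%g, %g] mm", which, rng[1], rng[2]))
  if (!any(thicknesses == 0)) stop("the thickness grid must include the 0 baseline")
  if (inherits(specs, "electrode_spec")) specs <- list(specs)
  thicknesses <- sort(thicknesses)
  readings <- matrix(NA_real_, length(thicknesses), length(specs))
  for (i in seq_along(thicknesses)) {
    layers <- lapply(model$layers, function(L) {
      if (L$name == which) L$thickness <- thicknesses[i]
      L
    })
    m_i <- abdomen_model(hemisphere_radius = model$hemisphere_radius,
                         layers = layers,
                         interior_conductivity = model$interior_conductivity,
                         myometrium_grounded = model$myometrium_grounded,
                         air_conductivity = model$air_conductivity,
                         grid_spacing = model$grid_spacing,
                         box_half_width = model$box_half_width,
                         solver_tol = model$solver_tol,
                         solver_maxit = model$solver_maxit)
    probe <- sensitivity_probe(m_i, band_params, depth_offset = depth_offset)
    noise_dipoles <- if (is.null(noise)) list()
                     else place_noise_dipoles(noise, m_i, band_params$p0)
    field <- solve_forward(m_i, c(list(probe), noise_dipoles))
    readings[i, ] <- vapply(specs, function(s) read_electrode(field, s), numeric(1))
  }
  ref <- as.numeric(readings[thicknesses == 0, ])
  if (any(ref == 0)) stop("reference error: zero reading at the thickness-0 baseline")
  att <- sweep(-20 * log10(abs(readings)), 2, -20 * log10(abs(ref)), `-`)
  colnames(att) <- vapply(specs, electrode_label, character(1))
  structure(list(which = which, thicknesses = thicknesses,
                 attenuation_db = att, readings = readings,
                 electrodes = colnames(att), noise = !is.null(noise)),
            class = "tissue_sweep_result")
}

#' @export
print.tissue_sweep_result <- function(x, ...) {
  cat(sprintf("Tissue sweep (%s thickness, noise: %s)\n", x$which, x$noise))
  print(cbind(thickness_mm = x$thicknesses, round(x$attenuation_db, 3)))
  invisible(x)
}

#' Record electrode waveforms while the band crosses the model
#'
#' Moves the band source along the z axis through its in-model span (the
#' 40 mm traversal window centred on the electrode), solves the forward
#' problem at every time step, and reads each electrode.  The band is
#' represented by the near-wall probe of [sensitivity_probe()], riding
#' just outside the grounded myometrium surface.
#'
#' @param model An [abdomen_model()].
#' @param band_params A [dipole_band_params()].
#' @param specs An [electrode_spec()] or list of them.
#' @param dt Time step, s.
#' @param z_range The band is recorded while its axial position lies within
#'   `[-z_range, z_range]` mm (the 40 mm in-model span by default).
#' @param probe Optional source override; default [sensitivity_probe()].
#' @return A `recorded_signals` object: `times`, `band_z`, and a
#'   `readings` matrix (time x electrode).
#' @export
record_waveforms <- function(model, band_params, specs, dt = 0.1,
                             z_range = 20, probe = NULL) {
  if (inherits(specs, "electrode_spec")) specs <- list(specs)
  c0 <- band_params$c; Ros <- band_params$Ros
  if (z_range >= model$box_half_width)
    stop("z_range must keep the band inside the solved domain")
  if (is.null(probe)) probe <- sensitivity_probe(model, band_params)
  # sample symmetrically about the instant the band crosses the electrode
  # plane (band_z = 0), so mirrored band positions are sampled exactly
  t_mid <- Ros / c0
  n_half <- floor(z_range / (c0 * dt))
  times <- t_mid + seq(-n_half, n_half) * dt
  sets <- displaced_sources(probe, band_z_position(band_params, times), "z")
  fields <- solve_forward_many(model, sets)
  readings <- vapply(fields, function(f)
    vapply(specs, function(s) read_electrode(f, s), numeric(1)),
    numeric(length(specs)))
  readings <- matrix(readings, nrow = length(times), byrow = TRUE)
  colnames(readings) <- vapply(specs, electrode_label, character(1))
  structure(list(times = times, band_z = band_z_position(band_params, times),
                 readings = readings, electrodes = colnames(readings)),
            class = "recorded_signals")
}

#' @export
print.recorded_signals <- function(x, ...) {
  cat(sprintf("Recorded signals: %d time steps, electrodes: %s\n",
              length(x$times), paste(x$electrodes, collapse = ", ")))
  invisible(x)
}

peak_time_quadratic <- function(times, values) {
  i <- which.max(values)
  if (values[i] == min(values)) stop("estimation error: flat signal, no peak")
  if (i == 1 || i == length(values)) return(times[i])
  dt <- times[i + 1] - times[i]
  y0 <- values[i - 1]; y1 <- values[i]; y2 <- values[i + 1]
  den <- y0 - 2 * y1 + y2
  if (den == 0) return(times[i])
  times[i] + dt * 0.5 * (y0 - y2) / den
}

onset_time_half_max <- function(times, values) {
  i <- which.max(values)
  if (values[i] == min(values)) stop("estimation error: flat signal, no peak")
  hv <- values[i] / 2
  j <- which(values[seq_len(i)] >= hv)[1]
  if (j == 1) return(times[1])
  stats::approx(values[(j - 1):j], times[(j - 1):j], xout = hv)$y
}

xcorr_delay <- function(t1, v1, t2, v2) {
  dt <- t1[2] - t1[1]
  nl <- min(length(v1), length(v2)) - 2L
  lags <- (-nl):nl
  cc <- vapply(lags, function(L) {
    if (L >= 0) sum(v1[(1 + L):length(v1)] * v2[seq_len(length(v1) - L)])
    else sum(v1[seq_len(length(v1) + L)] * v2[(1 - L):length(v2)])
  }, numeric(1))
  i <- which.max(cc)
  lag <- lags[i] * dt
  if (i > 1 && i < length(cc)) {
    y0 <- cc[i - 1]; y1 <- cc[i]; y2 <- cc[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den != 0) lag <- lag + dt * 0.5 * (y0 - y2) / den
  }
  lag
}

signal_parts <- function(w, outbound_only) {
  if (inherits(w, "source_waveform")) {
    t <- w$times; v <- w$values
  } else {
    t <- w$times; v <- if (!is.null(w$values)) w$values else w$readings[, 1]
  }
  if (outbound_only) {
    keep <- t <= (min(t) + max(t)) / 2
    t <- t[keep]; v <- v[keep]
  }
  list(times = t, values = v)
}

#' Estimate the band propagation speed from two recordings
#'
#' Computes the conduction delay between signals observed at two sites a
#' known distance apart and the implied propagation speed.  Delay
#' estimators:
#' \describe{
#'   \item{peak}{difference of quadratically-interpolated peak times
#'     (default);}
#'   \item{onset}{difference of half-maximum onset latencies (the rising
#'     edge crossing of 50% of the peak, linearly interpolated) — a
#'     standard conduction-velocity estimator for propagating surface
#'     signals;}
#'   \item{xcorr}{lag maximizing the cross-correlation, with quadratic
#'     refinement.}
#' }
#'
#' @param w1,w2 Two signals: `source_waveform` objects or lists with
#'   `times` and `values`, sampled on the same time grid.
#' @param spacing Distance between the two observation sites, mm.
#' @param method Delay estimator, see Details.
#' @param outbound_only Restrict to the first (outbound) half of a
#'   round-trip recording before locating features.
#' @return A list with `delay_s` (positive) and `speed_mm_s`
#'   (`spacing / delay_s`).
#' @export
estimate_propagation_speed <- function(w1, w2, spacing,
                                       method = c("peak", "onset", "xcorr"),
                                       outbound_only = TRUE) {
  method <- match.arg(method)
  s1 <- signal_parts(w1, outbound_only)
  s2 <- signal_parts(w2, outbound_only)
  delay <- switch(method,
    peak = peak_time_quadratic(s1$times, s1$values) -
           peak_time_quadratic(s2$times, s2$values),
    onset = onset_time_half_max(s1$times, s1$values) -
            onset_time_half_max(s2$times, s2$values),
    xcorr = xcorr_delay(s1$times, s1$values, s2$times, s2$values))
  delay <- abs(delay)
  if (delay == 0) stop("estimation error: zero delay between the two signals")
  list(delay_s = delay, speed_mm_s = spacing / delay, method = method)
}
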