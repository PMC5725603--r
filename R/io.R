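#' Default run configuration
#'
#' All model parameters with their standard values: band kinematics
#' (c = 30 mm/s, Ros = 400 mm, theta = 10 deg, delta = 6 mm,
#' p0 = 2.2e-13 C·mm, eps0 = 0.36), the three-layer abdomen (skin 2 mm,
#' fat 15 mm, muscle 8 mm on a 100 mm hemisphere), the four electrode
#' designs, six noise dipoles, and the experiment grids.
#'
#' @return A nested list of class `ehg_config`.
#' @export
default_config <- function() {
  structure(list(
    band = list(c = 30, Ros = 400, theta = 10, delta = 6,
                p0 = 2.2e-13, eps0 = 0.36),
    abdomen = list(
      hemisphere_radius = 100,
      skin = list(thickness = 2, conductivity = 2e-4, relative_permittivity = 40.01),
      fat = list(thickness = 15, conductivity = 0.04, relative_permittivity = 12.79),
      muscle = list(thickness = 8, conductivity = 0.35, relative_permittivity = 66.21),
      interior_conductivity = 1.6,
      myometrium_grounded = TRUE,
      air_conductivity = 1e-8),
    solver = list(grid_spacing = 5, box_half_width = 120,
                  tol = 1e-10, maxit = 20000),
    electrodes = list(
      list(kind = "monopolar", r = 5),
      list(kind = "bipolar", r = 5),
      list(kind = "quasi_bipolar", r = 5),
      list(kind = "tripolar", r = 5)),
    electrode_defaults = list(disc_radius = 2.5, ring_width = 1,
                              n_samples = 360, v0_mode = "disc"),
    noise = list(enabled = FALSE, n_dipoles = 6, moment_scale = 0.1,
                 max_angle_deg = 60),
    experiments = list(
      waveforms = list(dt = 0.1, z_range = 20),
      attenuation = list(from = -30, to = 30, by = 5, axis = "z",
                         depth_offset = 5),
      tissue = list(which = "fat", thicknesses = NULL),
      speed = list(zetas = c(0, 50), dt = 0.1, method = "onset")),
    seed = 1L,
    outdir = "ehgsim-output"
  ), class = "ehg_config")
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section `", path, "` must be a mapping")
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[k] <- list(merge_config(defaults[[k]], user[[k]],
                                       paste0(path, ".", k)))
    } else {
      defaults[k] <- list(user[[k]])   # [k]<- keeps explicit NULLs
    }
  }
  defaults
}

validate_config <- function(cfg) {
  b <- cfg$band
  dipole_band_params(b$c, b$Ros, b$theta, b$delta, b$p0, b$eps0)
  a <- cfg$abdomen
  if (a$fat$thickness < 0 || a$fat$thickness > 30)
    stop("config key abdomen.fat.thickness: must lie within the 0-30 mm range")
  if (a$muscle$thickness < 0 || a$muscle$thickness > 16)
    stop("config key abdomen.muscle.thickness: must lie within the 0-16 mm range")
  config_model(cfg)      # geometry/grid validation
  lapply(cfg$electrodes, function(e) do.call(electrode_spec,
    utils::modifyList(cfg$electrode_defaults, e)))
  invisible(cfg)
}

#' Load (and validate) a run configuration
#'
#' Reads a YAML configuration, fills every omitted key from
#' [default_config()], rejects unknown keys, and validates ranges and
#' geometry.  An empty file yields the all-defaults configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `ehg_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  class(cfg) <- "ehg_config"
  validate_config(cfg)
  cfg
}

#' Save a run configuration to YAML
#'
#' @param cfg An `ehg_config`.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname load_config
#' @param cfg An `ehg_config`.
#' @export
config_band <- function(cfg) {
  b <- cfg$band
  dipole_band_params(b$c, b$Ros, b$theta, b$delta, b$p0, b$eps0)
}

#' @rdname load_config
#' @export
config_model <- function(cfg) {
  a <- cfg$abdomen
  s <- cfg$solver
  abdomen_model(
    hemisphere_radius = a$hemisphere_radius,
    layers = list(
      tissue_layer("skin", a$skin$thickness, a$skin$conductivity,
                   a$skin$relative_permittivity),
      tissue_layer("fat", a$fat$thickness, a$fat$conductivity,
                   a$fat$relative_permittivity),
      tissue_layer("muscle", a$muscle$thickness, a$muscle$conductivity,
                   a$muscle$relative_permittivity)),
    interior_conductivity = a$interior_conductivity,
    myometrium_grounded = a$myometrium_grounded,
    air_conductivity = a$air_conductivity,
    grid_spacing = s$grid_spacing, box_half_width = s$box_half_width,
    solver_tol = s$tol, solver_maxit = s$maxit)
}

#' @rdname load_config
#' @export
config_electrodes <- function(cfg) {
  lapply(cfg$electrodes, function(e)
    do.call(electrode_spec, utils::modifyList(cfg$electrode_defaults, e)))
}

#' @rdname load_config
#' @export
config_noise <- function(cfg) {
  if (!isTRUE(cfg$noise$enabled)) return(NULL)
  noise_config(cfg$noise$n_dipoles, cfg$noise$moment_scale,
               seed = cfg$seed, max_angle_deg = cfg$noise$max_angle_deg)
}

#' Export source waveforms as CSV
#'
#' Columns: `time_s`, `band_z_mm`, `zeta_mm`, `potential`.
#'
#' @param waveforms A list of `source_waveform`s from
#'   [simulate_round_trip()].
#' @param path Output CSV path.
#' @export
write_source_waveforms <- function(waveforms, path) {
  df <- do.call(rbind, lapply(waveforms, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

log_stage <- function(quiet, stage, t0, ...) {
  if (quiet) return(invisible())
  message(sprintf("[ehgsim] %s (%.1f s) %s", stage,
                  proc.time()[3] - t0, paste0(..., collapse = " ")))
}

#' Run a configured experiment and write its artifacts
#'
#' Executes one of the three computational experiments and writes
#' deterministic CSV tables plus a JSON metadata file (the full effective
#' configuration and seed) to the output directory.
#'
#' @param cfg An `ehg_config` (see [default_config()], [load_config()]).
#' @param which `"waveforms"` (band crossing recorded by every electrode),
#'   `"attenuation"` (displacement sweep and 20 dB distances) or
#'   `"tissue"` (thickness sweep).
#' @param outdir Output directory; created if absent.  Defaults to
#'   `cfg$outdir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the paths of the written artifacts.
#' @export
run_experiment <- function(cfg, which = c("waveforms", "attenuation", "tissue"),
                           outdir = cfg$outdir, quiet = FALSE) {
  stopifnot(inherits(cfg, "ehg_config"))
  which <- match.arg(which)
  validate_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]
  band <- config_band(cfg)
  model <- config_model(cfg)
  specs <- config_electrodes(cfg)
  noise <- config_noise(cfg)
  paths <- character(0)

  if (which == "waveforms") {
    w <- cfg$experiments$waveforms
    rec <- record_waveforms(model, band, specs, dt = w$dt, z_range = w$z_range)
    for (j in seq_along(specs)) {
      p <- file.path(outdir, paste0("waveform_", rec$electrodes[j], ".csv"))
      utils::write.csv(data.frame(time_s = rec$times, band_z_mm = rec$band_z,
                                  reading = rec$readings[, j]),
                       p, row.names = FALSE)
      paths <- c(paths, p)
    }
    log_stage(quiet, "waveforms", t0, sprintf("%d steps", length(rec$times)))
  } else if (which == "attenuation") {
    a <- cfg$experiments$attenuation
    disp <- seq(a$from, a$to, by = a$by)
    probe <- sensitivity_probe(model, band, depth_offset = a$depth_offset)
    curves <- attenuation_sweep(model, band, specs, displacements = disp,
                                axis = a$axis, noise = noise, probe = probe)
    tab <- data.frame(displacement_mm = curves[[1]]$displacements)
    for (cu in curves) tab[[cu$electrode]] <- cu$attenuation_db
    p <- file.path(outdir, "attenuation.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    d20 <- data.frame(
      electrode = vapply(curves, `[[`, character(1), "electrode"),
      distance_20db_mm = vapply(curves, function(cu)
        as.numeric(distance_at_attenuation(cu, 20)), numeric(1)),
      censored = vapply(curves, function(cu)
        attr(distance_at_attenuation(cu, 20), "censored"), logical(1)))
    p2 <- file.path(outdir, "distance_20db.csv")
    utils::write.csv(d20, p2, row.names = FALSE)
    paths <- c(paths, p, p2)
    log_stage(quiet, "attenuation", t0, sprintf("%d displacements", length(disp)))
  } else {
    tw <- cfg$experiments$tissue
    res <- tissue_sweep(model, band, specs, which = tw$which,
                        thicknesses = tw$thicknesses, noise = noise)
    p <- file.path(outdir, paste0("tissue_", res$which, ".csv"))
    utils::write.csv(cbind(data.frame(thickness_mm = res$thicknesses),
                           as.data.frame(res$attenuation_db)),
                     p, row.names = FALSE)
    paths <- c(paths, p)
    log_stage(quiet, "tissue", t0, sprintf("%d thicknesses", length(res$thicknesses)))
  }

  meta <- list(experiment = which, seed = cfg$seed, config = unclass(cfg),
               elapsed_s = round(proc.time()[3] - t0, 2),
               package_version = as.character(utils::packageVersion("ehgsim")))
  pm <- file.path(outdir, paste0(which, "_metadata.json"))
  jsonlite::write_json(meta, pm, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(c(paths, pm))
}
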