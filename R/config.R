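# Experiment descriptor files: a flat key-value YAML mapping with units in
# the key names, validated against a fixed schema.

.CONFIG_KEYS <- c(
  "segment_length_mm", "inner_diameter_mm", "wall_thickness_mm",
  "density_kg_m3", "viscosity_cp", "glycerin_volume_pct", "temperature_c",
  "time_on_s", "time_off_s", "pincher_length_mm", "pincher_offset_mm",
  "occlusion_fraction", "young_modulus_kpa")

#' Read an experiment descriptor file
#'
#' The descriptor is a flat YAML mapping whose keys carry their units
#' (e.g. `inner_diameter_mm: 5`). Unknown keys are rejected. The fluid may
#' be given either directly (`density_kg_m3` + `viscosity_cp`) or as a
#' glycerol-water mixture (`glycerin_volume_pct` + `temperature_c`), in
#' which case viscosity and density come from [glycerol_water_fluid()].
#'
#' @param path path to the YAML file.
#' @return a list with components `geometry` ([tube_geometry()]), `fluid`
#'   ([fluid_properties()]), `protocol` ([compression_protocol()]) and
#'   `young_modulus` (Pa, or `NULL`).
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  experiment_config(raw)
}

#' Build an experiment descriptor from a flat key-value list
#'
#' @param raw named list with the keys described in
#'   [read_experiment_config()].
#' @return same structure as [read_experiment_config()].
#' @export
experiment_config <- function(raw) {
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  need <- function(k) {
    if (is.null(raw[[k]])) stop("missing config key: ", k, call. = FALSE)
    as.numeric(raw[[k]])
  }
  geom <- tube_geometry(inner_diameter = need("inner_diameter_mm") * 1e-3,
                        wall_thickness = need("wall_thickness_mm") * 1e-3,
                        segment_length = need("segment_length_mm") * 1e-3)
  fluid <- if (!is.null(raw$glycerin_volume_pct)) {
    glycerol_water_fluid(as.numeric(raw$glycerin_volume_pct) / 100,
                         temperature = if (is.null(raw$temperature_c)) 22
                                       else as.numeric(raw$temperature_c))
  } else {
    fluid_properties(density = need("density_kg_m3"),
                     viscosity = viscosity_cp_to_pas(need("viscosity_cp")))
  }
  protocol <- compression_protocol(
    time_on = need("time_on_s"), time_off = need("time_off_s"),
    pincher_length = need("pincher_length_mm") * 1e-3,
    pincher_offset = if (is.null(raw$pincher_offset_mm)) 0
                     else as.numeric(raw$pincher_offset_mm) * 1e-3,
    occlusion_fraction = if (is.null(raw$occlusion_fraction)) 1
                         else as.numeric(raw$occlusion_fraction))
  list(geometry = geom, fluid = fluid, protocol = protocol,
       young_modulus = if (is.null(raw$young_modulus_kpa)) NULL
                       else as.numeric(raw$young_modulus_kpa) * 1e3)
}

#' Write an experiment descriptor file
#'
#' Inverse of [read_experiment_config()].
#'
#' @param config a list as returned by [experiment_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  g <- config$geometry; f <- config$fluid; p <- config$protocol
  raw <- list(
    segment_length_mm = g$segment_length * 1e3,
    inner_diameter_mm = g$inner_diameter * 1e3,
    wall_thickness_mm = g$wall_thickness * 1e3,
    time_on_s = p$time_on, time_off_s = p$time_off,
    pincher_length_mm = p$pincher_length * 1e3,
    pincher_offset_mm = p$pincher_offset * 1e3,
    occlusion_fraction = p$occlusion_fraction)
  if (!is.null(f$glycerin_fraction)) {
    raw$glycerin_volume_pct <- f$glycerin_fraction * 100
    raw$temperature_c <- if (is.null(f$temperature)) 22 else f$temperature
  } else {
    raw$density_kg_m3 <- f$density
    raw$viscosity_cp <- viscosity_pas_to_cp(f$viscosity)
  }
  if (!is.null(config$young_modulus)) {
    raw$young_modulus_kpa <- config$young_modulus / 1e3
  }
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' One-row summary of all calculators for a configuration
#'
#' Evaluates the Womersley regime, wave physics and peristaltic reference
#' for one geometry / fluid / protocol triple and returns them as a single
#' flat row, suitable for `write.csv`.
#'
#' @inheritParams womersley_number
#' @param young_modulus optional wall Young's modulus (Pa); enables the
#'   wave-speed and natural-frequency columns.
#' @return a one-row `data.frame`.
#' @export
experiment_summary <- function(geom, fluid, protocol, young_modulus = NULL) {
  regime <- womersley_regime(geom, fluid, protocol)
  c_ms <- if (is.null(young_modulus)) NA_real_ else
    moens_korteweg_speed(young_modulus, geom, fluid)
  data.frame(
    segment_length_mm = geom$segment_length * 1e3,
    inner_diameter_mm = geom$inner_diameter * 1e3,
    wall_thickness_mm = geom$wall_thickness * 1e3,
    density_kg_m3 = fluid$density,
    viscosity_cp = viscosity_pas_to_cp(fluid$viscosity),
    frequency_hz = protocol$frequency,
    womersley = regime$womersley,
    kw = regime$kw,
    wave_speed_ms = c_ms,
    natural_frequency_hz = if (is.na(c_ms)) NA_real_ else
      natural_frequency(c_ms, geom),
    peristaltic_ulps = flow_m3s_to_ulps(peristaltic_flowrate(protocol, geom)))
}
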