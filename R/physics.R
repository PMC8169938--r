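# Closed-form pump physics: the experiment descriptors and every calculator
# used to interpret a valveless-pump run. All internal units are SI;
# reporting helpers in utils.R convert to mm/s, ul/s, ml/min, cP, kPa.

#' Standard gravity used for tensile-test stress (m/s^2)
#' @export
STANDARD_GRAVITY <- 9.81

#' Tensile test descriptor
#'
#' A single-point tensile test on a rectangular elastomer strip: a weight of
#' mass `mass` hangs from a strip of rest length `strip_length` and
#' cross-section `cross_section`, stretching it by `elongation`. Young's
#' modulus follows from the secant of the linear part of the stress-stretch
#' curve, which for the soft silicones targeted here extends to 100% strain.
#'
#' @param mass attached mass (kg).
#' @param strip_length rest length of the strip (m).
#' @param cross_section cross-sectional area of the strip (m^2).
#' @param elongation measured elongation (m).
#' @return an object of class `tensile_test`.
#' @export
tensile_test <- function(mass, strip_length, cross_section, elongation) {
  .check_positive(mass, "mass")
  .check_positive(strip_length, "strip_length")
  .check_positive(cross_section, "cross_section")
  .check_positive(elongation, "elongation")
  strain <- elongation / strip_length
  structure(
    list(mass = mass, strip_length = strip_length,
         cross_section = cross_section, elongation = elongation,
         strain = strain, linear_regime = strain <= 1,
         g = STANDARD_GRAVITY),
    class = "tensile_test")
}

#' Young's modulus from a single-point tensile test
#'
#' E = stress / strain = g m L / (A dL).
#'
#' @param test a [tensile_test()] object.
#' @return Young's modulus (Pa).
#' @export
young_modulus <- function(test) {
  stopifnot(inherits(test, "tensile_test"))
  if (!test$linear_regime) {
    warning("elongation exceeds the strip length: outside the linear regime",
            call. = FALSE)
  }
  test$g * test$mass * test$strip_length /
    (test$cross_section * test$elongation)
}

#' Tube geometry descriptor
#'
#' @param inner_diameter lumen diameter (m).
#' @param wall_thickness wall thickness (m).
#' @param segment_length length of the segment (m).
#' @return an object of class `tube_geometry` with derived `radius` (m) and
#'   `lumen_area` (m^2).
#' @export
tube_geometry <- function(inner_diameter, wall_thickness, segment_length) {
  .check_positive(inner_diameter, "inner_diameter")
  .check_positive(wall_thickness, "wall_thickness")
  .check_positive(segment_length, "segment_length")
  r <- inner_diameter / 2
  structure(
    list(inner_diameter = inner_diameter, wall_thickness = wall_thickness,
         segment_length = segment_length, radius = r,
         lumen_area = pi * r^2),
    class = "tube_geometry")
}

#' Fluid properties descriptor
#'
#' @param density fluid density (kg/m^3).
#' @param viscosity dynamic viscosity (Pa s).
#' @param glycerin_fraction optional glycerol volume fraction in \[0, 1\].
#' @param temperature optional temperature (degrees C).
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(density, viscosity, glycerin_fraction = NULL,
                             temperature = NULL) {
  .check_positive(density, "density")
  .check_positive(viscosity, "viscosity")
  if (!is.null(glycerin_fraction)) {
    .check_fraction(glycerin_fraction, "glycerin_fraction")
  }
  structure(
    list(density = density, viscosity = viscosity,
         glycerin_fraction = glycerin_fraction, temperature = temperature),
    class = "fluid_properties")
}

#' Glycerol-water working fluid at a given volume fraction
#'
#' Convenience constructor that fills in viscosity from
#' [glycerin_water_viscosity()] and density from volume-weighted mixing
#' (glycerol 1260 kg/m^3, water 998 kg/m^3).
#'
#' @param glycerin_fraction glycerol volume fraction in \[0, 1\].
#' @param temperature temperature (degrees C), default 22.
#' @return a [fluid_properties()] object.
#' @export
glycerol_water_fluid <- function(glycerin_fraction, temperature = 22) {
  .check_fraction(glycerin_fraction, "glycerin_fraction")
  mu <- glycerin_water_viscosity(glycerin_fraction, temperature)
  rho <- glycerin_fraction * 1260 + (1 - glycerin_fraction) * 998
  fluid_properties(density = rho, viscosity = mu,
                   glycerin_fraction = glycerin_fraction,
                   temperature = temperature)
}

#' Compression protocol descriptor
#'
#' The pincher dwell times define the compression frequency
#' F = 1 / (time_on + time_off).
#'
#' @param time_on compression (lumen occluded) time (s).
#' @param time_off release time (s).
#' @param pincher_length axial width of the pincher (m).
#' @param pincher_offset distance of the pincher from the nearest junction
#'   between the compliant tube and the stiff connector (m).
#' @param occlusion_fraction fraction of the lumen occluded at full
#'   compression, in \[0, 1\] (1 = full occlusion).
#' @return an object of class `compression_protocol` with derived `frequency`
#'   (Hz).
#' @export
compression_protocol <- function(time_on, time_off, pincher_length = 3.5e-3,
                                 pincher_offset = 0, occlusion_fraction = 1) {
  .check_positive(time_on, "time_on")
  .check_positive(time_off, "time_off")
  .check_positive(pincher_length, "pincher_length")
  if (pincher_offset < 0) {
    stop("invalid input: `pincher_offset` must be non-negative", call. = FALSE)
  }
  .check_fraction(occlusion_fraction, "occlusion_fraction")
  structure(
    list(time_on = time_on, time_off = time_off,
         frequency = 1 / (time_on + time_off),
         pincher_length = pincher_length, pincher_offset = pincher_offset,
         occlusion_fraction = occlusion_fraction),
    class = "compression_protocol")
}

#' Compression frequency from pincher dwell times
#'
#' @param time_on compression time (s).
#' @param time_off release time (s).
#' @return frequency (Hz).
#' @export
compression_frequency <- function(time_on, time_off) {
  .check_positive(time_on, "time_on")
  .check_positive(time_off, "time_off")
  1 / (time_on + time_off)
}

#' Womersley number
#'
#' Wo = r sqrt(rho omega / mu) with omega = 2 pi F: the ratio of oscillatory
#' inertial to viscous forces. Wo below ~1 gives a parabolic oscillatory
#' profile, above ~10 a flat one.
#'
#' @param geom a [tube_geometry()].
#' @param fluid a [fluid_properties()].
#' @param protocol a [compression_protocol()] (its frequency is used).
#' @return dimensionless Womersley number.
#' @export
womersley_number <- function(geom, fluid, protocol) {
  stopifnot(inherits(geom, "tube_geometry"),
            inherits(fluid, "fluid_properties"),
            inherits(protocol, "compression_protocol"))
  omega <- 2 * pi * protocol$frequency
  geom$radius * sqrt(fluid$density * omega / fluid$viscosity)
}

#' Oscillatory (Womersley) velocity-magnitude profile
#'
#' Magnitude of the fundamental oscillatory pipe-flow mode
#' u(xi) = 1 - J0(i^{3/2} Wo xi) / J0(i^{3/2} Wo) across the lumen,
#' normalized to 1 on the centerline; zero at the wall (no slip). At Wo -> 0
#' it reduces to the Poiseuille parabola 1 - xi^2.
#'
#' @param wo Womersley number (scalar, >= 0).
#' @param positions radial positions as fractions of the lumen radius, each
#'   in \[0, 1\].
#' @return normalized velocity magnitudes, same length as `positions`.
#' @export
womersley_profile <- function(wo, positions) {
  if (!is.numeric(wo) || length(wo) != 1L || is.na(wo) || wo < 0 ||
      !is.finite(wo)) {
    stop("invalid input: `wo` must be a single finite number >= 0",
         call. = FALSE)
  }
  .check_fraction(positions, "positions")
  if (wo < 1e-3) {
    return(1 - positions^2)
  }
  alpha <- wo * complex(modulus = 1, argument = 3 * pi / 4) # i^{3/2} Wo
  j0a <- .besselJ0_complex(alpha)
  num <- 1 - .besselJ0_complex(alpha * positions) / j0a
  cen <- 1 - 1 / j0a
  Mod(num) / Mod(cen)
}

#' Centerline-to-mean velocity correction factor k_w
#'
#' The ratio of the cross-section-averaged to the centerline time-averaged
#' velocity magnitude of the fundamental oscillatory mode,
#' k_w = 2 int_0^1 u(xi) xi dxi with u the normalized profile of
#' [womersley_profile()]. It converts a tracked centerline tracer velocity v
#' into the net flowrate Q = k_w A v. Bounded in \[0.5, 1\]: 0.5 is the
#' Poiseuille (parabolic) limit, 1 the flat-profile limit.
#'
#' @param wo Womersley number (>= 0); vectorized.
#' @param n_intervals number of radial intervals for the composite Simpson
#'   quadrature (even, default 512).
#' @return k_w in \[0.5, 1\], same length as `wo`.
#' @export
kw_correction <- function(wo, n_intervals = 512) {
  if (!is.numeric(wo) || length(wo) == 0L || anyNA(wo) || any(wo < 0)) {
    stop("invalid input: `wo` must be numeric >= 0", call. = FALSE)
  }
  if (n_intervals %% 2 != 0) n_intervals <- n_intervals + 1
  xi <- seq(0, 1, length.out = n_intervals + 1)
  w <- c(1, rep(c(4, 2), length.out = n_intervals - 1), 1)
  h <- 1 / n_intervals
  vapply(wo, function(a) {
    f <- womersley_profile(a, xi) * xi
    val <- 2 * sum(w * f) * h / 3
    min(max(val, 0.5), 1)
  }, numeric(1))
}

#' Womersley flow regime of an experimental configuration
#'
#' Bundles the angular frequency, Womersley number and k_w correction for a
#' geometry / fluid / protocol triple.
#'
#' @inheritParams womersley_number
#' @param kw optional k_w override in \[0.5, 1\]; when `NULL` (default) it is
#'   computed from the Womersley number with [kw_correction()].
#' @return an object of class `womersley_regime` with fields
#'   `angular_frequency` (rad/s), `womersley` and `kw`.
#' @export
womersley_regime <- function(geom, fluid, protocol, kw = NULL) {
  wo <- womersley_number(geom, fluid, protocol)
  if (is.null(kw)) {
    kw <- kw_correction(wo)
  } else {
    .check_fraction(kw, "kw", lo = 0.5, hi = 1)
  }
  structure(
    list(angular_frequency = 2 * pi * protocol$frequency,
         womersley = wo, kw = kw),
    class = "womersley_regime")
}

#' Moens-Korteweg pulse-wave speed
#'
#' c = sqrt(E h / (rho d)): the pressure-wave speed in a thin-walled elastic
#' tube of wall thickness h, inner diameter d and Young modulus E filled
#' with fluid of density rho.
#'
#' @param young_modulus Young's modulus of the wall (Pa).
#' @param geom a [tube_geometry()].
#' @param fluid a [fluid_properties()].
#' @return wave speed (m/s).
#' @export
moens_korteweg_speed <- function(young_modulus, geom, fluid) {
  .check_positive(young_modulus, "young_modulus")
  stopifnot(inherits(geom, "tube_geometry"),
            inherits(fluid, "fluid_properties"))
  sqrt(young_modulus * geom$wall_thickness /
         (fluid$density * geom$inner_diameter))
}

#' Natural (resonant) frequency of a compliant segment
#'
#' F_n = c / (2 L): the frequency at which reflected pressure waves form
#' standing patterns over a segment of length L.
#'
#' @param wave_speed pressure-wave speed c (m/s).
#' @param geom a [tube_geometry()] (its segment length is used).
#' @return frequency (Hz).
#' @export
natural_frequency <- function(wave_speed, geom) {
  .check_positive(wave_speed, "wave_speed")
  stopifnot(inherits(geom, "tube_geometry"))
  wave_speed / (2 * geom$segment_length)
}

#' Peristaltic reference flowrate
#'
#' Q = F A P: the maximal output of an idealized peristaltic pump with the
#' same lumen area A, pincher length P and compression frequency F — the
#' comparison baseline for valveless-pump output.
#'
#' @param protocol a [compression_protocol()].
#' @param geom a [tube_geometry()].
#' @return volumetric flowrate (m^3/s); use [flow_m3s_to_ulps()] to report
#'   in ul/s.
#' @export
peristaltic_flowrate <- function(protocol, geom) {
  stopifnot(inherits(protocol, "compression_protocol"),
            inherits(geom, "tube_geometry"))
  protocol$frequency * geom$lumen_area * protocol$pincher_length
}

#' Poiseuille resistance scaling
#'
#' R ~ mu L / r^4 with proportionality constant 1; meaningful only as a
#' ratio between configurations.
#'
#' @param fluid a [fluid_properties()].
#' @param geom a [tube_geometry()].
#' @return relative resistance (arbitrary units).
#' @export
poiseuille_resistance_scaling <- function(fluid, geom) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geom, "tube_geometry"))
  fluid$viscosity * geom$segment_length / geom$radius^4
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf(
    "Tube geometry: L = %.1f mm, inner d = %.2f mm, wall h = %.2f mm, lumen area = %.3f mm^2\n",
    x$segment_length * 1e3, x$inner_diameter * 1e3, x$wall_thickness * 1e3,
    x$lumen_area * 1e6))
  invisible(x)
}

#' @export
print.compression_protocol <- function(x, ...) {
  cat(sprintf(
    "Compression protocol: %.2f s on / %.2f s off -> %.2f Hz; pincher %.1f mm at %.1f mm from junction, occlusion %.0f%%\n",
    x$time_on, x$time_off, x$frequency, x$pincher_length * 1e3,
    x$pincher_offset * 1e3, 100 * x$occlusion_fraction))
  invisible(x)
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: rho = %.0f kg/m^3, mu = %.3f cP", x$density,
              viscosity_pas_to_cp(x$viscosity)))
  if (!is.null(x$glycerin_fraction)) {
    cat(sprintf(" (%.0f%% glycerol v/v)", 100 * x$glycerin_fraction))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.womersley_regime <- function(x, ...) {
  cat(sprintf("Womersley regime: omega = %.2f rad/s, Wo = %.2f, k_w = %.3f\n",
              x$angular_frequency, x$womersley, x$kw))
  invisible(x)
}
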