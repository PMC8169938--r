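# Sweep orchestration: flowrate versus compression frequency, fluid
# viscosity or pincher position on synthetic scenes, with ordinary
# least-squares trend fits and file reporting.

#' Default amplitude model mapping an operating point to the true flowrate
#'
#' The pincher-position and frequency dependence of the generated flow is a
#' declared input, not a physical simulation: Q = q_per_hz * F * (1 - 2
#' offset / L), clipped at zero. It is linear in frequency, zero for a
#' mid-tube pincher and maximal at the junction-proximal edge — the
#' qualitative behaviour of an asymmetrically pinched compliant tube —
#' without claiming mechanism.
#'
#' @param q_per_hz_ulps flowrate per unit frequency (ul/s per Hz,
#'   default 16).
#' @return a function `(geom, fluid, protocol) -> Q` in ul/s.
#' @export
default_amplitude_model <- function(q_per_hz_ulps = 16) {
  function(geom, fluid, protocol) {
    pos <- max(0, 1 - 2 * protocol$pincher_offset / geom$segment_length)
    q_per_hz_ulps * protocol$frequency * pos
  }
}

#' Sweep specification
#'
#' @param variable swept variable: `"frequency"` (Hz), `"viscosity"` (cP)
#'   or `"pincher_offset"` (mm from the junction).
#' @param grid strictly increasing, non-empty grid of values of `variable`.
#' @param base_config a [scene_config()] providing everything not swept.
#' @param amplitude_model function `(geom, fluid, protocol) -> Q` in ul/s
#'   defining the true flow at each grid point; default
#'   [default_amplitude_model()].
#' @param n_clips replicate clips per grid point (default from
#'   `base_config`).
#' @param base_seed base RNG seed; grid point i, clip k uses
#'   `base_seed + 1000 (i - 1) + k - 1`.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(variable = c("frequency", "viscosity",
                                    "pincher_offset"),
                       grid, base_config,
                       amplitude_model = default_amplitude_model(),
                       n_clips = base_config$n_clips,
                       base_seed = base_config$seed) {
  variable <- match.arg(variable)
  if (length(grid) == 0 || is.unsorted(grid, strictly = TRUE)) {
    stop("invalid input: `grid` must be non-empty and strictly increasing",
         call. = FALSE)
  }
  stopifnot(inherits(base_config, "scene_config"),
            is.function(amplitude_model))
  structure(
    list(variable = variable, grid = grid, base_config = base_config,
         amplitude_model = amplitude_model, n_clips = n_clips,
         base_seed = as.integer(base_seed)),
    class = "sweep_spec")
}

# build the scene config for one grid point
.sweep_point_config <- function(spec, i) {
  cfg <- spec$base_config
  v <- spec$grid[i]
  protocol <- cfg$protocol
  fluid <- cfg$fluid
  if (spec$variable == "frequency") {
    time_off <- 1 / v - protocol$time_on
    if (time_off <= 0) {
      stop("sweep point ", v, " Hz unreachable with time_on = ",
           protocol$time_on, " s", call. = FALSE)
    }
    protocol <- compression_protocol(protocol$time_on, time_off,
                                     protocol$pincher_length,
                                     protocol$pincher_offset,
                                     protocol$occlusion_fraction)
  } else if (spec$variable == "viscosity") {
    fluid <- fluid_properties(density = fluid$density,
                              viscosity = viscosity_cp_to_pas(v),
                              temperature = fluid$temperature)
  } else {
    protocol <- compression_protocol(protocol$time_on, protocol$time_off,
                                     protocol$pincher_length,
                                     pincher_offset = v * 1e-3,
                                     occlusion_fraction =
                                       protocol$occlusion_fraction)
  }
  q_target <- spec$amplitude_model(cfg$geometry, fluid, protocol)
  direction <- if (q_target == 0) "symmetric" else cfg$direction
  scene_config(cfg$geometry, fluid, protocol,
               target_flowrate_ulps = q_target,
               fps = cfg$fps, duration = cfg$duration, n_clips = spec$n_clips,
               fov_mm = cfg$fov_mm, pixel_scale_mm = cfg$pixel_scale_mm,
               particle_diameter_mm = cfg$particle_diameter_mm,
               particle_density = cfg$particle_density,
               direction = direction, amplitude_mms = cfg$amplitude_mms,
               max_radial_fraction = cfg$max_radial_fraction,
               jitter_sd_px = cfg$jitter_sd_px, miss_prob = cfg$miss_prob,
               false_positive_rate = cfg$false_positive_rate,
               seed = spec$base_seed + 1000L * (i - 1L))
}

#' Run a sweep
#'
#' For each grid point a scene is generated at the operating point, the
#' replicate clips are tracked and quantified, and an ordinary
#' least-squares line is fitted to (variable, Q) — unweighted, as the
#' experimental trends are reported without weighted fits. In viscosity
#' sweeps, points whose Womersley number exceeds 5 at the operating
#' frequency are fitted but flagged: there the oscillatory regime departs
#' from the quasi-steady resistance scaling and linearity is expected to
#' degrade.
#'
#' @param spec a [sweep_spec()].
#' @return an object of class `flow_sweep` with per-point results, the
#'   fitted slope/intercept, and R^2.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- vector("list", length(spec$grid))
  for (i in seq_along(spec$grid)) {
    cfg_i <- .sweep_point_config(spec, i)
    est <- tryCatch(
      estimate_scene_flowrate(cfg_i),
      error = function(e) {
        stop("sweep aborted at ", spec$variable, " = ", spec$grid[i], ": ",
             conditionMessage(e), call. = FALSE)
      })
    res <- est$result
    rows[[i]] <- data.frame(
      value = spec$grid[i],
      q_ulps = res$flowrate_ulps, sd_ulps = res$sd_ulps,
      q_true_ulps = est$truth_ulps,
      v_mms = res$velocity$mean_v_mms,
      womersley = res$regime$womersley, kw = res$regime$kw,
      flagged = spec$variable == "viscosity" && res$regime$womersley > 5)
  }
  points <- do.call(rbind, rows)
  fit <- NULL
  if (nrow(points) >= 3) {
    model <- stats::lm(q_ulps ~ value, data = points)
    fit <- list(slope = unname(stats::coef(model)[2]),
                intercept = unname(stats::coef(model)[1]),
                r_squared = summary(model)$r.squared)
  }
  structure(list(points = points, fit = fit, spec = spec),
            class = "flow_sweep")
}

#' @export
print.flow_sweep <- function(x, ...) {
  unit <- switch(x$spec$variable, frequency = "Hz", viscosity = "cP",
                 pincher_offset = "mm")
  cat(sprintf("Flowrate sweep over %s (%d points)\n", x$spec$variable,
              nrow(x$points)))
  if (!is.null(x$fit)) {
    cat(sprintf("  OLS fit: Q = %.3f + %.3f * %s  (R^2 = %.4f)\n",
                x$fit$intercept, x$fit$slope, unit, x$fit$r_squared))
  }
  if (any(x$points$flagged)) {
    cat(sprintf("  flagged (Wo > 5): %s %s\n",
                paste(x$points$value[x$points$flagged], collapse = ", "),
                unit))
  }
  invisible(x)
}

#' @export
summary.flow_sweep <- function(object, ...) object$points

#' @export
coef.flow_sweep <- function(object, ...) {
  if (is.null(object$fit)) {
    stop("no fit: fewer than 3 sweep points", call. = FALSE)
  }
  c(intercept = object$fit$intercept, slope = object$fit$slope)
}

#' @export
as.data.frame.flow_sweep <- function(x, ...) x$points

#' @export
plot.flow_sweep <- function(x, ...) {
  p <- x$points
  unit <- switch(x$spec$variable, frequency = "Hz", viscosity = "cP",
                 pincher_offset = "mm")
  ylim <- range(c(p$q_ulps - p$sd_ulps, p$q_ulps + p$sd_ulps, 0),
                na.rm = TRUE)
  graphics::plot(p$value, p$q_ulps, pch = 19, ylim = ylim,
                 xlab = paste0(x$spec$variable, " (", unit, ")"),
                 ylab = "net flowrate (ul/s)", ...)
  has_sd <- !is.na(p$sd_ulps)
  if (any(has_sd)) {
    graphics::arrows(p$value[has_sd], p$q_ulps[has_sd] - p$sd_ulps[has_sd],
                     p$value[has_sd], p$q_ulps[has_sd] + p$sd_ulps[has_sd],
                     angle = 90, code = 3, length = 0.03)
  }
  if (!is.null(x$fit)) graphics::abline(x$fit$intercept, x$fit$slope,
                                        lty = 2)
  if (any(p$flagged)) {
    graphics::points(p$value[p$flagged], p$q_ulps[p$flagged], pch = 1,
                     cex = 2)
  }
  invisible(x)
}

#' Measured output relative to the peristaltic reference
#'
#' Q_measured / (F A P): how much of the idealized peristaltic output of
#' the same lumen, pincher and frequency the pump achieves.
#'
#' @param result a [net_flowrate()] result, or a measured flowrate in ul/s.
#' @param protocol a [compression_protocol()].
#' @param geom a [tube_geometry()].
#' @return an object of class `peristaltic_comparison` with the ratio and
#'   both absolute flowrates (ul/s).
#' @export
peristaltic_comparison <- function(result, protocol, geom) {
  q_meas <- if (inherits(result, "flowrate_result")) result$flowrate_ulps
            else as.numeric(result)
  q_ref <- flow_m3s_to_ulps(peristaltic_flowrate(protocol, geom))
  if (q_ref <= 0) {
    stop("undefined ratio: zero peristaltic reference flowrate",
         call. = FALSE)
  }
  structure(list(ratio = q_meas / q_ref, measured_ulps = q_meas,
                 reference_ulps = q_ref),
            class = "peristaltic_comparison")
}

#' @export
print.peristaltic_comparison <- function(x, ...) {
  cat(sprintf(
    "Measured %.1f ul/s vs peristaltic reference %.1f ul/s: ratio %.3f\n",
    x$measured_ulps, x$reference_ulps, x$ratio))
  invisible(x)
}

#' Write sweep results to files
#'
#' Writes `points.csv` (one data row per grid point), `fit.json` (slope,
#' intercept, R^2), `sweep.png` (Q versus variable with replicate error
#' bars) and `run_log.txt` (configuration, seeds, package version) into
#' `dir`. Deterministic inputs give byte-identical CSV output.
#'
#' @param sweep a [run_sweep()] result.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
report_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "flow_sweep"))
  if (nrow(sweep$points) == 0) {
    stop("empty sweep: nothing to report", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot write to directory: ", dir,
                             call. = FALSE)
  points_csv <- file.path(dir, "points.csv")
  utils::write.csv(sweep$points, points_csv, row.names = FALSE)
  fit_json <- file.path(dir, "fit.json")
  jsonlite::write_json(
    if (is.null(sweep$fit)) list() else sweep$fit,
    fit_json, auto_unbox = TRUE, digits = NA)
  plot_png <- file.path(dir, "sweep.png")
  grDevices::png(plot_png, width = 800, height = 600)
  plot(sweep)
  grDevices::dev.off()
  log_txt <- file.path(dir, "run_log.txt")
  cfg <- sweep$spec$base_config
  writeLines(c(
    sprintf("liebauflow %s",
            as.character(utils::packageVersion("liebauflow"))),
    sprintf("sweep variable: %s", sweep$spec$variable),
    sprintf("grid: %s", paste(sweep$spec$grid, collapse = ", ")),
    sprintf("base seed: %d; clips per point: %d", sweep$spec$base_seed,
            sweep$spec$n_clips),
    sprintf("scene: %g fps, %g s, %g particles/frame, jitter %g px, miss %g",
            cfg$fps, cfg$duration, cfg$particle_density, cfg$jitter_sd_px,
            cfg$miss_prob)), log_txt)
  invisible(c(points_csv, fit_json, plot_png, log_txt))
}
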