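# Ground-truthed synthetic scenes: stand-ins for laboratory video of dark
# tracer particles advected through a straight observation tube by pulsatile
# flow with a known net flowrate. Detection tables are in pixels; the truth
# carries the generating centerline series, k_w and Wo.

#' Synthetic scene configuration
#'
#' Parameterizes one synthetic experiment: the observation-tube geometry,
#' fluid and compression protocol, the target net flowrate the flow must
#' carry, the camera model (frame rate, field of view, pixel scale), tracer
#' properties and detection-noise model.
#'
#' @param geometry a [tube_geometry()] of the observation tube.
#' @param fluid a [fluid_properties()].
#' @param protocol a [compression_protocol()].
#' @param target_flowrate_ulps net flowrate the generated flow carries
#'   (ul/s); may be negative (reversed flow) or 0 with
#'   `direction = "symmetric"`.
#' @param fps frames per second (default 60).
#' @param duration clip duration (s, default 30).
#' @param n_clips replicate clips per experiment (default 3).
#' @param fov_mm field of view as c(width, height) in mm; width is axial.
#'   Defaults to 15 mm by the tube inner diameter.
#' @param pixel_scale_mm mm per pixel (default 0.05, so a 0.5 mm tracer
#'   spans 10 px).
#' @param particle_diameter_mm tracer diameter (mm, default 0.5).
#' @param particle_density expected number of tracers in view per frame
#'   (default 8).
#' @param direction `"forward"` (one-sided pulses, net flow) or
#'   `"symmetric"` (back-and-forth pulses, zero net flow).
#' @param amplitude_mms peak centerline velocity for symmetric waveforms
#'   (mm/s, default 5); ignored for forward waveforms.
#' @param max_radial_fraction tracers ride at radial positions up to this
#'   fraction of the lumen radius (default 0.15: large dense tracers travel
#'   near the axis, so their speed tracks the centerline).
#' @param jitter_sd_px detection jitter s.d. (px, default 0.5).
#' @param miss_prob per-particle per-frame missed-detection probability
#'   (default 0.05).
#' @param false_positive_rate expected spurious detections per frame
#'   (default 0.1); each lasts a single frame.
#' @param seed RNG seed; clip k of an experiment uses `seed + k - 1`.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(geometry, fluid, protocol, target_flowrate_ulps,
                         fps = 60, duration = 30, n_clips = 3,
                         fov_mm = c(15, geometry$inner_diameter * 1e3),
                         pixel_scale_mm = 0.05,
                         particle_diameter_mm = 0.5, particle_density = 8,
                         direction = c("forward", "symmetric"),
                         amplitude_mms = 5, max_radial_fraction = 0.15,
                         jitter_sd_px = 0.5, miss_prob = 0.05,
                         false_positive_rate = 0.1, seed = 1L) {
  stopifnot(inherits(geometry, "tube_geometry"),
            inherits(fluid, "fluid_properties"),
            inherits(protocol, "compression_protocol"))
  direction <- match.arg(direction)
  .check_positive(fps, "fps")
  .check_positive(duration, "duration")
  .check_positive(pixel_scale_mm, "pixel_scale_mm")
  if (jitter_sd_px < 0) stop("invalid input: `jitter_sd_px` must be >= 0",
                             call. = FALSE)
  .check_fraction(miss_prob, "miss_prob", 0, 1 - 1e-12)
  .check_fraction(max_radial_fraction, "max_radial_fraction", 0, 1)
  structure(
    list(geometry = geometry, fluid = fluid, protocol = protocol,
         target_flowrate_ulps = target_flowrate_ulps, fps = fps,
         duration = duration, n_clips = n_clips, fov_mm = fov_mm,
         pixel_scale_mm = pixel_scale_mm,
         particle_diameter_mm = particle_diameter_mm,
         particle_density = particle_density, direction = direction,
         amplitude_mms = amplitude_mms,
         max_radial_fraction = max_radial_fraction,
         jitter_sd_px = jitter_sd_px, miss_prob = miss_prob,
         false_positive_rate = false_positive_rate,
         seed = as.integer(seed)),
    class = "scene_config")
}

#' Per-frame centerline velocity series of the compression waveform
#'
#' One compression period consists of a half-cosine rise to peak velocity
#' during the `time_on` of the protocol followed by an exponential decay
#' (time constant `time_on`) during `time_off`, reproducing the observed
#' intermittent advance-per-compression of tracers without claiming pump
#' mechanics. The series is scaled so that its k_w-corrected mean times the
#' lumen area equals the target net flowrate exactly (forward waveform), or
#' mirrored half a period later for a zero-net back-and-forth waveform
#' (symmetric, e.g. a mid-tube pincher).
#'
#' @param protocol a [compression_protocol()].
#' @param target_flowrate_ulps net flowrate to carry (ul/s); must be 0 for
#'   symmetric waveforms and non-zero for forward ones.
#' @param geom a [tube_geometry()].
#' @param kw centerline-to-mean correction of the generating flow.
#' @param fps frames per second.
#' @param duration series duration (s).
#' @param direction `"forward"` or `"symmetric"`.
#' @param amplitude_mms peak centerline velocity for symmetric waveforms.
#' @return numeric vector of per-frame centerline velocities (mm/s).
#' @export
pulse_waveform <- function(protocol, target_flowrate_ulps, geom, kw,
                           fps = 60, duration = 30,
                           direction = c("forward", "symmetric"),
                           amplitude_mms = 5) {
  direction <- match.arg(direction)
  stopifnot(inherits(protocol, "compression_protocol"),
            inherits(geom, "tube_geometry"))
  .check_fraction(kw, "kw", 0.5, 1)
  n <- round(fps * duration)
  period <- 1 / protocol$frequency
  t <- (seq_len(n) - 1) / fps
  shape_at <- function(ph) {
    ifelse(ph < protocol$time_on,
           0.5 * (1 - cos(pi * ph / protocol$time_on)),
           exp(-(ph - protocol$time_on) / protocol$time_on))
  }
  lumen_mm2 <- geom$lumen_area * 1e6
  if (direction == "forward") {
    base <- shape_at(t %% period)
    if (target_flowrate_ulps == 0) {
      stop("invalid config: a forward waveform cannot carry zero net flow; ",
           "use direction = \"symmetric\"", call. = FALSE)
    }
    if (mean(base) <= 0) {
      stop("invalid config: waveform amplitude is zero over the sampled ",
           "frames, target flowrate unreachable", call. = FALSE)
    }
    amp <- target_flowrate_ulps / (kw * lumen_mm2 * mean(base))
    amp * base
  } else {
    if (target_flowrate_ulps != 0) {
      stop("invalid config: a symmetric waveform carries zero net flow",
           call. = FALSE)
    }
    if (amplitude_mms == 0) {
      stop("invalid config: zero waveform amplitude", call. = FALSE)
    }
    base <- shape_at(t %% period) - shape_at((t + period / 2) %% period)
    base <- base - mean(base)
    amplitude_mms * base / max(abs(base))
  }
}

#' Generate one synthetic clip
#'
#' Tracers enter upstream, advect with axial velocity equal to the
#' centerline waveform times the Womersley profile at their (hidden) radial
#' position, and exit downstream, re-entering as new particles to keep the
#' in-view density constant. Detections are true pixel positions plus
#' Gaussian jitter, dropped with the configured miss probability; false
#' positives appear uniformly over the field for a single frame.
#'
#' @param config a [scene_config()].
#' @param clip clip index (1-based); clip k uses seed `config$seed + k - 1`,
#'   so replicate clips are independent but reproducible.
#' @return an object of class `liebau_scene` with components
#'   `detections` (data.frame: frame, x_px, y_px, area_px, is_truth),
#'   `truth` (trajectories, centerline and cross-section-mean velocity
#'   series, net flowrate, k_w, Wo), `config`, `clip`, `seed_used`, and
#'   frame dimensions.
#' @export
generate_scene <- function(config, clip = 1L) {
  stopifnot(inherits(config, "scene_config"))
  seed_used <- config$seed + as.integer(clip) - 1L
  set.seed(seed_used)

  geom <- config$geometry
  regime <- womersley_regime(geom, config$fluid, config$protocol)
  n_frames <- round(config$fps * config$duration)
  width_mm <- config$fov_mm[1]
  height_mm <- config$fov_mm[2]
  scale <- config$pixel_scale_mm
  width_px <- round(width_mm / scale)
  height_px <- round(height_mm / scale)
  r_mm <- geom$radius * 1e3
  lumen_mm2 <- geom$lumen_area * 1e6
  area_px <- pi * (config$particle_diameter_mm / 2 / scale)^2

  n_particles <- round(config$particle_density)
  if (n_particles < 1 || width_mm <= 0 || n_frames < 1) {
    stop("degenerate scene: no particles are ever in view", call. = FALSE)
  }

  u_c <- pulse_waveform(config$protocol, config$target_flowrate_ulps, geom,
                        kw = regime$kw, fps = config$fps,
                        duration = config$duration,
                        direction = config$direction,
                        amplitude_mms = config$amplitude_mms)

  new_radial <- function(k) {
    xi <- stats::runif(k, 0, config$max_radial_fraction)
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    list(xi = xi, y_mm = height_mm / 2 + sgn * xi * r_mm,
         phi = womersley_profile(regime$womersley, xi))
  }

  x_mm <- stats::runif(n_particles, 0, width_mm)
  rad <- new_radial(n_particles)
  y_mm <- rad$y_mm
  phi <- rad$phi
  ids <- seq_len(n_particles)
  next_id <- n_particles + 1L

  traj <- vector("list", n_frames)
  dets <- vector("list", n_frames)

  for (f in seq_len(n_frames)) {
    x_px <- x_mm / scale
    y_px <- y_mm / scale
    traj[[f]] <- data.frame(particle = ids, frame = f - 1L,
                            x_px = x_px, y_px = y_px)
    keep <- stats::runif(n_particles) >= config$miss_prob
    n_keep <- sum(keep)
    det_f <- if (n_keep > 0) {
      data.frame(
        frame = rep.int(f - 1L, n_keep),
        x_px = pmin(pmax(x_px[keep] +
                           stats::rnorm(n_keep, 0, config$jitter_sd_px), 0),
                    width_px - 1e-6),
        y_px = pmin(pmax(y_px[keep] +
                           stats::rnorm(n_keep, 0, config$jitter_sd_px), 0),
                    height_px - 1e-6),
        area_px = area_px * stats::runif(n_keep, 0.95, 1.05),
        is_truth = TRUE)
    } else NULL
    n_fp <- stats::rpois(1, config$false_positive_rate)
    if (n_fp > 0) {
      det_f <- rbind(det_f, data.frame(
        frame = rep.int(f - 1L, n_fp),
        x_px = stats::runif(n_fp, 0, width_px),
        y_px = stats::runif(n_fp, 0, height_px),
        area_px = area_px * stats::runif(n_fp, 0.5, 1.5),
        is_truth = FALSE))
    }
    dets[[f]] <- det_f

    # advance to the next frame; exited particles re-enter as new ones
    x_mm <- x_mm + u_c[f] * phi / config$fps
    out_r <- x_mm >= width_mm
    out_l <- x_mm < 0
    n_new <- sum(out_r) + sum(out_l)
    if (n_new > 0) {
      x_mm[out_r] <- x_mm[out_r] - width_mm
      x_mm[out_l] <- x_mm[out_l] + width_mm
      repl <- which(out_r | out_l)
      rad <- new_radial(length(repl))
      y_mm[repl] <- rad$y_mm
      phi[repl] <- rad$phi
      ids[repl] <- seq.int(next_id, length.out = length(repl))
      next_id <- next_id + length(repl)
    }
  }

  detections <- do.call(rbind, dets)
  rownames(detections) <- NULL
  mean_series <- regime$kw * u_c
  structure(
    list(detections = detections,
         truth = list(trajectories = do.call(rbind, traj),
                      centerline_mms = u_c,
                      frame_mean_mms = mean_series,
                      net_flowrate_ulps = mean(mean_series) * lumen_mm2,
                      kw = regime$kw, womersley = regime$womersley),
         config = config, clip = as.integer(clip), seed_used = seed_used,
         width_px = width_px, height_px = height_px),
    class = "liebau_scene")
}

#' Generate all replicate clips of an experiment
#'
#' @param config a [scene_config()].
#' @return list of `config$n_clips` [generate_scene()] results.
#' @export
generate_clips <- function(config) {
  lapply(seq_len(config$n_clips), function(k) generate_scene(config, k))
}

#' @export
print.liebau_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic clip %d (seed %d): %d frames of %d x %d px, %d detections\n",
    x$clip, x$seed_used, round(x$config$fps * x$config$duration),
    x$width_px, x$height_px, nrow(x$detections)))
  cat(sprintf("  truth: Q = %.3f ul/s, Wo = %.2f, k_w = %.3f\n",
              x$truth$net_flowrate_ulps, x$truth$womersley, x$truth$kw))
  invisible(x)
}

#' Render a scene as grayscale frames
#'
#' Draws each tracer as a dark anti-aliased disc on a light background and
#' adds Gaussian sensor noise. Pixel centers sit at integer (x, y)
#' coordinates, matching the detection convention.
#'
#' @param scene a [generate_scene()] result.
#' @param background background intensity (default 0.92).
#' @param particle_intensity disc intensity (default 0.08).
#' @param noise_sd sensor-noise s.d. (default 0.01).
#' @param seed RNG seed for the sensor noise.
#' @return list of numeric matrices (rows = y, cols = x) in \[0, 1\].
#' @export
render_frames <- function(scene, background = 0.92, particle_intensity = 0.08,
                          noise_sd = 0.01, seed = scene$seed_used + 9999L) {
  stopifnot(inherits(scene, "liebau_scene"))
  set.seed(seed)
  w <- scene$width_px
  h <- scene$height_px
  r_px <- scene$config$particle_diameter_mm / 2 / scene$config$pixel_scale_mm
  tr <- scene$truth$trajectories
  n_frames <- round(scene$config$fps * scene$config$duration)
  by_frame <- split(tr, tr$frame)
  lapply(seq_len(n_frames), function(f) {
    img <- matrix(background, nrow = h, ncol = w)
    pts <- by_frame[[as.character(f - 1L)]]
    if (!is.null(pts)) {
      for (i in seq_len(nrow(pts))) {
        cx <- pts$x_px[i]; cy <- pts$y_px[i]
        cols <- max(1, floor(cx - r_px)):min(w, ceiling(cx + r_px + 2))
        rows <- max(1, floor(cy - r_px)):min(h, ceiling(cy + r_px + 2))
        dx <- (cols - 1) - cx
        dy <- (rows - 1) - cy
        dist <- sqrt(outer(dy^2, dx^2, `+`))
        cov <- pmin(1, pmax(0, r_px + 0.5 - dist))
        img[rows, cols] <- img[rows, cols] -
          (background - particle_intensity) * cov
      }
    }
    if (noise_sd > 0) img <- img + stats::rnorm(h * w, 0, noise_sd)
    pmin(pmax(img, 0), 1)
  })
}

#' Write / read detection tables
#'
#' CSV with columns `frame, x_px, y_px, area_px` (plus `is_truth` in the
#' truth-annotated variant).
#'
#' @param detections detection data.frame.
#' @param path CSV path.
#' @param truth_column keep the `is_truth` column (default `FALSE`).
#' @return `path` invisibly / the detection data.frame.
#' @export
write_detections <- function(detections, path, truth_column = FALSE) {
  out <- detections
  if (!truth_column) out$is_truth <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  utils::read.csv(path)
}

#' Write rendered frames to numbered image files with a manifest
#'
#' @param frames list of matrices from [render_frames()].
#' @param dir output directory (created if needed).
#' @param format `"tiff"` or `"png"`.
#' @return the manifest path, invisibly.
#' @export
write_frames <- function(frames, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tiff") "tif" else "png"
  files <- sprintf("frame_%05d.%s", seq_along(frames) - 1, ext)
  for (i in seq_along(frames)) {
    p <- file.path(dir, files[i])
    if (format == "tiff") tiff::writeTIFF(frames[[i]], p)
    else png::writePNG(frames[[i]], p)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(n_frames = length(frames), format = format, files = files,
         height_px = nrow(frames[[1]]), width_px = ncol(frames[[1]])),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(manifest$files, function(f) {
    p <- file.path(dir, f)
    img <- if (manifest$format == "tiff") tiff::readTIFF(p)
           else png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
}

#' Write the ground truth of a scene as JSON
#'
#' @param scene a [generate_scene()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene_truth <- function(scene, path) {
  jsonlite::write_json(
    list(net_flowrate_ulps = scene$truth$net_flowrate_ulps,
         kw = scene$truth$kw, womersley = scene$truth$womersley,
         seed_used = scene$seed_used,
         centerline_mms = scene$truth$centerline_mms,
         frame_mean_mms = scene$truth$frame_mean_mms,
         trajectories = scene$truth$trajectories),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
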