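# From tracks to the headline quantity: time-averaged tracer velocity,
# k_w correction at the operating Womersley number, net volumetric flowrate
# with replicate variability.

#' Duration-weighted mean tracer velocity of one clip
#'
#' The observed aggregate velocity standing in for the centerline measure:
#' every linked step of every track contributes its axial velocity weighted
#' by its frame span.
#'
#' @param velocities a [track_velocities()] result (or its `steps`
#'   data.frame).
#' @return mean axial velocity (mm/s), signed.
#' @export
clip_mean_velocity <- function(velocities) {
  steps <- if (inherits(velocities, "track_velocities")) velocities$steps
           else velocities
  if (is.null(steps) || nrow(steps) == 0) {
    stop("empty clip: no tracked velocity samples survive filtering",
         call. = FALSE)
  }
  sum(steps$v_mms * steps$weight) / sum(steps$weight)
}

#' Combine replicate clip means into a velocity estimate
#'
#' @param clip_means numeric vector of per-clip mean velocities (mm/s).
#' @return an object of class `velocity_estimate` with fields `mean_v_mms`,
#'   `sd_mms` (sample s.d. across clips; `NA` and flagged when only one
#'   clip) and `n_clips`.
#' @export
replicate_velocity <- function(clip_means) {
  if (!is.numeric(clip_means) || length(clip_means) == 0 ||
      anyNA(clip_means)) {
    stop("invalid input: `clip_means` must be a non-empty numeric vector",
         call. = FALSE)
  }
  n <- length(clip_means)
  structure(
    list(mean_v_mms = mean(clip_means),
         sd_mms = if (n >= 2) stats::sd(clip_means) else NA_real_,
         sd_defined = n >= 2, n_clips = n),
    class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("Velocity estimate: %.3f mm/s", x$mean_v_mms))
  if (x$sd_defined) cat(sprintf(" +/- %.3f (sd over %d clips)", x$sd_mms,
                                x$n_clips))
  else cat(" (single clip; sd undefined)")
  cat("\n")
  invisible(x)
}

#' Net volumetric flowrate from a velocity estimate
#'
#' Q = k_w A v: the tracked velocity is mapped to the cross-section mean by
#' the k_w correction of the operating Womersley regime, then multiplied by
#' the lumen area. The flowrate is signed; negative values indicate flow
#' reversal. The replicate s.d. propagates linearly.
#'
#' @param estimate a [replicate_velocity()] result, or a single numeric
#'   mean velocity (mm/s).
#' @param geom a [tube_geometry()] of the observation tube.
#' @param regime a [womersley_regime()] computed for the same tube and
#'   operating point.
#' @return an object of class `flowrate_result` with flowrate in ul/s and
#'   ml/min, the replicate s.d., and the regime used.
#' @export
net_flowrate <- function(estimate, geom, regime) {
  if (is.numeric(estimate)) estimate <- replicate_velocity(estimate)
  stopifnot(inherits(estimate, "velocity_estimate"),
            inherits(geom, "tube_geometry"),
            inherits(regime, "womersley_regime"))
  .check_fraction(regime$kw, "regime$kw", 0.5, 1)
  lumen_mm2 <- geom$lumen_area * 1e6
  q <- regime$kw * lumen_mm2 * estimate$mean_v_mms   # mm^3/s == ul/s
  sd_q <- if (estimate$sd_defined) regime$kw * lumen_mm2 * estimate$sd_mms
          else NA_real_
  structure(
    list(flowrate_ulps = q, sd_ulps = sd_q,
         flowrate_mlmin = flow_ulps_to_mlmin(q),
         sd_mlmin = if (is.na(sd_q)) NA_real_ else flow_ulps_to_mlmin(sd_q),
         velocity = estimate, geometry = geom, regime = regime),
    class = "flowrate_result")
}

#' @export
print.flowrate_result <- function(x, ...) {
  cat(sprintf("Net flowrate: %.2f ul/s (%.3f ml/min)", x$flowrate_ulps,
              x$flowrate_mlmin))
  if (!is.na(x$sd_ulps)) {
    cat(sprintf(" +/- %.2f ul/s over %d clips", x$sd_ulps,
                x$velocity$n_clips))
  }
  cat(sprintf("\n  v = %.3f mm/s, Wo = %.2f, k_w = %.3f\n",
              x$velocity$mean_v_mms, x$regime$womersley, x$regime$kw))
  invisible(x)
}

#' @export
summary.flowrate_result <- function(object, ...) {
  data.frame(v_mms = object$velocity$mean_v_mms,
             sd_v_mms = object$velocity$sd_mms,
             n_clips = object$velocity$n_clips,
             womersley = object$regime$womersley,
             kw = object$regime$kw,
             q_ulps = object$flowrate_ulps,
             sd_q_ulps = object$sd_ulps,
             q_mlmin = object$flowrate_mlmin)
}

#' Full pipeline: detections of replicate clips to a flowrate
#'
#' Runs linking, velocity extraction and clip averaging on each clip's
#' detection table, then combines replicates and applies the Womersley
#' correction of the supplied regime.
#'
#' @param clips list of detection data.frames (one per replicate clip), or
#'   a list of [generate_scene()] results.
#' @param geom a [tube_geometry()].
#' @param regime a [womersley_regime()].
#' @param linker a [linker_config()].
#' @param pixel_scale_mm mm per pixel.
#' @param fps frames per second.
#' @return a [net_flowrate()] result.
#' @export
quantify_clips <- function(clips, geom, regime, linker, pixel_scale_mm, fps) {
  means <- vapply(clips, function(cl) {
    det <- if (inherits(cl, "liebau_scene")) cl$detections else cl
    ts <- link_tracks(det, linker)
    clip_mean_velocity(track_velocities(ts, pixel_scale_mm, fps))
  }, numeric(1))
  net_flowrate(replicate_velocity(means), geom, regime)
}

#' Quantify a synthetic experiment end to end
#'
#' Convenience wrapper: generates (or accepts) the replicate clips of a
#' [scene_config()], derives the default linker from the scene, and returns
#' the pipeline flowrate alongside the ground truth.
#'
#' @param config a [scene_config()].
#' @param linker optional [linker_config()]; default from
#'   [linker_config_for_scene()].
#' @return list with `result` (a [net_flowrate()] result) and
#'   `truth_ulps` (the generating net flowrate).
#' @export
estimate_scene_flowrate <- function(config, linker = NULL) {
  clips <- generate_clips(config)
  if (is.null(linker)) linker <- linker_config_for_scene(clips[[1]])
  regime <- womersley_regime(config$geometry, config$fluid, config$protocol)
  res <- quantify_clips(clips, config$geometry, regime, linker,
                        config$pixel_scale_mm, config$fps)
  list(result = res, truth_ulps = clips[[1]]$truth$net_flowrate_ulps)
}
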