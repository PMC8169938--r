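# Shared fixtures and independent oracles.

# Observation-tube geometry used throughout (Tygon, 3 mm ID) and the
# compliant-segment geometry of the frequency/viscosity experiments.
tygon_geom <- function() tube_geometry(3e-3, 0.5e-3, 38e-3)
compliant_geom <- function() tube_geometry(5e-3, 0.5e-3, 38e-3)
water_fluid <- function() fluid_properties(1000, 0.95e-3)

protocol_hz <- function(f, time_on = 0.2, ...) {
  compression_protocol(time_on, 1 / f - time_on, ...)
}

# small synthetic scene for tracking tests
small_scene_config <- function(q_ulps = 15, duration = 2, density = 4,
                               jitter = 0, miss = 0, fp = 0, seed = 1,
                               f_hz = 1.5, n_clips = 1, ...) {
  scene_config(tygon_geom(), water_fluid(), protocol_hz(f_hz),
               target_flowrate_ulps = q_ulps, duration = duration,
               n_clips = n_clips, particle_density = density,
               jitter_sd_px = jitter, miss_prob = miss,
               false_positive_rate = fp, seed = seed, ...)
}

# Brute-force oracle for the gated one-to-one assignment: minimal total
# cost over all partial matchings, where a link costs its Euclidean
# distance (allowed only within the gate) and every unmatched point on
# either side costs the gate distance b.
oracle_match_cost <- function(xy1, xy2, b) {
  n1 <- nrow(xy1)
  n2 <- nrow(xy2)
  if (n1 == 0 || n2 == 0) return(b * (n1 + n2))
  d <- sqrt(outer(xy1[, 1], xy2[, 1], `-`)^2 +
              outer(xy1[, 2], xy2[, 2], `-`)^2)
  best <- Inf
  rec <- function(i, used, cost) {
    if (cost >= best) return(invisible())
    if (i > n1) {
      best <<- min(best, cost + b * sum(!used))
      return(invisible())
    }
    rec(i + 1L, used, cost + b)   # leave i unmatched
    for (j in which(!used)) {
      if (d[i, j] <= b) {
        used2 <- used
        used2[j] <- TRUE
        rec(i + 1L, used2, cost + d[i, j])
      }
    }
  }
  rec(1L, rep(FALSE, n2), 0)
  best
}

# objective value achieved by the package's assignment
linker_match_cost <- function(xy1, xy2, b) {
  m <- assign_frame_pair(xy1, xy2, b)
  d <- sqrt(outer(xy1[, 1], xy2[, 1], `-`)^2 +
              outer(xy1[, 2], xy2[, 2], `-`)^2)
  linked <- which(!is.na(m))
  sum(d[cbind(linked, m[linked])]) +
    b * (sum(is.na(m)) + nrow(xy2) - length(linked))
}

# Independent fine-grid quadrature oracle for k_w: trapezoidal rule on a
# 10x denser radial grid than the implementation's Simpson default.
oracle_kw <- function(wo, n = 5120) {
  xi <- seq(0, 1, length.out = n + 1)
  f <- womersley_profile(wo, xi) * xi
  2 * sum((f[-1] + f[-length(f)]) / 2) / n
}
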