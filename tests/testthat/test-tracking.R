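make_det <- function(frame, x, y) {
  data.frame(frame = frame, x_px = x, y_px = y)
}

test_that("particle detection handles blank, single and separated discs", {
  blank <- list(matrix(0.9, 40, 60))
  expect_equal(nrow(detect_particles(blank)), 0)
  expect_error(detect_particles(list()), "empty")
  # render one disc at a known sub-pixel center and recover it
  cfg <- small_scene_config(duration = 2 / 60, density = 1, seed = 11,
                            fov_mm = c(6, 3))
  sc <- generate_scene(cfg)
  det <- detect_particles(render_frames(sc, noise_sd = 0))
  tr <- sc$truth$trajectories
  expect_equal(nrow(det), nrow(tr))
  expect_lt(max(sqrt((det$x_px - tr$x_px)^2 + (det$y_px - tr$y_px)^2)),
            0.25)
  # two discs > 3 diameters apart give exactly 2 detections
  img <- matrix(0.9, 50, 120)
  for (cpos in list(c(25, 20), c(25, 80))) {
    yy <- outer((0:49 - cpos[1])^2, (0:119 - cpos[2])^2, `+`)
    img[sqrt(yy) <= 5] <- 0.1
  }
  expect_equal(nrow(detect_particles(list(img))), 2)
})

test_that("two parallel non-crossing paths are tracked exactly", {
  frames <- 0:9
  det <- rbind(make_det(frames, 10 + 2 * frames, 10),
               make_det(frames, 10 + 2 * frames, 30))
  ts <- link_tracks(det, linker_config(5))
  expect_equal(length(unique(ts$tracks$track_id)), 2)
  for (id in unique(ts$tracks$track_id)) {
    tr <- ts$tracks[ts$tracks$track_id == id, ]
    expect_equal(tr$frame, frames)
    expect_equal(diff(tr$x_px), rep(2, 9))
    expect_equal(length(unique(tr$y_px)), 1)
  }
  expect_equal(nrow(ts$gaps), 0)
})

test_that("a deleted middle detection is bridged by gap closing", {
  frames <- 0:8
  det <- make_det(frames, 5 + 3 * frames, 12)
  det <- det[det$frame != 4, ]
  ts <- link_tracks(det, linker_config(5, max_gap_frames = 1))
  expect_equal(length(unique(ts$tracks$track_id)), 1)
  expect_equal(nrow(ts$gaps), 1)
  expect_equal(ts$gaps$length, 1L)
  expect_equal(ts$gaps$start_frame, 4L)
  expect_true(ts$tracks$gap_flag[ts$tracks$frame == 5])
  # without gap closing the two halves die below min_track_length
  ts0 <- link_tracks(det, linker_config(5, max_gap_frames = 0,
                                        min_track_length = 5))
  expect_equal(length(unique(ts0$tracks$track_id)), 0)
})

test_that("frame-pair assignment matches the brute-force oracle", {
  set.seed(77)
  for (rep in 1:40) {
    n1 <- sample(0:6, 1)
    n2 <- sample(0:6, 1)
    xy1 <- cbind(runif(n1, 0, 30), runif(n1, 0, 30))
    xy2 <- cbind(runif(n2, 0, 30), runif(n2, 0, 30))
    b <- runif(1, 5, 15)
    expect_equal(linker_match_cost(xy1, xy2, b),
                 oracle_match_cost(xy1, xy2, b), tolerance = 1e-9)
  }
})

test_that("linking is independent of detection row order", {
  sc <- generate_scene(small_scene_config(duration = 1.5, density = 5,
                                          seed = 21, jitter = 0.3,
                                          miss = 0.05, fp = 0.2))
  lc <- linker_config_for_scene(sc)
  t1 <- link_tracks(sc$detections, lc)
  shuffled <- sc$detections[sample(nrow(sc$detections)), ]
  t2 <- link_tracks(shuffled, lc)
  expect_equal(t1$tracks, t2$tracks)
  expect_equal(t1$gaps, t2$gaps)
})

test_that("noiseless well-separated scenes are recovered exactly", {
  cfg <- small_scene_config(duration = 2, density = 4, seed = 31)
  sc <- generate_scene(cfg)
  ts <- link_tracks(sc$detections, linker_config_for_scene(sc))
  tr <- sc$truth$trajectories
  counts <- table(tr$particle)
  expected_tracks <- sum(counts >= 5)
  expect_equal(length(unique(ts$tracks$track_id)), expected_tracks)
  expect_equal(nrow(ts$gaps), 0)
  # every recovered track equals one truth trajectory point for point
  truth_key <- paste(tr$frame, round(tr$x_px, 6), round(tr$y_px, 6))
  for (id in unique(ts$tracks$track_id)) {
    seg <- ts$tracks[ts$tracks$track_id == id, ]
    key <- paste(seg$frame, round(seg$x_px, 6), round(seg$y_px, 6))
    expect_true(all(key %in% truth_key))
    expect_equal(seg$frame, seq(min(seg$frame), max(seg$frame)))
  }
})

test_that("gap closing restores topology after any interior deletion", {
  cfg <- small_scene_config(duration = 1, density = 3, seed = 41)
  sc <- generate_scene(cfg)
  lc <- linker_config_for_scene(sc, max_gap_frames = 2)
  base <- link_tracks(sc$detections, lc)
  n_base <- length(unique(base$tracks$track_id))
  det <- sc$detections
  interior <- which(det$frame > min(det$frame) & det$frame < max(det$frame))
  for (i in interior) {
    ts <- link_tracks(det[-i, ], lc)
    expect_equal(length(unique(ts$tracks$track_id)), n_base)
  }
})

test_that("track velocities convert pixels to mm/s with gap handling", {
  det <- make_det(0:5, 10 + 2 * (0:5), 8)
  ts <- link_tracks(det, linker_config(5))
  tv <- track_velocities(ts, pixel_scale_mm = 0.05, fps = 60)
  expect_equal(tv$steps$v_mms, rep(6, 5))     # 2 px/frame @ 0.05 mm, 60 fps
  expect_equal(tv$per_track$mean_v_mms, 6)
  # stationary
  det0 <- make_det(0:5, 20, 8)
  tv0 <- track_velocities(link_tracks(det0, linker_config(5)), 0.05, 60)
  expect_equal(tv0$per_track$mean_v_mms, 0)
  # reversed motion is negative
  detr <- make_det(0:5, 40 - 2 * (0:5), 8)
  tvr <- track_velocities(link_tracks(detr, linker_config(5)), 0.05, 60)
  expect_equal(tvr$per_track$mean_v_mms, -6)
  # a closed gap of length 1 spans 2 frames: velocity divides by 2
  detg <- make_det(c(0:2, 4:6), 10 + 2 * c(0:2, 4:6), 8)
  tsg <- link_tracks(detg, linker_config(5, max_gap_frames = 1))
  tvg <- track_velocities(tsg, 0.05, 60)
  gap_step <- tvg$steps[tvg$steps$frame_from == 2, ]
  expect_equal(gap_step$v_mms, 4 * 0.05 * 60 / 2)
  expect_equal(gap_step$weight, 2)
  # single-point tracks are excluded with a count
  single <- data.frame(track_id = c(1, 1, 2),
                       frame = c(0, 1, 0), x_px = c(0, 2, 50), y_px = 1)
  tvs <- track_velocities(single, 0.05, 60)
  expect_equal(tvs$n_excluded_single, 1L)
})

test_that("velocity estimation is unbiased on constant-velocity truth", {
  # uniform drift, zero jitter: mean error below 0.25 px * scale * fps
  v0 <- 3.4                       # mm/s
  scale <- 0.05; fps <- 60
  x0 <- seq(10, 280, by = 30)
  det <- do.call(rbind, lapply(0:29, function(f) {
    data.frame(frame = f, x_px = x0 + v0 / scale / fps * f,
               y_px = seq(10, 50, length.out = length(x0)))
  }))
  ts <- link_tracks(det, linker_config(5))
  tv <- track_velocities(ts, scale, fps)
  expect_lt(abs(clip_mean_velocity(tv) - v0), 0.25 * scale * fps)
  expect_equal(clip_mean_velocity(tv), v0, tolerance = 1e-9)
})

test_that("empty input yields an empty track set", {
  ts <- link_tracks(data.frame(frame = integer(0), x_px = numeric(0),
                               y_px = numeric(0)), linker_config(5))
  expect_equal(nrow(ts$tracks), 0)
  expect_equal(ts$n_discarded_short, 0L)
})

test_that("track CSV export writes table and per-track summary", {
  det <- make_det(0:6, 10 + 2 * (0:6), 8)
  ts <- link_tracks(det, linker_config(5))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_tracks(ts, csv)
  expect_true(file.exists(csv))
  expect_true(file.exists(sub("\\.csv$", "_summary.csv", csv)))
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 7)
  expect_named(back, c("track_id", "frame", "x_px", "y_px", "gap_flag"))
})
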