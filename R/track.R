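# Trajectory linking: per-frame-pair globally optimal nearest-neighbor
# assignment with a distance gate, followed by gap closing across missed
# detections, both solved as linear assignment problems.

#' Linker configuration
#'
#' @param max_link_distance maximal frame-to-frame link distance (px); also
#'   the cost of leaving a detection unlinked, so links are always preferred
#'   when they beat the gate.
#' @param max_gap_frames maximal number of consecutive missed frames a gap
#'   may bridge (default 2; 0 disables gap closing).
#' @param max_gap_distance maximal distance for a gap-closing join (px,
#'   default twice `max_link_distance`; must be >= `max_link_distance`).
#' @param min_track_length minimal number of detections per kept track
#'   (default 5).
#' @return an object of class `linker_config`.
#' @export
linker_config <- function(max_link_distance, max_gap_frames = 2,
                          max_gap_distance = 2 * max_link_distance,
                          min_track_length = 5) {
  .check_positive(max_link_distance, "max_link_distance")
  if (max_gap_frames < 0) {
    stop("invalid input: `max_gap_frames` must be >= 0", call. = FALSE)
  }
  if (max_gap_distance < max_link_distance) {
    stop("invalid input: `max_gap_distance` must be >= `max_link_distance`",
         call. = FALSE)
  }
  .check_positive(min_track_length, "min_track_length")
  structure(
    list(max_link_distance = max_link_distance,
         max_gap_frames = as.integer(max_gap_frames),
         max_gap_distance = max_gap_distance,
         min_track_length = as.integer(min_track_length)),
    class = "linker_config")
}

#' Default linker configuration for a synthetic scene
#'
#' The link gate follows the configured peak velocity: 1.5 times the
#' maximal expected per-frame displacement, plus a jitter allowance of six
#' standard deviations of the apparent frame-to-frame noise displacement
#' (`sqrt(2)` times the detection jitter), with a 2 px floor. Without the
#' jitter allowance the gate would preferentially cut the largest true
#' displacements once noise is added, biasing the mean velocity low.
#'
#' @param scene a [generate_scene()] result.
#' @param ... overrides passed to [linker_config()].
#' @return a [linker_config()].
#' @export
linker_config_for_scene <- function(scene, ...) {
  peak_px <- max(abs(scene$truth$centerline_mms)) /
    scene$config$fps / scene$config$pixel_scale_mm
  args <- list(...)
  if (is.null(args$max_link_distance)) {
    jitter_allow <- 6 * sqrt(2) * scene$config$jitter_sd_px
    args$max_link_distance <- max(1.5 * peak_px + jitter_allow, 2)
  }
  do.call(linker_config, args)
}

#' Globally optimal gated assignment between two point sets
#'
#' The elementary linking step: a one-to-one assignment between the points
#' of two consecutive frames minimizing total Euclidean distance, subject
#' to a hard distance gate. Each point may instead stay unassigned at cost
#' `max_dist`, so the optimum minimizes
#' `sum(link distances) + max_dist * (number of unassigned points)`.
#'
#' @param xy1,xy2 two-column matrices of (x, y) coordinates.
#' @param max_dist the gate distance (and no-link alternative cost).
#' @return integer vector along rows of `xy1`: the matched row of `xy2`,
#'   or `NA` if unmatched.
#' @export
assign_frame_pair <- function(xy1, xy2, max_dist) {
  n1 <- nrow(xy1)
  n2 <- nrow(xy2)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  d <- sqrt(outer(xy1[, 1], xy2[, 1], `-`)^2 +
              outer(xy1[, 2], xy2[, 2], `-`)^2)
  d[d > max_dist] <- Inf
  .lap_link(d, max_dist)
}

# Augmented-matrix LAP: top-left = gated costs, diagonal alternatives at
# cost `alt`, bottom-right zero block for feasibility. Forbidden pairs are
# encoded as a penalty no optimal solution can touch.
.lap_link <- function(cost, alt) {
  n1 <- nrow(cost)
  n2 <- ncol(cost)
  finite <- is.finite(cost)
  big <- alt * (n1 + n2) + sum(cost[finite]) + 1
  n <- n1 + n2
  M <- matrix(big, n, n)
  ul <- cost
  ul[!finite] <- big
  M[seq_len(n1), seq_len(n2)] <- ul
  M[cbind(seq_len(n1), n2 + seq_len(n1))] <- alt
  M[cbind(n1 + seq_len(n2), seq_len(n2))] <- alt
  M[(n1 + 1):n, (n2 + 1):n] <- 0
  sol <- lap_solve(M)
  match <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    j <- sol[i]
    if (j <= n2 && finite[i, j]) match[i] <- j
  }
  match
}

#' Link detections into tracks
#'
#' Two passes. First, frame-to-frame linking: for every consecutive frame
#' pair, a globally optimal one-to-one assignment ([assign_frame_pair()])
#' gated at `max_link_distance`; unassigned detections terminate or start
#' tracks. Second, gap closing: track ends are joined to later track starts
#' within `max_gap_frames` missed frames and `max_gap_distance`, again by a
#' single globally optimal assignment, each end and start used at most
#' once. Tracks shorter than `min_track_length` detections are discarded.
#'
#' Detections within a frame are ordered by (x, y) before linking, so the
#' result is independent of input order.
#'
#' @param detections data.frame with columns `frame`, `x_px`, `y_px` (other
#'   columns are ignored).
#' @param config a [linker_config()].
#' @return an object of class `track_set`: list with `tracks` (data.frame
#'   `track_id`, `frame`, `x_px`, `y_px`, `gap_flag` — `TRUE` on the first
#'   detection after a closed gap), `gaps` (data.frame `track_id`,
#'   `start_frame`, `length`), `n_discarded_short`, and the config.
#' @export
link_tracks <- function(detections, config) {
  stopifnot(inherits(config, "linker_config"))
  empty <- list(
    tracks = data.frame(track_id = integer(0), frame = integer(0),
                        x_px = numeric(0), y_px = numeric(0),
                        gap_flag = logical(0)),
    gaps = data.frame(track_id = integer(0), start_frame = integer(0),
                      length = integer(0)),
    n_discarded_short = 0L, config = config)
  if (is.null(detections) || nrow(detections) == 0) {
    return(structure(empty, class = "track_set"))
  }
  det <- detections[order(detections$frame, detections$x_px,
                          detections$y_px), c("frame", "x_px", "y_px")]
  rownames(det) <- NULL
  n <- nrow(det)
  track_of <- integer(n)
  rows_by_frame <- split(seq_len(n), det$frame)
  frame_vals <- as.integer(names(rows_by_frame))

  n_tracks <- 0L
  tail_row <- integer(0)    # per track: row index of current tail
  tail_frame <- integer(0)

  for (k in seq_along(frame_vals)) {
    f <- frame_vals[k]
    rows <- rows_by_frame[[k]]
    active <- which(tail_frame == f - 1L)
    match <- rep(NA_integer_, length(rows))
    if (length(active) > 0) {
      xy1 <- cbind(det$x_px[tail_row[active]], det$y_px[tail_row[active]])
      xy2 <- cbind(det$x_px[rows], det$y_px[rows])
      m <- assign_frame_pair(xy1, xy2, config$max_link_distance)
      for (i in seq_along(m)) {
        if (!is.na(m[i])) match[m[i]] <- active[i]
      }
    }
    for (j in seq_along(rows)) {
      if (is.na(match[j])) {
        n_tracks <- n_tracks + 1L
        track_of[rows[j]] <- n_tracks
        tail_row[n_tracks] <- rows[j]
        tail_frame[n_tracks] <- f
      } else {
        tr <- match[j]
        track_of[rows[j]] <- tr
        tail_row[tr] <- rows[j]
        tail_frame[tr] <- f
      }
    }
  }

  # track endpoints for gap closing
  first_row <- integer(n_tracks)
  last_row <- integer(n_tracks)
  for (r in seq_len(n)) {
    tr <- track_of[r]
    if (first_row[tr] == 0L) first_row[tr] <- r
    last_row[tr] <- r
  }
  succ <- rep(NA_integer_, n_tracks)
  has_pred <- rep(FALSE, n_tracks)

  if (config$max_gap_frames > 0 && n_tracks > 1) {
    end_f <- det$frame[last_row]
    start_f <- det$frame[first_row]
    dt <- outer(start_f, end_f, `-`)      # [start b, end a]
    dist <- sqrt(outer(det$x_px[first_row], det$x_px[last_row], `-`)^2 +
                   outer(det$y_px[first_row], det$y_px[last_row], `-`)^2)
    ok <- t(dt >= 2 & dt <= config$max_gap_frames + 1L) &
      t(dist) <= config$max_gap_distance   # [end a, start b]
    diag(ok) <- FALSE
    ends <- which(rowSums(ok) > 0)
    starts <- which(colSums(ok) > 0)
    if (length(ends) > 0 && length(starts) > 0) {
      cost <- t(dist)[ends, starts, drop = FALSE]
      cost[!ok[ends, starts, drop = FALSE]] <- Inf
      m <- .lap_link(cost, config$max_gap_distance)
      for (i in seq_along(m)) {
        if (!is.na(m[i])) {
          succ[ends[i]] <- starts[m[i]]
          has_pred[starts[m[i]]] <- TRUE
        }
      }
    }
  }

  # walk merge chains, renumber tracks, record gaps
  out_tracks <- vector("list", n_tracks)
  out_gaps <- vector("list", n_tracks)
  new_id <- 0L
  n_short <- 0L
  heads <- which(!has_pred)
  # deterministic ordering: by first frame, then position
  heads <- heads[order(det$frame[first_row[heads]],
                       det$x_px[first_row[heads]],
                       det$y_px[first_row[heads]])]
  for (hd in heads) {
    chain <- hd
    while (!is.na(succ[chain[length(chain)]])) {
      chain <- c(chain, succ[chain[length(chain)]])
    }
    rows <- unlist(lapply(chain, function(tr) which(track_of == tr)))
    rows <- rows[order(det$frame[rows])]
    if (length(rows) < config$min_track_length) {
      n_short <- n_short + 1L
      next
    }
    new_id <- new_id + 1L
    fr <- det$frame[rows]
    gap_after <- which(diff(fr) > 1L)
    out_tracks[[new_id]] <- data.frame(
      track_id = new_id, frame = fr, x_px = det$x_px[rows],
      y_px = det$y_px[rows],
      gap_flag = seq_along(rows) %in% (gap_after + 1L))
    if (length(gap_after) > 0) {
      out_gaps[[new_id]] <- data.frame(
        track_id = new_id, start_frame = fr[gap_after] + 1L,
        length = as.integer(diff(fr)[gap_after] - 1L))
    }
  }
  tracks <- do.call(rbind, out_tracks[seq_len(new_id)])
  gaps <- do.call(rbind, out_gaps[seq_len(new_id)])
  if (is.null(tracks)) tracks <- empty$tracks
  if (is.null(gaps)) gaps <- empty$gaps
  rownames(tracks) <- NULL
  rownames(gaps) <- NULL
  structure(list(tracks = tracks, gaps = gaps,
                 n_discarded_short = n_short, config = config),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  n_tracks <- length(unique(x$tracks$track_id))
  cat(sprintf(
    "Track set: %d tracks (%d detections), %d closed gaps, %d short tracks discarded\n",
    n_tracks, nrow(x$tracks), nrow(x$gaps), x$n_discarded_short))
  invisible(x)
}

#' Per-step axial velocities of linked tracks
#'
#' Each linked step contributes the axial velocity
#' `dx_px * pixel_scale * fps / dframes`; steps spanning a closed gap of k
#' missed frames divide by k + 1. The sign convention is positive toward
#' the shorter compliant sub-segment (rightward, increasing x).
#'
#' @param tracks a [link_tracks()] result (or its `tracks` data.frame).
#' @param pixel_scale_mm mm per pixel.
#' @param fps frames per second.
#' @return an object of class `track_velocities`: list with `steps`
#'   (data.frame `track_id`, `frame_from`, `frame_to`, `v_mms`, `weight` in
#'   frames), `per_track` (data.frame `track_id`, `mean_v_mms`, `n_steps`),
#'   and `n_excluded_single` (length-1 tracks, excluded).
#' @export
track_velocities <- function(tracks, pixel_scale_mm, fps) {
  .check_positive(pixel_scale_mm, "pixel_scale_mm")
  .check_positive(fps, "fps")
  df <- if (inherits(tracks, "track_set")) tracks$tracks else tracks
  ids <- unique(df$track_id)
  steps <- vector("list", length(ids))
  n_single <- 0L
  for (i in seq_along(ids)) {
    tr <- df[df$track_id == ids[i], ]
    if (nrow(tr) < 2) {
      n_single <- n_single + 1L
      next
    }
    tr <- tr[order(tr$frame), ]
    dfr <- diff(tr$frame)
    steps[[i]] <- data.frame(
      track_id = ids[i],
      frame_from = tr$frame[-nrow(tr)],
      frame_to = tr$frame[-1],
      v_mms = diff(tr$x_px) * pixel_scale_mm * fps / dfr,
      weight = as.numeric(dfr))
  }
  steps <- do.call(rbind, steps)
  if (is.null(steps)) {
    steps <- data.frame(track_id = integer(0), frame_from = integer(0),
                        frame_to = integer(0), v_mms = numeric(0),
                        weight = numeric(0))
  }
  per_track <- if (nrow(steps) > 0) {
    agg <- lapply(split(steps, steps$track_id), function(s) {
      data.frame(track_id = s$track_id[1],
                 mean_v_mms = sum(s$v_mms * s$weight) / sum(s$weight),
                 n_steps = nrow(s))
    })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out[order(out$track_id), ]
  } else {
    data.frame(track_id = integer(0), mean_v_mms = numeric(0),
               n_steps = integer(0))
  }
  structure(list(steps = steps, per_track = per_track,
                 n_excluded_single = n_single,
                 pixel_scale_mm = pixel_scale_mm, fps = fps),
            class = "track_velocities")
}

#' Write a track set to CSV
#'
#' Writes the per-detection track table and, alongside it, a per-track
#' summary (`<path>` and `<path basename>_summary.csv`).
#'
#' @param track_set a [link_tracks()] result.
#' @param path output CSV path for the per-detection table.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(track_set, path) {
  utils::write.csv(track_set$tracks, path, row.names = FALSE)
  counts <- table(track_set$tracks$track_id)
  summary_df <- data.frame(track_id = as.integer(names(counts)),
                           n_detections = as.integer(counts))
  utils::write.csv(summary_df,
                   sub("\\.csv$", "_summary.csv", path), row.names = FALSE)
  invisible(path)
}
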