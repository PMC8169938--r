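# Particle detection on grayscale frame stacks: stack-wide automatic
# threshold (Otsu), connected-component labelling, intensity-weighted
# sub-pixel centroids. Stands on EBImage for thresholding and labelling.

#' Detect dark tracer particles in a frame stack
#'
#' Pixels darker than an automatically chosen intensity threshold are
#' labelled into connected components; each component at least
#' `min_area_fraction` of the expected particle area yields one detection
#' at its darkness-weighted centroid (sub-pixel). The threshold is chosen
#' once per stack (Otsu on the pooled histogram) rather than per frame, to
#' avoid frame-to-frame flicker artifacts.
#'
#' Coordinates are 0-based with pixel centers at integer positions:
#' `x_px` = column, `y_px` = row.
#'
#' @param frames a list of numeric matrices in \[0, 1\] (as from
#'   [render_frames()]), a 3-d array (h x w x frames), or a directory
#'   written by [write_frames()].
#' @param expected_area_px expected particle area in pixels (defaults to a
#'   0.5 mm disc at 0.05 mm/px).
#' @param threshold optional manual intensity threshold; components darker
#'   than this are particles.
#' @param min_area_fraction minimal component area as a fraction of
#'   `expected_area_px` (default 0.25).
#' @return data.frame with columns `frame` (0-based), `x_px`, `y_px`,
#'   `area_px` (component pixel count).
#' @export
detect_particles <- function(frames, expected_area_px = pi * 5^2,
                             threshold = NULL, min_area_fraction = 0.25) {
  if (is.character(frames)) frames <- read_frames(frames)
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  if (!is.list(frames) || length(frames) == 0) {
    stop("invalid input: empty frame stack", call. = FALSE)
  }
  if (is.null(threshold)) {
    # pooled stack histogram; sample frames for long clips
    idx <- if (length(frames) > 50) {
      round(seq(1, length(frames), length.out = 50))
    } else {
      seq_along(frames)
    }
    pooled <- unlist(frames[idx], use.names = FALSE)
    threshold <- EBImage::otsu(EBImage::Image(matrix(pooled, ncol = 1)),
                               range = c(0, 1))
  }
  min_area <- min_area_fraction * expected_area_px
  # background level for darkness weights: bulk of the image is background
  bg <- stats::median(unlist(lapply(
    frames[round(seq(1, length(frames), length.out = min(10, length(frames))))],
    as.vector), use.names = FALSE))
  brush <- EBImage::makeBrush(3, shape = "box")
  out <- lapply(seq_along(frames), function(f) {
    img <- frames[[f]]
    mask <- img < threshold
    if (!any(mask)) return(NULL)
    # dilate by 1 px so the anti-aliased rim contributes to the centroid
    dil <- EBImage::dilate(EBImage::Image(mask), brush)
    lab <- EBImage::bwlabel(dil)
    labv <- as.integer(EBImage::imageData(lab))
    pix <- which(labv > 0)
    if (length(pix) == 0) return(NULL)
    h <- nrow(img)
    row0 <- (pix - 1) %% h        # 0-based row -> y
    col0 <- (pix - 1) %/% h       # 0-based col -> x
    grp <- labv[pix]
    w <- pmax(bg - img[pix], 0)   # darkness-weighted (tracks disc coverage)
    sw <- rowsum(w, grp)
    area <- rowsum(as.numeric(img[pix] < threshold), grp)  # core pixels
    keep <- area[, 1] >= min_area & sw[, 1] > 0
    if (!any(keep)) return(NULL)
    data.frame(frame = f - 1L,
               x_px = (rowsum(w * col0, grp)[keep, 1] / sw[keep, 1]),
               y_px = (rowsum(w * row0, grp)[keep, 1] / sw[keep, 1]),
               area_px = area[keep, 1])
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_px = numeric(0))
  }
  rownames(res) <- NULL
  res
}
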