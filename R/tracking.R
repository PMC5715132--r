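#' Detect bright landmarks in a single frame
#'
#' Thresholds the frame (Otsu's method by default), labels connected
#' foreground components and returns their intensity-weighted centroids,
#' sorted by total mass, largest first. This automates the manual
#' frame-by-frame marking of the eye and proboscis tip.
#'
#' @param frame Numeric matrix (rows = y, columns = x) with intensities in
#'   `[0, 1]`.
#' @param threshold Foreground threshold; `NULL` (default) uses Otsu's
#'   method via \pkg{EBImage}.
#' @param min_mass Components with total intensity below this are ignored
#'   (guards against single hot pixels).
#' @return Data frame with one row per blob: `x`, `y` (0-based fractional
#'   pixel centroid), `mass`, `radius` (equivalent-area radius, px).
#'   Zero rows when nothing is above threshold.
#' @examples
#' fs <- render_frames(simulate_trace(trace_preset("TH/+", seed = 1)))
#' detect_landmarks(fs$pixels[, , 1])
#' @export
detect_landmarks <- function(frame, threshold = NULL, min_mass = 0.5) {
  if (!is.matrix(frame)) stop("'frame' must be a matrix")
  if (min(frame) < 0 || max(frame) > 1)
    stop("frame intensities must lie in [0, 1]")
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      mass = numeric(0), radius = numeric(0))
  rng <- range(frame)
  if (rng[2] - rng[1] < 1e-12) return(empty)
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(t(frame)))
  mask <- frame > threshold
  if (!any(mask)) return(empty)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  nlab <- max(lab)
  X <- matrix(0:(ncol(frame) - 1), nrow(frame), ncol(frame), byrow = TRUE)
  Y <- matrix(0:(nrow(frame) - 1), nrow(frame), ncol(frame))
  out <- lapply(seq_len(nlab), function(l) {
    idx <- lab == l
    w <- frame[idx]
    m <- sum(w)
    data.frame(x = sum(w * X[idx]) / m, y = sum(w * Y[idx]) / m,
               mass = m, radius = sqrt(sum(idx) / pi))
  })
  out <- do.call(rbind, out)
  out <- out[out$mass >= min_mass, , drop = FALSE]
  out <- out[order(-out$mass), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track the eye and proboscis-tip landmarks through a frame stack
#'
#' Detects blobs per frame and assigns eye/tip identities by
#' nearest-neighbor continuity with the previous frame. At the first
#' usable frame the eye is taken to be the leftmost blob (the render
#' convention; override with `eye_leftmost = FALSE` for footage where the
#' tip starts left of the eye). Frames with fewer than two detected blobs
#' are flagged (confidence 0) and filled by linear interpolation from
#' neighboring frames. More than `max_flagged_frac` flagged frames is a
#' hard error.
#'
#' @param stack A `frame_stack` (from [render_frames()] or
#'   [read_tiff_stack()]), or a height x width x n array.
#' @param threshold Per-frame threshold passed to [detect_landmarks()].
#' @param eye_leftmost Identity bootstrap: take the eye as the leftmost
#'   blob of the first usable frame.
#' @param max_flagged_frac Maximum tolerated fraction of flagged frames.
#' @return A data frame of class `landmark_track` with columns `frame`
#'   (0-based), `eye_x`, `eye_y`, `tip_x`, `tip_y`, `confidence`.
#' @examples
#' fs <- render_frames(simulate_trace(trace_preset("TH/+", seed = 1)))
#' trk <- track_stack(fs)
#' head(trk)
#' @export
track_stack <- function(stack, threshold = NULL, eye_leftmost = TRUE,
                        max_flagged_frac = 0.5) {
  pixels <- if (inherits(stack, "frame_stack")) stack$pixels else stack
  if (length(dim(pixels)) != 3L)
    stop("'stack' must contain a height x width x n_frames array")
  n <- dim(pixels)[3]
  if (n < 1) stop("stack must have at least one frame")
  eye <- matrix(NA_real_, n, 2)
  tip <- matrix(NA_real_, n, 2)
  flagged <- logical(n)
  prev_eye <- prev_tip <- NULL
  for (i in seq_len(n)) {
    blobs <- detect_landmarks(pixels[, , i], threshold = threshold)
    if (nrow(blobs) < 2L) {
      flagged[i] <- TRUE
      next
    }
    b <- blobs[1:2, ]                      # two most massive
    if (is.null(prev_eye)) {
      ord <- order(b$x)
      if (!eye_leftmost) ord <- rev(ord)
      e <- unlist(b[ord[1], c("x", "y")])
      p <- unlist(b[ord[2], c("x", "y")])
    } else {
      # assign the pair to minimize total squared displacement
      d11 <- sum((unlist(b[1, c("x", "y")]) - prev_eye)^2) +
             sum((unlist(b[2, c("x", "y")]) - prev_tip)^2)
      d21 <- sum((unlist(b[2, c("x", "y")]) - prev_eye)^2) +
             sum((unlist(b[1, c("x", "y")]) - prev_tip)^2)
      if (d11 <= d21) { e <- unlist(b[1, c("x", "y")]); p <- unlist(b[2, c("x", "y")]) }
      else            { e <- unlist(b[2, c("x", "y")]); p <- unlist(b[1, c("x", "y")]) }
    }
    eye[i, ] <- e; tip[i, ] <- p
    prev_eye <- e; prev_tip <- p
  }
  if (mean(flagged) > max_flagged_frac)
    stop("track unreliable: ", sum(flagged), " of ", n, " frames flagged")
  if (all(flagged)) stop("track unreliable: no frame has two landmarks")
  if (any(flagged)) {
    ok <- which(!flagged)
    fill <- function(v) approx(ok, v[ok], xout = seq_len(n), rule = 2)$y
    if (length(ok) == 1L) {
      eye[flagged, ] <- matrix(eye[ok, ], sum(flagged), 2, byrow = TRUE)
      tip[flagged, ] <- matrix(tip[ok, ], sum(flagged), 2, byrow = TRUE)
    } else {
      eye <- apply(eye, 2, fill)
      tip <- apply(tip, 2, fill)
    }
  }
  structure(data.frame(frame = seq_len(n) - 1L,
                       eye_x = eye[, 1], eye_y = eye[, 2],
                       tip_x = tip[, 1], tip_y = tip[, 2],
                       confidence = as.numeric(!flagged)),
            class = c("landmark_track", "data.frame"))
}

#' Convert a landmark track to a distance trace
#'
#' Computes the per-frame Euclidean eye-tip separation, converts it to
#' trace distance units through `px_scale`, and attaches uniform
#' timestamps `frame / frame_rate_hz`.
#'
#' @param track A `landmark_track` from [track_stack()].
#' @param frame_rate_hz Acquisition frame rate.
#' @param px_scale Pixels per trace distance unit (as used when rendering
#'   or calibrating the footage); the separation in pixels is divided by
#'   this factor.
#' @return A [distance_trace()].
#' @examples
#' fs <- render_frames(simulate_trace(trace_preset("TH/+", seed = 1)))
#' tr <- to_distance_trace(track_stack(fs), frame_rate_hz = 200)
#' @export
to_distance_trace <- function(track, frame_rate_hz, px_scale = 1) {
  stopifnot(inherits(track, "landmark_track") || is.data.frame(track))
  need <- c("eye_x", "eye_y", "tip_x", "tip_y")
  if (!all(need %in% names(track))) stop("track is missing landmark columns")
  if (anyNA(track[need])) stop("track is incomplete (NA coordinates)")
  sep <- sqrt((track$tip_x - track$eye_x)^2 + (track$tip_y - track$eye_y)^2)
  distance_trace(sep / px_scale, frame_rate_hz)
}
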