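#' Render a distance trace as a synthetic two-landmark frame stack
#'
#' Draws, for every sample of the trace, a dark frame with two bright
#' Gaussian-profile landmarks: the eye at a fixed position and the
#' proboscis tip displaced from the eye along +x by
#' `rest_offset_px + trace value * px_scale`. The rest offset models the
#' anatomical eye-tip separation of an unextended proboscis; it keeps the
#' two landmarks resolvable at rest (with offset 0 they coincide and
#' merge into a single blob). The exact landmark centers used for
#' rasterization are recorded as per-frame ground truth, so the implied
#' separation equals the input trace times `px_scale` plus the rest
#' offset, exactly.
#'
#' Coordinates are 0-based with origin at the top-left pixel center,
#' x rightward (columns) and y downward (rows).
#'
#' @param trace A [distance_trace()].
#' @param landmark_radius_px Nominal landmark radius; the Gaussian profile
#'   has `sigma = landmark_radius_px / 2`.
#' @param intensity Peak landmark intensity in `(0, 1]`.
#' @param width_px,height_px Frame size. Defaults leave a
#'   `2 * landmark_radius_px` margin around both landmarks at maximal
#'   extension.
#' @param eye_xy Eye center `c(x, y)`; default places it at the left
#'   margin, vertically centered.
#' @param px_scale Pixels per trace distance unit.
#' @param rest_offset_px Eye-tip separation (pixels) at zero extension.
#' @param noise_sd Optional additive pixel noise SD (clipped to `[0, 1]`).
#' @param seed Seed for the pixel noise.
#' @return A `frame_stack`: list with `pixels` (array height x width x
#'   n_frames, values in `[0, 1]`), `truth` (data frame `frame, eye_x,
#'   eye_y, tip_x, tip_y`), and `px_scale`.
#' @examples
#' tr <- simulate_trace(trace_preset("TH/+", seed = 1))
#' fs <- render_frames(tr)
#' dim(fs$pixels)
#' @export
render_frames <- function(trace, landmark_radius_px = 3, intensity = 1,
                          width_px = NULL, height_px = NULL, eye_xy = NULL,
                          px_scale = 1, rest_offset_px = 12,
                          noise_sd = 0, seed = NULL) {
  stopifnot(inherits(trace, "distance_trace"))
  if (px_scale <= 0) stop("'px_scale' must be > 0")
  if (rest_offset_px < 0) stop("'rest_offset_px' must be >= 0")
  if (intensity <= 0 || intensity > 1) stop("'intensity' must be in (0, 1]")
  r <- landmark_radius_px
  if (r <= 0) stop("'landmark_radius_px' must be > 0")
  margin <- 2 * r
  sep <- rest_offset_px + trace$d_px * px_scale
  if (is.null(height_px)) height_px <- ceiling(2 * margin + 1)
  if (is.null(eye_xy)) eye_xy <- c(margin, (height_px - 1) / 2)
  if (is.null(width_px))
    width_px <- ceiling(eye_xy[1] + max(sep) + margin + 1)
  n <- nrow(trace)
  tip_x <- eye_xy[1] + sep
  tip_y <- rep(eye_xy[2], n)
  bad <- which(tip_x + r > width_px - 1 | tip_x - r < 0 |
               tip_y + r > height_px - 1 | tip_y - r < 0 |
               eye_xy[1] - r < 0 | eye_xy[2] - r < 0 |
               eye_xy[1] + r > width_px - 1 | eye_xy[2] + r > height_px - 1)
  if (length(bad))
    stop("landmark would leave the frame at frame index ", bad[1],
         " (0-based ", bad[1] - 1, ")")
  X <- matrix(0:(width_px - 1), height_px, width_px, byrow = TRUE)
  Y <- matrix(0:(height_px - 1), height_px, width_px)
  s2 <- 2 * (r / 2)^2
  eye_img <- intensity * exp(-((X - eye_xy[1])^2 + (Y - eye_xy[2])^2) / s2)
  pixels <- array(0, dim = c(height_px, width_px, n))
  with_seed(seed, {
    for (i in seq_len(n)) {
      fr <- eye_img +
        intensity * exp(-((X - tip_x[i])^2 + (Y - tip_y[i])^2) / s2)
      if (noise_sd > 0) fr <- fr + rnorm(length(fr), 0, noise_sd)
      pixels[, , i] <- pmin(pmax(fr, 0), 1)
    }
  })
  structure(list(pixels = pixels,
                 truth = data.frame(frame = seq_len(n) - 1L,
                                    eye_x = eye_xy[1], eye_y = eye_xy[2],
                                    tip_x = tip_x, tip_y = tip_y),
                 px_scale = px_scale, rest_offset_px = rest_offset_px,
                 frame_rate_hz = attr(trace, "frame_rate_hz")),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Frame stack: %d frames of %d x %d px (px_scale %g)%s\n",
              d[3], d[1], d[2], x$px_scale,
              if (is.null(x$truth)) "" else ", with ground truth"))
  invisible(x)
}
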