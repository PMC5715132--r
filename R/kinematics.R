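#' Spline smoothing configuration
#'
#' Configuration of the least-squares piecewise-cubic smoothing used by
#' the tremor metric. Interior knots are placed uniformly every
#' `knot_spacing_s` seconds; the degree is fixed cubic. The default of
#' 0.05 s (one knot per 10 frames at 200 frames/s) follows the extension
#' kinematics (hundreds of milliseconds) while leaving fast tremor
#' oscillation in the residual.
#'
#' @param knot_spacing_s Interior-knot interval in seconds.
#' @return A list of class `spline_config`.
#' @export
spline_config <- function(knot_spacing_s = 0.05) {
  if (!is.numeric(knot_spacing_s) || length(knot_spacing_s) != 1L ||
      !is.finite(knot_spacing_s) || knot_spacing_s <= 0)
    stop("'knot_spacing_s' must be a positive scalar")
  structure(list(knot_spacing_s = knot_spacing_s, degree = 3L),
            class = "spline_config")
}

#' Detect the extension episode of a trace
#'
#' Estimates when the PER starts and ends. The baseline is the median of
#' the first `baseline_window_s` seconds; the episode is where the trace
#' exceeds `baseline + threshold_frac * (peak - baseline)`. A peak that
#' does not clear the baseline by at least three times the baseline noise
#' SD yields a distinguished "no episode" result (a non-responding fly),
#' never an error.
#'
#' By default only the first contiguous supra-threshold run is returned
#' (only the first PER of each fly is analyzed); with
#' `first_only = FALSE` the offset is the last sample above the level
#' anywhere in the trace.
#'
#' Crossing times are refined by linear interpolation between the frames
#' bracketing the level (sub-frame resolution). With
#' `edge_extrapolation = TRUE` (default) each endpoint is additionally
#' extrapolated from the level down to the baseline using the measured
#' time from the threshold level to 90% of the excursion on that edge,
#' with the extrapolation factor calibrated for a raised-cosine edge (the
#' canonical episode template). For near-instantaneous edges the measured
#' rise time is a fraction of a frame, so the correction vanishes and
#' step-like pulses are measured threshold-to-threshold.
#'
#' @param trace A [distance_trace()].
#' @param threshold_frac Fraction of the baseline-to-peak excursion used
#'   as the crossing level.
#' @param baseline_window_s Length of the initial baseline window.
#' @param first_only Restrict to the first contiguous episode.
#' @param edge_extrapolation Extrapolate endpoints to the episode base
#'   using the measured edge rise/fall time.
#' @return A list of class `per_episode`: `episode` (logical), `onset_s`,
#'   `offset_s`, `duration_s`, `baseline_px`, `level_px`, `peak_px` (all
#'   `NA` when no episode is found).
#' @examples
#' tr <- simulate_trace(trace_preset("TH/+", seed = 1))
#' detect_episode(tr)
#' @export
detect_episode <- function(trace, threshold_frac = 0.10,
                           baseline_window_s = 0.1, first_only = TRUE,
                           edge_extrapolation = TRUE) {
  stopifnot(inherits(trace, "distance_trace"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("'threshold_frac' must be in (0, 1)")
  t <- trace$t_s; d <- trace$d_px
  bidx <- which(t < t[1] + baseline_window_s)
  if (length(bidx) < 1L) bidx <- 1L
  baseline <- median(d[bidx])
  noise <- if (length(bidx) > 2L) sd(d[bidx]) else 0
  if (is.na(noise)) noise <- 0
  peak <- max(d)
  none <- structure(list(episode = FALSE, onset_s = NA_real_,
                         offset_s = NA_real_, duration_s = NA_real_,
                         baseline_px = baseline, level_px = NA_real_,
                         peak_px = peak, threshold_frac = threshold_frac),
                    class = "per_episode")
  if (peak - baseline <= max(3 * noise, 1e-9)) return(none)
  level <- baseline + threshold_frac * (peak - baseline)
  above <- d > level
  if (!any(above)) return(none)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values)
  if (first_only) {
    i1 <- starts[hit[1]]; i2 <- ends[hit[1]]
  } else {
    i1 <- starts[hit[1]]; i2 <- ends[hit[length(hit)]]
  }
  # sub-frame crossing times by linear interpolation at the level
  cross_up <- function(i) {
    if (i == 1L || d[i - 1L] >= level) return(t[i])
    t[i - 1L] + (level - d[i - 1L]) / (d[i] - d[i - 1L]) * (t[i] - t[i - 1L])
  }
  cross_dn <- function(i) {
    nn <- length(t)
    if (i == nn || d[i + 1L] >= level) return(t[i])
    t[i] + (d[i] - level) / (d[i] - d[i + 1L]) * (t[i + 1L] - t[i])
  }
  onset <- cross_up(i1)
  offset <- cross_dn(i2)
  ep_peak <- max(d[i1:i2])
  if (edge_extrapolation) {
    # extrapolation factor for a raised-cosine edge: time below the
    # threshold level, per unit of threshold-to-90% rise time
    u <- function(q) acos(1 - 2 * q)
    kappa <- u(threshold_frac) / (u(0.9) - u(threshold_frac))
    hi <- baseline + 0.9 * (ep_peak - baseline)
    seg <- i1:i2
    j_up <- seg[which(d[seg] >= hi)[1]]
    j_dn <- seg[max(which(d[seg] >= hi))]
    if (!is.na(j_up) && j_up > i1) {
      t90 <- t[j_up - 1L] +
        (hi - d[j_up - 1L]) / (d[j_up] - d[j_up - 1L]) * (t[j_up] - t[j_up - 1L])
      onset <- max(t[1], onset - kappa * (t90 - onset))
    }
    if (!is.na(j_dn) && j_dn < i2) {
      t90f <- t[j_dn] +
        (d[j_dn] - hi) / (d[j_dn] - d[j_dn + 1L]) * (t[j_dn + 1L] - t[j_dn])
      offset <- min(t[length(t)], offset + kappa * (offset - t90f))
    }
  }
  structure(list(episode = TRUE, onset_s = onset, offset_s = offset,
                 duration_s = offset - onset, baseline_px = baseline,
                 level_px = level, peak_px = ep_peak,
                 threshold_frac = threshold_frac),
            class = "per_episode")
}

#' @export
print.per_episode <- function(x, ...) {
  if (!x$episode) cat("No extension episode detected\n")
  else cat(sprintf(
    "Episode: onset %.4g s, offset %.4g s, duration %.4g s (peak %.4g px)\n",
    x$onset_s, x$offset_s, x$duration_s, x$peak_px))
  invisible(x)
}

#' Fit a least-squares piecewise-cubic smoothing spline
#'
#' Fits a cubic B-spline regression with uniformly spaced interior knots
#' (every `cfg$knot_spacing_s` seconds) to the trace by least squares and
#' evaluates it on the trace's own time grid. Deterministic.
#'
#' @param trace A [distance_trace()].
#' @param cfg A [spline_config()].
#' @return A [distance_trace()] holding the smoothed values.
#' @examples
#' tr <- simulate_trace(trace_preset("TH>G2019S", seed = 2))
#' sm <- fit_smoothing_spline(tr)
#' @export
fit_smoothing_spline <- function(trace, cfg = spline_config()) {
  stopifnot(inherits(trace, "distance_trace"),
            inherits(cfg, "spline_config"))
  fr <- attr(trace, "frame_rate_hz")
  if (cfg$knot_spacing_s < 2 / fr)
    stop("'knot_spacing_s' must be >= 2 frame intervals (",
         signif(2 / fr, 4), " s)")
  t <- trace$t_s; d <- trace$d_px
  n <- length(t)
  # interior knots spaced knot_spacing_s, centered in the record so the
  # knot grid (and hence the fit) is symmetric under time reversal
  span <- t[n] - t[1]
  m <- floor(span / cfg$knot_spacing_s - 1e-9)
  kn <- if (m >= 1L)
    t[1] + (span - (m - 1) * cfg$knot_spacing_s) / 2 +
      (seq_len(m) - 1) * cfg$knot_spacing_s
  else numeric(0)
  ncoef <- length(kn) + 4L
  if (n < ncoef)
    stop("trace too short for this knot spacing: need at least ", ncoef,
         " samples, got ", n)
  basis <- splines::bs(t, knots = kn, degree = 3L, intercept = TRUE,
                       Boundary.knots = c(t[1], t[n]))
  fit <- lm.fit(basis, d)
  out <- distance_trace(as.numeric(fit$fitted.values), fr, t_s = t)
  attr(out, "knots_s") <- kn
  out
}

#' Path length (total variation) of a sampled signal
#'
#' The path traced by a scalar signal is the sum of absolute successive
#' differences. This is the "path" of the tremor index: the proboscis
#' observable here is the scalar eye-tip separation per frame, so path is
#' one-dimensional total variation.
#'
#' @param values Numeric vector of at least 2 samples.
#' @return Total variation, in the input's units.
#' @examples
#' path_length(c(0, 1, 0))  # 2
#' @export
path_length <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("'values' must contain at least 2 numbers")
  sum(abs(diff(values)))
}

#' Extra-path tremor index of a trace
#'
#' Fits the smoothing spline to the whole trace and, over the detected
#' episode only, compares the path length (total variation) of the raw
#' trace with that of the smooth curve. A smooth extension contributes
#' equally to both, so the difference — the *extra path* — captures the
#' oscillatory tremor component. The RMS of the raw-minus-smoothed
#' residual over the episode is reported as a companion deviation metric.
#'
#' @param trace A [distance_trace()].
#' @param cfg A [spline_config()].
#' @param episode Optional precomputed [detect_episode()] result.
#' @param over_episode Compute the path statistics over the episode only
#'   (default) or over the whole recording.
#' @param ... Passed to [detect_episode()] when `episode` is NULL.
#' @return A list: `extra_path_px` (raw difference, may be marginally
#'   negative from numerics), `raw_path_px`, `smooth_path_px`,
#'   `rms_residual_px`, `episode`. When no episode is found all metrics
#'   are `NA` and `episode$episode` is `FALSE`.
#' @examples
#' tr <- simulate_trace(trace_preset("TH>G2019S", seed = 3))
#' tremor_extra_path(tr)$extra_path_px
#' @export
tremor_extra_path <- function(trace, cfg = spline_config(), episode = NULL,
                              over_episode = TRUE, ...) {
  stopifnot(inherits(trace, "distance_trace"))
  if (is.null(episode)) episode <- detect_episode(trace, ...)
  if (!episode$episode)
    return(list(extra_path_px = NA_real_, raw_path_px = NA_real_,
                smooth_path_px = NA_real_, rms_residual_px = NA_real_,
                episode = episode))
  sm <- fit_smoothing_spline(trace, cfg)
  idx <- if (over_episode)
    which(trace$t_s >= episode$onset_s & trace$t_s <= episode$offset_s)
  else seq_len(nrow(trace))
  if (length(idx) < 2L)       # degenerate one-frame episode: no path
    return(list(extra_path_px = 0, raw_path_px = 0, smooth_path_px = 0,
                rms_residual_px = sqrt(mean((trace$d_px[idx] - sm$d_px[idx])^2)),
                episode = episode))
  raw_p <- path_length(trace$d_px[idx])
  smo_p <- path_length(sm$d_px[idx])
  list(extra_path_px = raw_p - smo_p, raw_path_px = raw_p,
       smooth_path_px = smo_p,
       rms_residual_px = sqrt(mean((trace$d_px[idx] - sm$d_px[idx])^2)),
       episode = episode)
}

#' Summarize a trace into its kinematic features
#'
#' Composes episode detection, spline smoothing and the path metrics into
#' one record per trace: onset, offset, duration (the bradykinesia
#' readout), peak extension, raw/smoothed path length, extra path (the
#' tremor readout; clipped at zero in `extra_path_px`, with the unclipped
#' value kept in `extra_path_raw_px`), and RMS residual. Only the first
#' episode of a trace is analyzed. A trace with no detectable episode
#' yields a non-responder row with all kinematic fields `NA`.
#'
#' @param trace A [distance_trace()].
#' @param cfg A [spline_config()].
#' @param threshold_frac,baseline_window_s Passed to [detect_episode()].
#' @param trace_id Optional identifier stamped into the row.
#' @return One-row data frame with columns `trace_id`, `responded`,
#'   `onset_s`, `offset_s`, `duration_s`, `peak_px`, `raw_path_px`,
#'   `smooth_path_px`, `extra_path_px`, `extra_path_raw_px`,
#'   `rms_residual_px`.
#' @examples
#' summarize_trace(simulate_trace(trace_preset("TH/+", seed = 1)))
#' @export
summarize_trace <- function(trace, cfg = spline_config(),
                            threshold_frac = 0.10, baseline_window_s = 0.1,
                            trace_id = NA_character_) {
  ep <- detect_episode(trace, threshold_frac = threshold_frac,
                       baseline_window_s = baseline_window_s)
  if (!ep$episode) {
    return(data.frame(trace_id = trace_id, responded = FALSE,
                      onset_s = NA_real_, offset_s = NA_real_,
                      duration_s = NA_real_, peak_px = NA_real_,
                      raw_path_px = NA_real_, smooth_path_px = NA_real_,
                      extra_path_px = NA_real_, extra_path_raw_px = NA_real_,
                      rms_residual_px = NA_real_))
  }
  tp <- tremor_extra_path(trace, cfg, episode = ep)
  data.frame(trace_id = trace_id, responded = TRUE,
             onset_s = ep$onset_s, offset_s = ep$offset_s,
             duration_s = ep$duration_s, peak_px = ep$peak_px,
             raw_path_px = tp$raw_path_px, smooth_path_px = tp$smooth_path_px,
             extra_path_px = max(tp$extra_path_px, 0),
             extra_path_raw_px = tp$extra_path_px,
             rms_residual_px = tp$rms_residual_px)
}

#' Summarize a cohort of traces
#'
#' @param traces List of [distance_trace()] objects (e.g. from
#'   [simulate_cohort()]), optionally named.
#' @inheritParams summarize_trace
#' @return Data frame with one [summarize_trace()] row per trace.
#' @export
summarize_cohort <- function(traces, cfg = spline_config(),
                             threshold_frac = 0.10,
                             baseline_window_s = 0.1) {
  ids <- names(traces)
  if (is.null(ids)) ids <- sprintf("trace%03d", seq_along(traces))
  rows <- Map(function(tr, id)
    summarize_trace(tr, cfg, threshold_frac, baseline_window_s,
                    trace_id = id),
    traces, ids)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
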