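#' Construct a distance trace
#'
#' A distance trace is the uniformly sampled eye-to-proboscis-tip
#' separation over time — the primitive observable of a filmed PER.
#'
#' @param d_px Numeric vector of separations (pixels).
#' @param frame_rate_hz Sampling rate (frames per second).
#' @param t_s Optional timestamps; defaults to `(0:(n-1))/frame_rate_hz`.
#'   Must be uniform at the stated frame rate.
#' @return A data frame of class `distance_trace` with columns `t_s` and
#'   `d_px` and a `frame_rate_hz` attribute.
#' @export
distance_trace <- function(d_px, frame_rate_hz, t_s = NULL) {
  if (!is.numeric(d_px) || length(d_px) < 1L)
    stop("'d_px' must be a non-empty numeric vector")
  if (!all(is.finite(d_px))) stop("'d_px' must be finite")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0)
    stop("'frame_rate_hz' must be a positive scalar")
  n <- length(d_px)
  if (is.null(t_s)) t_s <- (seq_len(n) - 1) / frame_rate_hz
  if (length(t_s) != n) stop("'t_s' and 'd_px' lengths differ")
  if (n > 1L) {
    dt <- diff(t_s)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(dt - 1 / frame_rate_hz)) >= 1e-9)
      stop("timestamps are not uniform at 1/frame_rate_hz")
  }
  structure(data.frame(t_s = t_s, d_px = d_px),
            frame_rate_hz = frame_rate_hz,
            class = c("distance_trace", "data.frame"))
}

#' @export
print.distance_trace <- function(x, ...) {
  fr <- attr(x, "frame_rate_hz")
  cat(sprintf("Distance trace: %d frames at %g frames/s (%.3g s)\n",
              nrow(x), fr, nrow(x) / fr))
  tr <- attr(x, "truth")
  if (!is.null(tr))
    cat(sprintf("  ground truth: onset %.4g s, offset %.4g s, duration %.4g s\n",
                tr$onset_s, tr$offset_s, tr$duration_s))
  invisible(x)
}

#' @export
plot.distance_trace <- function(x, ...) {
  graphics::plot(x$t_s, x$d_px, type = "l", xlab = "time (s)",
                 ylab = "eye-tip separation (px)", ...)
  invisible(x)
}

# Raised-cosine rise-plateau-fall envelope in [0, 1] on phase u in [0, 1];
# each ramp occupies ramp_frac of the episode.
episode_envelope <- function(u, ramp_frac) {
  e <- numeric(length(u))
  inside <- u >= 0 & u <= 1
  ui <- u[inside]
  ei <- rep(1, length(ui))
  lo <- ui < ramp_frac
  hi <- ui > 1 - ramp_frac
  ei[lo] <- 0.5 * (1 - cos(pi * ui[lo] / ramp_frac))
  ei[hi] <- 0.5 * (1 - cos(pi * (1 - ui[hi]) / ramp_frac))
  e[inside] <- ei
  e
}

#' Simulate a PER distance trace
#'
#' Generates one eye-to-proboscis-tip distance trace: zero baseline until
#' `latency_s`, a raised-cosine rise-plateau-fall extension episode whose
#' duration is drawn from the truncated normal in `params`, a sinusoidal
#' tremor component with uniformly drawn phase gated to the episode by the
#' same envelope, and additive Gaussian sensor noise. The drawn (ground
#' truth) onset, offset and duration are attached as the `truth` attribute.
#'
#' RNG draws occur in a fixed order (duration, tremor phase, noise), so a
#' given `params$seed` yields a bit-identical trace.
#'
#' @param params A [trace_gen_params()] object.
#' @return A [distance_trace()] with attribute `truth`, a list with
#'   `onset_s`, `offset_s` and `duration_s`.
#' @examples
#' tr <- simulate_trace(trace_preset("TH/+", seed = 1))
#' attr(tr, "truth")$duration_s
#' @export
simulate_trace <- function(params) {
  stopifnot(inherits(params, "trace_gen_params"))
  validate_trace_gen_params(params)
  p <- params
  n <- round(p$total_duration_s * p$frame_rate_hz)
  if (n < 2) stop("recording too short: fewer than 2 frames")
  t <- (seq_len(n) - 1) / p$frame_rate_hz
  dt <- 1 / p$frame_rate_hz
  max_dur <- p$total_duration_s - p$latency_s
  with_seed(p$seed, {
    duration <- rtruncnorm(1, p$duration_mean_s, p$duration_sd_s,
                           lower = 2 * dt, upper = max_dur)
    if (duration > max_dur + 1e-12)
      stop("episode of ", signif(duration, 4),
           " s does not fit in the recording")
    phase <- runif(1, 0, 2 * pi)
    u <- (t - p$latency_s) / duration
    env <- episode_envelope(u, p$ramp_frac)
    d <- p$amplitude_px * env
    if (p$tremor_amplitude_px > 0)
      d <- d + p$tremor_amplitude_px *
        sin(2 * pi * p$tremor_freq_hz * t + phase) * env
    if (p$noise_sd_px > 0)
      d <- d + rnorm(n, 0, p$noise_sd_px)
    out <- distance_trace(d, p$frame_rate_hz, t_s = t)
    attr(out, "truth") <- list(onset_s = p$latency_s,
                               offset_s = p$latency_s + duration,
                               duration_s = duration)
    out
  })
}

#' Simulate a population PER assay
#'
#' Draws `n_flies` independent Bernoulli responses with the preset's
#' response probability. Responders additionally receive a response
#' latency drawn uniformly on `[0, 2)` s (the scoring window);
#' non-responders have latency `NA`.
#'
#' @param preset A [generator_preset()], or anything with elements `name`
#'   and `response_prob`.
#' @param n_flies Number of flies tested (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `assay_row` (one-row data frame: `group`,
#'   `n_tested`, `n_responded`) and `flies` (per-fly data frame: `fly`,
#'   `responded`, `latency_s`).
#' @examples
#' pop <- simulate_population(generator_preset("TH/+"), 100, seed = 1)
#' pop$assay_row
#' @export
simulate_population <- function(preset, n_flies, seed = NULL) {
  if (is.null(preset$response_prob) ||
      preset$response_prob < 0 || preset$response_prob > 1)
    stop("preset must carry a response probability in [0, 1]")
  if (!is.numeric(n_flies) || length(n_flies) != 1L || n_flies < 1)
    stop("'n_flies' must be >= 1")
  n_flies <- as.integer(n_flies)
  name <- if (is.null(preset$name)) NA_character_ else preset$name
  with_seed(seed, {
    responded <- runif(n_flies) < preset$response_prob
    latency <- rep(NA_real_, n_flies)
    if (any(responded)) latency[responded] <- runif(sum(responded), 0, 2)
    list(assay_row = data.frame(group = name, n_tested = n_flies,
                                n_responded = sum(responded)),
         flies = data.frame(fly = seq_len(n_flies), responded = responded,
                            latency_s = latency))
  })
}

#' Simulate a cohort of traces from one preset
#'
#' Convenience wrapper drawing `n` independent traces with per-trace seeds
#' derived deterministically from `seed`.
#'
#' @param params A [trace_gen_params()] object (its own `seed` is ignored).
#' @param n Number of traces.
#' @param seed Base seed; trace `i` uses `seed + i - 1`.
#' @return List of [distance_trace()] objects.
#' @export
simulate_cohort <- function(params, n, seed = 1) {
  stopifnot(inherits(params, "trace_gen_params"), n >= 1)
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- seed + i - 1
    simulate_trace(p)
  })
}
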