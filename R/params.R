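#' Trace generator parameters
#'
#' Bundles and validates the parameters of the distance-trace generator.
#' A trace is a uniformly sampled time series of the eye-to-proboscis-tip
#' separation: flat baseline at zero, one smooth rise-plateau-fall extension
#' episode whose duration is drawn from a truncated normal distribution,
#' an optional sinusoidal tremor component gated to the episode, and i.i.d.
#' additive Gaussian sensor noise.
#'
#' @param latency_s Seconds of baseline before extension onset.
#' @param duration_mean_s,duration_sd_s Mean and SD (seconds) of the
#'   extension-episode duration. Draws come from a normal truncated below
#'   at two frame intervals and above at `total_duration_s - latency_s`.
#' @param amplitude_px Full extension distance in pixels (plateau height).
#' @param tremor_amplitude_px Peak amplitude (pixels) of the sinusoidal
#'   tremor component. Zero disables tremor.
#' @param tremor_freq_hz Tremor oscillation frequency in Hz.
#' @param noise_sd_px SD of the additive Gaussian sensor noise in pixels.
#' @param frame_rate_hz Sampling rate in frames per second.
#' @param total_duration_s Total recording length in seconds.
#' @param ramp_frac Fraction of the episode occupied by each raised-cosine
#'   ramp (onset and offset); the remainder is plateau.
#' @param seed Optional integer RNG seed; when given, generation is fully
#'   reproducible and the caller's RNG state is left untouched.
#'
#' @return An object of class `trace_gen_params` (a validated list).
#' @seealso [simulate_trace()], [trace_preset()]
#' @examples
#' p <- trace_gen_params(duration_mean_s = 0.3, duration_sd_s = 0, seed = 1)
#' tr <- simulate_trace(p)
#' @export
trace_gen_params <- function(latency_s = 0.25,
                             duration_mean_s = 0.30,
                             duration_sd_s = 0.09,
                             amplitude_px = 30,
                             tremor_amplitude_px = 2,
                             tremor_freq_hz = 12,
                             noise_sd_px = 0.3,
                             frame_rate_hz = 200,
                             total_duration_s = 2,
                             ramp_frac = 0.25,
                             seed = NULL) {
  p <- list(latency_s = latency_s, duration_mean_s = duration_mean_s,
            duration_sd_s = duration_sd_s, amplitude_px = amplitude_px,
            tremor_amplitude_px = tremor_amplitude_px,
            tremor_freq_hz = tremor_freq_hz, noise_sd_px = noise_sd_px,
            frame_rate_hz = frame_rate_hz,
            total_duration_s = total_duration_s, ramp_frac = ramp_frac,
            seed = seed)
  validate_trace_gen_params(p)
  class(p) <- "trace_gen_params"
  p
}

validate_trace_gen_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("latency_s", "duration_mean_s", "duration_sd_s",
              "amplitude_px", "tremor_amplitude_px", "tremor_freq_hz",
              "noise_sd_px", "frame_rate_hz", "total_duration_s",
              "ramp_frac")) {
    if (!num1(p[[f]])) stop("'", f, "' must be a finite numeric scalar")
  }
  if (p$duration_sd_s < 0) stop("'duration_sd_s' must be >= 0")
  if (p$noise_sd_px < 0) stop("'noise_sd_px' must be >= 0")
  if (p$tremor_amplitude_px < 0) stop("'tremor_amplitude_px' must be >= 0")
  if (p$frame_rate_hz <= 0) stop("'frame_rate_hz' must be > 0")
  if (p$duration_mean_s <= 0) stop("'duration_mean_s' must be > 0")
  if (p$amplitude_px <= 0) stop("'amplitude_px' must be > 0")
  if (p$latency_s < 0) stop("'latency_s' must be >= 0")
  if (p$ramp_frac <= 0 || p$ramp_frac > 0.5)
    stop("'ramp_frac' must be in (0, 0.5]")
  if (p$total_duration_s <= p$latency_s)
    stop("'total_duration_s' must exceed 'latency_s'")
  if (!is.null(p$seed) &&
      !(is.numeric(p$seed) && length(p$seed) == 1L && is.finite(p$seed)))
    stop("'seed' must be NULL or a single integer")
  invisible(p)
}

#' @export
print.trace_gen_params <- function(x, ...) {
  cat("Trace generator parameters\n")
  cat(sprintf("  episode duration: %.3g +/- %.3g s (latency %.3g s)\n",
              x$duration_mean_s, x$duration_sd_s, x$latency_s))
  cat(sprintf("  amplitude %.3g px, tremor %.3g px @ %.3g Hz, noise %.3g px\n",
              x$amplitude_px, x$tremor_amplitude_px, x$tremor_freq_hz,
              x$noise_sd_px))
  cat(sprintf("  %.4g s at %.4g frames/s\n",
              x$total_duration_s, x$frame_rate_hz))
  invisible(x)
}

# Evaluate `code` under a deterministic seed without disturbing the
# caller's RNG stream. seed = NULL leaves the global stream in place.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = genv)
      else if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Inverse-CDF sampler for a normal truncated to [lower, upper].
# Exact for sd = 0 (degenerate at the clamped mean).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate duration ", signif(mean, 6),
           " lies outside the feasible interval [",
           signif(lower, 6), ", ", signif(upper, 6), "]")
    return(rep(mean, n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi - plo < 1e-12)
    stop("truncation interval [", signif(lower, 6), ", ",
         signif(upper, 6), "] carries no probability mass")
  qnorm(runif(n, plo, phi), mean, sd)
}
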