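test_that("trace generator parameters are validated", {
  expect_s3_class(trace_gen_params(), "trace_gen_params")
  expect_error(trace_gen_params(duration_sd_s = -1), "duration_sd_s")
  expect_error(trace_gen_params(frame_rate_hz = 0), "frame_rate_hz")
  expect_error(trace_gen_params(amplitude_px = 0), "amplitude_px")
  expect_error(trace_gen_params(total_duration_s = 0.1, latency_s = 0.2),
               "total_duration_s")
})

test_that("a noiseless degenerate draw has exact duration and amplitude", {
  p <- trace_gen_params(noise_sd_px = 0, tremor_amplitude_px = 0,
                        duration_mean_s = 0.3, duration_sd_s = 0, seed = 1)
  tr <- simulate_trace(p)
  truth <- attr(tr, "truth")
  expect_identical(truth$duration_s, 0.3)
  expect_equal(max(tr$d_px), p$amplitude_px, tolerance = 1e-12)
  expect_equal(nrow(tr), round(p$total_duration_s * p$frame_rate_hz))
  # baseline exactly zero outside the episode
  expect_true(all(tr$d_px[tr$t_s < truth$onset_s] == 0))
  expect_true(all(tr$d_px[tr$t_s > truth$offset_s] == 0))
})

test_that("the same seed gives bit-identical generator output", {
  p <- trace_preset("TH>G2019S", seed = 42)
  expect_identical(simulate_trace(p), simulate_trace(p))
  pop <- generator_preset("TH/+")
  expect_identical(simulate_population(pop, 500, seed = 9),
                   simulate_population(pop, 500, seed = 9))
  tr <- simulate_trace(trace_preset("TH/+", seed = 3))
  expect_identical(render_frames(tr, seed = 5), render_frames(tr, seed = 5))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(77)
  ref <- runif(3)
  set.seed(77)
  invisible(simulate_trace(trace_preset("TH/+", seed = 1)))
  invisible(simulate_population(generator_preset("TH/+"), 10, seed = 2))
  expect_identical(runif(3), ref)
})

test_that("drawn durations follow the truncated normal of the preset", {
  # Monte-Carlo mean of ground-truth durations vs the preset mean
  p <- trace_preset("TH/+")
  durs <- vapply(1:1000, function(i) {
    p$seed <- i
    attr(simulate_trace(p), "truth")$duration_s
  }, numeric(1))
  se <- sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - p$duration_mean_s), 3 * se)
  # lower truncation respected
  expect_true(all(durs >= 2 / p$frame_rate_hz))
})

test_that("slowed-preset durations exceed control durations", {
  draw <- function(preset) vapply(1:1000, function(i)
    attr(simulate_trace(trace_preset(preset, seed = i)), "truth")$duration_s,
    numeric(1))
  expect_gt(mean(draw("TH>G2019S")), mean(draw("TH/+")))
})

test_that("an episode that cannot fit the recording is an error", {
  expect_error(
    simulate_trace(trace_gen_params(duration_mean_s = 3, duration_sd_s = 0,
                                    total_duration_s = 2, seed = 1)),
    "outside the feasible interval")
})

test_that("population simulation matches its Bernoulli parameter", {
  pop <- simulate_population(list(name = "x", response_prob = 1), 50,
                             seed = 1)
  expect_identical(pop$assay_row$n_responded, 50L)
  expect_true(all(pop$flies$latency_s[pop$flies$responded] >= 0 &
                  pop$flies$latency_s[pop$flies$responded] < 2))
  pop0 <- simulate_population(list(name = "x", response_prob = 0), 50,
                              seed = 1)
  expect_identical(pop0$assay_row$n_responded, 0L)
  expect_true(all(is.na(pop0$flies$latency_s)))
  # binomial concentration at n = 10,000
  p <- 0.76
  big <- simulate_population(list(name = "x", response_prob = p), 10000,
                             seed = 3)
  phat <- big$assay_row$n_responded / 10000
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("the preset registry carries the published panels", {
  reg <- preset_registry()
  kp <- assay_panel("kinase_panel", reg)
  expect_equal(unname(kp[["TH/+"]]), 0.76)
  expect_equal(unname(kp[["TH>G2019S"]]), 0.35)
  g <- trace_preset("TH>G2019S", registry = reg)
  ctrl <- trace_preset("TH/+", registry = reg)
  expect_equal(g$duration_mean_s, 0.57)
  expect_equal(g$tremor_amplitude_px, 2 * ctrl$tremor_amplitude_px)
  expect_error(trace_preset("nonexistent"), "unknown trace preset")
  expect_error(assay_panel("nonexistent"), "unknown assay panel")
  gp <- generator_preset("TH>G2019S", panel = "kinase_panel")
  expect_equal(gp$response_prob, 0.35)
  expect_s3_class(gp$trace_params, "trace_gen_params")
})

test_that("rendered ground truth reproduces the input trace exactly", {
  tr <- simulate_trace(trace_preset("TH/+", seed = 8))
  fs <- render_frames(tr, px_scale = 1.5)
  implied <- sqrt((fs$truth$tip_x - fs$truth$eye_x)^2 +
                  (fs$truth$tip_y - fs$truth$eye_y)^2)
  expect_equal(implied - fs$rest_offset_px, tr$d_px * 1.5,
               tolerance = 1e-12)
  expect_identical(dim(fs$pixels)[3], nrow(tr))
  expect_true(all(fs$pixels >= 0 & fs$pixels <= 1))
})

test_that("render geometry behaves for degenerate traces", {
  z <- distance_trace(rep(0, 20), 200)
  fs0 <- render_frames(z, rest_offset_px = 0)
  expect_true(all(fs0$truth$tip_x == fs0$truth$eye_x))
  expect_true(all(fs0$truth$tip_y == fs0$truth$eye_y))
  ramp <- distance_trace(seq(0, 20, length.out = 50), 200)
  fsr <- render_frames(ramp)
  expect_true(all(diff(fsr$truth$tip_x) > 0))
})

test_that("a landmark leaving the frame is an error naming the frame", {
  ramp <- distance_trace(seq(0, 50, length.out = 10), 200)
  expect_error(render_frames(ramp, width_px = 40),
               "frame index")
})
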