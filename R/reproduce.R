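# Stable hash of a configuration: canonical JSON -> md5.
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Configuration of a full reproduction run
#'
#' @param seed Master integer seed; all stage seeds are derived from it.
#' @param assay_panel Name of the assay panel simulated (see
#'   [assay_panel()]).
#' @param n_flies_per_group Flies simulated per assay group.
#' @param trace_presets Names of the trace presets simulated as kinematic
#'   cohorts.
#' @param traces_per_group Traces per kinematic cohort.
#' @param n_rendered Traces per cohort additionally pushed through the
#'   render-track round trip as a self-check.
#' @param knot_spacing_s,threshold_frac Kinematics configuration.
#' @param adjust,alpha Statistics configuration.
#' @param reference Reference group for the assay report; defaults to the
#'   panel's first group.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       assay_panel = "kinase_panel",
                       n_flies_per_group = 60,
                       trace_presets = c("TH/+", "TH>hLRRK2", "TH>G2019S"),
                       traces_per_group = 26,
                       n_rendered = 2,
                       knot_spacing_s = 0.05,
                       threshold_frac = 0.10,
                       adjust = "fdr",
                       alpha = 0.05,
                       reference = NULL) {
  cfg <- list(seed = as.integer(seed), assay_panel = assay_panel,
              n_flies_per_group = as.integer(n_flies_per_group),
              trace_presets = trace_presets,
              traces_per_group = as.integer(traces_per_group),
              n_rendered = as.integer(n_rendered),
              knot_spacing_s = knot_spacing_s,
              threshold_frac = threshold_frac,
              adjust = adjust, alpha = alpha, reference = reference)
  class(cfg) <- "run_config"
  cfg
}

#' Reproduce the full analysis chain on packaged presets
#'
#' Deterministically chains the pipeline: simulate responder populations
#' for each group of the configured assay panel and analyze the resulting
#' assay table; simulate kinematic trace cohorts for the configured
#' presets, summarize every trace, and compare durations by ANOVA + Tukey
#' HSD; push a small subset of traces through the render-track round trip
#' and report the recovery error; and compute the two design power
#' numbers for the configured alpha. Two runs with the same configuration
#' produce byte-identical reports.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the bundle is written
#'   there (`report.json`, `assay.tsv`, `flies.tsv`, `kinematics.tsv`).
#' @return List of class `per_report_bundle` with elements `assay_table`,
#'   `flies`, `assay_report`, `kinematics`, `duration_anova`,
#'   `extra_path_means`, `roundtrip`, `power`, `config`, `config_hash`.
#' @examples
#' \donttest{
#' bundle <- reproduce(run_config(seed = 1, n_flies_per_group = 30,
#'                                traces_per_group = 6, n_rendered = 1))
#' bundle$assay_report
#' }
#' @export
reproduce <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  reg <- preset_registry()
  probs <- assay_panel(config$assay_panel, reg)
  reference <- if (is.null(config$reference)) names(probs)[1]
               else config$reference
  scfg <- spline_config(config$knot_spacing_s)

  # stage seeds derived from the master seed; kept below 2^31
  sd_pop <- (config$seed * 1000L) %% .Machine$integer.max
  sd_trc <- (config$seed * 1000L + 101L) %% .Machine$integer.max
  sd_rnd <- (config$seed * 1000L + 907L) %% .Machine$integer.max

  # --- population assay ---------------------------------------------------
  pops <- lapply(seq_along(probs), function(i) {
    simulate_population(list(name = names(probs)[i],
                             response_prob = probs[[i]]),
                        config$n_flies_per_group, seed = sd_pop + i)
  })
  assay_table <- do.call(rbind, lapply(pops, `[[`, "assay_row"))
  flies <- do.call(rbind, lapply(seq_along(pops), function(i)
    cbind(group = names(probs)[i], pops[[i]]$flies)))
  assay_report <- analyze_assay(assay_table, reference = reference,
                                adjust = config$adjust)

  # --- kinematic cohorts --------------------------------------------------
  kin <- NULL
  for (j in seq_along(config$trace_presets)) {
    pname <- config$trace_presets[j]
    traces <- simulate_cohort(trace_preset(pname, registry = reg),
                              config$traces_per_group,
                              seed = sd_trc + 1000L * j)
    rows <- summarize_cohort(traces, scfg,
                             threshold_frac = config$threshold_frac)
    rows <- cbind(group = pname, rows)
    rows$truth_duration_s <- vapply(traces, function(tr)
      attr(tr, "truth")$duration_s, numeric(1))
    kin <- rbind(kin, rows)
  }
  responded <- kin[kin$responded, ]
  duration_anova <- anova_tukey(data.frame(group = responded$group,
                                           value = responded$duration_s))
  extra_path_means <- tapply(responded$extra_path_px, responded$group, mean)
  extra_path_means <- extra_path_means[config$trace_presets]

  # --- render-track round trip self-check ---------------------------------
  roundtrip <- NULL
  if (config$n_rendered > 0) {
    for (j in seq_along(config$trace_presets)) {
      pname <- config$trace_presets[j]
      for (i in seq_len(config$n_rendered)) {
        p <- trace_preset(pname, registry = reg)
        p$seed <- sd_rnd + 1000L * j + i
        tr <- simulate_trace(p)
        fs <- render_frames(tr)
        rec <- to_distance_trace(track_stack(fs),
                                 attr(tr, "frame_rate_hz"),
                                 px_scale = fs$px_scale)
        s_in <- summarize_trace(tr, scfg,
                                threshold_frac = config$threshold_frac)
        s_out <- summarize_trace(rec, scfg,
                                 threshold_frac = config$threshold_frac)
        base_px <- fs$rest_offset_px / fs$px_scale
        roundtrip <- rbind(roundtrip, data.frame(
          group = pname, seed = p$seed,
          rms_sep_err_px = sqrt(mean((rec$d_px - base_px - tr$d_px)^2)),
          duration_err_s = s_out$duration_s - s_in$duration_s))
      }
    }
  }

  # --- design power numbers -----------------------------------------------
  power <- list(
    anova_medium_f = power_anova(0.25, k = 3, n_per_group = 26,
                                 alpha = config$alpha),
    anova_effect_0.3 = power_anova(0.3, k = 3, n_per_group = 26,
                                   alpha = config$alpha),
    chisq_medium_w = power_chisq(0.3, N = 500, df = 16, alpha = 0.01))

  hash <- config_hash(unclass(config))
  bundle <- structure(list(assay_table = assay_table, flies = flies,
                           assay_report = assay_report, kinematics = kin,
                           duration_anova = duration_anova,
                           extra_path_means = extra_path_means,
                           roundtrip = roundtrip, power = power,
                           config = config, config_hash = hash,
                           package_version =
                             as.character(packageVersion("perkin"))),
                      class = "per_report_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_assay_tsv(bundle$assay_table, file.path(out_dir, "assay.tsv"))
  write.table(bundle$flies, file.path(out_dir, "flies.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(bundle$kinematics, file.path(out_dir, "kinematics.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  report <- list(
    config = unclass(bundle$config),
    config_hash = bundle$config_hash,
    package_version = bundle$package_version,
    proportions = bundle$assay_report$proportions,
    omnibus = unclass(bundle$assay_report$omnibus),
    vs_reference = bundle$assay_report$vs_reference,
    duration_anova = list(F = bundle$duration_anova$statistic,
                          df = bundle$duration_anova$df,
                          p = bundle$duration_anova$p_raw,
                          tukey = bundle$duration_anova$tukey),
    extra_path_means_px = as.list(bundle$extra_path_means),
    roundtrip = bundle$roundtrip,
    power = bundle$power)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' @export
print.per_report_bundle <- function(x, ...) {
  cat("PER reproduction bundle (perkin ", x$package_version, ", hash ",
      x$config_hash, ")\n\n", sep = "")
  print(x$assay_report)
  cat("\nDuration ANOVA: ")
  print(x$duration_anova)
  cat("\nMean extra path (px):\n")
  print(round(x$extra_path_means, 2))
  cat(sprintf("\nDesign power: ANOVA (f=0.25, k=3, n=26) %.3f; chi-square (w=0.3, N=500, df=16, alpha=0.01) %.3f\n",
              x$power$anova_medium_f, x$power$chisq_medium_w))
  invisible(x)
}
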