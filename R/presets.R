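#' Generator preset registry
#'
#' perkin ships a registry of named generator presets keyed to published
#' PER assay groups: per-group response probabilities (the probability
#' that a fly responds to sucrose within the 2 s scoring window) and
#' per-genotype distance-trace parameters (episode duration distribution,
#' tremor amplitude). The registry lives in a plain-text YAML file under
#' `inst/extdata/presets.yaml` and can be replaced by the `path` argument.
#'
#' @param path Optional path to an alternative YAML registry.
#' @return A list with components `traces` (named list of
#'   [trace_gen_params()] field overrides), `assays` (named list of assay
#'   panels, each a named vector of response probabilities) and `defaults`.
#' @examples
#' reg <- preset_registry()
#' names(reg$assays)
#' @export
preset_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "presets.yaml", package = "perkin",
                        mustWork = TRUE)
  reg <- yaml::read_yaml(path)
  for (comp in c("defaults", "traces", "assays"))
    if (is.null(reg[[comp]])) stop("registry is missing '", comp, "'")
  for (panel in names(reg$assays)) {
    pr <- unlist(reg$assays[[panel]])
    if (any(pr < 0 | pr > 1))
      stop("panel '", panel, "' has a response probability outside [0, 1]")
    if (anyDuplicated(names(pr)))
      stop("panel '", panel, "' has duplicate preset names")
    reg$assays[[panel]] <- pr
  }
  if (anyDuplicated(names(reg$traces)))
    stop("duplicate trace preset names in registry")
  reg
}

#' Look up a trace preset
#'
#' @param name Preset name, e.g. `"TH/+"` or `"TH>G2019S"`.
#' @param seed Optional seed stored into the returned parameter set.
#' @param registry Registry list from [preset_registry()].
#' @param ... Field overrides passed to [trace_gen_params()], e.g.
#'   `tremor_amplitude_px = 4`.
#' @return A [trace_gen_params()] object.
#' @examples
#' trace_preset("TH>G2019S")
#' @export
trace_preset <- function(name, seed = NULL, registry = preset_registry(),
                         ...) {
  if (!name %in% names(registry$traces))
    stop("unknown trace preset '", name, "'; registry has: ",
         paste(names(registry$traces), collapse = ", "))
  fields <- modifyList(registry$defaults, as.list(registry$traces[[name]]))
  fields <- modifyList(fields, list(...))
  fields$seed <- seed
  do.call(trace_gen_params, fields)
}

#' Look up an assay panel's response probabilities
#'
#' @param panel Panel name, e.g. `"kinase_panel"`.
#' @inheritParams trace_preset
#' @return Named numeric vector of response probabilities in `[0, 1]`.
#' @examples
#' assay_panel("kinase_panel")
#' @export
assay_panel <- function(panel, registry = preset_registry()) {
  if (!panel %in% names(registry$assays))
    stop("unknown assay panel '", panel, "'; registry has: ",
         paste(names(registry$assays), collapse = ", "))
  registry$assays[[panel]]
}

#' Assemble a full generator preset
#'
#' Combines a response probability (from an assay panel) with trace
#' parameters (from the trace section, when the genotype has one) into a
#' single named preset suitable for population and trace simulation.
#'
#' @param name Group label, present in `panel`.
#' @param panel Assay panel name the response probability is read from.
#' @inheritParams trace_preset
#' @return A list of class `generator_preset` with elements `name`,
#'   `response_prob` and `trace_params` (NULL when the group has no trace
#'   parameterization).
#' @examples
#' generator_preset("TH>G2019S", panel = "kinase_panel")
#' @export
generator_preset <- function(name, panel = "kinase_panel", seed = NULL,
                             registry = preset_registry()) {
  probs <- assay_panel(panel, registry)
  if (!name %in% names(probs))
    stop("'", name, "' is not in panel '", panel, "'")
  tp <- if (name %in% names(registry$traces))
    trace_preset(name, seed = seed, registry = registry) else NULL
  structure(list(name = name, response_prob = unname(probs[[name]]),
                 trace_params = tp),
            class = "generator_preset")
}

#' @export
print.generator_preset <- function(x, ...) {
  cat("Generator preset '", x$name, "': response probability ",
      x$response_prob, "\n", sep = "")
  if (!is.null(x$trace_params)) print(x$trace_params)
  invisible(x)
}
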