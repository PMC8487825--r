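# Declarative run configuration: one YAML document holds the phantom
# geometry, noise model, denoiser and texture parameters, and cohort preset
# overrides; a master seed derives per-stage seeds so stages can be re-run
# independently yet reproducibly.

#' Path of the shipped default configuration
#'
#' @return Path to the package's `default-config.yaml`.
#' @export
default_config_path <- function() {
  system.file("extdata", "default-config.yaml", package = "sonovas",
              mustWork = TRUE)
}

#' Load a run configuration
#'
#' Reads a YAML configuration, fills unset keys from the shipped defaults,
#' and validates the basic parameter blocks. The resolved configuration is
#' fully explicit: every tunable has a value after loading.
#'
#' @param path YAML file, or `NULL` for the shipped defaults.
#' @param overrides Named list merged over the file (nested lists merge by
#'   key).
#' @return Named list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  base <- yaml::read_yaml(default_config_path())
  cfg <- if (is.null(path)) base else {
    if (!file.exists(path)) stop("load_run_config(): no such file: ", path)
    merge_config(base, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  if (cfg$texture$ng < 2) stop("load_run_config(): texture ng must be >= 2")
  if (cfg$nlmeans$h <= 0) stop("load_run_config(): nlmeans h must be > 0")
  structure(cfg, class = c("run_config", "list"))
}

merge_config <- function(base, over) {
  for (k in names(over)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
      merge_config(base[[k]], over[[k]])
    } else over[[k]]
  }
  base
}

#' Derive a per-stage seed from a master seed
#'
#' Splitting rule: `stage_seed = (master * 7919 + index(stage)) mod
#' (2^31 - 1)`, with stages indexed in the fixed order phantom, noise,
#' cohort, analysis. Keeps every derived seed a valid 32-bit integer and
#' decorrelates stages under small master seeds.
#'
#' @param master Integer master seed.
#' @param stage One of `"phantom"`, `"noise"`, `"cohort"`, `"analysis"`.
#' @return Integer seed.
#' @export
derive_stage_seed <- function(master, stage = c("phantom", "noise", "cohort",
                                                "analysis")) {
  stage <- match.arg(stage)
  idx <- match(stage, c("phantom", "noise", "cohort", "analysis"))
  m <- ((as.double(master) %% 2147483647) * 7919) %% 2147483647
  as.integer((m + idx) %% 2147483647)
}

config_to_params <- function(cfg) {
  list(
    phantom = do.call(phantom_spec, cfg$phantom),
    nlmeans = do.call(nlm_params, cfg$nlmeans),
    texture = cfg$texture,
    noise = cfg$noise,
    cohort = cfg$cohort)
}
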