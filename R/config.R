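#' Default simulation configuration
#'
#' A complete configuration list for the replicate engine and the
#' experiment driver, with every knob overridable. The exposure-law
#' defaults (`p_regular = 0.6`, `mu_x = 0.7`, `sigma_x = 1.5` on the log
#' scale) are documented placeholders for population parameters that are
#' study-specific; nominal-level properties (coverage, type-1 error of the
#' error-free estimator) are insensitive to them.
#'
#' @param ... Named overrides for any top-level field: `n_cases`,
#'   `n_controls`, `p_regular`, `metric_label`, `mu_x`, `sigma_x`,
#'   `hypothesis` (`"h0"`/`"h1"`), `or_star` (overrides `hypothesis` if
#'   given), `scenario_id`, `scenario_overrides` (named list passed to
#'   [scenario_preset()]), `mode`, `cutpoint_source`, `n_replicates`,
#'   `master_seed`.
#' @return A named list of class `sim_config`.
#' @examples
#' default_config(scenario_id = 1, n_replicates = 100)
#' @export
default_config <- function(...) {
  cfg <- list(
    n_cases = 1000L,
    n_controls = 2000L,
    p_regular = 0.6,
    metric_label = "duration",
    mu_x = 0.7,
    sigma_x = 1.5,
    hypothesis = "h0",
    or_star = NULL, # derived from hypothesis unless set
    scenario_id = 4L,
    scenario_overrides = list(),
    mode = "exact-count",
    cutpoint_source = "controls-only",
    n_replicates = 5000L,
    master_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_invalid("invalid_config", paste("unknown config fields:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = c("sim_config", "list")))
}

#' Validate a simulation configuration
#'
#' Checks every field against the documented schema; errors name the
#' offending field.
#'
#' @param cfg A config list.
#' @return The validated config (invisibly usable in pipelines).
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg)
    stop_invalid("invalid_config", sprintf("config$%s: %s", field, msg))
  if (!is_count(cfg$n_cases) || cfg$n_cases <= 0) fail("n_cases", "must be a positive integer")
  if (!is_count(cfg$n_controls) || cfg$n_controls <= 0) fail("n_controls", "must be a positive integer")
  if (!is_prob(cfg$p_regular)) fail("p_regular", "must be a probability in [0, 1]")
  if (!is_scalar_num(cfg$mu_x)) fail("mu_x", "must be a finite number")
  if (!is_scalar_num(cfg$sigma_x) || cfg$sigma_x < 0) fail("sigma_x", "must be >= 0")
  if (!cfg$hypothesis %in% c("h0", "h1")) fail("hypothesis", "must be 'h0' or 'h1'")
  if (!is.null(cfg$or_star) && (!is_scalar_num(cfg$or_star) || cfg$or_star <= 0))
    fail("or_star", "must be a positive number or NULL")
  if (!is_count(cfg$scenario_id) || !(cfg$scenario_id %in% 1:4))
    fail("scenario_id", "must be 1, 2, 3 or 4")
  if (!cfg$mode %in% c("exact-count", "expected-count")) fail("mode", "must be 'exact-count' or 'expected-count'")
  if (!cfg$cutpoint_source %in% c("controls-only", "all-regular"))
    fail("cutpoint_source", "must be 'controls-only' or 'all-regular'")
  if (!is_count(cfg$n_replicates) || cfg$n_replicates <= 0)
    fail("n_replicates", "must be a positive integer")
  if (!is_count(abs(cfg$master_seed))) fail("master_seed", "must be an integer")
  if (!is.list(cfg$scenario_overrides)) fail("scenario_overrides", "must be a named list")
  structure(cfg, class = unique(c("sim_config", class(cfg))))
}

#' Effective true odds ratio of a configuration
#'
#' `or_star` if set, else 1.0 under `"h0"` and 1.3 under `"h1"`.
#'
#' @param cfg A validated config.
#' @return Positive scalar.
#' @export
config_or_star <- function(cfg) {
  cfg$or_star %||% if (cfg$hypothesis == "h0") 1.0 else 1.3
}

#' Materialize config components
#'
#' Builds the design, exposure law, true effect and error scenario encoded
#' by a configuration.
#'
#' @param cfg A config list (validated on entry).
#' @return List with elements `design`, `dist`, `effect`, `scenario`.
#' @export
build_components <- function(cfg) {
  cfg <- validate_config(cfg)
  design <- study_design(cfg$n_cases, cfg$n_controls, cfg$p_regular, cfg$metric_label)
  dist <- exposure_distribution(cfg$mu_x, cfg$sigma_x)
  effect <- true_effect(config_or_star(cfg), dist)
  scenario <- do.call(scenario_preset,
                      c(list(scenario_id = cfg$scenario_id), cfg$scenario_overrides))
  list(design = design, dist = dist, effect = effect, scenario = scenario)
}

#' Read / write a configuration file
#'
#' Configs are stored as a single JSON object using the field names of
#' [default_config()]; unknown fields are rejected with their paths named.
#'
#' @param path JSON file path.
#' @param cfg A config list (for `write_config`).
#' @return `read_config` returns a validated `sim_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_invalid("invalid_config", paste("config file not found:", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(raw$scenario_overrides))
    raw$scenario_overrides <- raw$scenario_overrides
  else raw$scenario_overrides <- list()
  do.call(default_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}
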