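# Scenario configuration: strict structured-text (YAML) parsing. Unknown
# keys are errors, not warnings — configs are part of the scientific record.

.known_keys <- list(
  top = c("sites", "n_days", "n_replicates", "seed", "engine",
          "true_field", "error_params", "outcomes", "output"),
  sites = c("n", "width", "height", "file"),
  engine = c("integration", "q", "truncate_at_zero", "short_term_raw", "fit_truth"),
  true_field = c("pollutant", "site_type", "mu", "seas_amp", "seas_phase",
                 "rho_t", "sigma_t", "sigma_s", "range_m", "nugget", "sigma_r",
                 "sigma_inst", "cov_model"),
  error_params = c("pollutant", "site_type", "method", "alpha_s", "alpha_t",
                   "gamma_s", "gamma_t"),
  outcomes = c("outcome", "beta0", "sigma_b", "rr_short_per10", "rr_long_per10"),
  output = c("dir", "write_replicates")
)

.check_keys <- function(x, section) {
  unknown <- setdiff(names(x), .known_keys[[section]])
  if (length(unknown) > 0) {
    stop_airmes("unknown key(s) in '%s' section: %s", section,
                paste(unknown, collapse = ", "))
  }
  invisible(x)
}

#' Build a scenario configuration in R
#'
#' Assembles and validates the full description of a simulation scenario
#' batch: the site source, the true-field parameters per pollutant x site
#' type, the exposure-method error parameters, the outcome models, replicate
#' count and master seed. See [read_scenario_config()] for the equivalent
#' YAML interface.
#'
#' @param sites list: either `list(n=, width=, height=)` for synthetic
#'   sampling or `list(file=)` for a coordinates CSV.
#' @param n_days days per replicate (default 365).
#' @param n_replicates replicates per scenario cell (>= 1).
#' @param seed non-negative integer master seed.
#' @param true_field list of entries, each a list with `pollutant`,
#'   `site_type` and [true_field_params()] fields.
#' @param error_params list of [error_params()] objects or lists of their
#'   fields.
#' @param outcomes list of [outcome_params()] objects or lists of fields.
#' @param engine engine options: `integration` ("laplace"/"aghq"), `q`,
#'   `truncate_at_zero`, `short_term_raw`, `fit_truth`.
#' @param output list: `dir` (output directory or NULL), `write_replicates`.
#' @return a validated `scenario_config`.
#' @export
scenario_config <- function(sites, n_days = 365L, n_replicates = 1L, seed = 1L,
                            true_field = list(), error_params = list(),
                            outcomes = list(), engine = list(),
                            output = list()) {
  cfg <- list(sites = sites, n_days = n_days, n_replicates = n_replicates,
              seed = seed, engine = engine, true_field = true_field,
              error_params = error_params, outcomes = outcomes, output = output)
  validate_scenario_config(cfg)
}

#' Validate a scenario configuration
#'
#' Strict validation of structure, types and cross-references (every error
#' parameter set must reference a defined pollutant x site-type true field).
#' Returns the normalized `scenario_config`; errors on any problem.
#'
#' @param cfg a list as produced by [scenario_config()] or parsed from YAML.
#' @return validated `scenario_config`.
#' @export
validate_scenario_config <- function(cfg) {
  if (inherits(cfg, "scenario_config")) return(cfg)
  .check_keys(cfg, "top")
  if (is.null(cfg$sites)) stop_airmes("config needs a 'sites' section")
  .check_keys(cfg$sites, "sites")
  if (is.null(cfg$sites$file)) {
    if (is.null(cfg$sites$n)) stop_airmes("sites needs 'n' (or 'file')")
    cfg$sites$width <- cfg$sites$width %||% 50000
    cfg$sites$height <- cfg$sites$height %||% 50000
    if (cfg$sites$n < 2) stop_airmes("sites$n must be >= 2")
  }
  cfg$n_days <- as.integer(cfg$n_days %||% 365L)
  if (cfg$n_days < 2) stop_airmes("n_days must be >= 2")
  cfg$n_replicates <- as.integer(cfg$n_replicates %||% 1L)
  if (cfg$n_replicates < 1) stop_airmes("n_replicates must be >= 1")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.na(cfg$seed) || cfg$seed < 0) stop_airmes("seed must be a non-negative integer")

  eng <- cfg$engine %||% list()
  .check_keys(eng, "engine")
  eng <- modifyList(list(integration = "laplace", q = 9L,
                         truncate_at_zero = FALSE, short_term_raw = FALSE,
                         fit_truth = FALSE), eng)
  if (!eng$integration %in% c("laplace", "aghq")) {
    stop_airmes("engine$integration must be 'laplace' or 'aghq'")
  }
  cfg$engine <- eng

  if (length(cfg$true_field) == 0) stop_airmes("config needs >= 1 true_field entry")
  cfg$true_field <- lapply(cfg$true_field, function(e) {
    if (is.null(e$pollutant) || is.null(e$site_type)) {
      stop_airmes("each true_field entry needs 'pollutant' and 'site_type'")
    }
    if (inherits(e$params, "true_field_params")) return(e) # already normalized
    .check_keys(e, "true_field")
    pf <- e[setdiff(names(e), c("pollutant", "site_type"))]
    pf$truncate_at_zero <- eng$truncate_at_zero
    list(pollutant = as.character(e$pollutant),
         site_type = as.character(e$site_type),
         params = do.call(true_field_params, pf))
  })
  keys <- vapply(cfg$true_field, function(e) paste(e$pollutant, e$site_type, sep = "|"),
                 character(1))
  if (anyDuplicated(keys)) stop_airmes("duplicate pollutant x site_type true_field entries")

  if (length(cfg$error_params) == 0) stop_airmes("config needs >= 1 error_params entry")
  cfg$error_params <- lapply(cfg$error_params, function(e) {
    if (inherits(e, "error_params")) return(e)
    .check_keys(e, "error_params")
    do.call(error_params, e)
  })
  for (ep in cfg$error_params) {
    k <- paste(ep$pollutant, ep$site_type, sep = "|")
    if (!k %in% keys) {
      stop_airmes("error_params entry '%s' references undefined pollutant/site_type %s/%s",
                  ep$method, ep$pollutant, ep$site_type)
    }
  }

  if (length(cfg$outcomes) == 0) stop_airmes("config needs >= 1 outcomes entry")
  cfg$outcomes <- lapply(cfg$outcomes, function(e) {
    if (inherits(e, "outcome_params")) return(e)
    .check_keys(e, "outcomes")
    do.call(outcome_params, e)
  })

  out <- cfg$output %||% list()
  .check_keys(out, "output")
  cfg$output <- modifyList(list(dir = NULL, write_replicates = FALSE), out)

  structure(cfg, class = "scenario_config")
}

#' Read a scenario configuration from a YAML file
#'
#' @param path path to a YAML scenario configuration (see the example in
#'   `system.file("extdata", "scenario_example.yaml", package = "airmes")`).
#' @return validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop_airmes("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_scenario_config(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %d true-field cell(s), %d method(s), %d outcome(s); %d reps x %d days, seed %d\n",
              length(x$true_field), length(x$error_params), length(x$outcomes),
              x$n_replicates, x$n_days, x$seed))
  invisible(x)
}
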