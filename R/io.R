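# Configuration, result serialization and the fixture registry.

config_defaults <- function() {
  list(
    n_values = 10, m_values = 1:10,
    sigma_values = 0.3, A_values = seq(0.1, 1, by = 0.1),
    replicates = 2000, root_seed = 0,
    t_end = 1000, rel_tol = 1e-8, abs_tol = 1e-8, max_steps = 500000,
    convergence_tol = 1e-6, readout_floor = 1e-12, x0 = 0.1,
    kendall_variant = "standard_tau_a", pairing_mode = "paired",
    output_path = "tiles.csv", log_level = "info")
}

#' Default run configuration
#'
#' The defaults describe the headline heat-map slice (n = 10, sigma = 0.3)
#' at the 2,000-replicate desk profile.
#'
#' @return an object of class `run_config`.
#' @export
default_config <- function() {
  validate_config(config_defaults(), defaulted = character(0))
}

validate_config <- function(cfg, defaulted) {
  num_keys <- c("replicates", "root_seed", "t_end", "rel_tol", "abs_tol",
                "max_steps", "convergence_tol", "readout_floor", "x0")
  for (k in c("n_values", "m_values", "sigma_values", "A_values", num_keys))
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) == 0)
      antago_error(sprintf("config key '%s' must be numeric and nonempty", k),
                   "configuration_error")
  for (k in num_keys)
    if (length(cfg[[k]]) != 1)
      antago_error(sprintf("config key '%s' must be a single number", k),
                   "configuration_error")
  if (any(cfg$sigma_values <= 0))
    antago_error("config key 'sigma_values' must be > 0",
                 "configuration_error")
  if (any(cfg$A_values <= 0))
    antago_error("config key 'A_values' must be > 0", "configuration_error")
  if (!cfg$kendall_variant %in% c("standard_tau_a", "paper_literal"))
    antago_error("config key 'kendall_variant' must be 'standard_tau_a' or 'paper_literal'",
                 "configuration_error")
  if (!cfg$pairing_mode %in% c("paired", "independent"))
    antago_error("config key 'pairing_mode' must be 'paired' or 'independent'",
                 "configuration_error")
  if (!cfg$log_level %in% c("quiet", "info"))
    antago_error("config key 'log_level' must be 'quiet' or 'info'",
                 "configuration_error")
  settings <- integration_settings(
    t_end = cfg$t_end, rel_tol = cfg$rel_tol, abs_tol = cfg$abs_tol,
    max_steps = cfg$max_steps, convergence_tol = cfg$convergence_tol,
    readout_floor = cfg$readout_floor, x0 = cfg$x0)
  grid <- sweep_grid(cfg$n_values, cfg$m_values, cfg$sigma_values,
                     cfg$A_values, cfg$replicates, cfg$root_seed, settings)
  structure(c(cfg, list(grid = grid, settings = settings,
                        defaulted = defaulted)),
            class = "run_config")
}

#' Load a run configuration from a flat JSON file
#'
#' Reads a flat key-value JSON document, fills unspecified keys from the
#' defaults (recording which were defaulted), validates every value and
#' rejects unknown keys by name. Errors carry class `configuration_error`
#' and name the offending key.
#'
#' @param path path to a JSON config file.
#' @return an object of class `run_config`; `$grid` and `$settings` hold
#'   the ready-to-use [sweep_grid()] and [integration_settings()], and
#'   `$defaulted` lists the keys that were filled from defaults.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    antago_error(sprintf("config file not found: %s", path),
                 "configuration_error")
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    antago_error(sprintf("config parse failure: %s",
                                         conditionMessage(e)),
                                 "configuration_error"))
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    antago_error(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")),
                 "configuration_error")
  defaulted <- setdiff(names(defaults), names(cfg))
  full <- modifyList(defaults, cfg)
  out <- validate_config(full, defaulted)
  if (out$log_level == "info" && length(defaulted) > 0)
    message("defaulted config keys: ", paste(defaulted, collapse = ", "))
  out
}

#' Write a run configuration to a flat JSON file
#' @param config a `run_config` (or the output of [default_config()]).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  keys <- names(config_defaults())
  jsonlite::write_json(config[keys], path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write tile summaries to CSV
#'
#' One row per tile, header
#' `n,m,sigma,A,mean_bray_curtis,mean_kendall,replicates_used,degenerate_count`,
#' floats at full (round-trip) precision, rows sorted lexicographically by
#' (n, m, sigma, A).
#'
#' @param summaries a `tile_summary` data frame from [run_sweep()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_tile_table <- function(summaries, path) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0)
    antago_error("'summaries' must be a nonempty data frame",
                 "invalid_input_error")
  cols <- c("n", "m", "sigma", "A", "mean_bray_curtis", "mean_kendall",
            "replicates_used", "degenerate_count")
  if (!all(cols %in% names(summaries)))
    antago_error("'summaries' is missing tile-summary columns",
                 "invalid_input_error")
  df <- summaries[order(summaries$n, summaries$m, summaries$sigma,
                        summaries$A), cols]
  fmt <- df
  for (k in c("sigma", "A", "mean_bray_curtis", "mean_kendall"))
    fmt[[k]] <- sprintf("%.17g", df[[k]])
  con <- tryCatch(file(path, "w"), error = function(e)
    antago_error(sprintf("cannot open '%s' for writing", path), "io_error"))
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  writeLines(do.call(paste, c(unname(fmt), sep = ",")), con)
  invisible(path)
}

#' Read a tile-summary CSV back
#' @param path a file written by [write_tile_table()].
#' @return a `tile_summary` data frame.
#' @export
read_tile_table <- function(path) {
  df <- read.csv(path)
  class(df) <- c("tile_summary", "data.frame")
  df
}

#' Canned small scenarios with known expectations
#'
#' A registry of seeded fixture systems used in tests and documentation:
#' \describe{
#'   \item{single-logistic}{one species, r = 1, self-limitation 1; expected
#'     equilibrium density 1.}
#'   \item{symmetric-pair}{two species with symmetric competition a = 0.5;
#'     expected equilibrium 2/3 each.}
#'   \item{three-species-one-antagonist}{a random n = 3, m = 1 draw;
#'     expected total antagonist density 1 at equilibrium.}
#'   \item{zero-impact-antagonists}{a random n = 3, m = 2 draw with the
#'     antagonist-impact block forced to zero, plus its matched m = 0
#'     baseline; expected divergence (Bray-Curtis 0, Kendall 1).}
#' }
#'
#' @param name one of the registry names above.
#' @param seed seed for the random registry entries.
#' @return a list with `name`, `system`, `x0`, `expected` (a list of
#'   closed-form expectations where they exist) and, for the zero-impact
#'   scenario, `baseline`.
#' @export
generate_fixture <- function(name, seed = 42) {
  switch(
    name,
    "single-logistic" = {
      sys <- as_assembled_system(matrix(1, 1, 1), 1, 1L, 0L)
      list(name = name, system = sys, x0 = 0.1,
           expected = list(equilibrium = 1))
    },
    "symmetric-pair" = {
      a <- 0.5
      sys <- as_assembled_system(matrix(c(1, a, a, 1), 2, 2), c(1, 0.8),
                                 2L, 0L)
      list(name = name, system = sys, x0 = c(0.1, 0.1),
           expected = list(equilibrium = rep(symmetric_equilibrium(2, a), 2)))
    },
    "three-species-one-antagonist" = {
      sys <- assemble_system(community_spec(3, 1, sigma = 0.3, A = 0.5,
                                            seed = seed))
      list(name = name, system = sys, x0 = rep(0.1, 4),
           expected = list(antagonist_total = 1))
    },
    "zero-impact-antagonists" = {
      spec <- community_spec(3, 2, sigma = 0.3, A = 0.5, seed = seed)
      sys <- assemble_system(spec)
      sys$alpha[seq_len(3), 4:5] <- 0
      base <- assemble_system(community_spec(3, 0, sigma = 0.3, A = 0.5,
                                             seed = seed))
      list(name = name, system = sys, x0 = rep(0.1, 5), baseline = base,
           expected = list(bray_curtis = 0, kendall = 1))
    },
    antago_error(sprintf("unknown fixture name: %s", name),
                 "invalid_parameter_error"))
}

#' @rdname generate_fixture
#' @export
fixture_names <- function() {
  c("single-logistic", "symmetric-pair", "three-species-one-antagonist",
    "zero-impact-antagonists")
}
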