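#' Build a run configuration
#'
#' Collects every knob of an analysis run: input paths, horizon, discount
#' rate, willingness-to-pay, PSA iterations, seed and scenario toggles.
#' `NULL` paths fall back to the packaged parameter table and the synthetic
#' life/utility tables.
#'
#' @param params Path to the parameter table (default: packaged fixture).
#' @param life_table,utilities Paths to `age,qx` / `age,utility` CSVs
#'   (default: generated synthetic tables).
#' @param out Output directory (default `"excea-output"`).
#' @param horizon Time horizon in years (default 5).
#' @param discount Annual discount rate (default 0.05).
#' @param wtp Willingness-to-pay threshold (default 50,000 AUD/QALY).
#' @param iterations PSA iterations (default 10,000).
#' @param seed Integer seed (default 1).
#' @param extended_supervision Apply the extended-supervision add-on cost.
#' @param sweep Integer vector of horizons for the sweep (default `1:10`).
#' @param fatal_event_cost Optional named vector overriding the one-time
#'   fatal-event cost (`stroke`, `chd`, `hf`).
#' @return A validated list of class `ec_config`.
#' @export
run_config <- function(params = NULL, life_table = NULL, utilities = NULL,
                       out = "excea-output", horizon = 5, discount = 0.05,
                       wtp = 50000, iterations = 10000, seed = 1L,
                       extended_supervision = FALSE, sweep = 1:10,
                       fatal_event_cost = NULL) {
  cfg <- structure(list(
    params = params, life_table = life_table, utilities = utilities,
    out = out, horizon = horizon, discount = discount, wtp = wtp,
    iterations = iterations, seed = as.integer(seed),
    extended_supervision = isTRUE(extended_supervision),
    sweep = as.integer(sweep), fatal_event_cost = fatal_event_cost
  ), class = "ec_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$horizon < 1) abort("horizon must be >= 1.", class = "excea_config_error")
  if (cfg$discount < 0) abort("discount rate must be >= 0.",
                              class = "excea_config_error")
  if (cfg$iterations < 1) abort("iterations must be >= 1.",
                                class = "excea_config_error")
  for (p in c("params", "life_table", "utilities")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      abort(sprintf("config path `%s` does not exist: %s", p, cfg[[p]]),
            class = "excea_config_error")
    }
  }
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Fields mirror [run_config()] arguments; `overrides` (e.g. parsed command
#' line flags) take precedence over the file.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file, or `NULL`
#'   for defaults.
#' @param overrides Named list of fields overriding the file.
#' @return An `ec_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  fields <- if (is.null(path)) {
    list()
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  fields <- modifyList(fields, overrides[!vapply(overrides, is.null, logical(1))])
  known <- names(formals(run_config))
  do.call(run_config, fields[intersect(names(fields), known)])
}

config_inputs <- function(cfg) {
  list(
    registry = parse_parameter_table(cfg$params %||%
                                       excea_example("parameters.csv")),
    life = if (is.null(cfg$life_table)) generate_life_table()
           else read_age_table(cfg$life_table),
    util = if (is.null(cfg$utilities)) generate_utility_table()
           else read_age_table(cfg$utilities)
  )
}

config_stamp <- function(cfg) {
  list(config_hash = rlang::hash(unclass(cfg)), seed = cfg$seed)
}

write_summary_json <- function(x, cfg, path) {
  jsonlite::write_json(c(x, config_stamp(cfg)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the deterministic base case and write its outputs
#'
#' Writes `basecase_summary.json` (increments, ICER, iNMB, per-arm totals,
#' config hash and seed) and `basecase_trace.csv` (per-cycle occupancy for
#' both arms) under the configured output directory.
#'
#' @param config An `ec_config`.
#' @return Named vector of output paths, invisibly.
#' @export
cmd_basecase <- function(config) {
  inp <- config_inputs(config)
  addon <- if (config$extended_supervision) 36 * 75 else 0
  res <- base_case(inp$registry, horizon = config$horizon, wtp = config$wtp,
                   life_table = inp$life, utility_table = inp$util,
                   discount_rate = config$discount,
                   supervision_addon = addon,
                   fatal_event_cost = config$fatal_event_cost)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  draw <- point_estimates(inp$registry)
  traces <- dplyr::bind_rows(
    tidy(run_arm(draw, exercise_arm(addon), config$horizon, inp$life,
                 inp$util, config$discount)$trace) |>
      dplyr::mutate(arm = "exercise"),
    tidy(run_arm(draw, standard_care_arm(), config$horizon, inp$life,
                 inp$util, config$discount)$trace) |>
      dplyr::mutate(arm = "standard_care")
  )
  paths <- c(summary = file.path(config$out, "basecase_summary.json"),
             trace = file.path(config$out, "basecase_trace.csv"))
  readr::write_csv(traces, paths[["trace"]], progress = FALSE)
  write_summary_json(as.list(glance(res)), config, paths[["summary"]])
  invisible(paths)
}

#' Run the PSA and CEAC and write their outputs
#'
#' Writes `psa_iterations.csv`, `ceac.csv` and `psa_summary.json` under the
#' configured output directory.
#'
#' @param config An `ec_config`.
#' @return Named vector of output paths, invisibly.
#' @export
cmd_psa <- function(config) {
  inp <- config_inputs(config)
  addon <- if (config$extended_supervision) 36 * 75 else 0
  psa <- run_psa(inp$registry, n_iter = config$iterations, seed = config$seed,
                 horizon = config$horizon, wtp = config$wtp,
                 life_table = inp$life, utility_table = inp$util,
                 discount_rate = config$discount, supervision_addon = addon,
                 fatal_event_cost = config$fatal_event_cost)
  cc <- ceac(psa)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  paths <- c(iterations = file.path(config$out, "psa_iterations.csv"),
             ceac = file.path(config$out, "ceac.csv"),
             summary = file.path(config$out, "psa_summary.json"))
  long <- tidy(psa) |>
    tidyr::pivot_longer(c("cost_exercise", "qaly_exercise",
                          "cost_standard_care", "qaly_standard_care"),
                        names_to = c("quantity", "arm"),
                        names_pattern = "(cost|qaly)_(.*)",
                        values_to = "value") |>
    tidyr::pivot_wider(id_cols = c(".draw", "arm"),
                       names_from = "quantity", values_from = "value") |>
    dplyr::rename(iteration = ".draw")
  readr::write_csv(long, paths[["iterations"]], progress = FALSE)
  readr::write_csv(cc, paths[["ceac"]], progress = FALSE)
  write_summary_json(as.list(glance(psa)), config, paths[["summary"]])
  invisible(paths)
}

#' Run the tornado and horizon-sweep analyses and write their outputs
#'
#' Writes `tornado.csv` (sorted by bar width), `horizon_sweep.csv` and
#' `sensitivity_summary.json` (including `first_cost_effective_year` and
#' `first_dominant_year` flags) under the configured output directory.
#'
#' @param config An `ec_config`.
#' @return Named vector of output paths, invisibly.
#' @export
cmd_sensitivity <- function(config) {
  inp <- config_inputs(config)
  tor <- tornado(inp$registry, horizon = config$horizon, wtp = config$wtp,
                 life_table = inp$life, utility_table = inp$util,
                 discount_rate = config$discount,
                 fatal_event_cost = config$fatal_event_cost)
  sw <- horizon_sweep(inp$registry, years = config$sweep, wtp = config$wtp,
                      life_table = inp$life, utility_table = inp$util,
                      discount_rate = config$discount,
                      fatal_event_cost = config$fatal_event_cost)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tornado = file.path(config$out, "tornado.csv"),
             sweep = file.path(config$out, "horizon_sweep.csv"),
             summary = file.path(config$out, "sensitivity_summary.json"))
  readr::write_csv(tor, paths[["tornado"]], progress = FALSE)
  readr::write_csv(sw, paths[["sweep"]], progress = FALSE)
  write_summary_json(
    list(icer_base = attr(tor, "icer_base"),
         first_cost_effective_year = attr(sw, "first_cost_effective_year"),
         first_dominant_year = attr(sw, "first_dominant_year")),
    config, paths[["summary"]])
  invisible(paths)
}

#' Write the synthetic input bundle for a configuration
#'
#' @param config An `ec_config`; the bundle lands in its output directory.
#' @return Named vector of output paths, invisibly.
#' @export
cmd_fixtures <- function(config) {
  write_fixture_bundle(config$out, seed = config$seed)
}
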