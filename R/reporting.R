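# Run configuration, command-style entry points and tabular outputs
# (cost-effectiveness table, traces, tornado, two-way map, CEAC).

.default_config <- function() {
  list(
    parameters = "builtin",
    lifetable  = "builtin",
    output_dir = ".",
    horizon    = NULL,
    discount_rate = NULL,
    wtp        = NULL,
    settings   = list(),
    overrides  = list(),
    psa        = list(n = 50000, seed = 20230724, wtp = NULL),
    tornado    = list(range = 0.25),
    twoway     = list(param_x = "CE-CT.sensitivity", param_y = "MRI.sensitivity",
                      from_x = 0.4, to_x = 1, from_y = 0.4, to_y = 1, steps = 7),
    ceac       = list(from = 0, to = 2e5, by = 5e3),
    write_scatter = FALSE
  )
}

#' Load a run configuration
#'
#' Reads a YAML run configuration (or accepts one as a list) and fills in
#' defaults. Recognised keys: `parameters` (path to a parameter config or
#' `"builtin"`), `lifetable` (path or `"builtin"`), `output_dir`, `horizon`,
#' `discount_rate`, `wtp`,
#' `settings` (structural toggles, see [cea_parameters()]), `overrides`
#' (named base-value overrides), `psa` (`n`, `seed`, `wtp`), `tornado`
#' (`range`), `twoway` (`param_x`, `param_y`, grid bounds and `steps`),
#' `ceac` (`from`, `to`, `by`) and `write_scatter`.
#'
#' @param config path to a YAML file, or a list of settings, or `NULL` for
#'   all defaults.
#' @return the resolved configuration list.
#' @export
load_run_config <- function(config = NULL) {
  def <- .default_config()
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else {
    config
  }
  for (nm in names(user)) {
    if (is.list(def[[nm]]) && is.list(user[[nm]])) {
      def[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      def[[nm]] <- user[[nm]]
    }
  }
  def
}

#' Path to the committed calibration configuration
#'
#' The single configuration file that records the structural settings
#' (horizon, false-positive pathway, undiagnosed-state costing, detection
#' probability, recurrence annualisation, PSA size and seed) under which the
#' package reproduces its reference base-case and acceptability results; see
#' the methods vignette.
#'
#' @return file path of the bundled YAML configuration.
#' @export
calibration_config <- function() {
  path <- system.file("extdata", "calibration.yaml", package = "crlmcea")
  if (path == "") stop("bundled calibration config not found")
  path
}

# Materialise parameters, strategies and life table from a resolved config.
.resolve_inputs <- function(cfg) {
  if (identical(cfg$parameters, "builtin")) {
    bc <- builtin_basecase()
    params <- bc$params
    strategies <- bc$strategies
  } else {
    pt <- load_parameter_table(cfg$parameters)
    params <- pt$params
    strategies <- pt$strategies
  }
  if (!is.null(cfg$horizon)) params$horizon <- as.integer(cfg$horizon)
  if (!is.null(cfg$discount_rate)) params$discount_rate <- cfg$discount_rate
  if (!is.null(cfg$wtp)) params$wtp <- cfg$wtp
  if (length(cfg$settings)) {
    params$settings[names(cfg$settings)] <- cfg$settings
  }
  for (nm in names(cfg$overrides)) {
    upd <- .set_parameter(params, strategies, nm, cfg$overrides[[nm]])
    params <- upd$params
    strategies <- upd$strategies
  }
  validate_parameters(params)
  lifetable <- if (identical(cfg$lifetable, "builtin")) {
    builtin_lifetable()
  } else {
    load_lifetable(cfg$lifetable)
  }
  list(params = params, strategies = strategies, lifetable = lifetable)
}

.write_manifest <- function(cfg, outdir, command, extra = list()) {
  manifest <- c(list(command = command,
                     package = "crlmcea",
                     version = as.character(utils::packageVersion("crlmcea")),
                     config = cfg), extra)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.prepare_outdir <- function(cfg) {
  outdir <- cfg$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outdir
}

.safe_name <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Base-case cost-effectiveness run
#'
#' Runs every strategy through the cohort model, ranks them on the efficiency
#' frontier, writes `ce_table.csv` plus one trace CSV per strategy and a JSON
#' run manifest to the configured output directory, and prints the ranking.
#'
#' @param config path to a YAML run configuration, or a list (see
#'   [load_run_config()]).
#' @param quiet suppress console output.
#' @return the frontier table, invisibly.
#' @export
cmd_basecase <- function(config = NULL, quiet = FALSE) {
  cfg <- load_run_config(config)
  inp <- .resolve_inputs(cfg)
  outdir <- .prepare_outdir(cfg)
  runs <- lapply(seq_len(nrow(inp$strategies)), function(i)
    run_cohort(inp$strategies[i, ], inp$params, inp$lifetable))
  results <- do.call(rbind, lapply(runs, `[[`, "result"))
  front <- efficiency_frontier(results)
  export_ranking(front, file.path(outdir, "ce_table.csv"))
  for (i in seq_along(runs))
    export_trace(runs[[i]]$trace,
                 file.path(outdir, paste0("trace_",
                                          .safe_name(inp$strategies$name[i]),
                                          ".csv")))
  .write_manifest(cfg, outdir, "basecase")
  if (!quiet) {
    print(front, digits = 6)
  }
  invisible(front)
}

#' Probabilistic sensitivity analysis run
#'
#' Runs the Monte Carlo PSA at the configured size and seed, writes the
#' acceptability-curve grid (`ceac.csv`), the acceptability shares at the
#' configured willingness-to-pay (`acceptability.csv`), optionally the
#' per-iteration scatter (`psa_scatter.csv`), and a JSON run manifest.
#'
#' @inheritParams cmd_basecase
#' @return the `psa_result`, invisibly.
#' @export
cmd_psa <- function(config = NULL, quiet = FALSE) {
  cfg <- load_run_config(config)
  inp <- .resolve_inputs(cfg)
  outdir <- .prepare_outdir(cfg)
  wtp <- if (is.null(cfg$psa$wtp)) inp$params$wtp else cfg$psa$wtp
  psa <- run_psa(inp$params, inp$strategies, inp$lifetable,
                 n = cfg$psa$n, seed = cfg$psa$seed)
  grid <- seq(cfg$ceac$from, cfg$ceac$to, by = cfg$ceac$by)
  export_psa(psa, file.path(outdir, "ceac.csv"),
             scatter_path = if (isTRUE(cfg$write_scatter))
               file.path(outdir, "psa_scatter.csv") else NULL,
             wtp_grid = grid)
  acc <- acceptability_at(psa, wtp)
  acc_df <- data.frame(strategy = names(acc), wtp = wtp,
                       acceptability = unname(acc),
                       percent = 100 * unname(acc))
  utils::write.csv(acc_df, file.path(outdir, "acceptability.csv"),
                   row.names = FALSE)
  .write_manifest(cfg, outdir, "psa",
                  extra = list(psa_n = psa$n, psa_seed = psa$seed, wtp = wtp))
  if (!quiet) print(acc_df, digits = 4)
  invisible(psa)
}

#' Tornado deterministic sensitivity run
#'
#' Runs [tornado()] with the configured range rule and writes `tornado.csv`
#' (sorted by descending spread) and a JSON run manifest.
#'
#' @inheritParams cmd_basecase
#' @return the tornado table, invisibly.
#' @export
cmd_tornado <- function(config = NULL, quiet = FALSE) {
  cfg <- load_run_config(config)
  inp <- .resolve_inputs(cfg)
  outdir <- .prepare_outdir(cfg)
  tor <- tornado(inp$params, inp$strategies, inp$lifetable,
                 range_frac = cfg$tornado$range)
  export_tornado(tor, file.path(outdir, "tornado.csv"))
  .write_manifest(cfg, outdir, "tornado")
  if (!quiet) print(utils::head(tor), digits = 5)
  invisible(tor)
}

#' Two-way deterministic sensitivity run
#'
#' Evaluates the winning strategy over the configured two-parameter grid and
#' writes `twoway.csv` (rows indexed by the first parameter's grid) and a JSON
#' run manifest.
#'
#' @inheritParams cmd_basecase
#' @return the winner matrix, invisibly.
#' @export
cmd_twoway <- function(config = NULL, quiet = FALSE) {
  cfg <- load_run_config(config)
  inp <- .resolve_inputs(cfg)
  outdir <- .prepare_outdir(cfg)
  tw <- cfg$twoway
  gx <- seq(tw$from_x, tw$to_x, length.out = tw$steps)
  gy <- seq(tw$from_y, tw$to_y, length.out = tw$steps)
  m <- two_way(tw$param_x, tw$param_y, gx, gy,
               inp$params, inp$strategies, inp$lifetable)
  utils::write.csv(data.frame(x = rownames(m), m, check.names = FALSE),
                   file.path(outdir, "twoway.csv"), row.names = FALSE)
  .write_manifest(cfg, outdir, "twoway")
  if (!quiet) print(m)
  invisible(m)
}

#' Validate a run configuration and its inputs
#'
#' Loads and validates every input referenced by the configuration.
#'
#' @inheritParams cmd_basecase
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
cmd_validate <- function(config = NULL, quiet = FALSE) {
  cfg <- load_run_config(config)
  inp <- .resolve_inputs(cfg)
  validate_parameters(inp$params)
  validate_strategies(inp$strategies)
  validate_lifetable(inp$lifetable)
  if (!quiet) message("configuration and inputs are valid")
  invisible(TRUE)
}
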