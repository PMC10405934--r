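# Model inputs: named parameter specifications with uncertainty annotations,
# global run settings, strategy definitions, and config-file I/O.

#' @keywords internal
.required_parameters <- c(
  "overall_resection_cost", "delayed_resection_cost", "annual_crlm_cost",
  "u_tumor_free", "u_post_resection", "u_recurrence", "u_undetected",
  "p_metastases", "p_treatment_success", "p_recurrence_5y", "p_death_untreated"
)

.prob_parameters <- c(
  "u_tumor_free", "u_post_resection", "u_recurrence", "u_undetected",
  "p_metastases", "p_treatment_success", "p_recurrence_5y", "p_death_untreated"
)

.default_settings <- function() {
  list(
    p_detect         = 1,
    fp_pathway       = "confirmatory", # or "resection"
    fp_workup_cost   = 964,
    undiagnosed_cost = "none",          # or "crlm"
    recurrence_input = "cumulative_5y", # or "annual"
    recurrence_pathway = "terminal",    # or "salvage"
    dispersion_frac = 0.2               # default SE as fraction of base value
  )
}

#' Default dispersion for a sampled parameter
#'
#' Standard errors are not reported alongside the base-case inputs, so the
#' probabilistic analysis uses a conventional default of 20% of the base value,
#' capped for beta-family parameters so that the method-of-moments fit remains
#' feasible (the variance of a beta with mean m cannot reach m(1-m)).
#'
#' @param value base value.
#' @param dist distribution family, one of `"beta"`, `"gamma"`, `"point"`.
#' @param frac dispersion as a fraction of the base value (default 0.2).
#' @return standard error on the scale of `value`.
#' @export
default_dispersion <- function(value, dist, frac = 0.2) {
  if (dist == "point") return(0)
  s <- frac * value
  if (dist == "beta") {
    if (value <= 0 || value >= 1) return(0)
    s <- min(s, 0.95 * sqrt(value * (1 - value)))
  }
  s
}

.make_spec_df <- function(name, value, dist, dispersion = NULL, frac = 0.2) {
  if (is.null(dispersion)) {
    dispersion <- mapply(default_dispersion, value, dist,
                         MoreArgs = list(frac = frac))
  }
  data.frame(name = name, value = value, dist = dist,
             dispersion = dispersion, stringsAsFactors = FALSE)
}

#' Construct a parameter table
#'
#' @param specs data frame with columns `name`, `value`, `dist`
#'   (`"beta"`/`"gamma"`/`"point"`) and `dispersion` (standard error, same units
#'   as `value`).
#' @param discount_rate annual discount rate applied to costs and QALYs.
#' @param wtp willingness-to-pay threshold, USD per QALY.
#' @param horizon number of model cycles.
#' @param cycle_length cycle length in years.
#' @param start_age cohort age (years) at the diagnostic procedure.
#' @param settings structural model settings; see [builtin_basecase()] for the
#'   documented toggles (`p_detect`, `fp_pathway`, `fp_workup_cost`,
#'   `undiagnosed_cost`, `recurrence_input`).
#' @return an object of class `cea_parameters`.
#' @export
cea_parameters <- function(specs, discount_rate = 0.03, wtp = 1e5,
                           horizon = 5L, cycle_length = 1, start_age = 68,
                           settings = list()) {
  stopifnot(is.data.frame(specs))
  set <- .default_settings()
  set[names(settings)] <- settings
  obj <- structure(list(
    specs         = specs,
    discount_rate = discount_rate,
    wtp           = wtp,
    horizon       = as.integer(horizon),
    cycle_length  = cycle_length,
    start_age     = start_age,
    settings      = set
  ), class = "cea_parameters")
  validate_parameters(obj)
  obj
}

#' Construct a strategy table
#'
#' Each imaging strategy is a name plus its diagnostic accuracy and upfront
#' imaging tariff.
#'
#' @param name strategy labels.
#' @param sensitivity,specificity test accuracy, probabilities in \[0, 1\].
#' @param imaging_cost upfront imaging cost in USD.
#' @return a `cea_strategies` data frame.
#' @export
cea_strategies <- function(name, sensitivity, specificity, imaging_cost) {
  df <- data.frame(name = name, sensitivity = sensitivity,
                   specificity = specificity, imaging_cost = imaging_cost,
                   stringsAsFactors = FALSE)
  validate_strategies(df)
  class(df) <- c("cea_strategies", "data.frame")
  df
}

#' Validate a parameter table
#'
#' Checks presence of every required model input, uniqueness of names, range
#' constraints per distribution family (beta in \[0,1\], gamma non-negative,
#' dispersion non-negative and feasible), and global settings.
#'
#' @param params a `cea_parameters` object.
#' @return `TRUE`, invisibly; otherwise an error naming the offending entry.
#' @export
validate_parameters <- function(params) {
  sp <- params$specs
  need <- c("name", "value", "dist", "dispersion")
  if (!all(need %in% names(sp)))
    stop("parameter specs must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(sp$name))
    stop("duplicate parameter name: ", sp$name[duplicated(sp$name)][1])
  missing <- setdiff(.required_parameters, sp$name)
  if (length(missing))
    stop("missing required parameter(s): ", paste(missing, collapse = ", "))
  if (!all(sp$dist %in% c("beta", "gamma", "point")))
    stop("unknown distribution family: ",
         paste(setdiff(sp$dist, c("beta", "gamma", "point")), collapse = ", "))
  for (i in seq_len(nrow(sp))) {
    nm <- sp$name[i]; v <- sp$value[i]; d <- sp$dist[i]; s <- sp$dispersion[i]
    if (!is.finite(v)) stop("parameter '", nm, "' has non-finite value")
    if (d == "beta" && (v < 0 || v > 1))
      stop("parameter '", nm, "' (beta family) must lie in [0, 1], got ", v)
    if (d == "gamma" && v < 0)
      stop("parameter '", nm, "' (gamma family) must be >= 0, got ", v)
    if (nm %in% .prob_parameters && (v < 0 || v > 1))
      stop("parameter '", nm, "' must be a probability/utility in [0, 1], got ", v)
    if (!is.finite(s) || s < 0)
      stop("parameter '", nm, "' has invalid dispersion ", s)
  }
  for (g in c("discount_rate", "wtp", "horizon", "cycle_length", "start_age")) {
    if (is.null(params[[g]]) || !is.finite(params[[g]]))
      stop("missing or non-finite global '", g, "'")
  }
  if (params$discount_rate < 0) stop("discount_rate must be >= 0")
  if (params$horizon < 1) stop("horizon must be >= 1")
  if (params$cycle_length <= 0) stop("cycle_length must be > 0")
  set <- params$settings
  if (!set$fp_pathway %in% c("confirmatory", "resection"))
    stop("fp_pathway must be 'confirmatory' or 'resection'")
  if (!set$undiagnosed_cost %in% c("none", "crlm"))
    stop("undiagnosed_cost must be 'none' or 'crlm'")
  if (!set$recurrence_input %in% c("cumulative_5y", "annual"))
    stop("recurrence_input must be 'cumulative_5y' or 'annual'")
  if (!set$recurrence_pathway %in% c("terminal", "salvage"))
    stop("recurrence_pathway must be 'terminal' or 'salvage'")
  if (set$p_detect < 0 || set$p_detect > 1)
    stop("p_detect must lie in [0, 1]")
  if (!is.finite(set$dispersion_frac) || set$dispersion_frac < 0)
    stop("dispersion_frac must be >= 0")
  if (set$fp_workup_cost < 0) stop("fp_workup_cost must be >= 0")
  invisible(TRUE)
}

#' Validate a strategy table
#' @param strategies a strategy data frame.
#' @return `TRUE`, invisibly.
#' @export
validate_strategies <- function(strategies) {
  need <- c("name", "sensitivity", "specificity", "imaging_cost")
  if (!all(need %in% names(strategies)))
    stop("strategies must have columns ", paste(need, collapse = ", "))
  if (nrow(strategies) < 1) stop("at least one strategy is required")
  if (anyDuplicated(strategies$name))
    stop("duplicate strategy name: ",
         strategies$name[duplicated(strategies$name)][1])
  for (i in seq_len(nrow(strategies))) {
    nm <- strategies$name[i]
    for (f in c("sensitivity", "specificity")) {
      v <- strategies[[f]][i]
      if (v < 0 || v > 1)
        stop("strategy '", nm, "' ", f, " must lie in [0, 1], got ", v)
    }
    if (strategies$imaging_cost[i] < 0)
      stop("strategy '", nm, "' imaging_cost must be >= 0")
  }
  invisible(TRUE)
}

#' Built-in base-case inputs
#'
#' The package's built-in base case for comparing CE-CT, MRI and 18F-FDG PET/CT
#' in the detection of resectable colorectal liver metastases: diagnostic
#' accuracies averaged over two readers, 2023 US Medicare imaging tariffs, an
#' aggregate hepatic-resection cost, a delayed-resection cost of 1.3 times the
#' timely one, annual expenses with active metastatic disease, health-state
#' utilities, transition probabilities, a 3% annual discount rate, a
#' willingness-to-pay of $100,000/QALY and a cohort starting age of 68 years.
#'
#' Costs carry gamma uncertainty distributions, probabilities and utilities
#' beta ones (boundary utilities are fixed points); dispersions default to 20%
#' of the base value (see [default_dispersion()]).
#'
#' @param horizon number of annual cycles (default 5).
#' @param settings structural setting overrides, see [cea_parameters()]. A
#'   `dispersion_frac` entry sets the default standard error of every sampled
#'   parameter as a fraction of its base value (default 0.2).
#' @return a list with elements `params` (a `cea_parameters` table) and
#'   `strategies` (a `cea_strategies` data frame with CE-CT, MRI and PET/CT).
#' @export
#' @examples
#' bc <- builtin_basecase()
#' bc$strategies
builtin_basecase <- function(horizon = 5L, settings = list()) {
  frac <- if (!is.null(settings$dispersion_frac)) settings$dispersion_frac else 0.2
  specs <- .make_spec_df(frac = frac,
    name = c("overall_resection_cost", "delayed_resection_cost",
             "annual_crlm_cost",
             "u_tumor_free", "u_post_resection", "u_recurrence", "u_undetected",
             "p_metastases", "p_treatment_success", "p_recurrence_5y",
             "p_death_untreated"),
    value = c(21592, 1.3 * 21592, 63063,
              1, 0.78, 0.65, 0.85,
              0.275, 0.70, 0.62, 0.2417),
    dist = c("gamma", "gamma", "gamma",
             "beta", "beta", "beta", "beta",
             "beta", "beta", "beta", "beta")
  )
  params <- cea_parameters(specs, discount_rate = 0.03, wtp = 1e5,
                           horizon = horizon, cycle_length = 1, start_age = 68,
                           settings = settings)
  strategies <- cea_strategies(
    name         = c("CE-CT", "MRI", "PET/CT"),
    sensitivity  = c(0.6570, 0.8485, 0.7205),
    specificity  = c(0.9365, 0.9205, 0.9285),
    imaging_cost = c(464, 964, 1615)
  )
  list(params = params, strategies = strategies)
}

#' Look up a parameter base value
#' @param params a `cea_parameters` object.
#' @param name parameter name.
#' @return the base value.
#' @export
param_value <- function(params, name) {
  i <- match(name, params$specs$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  params$specs$value[i]
}

#' Build a sampleable distribution from a parameter specification
#'
#' Beta distributions are parameterised by the method of moments,
#' \eqn{\alpha = m(m(1-m)/s^2 - 1)}, \eqn{\beta = (1-m)(m(1-m)/s^2 - 1)};
#' gamma distributions by shape \eqn{k = (m/s)^2} and scale
#' \eqn{\theta = s^2/m}. A zero dispersion, or family `"point"`, yields a point
#' mass at the base value. In all cases the distribution mean equals the base
#' value.
#'
#' @param spec a one-row data frame or list with `name`, `value`, `dist`,
#'   `dispersion`.
#' @return a `cea_distribution`: list with `name`, `family`, `mean`, shape
#'   parameters, and a sampler `r(n)`.
#' @export
#' @examples
#' d <- make_distribution(list(name = "p", value = 0.7, dist = "beta",
#'                             dispersion = 0.1))
#' d$alpha; d$beta  # 14 and 6
make_distribution <- function(spec) {
  m <- spec$value; s <- spec$dispersion; fam <- spec$dist
  if (s < 0) stop("dispersion must be >= 0")
  if (fam == "point" || s == 0) {
    return(structure(list(name = spec$name, family = "point", mean = m,
                          r = function(n) rep(m, n)),
                     class = "cea_distribution"))
  }
  if (fam == "beta") {
    if (m <= 0 || m >= 1)
      stop("beta parameter '", spec$name,
           "' with mean at the boundary cannot carry dispersion > 0")
    if (s^2 >= m * (1 - m))
      stop("beta parameter '", spec$name, "': variance ", s^2,
           " is infeasible for mean ", m, " (must be < m(1-m) = ", m * (1 - m), ")")
    nu <- m * (1 - m) / s^2 - 1
    a <- m * nu; b <- (1 - m) * nu
    return(structure(list(name = spec$name, family = "beta", mean = m,
                          alpha = a, beta = b,
                          r = function(n) stats::rbeta(n, a, b)),
                     class = "cea_distribution"))
  }
  if (fam == "gamma") {
    if (m <= 0)
      stop("gamma parameter '", spec$name,
           "' with mean 0 cannot carry dispersion > 0")
    k <- (m / s)^2; theta <- s^2 / m
    return(structure(list(name = spec$name, family = "gamma", mean = m,
                          shape = k, scale = theta,
                          r = function(n) stats::rgamma(n, shape = k, scale = theta)),
                     class = "cea_distribution"))
  }
  stop("unknown distribution family: ", fam)
}

# ---- config file I/O --------------------------------------------------------

#' Write a parameter table (with strategies) to a YAML config file
#'
#' @param params a `cea_parameters` object.
#' @param strategies a `cea_strategies` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params, strategies, path) {
  sp <- params$specs
  plist <- lapply(seq_len(nrow(sp)), function(i)
    list(value = sp$value[i], dist = sp$dist[i], dispersion = sp$dispersion[i]))
  names(plist) <- sp$name
  slist <- lapply(seq_len(nrow(strategies)), function(i)
    list(name = strategies$name[i],
         sensitivity = strategies$sensitivity[i],
         specificity = strategies$specificity[i],
         imaging_cost = strategies$imaging_cost[i]))
  obj <- list(
    parameters = plist,
    strategies = slist,
    globals = list(discount_rate = params$discount_rate, wtp = params$wtp,
                   horizon = params$horizon, cycle_length = params$cycle_length,
                   start_age = params$start_age),
    settings = params$settings
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Load a parameter table from a YAML config file
#'
#' The file must contain a `parameters` map (each entry `value`, `dist`,
#' optional `dispersion`), a `strategies` list, and a `globals` map with
#' `discount_rate`, `wtp`, `horizon`, `cycle_length`, `start_age`. An optional
#' `settings` map overrides the structural defaults.
#' `write_parameter_table()` followed by `load_parameter_table()` is the
#' identity.
#'
#' @param path config file path.
#' @return list with `params` and `strategies`, validated.
#' @export
load_parameter_table <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- yaml::read_yaml(path)
  if (is.null(obj$parameters)) stop("config is missing 'parameters'")
  if (is.null(obj$strategies)) stop("config is missing 'strategies'")
  if (is.null(obj$globals)) stop("config is missing 'globals'")
  for (g in c("discount_rate", "wtp", "horizon", "cycle_length", "start_age")) {
    if (is.null(obj$globals[[g]]))
      stop("config 'globals' is missing '", g, "'")
  }
  specs <- data.frame(
    name = names(obj$parameters),
    value = vapply(obj$parameters, function(p) as.numeric(p$value), 0),
    dist = vapply(obj$parameters, function(p) as.character(p$dist), ""),
    dispersion = vapply(obj$parameters, function(p)
      if (is.null(p$dispersion)) NA_real_ else as.numeric(p$dispersion), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  na <- which(is.na(specs$dispersion))
  for (i in na)
    specs$dispersion[i] <- default_dispersion(specs$value[i], specs$dist[i])
  params <- cea_parameters(
    specs,
    discount_rate = obj$globals$discount_rate,
    wtp = obj$globals$wtp,
    horizon = obj$globals$horizon,
    cycle_length = obj$globals$cycle_length,
    start_age = obj$globals$start_age,
    settings = if (is.null(obj$settings)) list() else obj$settings
  )
  strategies <- cea_strategies(
    name = vapply(obj$strategies, function(s) as.character(s$name), ""),
    sensitivity = vapply(obj$strategies, function(s) as.numeric(s$sensitivity), 0),
    specificity = vapply(obj$strategies, function(s) as.numeric(s$specificity), 0),
    imaging_cost = vapply(obj$strategies, function(s) as.numeric(s$imaging_cost), 0)
  )
  list(params = params, strategies = strategies)
}

#' Export the parameter table as CSV
#'
#' Columns `name,value,dist,dispersion`; strategy rows are appended as
#' `<strategy>.sensitivity`, `<strategy>.specificity`, `<strategy>.imaging_cost`.
#'
#' @inheritParams write_parameter_table
#' @return `path`, invisibly.
#' @export
export_parameter_csv <- function(params, strategies, path) {
  sp <- params$specs[, c("name", "value", "dist", "dispersion")]
  srows <- do.call(rbind, lapply(seq_len(nrow(strategies)), function(i) {
    nm <- strategies$name[i]
    data.frame(
      name = paste0(nm, c(".sensitivity", ".specificity", ".imaging_cost")),
      value = c(strategies$sensitivity[i], strategies$specificity[i],
                strategies$imaging_cost[i]),
      dist = c("beta", "beta", "gamma"),
      dispersion = c(
        default_dispersion(strategies$sensitivity[i], "beta"),
        default_dispersion(strategies$specificity[i], "beta"),
        default_dispersion(strategies$imaging_cost[i], "gamma")),
      stringsAsFactors = FALSE)
  }))
  utils::write.csv(rbind(sp, srows), path, row.names = FALSE)
  invisible(path)
}
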