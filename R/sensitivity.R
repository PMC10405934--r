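# Deterministic (one-way tornado, two-way breaking-point) and probabilistic
# (Monte Carlo) sensitivity analyses.

# A sensitivity parameter is either a shared model input (a row of
# params$specs) or a strategy field addressed as "<strategy>.<field>", e.g.
# "MRI.specificity".
.set_parameter <- function(params, strategies, name, value) {
  i <- match(name, params$specs$name)
  if (!is.na(i)) {
    nm <- params$specs$name[i]
    if (params$specs$dist[i] == "beta" || nm %in% .prob_parameters) {
      if (value < 0 || value > 1)
        stop("value ", value, " for '", nm, "' leaves the legal range [0, 1]")
    } else if (value < 0) {
      stop("value ", value, " for '", nm, "' leaves the legal range [0, Inf)")
    }
    params$specs$value[i] <- value
    return(list(params = params, strategies = strategies))
  }
  m <- regmatches(name, regexec("^(.*)\\.(sensitivity|specificity|imaging_cost)$", name))[[1]]
  if (length(m) == 3 && m[2] %in% strategies$name) {
    j <- match(m[2], strategies$name)
    if (m[3] %in% c("sensitivity", "specificity") && (value < 0 || value > 1))
      stop("value ", value, " for '", name, "' leaves the legal range [0, 1]")
    if (m[3] == "imaging_cost" && value < 0)
      stop("value ", value, " for '", name, "' leaves the legal range [0, Inf)")
    strategies[[m[3]]][j] <- value
    return(list(params = params, strategies = strategies))
  }
  stop("unknown parameter: ", name)
}

# Base-case top two strategies by NMB (winner first).
.top_pair <- function(results, wtp) {
  b <- nmb(results, wtp)
  ord <- order(-b, results$cost, -results$qaly, results$strategy)
  results$strategy[ord[1:2]]
}

.pair_metrics <- function(results, pair, wtp) {
  a <- results[results$strategy == pair[1], ]
  b <- results[results$strategy == pair[2], ]
  ic <- icer(a, b)
  list(nmb_diff = nmb(a, wtp) - nmb(b, wtp),
       icer = if (ic$flag == "icer") ic$icer else NA_real_)
}

#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Re-runs the full model with the named parameter set to `low` and to `high`
#' (all other inputs at base values) and records the outcome metric at both
#' ends. The default metric is the net-monetary-benefit difference between the
#' two base-case leading strategies at the configured willingness-to-pay,
#' which stays well defined when one strategy dominates (where the pairwise
#' ICER does not); ICER endpoints are reported alongside where defined.
#'
#' @param param_name a shared parameter name or `"<strategy>.<field>"` (field
#'   one of `sensitivity`, `specificity`, `imaging_cost`).
#' @param low,high the two input values, `low <= high`, within legal bounds.
#' @param params a `cea_parameters` object.
#' @param strategies a `cea_strategies` data frame.
#' @param lifetable a `cea_lifetable`.
#' @param wtp willingness-to-pay for the NMB metric (default: from `params`).
#' @param pair the two strategies compared (default: base-case top two by NMB).
#' @return a one-row `tornado_entry` data frame: parameter, low, high,
#'   metric_low, metric_high, icer_low, icer_high, spread.
#' @export
one_way <- function(param_name, low, high, params, strategies, lifetable,
                    wtp = params$wtp, pair = NULL) {
  if (low > high) stop("low must be <= high")
  if (is.null(pair)) {
    base <- run_strategies(strategies, params, lifetable)
    pair <- .top_pair(base, wtp)
  }
  eval_at <- function(value) {
    mod <- .set_parameter(params, strategies, param_name, value)
    res <- run_strategies(mod$strategies, mod$params, lifetable)
    .pair_metrics(res, pair, wtp)
  }
  lo <- eval_at(low)
  hi <- eval_at(high)
  data.frame(parameter = param_name, low = low, high = high,
             metric_low = lo$nmb_diff, metric_high = hi$nmb_diff,
             icer_low = lo$icer, icer_high = hi$icer,
             spread = abs(hi$nmb_diff - lo$nmb_diff),
             stringsAsFactors = FALSE)
}

#' Tornado deterministic sensitivity analysis over all sampled parameters
#'
#' Applies [one_way()] to every uncertainty-carrying shared parameter and to
#' every strategy's sensitivity, specificity and imaging cost, varying each by
#' `range_frac` around its base value (clipped to legal bounds), with the
#' comparison pair fixed at the base-case top two strategies. Entries are
#' sorted by descending spread.
#'
#' @inheritParams one_way
#' @param range_frac half-width of the variation range as a fraction of the
#'   base value (default 0.25).
#' @return a `tornado_entry` data frame, one row per varied parameter, sorted
#'   by descending spread.
#' @export
tornado <- function(params, strategies, lifetable, range_frac = 0.25,
                    wtp = params$wtp) {
  base <- run_strategies(strategies, params, lifetable)
  pair <- .top_pair(base, wtp)
  sp <- params$specs
  shared <- sp[sp$dist != "point" & sp$dispersion > 0, ]
  targets <- data.frame(
    name = shared$name, value = shared$value,
    bounded = shared$dist == "beta" | shared$name %in% .prob_parameters,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(strategies))) {
    nm <- strategies$name[i]
    targets <- rbind(targets, data.frame(
      name = paste0(nm, c(".sensitivity", ".specificity", ".imaging_cost")),
      value = c(strategies$sensitivity[i], strategies$specificity[i],
                strategies$imaging_cost[i]),
      bounded = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    v <- targets$value[i]
    lo <- max(0, v * (1 - range_frac))
    hi <- if (targets$bounded[i]) min(1, v * (1 + range_frac)) else v * (1 + range_frac)
    one_way(targets$name[i], lo, hi, params, strategies, lifetable,
            wtp = wtp, pair = pair)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$parameter), ]
  rownames(out) <- NULL
  out
}

#' Two-way deterministic sensitivity analysis
#'
#' Evaluates the full model on a grid over two parameters and records the
#' cost-effective (argmax-NMB) strategy in each cell — the "breaking point"
#' map for when one strategy overtakes another.
#'
#' @inheritParams one_way
#' @param param_x,param_y parameter names (shared or `"<strategy>.<field>"`).
#' @param grid_x,grid_y numeric vectors of values, within legal ranges.
#' @return character matrix of winning strategy names, rows indexed by
#'   `grid_x`, columns by `grid_y`.
#' @export
two_way <- function(param_x, param_y, grid_x, grid_y, params, strategies,
                    lifetable, wtp = params$wtp) {
  out <- matrix(NA_character_, length(grid_x), length(grid_y),
                dimnames = list(format(grid_x, trim = TRUE),
                                format(grid_y, trim = TRUE)))
  for (i in seq_along(grid_x)) {
    mx <- .set_parameter(params, strategies, param_x, grid_x[i])
    for (j in seq_along(grid_y)) {
      mxy <- .set_parameter(mx$params, mx$strategies, param_y, grid_y[j])
      res <- run_strategies(mxy$strategies, mxy$params, lifetable)
      out[i, j] <- ce_choice(res, wtp)
    }
  }
  out
}

#' Export tornado results to CSV
#' @param entries a `tornado_entry` data frame from [tornado()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_tornado <- function(entries, path) {
  utils::write.csv(entries, path, row.names = FALSE)
  invisible(path)
}

# ---- probabilistic sensitivity analysis ------------------------------------

# The frame of sampled quantities, in the canonical draw order: shared
# parameters in table order, then per-strategy sensitivity, specificity and
# imaging cost in strategy row order. Drawing in this fixed order from a single
# seeded stream makes results independent of strategy evaluation order.
.psa_frame <- function(params, strategies) {
  sp <- params$specs
  frac <- params$settings$dispersion_frac
  shared <- sp[sp$dist != "point" & sp$dispersion > 0, , drop = FALSE]
  strat <- do.call(rbind, lapply(seq_len(nrow(strategies)), function(i) {
    nm <- strategies$name[i]
    data.frame(
      name = paste0(nm, c(".sensitivity", ".specificity", ".imaging_cost")),
      value = c(strategies$sensitivity[i], strategies$specificity[i],
                strategies$imaging_cost[i]),
      dist = c("beta", "beta", "gamma"),
      dispersion = c(
        default_dispersion(strategies$sensitivity[i], "beta", frac),
        default_dispersion(strategies$specificity[i], "beta", frac),
        default_dispersion(strategies$imaging_cost[i], "gamma", frac)),
      stringsAsFactors = FALSE)
  }))
  rbind(shared[, c("name", "value", "dist", "dispersion")], strat)
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Samples every uncertainty-carrying parameter (shared inputs and each
#' strategy's sensitivity, specificity and imaging cost) from its
#' method-of-moments distribution (see [make_distribution()]), rebuilds the
#' decision tree and cohort model per draw, and records per-iteration costs
#' and QALYs for every strategy. All draws come from one seeded stream in a
#' fixed documented order, so reruns with the same seed are bit-identical and
#' results do not depend on strategy evaluation order.
#'
#' @param params a `cea_parameters` object.
#' @param strategies a `cea_strategies` data frame.
#' @param lifetable a `cea_lifetable`.
#' @param n number of iterations (>= 1).
#' @param seed integer random seed.
#' @return a `psa_result`: list with `n`, `seed`, `strategies`, `cost` and
#'   `qaly` (n x strategy matrices), `wtp`, and `draws` (named matrix of the
#'   sampled parameter values).
#' @export
run_psa <- function(params, strategies, lifetable, n, seed) {
  stopifnot(n >= 1)
  validate_parameters(params)
  frame <- .psa_frame(params, strategies)
  set.seed(seed)
  draws <- matrix(NA_real_, n, nrow(frame),
                  dimnames = list(NULL, frame$name))
  for (i in seq_len(nrow(frame)))
    draws[, i] <- make_distribution(frame[i, ])$r(n)
  shared_names <- intersect(frame$name, params$specs$name)
  vals <- lapply(shared_names, function(nm) draws[, nm])
  names(vals) <- shared_names
  pv <- .model_pars(params, vals)
  S <- nrow(strategies)
  cost <- matrix(NA_real_, n, S, dimnames = list(NULL, strategies$name))
  qaly <- cost
  for (s in seq_len(S)) {
    nm <- strategies$name[s]
    sens <- if (paste0(nm, ".sensitivity") %in% colnames(draws))
      draws[, paste0(nm, ".sensitivity")] else strategies$sensitivity[s]
    spec <- if (paste0(nm, ".specificity") %in% colnames(draws))
      draws[, paste0(nm, ".specificity")] else strategies$specificity[s]
    ic <- if (paste0(nm, ".imaging_cost") %in% colnames(draws))
      draws[, paste0(nm, ".imaging_cost")] else strategies$imaging_cost[s]
    br <- .branches(sens, spec, ic, pv)
    eng <- .cohort_engine(.initial_state_masses(br), .upfront_cost(br),
                          pv, lifetable, trace = FALSE)
    cost[, s] <- eng$cost
    qaly[, s] <- eng$qaly
  }
  structure(list(n = n, seed = seed, strategies = strategies$name,
                 cost = cost, qaly = qaly, wtp = params$wtp, draws = draws),
            class = "psa_result")
}

# Winner per iteration at one WTP; ties broken lexicographically by strategy
# name (the same deterministic rule as the base-case ranking).
.psa_winner <- function(psa, wtp) {
  b <- wtp * psa$qaly - psa$cost
  ord <- order(psa$strategies)
  w <- max.col(b[, ord, drop = FALSE], ties.method = "first")
  psa$strategies[ord][w]
}

#' Acceptability of each strategy at one willingness-to-pay
#'
#' Fraction of PSA iterations in which each strategy has the maximal net
#' monetary benefit. Fractions sum to 1 across strategies.
#'
#' @param psa a `psa_result`.
#' @param wtp willingness-to-pay, USD/QALY.
#' @return named numeric vector of fractions, one per strategy.
#' @export
acceptability_at <- function(psa, wtp) {
  w <- .psa_winner(psa, wtp)
  out <- vapply(psa$strategies, function(s) mean(w == s), 0)
  names(out) <- psa$strategies
  out
}

#' Cost-effectiveness acceptability curves
#'
#' For every willingness-to-pay on the grid, the fraction of PSA iterations in
#' which each strategy is the argmax-NMB choice.
#'
#' @param psa a `psa_result`.
#' @param wtp_grid numeric vector of WTP values (default 0 to 200,000 by
#'   5,000).
#' @return data frame with column `wtp` and one acceptability column per
#'   strategy; each row sums to 1 across strategies.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2e5, by = 5e3)) {
  stopifnot(length(wtp_grid) >= 1)
  rows <- t(vapply(wtp_grid, function(w) acceptability_at(psa, w),
                   numeric(length(psa$strategies))))
  out <- data.frame(wtp = wtp_grid, rows, check.names = FALSE)
  names(out) <- c("wtp", psa$strategies)
  out
}

#' Export CEAC and PSA scatter data to CSV
#'
#' Writes the acceptability-curve grid (`wtp`, one column per strategy) and,
#' optionally, the per-iteration cost/QALY scatter
#' (`iteration,strategy,cost,qaly`).
#'
#' @param psa a `psa_result`.
#' @param ceac_path CSV path for the acceptability curves.
#' @param scatter_path optional CSV path for the per-iteration scatter.
#' @param wtp_grid WTP grid passed to [ceac()].
#' @return `ceac_path`, invisibly.
#' @export
export_psa <- function(psa, ceac_path, scatter_path = NULL,
                       wtp_grid = seq(0, 2e5, by = 5e3)) {
  utils::write.csv(ceac(psa, wtp_grid), ceac_path, row.names = FALSE)
  if (!is.null(scatter_path)) {
    sc <- data.frame(
      iteration = rep(seq_len(psa$n), times = length(psa$strategies)),
      strategy = rep(psa$strategies, each = psa$n),
      cost = as.vector(psa$cost),
      qaly = as.vector(psa$qaly)
    )
    utils::write.csv(sc, scatter_path, row.names = FALSE)
  }
  invisible(ceac_path)
}
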