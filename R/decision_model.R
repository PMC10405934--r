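# Diagnostic decision tree feeding a five-state annual-cycle Markov cohort
# model with age-dependent background mortality, discounting and cost/QALY
# accrual.
#
# States: TUMOR_FREE, UNDIAGNOSED_TUMOR (false negatives awaiting clinical
# detection), RESECTED (post hepatic resection), RECURRENCE (active disease
# after failed or recurred treatment), DEATH (absorbing).

#' Health-state labels of the cohort model
#' @return character vector of the five state names, in model order.
#' @export
health_states <- function() {
  c("TUMOR_FREE", "UNDIAGNOSED_TUMOR", "RESECTED", "RECURRENCE", "DEATH")
}

# Resolve all engine-level values from a parameter table, optionally overridden
# by sampled values (`vals`, scalars or equal-length vectors) for the PSA.
.model_pars <- function(params, vals = NULL) {
  gv <- function(nm) if (!is.null(vals[[nm]])) vals[[nm]] else param_value(params, nm)
  set <- params$settings
  p5 <- gv("p_recurrence_5y")
  p_rec <- if (set$recurrence_input == "cumulative_5y") {
    1 - (1 - p5)^(1 / 5)
  } else {
    p5
  }
  list(
    u_tf = gv("u_tumor_free"), u_ut = gv("u_undetected"),
    u_rs = gv("u_post_resection"), u_rc = gv("u_recurrence"),
    c_ut = if (set$undiagnosed_cost == "crlm") gv("annual_crlm_cost") else 0,
    c_rc = gv("annual_crlm_cost"),
    p_du = gv("p_death_untreated"), p_ts = gv("p_treatment_success"),
    p_detect = set$p_detect, p_rec = p_rec, p_met = gv("p_metastases"),
    rec_pathway = set$recurrence_pathway,
    resection_cost = gv("overall_resection_cost"),
    delayed_cost = gv("delayed_resection_cost"),
    fp_pathway = set$fp_pathway, fp_workup_cost = set$fp_workup_cost,
    horizon = params$horizon, discount_rate = params$discount_rate,
    cycle_length = params$cycle_length, start_age = params$start_age
  )
}

# The decision tree, as branch definitions shared by the cohort engine, the
# probabilistic analysis and the microsimulation oracle. All arithmetic
# vectorises over equal-length parameter draws.
.branches <- function(sensitivity, specificity, imaging_cost, pv) {
  pm <- pv$p_met; pts <- pv$p_ts
  fp_state <- if (pv$fp_pathway == "resection") "RESECTED" else "TUMOR_FREE"
  fp_cost <- if (pv$fp_pathway == "resection") {
    imaging_cost + pv$resection_cost
  } else {
    imaging_cost + pv$fp_workup_cost
  }
  list(
    tp_success = list(prob = pm * sensitivity * pts, state = "RESECTED",
                      cost = imaging_cost + pv$resection_cost),
    tp_failure = list(prob = pm * sensitivity * (1 - pts), state = "RECURRENCE",
                      cost = imaging_cost + pv$resection_cost),
    fn         = list(prob = pm * (1 - sensitivity), state = "UNDIAGNOSED_TUMOR",
                      cost = imaging_cost),
    tn         = list(prob = (1 - pm) * specificity, state = "TUMOR_FREE",
                      cost = imaging_cost),
    fp         = list(prob = (1 - pm) * (1 - specificity), state = fp_state,
                      cost = fp_cost)
  )
}

.initial_state_masses <- function(branches) {
  v <- stats::setNames(as.list(rep(0, 5)), health_states())
  for (b in branches) v[[b$state]] <- v[[b$state]] + b$prob
  v
}

.upfront_cost <- function(branches) {
  Reduce(`+`, lapply(branches, function(b) b$prob * b$cost))
}

#' Initial cohort allocation from the diagnostic decision tree
#'
#' Splits the cohort into true-positive, false-negative, true-negative and
#' false-positive branches according to disease prevalence and the strategy's
#' sensitivity/specificity. True positives undergo immediate hepatic resection
#' (success enters RESECTED, failure RECURRENCE) at the aggregate resection
#' cost; false negatives enter UNDIAGNOSED_TUMOR with only the imaging cost;
#' true negatives enter TUMOR_FREE; false positives either receive a
#' confirmatory work-up and enter TUMOR_FREE, or undergo an unnecessary
#' resection and enter RESECTED, depending on the `fp_pathway` setting.
#'
#' @param strategy one row of a `cea_strategies` data frame.
#' @param params a `cea_parameters` object.
#' @return a `cea_allocation`: list with branch masses `tp`, `fn`, `tn`, `fp`,
#'   a `branches` data frame (branch, probability, entry state, upfront cost)
#'   and the expected `upfront_cost`.
#' @export
#' @examples
#' bc <- builtin_basecase()
#' initial_allocation(bc$strategies[2, ], bc$params)
initial_allocation <- function(strategy, params) {
  pv <- .model_pars(params)
  br <- .branches(strategy$sensitivity, strategy$specificity,
                  strategy$imaging_cost, pv)
  masses <- vapply(br, function(b) b$prob, 0)
  stopifnot(abs(sum(masses) - 1) < 1e-12)
  structure(list(
    tp = unname(masses["tp_success"] + masses["tp_failure"]),
    fn = unname(masses["fn"]),
    tn = unname(masses["tn"]),
    fp = unname(masses["fp"]),
    branches = data.frame(
      branch = names(br),
      prob = unname(masses),
      state = vapply(br, function(b) b$state, ""),
      upfront_cost = vapply(br, function(b) b$cost, 0),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    upfront_cost = .upfront_cost(br)
  ), class = "cea_allocation")
}

# Transition rules shared by the cohort engine, the transition-matrix view and
# the microsimulation oracle: one definition of every transition probability
# and of the event cost charged when a delayed resection occurs. Disease-
# specific and background mortality combine independently,
# 1 - (1 - p_disease)(1 - q_background). Under the "salvage" recurrence
# pathway, patients with active recurrent disease are re-treated like detected
# untreated patients (successful salvage resection returns them to RESECTED at
# the delayed-resection cost); under "terminal" they persist in RECURRENCE
# until death.
.transition_rules <- function(pv, qb) {
  d_u <- 1 - (1 - pv$p_du) * (1 - qb)
  pd <- pv$p_detect
  rc_row <- if (identical(pv$rec_pathway, "salvage")) {
    list(RESECTED   = (1 - d_u) * pd * pv$p_ts,
         RECURRENCE = (1 - d_u) * (1 - pd * pv$p_ts),
         DEATH      = d_u)
  } else {
    list(RECURRENCE = 1 - d_u, DEATH = d_u)
  }
  M <- list(
    TUMOR_FREE = list(TUMOR_FREE = 1 - qb, DEATH = qb),
    UNDIAGNOSED_TUMOR = list(
      UNDIAGNOSED_TUMOR = (1 - d_u) * (1 - pd),
      RESECTED          = (1 - d_u) * pd * pv$p_ts,
      RECURRENCE        = (1 - d_u) * pd * (1 - pv$p_ts),
      DEATH             = d_u
    ),
    RESECTED = list(
      RESECTED   = (1 - qb) * (1 - pv$p_rec),
      RECURRENCE = (1 - qb) * pv$p_rec,
      DEATH      = qb
    ),
    RECURRENCE = rc_row,
    DEATH = list(DEATH = 1)
  )
  for (from in names(M)) {
    dev <- abs(Reduce(`+`, M[[from]]) - 1)
    if (max(dev) > 1e-12)
      stop("transition row '", from, "' deviates from sum 1 by ", max(dev))
  }
  ec <- list(UNDIAGNOSED_TUMOR = list(RESECTED = pv$delayed_cost,
                                      RECURRENCE = pv$delayed_cost))
  if (identical(pv$rec_pathway, "salvage"))
    ec$RECURRENCE <- list(RESECTED = pv$delayed_cost)
  list(M = M, event_cost = ec)
}

#' Per-cycle transition matrix of the cohort model
#'
#' Row-stochastic matrix over the five health states for the cycle in which the
#' cohort is `age` years old. DEATH is absorbing. Background mortality is taken
#' from the life table at `age`; in UNDIAGNOSED_TUMOR and RECURRENCE it
#' combines independently with the annual disease-specific death probability.
#' Undiagnosed patients are clinically detected with probability `p_detect`
#' per cycle and then undergo delayed resection (success to RESECTED, failure
#' to RECURRENCE); RESECTED transitions to RECURRENCE at the annualised
#' recurrence probability.
#'
#' @param params a `cea_parameters` object.
#' @param lifetable a `cea_lifetable` covering `age`.
#' @param age cohort age (years) during the cycle.
#' @return a 5x5 row-stochastic matrix with state dimnames.
#' @export
transition_matrix <- function(params, lifetable, age) {
  pv <- .model_pars(params)
  qb <- annual_mortality(lifetable, age)
  rules <- .transition_rules(pv, qb)
  st <- health_states()
  M <- matrix(0, 5, 5, dimnames = list(st, st))
  for (from in names(rules$M))
    for (to in names(rules$M[[from]]))
      M[from, to] <- rules$M[[from]][[to]]
  M
}

# The cohort recursion. `init` is a named list of five state masses and
# `upfront` the time-zero cost; both, and every entry of `pv`, may be scalars
# or equal-length vectors (one element per probabilistic draw). Cycle-t state
# accruals are discounted by (1+r)^-t with t = 0 undiscounted; the delayed-
# resection event cost of a transition out of UNDIAGNOSED_TUMOR between cycles
# t and t+1 is discounted at t+1 (in the trace it is attributed to the row of
# the cycle in which the transition was initiated).
.cohort_engine <- function(init, upfront, pv, lifetable, trace = FALSE) {
  H <- pv$horizon
  r <- pv$discount_rate
  cl <- pv$cycle_length
  st <- health_states()
  v <- init
  state_cost <- list(TUMOR_FREE = 0, UNDIAGNOSED_TUMOR = pv$c_ut,
                     RESECTED = 0, RECURRENCE = pv$c_rc, DEATH = 0)
  state_util <- list(TUMOR_FREE = pv$u_tf, UNDIAGNOSED_TUMOR = pv$u_ut,
                     RESECTED = pv$u_rs, RECURRENCE = pv$u_rc, DEATH = 0)
  total_cost <- 0
  total_qaly <- 0
  rows <- if (trace) vector("list", H) else NULL
  for (t in seq_len(H) - 1L) {
    disc <- (1 + r)^(-t)
    cyc_cost <- disc * Reduce(`+`, lapply(st, function(s) v[[s]] * state_cost[[s]]))
    cyc_qaly <- disc * cl * Reduce(`+`, lapply(st, function(s) v[[s]] * state_util[[s]]))
    if (t == 0) cyc_cost <- cyc_cost + upfront
    age <- pv$start_age + t * cl
    rules <- .transition_rules(pv, annual_mortality(lifetable, age))
    ev_cost <- 0
    for (from in names(rules$event_cost))
      for (to in names(rules$event_cost[[from]]))
        ev_cost <- ev_cost +
          v[[from]] * rules$M[[from]][[to]] * rules$event_cost[[from]][[to]]
    cyc_cost <- cyc_cost + ev_cost * (1 + r)^(-(t + 1))
    total_cost <- total_cost + cyc_cost
    total_qaly <- total_qaly + cyc_qaly
    if (trace) {
      occ <- vapply(st, function(s) v[[s]], 0)
      rows[[t + 1L]] <- c(cycle = t, age = age, occ,
                          cost = cyc_cost, qaly = cyc_qaly)
    }
    nv <- stats::setNames(as.list(rep(0, 5)), st)
    for (from in names(rules$M))
      for (to in names(rules$M[[from]]))
        nv[[to]] <- nv[[to]] + v[[from]] * rules$M[[from]][[to]]
    v <- nv
  }
  out <- list(cost = total_cost, qaly = total_qaly, final = v)
  if (trace) {
    tr <- as.data.frame(do.call(rbind, rows))
    tr$cum_cost <- cumsum(tr$cost)
    tr$cum_qaly <- cumsum(tr$qaly)
    out$trace <- tr
  }
  out
}

#' Run the Markov cohort model for one strategy
#'
#' Propagates the decision-tree allocation through the per-cycle transition
#' matrices over the configured horizon, accruing discounted costs and QALYs.
#' Time-zero (upfront) costs are undiscounted.
#'
#' @param strategy one row of a `cea_strategies` data frame.
#' @param params a `cea_parameters` object.
#' @param lifetable a `cea_lifetable` covering the cohort's ages.
#' @return list with `trace` (a `cohort_trace` data frame: cycle, age, state
#'   occupancies, discounted cycle cost/QALY, cumulative cost/QALY) and
#'   `result` (one-row data frame: strategy, cost, qaly).
#' @export
#' @examples
#' bc <- builtin_basecase()
#' lt <- synthetic_lifetable(0.013, 0.0935, 65:100)
#' run_cohort(bc$strategies[2, ], bc$params, lt)$result
run_cohort <- function(strategy, params, lifetable) {
  validate_parameters(params)
  pv <- .model_pars(params)
  br <- .branches(strategy$sensitivity, strategy$specificity,
                  strategy$imaging_cost, pv)
  init <- .initial_state_masses(br)
  eng <- .cohort_engine(init, .upfront_cost(br), pv, lifetable, trace = TRUE)
  occ_sum <- rowSums(eng$trace[, health_states()])
  if (max(abs(occ_sum - 1)) > 1e-12)
    stop("cohort occupancy lost mass (max deviation ",
         max(abs(occ_sum - 1)), ")")
  trace <- eng$trace
  class(trace) <- c("cohort_trace", "data.frame")
  result <- data.frame(strategy = strategy$name, cost = eng$cost,
                       qaly = eng$qaly, stringsAsFactors = FALSE)
  class(result) <- c("ce_result", "data.frame")
  list(trace = trace, result = result)
}

#' Run the cohort model for every strategy
#'
#' @param strategies a `cea_strategies` data frame.
#' @param params a `cea_parameters` object.
#' @param lifetable a `cea_lifetable`.
#' @return a `ce_result` data frame with one row per strategy
#'   (strategy, cost, qaly).
#' @export
run_strategies <- function(strategies, params, lifetable) {
  out <- do.call(rbind, lapply(seq_len(nrow(strategies)), function(i)
    run_cohort(strategies[i, ], params, lifetable)$result))
  class(out) <- c("ce_result", "data.frame")
  out
}

#' Export a cohort trace to CSV
#'
#' One row per cycle: cycle, age, occupancy per state, discounted cycle cost
#' and QALY, cumulative cost and QALY.
#'
#' @param trace a `cohort_trace` data frame from [run_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
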