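# Generators and oracles: random valid parameter tables, Gompertz-style
# synthetic life tables, and an individual-level microsimulation oracle used
# to validate the cohort engine. The oracle shares the decision-tree and
# transition-rule definitions with the cohort model (via initial_allocation()
# and transition_matrix()), so the two cannot drift apart silently.

#' Random valid model inputs
#'
#' Draws a complete parameter table and strategy set that pass validation:
#' probabilities in (0, 1), utilities in \[0, 1\], non-negative costs, and a
#' horizon/start age covered by the bundled life tables. Deterministic in the
#' seed. Intended for property-style testing of the downstream modules.
#'
#' @param seed integer seed.
#' @param n_strategies number of strategies to generate.
#' @param cost_scale approximate scale (USD) of the resection cost.
#' @param randomize_settings if `TRUE`, structural settings (detection
#'   probability, false-positive pathway, undiagnosed-state costing) are also
#'   drawn at random.
#' @return list with `params` and `strategies`.
#' @export
random_parameter_table <- function(seed, n_strategies = 3, cost_scale = 2e4,
                                   randomize_settings = TRUE) {
  set.seed(seed)
  ru <- function(lo, hi) stats::runif(1, lo, hi)
  resection <- cost_scale * ru(0.5, 2)
  u_post <- ru(0.5, 0.95)
  specs <- .make_spec_df(
    name = c("overall_resection_cost", "delayed_resection_cost",
             "annual_crlm_cost",
             "u_tumor_free", "u_post_resection", "u_recurrence", "u_undetected",
             "p_metastases", "p_treatment_success", "p_recurrence_5y",
             "p_death_untreated"),
    value = c(resection, 1.3 * resection, cost_scale * ru(1, 5),
              1, u_post, ru(0.3, u_post), ru(0.4, 0.95),
              ru(0.05, 0.6), ru(0.3, 0.95), ru(0.2, 0.9), ru(0.05, 0.5)),
    dist = c("gamma", "gamma", "gamma",
             "beta", "beta", "beta", "beta",
             "beta", "beta", "beta", "beta")
  )
  settings <- if (randomize_settings) {
    list(p_detect = ru(0.5, 1),
         fp_pathway = sample(c("confirmatory", "resection"), 1),
         fp_workup_cost = ru(0, 2000),
         undiagnosed_cost = sample(c("none", "crlm"), 1))
  } else {
    list()
  }
  params <- cea_parameters(
    specs,
    discount_rate = ru(0, 0.05), wtp = ru(2e4, 2e5),
    horizon = sample(3:15, 1), cycle_length = 1,
    start_age = sample(66:72, 1), settings = settings
  )
  strategies <- cea_strategies(
    name = paste0("S", seq_len(n_strategies)),
    sensitivity = stats::runif(n_strategies, 0.4, 0.99),
    specificity = stats::runif(n_strategies, 0.6, 0.99),
    imaging_cost = stats::runif(n_strategies, 300, 3000)
  )
  list(params = params, strategies = strategies)
}

#' Gompertz-style synthetic life table
#'
#' Annual mortality q(age) = min(1, base_rate * exp(slope * (age - min(age)))),
#' monotone non-decreasing in age. Used both as a test generator and to build
#' the bundled background-mortality fixture.
#'
#' @param base_rate annual death probability at the youngest age (> 0).
#' @param slope exponential increase per year of age (>= 0).
#' @param ages integer ages to cover (default 65:100).
#' @return a `cea_lifetable`.
#' @export
#' @examples
#' lt <- synthetic_lifetable(0.013, 0.0935)
#' annual_mortality(lt, 68)
synthetic_lifetable <- function(base_rate, slope, ages = 65:100) {
  stopifnot(base_rate > 0, slope >= 0)
  q <- pmin(1, base_rate * exp(slope * (ages - min(ages))))
  cea_lifetable(ages, q)
}

#' Individual-level microsimulation oracle for the cohort engine
#'
#' Simulates `n_patients` independent trajectories using exactly the same
#' decision-tree branches ([initial_allocation()]), transition matrices
#' ([transition_matrix()]), event costs, state costs/utilities and discounting
#' conventions as the cohort model, and returns sample means with standard
#' errors. By the law of large numbers the cohort model's expected cost and
#' QALYs must agree with the microsimulation means within Monte Carlo error;
#' this is a validation instrument, not a user-facing microsimulation.
#'
#' @param strategy one row of a `cea_strategies` data frame.
#' @param params a `cea_parameters` object.
#' @param lifetable a `cea_lifetable`.
#' @param n_patients number of simulated patients (>= 1).
#' @param seed integer seed.
#' @return list with `cost`, `qaly` (sample means), `sem_cost`, `sem_qaly`
#'   (standard errors) and `n`.
#' @export
microsim_oracle <- function(strategy, params, lifetable, n_patients, seed) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  pv <- .model_pars(params)
  alloc <- initial_allocation(strategy, params)
  br <- alloc$branches
  idx <- sample.int(nrow(br), n_patients, replace = TRUE, prob = br$prob)
  state <- match(br$state[idx], health_states())
  cost <- br$upfront_cost[idx]
  qaly <- numeric(n_patients)
  H <- params$horizon
  r <- params$discount_rate
  cl <- params$cycle_length
  state_cost <- c(0, pv$c_ut, 0, pv$c_rc, 0)
  state_util <- c(pv$u_tf, pv$u_ut, pv$u_rs, pv$u_rc, 0)
  delayed_from <- match("UNDIAGNOSED_TUMOR", health_states())
  delayed_to <- match(c("RESECTED", "RECURRENCE"), health_states())
  for (t in seq_len(H) - 1L) {
    disc <- (1 + r)^(-t)
    cost <- cost + disc * state_cost[state]
    qaly <- qaly + disc * cl * state_util[state]
    M <- transition_matrix(params, lifetable, pv$start_age + t * cl)
    cum <- t(apply(M, 1, cumsum))
    u <- stats::runif(n_patients)
    nxt <- integer(n_patients)
    for (s in 1:5) {
      in_s <- state == s
      if (any(in_s))
        nxt[in_s] <- 1L + findInterval(u[in_s], cum[s, 1:4])
    }
    ev <- state == delayed_from & nxt %in% delayed_to
    if (any(ev))
      cost[ev] <- cost[ev] + pv$delayed_cost * (1 + r)^(-(t + 1))
    state <- nxt
  }
  list(cost = mean(cost), qaly = mean(qaly),
       sem_cost = stats::sd(cost) / sqrt(n_patients),
       sem_qaly = stats::sd(qaly) / sqrt(n_patients),
       n = n_patients)
}
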