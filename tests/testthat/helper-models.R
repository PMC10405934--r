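# Shared test builders and independent oracles.

# A fully specified toy model: every parameter overridable, defaults chosen so
# degenerate analytic cases are easy to construct.
toy_inputs <- function(values = list(), settings = list(), horizon = 5L,
                       discount_rate = 0, cycle_length = 1, start_age = 65,
                       wtp = 1e5,
                       strategies = NULL) {
  base <- list(
    overall_resection_cost = 0, delayed_resection_cost = 0,
    annual_crlm_cost = 0,
    u_tumor_free = 1, u_post_resection = 1, u_recurrence = 1, u_undetected = 1,
    p_metastases = 0, p_treatment_success = 1, p_recurrence_5y = 0,
    p_death_untreated = 0
  )
  base[names(values)] <- values
  costs <- c("overall_resection_cost", "delayed_resection_cost",
             "annual_crlm_cost")
  specs <- data.frame(
    name = names(base),
    value = unlist(base, use.names = FALSE),
    dist = ifelse(names(base) %in% costs, "gamma", "beta"),
    dispersion = 0,
    stringsAsFactors = FALSE
  )
  set <- modifyList(list(fp_workup_cost = 0), settings)
  params <- cea_parameters(specs, discount_rate = discount_rate, wtp = wtp,
                           horizon = horizon, cycle_length = cycle_length,
                           start_age = start_age, settings = set)
  if (is.null(strategies))
    strategies <- cea_strategies("TEST", 1, 1, 0)
  list(params = params, strategies = strategies)
}

# Life table with constant annual mortality over a wide age span.
flat_lifetable <- function(q, ages = 40:140) cea_lifetable(ages, rep(q, length(ages)))

# Brute-force efficiency-frontier oracle: pairwise enumeration for strict
# dominance, exhaustive two-strategy blends for extended dominance.
frontier_oracle <- function(res) {
  n <- nrow(res)
  lab <- rep("on-frontier", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      strict <- res$cost[j] <= res$cost[i] && res$qaly[j] >= res$qaly[i] &&
        (res$cost[j] < res$cost[i] || res$qaly[j] > res$qaly[i])
      tie <- res$cost[j] == res$cost[i] && res$qaly[j] == res$qaly[i] &&
        res$strategy[j] < res$strategy[i]
      if (strict || tie) {
        lab[i] <- "dominated"
        break
      }
    }
  }
  for (i in which(lab == "on-frontier")) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (j == i || k == i || j == k) next
        if (res$qaly[j] <= res$qaly[i] && res$qaly[i] <= res$qaly[k] &&
            res$qaly[k] > res$qaly[j]) {
          lam <- (res$qaly[i] - res$qaly[j]) / (res$qaly[k] - res$qaly[j])
          blend <- (1 - lam) * res$cost[j] + lam * res$cost[k]
          if (blend < res$cost[i] - 1e-9) lab[i] <- "extendedly dominated"
        }
      }
    }
  }
  lab
}

# Inputs under the committed calibration configuration.
calibration_inputs <- function() {
  cfg <- load_run_config(calibration_config())
  inp <- crlmcea:::.resolve_inputs(cfg)
  inp$cfg <- cfg
  inp
}
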