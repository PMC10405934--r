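test_that("decision-tree allocation splits the cohort by accuracy and prevalence", {
  bc <- builtin_basecase()
  mri <- bc$strategies[bc$strategies$name == "MRI", ]
  al <- initial_allocation(mri, bc$params)
  expect_equal(al$tp, 0.275 * 0.8485)
  expect_equal(al$fn, 0.275 * (1 - 0.8485))
  expect_equal(al$tn, (1 - 0.275) * 0.9205)
  expect_equal(al$fp, (1 - 0.275) * (1 - 0.9205))
  expect_equal(al$tp + al$fn + al$tn + al$fp, 1, tolerance = 1e-12)
  expect_equal(sum(al$branches$prob), 1, tolerance = 1e-12)
  # frozen reference masses
  expect_equal(c(al$tp, al$fn, al$tn, al$fp),
               c(0.2333375, 0.0416625, 0.6673625, 0.0576375))

  # a perfect test puts all diseased mass in TP and none in FN/FP
  perfect <- cea_strategies("P", 1, 1, 100)
  alp <- initial_allocation(perfect, bc$params)
  expect_equal(alp$tp, 0.275)
  expect_equal(alp$tn, 0.725)
  expect_equal(alp$fn + alp$fp, 0)

  # with zero prevalence all mass is TN or FP regardless of sensitivity
  toy <- toy_inputs(values = list(p_metastases = 0),
                    strategies = cea_strategies("S", 0.3, 0.8, 10))
  al0 <- initial_allocation(toy$strategies, toy$params)
  expect_equal(al0$tn + al0$fp, 1)
  expect_equal(al0$tp + al0$fn, 0)
})

test_that("transition matrices are row-stochastic with absorbing death", {
  lt <- builtin_lifetable()
  for (settings in list(list(), list(recurrence_pathway = "salvage"),
                        list(p_detect = 0.6, undiagnosed_cost = "crlm"))) {
    bc <- builtin_basecase(settings = settings)
    for (age in c(68, 75, 90, 105)) {
      M <- transition_matrix(bc$params, lt, age)
      expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(unname(M["DEATH", ]), c(0, 0, 0, 0, 1))
    }
  }
})

test_that("disease and background mortality combine independently", {
  toy <- toy_inputs(values = list(p_death_untreated = 0.2417))
  lt <- flat_lifetable(0.02)
  M <- transition_matrix(toy$params, lt, 70)
  expect_equal(M["UNDIAGNOSED_TUMOR", "DEATH"],
               1 - (1 - 0.2417) * (1 - 0.02), tolerance = 1e-12)
  expect_equal(M["UNDIAGNOSED_TUMOR", "DEATH"], 0.256866, tolerance = 1e-9)
  expect_equal(M["RECURRENCE", "DEATH"], 0.256866, tolerance = 1e-9)
  expect_equal(M["TUMOR_FREE", "DEATH"], 0.02)
})

test_that("five-year cumulative recurrence is annualised as a constant hazard", {
  toy <- toy_inputs(values = list(p_recurrence_5y = 0.62))
  lt <- flat_lifetable(0)
  M <- transition_matrix(toy$params, lt, 70)
  expect_equal(M["RESECTED", "RECURRENCE"], 1 - (1 - 0.62)^(1 / 5),
               tolerance = 1e-12)
  expect_equal(M["RESECTED", "RECURRENCE"], 0.17594401, tolerance = 1e-7)
  # the five annualised steps recompose the cumulative probability
  expect_equal(1 - (1 - M["RESECTED", "RECURRENCE"])^5, 0.62,
               tolerance = 1e-12)
  # "annual" input mode uses the value as-is
  toy2 <- toy_inputs(values = list(p_recurrence_5y = 0.62),
                     settings = list(recurrence_input = "annual"))
  M2 <- transition_matrix(toy2$params, lt, 70)
  expect_equal(M2["RESECTED", "RECURRENCE"], 0.62)
})

test_that("with no mortality, unit utilities and no discounting QALYs equal the horizon", {
  toy <- toy_inputs(horizon = 5, discount_rate = 0,
                    values = list(p_metastases = 0.4, p_treatment_success = 0.5,
                                  p_recurrence_5y = 0.3),
                    strategies = cea_strategies("S", 0.7, 0.8, 0))
  out <- run_cohort(toy$strategies, toy$params, flat_lifetable(0))
  expect_equal(out$result$qaly, 5, tolerance = 1e-12)
})

test_that("discounted accrual matches the closed-form geometric sum", {
  # all mass enters RECURRENCE at t = 0 and stays; cost 100 per cycle
  toy <- toy_inputs(horizon = 2, discount_rate = 0.03,
                    values = list(p_metastases = 1, p_treatment_success = 0,
                                  annual_crlm_cost = 100),
                    strategies = cea_strategies("S", 1, 1, 0))
  out <- run_cohort(toy$strategies, toy$params, flat_lifetable(0))
  expect_equal(out$result$cost, 100 + 100 / 1.03, tolerance = 1e-9)
  expect_equal(out$result$cost, 197.0874, tolerance = 1e-4)
})

test_that("upfront imaging costs enter additively and undiscounted", {
  inp <- calibration_inputs()
  mri <- inp$strategies[inp$strategies$name == "MRI", ]
  base <- run_cohort(mri, inp$params, inp$lifetable)$result
  mri2 <- mri
  mri2$imaging_cost <- mri$imaging_cost + 250
  up <- run_cohort(mri2, inp$params, inp$lifetable)$result
  expect_equal(up$cost - base$cost, 250, tolerance = 1e-9)
  expect_equal(up$qaly, base$qaly)
})

test_that("trace satisfies conservation, death monotonicity and cumulative sums", {
  inp <- calibration_inputs()
  for (i in seq_len(nrow(inp$strategies))) {
    out <- run_cohort(inp$strategies[i, ], inp$params, inp$lifetable)
    tr <- out$trace
    expect_equal(unname(rowSums(tr[, health_states()])),
                 rep(1, nrow(tr)), tolerance = 1e-12)
    expect_true(all(diff(tr$DEATH) >= -1e-15))
    expect_equal(sum(tr$cost), out$result$cost, tolerance = 1e-9)
    expect_equal(sum(tr$qaly), out$result$qaly, tolerance = 1e-9)
    expect_equal(tr$cum_cost[nrow(tr)], out$result$cost, tolerance = 1e-9)
    expect_equal(tr$age, inp$params$start_age + tr$cycle)
    # QALYs cannot exceed the time horizon
    expect_lte(out$result$qaly, inp$params$horizon * inp$params$cycle_length)
  }
})

test_that("raising a state cost never lowers total cost; raising a utility never lowers QALYs", {
  lt <- builtin_lifetable()
  for (seed in 1:5) {
    rt <- random_parameter_table(seed)
    s <- rt$strategies[1, ]
    base <- run_cohort(s, rt$params, lt)$result
    up <- rt$params
    up$specs$value[up$specs$name == "annual_crlm_cost"] <-
      param_value(rt$params, "annual_crlm_cost") * 1.5
    rc <- run_cohort(s, up, lt)$result
    expect_gte(rc$cost, base$cost)
    uu <- rt$params
    uu$specs$value[uu$specs$name == "u_post_resection"] <-
      min(1, param_value(rt$params, "u_post_resection") + 0.1)
    rq <- run_cohort(s, uu, lt)$result
    expect_gte(rq$qaly, base$qaly)
  }
})

test_that("strategies with identical test characteristics give identical results", {
  bc <- builtin_basecase(horizon = 10)
  same <- cea_strategies(c("A", "B", "C"), rep(0.8, 3), rep(0.9, 3),
                        rep(700, 3))
  res <- run_strategies(same, bc$params, builtin_lifetable())
  expect_equal(res$cost, rep(res$cost[1], 3))
  expect_equal(res$qaly, rep(res$qaly[1], 3))
})

test_that("discounting vanishes smoothly as the rate goes to zero", {
  # single-state model: closed form sum_{t} c / (1+r)^t
  mk <- function(r) toy_inputs(horizon = 4, discount_rate = r,
                               values = list(p_metastases = 1,
                                             p_treatment_success = 0,
                                             annual_crlm_cost = 50),
                               strategies = cea_strategies("S", 1, 1, 0))
  lt <- flat_lifetable(0)
  for (r in c(0.1, 0.01, 1e-4, 0)) {
    out <- run_cohort(mk(r)$strategies, mk(r)$params, lt)$result
    expect_equal(out$cost, sum(50 / (1 + r)^(0:3)), tolerance = 1e-9)
  }
  r0 <- run_cohort(mk(0)$strategies, mk(0)$params, lt)$result
  expect_equal(r0$cost, 200)
})

test_that("trace export writes the documented per-cycle columns", {
  inp <- calibration_inputs()
  out <- run_cohort(inp$strategies[1, ], inp$params, inp$lifetable)
  path <- withr::local_tempfile(fileext = ".csv")
  export_trace(out$trace, path)
  df <- read.csv(path, check.names = FALSE)
  expect_true(all(c("cycle", "age", health_states(), "cost", "qaly",
                    "cum_cost", "cum_qaly") %in% names(df)))
  expect_equal(nrow(df), inp$params$horizon)
})
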