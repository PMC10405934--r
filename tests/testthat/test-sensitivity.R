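test_that("a parameter that cannot enter the computation has zero spread", {
  # with prevalence 1 there are no test negatives, so specificity is inert
  toy <- toy_inputs(values = list(p_metastases = 1, p_treatment_success = 0.6,
                                  annual_crlm_cost = 1000,
                                  p_death_untreated = 0.2),
                    strategies = cea_strategies(c("A", "B"), c(0.7, 0.9),
                                                c(0.8, 0.9), c(100, 300)))
  lt <- flat_lifetable(0.02)
  ow <- one_way("A.specificity", 0.5, 1, toy$params, toy$strategies, lt)
  expect_equal(ow$spread, 0)
  # sensitivity is not inert in the same model
  ow2 <- one_way("A.sensitivity", 0.5, 1, toy$params, toy$strategies, lt)
  expect_gt(ow2$spread, 0)
})

test_that("one-way analysis rejects inverted or out-of-range inputs", {
  inp <- calibration_inputs()
  expect_error(one_way("MRI.sensitivity", 0.9, 0.5, inp$params,
                       inp$strategies, inp$lifetable), "low")
  expect_error(one_way("MRI.sensitivity", 0.5, 1.2, inp$params,
                       inp$strategies, inp$lifetable), "legal range")
  expect_error(one_way("annual_crlm_cost", -10, 100, inp$params,
                       inp$strategies, inp$lifetable), "legal range")
  expect_error(one_way("not_a_parameter", 0, 1, inp$params,
                       inp$strategies, inp$lifetable), "unknown")
})

test_that("tornado covers every sampled parameter, sorted by spread", {
  inp <- calibration_inputs()
  tor <- tornado(inp$params, inp$strategies, inp$lifetable)
  # 10 uncertainty-carrying shared parameters (u_tumor_free is a fixed point)
  # plus 3 fields for each of 3 strategies
  expect_equal(nrow(tor), 10 + 9)
  expect_true(all(tor$spread >= 0))
  expect_true(all(diff(tor$spread) <= 1e-12))
  expect_true(all(tor$low <= tor$high))
})

test_that("widening a strategy parameter's range never shrinks its spread", {
  lt <- builtin_lifetable()
  for (seed in c(3, 11)) {
    rt <- random_parameter_table(seed)
    base <- run_strategies(rt$strategies, rt$params, lt)
    pair <- crlmcea:::.top_pair(base, rt$params$wtp)
    for (pname in paste0(pair[1], c(".sensitivity", ".imaging_cost"))) {
      fld <- sub("^.*\\.", "", pname)
      v <- rt$strategies[[fld]][rt$strategies$name == pair[1]]
      rng <- function(f) {
        lo <- max(0, v * (1 - f))
        hi <- if (fld == "imaging_cost") v * (1 + f) else min(1, v * (1 + f))
        one_way(pname, lo, hi, rt$params, rt$strategies, lt, pair = pair)$spread
      }
      expect_lte(rng(0.1), rng(0.2) + 1e-9)
      expect_lte(rng(0.2), rng(0.3) + 1e-9)
    }
  }
})

test_that("two-way winner map reduces to the base ranking and transposes consistently", {
  inp <- calibration_inputs()
  base_winner <- ce_choice(run_strategies(inp$strategies, inp$params,
                                          inp$lifetable), inp$params$wtp)
  cell <- two_way("CE-CT.sensitivity", "MRI.sensitivity",
                  0.6570, 0.8485, inp$params, inp$strategies, inp$lifetable)
  expect_equal(unname(cell[1, 1]), base_winner)
  expect_equal(base_winner, "MRI")

  gx <- c(0.5, 0.7, 0.95)
  gy <- c(0.5, 0.85)
  m1 <- two_way("CE-CT.sensitivity", "MRI.sensitivity", gx, gy,
                inp$params, inp$strategies, inp$lifetable)
  m2 <- two_way("MRI.sensitivity", "CE-CT.sensitivity", gy, gx,
                inp$params, inp$strategies, inp$lifetable)
  expect_identical(m1, t(m2))
})

test_that("a CE-CT region appears when its sensitivity overtakes MRI's", {
  inp <- calibration_inputs()
  m <- two_way("CE-CT.sensitivity", "MRI.sensitivity",
               c(0.657, 0.99), c(0.45, 0.8485),
               inp$params, inp$strategies, inp$lifetable)
  # base corner stays MRI; the high-CE-CT / low-MRI corner flips
  expect_equal(unname(m[1, 2]), "MRI")
  expect_equal(unname(m[2, 1]), "CE-CT")
})

test_that("PSA reruns with the same seed are bit-identical", {
  inp <- calibration_inputs()
  p1 <- run_psa(inp$params, inp$strategies, inp$lifetable, n = 200, seed = 5)
  p2 <- run_psa(inp$params, inp$strategies, inp$lifetable, n = 200, seed = 5)
  expect_identical(p1$cost, p2$cost)
  expect_identical(p1$qaly, p2$qaly)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(inp$params, inp$strategies, inp$lifetable, n = 200, seed = 6)
  expect_false(identical(p1$cost, p3$cost))
})

test_that("per-iteration PSA results equal a scalar cohort run on the same draws", {
  inp <- calibration_inputs()
  psa <- run_psa(inp$params, inp$strategies, inp$lifetable, n = 20, seed = 31)
  for (i in c(1, 7, 20)) {
    params_i <- inp$params
    shared <- intersect(colnames(psa$draws), params_i$specs$name)
    params_i$specs$value[match(shared, params_i$specs$name)] <-
      psa$draws[i, shared]
    for (s in seq_along(psa$strategies)) {
      nm <- psa$strategies[s]
      strat_i <- cea_strategies(
        nm,
        psa$draws[i, paste0(nm, ".sensitivity")],
        psa$draws[i, paste0(nm, ".specificity")],
        psa$draws[i, paste0(nm, ".imaging_cost")]
      )
      ref <- run_cohort(strat_i, params_i, inp$lifetable)$result
      expect_equal(psa$cost[i, nm], ref$cost, tolerance = 1e-9,
                   ignore_attr = TRUE)
      expect_equal(psa$qaly[i, nm], ref$qaly, tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("acceptability fractions partition the iterations at every WTP", {
  inp <- calibration_inputs()
  psa <- run_psa(inp$params, inp$strategies, inp$lifetable, n = 500, seed = 9)
  for (w in c(0, 2e4, 1e5, 2e5)) {
    a <- acceptability_at(psa, w)
    expect_equal(sum(a), 1, tolerance = 1e-12)
    expect_true(all(a >= 0 & a <= 1))
  }
  cc <- ceac(psa, seq(0, 2e5, by = 2.5e4))
  expect_equal(unname(rowSums(cc[, -1])), rep(1, nrow(cc)), tolerance = 1e-12)
})

test_that("winners at WTP zero are the per-iteration cheapest strategies", {
  rt <- random_parameter_table(17)
  lt <- builtin_lifetable()
  psa <- run_psa(rt$params, rt$strategies, lt, n = 300, seed = 12)
  a0 <- acceptability_at(psa, 0)
  cheapest <- apply(psa$cost, 1, function(x) {
    nm <- colnames(psa$cost)[x == min(x)]
    sort(nm)[1]
  })
  expect_equal(unname(a0[names(a0)]),
               unname(vapply(names(a0), function(s) mean(cheapest == s), 0)))
})

test_that("a degenerate PSA (all point masses) always picks the dominant strategy", {
  inp <- calibration_inputs()
  p0 <- inp$params
  p0$specs$dispersion <- 0
  p0$settings$dispersion_frac <- 0
  psa <- run_psa(p0, inp$strategies, inp$lifetable, n = 50, seed = 2)
  cc <- ceac(psa, seq(0, 2e5, by = 5e4))
  expect_true(all(cc$MRI == 1))
  expect_true(all(cc[["CE-CT"]] == 0))
})

test_that("cost-identical strategies split acceptability near one half", {
  toy <- toy_inputs(values = list(p_metastases = 0.3, p_treatment_success = 0.7,
                                  annual_crlm_cost = 2e4,
                                  overall_resection_cost = 2e4,
                                  delayed_resection_cost = 2.6e4,
                                  u_post_resection = 0.8, u_recurrence = 0.6,
                                  p_death_untreated = 0.2,
                                  p_recurrence_5y = 0.5),
                    discount_rate = 0.03, horizon = 10,
                    strategies = cea_strategies(c("A", "B"), c(0.8, 0.8),
                                                c(0.9, 0.9), c(500, 500)))
  lt <- builtin_lifetable()
  psa <- run_psa(toy$params, toy$strategies, lt, n = 4000, seed = 77)
  a <- acceptability_at(psa, 1e5)
  expect_equal(unname(a["A"]), 0.5, tolerance = 0.05)
  expect_equal(unname(a["B"]), 0.5, tolerance = 0.05)
})

test_that("tornado and PSA exports write the documented CSV shapes", {
  inp <- calibration_inputs()
  tor <- tornado(inp$params, inp$strategies, inp$lifetable)
  tpath <- withr::local_tempfile(fileext = ".csv")
  export_tornado(tor, tpath)
  tdf <- read.csv(tpath)
  expect_true(all(c("parameter", "low", "high", "metric_low", "metric_high",
                    "spread") %in% names(tdf)))

  psa <- run_psa(inp$params, inp$strategies, inp$lifetable, n = 50, seed = 4)
  cpath <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".csv")
  export_psa(psa, cpath, spath, wtp_grid = c(0, 1e5))
  cdf <- read.csv(cpath, check.names = FALSE)
  expect_named(cdf, c("wtp", psa$strategies))
  sdf <- read.csv(spath)
  expect_equal(nrow(sdf), 50 * 3)
  expect_named(sdf, c("iteration", "strategy", "cost", "qaly"))
})
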