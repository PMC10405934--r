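# Incremental cost-effectiveness ratios, dominance, the efficiency frontier
# and net monetary benefit.

#' Incremental cost-effectiveness ratio of one strategy against a reference
#'
#' ICER = (e1 - e0) / (q1 - q0), where e are total expected costs and q total
#' expected QALYs. A strategy that is cheaper and more effective than the
#' reference is flagged `dominant`; costlier and less effective, `dominated`.
#' With equal effectiveness the ratio is undefined and the cheaper strategy is
#' preferred; identical cost and effectiveness is a `tie`.
#'
#' @param new,ref one-row `ce_result` data frames (strategy, cost, qaly).
#' @return an `icer_result` list: `new`, `ref`, `delta_cost`, `delta_qaly`,
#'   `icer` (USD/QALY, `NA` when flagged) and `flag` (one of `"icer"`,
#'   `"dominant"`, `"dominated"`, `"undefined"`, `"tie"`).
#' @export
#' @examples
#' a <- data.frame(strategy = "PET/CT", cost = 43216.74, qaly = 8.48)
#' b <- data.frame(strategy = "CE-CT", cost = 42874.02, qaly = 8.47)
#' icer(a, b)$icer  # 34272
icer <- function(new, ref) {
  dc <- new$cost - ref$cost
  dq <- new$qaly - ref$qaly
  if (dc == 0 && dq == 0) {
    flag <- "tie"; ratio <- NA_real_
  } else if (dq == 0) {
    flag <- "undefined"; ratio <- NA_real_
  } else if (dc < 0 && dq > 0) {
    flag <- "dominant"; ratio <- NA_real_
  } else if (dc > 0 && dq < 0) {
    flag <- "dominated"; ratio <- NA_real_
  } else {
    flag <- "icer"; ratio <- dc / dq
  }
  structure(list(new = new$strategy, ref = ref$strategy,
                 delta_cost = dc, delta_qaly = dq,
                 icer = ratio, flag = flag),
            class = "icer_result")
}

#' Net monetary benefit
#'
#' NMB = WTP x QALYs - cost. At a given willingness-to-pay the strategy with
#' maximal NMB is the cost-effective choice.
#'
#' @param result a `ce_result` data frame (any number of rows).
#' @param wtp willingness-to-pay, USD/QALY (>= 0).
#' @return numeric NMB, one value per row of `result`.
#' @export
nmb <- function(result, wtp) {
  stopifnot(wtp >= 0)
  wtp * result$qaly - result$cost
}

# Deterministic tie-break shared with the PSA: lower cost, then higher QALYs,
# then lexicographically smaller strategy name.
.order_results <- function(results) {
  order(results$cost, -results$qaly, results$strategy)
}

#' Efficiency-frontier ranking of strategies
#'
#' Sorts strategies by cost and labels each as `on-frontier`, `dominated`
#' (some other strategy has no higher cost and no lower effectiveness, at
#' least one strictly) or `extendedly dominated` (removed by the standard
#' sweep that enforces strictly increasing incremental ICERs along the
#' frontier). Exact cost/QALY ties are broken lexicographically by name; the
#' later name is labelled dominated.
#'
#' @param results a `ce_result` data frame with one row per strategy.
#' @return the input rows sorted by cost with added columns `label`,
#'   `inc_cost`, `inc_qaly` and `icer` (incremental to the previous
#'   frontier strategy; `NA` for the cheapest frontier strategy and for
#'   non-frontier rows).
#' @export
efficiency_frontier <- function(results) {
  stopifnot(nrow(results) >= 1)
  res <- results[.order_results(results), , drop = FALSE]
  n <- nrow(res)
  label <- rep("on-frontier", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      leq_cost <- res$cost[j] <= res$cost[i]
      geq_qaly <- res$qaly[j] >= res$qaly[i]
      strict <- res$cost[j] < res$cost[i] || res$qaly[j] > res$qaly[i]
      tie <- res$cost[j] == res$cost[i] && res$qaly[j] == res$qaly[i] &&
        res$strategy[j] < res$strategy[i]
      if ((leq_cost && geq_qaly && strict) || tie) {
        label[i] <- "dominated"
        break
      }
    }
  }
  # extended dominance: repeatedly drop the strategy whose incremental ICER
  # exceeds that of the next more effective frontier strategy
  repeat {
    idx <- which(label == "on-frontier")
    if (length(idx) < 3) break
    ic <- diff(res$cost[idx]) / diff(res$qaly[idx])
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    label[idx[bad[1] + 1L]] <- "extendedly dominated"
  }
  res$label <- label
  res$inc_cost <- NA_real_
  res$inc_qaly <- NA_real_
  res$icer <- NA_real_
  idx <- which(label == "on-frontier")
  if (length(idx) > 1) {
    for (k in 2:length(idx)) {
      i <- idx[k]; p <- idx[k - 1]
      res$inc_cost[i] <- res$cost[i] - res$cost[p]
      res$inc_qaly[i] <- res$qaly[i] - res$qaly[p]
      res$icer[i] <- res$inc_cost[i] / res$inc_qaly[i]
    }
  }
  rownames(res) <- NULL
  res
}

#' The cost-effective strategy at a willingness-to-pay
#'
#' Argmax-NMB choice with the deterministic tie-break (lower cost, higher
#' QALYs, then lexicographic name).
#'
#' @inheritParams nmb
#' @return the winning strategy name.
#' @export
ce_choice <- function(result, wtp) {
  b <- nmb(result, wtp)
  cand <- which(b == max(b))
  if (length(cand) > 1) cand <- cand[.order_results(result[cand, ])[1]]
  result$strategy[cand]
}

#' Export a cost-effectiveness ranking table to CSV
#'
#' Columns: strategy, cost, incremental cost, QALYs, incremental QALYs,
#' ICER or dominance label.
#'
#' @param frontier output of [efficiency_frontier()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_ranking <- function(frontier, path) {
  out <- data.frame(
    strategy = frontier$strategy,
    cost = frontier$cost,
    inc_cost = frontier$inc_cost,
    qaly = frontier$qaly,
    inc_qaly = frontier$inc_qaly,
    icer = ifelse(frontier$label == "on-frontier",
                  ifelse(is.na(frontier$icer), "", as.character(frontier$icer)),
                  frontier$label),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
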