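#' Net monetary benefit
#'
#' `wtp * qaly - cost`: the strategy maximising net monetary benefit at a
#' willingness-to-pay threshold is the cost-effective choice.
#'
#' @param cost Cost in USD (vectorised).
#' @param qaly QALYs (vectorised).
#' @param wtp Willingness-to-pay threshold, USD/QALY (>= 0).
#' @return Net monetary benefit in USD.
#' @export
nmb <- function(cost, qaly, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * qaly - cost
}

#' Cost-effectiveness frontier with strong and extended dominance
#'
#' Ranks strategies by ascending cost and computes incremental
#' cost-effectiveness ratios (ICERs) against the next least-costly
#' non-dominated strategy. A strategy is *strongly dominated* if another
#' yields more QALYs at lower or equal cost; it is *weakly (extendedly)
#' dominated* if its ICER exceeds that of a more effective strategy.
#' Dominated strategies are removed and ICERs recomputed until the surviving
#' ICER sequence is increasing. The surviving strategy with the highest ICER
#' at or below the willingness-to-pay threshold (or the cheapest survivor if
#' none) is flagged cost-effective.
#'
#' Ties in cost are broken by higher QALYs, then by strategy label, so output
#' is deterministic and invariant to input order.
#'
#' @param outcomes List of `strategy_outcome` objects (or a data.frame with
#'   columns `strategy`, `cost`, `qaly`).
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return A data.frame with columns `strategy`, `cost`, `qaly`, `incr_cost`,
#'   `incr_qaly`, `icer`, `status` (`"on_frontier"`, `"strongly_dominated"`,
#'   `"weakly_dominated"`) and `cost_effective` (logical; exactly one `TRUE`).
#' @export
icer_frontier <- function(outcomes, wtp = 150000) {
  df <- if (is.data.frame(outcomes)) {
    outcomes[, c("strategy", "cost", "qaly")]
  } else {
    do.call(rbind, lapply(outcomes, function(o)
      data.frame(strategy = o$strategy, cost = o$disc_cost,
                 qaly = o$disc_qaly, stringsAsFactors = FALSE)))
  }
  stopifnot(nrow(df) >= 1)
  df <- df[order(df$cost, -df$qaly, df$strategy), ]
  rownames(df) <- NULL
  df$status <- "on_frontier"

  # strong dominance: fewer (or equal) QALYs at higher (or equal) cost than
  # some other strategy (ties resolved by the deterministic sort above)
  for (i in seq_len(nrow(df))) {
    others <- df[-i, , drop = FALSE]
    if (any(others$qaly >= df$qaly[i] & others$cost <= df$cost[i] &
            !(others$qaly == df$qaly[i] & others$cost == df$cost[i]))) {
      df$status[i] <- "strongly_dominated"
    } else if (any(others$qaly == df$qaly[i] & others$cost == df$cost[i])) {
      # exact tie: the sort's first occurrence survives
      first <- which(df$qaly == df$qaly[i] & df$cost == df$cost[i])[1]
      if (first != i) df$status[i] <- "strongly_dominated"
    }
  }

  # extended dominance: drop survivors whose ICER exceeds the next ICER
  repeat {
    on <- which(df$status == "on_frontier")
    if (length(on) <= 2) break
    icers <- diff(df$cost[on]) / diff(df$qaly[on])
    bad <- which(diff(icers) < 0)
    if (!length(bad)) break
    df$status[on[bad[1] + 1]] <- "weakly_dominated"
  }

  df$incr_cost <- df$incr_qaly <- df$icer <- NA_real_
  on <- which(df$status == "on_frontier")
  if (length(on) > 1) {
    df$incr_cost[on[-1]] <- diff(df$cost[on])
    df$incr_qaly[on[-1]] <- diff(df$qaly[on])
    df$icer[on[-1]] <- df$incr_cost[on[-1]] / df$incr_qaly[on[-1]]
  }

  df$cost_effective <- FALSE
  below <- on[!is.na(df$icer[on]) & df$icer[on] <= wtp]
  pick <- if (length(below)) below[length(below)] else on[1]
  df$cost_effective[pick] <- TRUE
  df[, c("strategy", "cost", "qaly", "incr_cost", "incr_qaly", "icer",
         "status", "cost_effective")]
}

#' Round an ICER for display
#'
#' The published tables round ICERs to the nearest $1,000; internal values
#' stay unrounded.
#'
#' @param icer ICER in USD/QALY.
#' @param to Rounding unit (default $1,000).
#' @return Rounded value.
#' @export
round_icer <- function(icer, to = 1000) round(icer / to) * to
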