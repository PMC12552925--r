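#' Model run settings
#'
#' Bundles the simulation conventions: monthly cycles, a lifetime horizon
#' capped at age 100, a 3% annual discount rate and a willingness-to-pay
#' threshold of $150,000/QALY (the value-of-information analysis instead uses
#' the threshold at the peak of decision uncertainty, $115,000/QALY by
#' default).
#'
#' @param cycle_length Cycle length in years (1/12 = monthly).
#' @param start_age Cohort age at cycle 0.
#' @param max_age Age at which the horizon is truncated.
#' @param discount_rate Annual discount rate.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @param voi_wtp Threshold used for value-of-information summaries.
#' @param life_table Background-mortality table.
#' @return A `cea_settings` list; `horizon_cycles` is derived.
#' @export
cea_settings <- function(cycle_length = 1 / 12, start_age = 66, max_age = 100,
                         discount_rate = 0.03, wtp = 150000, voi_wtp = 115000,
                         life_table = make_life_table()) {
  stopifnot(cycle_length > 0, max_age > start_age)
  horizon_cycles <- ceiling((max_age - start_age) / cycle_length)
  ages <- start_age + (seq_len(horizon_cycles) - 1) * cycle_length
  structure(
    list(cycle_length = cycle_length, start_age = start_age, max_age = max_age,
         discount_rate = discount_rate, wtp = wtp, voi_wtp = voi_wtp,
         life_table = life_table, horizon_cycles = horizon_cycles,
         q_cycles = background_mortality(ages, life_table, cycle_length)),
    class = "cea_settings"
  )
}

#' Lifetime outcomes of one imaging strategy
#'
#' Runs the full pipeline for a single strategy and parameter-value vector:
#' decision tree ([classify_cohort()]), initial state assignment
#' ([assign_initial_states()]), one Markov cohort per detection pathway
#' (early / delayed / false-negative, each with its hazard-ratio modifiers),
#' and economic accumulation ([accumulate_outcomes()]), weighting pathway
#' results by their cohort fractions.
#'
#' @param values Named parameter values (one stratum-resolved draw or the
#'   point estimates).
#' @param strategy One of [strategies()].
#' @param settings A [cea_settings()].
#' @param stratum Stratum label carried through to the output.
#' @return A `strategy_outcome`: list with `strategy`, `stratum`,
#'   `disc_cost`, `disc_qaly`, `undisc_cost`, `undisc_qaly`.
#' @export
run_strategy <- function(values, strategy, settings = cea_settings(),
                         stratum = "base") {
  dist <- classify_cohort(strategy, values, stratum)
  pathways <- assign_initial_states(dist, values)
  vm <- value_map(values)
  out <- c(disc_cost = 0, disc_qaly = 0, undisc_cost = 0, undisc_qaly = 0)
  for (pw in pathways) {
    builder <- transition_builder(
      values, pathway_modifiers(pw$modifier, values),
      start_age = settings$start_age, cycle_length = settings$cycle_length,
      horizon_cycles = settings$horizon_cycles,
      life_table = settings$life_table, q_cycles = settings$q_cycles
    )
    trace <- run_cohort(pw$init, builder)
    acc <- accumulate_outcomes(trace, vm, rate = settings$discount_rate)
    out <- out + pw$weight * unlist(acc)[names(out)]
  }
  out[["disc_cost"]] <- out[["disc_cost"]] + dist$imaging_cost
  out[["undisc_cost"]] <- out[["undisc_cost"]] + dist$imaging_cost
  structure(c(list(strategy = strategy, stratum = stratum), as.list(out)),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s (stratum %s): $%.0f, %.3f QALYs (discounted)\n",
              x$strategy, x$stratum, x$disc_cost, x$disc_qaly))
  invisible(x)
}

#' Deterministic (point-estimate) analysis
#'
#' Runs every strategy at the parameter point estimates for each requested
#' stratum and ranks them on the cost-effectiveness frontier.
#'
#' @param set A `parameter_set` (default: the shipped reference inputs).
#' @param strata Strata to analyse (subset of [psa_strata()]).
#' @param settings A [cea_settings()].
#' @return A data.frame with one row per strategy and stratum: discounted and
#'   undiscounted cost and QALYs plus the frontier columns of
#'   [icer_frontier()].
#' @export
run_deterministic <- function(set = reference_parameters(),
                              strata = psa_strata(),
                              settings = cea_settings()) {
  rows <- lapply(strata, function(st) {
    values <- point_estimates(set, st)
    outcomes <- lapply(strategies(), function(sg)
      run_strategy(values, sg, settings, stratum = st))
    fr <- icer_frontier(outcomes, wtp = settings$wtp)
    extra <- do.call(rbind, lapply(outcomes, function(o)
      data.frame(strategy = o$strategy, undisc_cost = o$undisc_cost,
                 undisc_qaly = o$undisc_qaly, stringsAsFactors = FALSE)))
    out <- merge(fr, extra, by = "strategy", sort = FALSE)
    out$stratum <- st
    out
  })
  do.call(rbind, rows)
}
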