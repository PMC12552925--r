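#' Discount factor
#'
#' `(1 + rate)^(-time)`, continuous in the cycle time.
#'
#' @param time Time in years (vectorised).
#' @param rate Annual discount rate (fraction, >= 0); the reference analysis
#'   uses 3%.
#' @return Discount factor(s).
#' @examples
#' discount_factor(1, 0.03) # 0.970874
#' @export
discount_factor <- function(time, rate = 0.03) {
  stopifnot(rate >= 0)
  (1 + rate)^(-time)
}

#' Utilities, recurring costs and one-off costs per health state
#'
#' Maps parameter values to the economic inputs of the accumulator:
#' \itemize{
#'   \item utilities per state-year (death states 0);
#'   \item recurring annual costs: state 4 carries ADT (systemic treatment of
#'     localized disease), state 6 ADT + ARSI, state 7 ADT, state 8 the mCRPC
#'     recipe — ADT plus a configurable ARSI/docetaxel mix
#'     (`share_mcrpc_arsi`);
#'   \item one-off costs charged on state entry: state 3 a local-therapy mix
#'     (mean of salvage prostatectomy, radiation and cryotherapy), state 7
#'     the metastasis-directed-therapy procedure.
#' }
#'
#' @param values Named parameter values.
#' @return A `value_map`: list with numeric length-10 vectors `utility`,
#'   `cost_annual`, `cost_entry`.
#' @export
value_map <- function(values) {
  u <- c(.get(values, "u_nrd"), .get(values, "u_loc_no_tx"),
         .get(values, "u_loc_local_tx"), .get(values, "u_loc_systemic"),
         .get(values, "u_nrd_after_local"), .get(values, "u_met_adt_arsi"),
         .get(values, "u_met_mdt"), .get(values, "u_mcrpc"), 0, 0)
  stopifnot(all(u >= 0), all(u <= 1))
  adt <- .get(values, "cost_adt")
  arsi <- .get(values, "cost_arsi")
  share <- .get(values, "share_mcrpc_arsi")
  c_annual <- c(0, 0, 0, adt, 0,
                adt + arsi, adt,
                adt + share * arsi + (1 - share) * .get(values, "cost_docetaxel"),
                0, 0)
  local_mix <- mean(c(.get(values, "cost_prostatectomy"),
                      .get(values, "cost_radiation"),
                      .get(values, "cost_cryotherapy")))
  c_entry <- c(0, 0, local_mix, 0, 0, 0, .get(values, "cost_mdt"), 0, 0, 0)
  names(u) <- names(c_annual) <- names(c_entry) <- health_states()
  structure(list(utility = u, cost_annual = c_annual, cost_entry = c_entry),
            class = "value_map")
}

#' Discounted lifetime outcomes from a cohort trace
#'
#' Accumulates quality-adjusted life-years and costs over a trace with
#' half-cycle (trapezoidal) correction for state-membership quantities:
#' `QALY = sum_t w_t d(t) sum_s occ(t, s) u(s) cycle_years` with
#' `w_0 = w_T = 1/2`, and recurring costs analogously. One-off costs (imaging
#' at cycle 0, local therapy and metastasis-directed therapy on state entry)
#' are charged at the entry time, discounted but not half-cycle corrected.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param values A [value_map()] (or named parameter values, converted
#'   internally).
#' @param rate Annual discount rate.
#' @param imaging_cost Per-patient up-front imaging cost charged at cycle 0.
#' @return A list with `disc_cost`, `disc_qaly`, `undisc_cost`,
#'   `undisc_qaly`.
#' @export
accumulate_outcomes <- function(trace, values, rate = 0.03, imaging_cost = 0) {
  stopifnot(inherits(trace, "cohort_trace"))
  vm <- if (inherits(values, "value_map")) values else value_map(values)
  occ <- trace$occupancy
  ent <- trace$entries
  if (ncol(occ) != length(vm$utility)) stop("state sets do not match")
  cl <- trace$cycle_length
  tt <- (seq_len(nrow(occ)) - 1) * cl
  w <- rep(1, nrow(occ)); w[1] <- w[length(w)] <- 0.5
  d <- discount_factor(tt, rate)

  per_cycle_q <- as.vector(occ %*% vm$utility) * cl
  per_cycle_c <- as.vector(occ %*% vm$cost_annual) * cl
  entry_c <- as.vector(pmax(ent, 0) %*% vm$cost_entry)

  list(
    disc_qaly = sum(w * d * per_cycle_q),
    disc_cost = sum(w * d * per_cycle_c) + sum(d * entry_c) + imaging_cost,
    undisc_qaly = sum(w * per_cycle_q),
    undisc_cost = sum(w * per_cycle_c) + sum(entry_c) + imaging_cost
  )
}
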