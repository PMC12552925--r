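#' Apply a hazard ratio to a per-cycle transition probability
#'
#' Hazard ratios act on the log-survival scale:
#' `p' = 1 - (1 - p)^hr`, equivalent to scaling the constant rate implied by
#' `p` within the cycle. A probability of exactly 1 has no finite rate and is
#' rejected unless the hazard ratio is 1.
#'
#' @param p_base Per-cycle probability in \[0, 1).
#' @param hr Hazard ratio (> 0).
#' @return Adjusted per-cycle probability.
#' @examples
#' adjust_probability(0.0227, 0.56) # 0.012776
#' @export
adjust_probability <- function(p_base, hr) {
  stopifnot(all(hr > 0), all(p_base >= 0), all(p_base <= 1))
  if (any(p_base == 1 & hr != 1)) {
    stop("cannot apply a hazard ratio to a certain event (p = 1)")
  }
  1 - (1 - p_base)^hr
}

#' Convert a probability between time scales
#'
#' `prob_rescale(p, f)` converts a probability over one period to the
#' equivalent probability over `f` periods under a constant hazard:
#' `1 - (1 - p)^f`. Annual-to-monthly conversion uses `f = 1/12`.
#'
#' @param p Probability in \[0, 1\].
#' @param f Ratio of target to source period length.
#' @return Rescaled probability.
#' @export
prob_rescale <- function(p, f) 1 - (1 - p)^f

#' Per-cycle background mortality at a given age
#'
#' Linear interpolation of the annual death probability in a life table
#' (columns `age`, `qx`), converted to the cycle length under a constant
#' within-year hazard.
#'
#' @param age Age in years (may be fractional); must lie within the table.
#' @param life_table Data frame with columns `age` and `qx`, e.g.
#'   [make_life_table()].
#' @param cycle_length Cycle length in years (1/12 for monthly cycles).
#' @return Per-cycle death probability (vectorised over `age`).
#' @export
background_mortality <- function(age, life_table = make_life_table(),
                                 cycle_length = 1 / 12) {
  if (any(age < min(life_table$age)) || any(age > max(life_table$age))) {
    stop("age outside the life table range [", min(life_table$age), ", ",
         max(life_table$age), "]")
  }
  q_annual <- stats::approx(life_table$age, life_table$qx, xout = age,
                            rule = 1)$y
  prob_rescale(q_annual, cycle_length)
}

#' Hazard-ratio modifiers for a detection pathway
#'
#' @param pathway `"early"` (disease detected by PSMA-PET: the early- vs
#'   delayed-treatment hazard ratio applies to disease-progression
#'   transitions), `"delayed"` (CTBS-detected or disease-free: baseline
#'   hazards), or `"false_negative"` (disease missed by CTBS: the increased
#'   progression hazard ratio applies for the lifetime of the pathway).
#' @param values Named parameter values supplying `hr_early`,
#'   `hr_false_negative` and `hr_mdt`.
#' @return List with `hr_progression` (applied to developing-disease,
#'   localized-to-metastatic and metastatic-to-mCRPC transitions) and
#'   `hr_mdt` (additional reduction on the metastasis-directed-therapy state's
#'   progression, applied multiplicatively).
#' @export
pathway_modifiers <- function(pathway, values) {
  pathway <- match.arg(pathway, c("early", "delayed", "false_negative"))
  hr <- switch(pathway,
    early = .get(values, "hr_early"),
    delayed = 1,
    false_negative = .get(values, "hr_false_negative")
  )
  list(hr_progression = hr, hr_mdt = .get(values, "hr_mdt"))
}

# Disease-transition matrix conditional on surviving background mortality for
# the cycle: 10 x 10, rows 9/10 identity. Age-independent, so it is built
# once per pathway and reused for every cycle.
.disease_matrix <- function(values, modifiers, cycle_length = 1 / 12) {
  hr <- modifiers$hr_progression
  hr_mdt <- modifiers$hr_mdt
  cl <- cycle_length
  mo <- function(name) prob_rescale(.get(values, name), cl)

  split <- .norm_block(c(.get(values, "p_loc_given_detect"),
                         .get(values, "p_met_given_detect")))
  tx_loc <- .norm_block(c(.get(values, "tx_loc_no_treatment"),
                          .get(values, "tx_loc_local"),
                          .get(values, "tx_loc_systemic")))
  tx_met <- .norm_block(c(.get(values, "tx_met_adt_arsi"),
                          .get(values, "tx_met_mdt")))

  s <- health_states()
  P <- matrix(0, 10, 10, dimnames = list(s, s))

  # state 1: develop localized or metastatic disease
  p_dev <- adjust_probability(mo("p_nrd_develop_disease"), hr)
  P[1, 2:4] <- p_dev * split[[1]] * tx_loc
  P[1, 6:7] <- p_dev * split[[2]] * tx_met
  # localized disease: progression to metastatic (by treatment state)
  p26 <- adjust_probability(mo("p_loc_progress_no_tx"), hr)
  P[2, 6:7] <- p26 * tx_met
  p36 <- adjust_probability(mo("p_loc_progress_local_tx"), hr)
  P[3, 6:7] <- p36 * tx_met
  P[3, 5] <- prob_rescale(.get(values, "p_loc_local_cure"), cl)
  p46 <- adjust_probability(mo("p_loc_progress_systemic"), hr)
  P[4, 6:7] <- p46 * tx_met
  # disease-free after local treatment: metastasis risk (baseline hazard;
  # the early/delayed contrast concerns detection of the presenting disease)
  P[5, 6:7] <- mo("p_met_after_local_nrd") * tx_met
  # metastatic -> mCRPC; metastasis-directed therapy lowers the hazard
  P[6, 8] <- adjust_probability(mo("p_met_to_mcrpc"), hr)
  P[7, 8] <- adjust_probability(mo("p_met_to_mcrpc"), hr * hr_mdt)
  # mCRPC -> prostate-cancer death (only route to state 9)
  P[8, 9] <- mo("p_mcrpc_death")

  diag_res <- 1 - rowSums(P)
  if (any(diag_res < -1e-12)) {
    stop("transition probabilities out of state '",
         s[which(diag_res < -1e-12)[1]], "' exceed 1")
  }
  diag(P) <- pmax(diag_res, 0)
  P
}

#' Build a transition-matrix generator for a pathway
#'
#' Returns a `transition_builder`: a per-cycle generator combining the
#' age-independent disease-transition matrix with age-specific background
#' mortality, competing-risk style — background mortality is applied first
#' each cycle and disease transitions operate on the survivors:
#' `M(t) = q(t) * (-> state 10) + (1 - q(t)) * P_disease` on every living
#' state's row. Both the cohort engine and the micro-simulation oracle
#' consume this one code path.
#'
#' @param values Named parameter values (stratum-resolved).
#' @param modifiers Output of [pathway_modifiers()].
#' @param start_age Age at cycle 0 (years).
#' @param cycle_length Cycle length in years.
#' @param horizon_cycles Number of cycles to cover.
#' @param life_table Background-mortality table (see [make_life_table()]).
#' @param q_cycles Optional precomputed per-cycle background-mortality vector
#'   (length `horizon_cycles`); bypasses the life-table lookup when many
#'   builders share one age grid.
#' @return A `transition_builder`; calling it with a cycle index (0-based)
#'   returns the 10 x 10 stochastic matrix for that cycle.
#' @export
transition_builder <- function(values, modifiers, start_age = 66,
                               cycle_length = 1 / 12, horizon_cycles = 408,
                               life_table = make_life_table(),
                               q_cycles = NULL) {
  P <- .disease_matrix(values, modifiers, cycle_length)
  qv <- if (!is.null(q_cycles)) {
    stopifnot(length(q_cycles) == horizon_cycles)
    q_cycles
  } else {
    ages <- start_age + (seq_len(horizon_cycles) - 1) * cycle_length
    background_mortality(ages, life_table, cycle_length)
  }
  f <- function(cycle) {
    stopifnot(cycle >= 0, cycle < horizon_cycles)
    q <- qv[cycle + 1]
    M <- (1 - q) * P
    M[, 10] <- M[, 10] + q
    M[9, ] <- 0; M[9, 9] <- 1
    M[10, ] <- 0; M[10, 10] <- 1
    M
  }
  structure(f, class = c("transition_builder", "function"),
            P_disease = P, q_cycles = qv, cycle_length = cycle_length,
            start_age = start_age, horizon_cycles = horizon_cycles)
}

#' Per-cycle transition matrix for a pathway at a given age
#'
#' Convenience wrapper building the full 10 x 10 stochastic matrix (disease
#' transitions plus background mortality) for a single age.
#'
#' @inheritParams transition_builder
#' @param age Age in years.
#' @return A 10 x 10 stochastic matrix (rows sum to 1).
#' @export
build_transition_matrix <- function(values, modifiers, age,
                                    cycle_length = 1 / 12,
                                    life_table = make_life_table()) {
  b <- transition_builder(values, modifiers, start_age = age,
                          cycle_length = cycle_length, horizon_cycles = 1,
                          life_table = life_table)
  b(0)
}

#' Propagate a cohort through the Markov model
#'
#' Deterministic cohort propagation: occupancy row `t + 1` equals row `t`
#' times the cycle-`t` transition matrix. For a [transition_builder()] a fast
#' path exploits the constant disease matrix; any plain function
#' `f(cycle) -> matrix` is also accepted (used by toy models in tests).
#'
#' @param init Length-10 initial state vector (sums to 1).
#' @param builder A [transition_builder()] or a function of the 0-based cycle
#'   index returning a stochastic matrix.
#' @param horizon_cycles Number of cycles to run.
#' @param cycle_length Cycle length in years (taken from the builder when
#'   available).
#' @param start_age Age at cycle 0 (taken from the builder when available).
#' @return A `cohort_trace`: list with `occupancy`
#'   (`(horizon_cycles + 1) x n_states`, rows summing to 1), `entries`
#'   (same shape; inflow into each state per cycle, with the initial vector
#'   as cycle-0 entries), `cycle_length`, `start_age`.
#' @export
run_cohort <- function(init, builder, horizon_cycles = NULL,
                       cycle_length = NULL, start_age = NULL) {
  n <- length(init)
  stopifnot(abs(sum(init) - 1) < 1e-9, all(init >= 0))
  fast <- inherits(builder, "transition_builder")
  if (fast) {
    if (is.null(horizon_cycles)) horizon_cycles <- attr(builder, "horizon_cycles")
    if (is.null(cycle_length)) cycle_length <- attr(builder, "cycle_length")
    if (is.null(start_age)) start_age <- attr(builder, "start_age")
  }
  stopifnot(!is.null(horizon_cycles))
  if (is.null(cycle_length)) cycle_length <- 1 / 12
  if (is.null(start_age)) start_age <- 66

  occ <- matrix(0, horizon_cycles + 1, n)
  ent <- matrix(0, horizon_cycles + 1, n)
  occ[1, ] <- init
  ent[1, ] <- init
  x <- init
  if (fast) {
    P <- attr(builder, "P_disease")
    qv <- attr(builder, "q_cycles")
    P18 <- P[1:8, , drop = FALSE]
    dimnames(P18) <- NULL
    stay <- c(diag(P)[1:8], 1, 1)
    x <- as.numeric(x)
    for (t in seq_len(horizon_cycles)) {
      q <- qv[t]
      living <- x[1:8]
      dead_flow <- sum(living) * q
      newx <- .colSums(living * (1 - q) * P18, 8, 10)
      newx[9] <- newx[9] + x[9]
      newx[10] <- newx[10] + x[10] + dead_flow
      stay_part <- x * stay
      stay_part[1:8] <- stay_part[1:8] * (1 - q)
      ent[t + 1, ] <- newx - stay_part
      occ[t + 1, ] <- newx
      x <- newx
    }
  } else {
    for (t in seq_len(horizon_cycles)) {
      M <- builder(t - 1)
      if (any(abs(rowSums(M) - 1) > 1e-10) || any(M < 0)) {
        stop("non-stochastic transition matrix at cycle ", t - 1)
      }
      newx <- as.vector(x %*% M)
      ent[t + 1, ] <- newx - x * diag(M)
      occ[t + 1, ] <- newx
      x <- newx
    }
  }
  if (n == 10) colnames(occ) <- colnames(ent) <- health_states()
  structure(
    list(occupancy = occ, entries = ent, cycle_length = cycle_length,
         start_age = start_age),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  tmax <- nrow(x$occupancy) - 1
  cat(sprintf("<cohort_trace> %d cycles of %.4g y from age %g\n",
              tmax, x$cycle_length, x$start_age))
  show <- unique(round(seq(1, tmax + 1, length.out = 6)))
  print(round(x$occupancy[show, , drop = FALSE], 4))
  invisible(x)
}
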