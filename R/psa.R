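#' Probabilistic analysis of the imaging strategies
#'
#' Propagates parameter uncertainty through the full pipeline by Monte Carlo
#' simulation: each iteration draws one value per parameter
#' ([sample_parameters()]) and runs all strategies on that common draw
#' (common random numbers), producing paired cost and QALY matrices.
#'
#' @param set A `parameter_set`.
#' @param n_draws Number of Monte Carlo iterations (10,000 in the reference
#'   analysis).
#' @param seed Integer RNG seed; identical seeds give identical results.
#' @param stratum One of [psa_strata()].
#' @param settings A [cea_settings()].
#' @return A `psa_matrix`: list with `costs` and `qalys`
#'   (`n_draws x n_strategies` matrices, strategies as columns), `draws`
#'   (the `parameter_draws`), `stratum`, `seed`, `settings`.
#' @export
run_psa <- function(set, n_draws = 10000, seed = 1, stratum = "base",
                    settings = cea_settings()) {
  draws <- sample_parameters(set, n_draws, seed, stratum)
  sgs <- strategies()
  costs <- qalys <- matrix(NA_real_, n_draws, length(sgs),
                           dimnames = list(NULL, sgs))
  for (i in seq_len(n_draws)) {
    values <- draws$draws[i, ]
    for (sg in sgs) {
      o <- tryCatch(run_strategy(values, sg, settings, stratum),
                    error = function(e)
                      stop("draw ", i, " failed for ", sg, ": ",
                           conditionMessage(e)))
      costs[i, sg] <- o$disc_cost
      qalys[i, sg] <- o$disc_qaly
    }
  }
  structure(
    list(costs = costs, qalys = qalys, draws = draws, stratum = stratum,
         seed = seed, settings = settings),
    class = "psa_matrix"
  )
}

#' @export
print.psa_matrix <- function(x, ...) {
  cat(sprintf("<psa_matrix> %d draws x %d strategies (stratum %s, seed %d)\n",
              nrow(x$costs), ncol(x$costs), x$stratum, x$seed))
  print(psa_summary(x))
  invisible(x)
}

#' Summarise a probabilistic analysis
#'
#' @param psa A `psa_matrix`.
#' @return Data.frame with per-strategy mean and 95% uncertainty interval
#'   (2.5th/97.5th percentiles) of discounted cost and QALYs.
#' @export
psa_summary <- function(psa) {
  q <- function(m, p) apply(m, 2, stats::quantile, probs = p)
  data.frame(
    strategy = colnames(psa$costs),
    cost_mean = colMeans(psa$costs),
    cost_lo = q(psa$costs, 0.025), cost_hi = q(psa$costs, 0.975),
    qaly_mean = colMeans(psa$qalys),
    qaly_lo = q(psa$qalys, 0.025), qaly_hi = q(psa$qalys, 0.975),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.nmb_matrix <- function(psa, wtp) wtp * psa$qalys - psa$costs

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of Monte Carlo draws in
#' which each strategy maximises net monetary benefit. Fractions sum to 1 at
#' every grid point; ties go to the first strategy in column order (they have
#' probability zero under continuous draws).
#'
#' @param psa A `psa_matrix`.
#' @param wtp_grid Vector of willingness-to-pay values (default $0-$300,000
#'   in $5,000 steps).
#' @return Data.frame with columns `wtp`, one probability column per
#'   strategy.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 300000, by = 5000)) {
  stopifnot(length(wtp_grid) >= 1)
  sgs <- colnames(psa$costs)
  out <- vapply(wtp_grid, function(w) {
    win <- max.col(.nmb_matrix(psa, w), ties.method = "first")
    tabulate(win, nbins = length(sgs)) / nrow(psa$costs)
  }, numeric(length(sgs)))
  res <- data.frame(wtp = wtp_grid, t(out))
  names(res)[-1] <- sgs
  res
}

#' Expected value of perfect information
#'
#' The expected gain from resolving all parameter uncertainty before
#' choosing a strategy: `E[max_s NMB_s] - max_s E[NMB_s]`, in USD per person;
#' always non-negative. The QALY-denominated value divides by the
#' willingness-to-pay threshold.
#'
#' @param psa A `psa_matrix`.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return List with `evpi_usd` and `evpi_qaly` (per person).
#' @export
evpi <- function(psa, wtp) {
  stopifnot(ncol(psa$costs) >= 2)
  nm <- .nmb_matrix(psa, wtp)
  v <- mean(apply(nm, 1, max)) - max(colMeans(nm))
  list(evpi_usd = max(v, 0), evpi_qaly = if (wtp > 0) max(v, 0) / wtp else NA_real_)
}

#' Regression-based expected value of partial perfect information
#'
#' Estimates the value of resolving uncertainty in one value-of-information
#' parameter group using the existing probabilistic draws: per strategy, a
#' generalized additive model smooths net monetary benefit on the group's
#' parameters; the conditional-expectation functional
#' `E[max_s E(NMB_s | group)] - max_s E[NMB_s]` is evaluated on the fitted
#' values. Non-negative up to Monte Carlo error (clamped at zero).
#'
#' @param psa A `psa_matrix`.
#' @param group Group id `1`-`4` or a character vector of parameter names.
#' @param wtp Willingness-to-pay threshold.
#' @param set Parameter set used to resolve group membership (defaults to the
#'   shipped reference inputs).
#' @param k Basis dimension per smooth term (passed to [mgcv::s()]).
#' @return List with `evppi_usd` and `evppi_qaly` (per person).
#' @export
evppi_regression <- function(psa, group, wtp, set = reference_parameters(),
                             k = 5) {
  cols <- if (is.character(group) && length(group) > 1 ||
              (is.character(group) && !group %in% as.character(1:4))) {
    group
  } else {
    voi_groups(set, psa$stratum)[[as.character(group)]]
  }
  cols <- intersect(cols, colnames(psa$draws$draws))
  if (!length(cols)) stop("empty value-of-information group")
  X <- psa$draws$draws[, cols, drop = FALSE]
  # drop degenerate (fixed / near-constant) group members
  keep <- apply(X, 2, function(x) stats::sd(x) > 1e-12 * (abs(mean(x)) + 1))
  X <- X[, keep, drop = FALSE]
  nm <- .nmb_matrix(psa, wtp)
  if (!ncol(X)) {
    return(list(evppi_usd = 0, evppi_qaly = if (wtp > 0) 0 else NA_real_))
  }
  dat <- as.data.frame(X)
  names(dat) <- paste0("x", seq_len(ncol(X)))
  terms <- paste(sprintf("s(%s, k = %d)", names(dat), k), collapse = " + ")
  fitted <- vapply(seq_len(ncol(nm)), function(j) {
    dat$y <- nm[, j]
    stats::fitted(mgcv::gam(stats::as.formula(paste("y ~", terms)),
                            data = dat))
  }, numeric(nrow(nm)))
  v <- mean(apply(fitted, 1, max)) - max(colMeans(nm))
  v <- max(v, 0)
  list(evppi_usd = v, evppi_qaly = if (wtp > 0) v / wtp else NA_real_)
}

#' Nested Monte Carlo expected value of partial perfect information
#'
#' Two-level estimator used as the validation oracle for
#' [evppi_regression()]: for each outer draw of the group's parameters, the
#' inner loop averages net monetary benefit over the remaining parameters;
#' EVPPI is `E_outer[max_s inner-mean NMB_s] - max_s E[NMB_s]`. Exact in the
#' limit of many draws but expensive — intended for small models and tests.
#'
#' @param model_fn Function mapping a named parameter-value vector to a
#'   vector of per-strategy net monetary benefits.
#' @param set A `parameter_set`.
#' @param group Group id or character vector of parameter names.
#' @param n_outer,n_inner Outer and inner sample sizes (`n_inner >= 2`).
#' @param seed Integer seed.
#' @param stratum Stratum for parameter resolution.
#' @return EVPPI in USD per person (non-negative).
#' @export
evppi_nested <- function(model_fn, set, group, n_outer = 100, n_inner = 100,
                         seed = 1, stratum = "base") {
  stopifnot(n_inner >= 2, n_outer >= 2)
  cols <- if (is.character(group) &&
              !all(group %in% as.character(1:4))) {
    group
  } else {
    voi_groups(set, stratum)[[as.character(group)]]
  }
  outer_draws <- sample_parameters(set, n_outer, seed, stratum)
  cols <- intersect(cols, colnames(outer_draws$draws))
  if (!length(cols)) stop("empty value-of-information group")
  inner_means <- matrix(NA_real_, n_outer, 0)
  per_outer <- vector("list", n_outer)
  for (i in seq_len(n_outer)) {
    inner <- sample_parameters(set, n_inner, seed + i, stratum)
    inner$draws[, cols] <- rep(outer_draws$draws[i, cols], each = n_inner)
    nmbs <- t(vapply(seq_len(n_inner),
                     function(j) model_fn(inner$draws[j, ]),
                     model_fn(inner$draws[1, ])))
    per_outer[[i]] <- colMeans(nmbs)
  }
  m <- do.call(rbind, per_outer)
  # overall expectation from the pooled inner samples
  v <- mean(apply(m, 1, max)) - max(colMeans(m))
  max(v, 0)
}

#' Scale per-person value of information to the population
#'
#' `per_person * (prevalence + sum_{t=1..horizon} incidence / (1 + rate)^t)`:
#' the prevalent cohort counts undiscounted at time zero and each incident
#' yearly cohort is discounted from year 1. The reference analysis assumes a
#' 10-year horizon, 50,000 prevalent and 40,000 incident patients per year,
#' and 3% discounting.
#'
#' @param per_person Per-person value (QALYs or USD).
#' @param prevalence Prevalent population at time zero.
#' @param incidence Incident patients per year.
#' @param horizon Accrual horizon in years.
#' @param rate Annual discount rate.
#' @return Population total on the same scale as `per_person`.
#' @export
population_voi <- function(per_person, prevalence = 50000, incidence = 40000,
                           horizon = 10, rate = 0.03) {
  stopifnot(per_person >= 0, prevalence >= 0, incidence >= 0, horizon >= 0)
  annuity <- if (horizon >= 1) sum((1 + rate)^-(seq_len(horizon))) else 0
  per_person * (prevalence + incidence * annuity)
}
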