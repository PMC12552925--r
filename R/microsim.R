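#' Individual-level micro-simulation oracle for the cohort engine
#'
#' Simulates `n_individuals` through the same per-cycle transition matrices
#' the cohort engine uses (one shared matrix-builder code path) and returns
#' occupancy fractions with per-cell Monte Carlo standard errors. Individuals
#' in the same state and cycle are exchangeable, so the simulation draws
#' multinomial counts per state per cycle — identical in distribution to
#' simulating individuals one at a time, at a fraction of the cost.
#'
#' @param init Length-`n` initial state vector (sums to 1); individuals are
#'   assigned by a multinomial draw.
#' @param builder A [transition_builder()] or function of the 0-based cycle
#'   index returning a stochastic matrix.
#' @param n_individuals Number of simulated individuals (>= 1).
#' @param horizon_cycles Number of cycles (defaults to the builder's horizon).
#' @param seed Integer seed.
#' @return List with `occupancy` (`(horizon_cycles + 1) x n` fraction
#'   matrix), `se` (binomial standard errors `sqrt(p(1-p)/n)`), `counts` and
#'   `n_individuals`.
#' @export
microsim_oracle <- function(init, builder, n_individuals, horizon_cycles = NULL,
                            seed = 1) {
  stopifnot(n_individuals >= 1, abs(sum(init) - 1) < 1e-9)
  if (is.null(horizon_cycles)) {
    horizon_cycles <- attr(builder, "horizon_cycles")
  }
  stopifnot(!is.null(horizon_cycles))
  n <- length(init)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  counts <- matrix(0L, horizon_cycles + 1, n)
  counts[1, ] <- as.integer(stats::rmultinom(1, n_individuals, init))
  x <- counts[1, ]
  for (t in seq_len(horizon_cycles)) {
    M <- builder(t - 1)
    newx <- integer(n)
    for (s in which(x > 0)) {
      newx <- newx + as.integer(stats::rmultinom(1, x[s], M[s, ]))
    }
    counts[t + 1, ] <- newx
    x <- newx
  }
  occ <- counts / n_individuals
  se <- sqrt(occ * (1 - occ) / n_individuals)
  if (n == 10) colnames(occ) <- colnames(se) <- colnames(counts) <- health_states()
  list(occupancy = occ, se = se, counts = counts,
       n_individuals = n_individuals)
}
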