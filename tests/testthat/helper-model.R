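# Shared fixtures: small parameter sets, toy builders and a fake PSA matrix
# constructor used by the value-of-information tests.

ref_set <- reference_parameters()
ref_values <- point_estimates(ref_set, "base")

# settings with a coarse yearly cycle for tests that only need structure
fast_settings <- function(...) cea_settings(cycle_length = 1, ...)

# two-state toy: alive -> dead with per-cycle probability p
decay_builder <- function(p) {
  function(cycle) matrix(c(1 - p, p, 0, 1), 2, 2, byrow = TRUE)
}

# construct a psa_matrix-shaped object directly from draw-level outcomes
fake_psa <- function(costs, qalys, draws = NULL, stratum = "base") {
  if (is.null(draws)) {
    draws <- matrix(numeric(0), nrow = nrow(costs), ncol = 0)
  }
  structure(
    list(costs = costs, qalys = qalys,
         draws = list(draws = draws, n_draws = nrow(costs), seed = 0L,
                      stratum = stratum),
         stratum = stratum, seed = 0L),
    class = "psa_matrix"
  )
}

# random valid 3-strategy (cost, qaly) instances for frontier properties
random_outcomes <- function() {
  data.frame(strategy = c("A", "B", "C"),
             cost = runif(3, 0, 5e5),
             qaly = runif(3, 1, 10),
             stringsAsFactors = FALSE)
}
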