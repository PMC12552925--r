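# Markov engine: hazard-ratio algebra, matrix structure, cohort propagation.

test_that("hazard ratios act on the log-survival scale", {
  expect_equal(adjust_probability(0.0227, 0.56), 0.012776, tolerance = 1e-4)
  # exponential-rate oracle: scale the implied constant rate, then invert
  rate_oracle <- function(p, hr) 1 - exp(log(1 - p) * hr)
  for (p in c(0, 0.01, 0.3, 0.9)) {
    for (hr in c(0.25, 0.56, 1, 1.79, 3)) {
      expect_equal(adjust_probability(p, hr), rate_oracle(p, hr),
                   tolerance = 1e-12)
    }
  }
  expect_equal(adjust_probability(0.37, 1), 0.37)
  expect_equal(adjust_probability(0, 2.5), 0)
  expect_error(adjust_probability(1, 0.5), "p = 1")
})

test_that("background mortality interpolates and rescales correctly", {
  lt <- make_life_table()
  q66 <- background_mortality(66, lt, cycle_length = 1)
  expect_equal(q66, lt$qx[lt$age == 66])
  expect_true(background_mortality(80, lt, 1) >= q66)
  # annual-to-monthly conversion: 1 - (1 - q)^(1/12)
  expect_equal(background_mortality(66, lt, 1 / 12),
               1 - (1 - q66)^(1 / 12), tolerance = 1e-12)
  expect_error(background_mortality(300, lt), "outside")
  # life table is increasing in age
  expect_true(all(diff(lt$qx) > 0))
})

test_that("transition matrices are stochastic with the permitted support", {
  adj <- transition_adjacency()
  draws <- sample_parameters(ref_set, 20, seed = 8)
  for (i in seq_len(20)) {
    v <- draws$draws[i, ]
    for (mod in c("early", "delayed", "false_negative")) {
      M <- build_transition_matrix(v, pathway_modifiers(mod, v), age = 70)
      expect_equal(rowSums(M), rep(1, 10), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_true(all(M >= 0))
      # nonzero entries exactly where the structure permits
      expect_true(all((M > 0) == adj))
    }
  }
})

test_that("degenerate inputs give the identity matrix", {
  v <- ref_values
  v[grep("^p_", names(v))] <- 0
  v["p_detect_psma"] <- 0.5 # classification params irrelevant here
  v["p_loc_given_detect"] <- 0.2
  v["p_met_given_detect"] <- 0.8
  b <- transition_builder(v, pathway_modifiers("delayed", v),
                          horizon_cycles = 5,
                          life_table = data.frame(age = 0:120, qx = 0))
  expect_equal(b(0), diag(10), ignore_attr = TRUE)
  tr <- run_cohort(c(1, rep(0, 9)), b)
  expect_true(all(tr$occupancy[, 1] == 1))
})

test_that("cohort propagation matches the two-state closed form", {
  tr <- run_cohort(c(1, 0), decay_builder(0.5), horizon_cycles = 12,
                   cycle_length = 1, start_age = 0)
  expect_equal(tr$occupancy[, 1], 2^-(0:12), tolerance = 1e-12)
  # absorbing occupancy is non-decreasing
  expect_true(all(diff(tr$occupancy[, 2]) >= 0))
  # non-stochastic matrices are rejected
  bad <- function(cycle) matrix(c(0.5, 0.4, 0, 1), 2, 2, byrow = TRUE)
  expect_error(run_cohort(c(1, 0), bad, horizon_cycles = 2), "non-stochastic")
})

test_that("trace rows conserve mass and deaths absorb the cohort", {
  pw <- assign_initial_states(classify_cohort("CTBS", ref_values), ref_values)
  for (p in pw) {
    b <- transition_builder(ref_values,
                            pathway_modifiers(p$modifier, ref_values))
    tr <- run_cohort(p$init, b)
    expect_equal(rowSums(tr$occupancy), rep(1, nrow(tr$occupancy)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    dead <- rowSums(tr$occupancy[, 9:10])
    expect_true(all(diff(dead) >= -1e-12))
    # entry flows reconcile with occupancy changes
    expect_true(all(tr$entries >= -1e-12))
  }
})

test_that("the fast builder path agrees with generic per-cycle propagation", {
  b <- transition_builder(ref_values, pathway_modifiers("early", ref_values),
                          horizon_cycles = 60)
  init <- c(0, 0.1, 0.2, 0.1, 0, 0.4, 0.2, 0, 0, 0)
  fast <- run_cohort(init, b)
  generic <- run_cohort(init, function(cycle) b(cycle), horizon_cycles = 60)
  expect_equal(fast$occupancy, generic$occupancy, tolerance = 1e-12)
  expect_equal(fast$entries, generic$entries, tolerance = 1e-12)
})

test_that("with all hazard ratios neutral, detected traces coincide across strategies", {
  set0 <- apply_scenario(ref_set, degenerate_scenario("hr_neutral"))
  v <- point_estimates(set0)
  b_early <- transition_builder(v, pathway_modifiers("early", v))
  b_delayed <- transition_builder(v, pathway_modifiers("delayed", v))
  b_fn <- transition_builder(v, pathway_modifiers("false_negative", v))
  init <- c(0, 0, 0, 0, 0, 0.8, 0.2, 0, 0, 0)
  t1 <- run_cohort(init, b_early)
  t2 <- run_cohort(init, b_delayed)
  t3 <- run_cohort(init, b_fn)
  expect_equal(t1$occupancy, t2$occupancy, tolerance = 1e-14)
  expect_equal(t2$occupancy, t3$occupancy, tolerance = 1e-14)
})

test_that("earlier detection weakly dominates on lifetime QALYs", {
  # directional sanity: with hr_early < 1 and hr_false_negative > 1 the
  # PSMA-PET strategy cannot yield fewer QALYs than CTBS
  q <- function(v, sg) run_strategy(v, sg)$disc_qaly
  expect_gte(q(ref_values, "PSMA_PET"), q(ref_values, "CTBS"))
  draws <- sample_parameters(ref_set, 8, seed = 21)
  for (i in seq_len(8)) {
    v <- draws$draws[i, ]
    if (v["hr_early"] < 1 && v["hr_false_negative"] > 1) {
      expect_gte(q(v, "PSMA_PET"), q(v, "CTBS"))
    }
  }
})

test_that("micro-simulation agrees with the cohort engine", {
  # two-state decay toy: binomial closed form
  ms <- microsim_oracle(c(1, 0), decay_builder(0.5), n_individuals = 1e6,
                        horizon_cycles = 10, seed = 4)
  expect_true(all(abs(ms$occupancy[, 1] - 2^-(0:10)) <=
                    3 * ms$se[, 1] + 1e-9))

  # full model: three distinct parameter sets, all pathways pooled
  draws <- sample_parameters(ref_set, 2, seed = 13)
  cases <- list(ref_values, draws$draws[1, ], draws$draws[2, ])
  for (ci in seq_along(cases)) {
    v <- cases[[ci]]
    pw <- assign_initial_states(classify_cohort("CTBS", v), v)
    p <- pw$false_negative
    b <- transition_builder(v, pathway_modifiers(p$modifier, v),
                            horizon_cycles = 120)
    tr <- run_cohort(p$init, b)
    ms <- microsim_oracle(p$init, b, n_individuals = 2e5,
                          horizon_cycles = 120, seed = 100 + ci)
    diff <- abs(ms$occupancy - tr$occupancy)
    tol <- 3 * ms$se + 5e-4 # binomial SE plus slack for near-empty cells
    expect_true(all(diff <= tol))
  }
})
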