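# Probabilistic analysis, acceptability curves and value of information.

test_that("an all-fixed parameter set makes every draw identical", {
  set0 <- apply_scenario(ref_set, degenerate_scenario("no_uncertainty"))
  psa <- run_psa(set0, n_draws = 4, seed = 1)
  det <- vapply(strategies(), function(sg)
    run_strategy(point_estimates(set0), sg)$disc_cost, numeric(1))
  for (i in 1:4) expect_equal(psa$costs[i, ], det, tolerance = 1e-12)
  # and EVPI vanishes
  expect_equal(evpi(psa, 150000)$evpi_usd, 0)
  cc <- ceac(psa, c(0, 150000))
  expect_true(all(rowSums(cc[, -1]) == 1))
})

test_that("probabilistic runs are seed-reproducible", {
  p1 <- run_psa(ref_set, n_draws = 5, seed = 42)
  p2 <- run_psa(ref_set, n_draws = 5, seed = 42)
  expect_identical(p1$costs, p2$costs)
  expect_identical(p1$qalys, p2$qalys)
  expect_identical(p1$draws$draws, p2$draws$draws)
})

test_that("acceptability curves normalise and capture dominance", {
  n <- 500
  set.seed(3)
  # strategy A dominates in every draw
  costs <- cbind(A = runif(n, 0, 10), B = runif(n, 100, 200))
  qalys <- cbind(A = runif(n, 5, 6), B = runif(n, 1, 2))
  psa <- fake_psa(costs, qalys)
  cc <- ceac(psa, seq(0, 1e5, by = 2e4))
  expect_true(all(cc$A == 1))
  expect_true(all(cc$B == 0))
  expect_equal(rowSums(cc[, -1]), rep(1, nrow(cc)), ignore_attr = TRUE)

  # symmetric toy: cost difference ~ N(c0, sd), QALY difference 1
  c0 <- 5e4
  costs2 <- cbind(A = rep(0, 4000), B = rnorm(4000, c0, 1e4))
  qalys2 <- cbind(A = rep(0, 4000), B = rep(1, 4000))
  cc2 <- ceac(fake_psa(costs2, qalys2), c0)
  expect_equal(cc2$B, 0.5, tolerance = 0.05)
})

test_that("EVPI matches the enumerable two-outcome oracle", {
  # NMB difference +/-100 with probability one half
  n <- 1000
  costs <- cbind(A = rep(0, n), B = rep(c(-100, 100), n / 2))
  qalys <- cbind(A = rep(0, n), B = rep(0, n))
  psa <- fake_psa(costs, qalys)
  expect_equal(evpi(psa, 1)$evpi_usd, 50)
  # in QALY terms at the same wtp
  expect_equal(evpi(psa, 1)$evpi_qaly, 50)
})

test_that("partial information is bounded by perfect information", {
  psa <- run_psa(ref_set, n_draws = 150, seed = 6)
  e <- evpi(psa, 150000)
  expect_gte(e$evpi_usd, 0)
  for (g in 1:4) {
    v <- evppi_regression(psa, g, 150000, set = ref_set)
    expect_gte(v$evppi_usd, 0)
    expect_lte(v$evppi_usd, e$evpi_usd * 1.05 + 1e-6) # MC slack
  }
  # a group of zero-variance parameters carries no information value
  fixed_hr <- apply_scenario(ref_set, list(hr_early = 0.56,
                                           hr_false_negative = 1.79,
                                           hr_mdt = 0.6, sens_ctbs = 0.3798,
                                           spec_ctbs = 0.9101,
                                           p_loc_given_ctbs_detect = 0.0342))
  psa0 <- run_psa(fixed_hr, n_draws = 60, seed = 7)
  v0 <- evppi_regression(psa0, 1, 150000, set = fixed_hr)
  expect_equal(v0$evppi_usd, 0)
})

test_that("regression and nested-MC EVPPI agree with an analytic toy", {
  # NMB_1 = 0, NMB_2 = theta1 + theta2 with independent normals:
  # E[max(0, S)] = mu * pnorm(mu/sd) + sd * dnorm(mu/sd)
  emax <- function(mu, sd) mu * pnorm(mu / sd) + sd * dnorm(mu / sd)
  evpi_true <- emax(0, sqrt(2))
  evppi_true <- emax(0, 1) # resolving theta1 (or theta2) alone

  set.seed(9)
  n <- 4000
  th <- cbind(theta1 = rnorm(n), theta2 = rnorm(n))
  costs <- cbind(A = rep(0, n), B = -(th[, 1] + th[, 2]))
  qalys <- cbind(A = rep(0, n), B = rep(0, n))
  psa <- fake_psa(costs, qalys, draws = th)

  expect_equal(evpi(psa, 1)$evpi_usd, evpi_true, tolerance = 0.05)
  v <- evppi_regression(psa, "theta1", 1)
  expect_equal(v$evppi_usd, evppi_true, tolerance = 0.08)

  # nested MC on the same generative model
  toy_tb <- data.frame(
    name = c("theta1", "theta2"), stratum = "base", family = "beta",
    mean = 0.5, ui_low = 0.30, ui_high = 0.70, voi_group = NA,
    units = "", source_note = "toy")
  toy_set <- parameter_set(toy_tb)
  sd_beta <- (0.7 - 0.3) / (2 * qnorm(0.975))
  model_fn <- function(v) c(A = 0, B = (v[["theta1"]] - 0.5) +
                                       (v[["theta2"]] - 0.5))
  nested <- evppi_nested(model_fn, toy_set, "theta1",
                         n_outer = 400, n_inner = 400, seed = 11)
  expect_equal(nested, emax(0, sd_beta), tolerance = 0.15)
})

test_that("uncertainty intervals cover the analytic quantiles of a linear toy", {
  # cost = 1000 * theta with theta ~ beta: quantiles scale linearly
  d <- fit_beta(0.5, 0.36, 0.64)
  set.seed(15)
  x <- draw_dist(d, 2e4)
  costs <- cbind(A = 1000 * x, B = rep(0, 2e4))
  qalys <- cbind(A = rep(1, 2e4), B = rep(0, 2e4))
  smry <- psa_summary(fake_psa(costs, qalys))
  a <- smry[smry$strategy == "A", ]
  expect_equal(a$cost_lo, 1000 * qbeta(0.025, d$shape$alpha, d$shape$beta),
               tolerance = 0.02)
  expect_equal(a$cost_hi, 1000 * qbeta(0.975, d$shape$alpha, d$shape$beta),
               tolerance = 0.02)
})

test_that("population scaling uses the prevalent + discounted incident formula", {
  expect_equal(population_voi(0, 50000, 40000, 10, 0.03), 0)
  expect_equal(population_voi(0.1, 50000, 40000, 10, 0.03), 39120.81,
               tolerance = 1e-6)
  expect_equal(population_voi(2, 1000, 500, 1, 0), 2 * 1500)
  expect_equal(population_voi(1, 1000, 500, 0, 0.03), 1000)
})
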