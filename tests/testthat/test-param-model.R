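# Distribution fitting and seeded sampling of the model inputs.

test_that("beta fitting matches the moment-matching closed form", {
  d <- fit_beta(0.7512, 0.7105, 0.7880)
  expect_equal(d$family, "beta")
  expect_equal(d$shape$alpha, 358.4, tolerance = 0.002)
  expect_equal(d$shape$beta, 118.7, tolerance = 0.002)
  # mean of a beta(a, b) is a/(a+b): fitting must preserve it exactly
  expect_equal(with(d$shape, alpha / (alpha + beta)), 0.7512, tolerance = 1e-12)

  # highly asymmetric published interval still yields a valid beta
  d2 <- fit_beta(0.0342, 0.0071, 0.0832)
  expect_true(d2$shape$alpha > 0 && d2$shape$beta > 0)

  # zero-width interval degenerates to a fixed spec
  expect_equal(fit_beta(0.5, 0.5, 0.5)$family, "fixed")

  # interval too wide for a beta with this mean is rejected with a diagnostic
  expect_error(fit_beta(0.02, 0, 0.9), "too wide")
})

test_that("beta sampling recovers the published mean and percentiles", {
  d <- fit_beta(0.7512, 0.7105, 0.7880)
  set.seed(42)
  x <- draw_dist(d, 1e5)
  expect_equal(mean(x), 0.7512, tolerance = 0.01)
  qs <- quantile(x, c(0.025, 0.975))
  expect_equal(unname(qs[1]), 0.7105, tolerance = 0.01)
  expect_equal(unname(qs[2]), 0.7880, tolerance = 0.01)
  expect_true(all(x >= 0 & x <= 1))
})

test_that("gamma fitting uses the 20% CV rule and interval override", {
  d <- fit_gamma(1898)
  expect_equal(d$shape$shape, 25, tolerance = 1e-10)
  expect_equal(d$shape$scale, 75.92, tolerance = 1e-10)

  d2 <- fit_gamma(1898, 1242, 2727)
  expect_equal(d2$shape$shape, 25.1, tolerance = 0.01)
  set.seed(7)
  x <- draw_dist(d2, 1e5)
  expect_equal(mean(x), 1898, tolerance = 0.01 * 1898)
  expect_true(all(x > 0))

  expect_equal(fit_gamma(100, 100, 100)$family, "fixed")
  expect_error(fit_gamma(-5), "mean > 0")
})

test_that("lognormal fitting anchors the median and takes sd from log-width", {
  d <- fit_lognormal(0.56, 0.49, 0.92)
  expect_equal(d$shape$meanlog, log(0.56), tolerance = 1e-12)
  expect_equal(d$shape$sdlog, 0.1606, tolerance = 1e-3)
  set.seed(11)
  expect_equal(median(draw_dist(d, 1e5)), 0.56, tolerance = 0.01 * 0.56)

  d2 <- fit_lognormal(1.79, 1.09, 2.05)
  expect_equal(d2$shape$sdlog, 0.1612, tolerance = 1e-3)

  expect_equal(fit_lognormal(1, 1, 1)$family, "fixed")
  expect_error(fit_lognormal(0.5, -0.1, 0.9))
})

test_that("parameter tables load, reject duplicates and malformed strata", {
  path <- system.file("extdata", "parameters.csv", package = "petcea")
  set <- load_parameter_table(path)
  v <- point_estimates(set, "base")
  expect_equal(unname(v["sens_ctbs"]), 0.3798)

  tb <- as.data.frame(set)
  expect_error(parameter_set(rbind(tb, tb[1, ])), "duplicate")
  tb_bad <- tb; tb_bad$stratum[1] <- "psa<2"
  expect_error(parameter_set(tb_bad), "malformed stratum")
  expect_error(parameter_set(tb[0, ]), "empty")
  expect_error(load_parameter_table(tempfile()), "not found")
})

test_that("stratum resolution falls back to base-case values", {
  v_lt2 <- point_estimates(ref_set, "lt2")
  expect_equal(unname(v_lt2["p_detect_psma"]), 0.6019)
  expect_equal(unname(v_lt2["p_loc_given_detect"]), 0.2545)
  # not stratified: falls back to base
  expect_equal(unname(v_lt2["sens_ctbs"]), 0.3798)
  expect_equal(unname(v_lt2["cost_psma_pet"]), 1898)
})

test_that("sampling is seed-deterministic and respects support", {
  d1 <- sample_parameters(ref_set, 200, seed = 1)
  d2 <- sample_parameters(ref_set, 200, seed = 1)
  expect_identical(d1$draws, d2$draws)
  d3 <- sample_parameters(ref_set, 200, seed = 2)
  expect_false(identical(d1$draws, d3$draws))

  # support: probabilities and utilities in [0,1]; costs and HRs positive
  beta_cols <- grep("^(p_|tx_|u_|sens_|spec_)", colnames(d1$draws))
  expect_true(all(d1$draws[, beta_cols] >= 0 & d1$draws[, beta_cols] <= 1))
  pos_cols <- grep("^(cost_|hr_)", colnames(d1$draws))
  expect_true(all(d1$draws[, pos_cols] > 0))

  # fixed parameters repeat their point estimates
  fixed_set <- apply_scenario(ref_set, degenerate_scenario("no_uncertainty"))
  df <- sample_parameters(fixed_set, 5, seed = 9)
  pe <- point_estimates(fixed_set)
  for (i in 1:5) expect_equal(df$draws[i, names(pe)], pe)
})

test_that("column means converge to the point estimates (round trip)", {
  d <- sample_parameters(ref_set, 1e5, seed = 3)
  pe <- point_estimates(ref_set)
  # beta and gamma: mean matches the point estimate within 1% relative error
  for (nm in c("p_detect_psma", "sens_ctbs", "u_mcrpc", "cost_arsi",
               "cost_psma_pet")) {
    expect_equal(mean(d$draws[, nm]), unname(pe[nm]),
                 tolerance = 0.01, ignore_attr = TRUE)
  }
  # lognormal: the *median* matches the published hazard ratio
  for (nm in c("hr_early", "hr_false_negative")) {
    expect_equal(median(d$draws[, nm]), unname(pe[nm]),
                 tolerance = 0.01, ignore_attr = TRUE)
  }
})
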