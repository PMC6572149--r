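fx <- study_fixture()

test_that("degenerate inputs give exactly p_raw * mean hazard", {
  pm <- factor_profile("ventilation",
    stats::setNames(rep(list(c(0, 0)), 8), letters[1:8]))  # F = 1.5
  spec <- hazard_spec("ventilation", "OIW", 2, 0)
  cfg <- sim_config(iterations = 100, seed = 4)
  r <- simulate_behavior_risk(0.3, pm, spec, cfg)
  expect_equal(r, rep(0.3 * 1.5 * 2, 100))
})

test_that("simulated moments match the moment-propagation oracle", {
  cases <- list(
    list(wt = "ventilation", bc = "OIW", p = 0.16),
    list(wt = "gas_prevention_fire", bc = "OIW", p = 0.105),
    list(wt = "blasting", bc = "UUD", p = 0.065))
  n <- 1e4
  for (cs in cases) {
    prof <- fx$study$profiles[[cs$wt]]
    hz <- fixture_hazard_cell(fx$study, cs$wt, cs$bc)
    o <- oracle_risk_moments(cs$p, prof, hz$mean, hz$sd)
    r <- simulate_behavior_risk(cs$p, prof,
                                hazard_spec(cs$wt, cs$bc, hz$mean, hz$sd),
                                sim_config(iterations = n, seed = 17))
    expect_lt(abs(mean(r) - o$mean), 3 * o$sd / sqrt(n))
    expect_lt(abs(sd(r) - o$sd), 4 * o$sd / sqrt(2 * n))
  }
})

test_that("simulation is seed-deterministic", {
  cfg <- sim_config(iterations = 500, seed = 99)
  prof <- fx$study$profiles$ventilation
  spec <- hazard_spec("ventilation", "UUD", 1.5, 0.6)
  expect_identical(simulate_behavior_risk(0.075, prof, spec, cfg),
                   simulate_behavior_risk(0.075, prof, spec, cfg))
  s1 <- simulate_working_type(fx$study, "blasting", cfg)
  s2 <- simulate_working_type(fx$study, "blasting", cfg)
  expect_identical(s1$samples, s2$samples)
})

test_that("risk scales with the hazard-index scale", {
  cfg <- sim_config(iterations = 5000, seed = 31)
  prof <- fx$study$profiles$electrician
  r1 <- simulate_behavior_risk(0.035, prof,
                               hazard_spec("electrician", "OIW", 2, 0.45), cfg)
  r3 <- simulate_behavior_risk(0.035, prof,
                               hazard_spec("electrician", "OIW", 6, 1.35), cfg)
  expect_equal(r3, 3 * r1, tolerance = 1e-12)
})

test_that("summaries carry moments, quantiles and interval", {
  x <- withr::with_seed(5, stats::rlnorm(2000, -1, 0.5))
  s <- suppressMessages(summarize_risk(x, confidence = 0.9))
  expect_equal(s$mean, mean(x))
  expect_equal(s$sd, sd(x))
  qs <- unlist(s$quantiles)
  expect_true(all(diff(qs) >= 0))
  expect_equal(unname(qs[c(1, 5)]), range(x))
  expect_equal(s$interval$level, 0.9)
  expect_lt(s$interval$lower, s$interval$upper)
  # constant samples: sd 0, all quantiles equal, no fit attempted
  expect_error(summarize_risk(rep(1, 60)), NA)
  sc <- summarize_risk(rep(1, 10))
  expect_equal(sc$sd, 0)
  expect_true(all(unlist(sc$quantiles) == 1))
  expect_error(summarize_risk(3.14), "at least 2")
})

test_that("distribution fitting is self-consistent on synthetic draws", {
  ln <- withr::with_seed(41, stats::rlnorm(1e4, -1, 0.6))
  expect_equal(fit_distribution(ln)$family, "lognormal")
  nm <- withr::with_seed(42, stats::rnorm(1e4, 2, 1.2))
  fit_nm <- suppressMessages(fit_distribution(nm))
  expect_equal(fit_nm$family, "normal")
  expect_true("lognormal" %in% fit_nm$skipped)  # negatives present
  un <- withr::with_seed(43, runif(1e4, 2, 5))
  expect_equal(fit_distribution(un)$family, "uniform")
  tr <- withr::with_seed(44, rtri(1e4, 1, 7))
  expect_equal(fit_distribution(tr)$family, "triangular")
  expect_error(fit_distribution(stats::rnorm(30)), "at least 50")
  expect_error(fit_distribution(rep(2, 100)), "constant")
})

test_that("totals honour coupling modes", {
  set.seed(55)
  comp <- list(a = stats::rlnorm(4000, -2, 0.8),
               b = stats::rlnorm(4000, -3, 0.5),
               c = runif(4000))
  tot_c <- suppressMessages(total_risk(comp, mode = "comonotonic"))
  tot_i <- suppressMessages(total_risk(comp, mode = "independent"))
  expect_equal(tot_c$mean, tot_i$mean, tolerance = 1e-12)
  expect_gte(tot_c$sd, tot_i$sd)  # comonotonic coupling maximizes the SD
  # the sum of component SDs bounds the comonotonic SD from above
  expect_lte(tot_c$sd, sum(sapply(comp, sd)) * (1 + 1e-12))
  expect_gte(tot_c$sd, sqrt(sum(sapply(comp, sd)^2)))
  # single component: total is that component's summary in both modes
  one <- list(a = comp$a)
  s1 <- suppressMessages(total_risk(one, "comonotonic"))
  s2 <- suppressMessages(total_risk(one, "independent"))
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$sd, s2$sd)
  expect_equal(unlist(s1$quantiles), unlist(s2$quantiles))
  expect_error(total_risk(list(a = 1:5, b = 1:4)), "same length")
})

test_that("within-type totals under both generation modes", {
  cfg_c <- sim_config(iterations = 1e4, seed = 70, total_mode = "comonotonic")
  cfg_i <- sim_config(iterations = 1e4, seed = 70, total_mode = "independent")
  sim_c <- simulate_working_type(fx$study, "ventilation", cfg_c)
  sim_i <- simulate_working_type(fx$study, "ventilation", cfg_i)
  expect_equal(mean(sim_c$total), mean(sim_i$total), tolerance = 0.02)
  expect_gt(sd(sim_c$total), sd(sim_i$total))
  # comonotonic total SD ~ sum of component SDs
  expect_equal(sd(sim_c$total), sum(apply(sim_c$samples, 2, sd)),
               tolerance = 0.02)
  # independent total SD ~ root-sum-square of component SDs
  expect_equal(sd(sim_i$total),
               sqrt(sum(apply(sim_i$samples, 2, sd)^2)), tolerance = 0.05)
})
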