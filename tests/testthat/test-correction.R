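test_that("correction factor reproduces published values at midpoints", {
  vent <- c(a = 0.5, b = 0.5, c = 6.5, d = 6.5, e = 0.5, f = 6.5,
            g = 2, h = 0.5)
  expect_equal(round(correction_factor(vent), 3), 1.376)
  gas <- vent; gas[["c"]] <- 2
  expect_equal(round(correction_factor(gas), 3), 1.391)
  expect_equal(correction_factor(vent), oracle_cf(vent), tolerance = 1e-12)
  # boundary evaluations
  all0 <- stats::setNames(rep(0, 8), letters[1:8])
  expect_equal(correction_factor(all0), 1.5)
  all10 <- stats::setNames(rep(10, 8), letters[1:8])
  expect_equal(correction_factor(all10), 1.5 - 0.0167 * 30)
})

test_that("profile means reproduce all four published correction factors", {
  profiles <- study_fixture()$study$profiles
  for (wt in key_wts) {
    expect_equal(round(correction_factor_mean(profiles[[wt]]), 3),
                 unname(frozen_cf_3dp[wt]), info = wt)
  }
  # point-mass profile evaluates exactly at the point
  pm <- factor_profile("blasting",
    stats::setNames(rep(list(c(2, 2)), 8), letters[1:8]))
  expect_equal(correction_factor_mean(pm),
               correction_factor(stats::setNames(rep(2, 8), letters[1:8])))
})

test_that("F is strictly decreasing in each factor and bounded", {
  set.seed(21)
  for (rep in 1:20) {
    v <- stats::setNames(runif(8, 0, 10), letters[1:8])
    F0 <- correction_factor(v)
    expect_gte(F0, 0.999 - 1e-12)
    expect_lte(F0, 1.5 + 1e-12)
    for (k in letters[1:8]) {
      v2 <- v
      v2[[k]] <- min(v[[k]] + 0.5, 10)
      if (v2[[k]] > v[[k]]) expect_lt(correction_factor(v2), F0)
    }
  }
})

test_that("validation rejects missing factors and out-of-range scores", {
  v <- stats::setNames(rep(1, 8), letters[1:8])
  expect_error(correction_factor(v[-3]), "missing factor")
  v[["d"]] <- 11
  expect_error(correction_factor(v), "\\[0, 10\\]")
  expect_error(factor_profile("ventilation", list(a = c(0, 1))),
               "eight factors")
  expect_error(
    factor_profile("ventilation",
      c(stats::setNames(rep(list(c(0, 1)), 7), letters[1:7]),
        list(h = c(3, 1)))),
    "factors.h")
})

test_that("factor sampling is seed-deterministic with correct means", {
  prof <- study_fixture()$study$profiles$ventilation
  s1 <- sample_factors(prof, 1e5, seed = 42)
  s2 <- sample_factors(prof, 1e5, seed = 42)
  expect_identical(s1, s2)
  expect_equal(mean(s1[, "c"]), 6.5, tolerance = 0.05 / 6.5)
  expect_equal(mean(s1[, "a"]), 0.5, tolerance = 0.02)
  expect_true(all(s1[, "g"] >= 1 & s1[, "g"] <= 3))
  # point-mass profile: all samples equal the point
  pm <- factor_profile("blasting",
    stats::setNames(rep(list(c(4, 4)), 8), letters[1:8]))
  expect_true(all(sample_factors(pm, 50, seed = 1) == 4))
  expect_error(sample_factors(prof, 0), "positive count")
})

test_that("Monte Carlo mean of F agrees with the analytic mean", {
  prof <- study_fixture()$study$profiles$gas_prevention_fire
  n <- 2e4
  fac <- sample_factors(prof, n, seed = 5)
  Fs <- apply(fac, 1, function(r) correction_factor(r))
  se <- sd(Fs) / sqrt(n)
  expect_lt(abs(mean(Fs) - correction_factor_mean(prof)), 4 * se)
})

test_that("probability revision multiplies, clamps and validates", {
  expect_equal(round(revised_probability(0.16, 1.3756), 2), 0.22)
  expect_equal(round(revised_probability(0.105, 1.3906), 2), 0.15)
  p <- c(0, 0.3, 1)
  expect_equal(revised_probability(p, 1), p)
  expect_warning(out <- revised_probability(0.9, 1.4), "clamped")
  expect_equal(out, 1)
  expect_error(revised_probability(-0.1, 1.2), "\\[0, 1\\]")
  expect_error(revised_probability(0.5, 0), "positive")
})
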