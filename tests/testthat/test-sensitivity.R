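test_that("a single perfectly correlated input owns 100%", {
  x <- withr::with_seed(1, runif(500))
  res <- contribution_to_variance(list(x = x), x)
  expect_equal(res$contribution, 100)
  expect_equal(res$rho, 1)
  expect_equal(nrow(rank_sensitivities(res)), 1)
})

test_that("two iid uniform addends split the variance evenly", {
  n <- 1e5
  withr::with_seed(2, {
    x1 <- runif(n); x2 <- runif(n)
  })
  res <- contribution_to_variance(list(x1 = x1, x2 = x2), x1 + x2)
  expect_equal(res$contribution[1], 50, tolerance = 2 / 50)
  expect_equal(res$contribution[2], 50, tolerance = 2 / 50)
  expect_equal(sum(abs(res$contribution)), 100, tolerance = 1e-6)
})

test_that("contributions are invariant under monotone input transforms", {
  n <- 2000
  withr::with_seed(3, {
    x <- runif(n); y <- stats::rnorm(n)
  })
  out <- 2 * x - y + withr::with_seed(4, stats::rnorm(n, sd = 0.3))
  r1 <- contribution_to_variance(list(x = x, y = y), out)
  r2 <- contribution_to_variance(list(x = exp(3 * x), y = y^3), out)
  expect_equal(r1$contribution, r2$contribution, tolerance = 1e-10)
  expect_lt(r1$contribution[2], 0)  # negative effect keeps negative sign
})

test_that("degenerate inputs warn or error as contracted", {
  x <- withr::with_seed(5, runif(200))
  expect_warning(res <- contribution_to_variance(
    list(x = x, z = rep(1, 200)), x), "zero variance")
  expect_equal(res$contribution[res$input == "z"], 0)
  expect_error(
    suppressWarnings(contribution_to_variance(list(z = rep(1, 200)), x)),
    "no attributable variance")
  expect_error(contribution_to_variance(list(x = x[1:50]), x[1:50]),
               "at least 100")
  expect_error(contribution_to_variance(list(x, x), x), "named")
})

test_that("ranking is by magnitude with alphabetical tie-break", {
  res <- structure(data.frame(input = c("b", "a", "c"),
                              rho = c(0.5, -0.5, 0.1),
                              contribution = c(40, -40, 20)),
                   class = c("sensitivity_result", "data.frame"))
  ord <- rank_sensitivities(res)
  expect_equal(ord$input, c("a", "b", "c"))
  expect_error(rank_sensitivities(res[0, ]), "empty")
})

test_that("an independent input barely perturbs the decomposition", {
  n <- 1e5
  withr::with_seed(6, {
    x1 <- runif(n); x2 <- runif(n); noise <- runif(n)
  })
  out <- x1 + 0.5 * x2
  base <- contribution_to_variance(list(x1 = x1, x2 = x2), out)
  with_noise <- contribution_to_variance(
    list(x1 = x1, x2 = x2, noise = noise), out)
  expect_lt(abs(with_noise$contribution[3]), 2)
  expect_lt(max(abs(with_noise$contribution[1:2] - base$contribution[1:2])), 3)
})

test_that("pooled decomposition has the modelled sign structure", {
  study <- study_fixture()$study
  res <- sensitivity_pooled(study, iterations = 2e5, seed = 13)
  expect_setequal(res$input, c(letters[1:8], "I"))
  expect_equal(sum(abs(res$contribution)), 100, tolerance = 1e-6)
  iI <- res$input == "I"
  expect_gt(res$contribution[iI], 0)
  expect_true(all(res$contribution[!iI] < 0))
  expect_equal(rank_sensitivities(res)$input[1], "I")
})
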