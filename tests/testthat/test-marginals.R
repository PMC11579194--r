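test_that("continuous KDE marginal tracks the empirical distribution", {
  set.seed(11)
  x <- rnorm(1000)
  m <- fit_marginal(x, name = "z")
  expect_s3_class(m, "marginal_model")
  expect_equal(m$n_used, 1000)
  # cdf at the sample median is near one half
  expect_gt(pit(m, median(x)), 0.45)
  expect_lt(pit(m, median(x)), 0.55)
  # closed-form normal CDF oracle at 0
  expect_lt(abs(pit(m, 0) - pnorm(0)), 0.02)
  # strictly increasing in x
  grid <- seq(-2, 2, length.out = 50)
  expect_true(all(diff(pit(m, grid)) > 0))
  # left tail: 10 bandwidths below the data
  expect_lte(pit(m, min(x) - 10 * m$bw), 0.01)
  # missing values propagate
  expect_true(is.na(pit(m, c(NA, 0))[1]))
})

test_that("quantile and pit are inverse within tolerance", {
  set.seed(12)
  x <- rlnorm(800, meanlog = 3, sdlog = 0.4)
  m <- fit_marginal(x, log_scale = TRUE, name = "alt")
  # roundtrip at the 10/50/90 empirical percentiles
  for (q in quantile(x, c(0.1, 0.5, 0.9))) {
    expect_lt(abs(quantile(m, pit(m, q)) - q) / q, 1e-4)
  }
  # pit(quantile(u)) = u on the same interpolation table
  u <- c(0.05, 0.3, 0.5, 0.9)
  expect_lt(max(abs(pit(m, quantile(m, u)) - u)), 1e-6)
  # log-scale outputs strictly positive even in the far tails
  expect_true(all(quantile(m, c(1e-9, 0.5, 1 - 1e-9)) > 0))
  expect_error(quantile(m, 1.2), "inside \\(0, 1\\)")
})

test_that("PIT of a sample from the fitted model is uniform", {
  set.seed(13)
  m <- fit_marginal(rnorm(2000, 5, 2))
  u <- pit(m, quantile(m, runif(1e4)))
  expect_lt(ks_stat_uniform(u), 0.02)
})

test_that("categorical marginals and the randomized PIT behave", {
  m1 <- fit_marginal(rep("a", 50), kind = "categorical")
  expect_equal(m1$probs, c(a = 1))
  withr::with_seed(1, expect_true(all(pit_categorical(m1, rep("a", 100)) > 0 &
                                        pit_categorical(m1, rep("a", 100)) <= 1)))

  m2 <- fit_marginal(rep(c("lo", "hi"), each = 50), kind = "categorical",
                     levels = c("lo", "hi"))
  expect_lt(abs(sum(m2$probs) - 1), 1e-12)
  withr::with_seed(2, {
    u_lo <- pit_categorical(m2, rep("lo", 200))
    expect_true(all(u_lo > 0 & u_lo <= 0.5))
  })
  expect_error(pit_categorical(m2, "unseen"), "unknown level")
  expect_error(pit(m2, 1), "continuous")
  expect_error(pit_categorical(fit_marginal(rnorm(50)), "a"), "categorical")

  # randomized PIT uniformity: mixing levels with probs (0.2, 0.8)
  m3 <- fit_marginal(c(rep("a", 20), rep("b", 80)), kind = "categorical")
  withr::with_seed(3, {
    labs <- sample(c("a", "b"), 1e5, replace = TRUE, prob = c(0.2, 0.8))
    u <- pit_categorical(m3, labs)
  })
  expect_lt(ks_stat_uniform(u), 0.01)
})

test_that("weights rescale observations consistently", {
  set.seed(14)
  x <- rnorm(200, 50, 8)
  m0 <- fit_marginal(x)
  m1 <- fit_marginal(x, weights = rep(1, 200))
  expect_lt(max(abs(m0$cdf - m1$cdf)), 1e-10)
  # duplicating a row equals doubling its weight
  w <- rep(1, 200); w[7] <- 2
  md <- fit_marginal(c(x, x[7]))
  mw <- fit_marginal(x, weights = w)
  expect_equal(md$grid, mw$grid)
  expect_lt(max(abs(md$cdf - mw$cdf)), 1e-8)
  # weighted categorical frequencies
  mc <- fit_marginal(c("a", "b"), weights = c(3, 1), kind = "categorical")
  expect_equal(unname(mc$probs), c(0.75, 0.25))
})

test_that("marginal estimation rejects invalid inputs", {
  expect_error(fit_marginal(rep(NA_real_, 20)), ">= 10 non-missing")
  expect_error(fit_marginal(rnorm(5)), ">= 10 non-missing")
  expect_error(fit_marginal(c(rlnorm(20), -1), log_scale = TRUE,
                            name = "scr"),
               "index 21")
  expect_error(fit_marginal(rep(1, 30)), "zero variance")
  expect_error(fit_marginal(rnorm(10), weights = rep(0, 10)), "not all zero")
})

test_that("marginal models roundtrip through JSON", {
  set.seed(15)
  m <- fit_marginal(rlnorm(300), log_scale = TRUE, name = "scr")
  m2 <- marginal_from_json(marginal_to_json(m))
  u <- c(0.1, 0.5, 0.9)
  expect_equal(quantile(m2, u), quantile(m, u))
  mc <- fit_marginal(c("a", "a", "b"), kind = "categorical")
  mc2 <- marginal_from_json(marginal_to_json(mc))
  expect_equal(mc2$probs, mc$probs)
  expect_equal(mc2$levels, mc$levels)
})
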