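test_that("independence and zero-correlation densities are flat", {
  expect_equal(dbicop(0.37, 0.91, bicop_dist("independence")), 1.0)
  expect_equal(dbicop(0.3, 0.7, bicop_dist("gaussian", 0, 0)), 1.0)
  ind <- bicop_dist("independence")
  expect_equal(hbicop(0.4, 0.9, ind), 0.4)
  expect_equal(hbicop(0.4, 0.9, ind, cond_var = 1), 0.9)
  expect_equal(hbicop_inv(0.25, 0.6, ind), 0.25)
})

test_that("copula densities have uniform margins", {
  for (cop in example_bicops()) {
    m <- integrate(function(v) dbicop(rep(0.3, length(v)), v, cop), 0, 1,
                   rel.tol = 1e-6)$value
    expect_lt(abs(m - 1), 1e-3)
    m2 <- integrate(function(u) dbicop(u, rep(0.8, length(u)), cop), 0, 1,
                    rel.tol = 1e-6)$value
    expect_lt(abs(m2 - 1), 1e-3)
  }
})

test_that("clayton density matches the mixed partial of its CDF", {
  cop <- bicop_dist("clayton", 0, 2)
  h <- 1e-4
  fd <- (pbicop(0.5 + h, 0.5 + h, cop) - pbicop(0.5 + h, 0.5 - h, cop) -
           pbicop(0.5 - h, 0.5 + h, cop) + pbicop(0.5 - h, 0.5 - h, cop)) /
    (4 * h^2)
  expect_lt(abs(dbicop(0.5, 0.5, cop) - fd) / fd, 1e-4)
})

test_that("h-functions match finite differences of the CDF", {
  set.seed(21)
  for (cop in example_bicops()) {
    u <- runif(5, 0.15, 0.85)
    v <- runif(5, 0.15, 0.85)
    expect_lt(max(abs(hbicop(u, v, cop, 2) - hfunc_fd(cop, u, v, 2))), 1e-4)
    expect_lt(max(abs(hbicop(u, v, cop, 1) - hfunc_fd(cop, u, v, 1))), 1e-4)
  }
})

test_that("h-functions hit the boundaries and increase in the argument", {
  for (cop in example_bicops()) {
    v <- 0.37
    expect_lt(hbicop(1e-9, v, cop), 1e-3)
    expect_gt(hbicop(1 - 1e-9, v, cop), 1 - 1e-3)
    u <- seq(0.02, 0.98, length.out = 40)
    expect_true(all(diff(hbicop(u, rep(v, 40), cop)) > 0))
  }
})

test_that("hinv inverts hfunc to 1e-8 for every family and rotation", {
  set.seed(22)
  for (cop in example_bicops()) {
    p <- runif(100, 0.01, 0.99)
    v <- runif(100, 0.01, 0.99)
    u <- hbicop_inv(p, v, cop, 2)
    expect_lt(max(abs(hbicop(u, v, cop, 2) - p)), 1e-8)
    y <- hbicop_inv(p, v, cop, 1)
    expect_lt(max(abs(hbicop(v, y, cop, 1) - p)), 1e-8)
  }
})

test_that("par_to_tau matches closed forms and Monte Carlo", {
  expect_equal(par_to_tau(bicop_dist("clayton", 0, 2)), 0.5)
  expect_equal(par_to_tau(bicop_dist("gumbel", 0, 1)), 0)
  expect_equal(par_to_tau(bicop_dist("gaussian", 0, 0)), 0)
  expect_equal(par_to_tau(bicop_dist("gaussian", 0, 0.8)),
               2 / pi * asin(0.8))
  # rotations flip the sign
  expect_equal(par_to_tau(bicop_dist("clayton", 90, 2)), -0.5)
  expect_equal(par_to_tau(bicop_dist("clayton", 180, 2)), 0.5)
  # integral-based taus cross-checked by simulation
  for (cop in list(bicop_dist("joe", 0, 3), bicop_dist("bb8", 0, c(4, 0.7)),
                   bicop_dist("frank", 0, -4))) {
    uv <- simulate_bicop(cop, 2e4, seed = 5)
    expect_lt(abs(ktau(uv[, 1], uv[, 2]) - par_to_tau(cop)), 0.03)
  }
})

test_that("simulation is seeded, uniform in its margins, and tau-correct", {
  cop <- bicop_dist("gaussian", 0, 0.8)
  expect_equal(nrow(simulate_bicop(cop, 0)), 0)
  expect_identical(simulate_bicop(cop, 50, seed = 3),
                   simulate_bicop(cop, 50, seed = 3))
  uv <- simulate_bicop(cop, 1e4, seed = 4)
  expect_lt(abs(ktau(uv[, 1], uv[, 2]) - 2 / pi * asin(0.8)), 0.03)
  for (cop in list(bicop_dist("gumbel", 180, 2), bicop_dist("bb1", 0, c(1, 2)))) {
    uv <- simulate_bicop(cop, 1e4, seed = 6)
    expect_lt(ks_stat_uniform(uv[, 1]), 0.02)
    expect_lt(ks_stat_uniform(uv[, 2]), 0.02)
  }
})

test_that("fit_bicop recovers parameters and respects AIC dominance", {
  uv <- simulate_bicop(bicop_dist("clayton", 0, 2), 5000, seed = 11)
  fit <- fit_bicop(uv[, 1], uv[, 2])
  expect_equal(fit$family, "clayton")
  expect_lt(abs(par_to_tau(fit) - 0.5), 0.05)
  expect_lte(fit$aic, 0)  # independence is always a candidate with AIC 0

  # null data: independence or negligible dependence
  withr::with_seed(12, {
    u <- runif(5000); v <- runif(5000)
  })
  fit0 <- fit_bicop(u, v)
  expect_true(fit0$family == "independence" || abs(par_to_tau(fit0)) < 0.05)
})

test_that("fitting a 90-rotated clayton finds negative dependence", {
  uv <- simulate_bicop(bicop_dist("clayton", 90, 2), 5000, seed = 13)
  fit <- fit_bicop(uv[, 1], uv[, 2])
  expect_lt(par_to_tau(fit), 0)
  expect_lt(abs(abs(par_to_tau(fit)) - 0.5), 0.05)
})

test_that("doubling weights equals duplicating rows in fit_bicop", {
  uv <- simulate_bicop(bicop_dist("gumbel", 0, 1.8), 400, seed = 14)
  f1 <- fit_bicop(rep(uv[, 1], 2), rep(uv[, 2], 2), family_set = "gumbel")
  f2 <- fit_bicop(uv[, 1], uv[, 2], weights = rep(2, 400),
                  family_set = "gumbel")
  expect_lt(max(abs(f1$parameters - f2$parameters)), 1e-6)
})

test_that("small samples fall back to independence with a warning", {
  expect_warning(fit <- fit_bicop(runif(10), runif(10)), "independence")
  expect_equal(fit$family, "independence")
  expect_equal(fit$aic, 0)
})

test_that("parameter validation rejects inadmissible values", {
  expect_error(bicop_dist("clayton", 0, -1), "admissible")
  expect_error(bicop_dist("gaussian", 0, 1.5), "admissible")
  expect_error(bicop_dist("gaussian", 90, 0.5), "rotation")
  expect_error(bicop_dist("student_t", 0, 0.5), "parameter")
  expect_error(bicop_dist("nope"), "arg")
})

test_that("bicop JSON roundtrip preserves evaluation", {
  cop <- bicop_dist("bb1", 270, c(1.2, 1.7))
  cop2 <- bicop_from_json(bicop_to_json(cop))
  u <- c(0.2, 0.5, 0.8); v <- c(0.7, 0.3, 0.6)
  expect_identical(dbicop(u, v, cop2), dbicop(u, v, cop))
  expect_identical(cop2$rotation, cop$rotation)
})
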