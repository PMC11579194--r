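test_that("relative error follows its definition", {
  expect_equal(relative_error(1.1, 1.0), 0.1)
  expect_equal(relative_error(5, 5), 0)
  expect_equal(relative_error(0.9, 1.0), -0.1)
  expect_error(relative_error(1, 0), "undefined")
})

test_that("marginal metrics agree with a brute-force oracle", {
  expect_equal(marginal_metrics(rep(3, 10)),
               c(mean = 3, sd = 0, p5 = 3, p50 = 3, p95 = 3))
  expect_equal(marginal_metrics(1:100)[["p50"]], 50.5)
  # brute-force type-7 percentile: interpolate expanded order statistics
  oracle_q <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  withr::with_seed(61, {
    for (n in c(17, 53, 100)) {
      x <- rnorm(n)
      m <- marginal_metrics(x)
      expect_equal(m[["mean"]], sum(x) / n)
      expect_equal(m[["sd"]], sqrt(sum((x - mean(x))^2) / (n - 1)))
      expect_equal(m[["p5"]], oracle_q(x, 0.05))
      expect_equal(m[["p95"]], oracle_q(x, 0.95))
    }
  })
  # large-sample normal quantile
  withr::with_seed(62, x <- rnorm(1e5))
  expect_lt(abs(marginal_metrics(x)[["p95"]] - qnorm(0.95)), 0.02)
  expect_error(marginal_metrics(numeric(0)), "non-missing")
})

test_that("density contours enclose the target mass with sensible area", {
  withr::with_seed(63, {
    x <- rnorm(5000); y <- rnorm(5000)
  })
  dc <- density_contour(x, y)
  expect_s3_class(dc, "density_contour")
  expect_gte(dc$enclosed_mass, 0.94)
  expect_lte(dc$enclosed_mass, 0.96)
  # analytic 95% HDR of the standard bivariate normal has area 2*pi*log(20)
  expect_lt(abs(dc$area - 2 * pi * log(20)) / (2 * pi * log(20)), 0.15)
  expect_gte(length(dc$rings), 1)

  # two well-separated clusters yield at least two rings
  withr::with_seed(64, {
    x2 <- c(rnorm(500), rnorm(500) + 30)
    y2 <- c(rnorm(500), rnorm(500) + 30)
  })
  dc2 <- density_contour(x2, y2)
  expect_gte(length(dc2$rings), 2)

  expect_error(density_contour(rep(1, 200), rnorm(200)), "degenerate")
  expect_error(density_contour(rnorm(50), rnorm(50)), "100")
})

test_that("the Jaccard overlap is calibrated, symmetric and bounded", {
  withr::with_seed(65, {
    a <- matrix(rnorm(4000), ncol = 2)
    b <- matrix(rnorm(4000), ncol = 2)
  })
  expect_gte(overlap_metric(a, a), 99)
  expect_equal(overlap_metric(a, b + 100), 0)
  o1 <- overlap_metric(a, b)
  expect_identical(o1, overlap_metric(b, a))
  expect_gte(o1, 0); expect_lte(o1, 100)
  expect_gt(o1, 70)  # same distribution at n = 2000 overlaps strongly
})

test_that("correlation comparison reports per-pair absolute errors", {
  withr::with_seed(66, {
    z <- rnorm(2000)
    obs <- data.frame(x = z + rnorm(2000, sd = 0.7), y = z, w = rnorm(2000))
    sim_ind <- data.frame(x = rnorm(2000), y = rnorm(2000), w = rnorm(2000))
  })
  same <- correlation_comparison(covariate_table(obs), obs)
  expect_true(all(same$abs_error == 0))
  cc <- correlation_comparison(covariate_table(obs), sim_ind)
  r_obs <- cor(obs$x, obs$y)
  got <- cc$abs_error[cc$var1 == "x" & cc$var2 == "y"]
  expect_lt(abs(got - abs(r_obs)), 0.05)
  # antithetic versus identical pair: error 2
  anti <- data.frame(x = z, y = z, w = rnorm(2000))
  anti_sim <- data.frame(x = z, y = -z, w = rnorm(2000))
  cc2 <- correlation_comparison(covariate_table(anti), anti_sim)
  expect_equal(cc2$abs_error[cc2$var1 == "x" & cc2$var2 == "y"], 2,
               tolerance = 1e-12)
  # constant columns are skipped with a warning
  obs$w <- 1
  expect_warning(correlation_comparison(covariate_table(obs), sim_ind),
                 "constant")
})

test_that("evaluate_model is self-consistent on its own training data", {
  tab <- generate_fixture(fixture_spec(
    n = 3000, seed = 67, covariates = c("sex", "age", "weight", "height", "scr"),
    missingness = NULL))
  fit <- fit_vine(tab)
  rep3 <- evaluate_model(tab, fit, n_replicates = 3, seed = 68,
                         gridsize = 128)
  expect_s3_class(rep3, "evaluation_report")
  expect_lt(rep3$summary$median_abs_re, 0.1)
  expect_lt(rep3$summary$median_correlation_error, 0.1)
  expect_gt(rep3$summary$median_overlap, 80)
  # replicates differ but share a schema
  expect_gt(length(unique(rep3$marginal$m_sim)), 5)
  expect_equal(sort(unique(rep3$marginal$replicate)), 1:3)
  expect_equal(nrow(rep3$summary$overlap_by_pair), choose(4, 2))
  # single replicate: coefficient of variation is undefined, flagged NA
  rep1 <- evaluate_model(tab, fit, n_replicates = 1, seed = 69,
                         gridsize = 64)
  expect_true(all(is.na(rep1$summary$re_by_metric$cv_sim)))
})

test_that("holdout validation reconstructs an MCAR-independent target", {
  # target independent of the anchor: masking by anchor bands is ignorable
  withr::with_seed(70, {
    df <- data.frame(age = runif(1500, 20, 80),
                     target = rlnorm(1500, 3, 0.3),
                     other = rnorm(1500, 50, 5))
  })
  tab <- covariate_table(df, log_scale = "target")
  out <- holdout_missing_validation(tab, "target",
                                    list(c(40, 60)), anchor_covariate = "age",
                                    family_set = c("independence", "gaussian"),
                                    seed = 71)
  expect_equal(nrow(out), 1)
  expect_lt(abs(out$re_mean), 0.1)

  # no bands: reduces to a whole-table check of the target
  out0 <- holdout_missing_validation(tab, "target", list(),
                                     family_set = "gaussian", seed = 72)
  expect_true(is.na(out0$band_lower))
  expect_lt(abs(out0$re_mean), 0.1)

  # masking all target data makes the marginal unestimable
  expect_error(
    holdout_missing_validation(tab, "target", list(c(0, 100)),
                               family_set = "gaussian", seed = 73),
    "target")
})

test_that("subgroup strategies coincide for a homogeneous population", {
  tab <- generate_fixture(fixture_spec(
    n = 1200, seed = 74, covariates = c("weight", "height", "scr"),
    missingness = NULL))
  withr::with_seed(75, g <- sample(c("g1", "g2"), nrow(tab), replace = TRUE))
  df <- as.data.frame(tab)
  df$grp <- g
  tabg <- covariate_table(df, kinds = c(grp = "categorical"),
                          log_scale = "scr")
  cmp <- compare_subgroup_strategies(tabg, "grp",
                                     family_set = c("independence",
                                                    "gaussian"),
                                     n_replicates = 2, seed = 76,
                                     gridsize = 128)
  expect_named(cmp, c("g1", "g2"))
  for (g in names(cmp)) {
    d <- abs(cmp[[g]]$filtered_full$summary$median_overlap -
               cmp[[g]]$subgroup$summary$median_overlap)
    expect_lt(d, 5)
  }
  # undersized groups are skipped with a warning
  df$grp[df$grp == "g2"] <- "g1"
  df$grp[1:50] <- "tiny"
  tabs <- covariate_table(df, kinds = c(grp = "categorical"),
                          log_scale = "scr")
  expect_warning(
    cmp2 <- compare_subgroup_strategies(tabs, "grp",
                                        family_set = "independence",
                                        n_replicates = 1, seed = 77,
                                        gridsize = 64),
    "skipped")
  expect_named(cmp2, "g1")
})
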