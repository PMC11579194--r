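test_that("select_tree picks the maximum spanning tree deterministically", {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- w["B", "A"] <- 0.6
  w["B", "C"] <- w["C", "B"] <- 0.5
  w["A", "C"] <- w["C", "A"] <- 0.1
  tr <- select_tree(c("A", "B", "C"), w)
  expect_equal(tree_edge_set(tr), c("A~B", "B~C"))

  # two nodes: the single edge
  w2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(nrow(select_tree(c("x", "y"), w2)), 1)

  # 12 covariates give 11 first-tree edges
  set.seed(31)
  nms <- paste0("c", 1:12)
  w12 <- matrix(runif(144), 12, dimnames = list(nms, nms))
  w12 <- (w12 + t(w12)) / 2
  diag(w12) <- 0
  expect_equal(nrow(select_tree(nms, w12)), 11)
})

test_that("select_tree agrees with brute-force enumeration", {
  for (s in 1:20) {
    withr::with_seed(100 + s, {
      k <- sample(3:6, 1)
      nms <- letters[1:k]
      w <- matrix(runif(k * k), k, dimnames = list(nms, nms))
      w <- (w + t(w)) / 2
      diag(w) <- 0
    })
    tr <- select_tree(nms, w)
    bf <- brute_force_mst(nms, w)
    expect_equal(sum(tr$weight), bf$weight, tolerance = 1e-12)
  }
})

test_that("a two-covariate vine reduces to a single bivariate copula", {
  tab <- sim_gauss_dvine(800, seed = 2)[, c("v1", "v2")]
  fit <- fit_vine(covariate_table(as.data.frame(tab)))
  expect_length(fit$edges, 1)
  expect_equal(fit$loglik, fit$edges[[1]]$cop$loglik)
  expect_equal(loglik_vine(fit, tab), fit$loglik, tolerance = 1e-8)
})

test_that("fitted vines satisfy the regular-vine structure invariants", {
  tab <- generate_fixture(fixture_spec(
    n = 600, seed = 41,
    covariates = c("sex", "age", "weight", "height", "scr", "alt"),
    missingness = NULL))
  fit <- fit_vine(tab, family_set = c("gaussian", "clayton", "frank"))
  expect_silent(vinepop:::validate_vine_structure(fit))
  d <- length(fit$variables)
  expect_length(fit$trees, d - 1)
  for (t in seq_along(fit$trees)) {
    expect_length(fit$trees[[t]], d - t)
    for (id in fit$trees[[t]])
      expect_length(fit$edges[[id]]$conditioning, t - 1)
  }
})

test_that("fit_vine recovers a known Gaussian D-vine", {
  taus <- c(0.6, 0.5, 0.4)
  tab <- sim_gauss_dvine(5000, taus, seed = 7)
  fit <- fit_vine(tab, family_set = "gaussian")
  expect_equal(first_tree_edges(fit), c("v1~v2", "v2~v3", "v3~v4"))
  got <- sapply(fit$trees[[1]], function(id) {
    e <- fit$edges[[id]]
    setNames(par_to_tau(e$cop), paste(e$conditioned, collapse = "~"))
  })
  expect_lt(max(abs(got[c("v1~v2", "v2~v3", "v3~v4")] - taus)), 0.05)
})

test_that("simulate-then-refit recovers first-tree taus", {
  tab <- sim_gauss_dvine(4000, seed = 8)
  fit <- fit_vine(tab, family_set = "gaussian")
  vp <- simulate_vine(fit, 5000, seed = 9)
  refit <- fit_vine(vp, family_set = "gaussian")
  expect_equal(first_tree_edges(refit), first_tree_edges(fit))
  tau_of <- function(m) sort(sapply(m$trees[[1]], function(id)
    setNames(par_to_tau(m$edges[[id]]$cop),
             paste(m$edges[[id]]$conditioned, collapse = "~"))))
  expect_lt(max(abs(tau_of(refit) - tau_of(fit))), 0.05)
})

test_that("missing data degrade the fit gracefully", {
  tab <- sim_gauss_dvine(4000, seed = 10)
  full <- fit_vine(tab, family_set = "gaussian")
  tab2 <- tab
  withr::with_seed(11, {
    tab2$v2[runif(nrow(tab2)) < 0.3] <- NA
  })
  part <- fit_vine(covariate_table(as.data.frame(tab2)),
                   family_set = "gaussian")
  tau_of <- function(m) sapply(m$trees[[1]], function(id)
    setNames(par_to_tau(m$edges[[id]]$cop),
             paste(m$edges[[id]]$conditioned, collapse = "~")))
  t1 <- tau_of(full); t2 <- tau_of(part)
  shared <- intersect(names(t1), names(t2))
  expect_gt(length(shared), 0)
  expect_lt(max(abs(t1[shared] - t2[shared])), 0.07)
})

test_that("unit weights reproduce the unweighted fit exactly", {
  tab <- sim_gauss_dvine(800, seed = 12)
  f0 <- fit_vine(tab, family_set = c("gaussian", "clayton"))
  f1 <- fit_vine(tab, family_set = c("gaussian", "clayton"),
                 weights = rep(1, nrow(tab)))
  p0 <- unlist(lapply(f0$edges, function(e) e$cop$parameters))
  p1 <- unlist(lapply(f1$edges, function(e) e$cop$parameters))
  expect_identical(p0, p1)
})

test_that("categorical ordering search enumerates k! candidates", {
  tab <- generate_fixture(fixture_spec(n = 300, seed = 13,
                                       covariates = c("race", "height"),
                                       missingness = NULL))
  # collapse to 3 race levels for a 3! = 6 candidate search
  df <- as.data.frame(tab)
  df$race <- c(hispanic = "g1", white = "g1", african_american = "g2",
               asian = "g3", other = "g3")[df$race]
  tab3 <- covariate_table(df, kinds = c(race = "categorical",
                                        height = "continuous"))
  fit <- fit_vine_with_categorical(tab3, "race",
                                   family_set = c("independence", "gaussian"))
  expect_equal(fit$order_search$n_candidates, 6)
  expect_equal(fit$aic, min(fit$order_search$aic))

  # single level: a lone fit with a trivial order
  df$race <- "only"
  tab1 <- covariate_table(df, kinds = c(race = "categorical",
                                        height = "continuous"))
  fit1 <- fit_vine_with_categorical(tab1, "race", family_set = "gaussian")
  expect_equal(fit1$order_search$n_candidates, 1)
})

test_that("the ordering search refuses factorial explosions", {
  df <- data.frame(g = sample(letters[1:8], 300, replace = TRUE),
                   x = rnorm(300))
  tab <- covariate_table(df, kinds = c(g = "categorical", x = "continuous"))
  expect_error(fit_vine_with_categorical(tab, "g"), "pre-specify")
})

test_that("vine likelihood identities hold", {
  tab <- sim_gauss_dvine(1000, seed = 14)
  # an all-independence vine has zero log-likelihood
  f_ind <- fit_vine(tab, family_set = "independence")
  expect_equal(f_ind$loglik, 0)
  expect_equal(loglik_vine(f_ind, tab), 0)
  expect_equal(aic_vine(f_ind), 0)
  # a fitted vine dominates independence in AIC
  f <- fit_vine(tab, family_set = c("gaussian", "frank"))
  expect_lt(aic_vine(f), aic_vine(f_ind))
  expect_equal(aic_vine(f), 2 * f$npars - 2 * f$loglik)
  # schema mismatch
  expect_error(loglik_vine(f, tab[, c("v1", "v2")]), "missing covariates")
})

test_that("vine models roundtrip through JSON with identical simulations", {
  tab <- generate_fixture(fixture_spec(
    n = 500, seed = 15, covariates = c("sex", "age", "weight"),
    missingness = NULL))
  fit <- fit_vine(tab, family_set = c("gaussian", "clayton", "frank"))
  tf <- withr::local_tempfile(fileext = ".json")
  vine_to_json(fit, path = tf)
  fit2 <- vine_from_json(tf)
  expect_identical(simulate_vine(fit, 100, seed = 3),
                   simulate_vine(fit2, 100, seed = 3))
  expect_equal(fit2$aic, fit$aic)
  # serialization itself is deterministic
  tf2 <- withr::local_tempfile(fileext = ".json")
  vine_to_json(fit, path = tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("estimation errors name the offending covariate", {
  df <- data.frame(a = rnorm(30), b = c(rnorm(5), rep(NA, 25)))
  expect_error(fit_vine(covariate_table(df)), "'b'")
})
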