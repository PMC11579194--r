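# Virtual population simulation: inverse Rosenblatt transform through the
# vine, then per-covariate quantile back-transformation.

# Sampling order and per-variable h-inversion chains, derived from the tree
# sequence. The top tree's single edge has two conditioned variables; either
# is a "leaf" of the vine, appearing as a conditioned variable in exactly
# one edge per tree. Eliminating it (and its edges) leaves a regular vine on
# the remaining variables, so the construction recurses. The variable
# eliminated at stage k is sampled k-th, by inverting the chain
#   w -> hinv over trees k-1 .. 1
# against the conditional CDFs of its per-tree partners.
simulation_order <- function(model) {
  edges <- model$edges
  trees_work <- lapply(model$trees, function(ids) ids)
  d <- length(model$variables)
  remaining <- model$variables
  plan <- vector("list", d)
  for (k in d:2) {
    top_ids <- trees_work[[k - 1L]]
    stopifnot(length(top_ids) == 1L)
    a <- sort(edges[[top_ids]]$conditioned)[2]
    eids <- integer(k - 1L)
    partners <- character(k - 1L)
    for (t in seq_len(k - 1L)) {
      hit <- Filter(function(id) a %in% edges[[id]]$conditioned,
                    trees_work[[t]])
      stopifnot(length(hit) == 1L)
      e <- edges[[hit]]
      eids[t] <- hit
      partners[t] <- setdiff(e$conditioned, a)
      trees_work[[t]] <- setdiff(trees_work[[t]], hit)
    }
    plan[[k]] <- list(var = a, edge_ids = eids, partners = partners)
    remaining <- setdiff(remaining, a)
  }
  stopifnot(length(remaining) == 1L)
  plan[[1]] <- list(var = remaining, edge_ids = integer(0),
                    partners = character(0))
  plan
}

#' Simulate a virtual population from a fitted vine model
#'
#' Draws `n` complete covariate rows: independent uniforms are converted to
#' a dependent uniform-scale sample by chaining inverse h-functions through
#' the vine (inverse Rosenblatt transform), then each column is mapped to
#' its natural scale by the marginal quantile function — exponentiated for
#' log-scale covariates, so biochemical covariates are strictly positive —
#' and categorical columns are decoded by locating the uniform within the
#' cumulative level probabilities under the model's level ordering.
#'
#' @param model a fitted `vine_model`.
#' @param n number of subjects (`n = 0` gives an empty table with full
#'   schema).
#' @param seed optional integer seed; the draw is deterministic given the
#'   seed and does not disturb the caller's RNG state.
#' @return a [covariate_table()] with `n` rows and no missing values.
#' @examples
#' tab <- generate_fixture(fixture_spec(n = 500, seed = 1,
#'                                      covariates = c("age", "weight", "height")))
#' fit <- fit_vine(tab, family_set = "gaussian")
#' vp <- simulate_vine(fit, 200, seed = 7)
#' summary(vp$weight)
#' @export
simulate_vine <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "vine_model"), n >= 0)
  covs <- model$variables
  d <- length(covs)
  U <- with_seed_maybe(seed, {
    W <- matrix(runif(n * d), nrow = n, ncol = d)
    plan <- simulation_order(model)
    Um <- matrix(NA_real_, n, d, dimnames = list(NULL, covs))
    engine <- make_cond_engine(model$edges, Um)
    for (k in seq_len(d)) {
      st <- plan[[k]]
      z <- W[, k]
      if (k > 1L) {
        for (t in rev(seq_along(st$edge_ids))) {
          e <- model$edges[[st$edge_ids[t]]]
          b <- st$partners[t]
          cond <- get_cond(engine, model$edges, b, e$conditioning)
          cond_var <- if (e$conditioned[1] == st$var) 2L else 1L
          z <- hbicop_inv(z, cond, e$cop, cond_var = cond_var)
        }
      }
      Um[, st$var] <- z
      engine$U <- Um
    }
    Um
  })

  out <- as.data.frame(lapply(covs, function(nm) {
    m <- model$marginals[[nm]]
    if (n == 0) {
      if (m$kind == "continuous") numeric(0) else character(0)
    } else {
      quantile(m, U[, nm])
    }
  }), stringsAsFactors = FALSE, col.names = covs)
  names(out) <- covs
  covariate_table(out, kinds = model$schema$kinds[covs],
                  log_scale = names(which(model$schema$log_scale)))
}

#' @export
simulate.vine_model <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_vine(object, n = nsim, seed = seed)
}

#' Simulate a filtered subgroup population
#'
#' Rejection sampling for subgroup generation: simulate from the full model
#' in geometrically growing batches and keep the rows satisfying every
#' filter, until `n` rows are collected or the attempt budget is exhausted.
#' This is the "simulate from the full copula and filter out irrelevant
#' individuals" strategy; the alternative is fitting a copula to the
#' subgroup data directly (see [compare_subgroup_strategies()]).
#'
#' @param model a fitted `vine_model`.
#' @param n rows required.
#' @param filters a list of filter specifications, each a list with
#'   `covariate` and either `values` (category membership) or `min`/`max`
#'   (inclusive numeric range), e.g.
#'   `list(list(covariate = "sex", values = "female"),
#'         list(covariate = "age", min = 18, max = 60))`.
#' @param seed optional integer seed.
#' @param max_attempts cap on the total number of rows simulated (default
#'   `1e6`); if the empirical acceptance rate falls below `1e-4` once the
#'   cap is hit, the filter set is declared infeasible.
#' @return a [covariate_table()] with `n` rows (attribute `acceptance_rate`
#'   gives the empirical acceptance probability).
#' @export
simulate_subgroup <- function(model, n, filters = list(), seed = NULL,
                              max_attempts = 1e6) {
  stopifnot(inherits(model, "vine_model"), n >= 0)
  for (f in filters) {
    if (!is.list(f) || is.null(f$covariate) ||
        !f$covariate %in% model$variables)
      stop_domain("each filter needs a 'covariate' present in the model")
  }
  with_seed_maybe(seed, {
    kept <- NULL
    attempts <- 0
    batch <- max(4 * n, 100)
    while (is.null(kept) || nrow(kept) < n) {
      sim <- simulate_vine(model, batch)
      attempts <- attempts + batch
      keep <- rep(TRUE, nrow(sim))
      for (f in filters) {
        x <- sim[[f$covariate]]
        if (!is.null(f$values)) keep <- keep & x %in% f$values
        if (!is.null(f$min)) keep <- keep & x >= f$min
        if (!is.null(f$max)) keep <- keep & x <= f$max
      }
      kept <- if (is.null(kept)) sim[keep, ]
              else rbind(kept, sim[keep, ])
      rate <- nrow(kept) / attempts
      if (nrow(kept) < n && attempts >= max_attempts) {
        if (rate < 1e-4)
          stop_domain("infeasible filters: acceptance rate ",
                      signif(rate, 3), " after ", attempts, " attempts")
        break
      }
      batch <- min(2 * batch, max(max_attempts - attempts, 1))
    }
    out <- head(kept, n)
    attr(out, "acceptance_rate") <- nrow(kept) / attempts
    out
  })
}

#' Derive body mass index
#'
#' Appends `bmi = weight / (height / 100)^2` (kg/m^2) from a weight column
#' in kg and a height column in cm.
#'
#' @param table a covariate table or data.frame.
#' @param weight,height column names.
#' @return the table with a `bmi` column appended.
#' @examples
#' derive_bmi(data.frame(weight = 82.02, height = 167.16))$bmi  # 29.35
#' @export
derive_bmi <- function(table, weight = "weight", height = "height") {
  if (!all(c(weight, height) %in% names(table)))
    stop_domain("derive_bmi needs columns '", weight, "' and '", height, "'")
  h <- table[[height]]
  if (any(h <= 0, na.rm = TRUE))
    stop_domain("nonpositive height; BMI undefined")
  bmi <- table[[weight]] / (h / 100)^2
  if (inherits(table, "covariate_table")) {
    s <- ct_schema(table)
    df <- as.data.frame(table)
    df$bmi <- bmi
    covariate_table(df, kinds = c(s$kinds, bmi = "continuous"),
                    log_scale = names(which(s$log_scale)),
                    weight_col = s$weight_col, units = s$units)
  } else {
    table$bmi <- bmi
    table
  }
}
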