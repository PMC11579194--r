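# Vine copula estimation: sequential tree selection (maximum spanning tree
# on |Kendall tau| under the proximity condition) with per-edge AIC family
# selection, following the standard pair-copula-construction methodology.

# Pseudo-observations on the uniform scale. Continuous covariates go through
# the fitted KDE CDF; categorical covariates use the randomized PIT with the
# supplied jitter matrix (one uniform per row and categorical covariate) so
# that candidate level orderings can share a jitter realization.
pseudo_obs <- function(table, marginals, jitter) {
  covs <- names(marginals)
  U <- matrix(NA_real_, nrow(table), length(covs),
              dimnames = list(NULL, covs))
  for (nm in covs) {
    m <- marginals[[nm]]
    U[, nm] <- if (m$kind == "continuous") pit(m, table[[nm]])
               else pit_categorical(m, table[[nm]], jitter = jitter[, nm])
  }
  U
}

draw_jitter <- function(n, cat_covs, pit_seed) {
  J <- matrix(numeric(0), n, 0)
  if (length(cat_covs))
    J <- with_seed_maybe(pit_seed,
                         matrix(runif(n * length(cat_covs)), n,
                                dimnames = list(NULL, cat_covs)))
  J
}

# Memoized conditional-CDF engine. get(var, condset) returns the vector
# F(u_var | u_condset) for every row of env$U, by locating the fitted edge
# whose conditioned set contains `var` and whose variable set equals
# {var} U condset, then recursing through its h-function. Regular-vine
# structure guarantees the required edge exists for every query raised by
# fitting, likelihood evaluation and simulation; NAs propagate row-wise.
make_cond_engine <- function(edges, U) {
  env <- new.env(parent = emptyenv())
  env$U <- U
  env$cache <- new.env(parent = emptyenv())
  lookup <- new.env(parent = emptyenv())
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    for (a in e$conditioned) {
      b <- setdiff(e$conditioned, a)
      key <- cond_key(a, c(b, e$conditioning))
      assign(key, i, envir = lookup)
    }
  }
  env$lookup <- lookup
  env
}

cond_key <- function(var, condset) {
  paste0(var, "|", paste(sort(condset), collapse = ","))
}

get_cond <- function(engine, edges, var, condset) {
  if (!length(condset)) return(engine$U[, var])
  key <- cond_key(var, condset)
  if (!is.null(engine$cache[[key]])) return(engine$cache[[key]])
  if (is.null(engine$lookup[[key]]))
    stop_domain("conditional F(", var, " | ",
                paste(condset, collapse = ","),
                ") is not representable in this vine")
  e <- edges[[engine$lookup[[key]]]]
  other <- setdiff(e$conditioned, var)
  D <- e$conditioning
  x <- get_cond(engine, edges, e$conditioned[1], D)
  y <- get_cond(engine, edges, e$conditioned[2], D)
  val <- hbicop(x, y, e$cop, cond_var = if (e$conditioned[1] == var) 2 else 1)
  engine$cache[[key]] <- val
  val
}

#' Fit a vine copula model to a covariate table
#'
#' Estimates the full joint distribution of a covariate table: marginals by
#' kernel density estimation (log scale where the schema says so), then a
#' regular vine over the pseudo-observations. Each tree is selected by a
#' maximum spanning tree on absolute pairwise Kendall taus of the
#' (conditional) pseudo-observations, restricted by the proximity condition;
#' each selected edge gets the AIC-best parametric pair copula. Rows missing
#' any variable an edge needs are dropped for that edge only, so incomplete
#' tables are usable without imputation.
#'
#' @param table a [covariate_table()] (or data.frame coerced with default
#'   schema).
#' @param family_set candidate pair-copula families (see [bicop_dist()]).
#' @param weights optional per-subject sampling weights; defaults to the
#'   table's weight column. Weighted fits rescale every observation's
#'   log-likelihood contribution.
#' @param truncation fit copulas only up to this tree level; higher trees
#'   are set to independence (the default `Inf` fits all `d - 1` trees).
#' @param pit_seed integer seed for the randomized PIT jitter of categorical
#'   covariates; recorded in the model so fits are reproducible.
#' @param categorical_levels optional named list giving the level ordering
#'   to use for categorical covariates (defaults to sorted levels; see
#'   [fit_vine_with_categorical()] for the AIC search over orderings).
#' @return an object of class `vine_model`: variables, trees, fitted edges,
#'   marginals, log-likelihood, AIC, parameter count and seeds.
#' @examples
#' tab <- generate_fixture(fixture_spec(n = 400, seed = 1,
#'                                      covariates = c("age", "weight", "height")))
#' fit <- fit_vine(tab, family_set = "gaussian")
#' fit
#' @export
fit_vine <- function(table, family_set = FAMILY_NAMES, weights = NULL,
                     truncation = Inf, pit_seed = 1L,
                     categorical_levels = NULL) {
  if (!inherits(table, "covariate_table")) table <- covariate_table(table)
  schema <- ct_schema(table)
  covs <- ct_covariates(table)
  d <- length(covs)
  if (d < 2L) stop_domain("need at least 2 covariates")
  n <- nrow(table)
  w <- weights %||% ct_weights(table)
  if (!is.null(w) && length(w) != n)
    stop_domain("weights must have one entry per row")

  marginals <- lapply(covs, function(nm) {
    fit_marginal(table[[nm]], weights = w,
                 log_scale = schema$log_scale[[nm]],
                 kind = schema$kinds[[nm]], name = nm,
                 levels = categorical_levels[[nm]])
  })
  names(marginals) <- covs

  cat_covs <- covs[vapply(marginals, function(m) m$kind == "categorical",
                          logical(1))]
  jitter <- draw_jitter(n, cat_covs, pit_seed)
  U <- pseudo_obs(table, marginals, jitter)

  edges <- list()
  trees <- list()
  engine <- make_cond_engine(edges, U)

  # nodes of the current tree: tree 1 has variables, later trees have the
  # previous tree's edge ids; each node knows its variable (full) set
  node_labels <- covs
  node_sets <- as.list(covs)

  for (t in seq_len(d - 1L)) {
    # candidate edges under proximity, weighted by |tau|
    if (t == 1L) {
      cand_pairs <- utils::combn(seq_along(node_labels), 2)
    } else {
      prev_edges <- lapply(trees[[t - 1L]], function(id) edges[[id]])
      adj <- utils::combn(seq_along(node_labels), 2)
      share <- apply(adj, 2, function(ij) {
        length(intersect(as.character(prev_edges[[ij[1]]]$nodes),
                         as.character(prev_edges[[ij[2]]]$nodes))) > 0
      })
      cand_pairs <- adj[, share, drop = FALSE]
    }
    if (!ncol(cand_pairs))
      stop_domain("no admissible edges in tree ", t)

    cand <- vector("list", ncol(cand_pairs))
    for (k in seq_len(ncol(cand_pairs))) {
      i <- cand_pairs[1, k]; j <- cand_pairs[2, k]
      si <- node_sets[[i]]; sj <- node_sets[[j]]
      conditioned <- sort(c(setdiff(si, sj), setdiff(sj, si)))
      conditioning <- sort(intersect(si, sj))
      x <- get_cond(engine, edges, conditioned[1], conditioning)
      y <- get_cond(engine, edges, conditioned[2], conditioning)
      tau <- ktau(x, y)
      cand[[k]] <- list(i = i, j = j, conditioned = conditioned,
                        conditioning = conditioning,
                        weight = if (is.na(tau)) 0 else abs(tau),
                        tau = tau)
    }
    cdf_ <- data.frame(
      from = node_labels[vapply(cand, `[[`, integer(1), "i")],
      to = node_labels[vapply(cand, `[[`, integer(1), "j")],
      weight = vapply(cand, `[[`, numeric(1), "weight"),
      k = seq_along(cand), stringsAsFactors = FALSE
    )
    mst <- kruskal_max(node_labels, cdf_)

    new_ids <- integer(0)
    for (r in seq_len(nrow(mst))) {
      ce <- cand[[mst$k[r]]]
      x <- get_cond(engine, edges, ce$conditioned[1], ce$conditioning)
      y <- get_cond(engine, edges, ce$conditioned[2], ce$conditioning)
      ok <- !is.na(x) & !is.na(y)
      cop <- if (t > truncation) {
        ind <- bicop_dist("independence")
        ind$loglik <- 0; ind$n_fit <- sum(ok); ind$aic <- 0
        ind
      } else {
        fit_bicop(x[ok], y[ok],
                  weights = if (is.null(w)) NULL else w[ok],
                  family_set = family_set)
      }
      id <- length(edges) + 1L
      node_ids <- if (t == 1L) ce$conditioned
                  else c(trees[[t - 1L]][ce$i], trees[[t - 1L]][ce$j])
      edges[[id]] <- list(
        id = id, tree = t, conditioned = ce$conditioned,
        conditioning = ce$conditioning, nodes = node_ids,
        cop = cop, tau_emp = ce$tau, n_complete = sum(ok)
      )
      new_ids <- c(new_ids, id)
    }
    trees[[t]] <- new_ids
    # rebuild engine lookup with the new edges; keep the value cache
    cache <- engine$cache
    engine <- make_cond_engine(edges, U)
    engine$cache <- cache

    node_labels <- as.character(new_ids)
    node_sets <- lapply(new_ids, function(id)
      sort(c(edges[[id]]$conditioned, edges[[id]]$conditioning)))
  }

  loglik <- sum(vapply(edges, function(e) e$cop$loglik, numeric(1)))
  npars <- sum(vapply(edges, function(e) length(e$cop$parameters),
                      numeric(1)))
  model <- structure(
    list(variables = covs, trees = trees, edges = edges,
         marginals = marginals, schema = schema,
         categorical_order = lapply(marginals[cat_covs], `[[`, "levels"),
         pit_seed = as.integer(pit_seed), weighted = !is.null(w),
         family_set = family_set, truncation = truncation,
         n_fit = n, loglik = loglik, npars = npars,
         aic = 2 * npars - 2 * loglik),
    class = "vine_model"
  )
  validate_vine_structure(model)
  model
}

#' Search categorical level orderings by AIC
#'
#' Copulas over unordered categorical variables are not identified: the
#' randomized PIT depends on the level ordering. This fits one vine per
#' permutation of the levels of `categorical_covariate` (k! candidates,
#' sharing a single PIT jitter realization so AICs are comparable) and
#' returns the minimum-AIC model, which records the chosen order.
#'
#' @inheritParams fit_vine
#' @param categorical_covariate name of the categorical covariate whose
#'   level ordering is searched; must have at most 7 levels (beyond that,
#'   pre-specify an order via `categorical_levels` in [fit_vine()]).
#' @return the minimum-AIC `vine_model`, with `$order_search` recording the
#'   number of candidate fits and the AIC per ordering.
#' @export
fit_vine_with_categorical <- function(table, categorical_covariate,
                                      family_set = FAMILY_NAMES,
                                      weights = NULL, truncation = Inf,
                                      pit_seed = 1L) {
  if (!inherits(table, "covariate_table")) table <- covariate_table(table)
  schema <- ct_schema(table)
  if (!categorical_covariate %in% ct_covariates(table) ||
      schema$kinds[[categorical_covariate]] != "categorical")
    stop_domain("'", categorical_covariate,
                "' is not a categorical covariate of the table")
  lev <- sort(unique(stats::na.omit(as.character(
    table[[categorical_covariate]]))))
  k <- length(lev)
  if (k > 7L)
    stop_domain(k, " levels give ", factorial(k), " orderings; ",
                "pre-specify an order via categorical_levels in fit_vine()")
  orders <- permutations_of(lev)
  fits <- vector("list", length(orders))
  aics <- numeric(length(orders))
  for (i in seq_along(orders)) {
    cl <- list(orders[[i]])
    names(cl) <- categorical_covariate
    fits[[i]] <- fit_vine(table, family_set = family_set, weights = weights,
                          truncation = truncation, pit_seed = pit_seed,
                          categorical_levels = cl)
    aics[i] <- fits[[i]]$aic
  }
  best <- which.min(aics)
  model <- fits[[best]]
  model$order_search <- list(
    covariate = categorical_covariate,
    n_candidates = length(orders),
    orders = vapply(orders, paste, character(1), collapse = " < "),
    aic = aics,
    selected = best
  )
  model
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}

#' Vine log-likelihood and AIC on a covariate table
#'
#' Evaluates the copula log-likelihood of `table` under a fitted model: the
#' pseudo-observations are recomputed with the model's marginals (and its
#' recorded PIT jitter seed for categorical covariates), propagated through
#' the vine's h-functions, and summed over the per-edge log-densities on
#' each edge's complete cases.
#'
#' @param model a `vine_model`.
#' @param table a covariate table with the model's covariates.
#' @return `loglik_vine()` a scalar log-likelihood; `aic_vine()` the model
#'   AIC `2 * npars - 2 * loglik`.
#' @export
loglik_vine <- function(model, table) {
  stopifnot(inherits(model, "vine_model"))
  if (!inherits(table, "covariate_table")) table <- covariate_table(table)
  if (!all(model$variables %in% names(table)))
    stop_domain("table is missing covariates: ",
                paste(setdiff(model$variables, names(table)), collapse = ", "))
  cat_covs <- names(model$categorical_order)
  jitter <- draw_jitter(nrow(table), cat_covs, model$pit_seed)
  U <- pseudo_obs(table, model$marginals, jitter)
  engine <- make_cond_engine(model$edges, U)
  ll <- 0
  for (e in model$edges) {
    x <- get_cond(engine, model$edges, e$conditioned[1], e$conditioning)
    y <- get_cond(engine, model$edges, e$conditioned[2], e$conditioning)
    ok <- !is.na(x) & !is.na(y)
    ll <- ll + sum(dbicop(x[ok], y[ok], e$cop, log = TRUE))
  }
  ll
}

#' @rdname loglik_vine
#' @export
aic_vine <- function(model) {
  stopifnot(inherits(model, "vine_model"))
  model$aic
}

#' Serialize / restore a vine model as JSON
#'
#' The JSON document holds the complete fitted model — structure, per-edge
#' copulas, tabulated marginals, categorical level orders and seeds — and is
#' the shareable artifact: it contains no subject-level data.
#'
#' @param model a `vine_model`.
#' @param path optional file path; when given the JSON is written there.
#' @return `vine_to_json()` a JSON string (invisibly when `path` is given);
#'   `vine_from_json()` a `vine_model`.
#' @export
vine_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "vine_model"))
  doc <- list(
    package = "vinepop",
    variables = model$variables,
    schema = list(kinds = as.list(model$schema$kinds),
                  log_scale = names(which(model$schema$log_scale)),
                  weight_col = model$schema$weight_col),
    trees = model$trees,
    edges = lapply(model$edges, function(e) {
      list(id = e$id, tree = e$tree, conditioned = e$conditioned,
           conditioning = e$conditioning, nodes = as.character(e$nodes),
           tau_emp = e$tau_emp, n_complete = e$n_complete,
           cop = unclass(e$cop))
    }),
    marginals = lapply(model$marginals, marginal_to_list),
    categorical_order = model$categorical_order,
    pit_seed = model$pit_seed, weighted = model$weighted,
    family_set = model$family_set,
    truncation = if (is.finite(model$truncation)) model$truncation,
    n_fit = model$n_fit, loglik = model$loglik, npars = model$npars,
    aic = model$aic
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname vine_to_json
#' @param json a JSON string (alternative to `path`).
#' @export
vine_from_json <- function(path = NULL, json = NULL) {
  doc <- jsonlite::fromJSON(json %||% paste(readLines(path, warn = FALSE),
                                            collapse = "\n"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  covs <- unlist(doc$variables)
  edges <- lapply(doc$edges, function(e) {
    tr <- as.integer(e$tree)
    list(id = as.integer(e$id), tree = tr,
         conditioned = as.character(unlist(e$conditioned)),
         conditioning = as.character(unlist(e$conditioning %||% list())),
         nodes = if (tr == 1L) as.character(unlist(e$nodes))
                 else as.integer(unlist(e$nodes)),
         cop = bicop_from_list(e$cop),
         tau_emp = e$tau_emp %||% NA_real_,
         n_complete = e$n_complete %||% NA_integer_)
  })
  marginals <- lapply(doc$marginals, marginal_from_list)
  names(marginals) <- covs
  kinds <- unlist(doc$schema$kinds)
  log_sc <- setNames(covs %in% unlist(doc$schema$log_scale), covs)
  structure(
    list(variables = covs,
         trees = lapply(doc$trees, function(x) as.integer(unlist(x))),
         edges = edges, marginals = marginals,
         schema = list(kinds = kinds[covs], log_scale = log_sc,
                       weight_col = doc$schema$weight_col),
         categorical_order = lapply(doc$categorical_order, unlist),
         pit_seed = as.integer(doc$pit_seed),
         weighted = isTRUE(doc$weighted),
         family_set = unlist(doc$family_set),
         truncation = doc$truncation %||% Inf,
         n_fit = doc$n_fit, loglik = doc$loglik, npars = doc$npars,
         aic = doc$aic),
    class = "vine_model"
  )
}

#' @export
print.vine_model <- function(x, ...) {
  d <- length(x$variables)
  cat(sprintf(
    "<vine_model> %d covariates, %d trees, loglik = %.2f, AIC = %.2f%s\n",
    d, length(x$trees), x$loglik, x$aic,
    if (x$weighted) " (weighted)" else ""))
  cat("first tree:\n")
  for (id in x$trees[[1]]) {
    e <- x$edges[[id]]
    cat(sprintf("  %s -- %s : %s%s, tau = %.3f\n",
                e$conditioned[1], e$conditioned[2], e$cop$family,
                if (e$cop$rotation != 0) paste0(" rot", e$cop$rotation) else "",
                par_to_tau(e$cop)))
  }
  invisible(x)
}
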