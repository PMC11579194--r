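# Model evaluation: relative errors of marginal metrics, category
# frequencies, pairwise Pearson correlation errors, and the Jaccard overlap
# of 95% highest-density-region contours between observed and simulated
# populations.

#' Relative error of a summary metric
#'
#' `RE = (M_sim - M_obs) / M_obs`.
#'
#' @param m_sim,m_obs simulated and observed metric values; `m_obs` must be
#'   nonzero.
#' @return the relative error.
#' @export
relative_error <- function(m_sim, m_obs) {
  if (any(m_obs == 0))
    stop_domain("relative error undefined for observed metric 0")
  (m_sim - m_obs) / m_obs
}

#' Marginal summary metrics
#'
#' The five marginal metrics compared between observed and virtual
#' populations: mean, SD, and the 5th/50th/95th percentiles (linear
#' interpolation between order statistics, `quantile` type 7).
#'
#' @param column numeric vector; missing values dropped; at least 2
#'   non-missing values required.
#' @return named vector `c(mean, sd, p5, p50, p95)`.
#' @export
marginal_metrics <- function(column) {
  x <- column[!is.na(column)]
  if (length(x) < 2L) stop_domain("need at least 2 non-missing values")
  q <- quantile(x, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  c(mean = mean(x), sd = sd(x), p5 = q[1], p50 = q[2], p95 = q[3])
}

kde2d_grid <- function(x, y, gridsize, range_x, range_y) {
  bw <- c(bw.nrd0(x), bw.nrd0(y))
  f <- KernSmooth::bkde2D(cbind(x, y), bandwidth = bw,
                          gridsize = c(gridsize, gridsize),
                          range.x = list(range_x, range_y))
  f$fhat[f$fhat < 0] <- 0
  f
}

# density threshold whose superlevel set holds `mass` of the (discretized)
# probability
hdr_level <- function(fhat, mass) {
  p <- fhat / sum(fhat)
  ord <- order(fhat, decreasing = TRUE)
  cum <- cumsum(p[ord])
  fhat[ord[which(cum >= mass)[1]]]
}

#' Highest-density-region contour of a covariate pair
#'
#' Estimates the joint density of `(x, y)` by a binned 2D Gaussian KDE on a
#' regular grid (default 256 x 256, extended 3 bandwidths beyond the data
#' range) and finds the density level whose superlevel set encloses `mass`
#' of the estimated probability — the "95% density contour" when
#' `mass = 0.95`. Contour rings are extracted at that level.
#'
#' @param x,y paired observations (rows with missing values dropped;
#'   at least 100 required).
#' @param mass probability mass to enclose (default 0.95).
#' @param gridsize grid resolution per axis.
#' @param names optional covariate-pair names, kept as metadata.
#' @return an object of class `density_contour`: the grid, density, level,
#'   HDR indicator matrix, enclosed mass, total area, and the contour
#'   `rings` (closed polylines with shoelace areas).
#' @export
density_contour <- function(x, y, mass = 0.95, gridsize = 256,
                            names = c("x", "y")) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 100L)
    stop_domain("need at least 100 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop_domain("degenerate (zero-variance) input")
  bx <- bw.nrd0(x); by <- bw.nrd0(y)
  f <- kde2d_grid(x, y, gridsize,
                  c(min(x) - 3 * bx, max(x) + 3 * bx),
                  c(min(y) - 3 * by, max(y) + 3 * by))
  level <- hdr_level(f$fhat, mass)
  ind <- f$fhat >= level
  dx <- diff(f$x1[1:2]); dy <- diff(f$x2[1:2])
  rings <- contourLines(f$x1, f$x2, f$fhat, levels = level)
  ring_area <- function(r) {
    xs <- r$x; ys <- r$y
    abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  }
  structure(
    list(names = names, mass = mass, level = level,
         grid_x = f$x1, grid_y = f$x2, density = f$fhat, indicator = ind,
         enclosed_mass = sum(f$fhat[ind]) / sum(f$fhat),
         area = sum(ind) * dx * dy,
         rings = lapply(rings, function(r)
           list(x = r$x, y = r$y, area = ring_area(r)))),
    class = "density_contour"
  )
}

#' Jaccard overlap of two 95% density contours
#'
#' The dependency-shape metric: both samples' densities are estimated on one
#' shared grid covering the union of their ranges, the `mass`-HDR region is
#' extracted for each, and the overlap is `100 * area(A and B) /
#' area(A or B)` (in percent), computed by grid-cell counting. Symmetric in
#' its arguments; 100 for identical samples, 0 for disjoint clouds.
#'
#' @param obs_pair,sim_pair two-column matrices or data.frames of paired
#'   observations.
#' @param mass HDR probability mass (default 0.95).
#' @param gridsize shared grid resolution per axis.
#' @return overlap percentage in \[0, 100\].
#' @export
overlap_metric <- function(obs_pair, sim_pair, mass = 0.95, gridsize = 256) {
  pairs <- lapply(list(obs_pair, sim_pair), function(p) {
    p <- as.matrix(p)
    p[!is.na(p[, 1]) & !is.na(p[, 2]), , drop = FALSE]
  })
  for (p in pairs) {
    if (nrow(p) < 100L) stop_domain("need at least 100 paired observations")
    if (sd(p[, 1]) == 0 || sd(p[, 2]) == 0)
      stop_domain("degenerate (zero-variance) input")
  }
  bx <- max(vapply(pairs, function(p) bw.nrd0(p[, 1]), numeric(1)))
  by <- max(vapply(pairs, function(p) bw.nrd0(p[, 2]), numeric(1)))
  rx <- range(vapply(pairs, function(p) range(p[, 1]), numeric(2)))
  ry <- range(vapply(pairs, function(p) range(p[, 2]), numeric(2)))
  rx <- c(rx[1] - 3 * bx, rx[2] + 3 * bx)
  ry <- c(ry[1] - 3 * by, ry[2] + 3 * by)
  inds <- lapply(pairs, function(p) {
    f <- kde2d_grid(p[, 1], p[, 2], gridsize, rx, ry)
    f$fhat >= hdr_level(f$fhat, mass)
  })
  union_cells <- sum(inds[[1]] | inds[[2]])
  if (union_cells == 0) stop_domain("zero union area: overlap undefined")
  100 * sum(inds[[1]] & inds[[2]]) / union_cells
}

# modelling-scale view of a continuous covariate (log for log-scale flags)
mod_scale <- function(table, nm, log_flags) {
  x <- table[[nm]]
  if (isTRUE(log_flags[[nm]])) log(x) else x
}

#' Pairwise correlation comparison
#'
#' Pearson correlations of every continuous covariate pair, on the
#' modelling scale (log-transformed for log-scale covariates), compared
#' between the observed and simulated tables; the error per pair is
#' `|r_sim - r_obs|`. Constant columns are skipped with a warning.
#'
#' @param obs_table,sim_table covariate tables sharing continuous
#'   covariates.
#' @return a data.frame with one row per pair: `var1`, `var2`, `r_obs`,
#'   `r_sim`, `abs_error`.
#' @export
correlation_comparison <- function(obs_table, sim_table) {
  if (!inherits(obs_table, "covariate_table"))
    obs_table <- covariate_table(obs_table)
  s <- ct_schema(obs_table)
  covs <- intersect(names(which(s$kinds == "continuous")), names(sim_table))
  keep <- vapply(covs, function(nm)
    sd(obs_table[[nm]], na.rm = TRUE) > 0 &&
      sd(sim_table[[nm]], na.rm = TRUE) > 0, logical(1))
  if (any(!keep))
    warning("skipping constant column(s): ",
            paste(covs[!keep], collapse = ", "))
  covs <- covs[keep]
  if (length(covs) < 2L) stop_domain("need at least 2 usable covariates")
  pairs <- utils::combn(covs, 2)
  out <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ],
                    r_obs = NA_real_, r_sim = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    out$r_obs[k] <- cor(mod_scale(obs_table, a, s$log_scale),
                        mod_scale(obs_table, b, s$log_scale),
                        use = "pairwise.complete.obs")
    out$r_sim[k] <- cor(mod_scale(sim_table, a, s$log_scale),
                        mod_scale(sim_table, b, s$log_scale),
                        use = "pairwise.complete.obs")
  }
  out$abs_error <- abs(out$r_sim - out$r_obs)
  out
}

# Core comparison of an observed table against a list of simulated tables
# (one per replicate). Marginal metrics are computed on the observed
# non-missing values of each covariate and on an equally sized head of the
# simulated column, so simulated values standing in for never-observed
# (extrapolated) rows do not enter the comparison.
evaluate_tables <- function(obs_table, sim_tables, contour_mass = 0.95,
                            gridsize = 256) {
  s <- ct_schema(obs_table)
  cont <- names(which(s$kinds == "continuous"))
  cats <- names(which(s$kinds == "categorical"))
  pairs <- if (length(cont) >= 2) utils::combn(cont, 2) else
    matrix(character(0), 2, 0)

  marg <- list(); catf <- list(); corr <- list(); ovl <- list()
  for (r in seq_along(sim_tables)) {
    sim <- sim_tables[[r]]
    for (nm in cont) {
      obs_vals <- obs_table[[nm]][!is.na(obs_table[[nm]])]
      sim_vals <- sim[[nm]][seq_len(min(length(obs_vals), nrow(sim)))]
      mo <- marginal_metrics(obs_vals)
      ms <- marginal_metrics(sim_vals)
      marg[[length(marg) + 1L]] <- data.frame(
        replicate = r, covariate = nm, metric = names(mo),
        m_obs = unname(mo), m_sim = unname(ms),
        re = unname(relative_error(ms, mo)), stringsAsFactors = FALSE)
    }
    for (nm in cats) {
      obs_vals <- obs_table[[nm]][!is.na(obs_table[[nm]])]
      lev <- sort(unique(obs_vals))
      fo <- vapply(lev, function(l) mean(obs_vals == l), numeric(1))
      fs <- vapply(lev, function(l) mean(sim[[nm]] == l), numeric(1))
      catf[[length(catf) + 1L]] <- data.frame(
        replicate = r, covariate = nm, level = lev,
        freq_obs = fo, freq_sim = fs, stringsAsFactors = FALSE)
    }
    if (ncol(pairs)) {
      cc <- correlation_comparison(obs_table, sim)
      cc$replicate <- r
      corr[[length(corr) + 1L]] <- cc
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; b <- pairs[2, k]
        xo <- mod_scale(obs_table, a, s$log_scale)
        yo <- mod_scale(obs_table, b, s$log_scale)
        ok <- !is.na(xo) & !is.na(yo)
        m <- min(sum(ok), nrow(sim))
        o <- tryCatch(
          overlap_metric(cbind(xo[ok], yo[ok]),
                         cbind(mod_scale(sim, a, s$log_scale),
                               mod_scale(sim, b, s$log_scale))[seq_len(m), ,
                                                               drop = FALSE],
                         mass = contour_mass, gridsize = gridsize),
          error = function(e) NA_real_)
        ovl[[length(ovl) + 1L]] <- data.frame(
          replicate = r, var1 = a, var2 = b, overlap = o,
          stringsAsFactors = FALSE)
      }
    }
  }
  marg <- do.call(rbind, marg)
  corr <- if (length(corr)) do.call(rbind, corr)
  ovl <- if (length(ovl)) do.call(rbind, ovl)
  catf <- if (length(catf)) do.call(rbind, catf)

  cv <- function(x) if (length(x) < 2 || mean(x) == 0) NA_real_
                    else sd(x) / abs(mean(x))
  by_cm <- split(marg, paste(marg$covariate, marg$metric))
  summary <- list(
    n_replicates = length(sim_tables),
    median_abs_re = median(abs(marg$re)),
    re_by_metric = do.call(rbind, lapply(by_cm, function(g) data.frame(
      covariate = g$covariate[1], metric = g$metric[1],
      median_re = median(g$re), cv_sim = cv(g$m_sim),
      stringsAsFactors = FALSE))),
    median_correlation_error = if (!is.null(corr)) median(corr$abs_error),
    median_overlap = if (!is.null(ovl)) median(ovl$overlap, na.rm = TRUE),
    overlap_by_pair = if (!is.null(ovl)) {
      bp <- split(ovl, paste(ovl$var1, ovl$var2))
      do.call(rbind, lapply(bp, function(g) data.frame(
        var1 = g$var1[1], var2 = g$var2[1],
        median_overlap = median(g$overlap, na.rm = TRUE),
        stringsAsFactors = FALSE)))
    }
  )
  rownames(summary$re_by_metric) <- NULL
  if (!is.null(summary$overlap_by_pair))
    rownames(summary$overlap_by_pair) <- NULL
  structure(list(marginal = marg, categorical = catf, correlation = corr,
                 overlap = ovl, summary = summary),
            class = "evaluation_report")
}

#' Evaluate a fitted vine model against observed data
#'
#' The simulation-based evaluation strategy: the model simulates
#' `n_replicates` virtual populations of the observed size; each replicate
#' is compared with the observed table through relative errors of the five
#' marginal metrics per continuous covariate, category frequencies,
#' pairwise Pearson correlation errors, and the Jaccard overlap of the 95%
#' density contours per continuous pair (on the modelling scale). Marginal
#' comparisons for each covariate use only the observed non-missing values
#' and an equal number of simulated ones, so simulated values extrapolated
#' into never-observed regions (e.g. fat mass at age >= 60) are excluded.
#' Summaries report medians and the coefficient of variation across
#' replicates.
#'
#' @param obs_table the observed [covariate_table()].
#' @param model a `vine_model` fitted on the same schema.
#' @param n_replicates number of simulated populations (the reference
#'   analysis uses 100; 10 gives stable medians at a tenth of the cost).
#' @param seed integer seed scoping all replicate simulations.
#' @param contour_mass,gridsize HDR mass and grid resolution passed to
#'   [overlap_metric()].
#' @return an `evaluation_report`: per-replicate data.frames `marginal`,
#'   `categorical`, `correlation`, `overlap` and a `summary` list.
#' @export
evaluate_model <- function(obs_table, model, n_replicates = 100, seed = 1,
                           contour_mass = 0.95, gridsize = 256) {
  stopifnot(inherits(model, "vine_model"))
  if (!inherits(obs_table, "covariate_table"))
    obs_table <- covariate_table(obs_table)
  if (!all(model$variables %in% ct_covariates(obs_table)))
    stop_domain("observed table is missing model covariates")
  sims <- with_seed_maybe(seed, lapply(seq_len(n_replicates), function(r)
    simulate_vine(model, nrow(obs_table))))
  evaluate_tables(obs_table, sims, contour_mass = contour_mass,
                  gridsize = gridsize)
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<evaluation_report> %d replicate(s)\n", s$n_replicates))
  cat(sprintf("  median |RE| over marginal metrics : %.4f\n",
              s$median_abs_re))
  if (!is.null(s$median_correlation_error))
    cat(sprintf("  median correlation error          : %.4f\n",
                s$median_correlation_error))
  if (!is.null(s$median_overlap))
    cat(sprintf("  median contour overlap            : %.1f%%\n",
                s$median_overlap))
  invisible(x)
}

#' Compare subgroup simulation strategies
#'
#' Virtual subgroup populations can be obtained by simulating from the full
#' model and filtering, or by fitting a copula to the subgroup data and
#' simulating from it directly. For each level of `group_column` with at
#' least `min_group_n` observed rows, both strategies are evaluated against
#' the group's observed rows and the paired reports are returned.
#'
#' @param obs_table observed [covariate_table()] including `group_column`.
#' @param group_column name of the categorical grouping covariate.
#' @param family_set pair-copula families for all fits.
#' @param n_replicates simulated populations per strategy and group.
#' @param seed integer seed.
#' @param min_group_n groups below this size are skipped with a warning.
#' @param gridsize contour grid resolution.
#' @return a list with one entry per evaluated group:
#'   `list(n_obs, filtered_full, subgroup)`, each report an
#'   `evaluation_report`.
#' @export
compare_subgroup_strategies <- function(obs_table, group_column,
                                        family_set = FAMILY_NAMES,
                                        n_replicates = 10, seed = 1,
                                        min_group_n = 200, gridsize = 256) {
  if (!inherits(obs_table, "covariate_table"))
    obs_table <- covariate_table(obs_table)
  s <- ct_schema(obs_table)
  if (!group_column %in% ct_covariates(obs_table) ||
      s$kinds[[group_column]] != "categorical")
    stop_domain("'", group_column, "' must be a categorical covariate")
  full <- fit_vine(obs_table, family_set = family_set, pit_seed = seed)
  groups <- sort(unique(obs_table[[group_column]][
    !is.na(obs_table[[group_column]])]))
  out <- list()
  for (g in groups) {
    rows <- which(!is.na(obs_table[[group_column]]) &
                    obs_table[[group_column]] == g)
    if (length(rows) < min_group_n) {
      warning("group '", g, "' has ", length(rows),
              " rows (< ", min_group_n, "); skipped")
      next
    }
    obs_g <- ct_drop(obs_table[rows, ], group_column)
    sub_model <- fit_vine(obs_g, family_set = family_set, pit_seed = seed)
    filt_sims <- with_seed_maybe(seed, lapply(seq_len(n_replicates),
      function(r) {
        sim <- simulate_subgroup(full, nrow(obs_g),
                                 filters = list(list(covariate = group_column,
                                                     values = g)))
        ct_drop(sim, group_column)
      }))
    out[[g]] <- list(
      n_obs = length(rows),
      filtered_full = evaluate_tables(obs_g, filt_sims,
                                      gridsize = gridsize),
      subgroup = evaluate_model(obs_g, sub_model,
                                n_replicates = n_replicates, seed = seed,
                                gridsize = gridsize)
    )
  }
  structure(out, class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat("<subgroup_comparison>\n")
  for (g in names(x)) {
    cat(sprintf(
      "  %s (n = %d): median overlap filtered-full %.1f%% vs subgroup %.1f%%\n",
      g, x[[g]]$n_obs,
      x[[g]]$filtered_full$summary$median_overlap,
      x[[g]]$subgroup$summary$median_overlap))
  }
  invisible(x)
}

#' Holdout validation for structurally missing data
#'
#' Assesses whether the model can reconstruct a covariate in regions where
#' it was never observed (the fat-mass question): for each band of the
#' anchor covariate, the target's observed values inside the band are
#' masked, the vine is refitted, a population is simulated, and the
#' simulated target distribution inside the band is compared with the
#' held-out values (relative errors of mean and SD, and the contour overlap
#' of the anchor-target pair in the band).
#'
#' @param obs_table observed [covariate_table()].
#' @param target_covariate continuous covariate to mask and predict.
#' @param holdout_bands list of `c(lower, upper)` anchor ranges (upper
#'   exclusive); bands holding no observed target values are skipped. An
#'   empty list evaluates the unmasked model on the target covariate only.
#' @param anchor_covariate continuous covariate defining the bands
#'   (default `"age"`).
#' @param family_set pair-copula families.
#' @param seed integer seed.
#' @return a data.frame with one row per band: holdout size, relative error
#'   of mean and SD, and the in-band anchor-target overlap.
#' @export
holdout_missing_validation <- function(obs_table, target_covariate,
                                       holdout_bands,
                                       anchor_covariate = "age",
                                       family_set = FAMILY_NAMES,
                                       seed = 1) {
  if (!inherits(obs_table, "covariate_table"))
    obs_table <- covariate_table(obs_table)
  s <- ct_schema(obs_table)
  for (nm in c(target_covariate, anchor_covariate))
    if (!nm %in% ct_covariates(obs_table) || s$kinds[[nm]] != "continuous")
      stop_domain("'", nm, "' must be a continuous covariate of the table")

  if (!length(holdout_bands)) {
    model <- fit_vine(obs_table, family_set = family_set, pit_seed = seed)
    sim <- simulate_vine(model, nrow(obs_table), seed = seed)
    mo <- marginal_metrics(obs_table[[target_covariate]])
    msim <- marginal_metrics(sim[[target_covariate]][
      seq_len(sum(!is.na(obs_table[[target_covariate]])))])
    return(data.frame(band_lower = NA_real_, band_upper = NA_real_,
                      n_holdout = sum(!is.na(obs_table[[target_covariate]])),
                      re_mean = relative_error(msim[["mean"]], mo[["mean"]]),
                      re_sd = relative_error(msim[["sd"]], mo[["sd"]]),
                      overlap = NA_real_))
  }

  out <- list()
  for (band in holdout_bands) {
    lo <- band[1]; hi <- band[2]
    anchor <- obs_table[[anchor_covariate]]
    in_band <- !is.na(anchor) & anchor >= lo & anchor < hi
    held <- in_band & !is.na(obs_table[[target_covariate]])
    if (!any(held)) {
      warning("band [", lo, ", ", hi, ") holds no observed '",
              target_covariate, "' values; skipped")
      next
    }
    masked <- obs_table
    masked[[target_covariate]][in_band] <- NA
    model <- fit_vine(masked, family_set = family_set, pit_seed = seed)
    sim <- simulate_vine(model, max(nrow(obs_table), 2000), seed = seed)
    sim_band <- sim[sim[[anchor_covariate]] >= lo &
                      sim[[anchor_covariate]] < hi, ]
    obs_vals <- obs_table[[target_covariate]][held]
    mo <- marginal_metrics(obs_vals)
    msim <- marginal_metrics(sim_band[[target_covariate]])
    o <- tryCatch(overlap_metric(
      cbind(anchor[held],
            mod_scale(obs_table, target_covariate, s$log_scale)[held]),
      cbind(sim_band[[anchor_covariate]],
            mod_scale(sim_band, target_covariate, s$log_scale))),
      error = function(e) NA_real_)
    out[[length(out) + 1L]] <- data.frame(
      band_lower = lo, band_upper = hi, n_holdout = sum(held),
      re_mean = relative_error(msim[["mean"]], mo[["mean"]]),
      re_sd = relative_error(msim[["sd"]], mo[["sd"]]),
      overlap = o)
  }
  if (!length(out))
    stop_domain("no band held any observed target values")
  do.call(rbind, out)
}
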