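# Synthetic NHANES-like covariate tables. Margins target the published
# adult summary statistics (mean, SD, range, category frequencies) of the
# 12 standard pharmacokinetic covariates; dependence comes from a latent
# Gaussian copula with a fixed correlation matrix qualitatively matching
# the strong weight-height-fat block and the sex effects on height and the
# biochemical covariates. Missingness emulates the structured rule (fat
# mass unmeasured for subjects aged >= 60) plus random missingness per
# laboratory covariate.

FIXTURE_COVARIATES <- c("sex", "race", "age", "weight", "height", "fat",
                        "scr", "alt", "ast", "alp", "albumin", "br")

fixture_margins_default <- function() {
  list(
    # "male" first: the latent sex coordinate then points towards female,
    # so e.g. set_r("sex", "height", -0.5) makes women shorter
    sex = list(kind = "categorical",
               levels = c("male", "female"), probs = c(0.485, 0.515)),
    race = list(kind = "categorical",
                levels = c("hispanic", "white", "african_american",
                           "asian", "other"),
                probs = c(0.266, 0.369, 0.228, 0.106, 0.031)),
    age = list(kind = "truncnorm", mean = 46.05, sd = 17.21,
               lower = 18, upper = 79),
    weight = list(kind = "truncnorm", mean = 82.02, sd = 22.17,
                  lower = 32.3, upper = 242.6),
    height = list(kind = "truncnorm", mean = 167.16, sd = 10.09,
                  lower = 123.3, upper = 204.5),
    fat = list(kind = "lognormal", mean = 27.11, sd = 11.93),
    scr = list(kind = "lognormal", mean = 0.88, sd = 0.45),
    alt = list(kind = "lognormal", mean = 25.57, sd = 20.42),
    ast = list(kind = "lognormal", mean = 25.93, sd = 17.13),
    alp = list(kind = "lognormal", mean = 69.34, sd = 24.59),
    albumin = list(kind = "truncnorm", mean = 4.28, sd = 0.35,
                   lower = 2.0, upper = 5.6),
    br = list(kind = "lognormal", mean = 0.62, sd = 0.31)
  )
}

# Latent-correlation defaults: a moderate positive weight-height-fat block,
# mild age effects on renal/hepatic markers, strong ALT-AST association and
# sex shifts (the latent "sex" coordinate points towards female).
fixture_dependence_default <- function() {
  covs <- FIXTURE_COVARIATES
  R <- diag(length(covs))
  dimnames(R) <- list(covs, covs)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("weight", "height", 0.45)
  set_r("weight", "fat", 0.70)
  set_r("height", "fat", 0.10)
  set_r("weight", "scr", 0.10)
  set_r("age", "scr", 0.25)
  set_r("age", "alp", 0.15)
  set_r("age", "albumin", -0.25)
  set_r("age", "height", -0.15)
  set_r("alt", "ast", 0.70)
  set_r("alt", "alp", 0.25)
  set_r("ast", "alp", 0.25)
  set_r("alt", "fat", 0.15)
  set_r("ast", "br", 0.20)
  set_r("sex", "height", -0.50)
  set_r("sex", "scr", -0.35)
  set_r("sex", "br", -0.30)
  set_r("sex", "fat", 0.30)
  set_r("sex", "albumin", -0.25)
  set_r("sex", "alt", -0.20)
  set_r("sex", "weight", -0.10)
  R
}

fixture_missingness_default <- function() {
  list(
    structured = list(target = "fat", anchor = "age", threshold = 60),
    mcar = c(fat = 0.45, weight = 0.01, height = 0.01, scr = 0.063,
             alt = 0.063, ast = 0.064, alp = 0.063, albumin = 0.063,
             br = 0.063)
  )
}

#' Specify a synthetic NHANES-like covariate table
#'
#' Builds the configuration consumed by [generate_fixture()]. The defaults
#' emulate the adult reference table: continuous margins matching the
#' published mean +/- SD (truncated normal for age/weight/height/albumin
#' with the published ranges, moment-matched lognormal for the biochemical
#' covariates), category frequencies 51.5% female and the five
#' race-ethnicity groups, a fixed latent-Gaussian dependence structure, fat
#' mass missing for all subjects aged >= 60 plus random missingness per
#' laboratory covariate, and optional lognormal sampling weights.
#'
#' @param n number of subjects.
#' @param seed integer seed for [generate_fixture()].
#' @param covariates subset of
#'   `c("sex","race","age","weight","height","fat","scr","alt","ast","alp",
#'   "albumin","br")`; margins and the dependence matrix are restricted
#'   accordingly.
#' @param margins,dependence,missingness overrides of the default
#'   specification components (see the defaults in the package source);
#'   `missingness = NULL` produces complete tables.
#' @param include_weights add a `sample_weight` column of lognormal(0, 0.5)
#'   sampling weights.
#' @return a `fixture_spec` list.
#' @examples
#' spec <- fixture_spec(n = 200, seed = 1, covariates = c("age", "weight"))
#' tab <- generate_fixture(spec)
#' @export
fixture_spec <- function(n = 10000, seed = NULL,
                         covariates = FIXTURE_COVARIATES,
                         margins = NULL, dependence = NULL,
                         missingness = fixture_missingness_default(),
                         include_weights = FALSE) {
  covariates <- match.arg(covariates, FIXTURE_COVARIATES, several.ok = TRUE)
  m <- fixture_margins_default()[covariates]
  if (!is.null(margins)) m <- modifyList(m, margins)
  R <- dependence %||% fixture_dependence_default()[covariates, covariates,
                                                    drop = FALSE]
  if (!is.null(missingness)) {
    missingness$mcar <- missingness$mcar[
      names(missingness$mcar) %in% covariates]
    if (!is.null(missingness$structured) &&
        !all(c(missingness$structured$target,
               missingness$structured$anchor) %in% covariates))
      missingness$structured <- NULL
  }
  structure(
    list(n = n, seed = seed, covariates = covariates, margins = m,
         dependence = R, missingness = missingness,
         include_weights = include_weights),
    class = "fixture_spec"
  )
}

# Untruncated normal parameters whose [lower, upper] truncation has the
# requested mean and SD (2-parameter moment match).
truncnorm_match <- function(mean, sd, lower, upper) {
  obj <- function(p) {
    mu <- p[1]; sg <- exp(p[2])
    a <- (lower - mu) / sg; b <- (upper - mu) / sg
    Z <- pnorm(b) - pnorm(a)
    da <- dnorm(a); db <- dnorm(b)
    m1 <- mu + sg * (da - db) / Z
    v <- sg^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
    (m1 - mean)^2 + (sqrt(max(v, 0)) - sd)^2
  }
  o <- optim(c(mean, log(sd)), obj, control = list(reltol = 1e-12))
  list(mu = o$par[1], sigma = exp(o$par[2]))
}

qtruncnorm <- function(u, mu, sigma, lower, upper) {
  pa <- pnorm(lower, mu, sigma)
  pb <- pnorm(upper, mu, sigma)
  qnorm(pa + u * (pb - pa), mu, sigma)
}

# mean/SD -> lognormal parameters
lognormal_match <- function(mean, sd) {
  s2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic covariate table
#'
#' Draws `spec$n` subjects from the latent Gaussian copula and marginal
#' specification of a [fixture_spec()], applies the missingness
#' specification, and returns a schema-complete [covariate_table()] (log
#' scale flagged for the biochemical covariates and fat mass).
#'
#' @param spec a `fixture_spec`.
#' @return a `covariate_table` with `spec$n` rows.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  covs <- spec$covariates
  R <- as.matrix(spec$dependence)
  ch <- tryCatch(chol(R), error = function(e)
    stop_domain("dependence correlation matrix is not positive definite"))
  n <- spec$n

  log_covs <- intersect(c("fat", "scr", "alt", "ast", "alp", "albumin",
                          "br"), covs)
  kinds <- vapply(covs, function(nm)
    if (spec$margins[[nm]]$kind == "categorical") "categorical"
    else "continuous", character(1))

  with_seed_maybe(spec$seed, {
    Z <- matrix(rnorm(n * length(covs)), n) %*% ch
    U <- pnorm(Z)
    colnames(U) <- covs
    cols <- lapply(covs, function(nm) {
      mg <- spec$margins[[nm]]
      u <- U[, nm]
      switch(mg$kind,
        truncnorm = {
          p <- truncnorm_match(mg$mean, mg$sd, mg$lower, mg$upper)
          qtruncnorm(u, p$mu, p$sigma, mg$lower, mg$upper)
        },
        lognormal = {
          p <- lognormal_match(mg$mean, mg$sd)
          exp(qnorm(u, p$meanlog, p$sdlog))
        },
        categorical = {
          idx <- findInterval(u, cumsum(mg$probs), left.open = TRUE) + 1L
          mg$levels[pmin(idx, length(mg$levels))]
        },
        stop_domain("unknown margin kind: ", mg$kind)
      )
    })
    names(cols) <- covs
    df <- as.data.frame(cols, stringsAsFactors = FALSE)
    if (spec$include_weights) df$sample_weight <- exp(rnorm(n, 0, 0.5))
    out <- covariate_table(df, kinds = kinds, log_scale = log_covs,
                           weight_col = if (spec$include_weights)
                             "sample_weight")
    if (is.null(spec$missingness)) out else apply_missingness(out, spec)
  })
}

#' Apply a missingness specification
#'
#' The structured rule blanks the target covariate for every row whose
#' anchor covariate is at or above the threshold (fat mass unmeasured from
#' age 60); independent random (MCAR) missingness is then applied at the
#' per-covariate rates, on the rows still observed. Draws come from the
#' current RNG stream (seed it, or call via [generate_fixture()] whose seed
#' scopes the whole generation).
#'
#' @param table a `covariate_table`.
#' @param spec a `fixture_spec` (its `$missingness` component is used), or a
#'   list with elements `structured` and/or `mcar`.
#' @return the table with missing values inserted; the logical mask is
#'   attached as attribute `missing_mask`.
#' @export
apply_missingness <- function(table, spec) {
  ms <- if (inherits(spec, "fixture_spec")) spec$missingness else spec
  if (is.null(ms) || (is.null(ms$structured) && !length(ms$mcar)))
    return(table)
  bad <- setdiff(c(names(ms$mcar), ms$structured$target,
                   ms$structured$anchor), names(table))
  if (length(bad))
    stop_domain("missingness references unknown covariates: ",
                paste(bad, collapse = ", "))
  mask <- matrix(FALSE, nrow(table), length(ct_covariates(table)),
                 dimnames = list(NULL, ct_covariates(table)))
  if (!is.null(ms$structured)) {
    st <- ms$structured
    mask[, st$target] <- !is.na(table[[st$anchor]]) &
      table[[st$anchor]] >= st$threshold
  }
  for (nm in names(ms$mcar)) {
    r <- ms$mcar[[nm]]
    hit <- runif(nrow(table)) < r
    mask[, nm] <- mask[, nm] | hit
  }
  for (nm in colnames(mask)) table[[nm]][mask[, nm]] <- NA
  attr(table, "missing_mask") <- mask
  table
}
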