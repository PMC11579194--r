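#' Fit a univariate marginal distribution
#'
#' Continuous covariates are modelled by a Gaussian kernel density estimate
#' (Silverman rule-of-thumb bandwidth) on the modelling scale — the natural
#' scale, or the log scale for covariates flagged `log_scale` so that
#' back-transformed values are strictly positive. The estimate is tabulated
#' on a 512-point grid extending 4 bandwidths beyond the data range, and the
#' CDF is obtained by trapezoidal integration of the tabulated density.
#' Categorical covariates are described by their (optionally weighted) level
#' frequencies under an explicit level ordering.
#'
#' Missing values are excluded; sampling weights, when supplied, rescale each
#' observation's contribution (duplicating a row is equivalent to doubling
#' its weight).
#'
#' @param values numeric vector (continuous) or character/factor vector
#'   (categorical); missing values allowed.
#' @param weights optional nonnegative sampling weights, same length as
#'   `values`.
#' @param log_scale logical; fit the KDE to `log(values)` (continuous only,
#'   requires strictly positive values).
#' @param kind `"continuous"` or `"categorical"`.
#' @param name covariate name carried in the model.
#' @param levels optional level ordering for categorical fits; defaults to
#'   sorted unique values.
#' @return an object of class `marginal_model`.
#' @examples
#' m <- fit_marginal(rnorm(500, 50, 10), name = "age")
#' pit(m, 50)
#' quantile(m, 0.5)
#' @export
fit_marginal <- function(values, weights = NULL, log_scale = FALSE,
                         kind = c("continuous", "categorical"),
                         name = "x", levels = NULL) {
  kind <- match.arg(kind)
  if (!is.null(weights)) {
    if (length(weights) != length(values))
      stop_domain("weights must align with values")
    if (any(weights < 0, na.rm = TRUE) || !any(weights > 0, na.rm = TRUE))
      stop_domain("weights must be nonnegative and not all zero")
  }

  if (kind == "categorical") {
    ok <- !is.na(values)
    v <- as.character(values[ok])
    if (!length(v)) stop_domain("covariate '", name, "': all values missing")
    w <- if (is.null(weights)) rep(1, length(v)) else weights[ok]
    levels <- levels %||% sort(unique(v))
    if (!all(v %in% levels))
      stop_domain("covariate '", name, "': values outside declared levels")
    probs <- vapply(levels, function(l) sum(w[v == l]), numeric(1))
    probs <- probs / sum(probs)
    return(structure(
      list(covariate_name = name, kind = "categorical", levels = levels,
           probs = probs, cumprobs = cumsum(probs),
           n_used = length(v), weighted = !is.null(weights)),
      class = "marginal_model"
    ))
  }

  ok <- !is.na(values)
  x <- as.numeric(values[ok])
  w <- if (is.null(weights)) NULL else weights[ok]
  if (length(x) < 10L)
    stop_domain("covariate '", name, "': need >= 10 non-missing values, got ",
                length(x))
  if (log_scale && any(x <= 0)) {
    idx <- which(ok)[which(x <= 0)[1]]
    stop_domain("covariate '", name, "': log_scale requires positive values; ",
                "value at index ", idx, " is ", values[idx])
  }
  z <- if (log_scale) log(x) else x
  if (sd(z) == 0)
    stop_domain("covariate '", name, "': zero variance")

  wn <- if (is.null(w)) NULL else w / sum(w)
  # weight-aware Silverman bandwidth: reduces to bw.nrd0 for unit weights,
  # and treats integer weights exactly like duplicated rows
  bw <- bw_silverman_weighted(z, w)
  d <- density(z, bw = bw, kernel = "gaussian", n = 512, cut = 4,
               weights = wn)
  cdf <- cum_trapezoid_cdf(d$x, d$y)

  structure(
    list(covariate_name = name, kind = "continuous", log_scale = log_scale,
         grid = d$x, density = d$y, cdf = cdf, bw = d$bw,
         bounds = range(d$x), n_used = length(x),
         weighted = !is.null(weights)),
    class = "marginal_model"
  )
}

#' Probability integral transform of a continuous marginal
#'
#' Maps natural-scale values through the fitted CDF to the uniform scale
#' (pseudo-observations). Values are clamped to `[1e-10, 1 - 1e-10]` so
#' copula estimation never sees the boundary. For categorical marginals use
#' [pit_categorical()].
#'
#' @param model a continuous `marginal_model`.
#' @param x numeric vector on the natural scale (log applied internally for
#'   log-scale models). Missing values propagate.
#' @return pseudo-observations in (0, 1).
#' @export
pit <- function(model, x) {
  stopifnot(inherits(model, "marginal_model"))
  if (model$kind != "continuous")
    stop_domain("pit() is for continuous marginals; use pit_categorical()")
  u <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  z <- as.numeric(x[ok])
  if (model$log_scale) {
    if (any(z <= 0))
      stop_domain("nonpositive value under log_scale in pit()")
    z <- log(z)
  }
  u[ok] <- clamp01(approx(model$grid, model$cdf, xout = z, rule = 2)$y)
  u
}

#' Randomized probability integral transform for categorical marginals
#'
#' A categorical level occupies a probability interval `(F(level-),
#' F(level)]` under the model's level ordering; the transform draws uniformly
#' within that interval (randomized PIT), the standard identifiability device
#' for discrete variables in copula estimation. The jitter comes from the
#' current RNG stream, so results are reproducible under `set.seed()`;
#' alternatively pre-drawn jitter quantiles can be supplied, which lets
#' different candidate level orderings share one jitter realization.
#'
#' @param model a categorical `marginal_model`.
#' @param labels vector of observed labels; missing values propagate.
#' @param jitter optional vector of uniforms in (0,1), one per label,
#'   overriding the RNG draw.
#' @return pseudo-observations in (0, 1).
#' @export
pit_categorical <- function(model, labels, jitter = NULL) {
  stopifnot(inherits(model, "marginal_model"))
  if (model$kind != "categorical")
    stop_domain("pit_categorical() is for categorical marginals")
  labels <- as.character(labels)
  u <- rep(NA_real_, length(labels))
  ok <- !is.na(labels)
  idx <- match(labels[ok], model$levels)
  if (anyNA(idx))
    stop_domain("unknown level(s): ",
                paste(unique(labels[ok][is.na(idx)]), collapse = ", "))
  q <- jitter %||% runif(length(labels))
  lo <- c(0, model$cumprobs)[idx]
  u[ok] <- clamp01(lo + q[ok] * model$probs[idx])
  u
}

#' Quantile function of a fitted marginal
#'
#' Inverse of the PIT: maps uniforms back to the natural scale by monotone
#' interpolation of the tabulated CDF, exponentiating for log-scale models so
#' outputs are strictly positive. For categorical marginals returns the label
#' whose cumulative probability interval contains `probs`.
#'
#' @param x a `marginal_model`.
#' @param probs numeric vector in (0, 1).
#' @param ... unused.
#' @return natural-scale values (continuous) or labels (categorical).
#' @export
quantile.marginal_model <- function(x, probs, ...) {
  model <- x
  if (any(!is.na(probs) & (probs <= 0 | probs >= 1)))
    stop_domain("quantile() requires probabilities strictly inside (0, 1)")
  if (model$kind == "categorical") {
    idx <- findInterval(probs, model$cumprobs, left.open = TRUE) + 1L
    idx <- pmin(idx, length(model$levels))
    return(model$levels[idx])
  }
  z <- approx(model$cdf, model$grid, xout = probs, rule = 2)$y
  if (model$log_scale) exp(z) else z
}

#' Serialize / restore a marginal model as JSON
#'
#' The JSON carries the tabulated density (grid, values, bandwidth) or the
#' level probabilities — summary objects that can be shared without
#' subject-level data. The CDF is recomputed deterministically on load.
#'
#' @param model a `marginal_model`.
#' @return `marginal_to_json()` a JSON string; `marginal_from_json()` a
#'   `marginal_model`.
#' @export
marginal_to_json <- function(model) {
  jsonlite::toJSON(marginal_to_list(model), auto_unbox = TRUE, digits = I(17))
}

marginal_to_list <- function(model) {
  unclass(model)[setdiff(names(model), c("cdf", "cumprobs"))]
}

marginal_from_list <- function(l) {
  if (l$kind == "continuous") {
    l$grid <- as.numeric(l$grid)
    l$density <- as.numeric(l$density)
    l$cdf <- cum_trapezoid_cdf(l$grid, l$density)
    l$bounds <- as.numeric(l$bounds)
  } else {
    l$levels <- as.character(l$levels)
    l$probs <- setNames(as.numeric(l$probs), l$levels)
    l$cumprobs <- cumsum(l$probs)
  }
  structure(l, class = "marginal_model")
}

#' @rdname marginal_to_json
#' @param json a JSON string produced by `marginal_to_json()`.
#' @export
marginal_from_json <- function(json) {
  marginal_from_list(jsonlite::fromJSON(json, simplifyVector = TRUE))
}

#' @export
print.marginal_model <- function(x, ...) {
  if (x$kind == "continuous") {
    cat(sprintf("<marginal_model> %s: continuous%s KDE, bw = %.4g, n = %d%s\n",
                x$covariate_name, if (x$log_scale) " (log scale)" else "",
                x$bw, x$n_used, if (x$weighted) ", weighted" else ""))
  } else {
    cat(sprintf("<marginal_model> %s: categorical (%s), n = %d%s\n",
                x$covariate_name,
                paste(sprintf("%s: %.3f", x$levels, x$probs), collapse = ", "),
                x$n_used, if (x$weighted) ", weighted" else ""))
  }
  invisible(x)
}
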