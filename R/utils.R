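# Internal numerical helpers shared across modules.

# Pseudo-observations must stay strictly inside (0,1); copula densities and
# h-functions blow up at the corners.
UEPS <- 1e-10

clamp01 <- function(u, eps = UEPS) pmin(pmax(u, eps), 1 - eps)

# Cumulative trapezoid of a density tabulated on an (increasing) grid,
# normalized to end at 1 and nudged to be strictly increasing so the inverse
# is well defined.
cum_trapezoid_cdf <- function(grid, dens) {
  dx <- diff(grid)
  cdf <- c(0, cumsum(dx * (head(dens, -1) + dens[-1]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  ramp <- seq(0, 1e-9, length.out = length(cdf))
  (cdf + ramp) / (1 + 1e-9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_domain <- function(...) stop(..., call. = FALSE)

# Deterministic RNG scope: evaluates expr under the given seed when provided,
# otherwise uses the current RNG stream.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Weighted quantile matching stats::quantile type 7 on the sample expanded
# by integer weights (linear interpolation of expanded order statistics).
weighted_quantile7 <- function(z, w, probs) {
  ord <- order(z)
  z <- z[ord]
  cw <- cumsum(w[ord])
  W <- cw[length(cw)]
  val <- function(j) z[which(cw >= j - 1e-9)[1]]
  vapply(probs, function(p) {
    h <- (W - 1) * p + 1
    lo <- floor(h)
    v1 <- val(max(lo, 1))
    v2 <- val(min(lo + 1, W))
    v1 + (h - lo) * (v2 - v1)
  }, numeric(1))
}

# Silverman rule-of-thumb bandwidth (as stats::bw.nrd0) generalized to
# sampling weights: weighted SD and IQR with total weight standing in for
# the sample size, so that duplicating a row equals doubling its weight.
bw_silverman_weighted <- function(z, w = NULL) {
  if (is.null(w)) return(bw.nrd0(z))
  W <- sum(w)
  m <- sum(w * z) / W
  s <- sqrt(sum(w * (z - m)^2) / (W - 1))
  iqr <- diff(weighted_quantile7(z, w, c(0.25, 0.75)))
  lo <- min(s, iqr / 1.34)
  if (lo == 0) lo <- s
  if (lo == 0) lo <- abs(z[1])
  if (lo == 0) lo <- 1
  0.9 * lo * W^(-0.2)
}
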