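# Parametric bivariate copula families.
#
# The Archimedean families (clayton, gumbel, frank, joe, bb1, bb8) are
# implemented through their generator phi and inverse-generator psi:
#   C(u,v)   = psi(phi(u) + phi(v))
#   h2(u|v)  = psi'(s)  * phi'(v),          s = phi(u) + phi(v)
#   c(u,v)   = psi''(s) * phi'(u) * phi'(v)
# All derivative pieces are evaluated on the log scale (phi' < 0 and
# psi'' > 0 throughout) so that strong dependence and near-boundary
# pseudo-observations do not overflow. Parameter boxes are chosen so that
# phi() itself stays within double range at u = 1e-10; they comfortably
# cover Kendall taus beyond 0.9 per family.
#
# The elliptical families (gaussian, student_t) use closed-form densities
# and h-functions on the normal / t quantile scale.

FAMILY_NAMES <- c("independence", "gaussian", "student_t", "clayton",
                  "gumbel", "frank", "joe", "bb1", "bb8")

# families whose base orientation only captures positive dependence and
# which are therefore offered with 90/180/270 rotations
ASYMMETRIC_FAMILIES <- c("clayton", "gumbel", "joe", "bb1", "bb8")

family_spec <- function(family) {
  switch(family,
    independence = list(npars = 0L, lower = numeric(0), upper = numeric(0)),
    gaussian  = list(npars = 1L, lower = -0.999, upper = 0.999),
    student_t = list(npars = 2L, lower = c(-0.999, 2), upper = c(0.999, 50)),
    clayton   = list(npars = 1L, lower = 1e-4, upper = 20),
    gumbel    = list(npars = 1L, lower = 1, upper = 17),
    frank     = list(npars = 1L, lower = -35, upper = 35),
    joe       = list(npars = 1L, lower = 1, upper = 30),
    bb1       = list(npars = 2L, lower = c(1e-4, 1), upper = c(4, 4)),
    bb8       = list(npars = 2L, lower = c(1, 1e-4), upper = c(8, 1)),
    stop_domain("unknown copula family: ", family)
  )
}

# ---- Archimedean generator pieces ------------------------------------------
# Each returns vectorized functions of t in (0,1) or s > 0 for parameter
# vector p. log_neg_dphi = log(-phi'(t)); log_neg_dpsi = log(-psi'(s));
# log_d2psi = log(psi''(s)).

arch_pieces <- function(family, p) {
  switch(family,
    clayton = {
      th <- p[1]
      list(
        phi = function(t) expm1(-th * log(t)),
        log_neg_dphi = function(t) log(th) - (th + 1) * log(t),
        psi = function(s) exp(-log1p(s) / th),
        log_neg_dpsi = function(s) -log(th) - (1 / th + 1) * log1p(s),
        log_d2psi = function(s)
          log(1 / th) + log(1 / th + 1) - (1 / th + 2) * log1p(s)
      )
    },
    gumbel = {
      th <- p[1]
      a <- 1 / th
      list(
        phi = function(t) (-log(t))^th,
        log_neg_dphi = function(t) log(th) + (th - 1) * log(-log(t)) - log(t),
        psi = function(s) exp(-s^a),
        log_neg_dpsi = function(s) log(a) + (a - 1) * log(s) - s^a,
        log_d2psi = function(s) {
          w <- s^a
          log(a) + (a - 2) * log(s) - w + log(a * w + 1 - a)
        }
      )
    },
    frank = {
      th <- p[1]
      em <- expm1(-th)
      g <- function(s) exp(-s) * em
      list(
        phi = function(t) log(em / expm1(-th * t)),
        log_neg_dphi = function(t) log(abs(th)) - th * t - log(abs(expm1(-th * t))),
        psi = function(s) -log1p(g(s)) / th,
        log_neg_dpsi = function(s) {
          gs <- g(s)
          log(abs(gs)) - log(abs(th)) - log1p(gs)
        },
        log_d2psi = function(s) {
          gs <- g(s)
          log(abs(gs)) - log(abs(th)) - 2 * log1p(gs)
        }
      )
    },
    joe = {
      th <- p[1]
      a <- 1 / th
      list(
        phi = function(t) -log(-expm1(th * log1p(-t))),
        log_neg_dphi = function(t)
          log(th) + (th - 1) * log1p(-t) - log(-expm1(th * log1p(-t))),
        psi = function(s) -expm1(a * log(-expm1(-s))),
        log_neg_dpsi = function(s) {
          lq <- log(-expm1(-s))             # log(1 - e^-s)
          log(a) + (a - 1) * lq - s
        },
        log_d2psi = function(s) {
          q <- -expm1(-s)
          log(a) + (a - 2) * log(q) - s + log(1 - a + a * q)
        }
      )
    },
    bb1 = {
      th <- p[1]; de <- p[2]
      a <- 1 / de; b <- 1 / th
      list(
        phi = function(t) exp(de * log(expm1(-th * log(t)))),
        log_neg_dphi = function(t)
          log(th * de) + (de - 1) * log(expm1(-th * log(t))) - (th + 1) * log(t),
        psi = function(s) exp(-b * log1p(s^a)),
        log_neg_dpsi = function(s)
          log(a * b) - (b + 1) * log1p(s^a) + (a - 1) * log(s),
        log_d2psi = function(s) {
          w <- s^a
          z <- 1 + w
          log(a * b) + (a - 2) * log(s) - (b + 2) * log(z) +
            log((b + 1) * a * w + (1 - a) * z)
        }
      )
    },
    bb8 = {
      th <- p[1]; de <- p[2]
      a <- 1 / th
      eta <- -expm1(th * log1p(-de))        # 1 - (1 - delta)^theta
      list(
        phi = function(t) log(eta) - log(-expm1(th * log1p(-de * t))),
        log_neg_dphi = function(t)
          log(th * de) + (th - 1) * log1p(-de * t) -
            log(-expm1(th * log1p(-de * t))),
        psi = function(s) -expm1(a * log1p(-eta * exp(-s))) / de,
        log_neg_dpsi = function(s) {
          r <- 1 - eta * exp(-s)
          log(a / de) + (a - 1) * log(r) + log(eta) - s
        },
        log_d2psi = function(s) {
          r <- 1 - eta * exp(-s)
          log(a / de) + log(eta) - s + (a - 2) * log(r) +
            log((1 - a) * (1 - r) + r)
        }
      )
    },
    stop_domain("not an Archimedean family: ", family)
  )
}

is_archimedean <- function(family)
  family %in% c("clayton", "gumbel", "frank", "joe", "bb1", "bb8")

# ---- base-orientation evaluators (rotation 0) ------------------------------

base_logpdf <- function(family, p, u, v) {
  switch(family,
    independence = rep(0, length(u)),
    gaussian = {
      r <- p[1]
      x <- qnorm(u); y <- qnorm(v)
      -0.5 * log1p(-r^2) -
        (r^2 * (x^2 + y^2) - 2 * r * x * y) / (2 * (1 - r^2))
    },
    student_t = {
      r <- p[1]; nu <- p[2]
      x <- qt(u, nu); y <- qt(v, nu)
      q <- (x^2 - 2 * r * x * y + y^2) / (1 - r^2)
      lgamma((nu + 2) / 2) + lgamma(nu / 2) - 2 * lgamma((nu + 1) / 2) -
        0.5 * log1p(-r^2) - ((nu + 2) / 2) * log1p(q / nu) +
        ((nu + 1) / 2) * (log1p(x^2 / nu) + log1p(y^2 / nu))
    },
    frank = if (abs(p[1]) < 1e-6) rep(0, length(u)) else {
      ar <- arch_pieces(family, p)
      s <- ar$phi(u) + ar$phi(v)
      ar$log_d2psi(s) + ar$log_neg_dphi(u) + ar$log_neg_dphi(v)
    },
    {
      ar <- arch_pieces(family, p)
      s <- ar$phi(u) + ar$phi(v)
      ar$log_d2psi(s) + ar$log_neg_dphi(u) + ar$log_neg_dphi(v)
    }
  )
}

base_cdf <- function(family, p, u, v) {
  switch(family,
    independence = u * v,
    gaussian = {
      r <- p[1]
      s2 <- sqrt(1 - r^2)
      mapply(function(ui, vi) {
        x <- qnorm(ui)
        integrate(function(t) dnorm(t) * pnorm((x - r * t) / s2),
                  -Inf, qnorm(vi), rel.tol = 1e-10)$value
      }, u, v)
    },
    student_t = {
      r <- p[1]; nu <- p[2]
      s2 <- sqrt(1 - r^2)
      mapply(function(ui, vi) {
        x <- qt(ui, nu)
        integrate(function(t) {
          scale <- s2 * sqrt((nu + t^2) / (nu + 1))
          dt(t, nu) * pt((x - r * t) / scale, nu + 1)
        }, -Inf, qt(vi, nu), rel.tol = 1e-10)$value
      }, u, v)
    },
    frank = if (abs(p[1]) < 1e-6) u * v else {
      ar <- arch_pieces(family, p)
      ar$psi(ar$phi(u) + ar$phi(v))
    },
    {
      ar <- arch_pieces(family, p)
      ar$psi(ar$phi(u) + ar$phi(v))
    }
  )
}

# h2(u | v) = dC/dv in base orientation; all base families are exchangeable,
# so h1 is obtained by swapping arguments.
base_hfunc2 <- function(family, p, u, v) {
  switch(family,
    independence = u,
    gaussian = {
      r <- p[1]
      pnorm((qnorm(u) - r * qnorm(v)) / sqrt(1 - r^2))
    },
    student_t = {
      r <- p[1]; nu <- p[2]
      x <- qt(u, nu); y <- qt(v, nu)
      pt((x - r * y) / sqrt((1 - r^2) * (nu + y^2) / (nu + 1)), nu + 1)
    },
    frank = if (abs(p[1]) < 1e-6) u else {
      ar <- arch_pieces(family, p)
      exp(ar$log_neg_dpsi(ar$phi(u) + ar$phi(v)) + ar$log_neg_dphi(v))
    },
    {
      ar <- arch_pieces(family, p)
      exp(ar$log_neg_dpsi(ar$phi(u) + ar$phi(v)) + ar$log_neg_dphi(v))
    }
  )
}

# Inverse of base_hfunc2 in its first argument. Closed form where available,
# otherwise monotone bisection (vectorized; h2 is increasing in u).
base_hinv2 <- function(family, p, pr, v) {
  switch(family,
    independence = pr,
    gaussian = {
      r <- p[1]
      pnorm(qnorm(pr) * sqrt(1 - r^2) + r * qnorm(v))
    },
    student_t = {
      r <- p[1]; nu <- p[2]
      y <- qt(v, nu)
      x <- qt(pr, nu + 1) * sqrt((1 - r^2) * (nu + y^2) / (nu + 1)) + r * y
      pt(x, nu)
    },
    clayton = {
      th <- p[1]
      x <- exp(-(th / (th + 1)) * (log(pr) + (th + 1) * log(v)))
      clamp01(exp(-log(x - v^(-th) + 1) / th))
    },
    {
      lo <- rep(UEPS, length(pr))
      hi <- rep(1 - UEPS, length(pr))
      for (i in seq_len(60)) {
        mid <- (lo + hi) / 2
        high <- base_hfunc2(family, p, mid, v) >= pr
        hi[high] <- mid[high]
        lo[!high] <- mid[!high]
      }
      (lo + hi) / 2
    }
  )
}

# Kendall's tau. Closed form where known; otherwise the Archimedean
# integral  tau = 1 + 4 * int_0^1 phi(t)/phi'(t) dt.
base_tau <- function(family, p) {
  switch(family,
    independence = 0,
    gaussian = ,
    student_t = (2 / pi) * asin(p[1]),
    clayton = p[1] / (p[1] + 2),
    gumbel = 1 - 1 / p[1],
    bb1 = 1 - 2 / (p[2] * (p[1] + 2)),
    frank = frank_tau(p[1]),
    arch_tau_integral(family, p)
  )
}

# tau = 1 - 4/theta * (1 - D1(theta)) with D1 the first Debye function;
# odd in theta.
frank_tau <- function(theta) {
  if (abs(theta) < 1e-6) return(0)
  a <- abs(theta)
  d1 <- integrate(function(t) t / expm1(t), 0, a, rel.tol = 1e-10)$value / a
  sign(theta) * (1 - 4 / a * (1 - d1))
}

arch_tau_integral <- function(family, p) {
  ar <- arch_pieces(family, p)
  f <- function(t) -exp(log(ar$phi(t)) - ar$log_neg_dphi(t))
  int <- integrate(f, 0, 1, rel.tol = 1e-8, subdivisions = 1000L,
                   stop.on.error = FALSE)
  1 + 4 * int$value
}

# Starting parameters for likelihood optimization, by tau inversion where a
# closed form exists and by numeric inversion / coarse defaults otherwise.
# `atau` is the absolute empirical tau (base orientation captures positive
# dependence; rotations handle the sign).
start_params <- function(family, atau, signed_tau) {
  spec <- family_spec(family)
  cl <- function(x) pmin(pmax(x, spec$lower + 1e-6), spec$upper - 1e-6)
  switch(family,
    gaussian = cl(sin(pi * signed_tau / 2)),
    student_t = c(cl(c(sin(pi * signed_tau / 2), 10))[1], 10),
    clayton = cl(2 * atau / max(1 - atau, 0.05)),
    gumbel = cl(1 / max(1 - atau, 1 / 17)),
    frank = {
      f <- function(th) base_tau("frank", th) - signed_tau
      if (abs(signed_tau) < 0.01) 0.1 * sign(signed_tau + 1e-12)
      else uniroot(f, c(-34.9, 34.9), tol = 1e-6)$root
    },
    joe = {
      f <- function(th) base_tau("joe", th) - atau
      if (atau < 0.01) 1.05
      else if (f(29.9) < 0) 29.9
      else uniroot(f, c(1 + 1e-6, 29.9), tol = 1e-6)$root
    },
    bb1 = {
      de <- 1.2
      c(cl(c(2 / (max(1 - atau, 0.1) * de) - 2, de))[1], de)
    },
    bb8 = c(3, 0.7),
    numeric(0)
  )
}
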