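# Shared test helpers: known-truth generators and brute-force oracles.

# Simulate uniform-scale data from a known 4-dimensional Gaussian D-vine
# 1-2-3-4 with first-tree Kendall taus `taus` and zero partial correlations
# in the higher trees. Under these conditions the joint is a Gaussian copula
# with Markov-chain correlation r_ij = prod of consecutive first-tree rhos,
# which is simulated directly from the multivariate normal — an oracle
# independent of the package's vine machinery.
sim_gauss_dvine <- function(n, taus = c(0.6, 0.5, 0.4), seed = 1) {
  rho <- sin(pi * taus / 2)
  R <- diag(4)
  for (i in 1:3) for (j in (i + 1):4)
    R[i, j] <- R[j, i] <- prod(rho[i:(j - 1)])
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * 4), n) %*% chol(R)
    U <- pnorm(Z)
  })
  colnames(U) <- paste0("v", 1:4)
  covariate_table(as.data.frame(U))
}

# Brute-force maximum spanning tree: enumerate all (n-1)-subsets of the
# admissible edges, keep spanning ones, return the maximum total weight and
# the corresponding edge set.
brute_force_mst <- function(nodes, w) {
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  keep <- !is.na(w[pairs])
  pairs <- pairs[keep, , drop = FALSE]
  k <- length(nodes) - 1L
  best <- NULL
  best_w <- -Inf
  for (sel in utils::combn(nrow(pairs), k, simplify = FALSE)) {
    parent <- seq_along(nodes)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    ok <- TRUE
    for (r in sel) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a == b) {
        ok <- FALSE
        break
      }
      parent[a] <- b
    }
    if (!ok) next
    tw <- sum(w[pairs[sel, , drop = FALSE]])
    if (tw > best_w) {
      best_w <- tw
      best <- pairs[sel, , drop = FALSE]
    }
  }
  list(weight = best_w, edges = best)
}

# Edge set of a select_tree() result as a sorted canonical string
tree_edge_set <- function(tree_df) {
  sort(apply(tree_df[, c("from", "to")], 1, function(e)
    paste(sort(e), collapse = "~")))
}

first_tree_edges <- function(model) {
  sort(vapply(model$trees[[1]], function(id)
    paste(model$edges[[id]]$conditioned, collapse = "~"), character(1)))
}

ks_stat_uniform <- function(u) {
  u <- sort(u)
  n <- length(u)
  max(abs(u - (seq_len(n) - 0.5) / n)) + 0.5 / n
}

# central finite difference of the copula CDF, the independent oracle for
# h-functions
hfunc_fd <- function(cop, u, v, cond_var = 2, h = 1e-5) {
  if (cond_var == 2)
    (pbicop(u, v + h, cop) - pbicop(u, v - h, cop)) / (2 * h)
  else
    (pbicop(u + h, v, cop) - pbicop(u - h, v, cop)) / (2 * h)
}

example_bicops <- function() {
  list(
    bicop_dist("gaussian", 0, 0.5),
    bicop_dist("student_t", 0, c(0.5, 6)),
    bicop_dist("clayton", 0, 2),
    bicop_dist("clayton", 90, 2),
    bicop_dist("gumbel", 180, 2),
    bicop_dist("frank", 0, -4),
    bicop_dist("joe", 0, 3),
    bicop_dist("bb1", 270, c(1, 2)),
    bicop_dist("bb8", 90, c(4, 0.7))
  )
}
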