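#' Maximum spanning tree selection
#'
#' Selects the spanning tree over `nodes` maximizing the total edge weight,
#' the structure-selection step of sequential vine estimation (edge weights
#' are absolute Kendall taus of the candidate pairs). Kruskal's algorithm
#' with a deterministic tie-break: candidate edges are ordered by weight
#' (descending), then lexicographically by node names, so repeated runs give
#' identical structures.
#'
#' @param nodes character vector of node labels (length >= 2).
#' @param pairwise_weights symmetric numeric matrix of nonnegative edge
#'   weights with dimnames matching `nodes`, or an unnamed matrix in node
#'   order. Forbidden pairs can be marked `NA`.
#' @return a data.frame with columns `from`, `to`, `weight`; `nrow ==
#'   length(nodes) - 1`.
#' @examples
#' w <- matrix(c(0, .6, .1, .6, 0, .5, .1, .5, 0), 3,
#'             dimnames = list(c("A","B","C"), c("A","B","C")))
#' select_tree(c("A", "B", "C"), w)   # keeps AB and BC
#' @export
select_tree <- function(nodes, pairwise_weights) {
  stopifnot(length(nodes) >= 2)
  w <- as.matrix(pairwise_weights)
  if (is.null(dimnames(w)[[1]])) dimnames(w) <- list(nodes, nodes)
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  cand <- data.frame(
    from = rownames(w)[pairs[, 1]],
    to = colnames(w)[pairs[, 2]],
    weight = w[pairs],
    stringsAsFactors = FALSE
  )
  kruskal_max(nodes, cand)
}

# Kruskal maximum spanning tree over an explicit candidate edge list
# (data.frame from/to/weight). Edges with NA weight are inadmissible.
kruskal_max <- function(nodes, cand) {
  cand <- cand[!is.na(cand$weight), , drop = FALSE]
  if (!all(is.finite(cand$weight)))
    stop_domain("edge weights must be finite")
  ord <- order(-cand$weight, cand$from, cand$to)
  cand <- cand[ord, , drop = FALSE]

  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  chosen <- integer(0)
  for (k in seq_len(nrow(cand))) {
    ri <- find(match(cand$from[k], nodes))
    rj <- find(match(cand$to[k], nodes))
    if (ri != rj) {
      parent[ri] <- rj
      chosen <- c(chosen, k)
      if (length(chosen) == length(nodes) - 1L) break
    }
  }
  if (length(chosen) != length(nodes) - 1L)
    stop_domain("admissible graph is disconnected: no spanning tree exists")
  out <- cand[chosen, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- structural checks (used by tests and validation) ----------------------

# Verifies regular-vine structure: tree t has d - t edges forming a spanning
# tree on its node set, conditioning sets have size t - 1, and each
# tree-(t+1) edge joins two tree-t edges sharing a node (proximity). Edges
# carry `nodes`: the two endpoints in the tree's node set (variable names in
# tree 1, edge ids of the previous tree otherwise).
validate_vine_structure <- function(model) {
  d <- length(model$variables)
  if (length(model$trees) != d - 1L)
    stop_domain("expected ", d - 1L, " trees, found ", length(model$trees))
  for (t in seq_along(model$trees)) {
    ids <- model$trees[[t]]
    if (length(ids) != d - t)
      stop_domain("tree ", t, " has ", length(ids), " edges, expected ", d - t)
    node_set <- if (t == 1L) model$variables else model$trees[[t - 1L]]
    seen <- character(0)
    for (id in ids) {
      e <- model$edges[[id]]
      if (length(e$conditioned) != 2L || length(e$conditioning) != t - 1L)
        stop_domain("edge ", id, " malformed for tree ", t)
      if (length(intersect(e$conditioned, e$conditioning)))
        stop_domain("edge ", id, ": conditioned and conditioning sets overlap")
      if (!all(e$nodes %in% as.character(node_set)))
        stop_domain("edge ", id, " references nodes outside tree ", t)
      if (t > 1L) {
        p <- model$edges[as.integer(e$nodes)]
        if (!length(intersect(as.character(p[[1]]$nodes),
                              as.character(p[[2]]$nodes))))
          stop_domain("proximity condition violated at tree ", t)
      }
      seen <- union(seen, as.character(e$nodes))
    }
    # d - t edges touching all d - t + 1 nodes without leftover nodes is a
    # spanning tree iff connected; verify connectivity by union-find
    nodes_chr <- as.character(node_set)
    parent <- seq_along(nodes_chr)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (id in ids) {
      e <- model$edges[[id]]
      ri <- find(match(as.character(e$nodes)[1], nodes_chr))
      rj <- find(match(as.character(e$nodes)[2], nodes_chr))
      if (ri == rj) stop_domain("cycle detected in tree ", t)
      parent[ri] <- rj
    }
  }
  invisible(TRUE)
}
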