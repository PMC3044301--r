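# Independent brute-force oracles.  Clusters are represented as recursive
# trees (leaf: list(members = <chr>); join: list(members, left, right)) and
# every score is recomputed from scratch from a dense adjacency matrix, so
# nothing here shares code with the package's incremental engine.

adj_matrix <- function(net) {
  vs <- net$vertices
  A <- matrix(FALSE, length(vs), length(vs), dimnames = list(vs, vs))
  if (nrow(net$edges)) {
    A[net$edges] <- TRUE
    A[net$edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  A
}

o_lml <- function(e, t) {
  if (t == 0) return(0)
  h <- t - e
  s <- 0
  if (e > 0) s <- s + e * log(e / t)
  if (h > 0) s <- s + h * log(h / t)
  s
}
o_lbayes <- function(e, t) lbeta(e + 1, t - e + 1)

o_cross <- function(A, x, y) sum(A[x, y, drop = FALSE])
o_within <- function(A, x) sum(A[x, x, drop = FALSE]) / 2

o_leaf <- function(v) list(members = v)
o_join <- function(l, r) list(members = c(l$members, r$members),
                              left = l, right = r)

# sum of the per-node crossing terms of one cluster tree
o_tree_terms <- function(tr, A, fn) {
  if (is.null(tr$left)) {
    m <- tr$members   # terminal: within-group term (0 for singletons)
    return(fn(o_within(A, m), choose(length(m), 2)))
  }
  fn(o_cross(A, tr$left$members, tr$right$members),
     length(tr$left$members) * length(tr$right$members)) +
    o_tree_terms(tr$left, A, fn) + o_tree_terms(tr$right, A, fn)
}

# full hierarchical model score of a forest: root-pair block terms plus all
# node terms; every vertex pair is governed by exactly one term
o_forest_score <- function(forest, A, fn) {
  K <- length(forest)
  s <- 0
  if (K >= 2) for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    mi <- forest[[i]]$members; mj <- forest[[j]]$members
    s <- s + fn(o_cross(A, mi, mj), length(mi) * length(mj))
  }
  s + sum(vapply(forest, o_tree_terms, 0, A = A, fn = fn))
}

# the same likelihood evaluated pair-by-pair through each pair's governing
# term (LCA / terminal / root pair), as an independent route for the ML form
o_pairwise_loglik <- function(forest, A) {
  vs <- rownames(A)
  gov_density <- function(u, v) {
    for (tr in forest) {
      if (!(u %in% tr$members) || !(v %in% tr$members)) next
      while (!is.null(tr$left)) {
        inl <- c(u %in% tr$left$members, v %in% tr$left$members)
        if (inl[1] != inl[2])
          return(o_cross(A, tr$left$members, tr$right$members) /
                   (length(tr$left$members) * length(tr$right$members)))
        tr <- if (inl[1]) tr$left else tr$right
      }
      return(o_within(A, tr$members) / choose(length(tr$members), 2))
    }
    ri <- which(vapply(forest, function(t) u %in% t$members, TRUE))
    rj <- which(vapply(forest, function(t) v %in% t$members, TRUE))
    o_cross(A, forest[[ri]]$members, forest[[rj]]$members) /
      (length(forest[[ri]]$members) * length(forest[[rj]]$members))
  }
  s <- 0
  for (a in seq_len(length(vs) - 1)) for (b in seq(a + 1, length(vs))) {
    th <- gov_density(vs[a], vs[b])
    p <- if (A[vs[a], vs[b]]) th else 1 - th
    s <- s + if (p > 0) log(p) else 0   # 0^0 = 1 convention
  }
  s
}

# convert a forest to the cluster list the package's cluster_state() takes
o_clusters <- function(forest) lapply(forest, `[[`, "members")

# a random partial agglomeration state (forest) over the vertices of net
o_random_forest <- function(net, n_merges, seed) {
  set.seed(seed)
  forest <- lapply(net$vertices, o_leaf)
  for (s in seq_len(n_merges)) {
    if (length(forest) < 2) break
    ij <- sample.int(length(forest), 2)
    forest[[ij[1]]] <- o_join(forest[[ij[1]]], forest[[ij[2]]])
    forest[[ij[2]]] <- NULL
  }
  forest
}

# global Newman modularity of a partition (via igraph when available)
o_modularity <- function(net, clusters) {
  ig <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  ig <- igraph::add_vertices(
    ig, length(setdiff(net$vertices, igraph::V(ig)$name)),
    name = setdiff(net$vertices, igraph::V(ig)$name))
  memb <- integer(0)
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  igraph::modularity(ig, memb[igraph::V(ig)$name])
}
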