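#' Log maximum-likelihood of a Bernoulli block term
#'
#' For a block with `e` edges among `t` vertex pairs (holes `h = t - e`),
#' the profile likelihood at the ML estimate `theta = e/t` is
#' `(e/t)^e (h/t)^h`, with the convention `0^0 = 1`.  A block with `t = 0`
#' contributes nothing (returns 0).
#'
#' @param e edge count(s), `0 <= e <= t`.
#' @param t total pair count(s).
#' @return log-likelihood, vectorized over `e` and `t`.
#' @export
log_ml_bernoulli <- function(e, t) {
  n <- max(length(e), length(t))
  e <- rep_len(as.numeric(e), n)
  t <- rep_len(as.numeric(t), n)
  h <- t - e
  if (any(e < 0) || any(h < 0)) stop("log_ml_bernoulli: need 0 <= e <= t")
  out <- numeric(n)
  i <- e > 0 & h > 0
  out[i] <- e[i] * log(e[i] / t[i]) + h[i] * log(h[i] / t[i])
  out
}

#' Log marginal probability of a Bernoulli block term
#'
#' Integrating the block's edge probability out under a uniform prior gives
#' `Beta(e + 1, h + 1)` with `h = t - e`; computed in log space via
#' `lbeta()`.  `t = 0` gives `Beta(1, 1) = 1`, i.e. 0.
#'
#' @inheritParams log_ml_bernoulli
#' @return log marginal probability, vectorized.
#' @export
log_bayes_bernoulli <- function(e, t) {
  n <- max(length(e), length(t))
  e <- rep_len(as.numeric(e), n)
  t <- rep_len(as.numeric(t), n)
  h <- t - e
  if (any(e < 0) || any(h < 0)) stop("log_bayes_bernoulli: need 0 <= e <= t")
  lbeta(e + 1, h + 1)
}

## Score change from pooling two blocks (e1,t1), (e2,t2) into one, per layer.
## Used by both the public merge scores and the agglomeration engine.
.term_ml <- function(e1, e2, t1, t2)
  log_ml_bernoulli(e1 + e2, t1 + t2) -
    log_ml_bernoulli(e1, t1) - log_ml_bernoulli(e2, t2)

.term_bayes <- function(e1, e2, t1, t2)
  log_bayes_bernoulli(e1 + e2, t1 + t2) -
    log_bayes_bernoulli(e1, t1) - log_bayes_bernoulli(e2, t2)

## log lambda^C for homogenizing two collapsed groups, per layer (vectors).
.term_collapse <- function(eii, ejj, eij, ni, nj) {
  tw <- choose(ni + nj, 2)
  log_bayes_bernoulli(eii + ejj + eij, tw) -
    log_bayes_bernoulli(eii, choose(ni, 2)) -
    log_bayes_bernoulli(ejj, choose(nj, 2)) -
    log_bayes_bernoulli(eij, ni * nj)
}

## ---------------------------------------------------------------------------
## Cluster states: a partition of the vertex set plus the block edge counts
## that every merge score is computed from.

#' Build a cluster state (partition plus block counts)
#'
#' A cluster state holds the current top-level partition together with the
#' within-group and between-group edge counts of every layer — the
#' sufficient statistics for all merge scores.
#'
#' @param net a `hac_network` or `hac_multinet`; for multi-layer input all
#'   layers must share one vertex set (see [intersect_layers()]).
#' @param clusters the partition: a list of character vectors of vertex
#'   ids, a membership vector named by vertex, or `NULL` for the
#'   all-singletons partition.
#' @return An object of class `hac_state`.
#' @export
cluster_state <- function(net, clusters = NULL) {
  mnet <- as_multinet(net)
  verts <- mnet$layers[[1L]]$vertices
  for (l in mnet$layers)
    if (!identical(l$vertices, verts))
      stop("layers differ in vertex set; run intersect_layers() first")
  nv <- length(verts)
  if (nv == 0L) stop("empty network")
  vidx <- seq_len(nv)
  names(vidx) <- verts
  if (is.null(clusters)) {
    members <- as.list(vidx)
  } else if (is.list(clusters)) {
    members <- lapply(clusters, function(m) unname(vidx[as.character(m)]))
  } else {
    grp <- as.character(clusters)
    who <- names(clusters)
    if (is.null(who)) {
      if (length(grp) != nv) stop("unnamed membership must cover all vertices")
      who <- verts
    }
    members <- lapply(split(who, grp), function(m) unname(vidx[m]))
  }
  flat <- sort(unlist(members, use.names = FALSE))
  if (anyNA(flat) || length(flat) != nv ||
      !identical(as.integer(flat), seq_len(nv)))
    stop("clusters must form a partition of the vertex set")
  members <- unname(members)
  K <- length(members)
  L <- length(mnet$layers)
  memb <- integer(nv)
  for (i in seq_len(K)) memb[members[[i]]] <- i

  adj <- lapply(mnet$layers, function(l) {
    a <- vector("list", nv)
    if (nrow(l$edges)) {
      eu <- vidx[l$edges[, 1L]]
      ev <- vidx[l$edges[, 2L]]
      for (r in seq_along(eu)) {
        a[[eu[r]]] <- c(a[[eu[r]]], ev[r])
        a[[ev[r]]] <- c(a[[ev[r]]], eu[r])
      }
    }
    lapply(a, function(x) sort(unique(as.integer(x))))
  })

  e_cross <- array(0, dim = c(K, K, L))
  e_within <- matrix(0, K, L)
  deg_sum <- matrix(0, K, L)
  E <- numeric(L)
  for (l in seq_len(L)) {
    ed <- mnet$layers[[l]]$edges
    E[l] <- nrow(ed)
    if (!nrow(ed)) next
    gu <- memb[vidx[ed[, 1L]]]
    gv <- memb[vidx[ed[, 2L]]]
    for (r in seq_along(gu)) {
      if (gu[r] == gv[r]) {
        e_within[gu[r], l] <- e_within[gu[r], l] + 1
      } else {
        i <- min(gu[r], gv[r]); j <- max(gu[r], gv[r])
        e_cross[i, j, l] <- e_cross[i, j, l] + 1
        e_cross[j, i, l] <- e_cross[i, j, l]
      }
    }
    dg <- tabulate(c(vidx[ed[, 1L]], vidx[ed[, 2L]]), nbins = nv)
    for (i in seq_len(K)) deg_sum[i, l] <- sum(dg[members[[i]]])
  }
  structure(list(vertices = verts, layers = names(mnet$layers),
                 members = members, membership = memb,
                 sizes = lengths(members), K = K, L = L, nv = nv,
                 e_cross = e_cross, e_within = e_within,
                 deg_sum = deg_sum, E = E, adj = adj),
            class = "hac_state")
}

#' @export
print.hac_state <- function(x, ...) {
  cat(sprintf("<hac_state> %d vertices in %d cluster(s), %d layer(s)\n",
              x$nv, x$K, x$L))
  invisible(x)
}

.check_state_pair <- function(state, i, j) {
  stopifnot(inherits(state, "hac_state"))
  if (i == j || i < 1L || j < 1L || i > state$K || j > state$K)
    stop("i and j must be two distinct top-level cluster indices")
}

#' Flat block-model scores of a partition
#'
#' Sums the Bernoulli block terms over all within-group and between-group
#' blocks of a flat `K`-group model (`K(K+1)/2` parameters), in both the
#' maximum-likelihood and the fully Bayesian (integrated) form.  Layers of
#' a multi-layer network contribute additively.
#'
#' @inheritParams cluster_state
#' @return list with `log_likelihood`, `log_prob`, and a `per_layer` data
#'   frame.
#' @export
flat_model_scores <- function(net, clusters = NULL) {
  st <- if (inherits(net, "hac_state")) net else cluster_state(net, clusters)
  K <- st$K
  ll <- lp <- numeric(st$L)
  for (l in seq_len(st$L)) {
    tw <- choose(st$sizes, 2)
    ll[l] <- sum(log_ml_bernoulli(st$e_within[, l], tw))
    lp[l] <- sum(log_bayes_bernoulli(st$e_within[, l], tw))
    if (K >= 2L) {
      for (i in seq_len(K - 1L)) for (j in seq(i + 1L, K)) {
        tt <- st$sizes[i] * st$sizes[j]
        ll[l] <- ll[l] + log_ml_bernoulli(st$e_cross[i, j, l], tt)
        lp[l] <- lp[l] + log_bayes_bernoulli(st$e_cross[i, j, l], tt)
      }
    }
  }
  list(log_likelihood = sum(ll), log_prob = sum(lp),
       per_layer = data.frame(layer = st$layers,
                              log_likelihood = ll, log_prob = lp))
}

#' Hierarchical model scores of a dendrogram
#'
#' Evaluates the hierarchical block-model objective for a merge forest: one
#' Bernoulli term per pair of top-level roots (edges/holes crossing between
#' them), one term per branching node (edges/holes crossing between its
#' left and right subtrees), and one within-group term per collapsed
#' terminal.  Every vertex pair is governed by exactly one term.  All
#' counts are re-tallied from `net`; with `check_counts = TRUE` they are
#' also compared against the counts stored in the dendrogram (audit mode).
#'
#' @param dend a `hac_dendrogram` (see [run_hac()]).
#' @param net the network(s) the model describes.
#' @param check_counts verify stored node counts against the recount.
#' @return list with `log_likelihood`, `log_prob` and `per_layer`.
#' @export
tree_model_scores <- function(dend, net, check_counts = FALSE) {
  stopifnot(inherits(dend, "hac_dendrogram"))
  mnet <- as_multinet(net)
  L <- length(mnet$layers)
  if (check_counts && L != length(dend$layers))
    stop("count audit needs the same layers the tree was fitted on")
  verts <- mnet$layers[[1L]]$vertices
  if (!setequal(verts, dend$labels))
    stop("dendrogram members do not partition the network's vertices")
  vidx <- seq_along(dend$labels)
  names(vidx) <- dend$labels
  nv <- length(vidx)
  edges <- lapply(mnet$layers, function(l)
    cbind(vidx[l$edges[, 1L]], vidx[l$edges[, 2L]]))

  live <- which(!dend$nodes$pruned)
  ll <- lp <- numeric(L)
  side <- integer(nv)
  for (id in live) {
    nd <- dend$nodes[id, ]
    memb <- dend$members[[id]]
    if (nd$collapsed || is.na(nd$left)) {   # terminal (within-group term)
      tt <- choose(length(memb), 2)
      inm <- logical(nv); inm[memb] <- TRUE
      for (l in seq_len(L)) {
        ed <- edges[[l]]
        e <- if (nrow(ed)) sum(inm[ed[, 1L]] & inm[ed[, 2L]]) else 0
        if (check_counts && e != dend$e_within[id, l])
          stop(sprintf("stored within-count of node %d, layer %d is stale", id, l))
        ll[l] <- ll[l] + log_ml_bernoulli(e, tt)
        lp[l] <- lp[l] + log_bayes_bernoulli(e, tt)
      }
    } else {                                # branching node (crossing term)
      side[] <- 0L
      side[dend$members[[nd$left]]] <- 1L
      side[dend$members[[nd$right]]] <- 2L
      tt <- length(dend$members[[nd$left]]) * length(dend$members[[nd$right]])
      for (l in seq_len(L)) {
        ed <- edges[[l]]
        e <- if (nrow(ed)) {
          s1 <- side[ed[, 1L]]; s2 <- side[ed[, 2L]]
          sum(s1 != 0L & s2 != 0L & s1 != s2)
        } else 0
        if (check_counts && e != dend$e_cross[id, l])
          stop(sprintf("stored crossing count of node %d, layer %d is stale", id, l))
        ll[l] <- ll[l] + log_ml_bernoulli(e, tt)
        lp[l] <- lp[l] + log_bayes_bernoulli(e, tt)
      }
    }
  }
  roots <- dend$roots
  if (length(roots) >= 2L) {
    rmemb <- integer(nv)
    for (r in roots) rmemb[dend$members[[r]]] <- r
    for (a in seq_len(length(roots) - 1L)) for (b in seq(a + 1L, length(roots))) {
      ra <- roots[a]; rb <- roots[b]
      tt <- length(dend$members[[ra]]) * length(dend$members[[rb]])
      for (l in seq_len(L)) {
        ed <- edges[[l]]
        e <- if (nrow(ed)) {
          r1 <- rmemb[ed[, 1L]]; r2 <- rmemb[ed[, 2L]]
          sum((r1 == ra & r2 == rb) | (r1 == rb & r2 == ra))
        } else 0
        ll[l] <- ll[l] + log_ml_bernoulli(e, tt)
        lp[l] <- lp[l] + log_bayes_bernoulli(e, tt)
      }
    }
  }
  list(log_likelihood = sum(ll), log_prob = sum(lp),
       per_layer = data.frame(layer = names(mnet$layers),
                              log_likelihood = ll, log_prob = lp))
}
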