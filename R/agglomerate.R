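#' Greedy hierarchical agglomerative clustering (HAC)
#'
#' Builds a guide tree by repeatedly merging the pair of top-level clusters
#' with the best merge score, starting from singletons.  The default score
#' is the maximum-likelihood ratio of the hierarchical block model
#' (HAC-ML, [merge_score_ml()]); alternatives are its fully Bayesian form
#' and the heuristics edge density (HAC-E), edge plus shared-neighbour
#' density (HAC-ES) and decomposed Newman modularity (HAC-Q).  Candidate
#' pairs are restricted to clusters connected by an edge or sharing a
#' neighbouring cluster, managed in a lazy priority queue with version
#' stamps.  At every accepted merge the Bayesian ratio lambda-B is recorded
#' (it defines the top-level cut but never stops the tree construction,
#' which continues so that link prediction can use all tree levels), and
#' when both children are collapsed the collapse ratio lambda-C decides
#' whether the merged cluster becomes a single homogeneous terminal.
#' For multi-layer input, scores are sums of per-layer log scores and the
#' candidate set is the union over layers.
#'
#' Disconnected inputs yield a forest: no candidate ever spans components,
#' so the loop can end with several roots.
#'
#' @param net a `hac_network` or `hac_multinet` (layers must share one
#'   vertex set, see [intersect_layers()]).
#' @param method merge-score choice: `"ml"`, `"bayes"`, `"e"`, `"es"`,
#'   `"q"`.
#' @param collapse evaluate lambda-C and collapse homogeneous terminals
#'   (default `TRUE`).
#' @param stop_criterion how the recorded Bayesian ratios define the
#'   top-level cut.  `"subtree"` (the default) scores every join by its
#'   full Bayesian evidence — log lambda-B plus log lambda-C whenever the
#'   internal-coherence test was made (both children collapsed) — and
#'   reports the maximal subtrees containing no disfavoured join; this is
#'   the rule that resolves block structure (see the vignette).
#'   `"first-drop"` and `"cummax"` are trajectory rules (the state before
#'   the first accepted merge with lambda-B < 1, or at the earliest
#'   maximum of cumulative log lambda-B); `"none"` reports the roots.
#' @param max_merges optional cap on the number of merges.
#' @return An object of class `hac_result`: list with `dendrogram`
#'   (`hac_dendrogram`), `merge_sequence` (one row per merge: step, child
#'   ids, node id, ordering score, log lambda-ML, log lambda-B,
#'   log lambda-C, collapsed flag), `top_level` and `bottom_level` (lists
#'   of character vectors), `roots`, `stop_step`, `log_likelihood`,
#'   `log_prob`, `per_layer`, `method`, `stop_criterion`, and `network`.
#' @export
run_hac <- function(net, method = c("ml", "bayes", "e", "es", "q"),
                    collapse = TRUE,
                    stop_criterion = c("subtree", "first-drop", "cummax",
                                       "none"),
                    max_merges = Inf) {
  method <- match.arg(method)
  stop_criterion <- match.arg(stop_criterion)
  mnet <- as_multinet(net)
  verts <- mnet$layers[[1L]]$vertices
  for (l in mnet$layers)
    if (!identical(l$vertices, verts))
      stop("layers differ in vertex set; run intersect_layers() first")
  nv <- length(verts)
  if (nv == 0L) stop("empty network")
  L <- length(mnet$layers)
  vidx <- seq_len(nv)
  names(vidx) <- verts

  adj <- lapply(mnet$layers, function(l) {
    a <- rep(list(integer(0)), nv)
    if (nrow(l$edges)) {
      eu <- vidx[l$edges[, 1L]]; ev <- vidx[l$edges[, 2L]]
      for (r in seq_along(eu)) {
        a[[eu[r]]] <- c(a[[eu[r]]], ev[r])
        a[[ev[r]]] <- c(a[[ev[r]]], eu[r])
      }
    }
    lapply(a, sort)
  })
  E_tot <- vapply(mnet$layers, n_edges, 0L)
  degs <- vapply(seq_len(L), function(l) lengths(adj[[l]]), integer(nv))
  if (nv == 1L) degs <- matrix(degs, 1L, L)

  nn_max <- 2L * nv
  left <- right <- rep(NA_integer_, nn_max)
  size <- integer(nn_max)
  collapsed_f <- logical(nn_max)
  pruned <- logical(nn_max)
  parent <- integer(nn_max)
  step_of <- rep(NA_integer_, nn_max)
  minmem <- character(nn_max)
  version <- integer(nn_max)
  active <- logical(nn_max)
  members <- vector("list", nn_max)
  e_within <- matrix(0, nn_max, L)
  e_cross <- matrix(NA_real_, nn_max, L)
  t_cross <- rep(NA_real_, nn_max)
  deg_sum <- matrix(0, nn_max, L)
  nbrs <- rep(list(integer(0)), nn_max)

  for (v in seq_len(nv)) {
    size[v] <- 1L
    collapsed_f[v] <- TRUE
    active[v] <- TRUE
    minmem[v] <- verts[v]
    members[[v]] <- v
    deg_sum[v, ] <- degs[v, ]
  }
  ntop <- nv

  ## sparse between-cluster counts (per-layer vectors), keyed "i,j" (i < j)
  xe <- new.env(hash = TRUE, parent = emptyenv())
  xkey <- function(i, j) if (i < j) paste0(i, ",", j) else paste0(j, ",", i)
  xe_get <- function(i, j) {
    v <- xe[[xkey(i, j)]]
    if (is.null(v)) numeric(L) else v
  }
  for (l in seq_len(L)) {
    ed <- mnet$layers[[l]]$edges
    if (!nrow(ed)) next
    eu <- vidx[ed[, 1L]]; ev <- vidx[ed[, 2L]]
    for (r in seq_along(eu)) {
      k <- xkey(eu[r], ev[r])
      v <- xe[[k]]
      if (is.null(v)) v <- numeric(L)
      v[l] <- v[l] + 1
      xe[[k]] <- v
    }
  }
  for (v in seq_len(nv))
    nbrs[[v]] <- sort(unique(unlist(lapply(adj, `[[`, v), use.names = FALSE)))

  score_ml_pair <- function(i, j) {
    nb <- setdiff(unique(c(nbrs[[i]], nbrs[[j]])), c(i, j))
    s <- 0
    for (k in nb)
      s <- s + sum(.term_ml(xe_get(i, k), xe_get(j, k),
                            size[i] * size[k], size[j] * size[k]))
    s
  }
  score_bayes_pair <- function(i, j) {
    s <- 0
    for (k in which(active[seq_len(ntop)])) {
      if (k == i || k == j) next
      s <- s + sum(.term_bayes(xe_get(i, k), xe_get(j, k),
                               size[i] * size[k], size[j] * size[k]))
    }
    s
  }
  score_e_pair <- function(i, j) sum(xe_get(i, j) / (size[i] * size[j]))
  score_s_pair <- function(i, j) {
    outside <- nv - size[i] - size[j]
    if (outside == 0L) return(0)
    inside <- logical(nv)
    inside[c(members[[i]], members[[j]])] <- TRUE
    s <- 0
    for (l in seq_len(L)) {
      nb_i <- unique(unlist(adj[[l]][members[[i]]], use.names = FALSE))
      nb_j <- unique(unlist(adj[[l]][members[[j]]], use.names = FALSE))
      shared <- intersect(nb_i, nb_j)
      s <- s + sum(!inside[shared]) / outside
    }
    s
  }
  score_q_pair <- function(i, j)
    sum(xe_get(i, j) / E_tot - deg_sum[i, ] * deg_sum[j, ] / (2 * E_tot^2))
  score_pair <- switch(method,
    ml = score_ml_pair,
    bayes = score_bayes_pair,
    e = score_e_pair,
    es = function(i, j) score_e_pair(i, j) + score_s_pair(i, j),
    q = score_q_pair)
  if (method == "q" && any(E_tot == 0))
    stop("HAC-Q is undefined on a layer with no edges")

  gv <- 0L
  heap <- .heap_new()
  pair_key <- function(i, j) {
    a <- minmem[i]; b <- minmem[j]
    if (a < b) paste0(a, "\t", b) else paste0(b, "\t", a)
  }

  ## Current candidate pairs and their scores.  The heap only holds stamped
  ## copies: whenever a pair's score changes, a freshly stamped entry is
  ## pushed, and any copy with outdated stamps is discarded when popped.
  ## A merge changes the lambda-ML score of exactly the candidate pairs
  ## with an endpoint adjacent to the merged cluster (the third-cluster
  ## terms for i, j and r), and those are updated in O(1) each; scores can
  ## move in either direction, so a purely lazy queue would be wrong.  The
  ## heuristic scores (e, es, q) of an existing pair never change, and the
  ## fully Bayesian ordering depends on all clusters, so it is rescored
  ## globally (small inputs only).
  cand_score <- new.env(hash = TRUE, parent = emptyenv())
  cand_nbrs <- rep(list(integer(0)), nn_max)
  push_entry <- function(i, j, s)
    .heap_push(heap, s, i, j, version[i], version[j], gv, pair_key(i, j))
  set_score <- function(i, j, s) {
    key <- xkey(i, j)
    if (is.null(cand_score[[key]])) {
      cand_nbrs[[i]] <<- c(cand_nbrs[[i]], j)
      cand_nbrs[[j]] <<- c(cand_nbrs[[j]], i)
    }
    cand_score[[key]] <- s
    push_entry(i, j, s)
  }

  for (u in seq_len(nv)) {
    nb <- nbrs[[u]]
    for (v in nb)
      if (u < v && is.null(cand_score[[xkey(u, v)]]))
        set_score(u, v, score_pair(u, v))
    if (length(nb) >= 2L)
      for (a in seq_len(length(nb) - 1L))
        for (b in seq(a + 1L, length(nb))) {
          p <- nb[a]; q <- nb[b]
          if (is.null(cand_score[[xkey(p, q)]]))
            set_score(p, q, score_pair(p, q))
        }
  }

  mseq <- vector("list", nv)
  step <- 0L
  while (!is.null(top <- .heap_pop(heap))) {
    i <- top$i; j <- top$j
    if (!active[i] || !active[j]) next
    stale <- switch(method,
      ml = version[i] != top$vi || version[j] != top$vj,
      bayes = gv != top$gv,
      FALSE)
    if (stale) next                      # a fresher copy is in the heap

    ## accept the merge of i and j
    step <- step + 1L
    lml <- if (method == "ml") top$score else score_ml_pair(i, j)
    lb <- score_bayes_pair(i, j)
    ## internal-coherence statistic of the join (one homogeneous group vs
    ## separate within/within/between blocks); equals lambda-C when both
    ## children are collapsed, but is recorded for every join because the
    ## top-level cut uses it
    lcoh <- sum(.term_collapse(e_within[i, ], e_within[j, ], xe_get(i, j),
                               size[i], size[j]))
    lc <- NA_real_
    do_collapse <- FALSE
    if (collapse && collapsed_f[i] && collapsed_f[j]) {
      lc <- lcoh
      do_collapse <- lc >= 0
    }

    r <- ntop + 1L
    ntop <- r
    eij <- xe_get(i, j)
    left[r] <- i; right[r] <- j
    size[r] <- size[i] + size[j]
    members[[r]] <- c(members[[i]], members[[j]])
    minmem[r] <- min(minmem[i], minmem[j])
    e_cross[r, ] <- eij
    t_cross[r] <- as.numeric(size[i]) * size[j]
    e_within[r, ] <- e_within[i, ] + e_within[j, ] + eij
    deg_sum[r, ] <- deg_sum[i, ] + deg_sum[j, ]
    step_of[r] <- step
    parent[i] <- parent[j] <- r
    active[i] <- active[j] <- FALSE
    active[r] <- TRUE
    collapsed_f[r] <- do_collapse
    if (do_collapse) pruned[i] <- pruned[j] <- TRUE

    ## snapshot the pre-merge cross counts to i and j, and the candidate
    ## partners of every affected neighbour, before mutating the state
    nb <- setdiff(unique(c(nbrs[[i]], nbrs[[j]])), c(i, j))
    pre_ei <- lapply(nb, function(k) xe_get(i, k))
    pre_ej <- lapply(nb, function(k) xe_get(j, k))
    affected <- lapply(nb, function(k) setdiff(cand_nbrs[[k]], c(i, j)))
    ni_old <- size[i]; nj_old <- size[j]

    for (t in seq_along(nb)) {
      k <- nb[t]
      xe[[xkey(r, k)]] <- pre_ei[[t]] + pre_ej[[t]]
      if (!is.null(xe[[xkey(i, k)]])) rm(list = xkey(i, k), envir = xe)
      if (!is.null(xe[[xkey(j, k)]])) rm(list = xkey(j, k), envir = xe)
      nbrs[[k]] <- sort(unique(c(setdiff(nbrs[[k]], c(i, j)), r)))
      version[k] <- version[k] + 1L
    }
    if (!is.null(xe[[xkey(i, j)]])) rm(list = xkey(i, j), envir = xe)
    nbrs[[r]] <- nb
    version[r] <- 1L
    gv <- gv + 1L

    ## retire candidate entries involving the merged children
    for (x in cand_nbrs[[i]]) {
      if (!is.null(cand_score[[xkey(i, x)]])) rm(list = xkey(i, x), envir = cand_score)
      cand_nbrs[[x]] <- setdiff(cand_nbrs[[x]], i)
    }
    for (x in cand_nbrs[[j]]) {
      if (!is.null(cand_score[[xkey(j, x)]])) rm(list = xkey(j, x), envir = cand_score)
      cand_nbrs[[x]] <- setdiff(cand_nbrs[[x]], j)
    }
    cand_nbrs[[i]] <- cand_nbrs[[j]] <- integer(0)

    if (method == "ml") {
      ## O(1) score delta for every candidate pair touching a neighbour of
      ## r: only its third-cluster terms for i, j (removed) and r (added)
      ## change
      done <- new.env(hash = TRUE, parent = emptyenv())
      nr <- size[r]
      for (t in seq_along(nb)) {
        k <- nb[t]
        nk <- size[k]
        for (x in affected[[t]]) {
          key <- xkey(k, x)
          if (!is.null(done[[key]])) next
          done[[key]] <- TRUE
          p <- match(x, nb)
          e_xi <- if (is.na(p)) numeric(L) else pre_ei[[p]]
          e_xj <- if (is.na(p)) numeric(L) else pre_ej[[p]]
          nx <- size[x]
          dlt <- sum(.term_ml(pre_ei[[t]] + pre_ej[[t]], e_xi + e_xj,
                              nk * nr, nx * nr)) -
                 sum(.term_ml(pre_ei[[t]], e_xi, nk * ni_old, nx * ni_old)) -
                 sum(.term_ml(pre_ej[[t]], e_xj, nk * nj_old, nx * nj_old))
          s <- cand_score[[key]] + dlt
          cand_score[[key]] <- s
          push_entry(k, x, s)
        }
      }
    }

    ## merges can create new shared-neighbour candidates among the
    ## neighbours of r
    if (length(nb) >= 2L)
      for (a in seq_len(length(nb) - 1L))
        for (b in seq(a + 1L, length(nb))) {
          p <- nb[a]; q <- nb[b]
          if (is.null(cand_score[[xkey(p, q)]]))
            set_score(p, q, score_pair(p, q))
        }

    ## candidate pairs involving the new cluster
    partners <- setdiff(unique(c(nb, unlist(nbrs[nb], use.names = FALSE))), r)
    partners <- partners[active[partners]]
    for (x in partners) set_score(r, x, score_pair(r, x))

    if (method == "bayes") {
      ## every pair's Bayesian score depends on all clusters: rescore all
      for (key in ls(cand_score)) {
        pq <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
        s <- score_pair(pq[1L], pq[2L])
        cand_score[[key]] <- s
        push_entry(pq[1L], pq[2L], s)
      }
    }

    mseq[[step]] <- data.frame(step = step, left = i, right = j, node = r,
                               score = top$score, log_lambda_ml = lml,
                               log_lambda_bayes = lb,
                               log_lambda_coherence = lcoh,
                               log_lambda_collapse = lc,
                               collapsed = do_collapse)

    if (step >= max_merges) break
  }

  mseq <- if (step > 0L) do.call(rbind, mseq[seq_len(step)]) else
    data.frame(step = integer(0), left = integer(0), right = integer(0),
               node = integer(0), score = numeric(0),
               log_lambda_ml = numeric(0), log_lambda_bayes = numeric(0),
               log_lambda_coherence = numeric(0),
               log_lambda_collapse = numeric(0), collapsed = logical(0))

  nn <- ntop
  roots <- which(active[seq_len(nn)])
  dend <- structure(list(
    labels = verts,
    layers = names(mnet$layers),
    n_leaves = nv,
    nodes = data.frame(
      id = seq_len(nn),
      left = left[seq_len(nn)], right = right[seq_len(nn)],
      size = size[seq_len(nn)],
      collapsed = collapsed_f[seq_len(nn)], pruned = pruned[seq_len(nn)],
      step = step_of[seq_len(nn)]),
    members = members[seq_len(nn)],
    e_cross = e_cross[seq_len(nn), , drop = FALSE],
    t_cross = t_cross[seq_len(nn)],
    e_within = e_within[seq_len(nn), , drop = FALSE],
    parent = parent[seq_len(nn)],
    bottom = .bottom_at(parent[seq_len(nn)], collapsed_f[seq_len(nn)],
                        step_of[seq_len(nn)], nv, Inf),
    roots = roots), class = "hac_dendrogram")
  dend$nodes$log_lambda_ml <- NA_real_
  dend$nodes$log_lambda_bayes <- NA_real_
  dend$nodes$log_lambda_coherence <- NA_real_
  dend$nodes$log_lambda_collapse <- NA_real_
  if (step > 0L) {
    dend$nodes$log_lambda_ml[mseq$node] <- mseq$log_lambda_ml
    dend$nodes$log_lambda_bayes[mseq$node] <- mseq$log_lambda_bayes
    dend$nodes$log_lambda_coherence[mseq$node] <- mseq$log_lambda_coherence
    dend$nodes$log_lambda_collapse[mseq$node] <- mseq$log_lambda_collapse
  }

  ## final model score from the maintained counts (additive over layers)
  ll_layer <- lp_layer <- numeric(L)
  for (id in seq_len(nn)) {
    if (pruned[id]) next
    if (collapsed_f[id] || is.na(left[id])) {
      tt <- choose(size[id], 2)
      ll_layer <- ll_layer + log_ml_bernoulli(e_within[id, ], rep(tt, L))
      lp_layer <- lp_layer + log_bayes_bernoulli(e_within[id, ], rep(tt, L))
    } else {
      ll_layer <- ll_layer + log_ml_bernoulli(e_cross[id, ], rep(t_cross[id], L))
      lp_layer <- lp_layer + log_bayes_bernoulli(e_cross[id, ], rep(t_cross[id], L))
    }
  }
  root_cross <- NULL
  if (length(roots) >= 2L) {
    root_cross <- array(0, dim = c(length(roots), length(roots), L))
    for (a in seq_len(length(roots) - 1L)) for (b in seq(a + 1L, length(roots))) {
      e <- xe_get(roots[a], roots[b])
      root_cross[a, b, ] <- root_cross[b, a, ] <- e
      tt <- as.numeric(size[roots[a]]) * size[roots[b]]
      ll_layer <- ll_layer + log_ml_bernoulli(e, rep(tt, L))
      lp_layer <- lp_layer + log_bayes_bernoulli(e, rep(tt, L))
    }
  }

  res <- structure(list(
    dendrogram = dend,
    merge_sequence = mseq,
    method = method,
    stop_criterion = stop_criterion,
    roots = roots,
    root_cross = root_cross,
    log_likelihood = sum(ll_layer),
    log_prob = sum(lp_layer),
    per_layer = data.frame(layer = names(mnet$layers),
                           log_likelihood = ll_layer, log_prob = lp_layer),
    network = mnet), class = "hac_result")
  res$stop_step <- .stop_step(mseq, stop_criterion)
  res$top_level <- top_level_clusters(res, stop_criterion)
  res$bottom_level <- bottom_level_clusters(res, stop_criterion)
  res
}

#' @export
print.hac_result <- function(x, ...) {
  cat(sprintf(paste0("<hac_result> HAC-%s: %d vertices, %d merges, ",
                     "%d root(s)\n  %d top-level / %d bottom-level clusters",
                     " (stop: %s)\n  log L = %.4f, log P = %.4f\n"),
              toupper(x$method), x$dendrogram$n_leaves,
              nrow(x$merge_sequence), length(x$roots),
              length(x$top_level), length(x$bottom_level), x$stop_criterion,
              x$log_likelihood, x$log_prob))
  invisible(x)
}

## number of merges to keep for a trajectory stopping rule; the cut state
## is the state after that many merges.
.stop_step <- function(mseq, stop_criterion) {
  lb <- mseq$log_lambda_bayes
  switch(stop_criterion,
    "first-drop" = {
      drop <- which(lb < -1e-9)
      if (length(drop)) drop[1L] - 1L else NA_integer_
    },
    "cummax" = {
      if (!length(lb)) return(NA_integer_)
      cm <- c(0, cumsum(lb))
      min(which(cm >= max(cm) - 1e-9)) - 1L
    },
    NA_integer_)
}

## Full Bayesian evidence that a join's two children form one group:
## profile terms (log lambda-B), the internal-coherence statistic (the
## lambda-C Beta ratio on the children's within/between counts), and the
## prior-odds term ln(2^(n-1) - 1) for the 2^(n-1)-1 possible bipartitions
## the split hypothesis must choose among.  NA for leaves.
.join_evidence <- function(dend) {
  lb <- dend$nodes$log_lambda_bayes
  lc <- dend$nodes$log_lambda_coherence
  n <- dend$nodes$size
  mult <- (n - 1) * log(2) + log1p(-0.5^(n - 1))
  ifelse(is.na(lb), NA_real_, lb + ifelse(is.na(lc), 0, lc) + mult)
}

## Node ids forming the top-level cut.
.top_nodes <- function(result, stop_criterion) {
  d <- result$dendrogram
  nd <- d$nodes
  if (stop_criterion %in% c("first-drop", "cummax")) {
    s <- .stop_step(result$merge_sequence, stop_criterion)
    if (is.na(s)) s <- nrow(result$merge_sequence)
    formed <- is.na(nd$step) | nd$step < s + 1L
    return(which(formed & (d$parent == 0L | !formed[pmax(d$parent, 1L)])))
  }
  if (stop_criterion == "none") return(d$roots)
  ## "subtree": maximal subtrees whose every join is favoured
  ev <- .join_evidence(d)
  good <- is.na(ev) | ev >= -1e-9          # leaves are always coherent
  goodstar <- logical(nrow(nd))
  for (id in seq_len(nrow(nd))) {
    goodstar[id] <- if (is.na(nd$left[id])) TRUE else
      good[id] && goodstar[nd$left[id]] && goodstar[nd$right[id]]
  }
  which(goodstar & (d$parent == 0L | !goodstar[pmax(d$parent, 1L)]))
}

## join evidence between two clusters of a flat state: profile terms plus
## internal coherence plus the bipartition prior-odds term.
.pair_evidence <- function(st, i, j) {
  n <- st$sizes[i] + st$sizes[j]
  merge_score_bayes(st, i, j) +
    sum(.term_collapse(st$e_within[i, ], st$e_within[j, ],
                       st$e_cross[i, j, ], st$sizes[i], st$sizes[j])) +
    (n - 1) * log(2) + log1p(-0.5^(n - 1))
}

## Greedily merge top-level clusters whose pairwise join evidence is
## positive, so the reported top level is a fixpoint: joining any two
## reported clusters would lower the model evidence.  Repairs clusters the
## greedy guide-tree order tore across subtrees.
.consolidate_top <- function(net, clusters) {
  repeat {
    if (length(clusters) < 2L) return(clusters)
    st <- cluster_state(net, clusters)
    cp <- candidate_pairs(st)
    if (!nrow(cp)) return(clusters)
    ev <- vapply(seq_len(nrow(cp)), function(r)
      .pair_evidence(st, cp$i[r], cp$j[r]), 0)
    keys <- vapply(seq_len(nrow(cp)), function(r)
      paste(sort(c(min(clusters[[cp$i[r]]]), min(clusters[[cp$j[r]]]))),
            collapse = "\t"), "")
    ok <- ev >= 1e-9
    if (!any(ok)) return(clusters)
    pick <- which(ok)[order(-ev[ok], keys[ok])][1L]
    a <- cp$i[pick]; b <- cp$j[pick]
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
  }
}

#' Extract the top-level cut of a clustering result
#'
#' Re-derives the top-level clusters from a finished [run_hac()] result
#' under any of the stopping rules (see [run_hac()]) without re-running
#' the engine.  Under the `"subtree"` rule the cut is additionally made
#' consistent: any two reported clusters whose joint Bayesian evidence
#' favours merging (which can happen when the greedy merge order split a
#' group across subtrees) are merged, highest evidence first, until no
#' such pair remains.
#'
#' @param result a `hac_result`.
#' @param stop_criterion `"subtree"`, `"first-drop"`, `"cummax"` or
#'   `"none"`; defaults to the rule the result was built with.
#' @param consolidate apply the fixpoint consolidation (subtree rule
#'   only).
#' @return list of character vectors of vertex ids.
#' @export
top_level_clusters <- function(result, stop_criterion = result$stop_criterion,
                               consolidate = TRUE) {
  stopifnot(inherits(result, "hac_result"))
  d <- result$dendrogram
  cl <- lapply(.top_nodes(result, stop_criterion),
               function(id) d$labels[d$members[[id]]])
  if (identical(stop_criterion, "subtree") && consolidate)
    cl <- .consolidate_top(result$network, cl)
  cl
}

#' @rdname top_level_clusters
#' @return for `bottom_level_clusters`, the collapsed-terminal member
#'   sets, restricted to terminals inside the top-level cut so that the
#'   bottom level always refines the top level.
#' @export
bottom_level_clusters <- function(result,
                                  stop_criterion = result$stop_criterion) {
  stopifnot(inherits(result, "hac_result"))
  d <- result$dendrogram
  tops <- .top_nodes(result, stop_criterion)
  top_of <- integer(d$n_leaves)
  for (id in tops) top_of[d$members[[id]]] <- id
  bot <- vapply(seq_len(d$n_leaves), function(v) {
    node <- v
    while (node != top_of[v]) {
      p <- d$parent[node]
      if (p == 0L || !d$nodes$collapsed[p]) break
      node <- p
    }
    node
  }, 0L)
  unname(lapply(split(seq_len(d$n_leaves), bot), function(v) d$labels[v]))
}

## bottom node of each vertex over the whole forest: topmost collapsed
## ancestor (leaves count as collapsed); used for link prediction.
.bottom_at <- function(parent, collapsed, step, nv, s_cut) {
  vapply(seq_len(nv), function(v) {
    node <- v
    repeat {
      p <- parent[node]
      if (p == 0L || !collapsed[p] || !(step[p] < s_cut)) break
      node <- p
    }
    node
  }, 0L)
}

#' Clusters present at a given merge step
#'
#' @param dend a `hac_dendrogram`.
#' @param s step index; returns the partition after `s - 1` merges (so
#'   `s = 1` is the all-singletons start).
#' @return list of character vectors of vertex ids.
#' @export
clusters_at_step <- function(dend, s) {
  stopifnot(inherits(dend, "hac_dendrogram"))
  nd <- dend$nodes
  formed <- is.na(nd$step) | nd$step < s
  par_later <- dend$parent == 0L | !formed[pmax(dend$parent, 1L)]
  act <- which(formed & par_later)
  lapply(act, function(id) dend$labels[dend$members[[id]]])
}

#' Audited parameter count of a hierarchical model
#'
#' `K(K-1)/2` top-level block parameters plus one per node of the merge
#' forest (collapsed terminals count once; nodes absorbed by a collapse do
#' not count).
#'
#' @param dend a `hac_dendrogram`.
#' @return integer.
#' @export
n_parameters <- function(dend) {
  stopifnot(inherits(dend, "hac_dendrogram"))
  K <- length(dend$roots)
  K * (K - 1) / 2 + sum(!dend$nodes$pruned)
}

#' Two-level cluster assignment table
#'
#' @param result a `hac_result`.
#' @return data frame with columns `vertex`, `top_cluster`,
#'   `bottom_cluster`, sorted by vertex id; cluster ids are integers
#'   assigned in order of each cluster's smallest member id, and bottom
#'   ids refine top ids.
#' @export
assign_clusters <- function(result) {
  stopifnot(inherits(result, "hac_result"))
  label_of <- function(clusters) {
    ord <- order(vapply(clusters, min, ""))
    out <- character(0)
    for (rank in seq_along(ord)) {
      m <- clusters[[ord[rank]]]
      out[m] <- rank
    }
    out
  }
  top <- label_of(result$top_level)
  bot <- label_of(result$bottom_level)
  v <- sort(result$dendrogram$labels)
  data.frame(vertex = v, top_cluster = as.integer(top[v]),
             bottom_cluster = as.integer(bot[v]), row.names = NULL)
}
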