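#' Hold out a fraction of edges for cross-validation
#'
#' Removes a uniform random sample (without replacement) of
#' `round(fraction * |E|)` edges — at least one — to form a training
#' network; all vertices are kept, so vertices that drop below degree 2 in
#' training are retained.
#'
#' @param net a `hac_network`.
#' @param fraction fraction of observed edges to hold out, in (0, 1).
#' @param seed optional RNG seed for a deterministic split.
#' @return list with `training` (a `hac_network`) and `held_out`
#'   (two-column character matrix of removed edges).
#' @export
split_edges <- function(net, fraction, seed = NULL) {
  stopifnot(inherits(net, "hac_network"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  ne <- n_edges(net)
  if (ne < 1L) stop("network has no edges to split")
  n_held <- max(1L, as.integer(round(fraction * ne)))
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(ne, n_held)
  held <- net$edges[idx, , drop = FALSE]
  training <- hac_network(net$edges[-idx, , drop = FALSE],
                          vertices = net$vertices, layer = net$layer)
  list(training = training, held_out = held)
}

#' Sample holes (absent edges) uniformly
#'
#' Draws `n` distinct unordered vertex pairs that carry no edge in `net`,
#' uniformly at random.  In cross-validation the holes are always sampled
#' from the *original* network, so a held-out edge can never be drawn as a
#' negative test pair.
#'
#' @param net a `hac_network`.
#' @param n number of holes.
#' @param seed optional RNG seed.
#' @return two-column character matrix of vertex pairs.
#' @export
sample_holes <- function(net, n, seed = NULL) {
  stopifnot(inherits(net, "hac_network"), n >= 1)
  verts <- net$vertices
  nv <- length(verts)
  total <- nv * (nv - 1) / 2
  ne <- n_edges(net)
  if (n > total - ne)
    stop(sprintf("requested %d holes but only %d exist", n, total - ne))
  vidx <- seq_len(nv)
  names(vidx) <- verts
  ## rank of pair (i < j) in the row-major upper triangle
  pair_rank <- function(i, j) (i - 1) * nv - i * (i - 1) / 2 + (j - i)
  cums <- cumsum(nv - seq_len(nv - 1L))
  decode <- function(r) {
    i <- findInterval(r - 0.5, c(0, cums))
    j <- i + r - c(0, cums)[i]
    cbind(i, j)
  }
  e_rank <- sort(pair_rank(vidx[net$edges[, 1L]], vidx[net$edges[, 2L]]))
  if (!is.null(seed)) set.seed(seed)
  r <- sample.int(total - ne, n)        # ranks among holes only
  a <- r
  repeat {                              # shift past the edge ranks
    a2 <- r + findInterval(a, e_rank)
    if (identical(a2, a)) break
    a <- a2
  }
  ij <- decode(a)
  cbind(verts[ij[, 1L]], verts[ij[, 2L]])
}

#' Model-based link score of a vertex pair
#'
#' The estimated edge probability of an unobserved pair under a fitted
#' hierarchical model: the within-group density of the collapsed terminal
#' if both vertices share one, otherwise the crossing density `e_r / t_r`
#' of their lowest common ancestor in the guide tree, otherwise (different
#' roots) the top-level block density between the two roots.  Densities
#' are maximum-likelihood estimates from the training counts; with
#' `smooth = TRUE` the Laplace form `(e + 1) / (t + 2)` is used instead to
#' break the many exact-zero ties.
#'
#' @param result a `hac_result` fitted on the training network.
#' @param u,v distinct vertex ids present in the model.
#' @param layer layer name or index whose counts provide the density;
#'   mandatory for multi-layer fits.
#' @param smooth use Laplace-smoothed densities.
#' @return score in `[0, 1]`.
#' @export
pair_link_score <- function(result, u, v, layer = NULL, smooth = FALSE) {
  stopifnot(inherits(result, "hac_result"))
  d <- result$dendrogram
  l <- .resolve_layer(d$layers, layer)
  iu <- match(u, d$labels)
  iv <- match(v, d$labels)
  if (is.na(iu) || is.na(iv)) stop("unknown vertex: ", if (is.na(iu)) u else v)
  if (iu == iv) stop("u and v must differ")
  dens <- function(e, t) {
    if (smooth) (e + 1) / (t + 2)
    else if (t == 0) 0 else e / t
  }
  bu <- d$bottom[iu]; bv <- d$bottom[iv]
  if (bu == bv)
    return(dens(d$e_within[bu, l], choose(d$nodes$size[bu], 2)))
  anc_u <- .ancestors(d$parent, bu)
  anc_v <- .ancestors(d$parent, bv)
  common <- intersect(anc_u, anc_v)
  if (length(common)) {
    a <- common[1L]                      # lowest common ancestor
    return(dens(d$e_cross[a, l], d$t_cross[a]))
  }
  ru <- anc_u[length(anc_u)]; rv <- anc_v[length(anc_v)]
  ia <- match(ru, result$roots); ib <- match(rv, result$roots)
  e <- result$root_cross[ia, ib, l]
  tt <- as.numeric(d$nodes$size[ru]) * d$nodes$size[rv]
  dens(e, tt)
}

.ancestors <- function(parent, node) {
  out <- node
  while (parent[node] != 0L) {
    node <- parent[node]
    out <- c(out, node)
  }
  out
}

.resolve_layer <- function(layers, layer) {
  if (is.null(layer)) {
    if (length(layers) > 1L)
      stop("multi-layer model: specify the target layer")
    return(1L)
  }
  if (is.numeric(layer)) return(as.integer(layer))
  l <- match(layer, layers)
  if (is.na(l)) stop("unknown layer: ", layer)
  l
}

#' Score a set of test pairs
#'
#' @param result a fitted `hac_result`.
#' @param pairs two-column character matrix of vertex pairs.
#' @inheritParams pair_link_score
#' @return numeric vector of scores.
#' @export
link_scores <- function(result, pairs, layer = NULL, smooth = FALSE) {
  vapply(seq_len(nrow(pairs)), function(r)
    pair_link_score(result, pairs[r, 1L], pairs[r, 2L], layer, smooth), 0)
}

#' Precision/recall, F-score and AUC of ranked link predictions
#'
#' Test pairs are ranked by score (descending; ties broken by canonical
#' pair order for determinism).  Precision `TP/(TP+FP)` and recall
#' `TP/(TP+FN)` are computed at every prediction count; the F-score is the
#' maximum over cutoffs of their harmonic mean; the AUC is the rank
#' statistic `P(score_pos > score_neg)` using midranks, so exact ties do
#' not bias it.
#'
#' @param pred data frame with columns `u`, `v`, `score` and logical
#'   `label` (`TRUE` for held-out edges, `FALSE` for holes).
#' @return An object of class `hac_linkpred`: list with `ranked` (the
#'   reordered input), `curve` (per-cutoff precision/recall), `f_score`,
#'   `auc`, `n_pos`, `n_neg`.
#' @export
evaluate_predictions <- function(pred) {
  stopifnot(is.data.frame(pred),
            all(c("u", "v", "score", "label") %in% names(pred)))
  if (!nrow(pred)) stop("empty test set")
  n_pos <- sum(pred$label)
  n_neg <- sum(!pred$label)
  key <- paste(pmin(pred$u, pred$v), pmax(pred$u, pred$v))
  ord <- order(-pred$score, key)
  ranked <- pred[ord, , drop = FALSE]
  tp <- cumsum(ranked$label)
  k <- seq_len(nrow(ranked))
  precision <- tp / k
  recall <- if (n_pos > 0) tp / n_pos else rep(0, length(k))
  denom <- precision + recall
  f_all <- ifelse(denom > 0, 2 * precision * recall / denom, 0)
  auc <- if (n_pos > 0 && n_neg > 0) {
    rk <- rank(pred$score)               # midranks for ties
    (sum(rk[pred$label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else NA_real_
  structure(list(ranked = ranked,
                 curve = data.frame(n_pred = k, tp = tp,
                                    precision = precision, recall = recall),
                 f_score = max(f_all), auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "hac_linkpred")
}

#' @export
print.hac_linkpred <- function(x, ...) {
  cat(sprintf("<hac_linkpred> %d positives, %d negatives: F = %.3f, AUC = %.3f\n",
              x$n_pos, x$n_neg, x$f_score, x$auc))
  invisible(x)
}

#' Cross-validated link prediction
#'
#' Repeats the hold-out protocol: delete a fraction of the target layer's
#' edges, fit the clustering on the training data (jointly over all layers
#' for multi-layer input), score the held-out edges against an equal
#' number of holes sampled from the original target layer, and evaluate.
#' For multi-layer input the model is trained jointly but each target
#' layer is split and evaluated separately.
#'
#' @param net a `hac_network` or `hac_multinet`.
#' @param method merge-score method, see [run_hac()].
#' @param fraction hold-out fraction of observed edges (default 0.075, an
#'   85/15 test set once the equal number of holes is added).
#' @param replicates number of random splits.
#' @param seed master RNG seed; every split and hole sample derives from
#'   it.
#' @param target_layer layer name(s) to predict; default all layers.
#' @param smooth use Laplace-smoothed link scores.
#' @param collapse,stop_criterion passed to [run_hac()].
#' @return An object of class `hac_cv`: list with `replicates` (one row
#'   per replicate and target layer: `replicate`, `layer`, `f_score`,
#'   `auc`, `n_test`) and `summary` (mean and SD per layer).
#' @export
cross_validate <- function(net, method = "ml", fraction = 0.075,
                           replicates = 10, seed = 1, target_layer = NULL,
                           smooth = FALSE, collapse = TRUE,
                           stop_criterion = "first-drop") {
  mnet <- as_multinet(net)
  lnames <- names(mnet$layers)
  targets <- if (is.null(target_layer)) lnames else target_layer
  if (!all(targets %in% lnames)) stop("unknown target layer")
  set.seed(seed)
  seeds <- matrix(sample.int(2^31 - 2, 2L * replicates * length(targets)),
                  ncol = 2L)
  rows <- list()
  srow <- 0L
  for (rep_i in seq_len(replicates)) {
    for (tg in targets) {
      srow <- srow + 1L
      tnet <- mnet$layers[[tg]]
      sp <- split_edges(tnet, fraction, seed = seeds[srow, 1L])
      ## training must never contain a held-out edge
      train_keys <- paste(sp$training$edges[, 1L], sp$training$edges[, 2L])
      stopifnot(!any(paste(sp$held_out[, 1L], sp$held_out[, 2L]) %in% train_keys))
      layers <- mnet$layers
      layers[[tg]] <- sp$training
      fit <- run_hac(hac_multinet(layers), method = method,
                     collapse = collapse, stop_criterion = stop_criterion)
      holes <- sample_holes(tnet, nrow(sp$held_out), seed = seeds[srow, 2L])
      pairs <- rbind(sp$held_out, holes)
      lab <- rep(c(TRUE, FALSE), c(nrow(sp$held_out), nrow(holes)))
      lyr <- if (length(lnames) > 1L) tg else NULL
      sc <- link_scores(fit, pairs, layer = lyr, smooth = smooth)
      ev <- evaluate_predictions(data.frame(
        u = pairs[, 1L], v = pairs[, 2L], score = sc, label = lab))
      rows[[srow]] <- data.frame(replicate = rep_i, layer = tg,
                                 f_score = ev$f_score, auc = ev$auc,
                                 n_test = nrow(pairs))
    }
  }
  reps <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(reps, reps$layer), function(d)
    data.frame(layer = d$layer[1L], replicates = nrow(d),
               mean_f = mean(d$f_score), sd_f = stats::sd(d$f_score),
               mean_auc = mean(d$auc), sd_auc = stats::sd(d$auc))))
  rownames(smry) <- NULL
  structure(list(replicates = reps, summary = smry, method = method,
                 fraction = fraction), class = "hac_cv")
}

#' @export
print.hac_cv <- function(x, ...) {
  cat(sprintf("<hac_cv> HAC-%s, %.1f%% hold-out\n", toupper(x$method),
              100 * x$fraction))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
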