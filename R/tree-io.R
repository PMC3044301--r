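#' Write a merge forest to a JSON tree file
#'
#' Serializes a `hac_dendrogram` losslessly: per node its children (absent
#' for leaves), size, collapsed/pruned flags, merge-step index, the
#' recorded log lambda values, the governing counts (crossing `e`/`h`/`t`
#' for branching nodes, within-group counts for terminals) and, for
#' collapsed terminals, the member list.  [read_tree()] restores an
#' identical object.
#'
#' @param dend a `hac_dendrogram` (from a [run_hac()] result).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(dend, path) {
  stopifnot(inherits(dend, "hac_dendrogram"))
  nd <- dend$nodes
  nodes <- lapply(seq_len(nrow(nd)), function(id) {
    rec <- list(id = id, size = nd$size[id], collapsed = nd$collapsed[id],
                pruned = nd$pruned[id], step = nd$step[id],
                log_lambda_ml = nd$log_lambda_ml[id],
                log_lambda_bayes = nd$log_lambda_bayes[id],
                log_lambda_coherence = nd$log_lambda_coherence[id],
                log_lambda_collapse = nd$log_lambda_collapse[id])
    if (!is.na(nd$left[id]))
      rec$children <- c(nd$left[id], nd$right[id])
    terminal <- nd$collapsed[id] && !nd$pruned[id]
    if (terminal)
      rec$members <- dend$labels[dend$members[[id]]]
    if (!is.na(nd$left[id])) {
      rec$e_cross <- dend$e_cross[id, ]
      rec$t_cross <- dend$t_cross[id]
    }
    rec$e_within <- dend$e_within[id, ]
    rec
  })
  obj <- list(format = "hacnet-tree", version = 1L,
              labels = dend$labels, layers = dend$layers,
              roots = dend$roots, nodes = nodes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON tree file back into a dendrogram
#'
#' @param path a file written by [write_tree()].
#' @return a `hac_dendrogram`.
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "hacnet-tree"))
    stop(path, " is not a hacnet tree file")
  labels <- unlist(obj$labels)
  layers <- unlist(obj$layers)
  L <- length(layers)
  nv <- length(labels)
  nn <- length(obj$nodes)
  num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  int1 <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
  nd <- data.frame(
    id = seq_len(nn),
    left = vapply(obj$nodes, function(n)
      if (is.null(n$children)) NA_integer_ else as.integer(n$children[[1L]]), 0L),
    right = vapply(obj$nodes, function(n)
      if (is.null(n$children)) NA_integer_ else as.integer(n$children[[2L]]), 0L),
    size = vapply(obj$nodes, function(n) as.integer(n$size), 0L),
    collapsed = vapply(obj$nodes, function(n) isTRUE(n$collapsed), TRUE),
    pruned = vapply(obj$nodes, function(n) isTRUE(n$pruned), TRUE),
    step = vapply(obj$nodes, function(n) int1(n$step), 0L))
  nd$log_lambda_ml <- vapply(obj$nodes, function(n) num1(n$log_lambda_ml), 0)
  nd$log_lambda_bayes <- vapply(obj$nodes, function(n)
    num1(n$log_lambda_bayes), 0)
  nd$log_lambda_coherence <- vapply(obj$nodes, function(n)
    num1(n$log_lambda_coherence), 0)
  nd$log_lambda_collapse <- vapply(obj$nodes, function(n)
    num1(n$log_lambda_collapse), 0)
  e_cross <- matrix(NA_real_, nn, L)
  e_within <- matrix(0, nn, L)
  t_cross <- rep(NA_real_, nn)
  for (id in seq_len(nn)) {
    n <- obj$nodes[[id]]
    if (!is.null(n$e_cross)) {
      e_cross[id, ] <- vapply(n$e_cross, as.numeric, 0)
      t_cross[id] <- as.numeric(n$t_cross)
    }
    if (!is.null(n$e_within))
      e_within[id, ] <- vapply(n$e_within, as.numeric, 0)
  }
  vidx <- seq_len(nv)
  names(vidx) <- labels
  members <- vector("list", nn)
  parent <- integer(nn)
  for (id in seq_len(nn)) {
    if (is.na(nd$left[id])) {
      members[[id]] <- id              # leaf id equals vertex index
    } else {
      members[[id]] <- c(members[[nd$left[id]]], members[[nd$right[id]]])
      parent[nd$left[id]] <- parent[nd$right[id]] <- id
    }
  }
  structure(list(labels = labels, layers = layers, n_leaves = nv,
                 nodes = nd, members = members,
                 e_cross = e_cross, t_cross = t_cross, e_within = e_within,
                 parent = parent,
                 bottom = .bottom_at(parent, nd$collapsed, nd$step, nv, Inf),
                 roots = vapply(obj$roots, as.integer, 0L)),
            class = "hac_dendrogram")
}

#' @export
print.hac_dendrogram <- function(x, ...) {
  cat(sprintf(paste0("<hac_dendrogram> %d leaves, %d node(s), %d root(s), ",
                     "%d collapsed terminal(s), %d layer(s)\n"),
              x$n_leaves, sum(!x$nodes$pruned), length(x$roots),
              length(unique(x$bottom)), length(x$layers)))
  invisible(x)
}
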