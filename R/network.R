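#' Construct an undirected, unweighted network
#'
#' A network is a set of string vertex ids plus a set of unordered vertex
#' pairs.  Self loops and duplicate pairs (in either orientation) are
#' dropped on construction, so the object always satisfies the simple-graph
#' invariants.
#'
#' @param edges two-column character matrix or data frame of endpoints; may
#'   have zero rows.
#' @param vertices optional character vector of vertex ids to include even
#'   when isolated (endpoints of `edges` are always included).
#' @param layer edge-type label, default `"default"`.
#' @return An object of class `hac_network` with elements `vertices`
#'   (sorted), `edges` (canonicalized two-column character matrix with
#'   `edges[,1] < edges[,2]`, sorted rows) and `layer`.
#' @export
hac_network <- function(edges = NULL, vertices = NULL, layer = "default") {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), 0L, 2L)
  } else {
    if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
    if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L, byrow = TRUE)
    em <- matrix(as.character(edges[, 1:2]), ncol = 2L)
    em <- em[em[, 1L] != em[, 2L], , drop = FALSE]              # self loops
    a <- pmin(em[, 1L], em[, 2L])
    b <- pmax(em[, 1L], em[, 2L])
    keep <- !duplicated(paste(a, b, sep = "\r"))
    em <- cbind(a[keep], b[keep])
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }
  v <- sort(unique(c(as.character(vertices), as.vector(em))))
  structure(list(vertices = v, edges = em, layer = as.character(layer)[1L]),
            class = "hac_network")
}

#' @export
print.hac_network <- function(x, ...) {
  cat(sprintf("<hac_network> layer '%s': %d vertices, %d edges\n",
              x$layer, length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Number of vertices / edges of a network
#' @param net a `hac_network`
#' @return integer count.
#' @export
n_vertices <- function(net) length(net$vertices)

#' @rdname n_vertices
#' @export
n_edges <- function(net) nrow(net$edges)

#' Vertex degrees
#'
#' @param net a `hac_network`
#' @return named integer vector over all vertices (isolated vertices get 0).
#' @export
vertex_degrees <- function(net) {
  d <- integer(length(net$vertices))
  names(d) <- net$vertices
  if (nrow(net$edges)) {
    tb <- table(c(net$edges[, 1L], net$edges[, 2L]))
    d[names(tb)] <- as.integer(tb)
  }
  d
}

#' Bundle one network per edge type
#'
#' @param layers a list of `hac_network` objects; names default to each
#'   layer's `layer` label.
#' @return An object of class `hac_multinet`.
#' @export
hac_multinet <- function(layers) {
  if (inherits(layers, "hac_network")) layers <- list(layers)
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "hac_network")))
  if (is.null(names(layers)))
    names(layers) <- vapply(layers, `[[`, "", "layer")
  structure(list(layers = layers), class = "hac_multinet")
}

#' @export
print.hac_multinet <- function(x, ...) {
  cat(sprintf("<hac_multinet> %d layer(s)\n", length(x$layers)))
  for (l in x$layers) print(l)
  invisible(x)
}

#' Coerce to a multi-layer network
#' @param x a `hac_network` or `hac_multinet`.
#' @return a `hac_multinet`.
#' @export
as_multinet <- function(x) {
  if (inherits(x, "hac_multinet")) return(x)
  if (inherits(x, "hac_network")) return(hac_multinet(list(x)))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to hac_multinet")
}

#' Read a plain-text edge list
#'
#' Each non-comment line holds at least two whitespace- or tab-separated
#' vertex ids; an optional extra column carries an edge-type label used to
#' split the input into layers.  Lines starting with `#` and blank lines are
#' skipped; columns beyond the layer column are ignored.  Duplicate pairs
#' (either orientation) and self loops are dropped with a message.
#'
#' @param path path to the edge-list file.
#' @param layer_column 1-based column index of the edge-type label, or
#'   `NULL` (single layer named `"default"`).
#' @return a `hac_multinet`, one layer per distinct label.
#' @export
read_edge_list <- function(path, layer_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty edge list: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  need <- if (is.null(layer_column)) 2L else max(2L, layer_column)
  bad <- which(lengths(toks) < need)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected >= %d columns",
                 lineno[bad[1L]], path, need))
  a <- vapply(toks, `[[`, "", 1L)
  b <- vapply(toks, `[[`, "", 2L)
  lab <- if (is.null(layer_column)) rep("default", length(a))
         else vapply(toks, `[[`, "", layer_column)
  layers <- lapply(split(seq_along(a), lab), function(idx) {
    net <- hac_network(cbind(a[idx], b[idx]), layer = lab[idx[1L]])
    n_loop <- sum(a[idx] == b[idx])
    n_dup <- length(idx) - n_loop - nrow(net$edges)
    if (n_loop + n_dup > 0L)
      message(sprintf("layer '%s': dropped %d self loop(s), %d duplicate pair(s)",
                      lab[idx[1L]], n_loop, n_dup))
    net
  })
  hac_multinet(layers)
}

#' Iteratively remove low-degree vertices
#'
#' Repeatedly deletes every vertex of degree <= 1 (isolated or pendant) and
#' its incident edge until none remains; such vertices carry almost no
#' information for block-model clustering.  The result has minimum degree
#' >= 2 or is empty.  Applying the filter twice equals applying it once.
#'
#' @param net a `hac_network` or `hac_multinet` (filtered per layer).
#' @return filtered object of the same class.
#' @export
prune_low_degree <- function(net) {
  if (inherits(net, "hac_multinet"))
    return(hac_multinet(lapply(net$layers, prune_low_degree)))
  stopifnot(inherits(net, "hac_network"))
  repeat {
    deg <- vertex_degrees(net)
    drop <- names(deg)[deg <= 1L]
    if (!length(drop)) break
    keep_v <- setdiff(net$vertices, drop)
    e <- net$edges
    e <- e[e[, 1L] %in% keep_v & e[, 2L] %in% keep_v, , drop = FALSE]
    net <- hac_network(e, vertices = keep_v, layer = net$layer)
  }
  net
}

#' Restrict all layers to their common vertex set
#'
#' Joint multi-layer clustering assumes one shared vertex set; this drops
#' every vertex absent from any layer, together with its edges.  The
#' low-degree filter is *not* re-applied (that is the caller's decision).
#'
#' @param mnet a `hac_multinet`.
#' @return a `hac_multinet` whose layers all have the identical vertex set.
#' @export
intersect_layers <- function(mnet) {
  mnet <- as_multinet(mnet)
  common <- Reduce(intersect, lapply(mnet$layers, `[[`, "vertices"))
  if (!length(common)) stop("layers have an empty vertex intersection")
  hac_multinet(lapply(mnet$layers, function(l) {
    e <- l$edges
    e <- e[e[, 1L] %in% common & e[, 2L] %in% common, , drop = FALSE]
    hac_network(e, vertices = common, layer = l$layer)
  }))
}

#' Write a two-level cluster assignment as TSV
#'
#' @param assignment data frame with columns `vertex`, `top_cluster`,
#'   `bottom_cluster` (as produced by [assign_clusters()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(assignment, path) {
  stopifnot(is.data.frame(assignment),
            all(c("vertex", "top_cluster", "bottom_cluster") %in%
                  names(assignment)))
  if (any(grepl("\t", assignment$vertex)))
    stop("vertex ids must not contain tab characters")
  assignment <- assignment[order(assignment$vertex), , drop = FALSE]
  utils::write.table(assignment[, c("vertex", "top_cluster", "bottom_cluster")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network back out as a canonical edge list
#'
#' @param net a `hac_network` or `hac_multinet`.
#' @param path output path.
#' @param layer_column logical; write the layer label as a third column
#'   (forced for multi-layer input).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, layer_column = FALSE) {
  mnet <- as_multinet(net)
  multi <- length(mnet$layers) > 1L || layer_column
  rows <- do.call(rbind, lapply(mnet$layers, function(l) {
    if (!nrow(l$edges)) return(NULL)
    if (multi) cbind(l$edges, l$layer) else l$edges
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(rows))
    writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
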