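#' Sample a planted-partition network
#'
#' Every within-block vertex pair becomes an edge independently with
#' probability `p_in`, every between-block pair with probability `p_out`
#' (a Bernoulli stochastic block model).  `p_in > p_out` gives assortative
#' structure; `p_in < p_out` gives disassortative (bipartite-like)
#' structure, in which blocks are glued by shared neighbours rather than
#' internal edges.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in,p_out within- and between-block edge probabilities.
#' @param seed optional RNG seed.
#' @param layer layer label of the generated network.
#' @return list with `network` (a `hac_network` including isolated
#'   vertices) and `labels` (integer block labels named by vertex id).
#' @export
sample_planted <- function(block_sizes, p_in, p_out, seed = NULL,
                           layer = "default") {
  stopifnot(all(block_sizes >= 1), p_in >= 0, p_in <= 1,
            p_out >= 0, p_out <= 1)
  if (!is.null(seed)) set.seed(seed)
  nv <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  verts <- sprintf("v%0*d", nchar(as.character(nv)), seq_len(nv))
  pr <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
  p <- ifelse(lab[pr[, 1L]] == lab[pr[, 2L]], p_in, p_out)
  sel <- stats::runif(nrow(pr)) < p
  net <- hac_network(cbind(verts[pr[sel, 1L]], verts[pr[sel, 2L]]),
                     vertices = verts, layer = layer)
  names(lab) <- verts
  list(network = net, labels = lab)
}

#' Sample a hierarchical random graph
#'
#' Takes a dendrogram specification in which every internal node carries a
#' crossing probability and every terminal a within-group probability, and
#' draws each vertex pair as an independent Bernoulli edge with the
#' probability of its governing node (the terminal containing both
#' vertices, or their lowest common ancestor).
#'
#' @param tree recursive list: a terminal is
#'   `list(members = <character>, theta = p)`, an internal node is
#'   `list(left = <node>, right = <node>, theta = p)`.
#' @param seed optional RNG seed.
#' @param layer layer label.
#' @return a `hac_network` over the union of terminal members.
#' @export
sample_hrg <- function(tree, seed = NULL, layer = "default") {
  if (!is.null(seed)) set.seed(seed)
  sample_pairs <- function(a, b, theta) {
    if (!length(a) || !length(b)) return(NULL)
    pr <- expand.grid(a, b, stringsAsFactors = FALSE)
    pr[stats::runif(nrow(pr)) < theta, , drop = FALSE]
  }
  gen <- function(node) {
    th <- node$theta
    if (is.null(th) || th < 0 || th > 1)
      stop("every node needs a theta in [0, 1]")
    if (!is.null(node$members)) {
      m <- as.character(node$members)
      ed <- NULL
      if (length(m) >= 2L) {
        pr <- t(utils::combn(m, 2L))
        ed <- pr[stats::runif(nrow(pr)) < th, , drop = FALSE]
      }
      return(list(members = m, edges = ed))
    }
    l <- gen(node$left); r <- gen(node$right)
    if (length(intersect(l$members, r$members)))
      stop("terminal member sets must be disjoint")
    cross <- sample_pairs(l$members, r$members, th)
    list(members = c(l$members, r$members),
         edges = rbind(l$edges, r$edges,
                       if (!is.null(cross)) as.matrix(cross)))
  }
  g <- gen(tree)
  hac_network(g$edges, vertices = g$members, layer = layer)
}

#' Sample a multi-layer network over one planted block structure
#'
#' All layers share a single vertex set and block assignment; conditioned
#' on the blocks, layers are generated independently, so one layer can be
#' assortative and another disassortative over the same groups.
#'
#' @param block_sizes integer vector of block sizes (shared).
#' @param layer_specs named list; each element is `list(p_in =, p_out =)`.
#' @param seed optional RNG seed.
#' @return list with `multinet` (a `hac_multinet`) and `labels`.
#' @export
sample_multilayer <- function(block_sizes, layer_specs, seed = NULL) {
  stopifnot(is.list(layer_specs), length(layer_specs) >= 1L)
  if (is.null(names(layer_specs)))
    names(layer_specs) <- paste0("layer", seq_along(layer_specs))
  if (!is.null(seed)) set.seed(seed)
  labels <- NULL
  layers <- lapply(names(layer_specs), function(nm) {
    sp <- layer_specs[[nm]]
    g <- sample_planted(block_sizes, sp$p_in, sp$p_out, seed = NULL,
                        layer = nm)
    labels <<- g$labels
    g$network
  })
  names(layers) <- names(layer_specs)
  list(multinet = hac_multinet(layers), labels = labels)
}
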