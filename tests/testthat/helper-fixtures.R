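# Graph fixtures built in code; no files.

em <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

clique_edges <- function(vs) t(utils::combn(vs, 2))

# two 5-cliques a1..a5 and b1..b5 joined by the bridge a1-b1
two_cliques_bridge <- function(n = 5) {
  a <- sprintf("a%d", seq_len(n))
  b <- sprintf("b%d", seq_len(n))
  hac_network(rbind(clique_edges(a), clique_edges(b), c("a1", "b1")))
}

path_net <- function(vs) hac_network(cbind(vs[-length(vs)], vs[-1]))

# Erdos-Renyi G(n, p) over named vertices, isolated vertices kept
gnp <- function(n, p, seed, prefix = "v") {
  set.seed(seed)
  vs <- sprintf("%s%02d", prefix, seq_len(n))
  pr <- t(utils::combn(vs, 2))
  hac_network(pr[stats::runif(nrow(pr)) < p, , drop = FALSE], vertices = vs)
}

edge_key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
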