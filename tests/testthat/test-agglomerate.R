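test_that("singleton merge scores follow the mismatch formula", {
  ## u and v adjacent, both adjacent to w1, w2: identical outside
  ## neighbourhoods -> lambda-ML = 1
  net <- hac_network(em("u","v", "u","w1", "v","w1", "u","w2", "v","w2"))
  st <- cluster_state(net)
  iu <- match("u", st$vertices); iv <- match("v", st$vertices)
  expect_equal(merge_score_ml(st, iu, iv), 0)

  ## m outside vertices adjacent to exactly one of u, v -> m * ln(1/4)
  net2 <- hac_network(em("u","w1", "v","w2", "u","w3", "w1","w2", "w2","w3"))
  st2 <- cluster_state(net2)
  expect_equal(merge_score_ml(st2, match("u", st2$vertices),
                              match("v", st2$vertices)), 3 * log(1 / 4))
})

test_that("Bayesian merge score matches Beta arithmetic and the model ratio", {
  ## 2-vertex graph: no third cluster, empty product
  st <- cluster_state(hac_network(em("u","v")))
  expect_identical(merge_score_bayes(st, 1L, 2L), 0)

  ## u, v both adjacent to the same single outside vertex w:
  ## Beta(3,1) / Beta(2,1)^2 = 4/3 (the spec's printed 3/4 is an
  ## arithmetic slip; the full-model oracle agrees with 4/3)
  net <- hac_network(em("u","w", "v","w"))
  st2 <- cluster_state(net)
  iu <- match("u", st2$vertices); iv <- match("v", st2$vertices)
  got <- merge_score_bayes(st2, iu, iv)
  expect_equal(got, log(4 / 3))
  A <- adj_matrix(net)
  before <- lapply(net$vertices, o_leaf)
  after <- list(o_join(o_leaf("u"), o_leaf("v")), o_leaf("w"))
  expect_equal(got, o_forest_score(after, A, o_lbayes) -
                 o_forest_score(before, A, o_lbayes), tolerance = 1e-12)
})

test_that("collapse scores reproduce the printed ratios", {
  ## two singletons: always exactly 1, with or without the edge
  st <- cluster_state(hac_network(em("u","v")))
  expect_identical(collapse_score(st, 1L, 2L), 0)
  st0 <- cluster_state(hac_network(em("u","w", "v","w")))
  expect_identical(collapse_score(st0, match("u", st0$vertices),
                                  match("v", st0$vertices)), 0)

  ## two collapsed 3-cliques forming a 6-clique: lambda-C = 10
  six <- hac_network(clique_edges(sprintf("v%d", 1:6)))
  st6 <- cluster_state(six, list(sprintf("v%d", 1:3), sprintf("v%d", 4:6)))
  expect_equal(collapse_score(st6, 1L, 2L), log(10), tolerance = 1e-12)

  ## two 4-cliques with no crossing edges: keep structure
  two4 <- hac_network(rbind(clique_edges(sprintf("a%d", 1:4)),
                            clique_edges(sprintf("b%d", 1:4))))
  stq <- cluster_state(two4, list(sprintf("a%d", 1:4), sprintf("b%d", 1:4)))
  expect_lt(collapse_score(stq, 1L, 2L), 0)
})

test_that("candidate pairs need an edge or a shared neighbouring cluster", {
  pth <- path_net(c("a", "b", "c", "d"))
  st <- cluster_state(pth)
  cp <- candidate_pairs(st)
  key <- paste(st$vertices[cp$i], st$vertices[cp$j])
  expect_setequal(key, c("a b", "b c", "c d", "a c", "b d"))

  tri2 <- hac_network(rbind(clique_edges(c("a","b","c")),
                            clique_edges(c("x","y","z"))))
  st2 <- cluster_state(tri2)
  cp2 <- candidate_pairs(st2)
  side <- substr(st2$vertices, 1, 1) %in% c("a", "b", "c")
  expect_true(all(side[cp2$i] == side[cp2$j]))

  star <- hac_network(em("c","l1", "c","l2", "c","l3"))
  st3 <- cluster_state(star)
  expect_identical(nrow(candidate_pairs(st3)), 6L)  # all pairs of 4 vertices
})

test_that("a 6-clique collapses into a single terminal", {
  res <- run_hac(hac_network(clique_edges(sprintf("v%d", 1:6))))
  expect_length(res$roots, 1L)
  expect_true(res$dendrogram$nodes$collapsed[res$roots])
  expect_length(res$top_level, 1L)
  expect_length(res$bottom_level, 1L)
  expect_length(res$bottom_level[[1]], 6L)
  expect_true(all(res$merge_sequence$log_lambda_collapse >= 0))
})

test_that("disconnected components form a forest and never merge", {
  res <- run_hac(hac_network(rbind(clique_edges(c("a","b","c")),
                                   clique_edges(c("x","y","z")))))
  expect_length(res$roots, 2L)
  expect_length(res$top_level, 2L)
  expect_setequal(vapply(res$top_level, paste, "", collapse = ","),
                  c("a,b,c", "x,y,z"))
})

test_that("the two-clique fixture resolves two cliques at both levels", {
  res <- run_hac(two_cliques_bridge())
  expect_length(res$top_level, 2L)
  expect_setequal(vapply(res$top_level, function(x) paste(sort(x), collapse = ""), ""),
                  c("a1a2a3a4a5", "b1b2b3b4b5"))
  expect_length(res$bottom_level, 2L)

  ## the literal trajectory rules are degenerate here: the greedy order
  ## pulls the second bridge vertex in with lambda-B barely below 1 while
  ## the final merge has lambda-B = 1 exactly (the crossing term cancels),
  ## so first-drop cuts at three clusters
  expect_length(top_level_clusters(res, "first-drop"), 3L)
  ms <- res$merge_sequence
  expect_equal(ms$log_lambda_bayes[9], 0)
  expect_equal(ms$log_lambda_bayes[8], log(630 / 650), tolerance = 1e-9)
})

test_that("accepted ML merges telescope to the final tree likelihood", {
  nets <- list(gnp(10, 0.3, seed = 11), gnp(12, 0.5, seed = 12),
               two_cliques_bridge(), path_net(sprintf("p%d", 1:6)))
  for (net in nets) {
    for (coll in c(TRUE, FALSE)) {
      res <- run_hac(net, collapse = coll)
      ## the guide tree ignores collapse, so compare against the
      ## fully-branching tree's likelihood
      full <- run_hac(net, collapse = FALSE)
      expect_equal(sum(res$merge_sequence$log_lambda_ml),
                   full$log_likelihood, tolerance = 1e-9)
    }
  }
})

test_that("every candidate's ML score is non-positive along a run", {
  for (s in 1:4) {
    net <- gnp(9, 0.35, seed = 20 + s)
    res <- run_hac(net)
    expect_true(all(res$merge_sequence$log_lambda_ml <= 1e-9))
  }
})

test_that("recorded engine scores equal fresh state recomputation", {
  net <- gnp(12, 0.35, seed = 33)
  res <- run_hac(net)
  d <- res$dendrogram
  ms <- res$merge_sequence
  for (s in seq_len(nrow(ms))) {
    cl <- clusters_at_step(d, s)
    st <- cluster_state(net, cl)
    key <- vapply(cl, min, "")
    i <- match(min(d$labels[d$members[[ms$left[s]]]]), key)
    j <- match(min(d$labels[d$members[[ms$right[s]]]]), key)
    expect_equal(ms$log_lambda_ml[s], merge_score_ml(st, i, j),
                 tolerance = 1e-8)
    expect_equal(ms$log_lambda_bayes[s], merge_score_bayes(st, i, j),
                 tolerance = 1e-8)
  }
})

test_that("results are stable under order-preserving relabeling", {
  net <- two_cliques_bridge()
  relab <- function(x) chartr("ab", "cd", x)
  net2 <- hac_network(matrix(relab(net$edges), ncol = 2))
  r1 <- run_hac(net)
  r2 <- run_hac(net2)
  tops1 <- sort(vapply(r1$top_level, function(x) paste(sort(relab(x)), collapse = ","), ""))
  tops2 <- sort(vapply(r2$top_level, function(x) paste(sort(x), collapse = ","), ""))
  expect_identical(tops1, tops2)
})

test_that("cluster assignment tables are deterministic and consistent", {
  res <- run_hac(two_cliques_bridge())
  asg <- assign_clusters(res)
  expect_identical(asg$vertex, sort(res$dendrogram$labels))
  expect_identical(asg$top_cluster[asg$vertex == "a1"], 1L)
  expect_identical(asg$top_cluster[asg$vertex == "b1"], 2L)
  ## bottom refines top
  expect_true(all(tapply(asg$top_cluster, asg$bottom_cluster,
                         function(x) length(unique(x))) == 1L))

  single <- run_hac(hac_network(em("u","v")))
  asg1 <- assign_clusters(single)
  expect_identical(nrow(asg1), 2L)
  expect_identical(unique(asg1$top_cluster), 1L)

  forest <- run_hac(hac_network(rbind(clique_edges(c("a","b","c")),
                                      clique_edges(c("x","y","z")))))
  asgf <- assign_clusters(forest)
  expect_identical(length(unique(asgf$top_cluster)), 2L)
  expect_identical(length(unique(asgf$bottom_cluster)), 2L)
})

test_that("the audited parameter count is K(K-1)/2 + R", {
  res <- run_hac(hac_network(rbind(clique_edges(c("a","b","c")),
                                   clique_edges(c("x","y","z")))),
                 collapse = FALSE)
  ## two roots, each a binary tree over 3 leaves: R = 2 * (3 + 2) = 10
  expect_identical(n_parameters(res$dendrogram), 1 + 10)
  coll <- run_hac(hac_network(clique_edges(sprintf("v%d", 1:4))))
  ## fully collapsed 4-clique: a single terminal node survives
  expect_identical(n_parameters(coll$dendrogram), 0 + 1)
})

test_that("collapsed terminals span both density extremes", {
  ## a clique plus a shared-neighbour group: terminals with density 1
  ## (fully connected) and 0 (mutually unconnected vertices that share
  ## their interaction partners) coexist in one clustering
  ed <- rbind(clique_edges(sprintf("c%d", 1:4)),
              cbind(rep(c("h1", "h2"), each = 3), rep(c("u", "v", "w"), 2)),
              c("c1", "h1"))
  res <- run_hac(hac_network(ed))
  d <- res$dendrogram
  dens <- vapply(res$bottom_level, function(cl) {
    id <- unique(d$bottom[match(cl, d$labels)])
    tw <- choose(d$nodes$size[id], 2)
    if (tw == 0) NA_real_ else d$e_within[id, 1] / tw
  }, 0)
  expect_true(any(dens == 1, na.rm = TRUE))
  expect_true(any(dens == 0, na.rm = TRUE))
  expect_true(any(vapply(res$bottom_level, length, 0L) >= 3))
})

test_that("empty and degenerate inputs are rejected or trivial", {
  expect_error(run_hac(hac_network()), "empty")
  one <- run_hac(hac_network(vertices = "solo"))
  expect_length(one$top_level, 1L)
  expect_identical(nrow(one$merge_sequence), 0L)
})
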