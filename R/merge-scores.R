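#' Maximum-likelihood merge score (log lambda-ML)
#'
#' The log-likelihood ratio of the hierarchical model after versus before
#' merging top-level clusters `i` and `j`.  Only blocks to third clusters
#' `k` change: the pooled term on `(e_ik + e_jk, t_ik + t_jk)` replaces the
#' two separate terms; the `(i, j)` crossing term moves unchanged from the
#' top-level block into the new internal node and cancels.  The value is
#' always `<= 0` (pooling removes parameters) and is 0 exactly when `i` and
#' `j` have interchangeable connectivity to the rest of the network, so for
#' two singleton vertices with `m` mismatched outside neighbours the score
#' is `m * log(1/4)`.  Layers contribute additively.
#'
#' @param state a `hac_state` from [cluster_state()].
#' @param i,j distinct top-level cluster indices.
#' @return log lambda-ML (scalar).
#' @seealso [merge_score_bayes()], [collapse_score()], [run_hac()]
#' @export
merge_score_ml <- function(state, i, j) {
  .check_state_pair(state, i, j)
  ni <- state$sizes[i]; nj <- state$sizes[j]
  s <- 0
  for (k in seq_len(state$K)) {
    if (k == i || k == j) next
    s <- s + sum(.term_ml(state$e_cross[i, k, ], state$e_cross[j, k, ],
                          ni * state$sizes[k], nj * state$sizes[k]))
  }
  s
}

#' Fully Bayesian merge score (log lambda-B)
#'
#' Same structure as [merge_score_ml()] with the integrated Beta form in
#' place of the profile likelihood: each third-cluster block contributes
#' `ln Beta(e_ik+e_jk+1, h_ik+h_jk+1) - ln Beta(e_ik+1, h_ik+1) - ln
#' Beta(e_jk+1, h_jk+1)`.  No merge-multiplicity factor is applied.  Unlike
#' the ML score this can be positive (the integrated form rewards pooling
#' blocks of compatible density), which is what makes it usable as a
#' stopping criterion: agglomeration has gone far enough when the best
#' merge has `lambda-B < 1`.
#'
#' @inheritParams merge_score_ml
#' @return log lambda-B (scalar).
#' @export
merge_score_bayes <- function(state, i, j) {
  .check_state_pair(state, i, j)
  ni <- state$sizes[i]; nj <- state$sizes[j]
  s <- 0
  for (k in seq_len(state$K)) {
    if (k == i || k == j) next
    s <- s + sum(.term_bayes(state$e_cross[i, k, ], state$e_cross[j, k, ],
                             ni * state$sizes[k], nj * state$sizes[k]))
  }
  s
}

#' Bayesian collapse score (log lambda-C)
#'
#' Probability ratio between modelling the union of two groups as a single
#' homogeneous Bernoulli group versus keeping the three separate terms
#' (within `i`, within `j`, between), all in integrated Beta form:
#' `Beta(e_w+1, h_w+1) / [Beta(e_ii+1, h_ii+1) Beta(e_jj+1, h_jj+1)
#' Beta(e_ij+1, h_ij+1)]` with `e_w = e_ii + e_jj + e_ij`.  No
#' split-multiplicity factor is applied.  For two singleton clusters all
#' three denominator terms reproduce the numerator exactly, so lambda-C = 1
#' whatever the adjacency: pairs are always collapsed.
#'
#' @inheritParams merge_score_ml
#' @return log lambda-C (scalar); collapse is favoured when `>= 0`.
#' @export
collapse_score <- function(state, i, j) {
  .check_state_pair(state, i, j)
  sum(.term_collapse(state$e_within[i, ], state$e_within[j, ],
                     state$e_cross[i, j, ], state$sizes[i], state$sizes[j]))
}

#' Candidate merge pairs
#'
#' The merge loop only ever considers pairs of top-level clusters that are
#' directly connected by an edge or that share at least one neighbouring
#' cluster (in any layer); all other pairs have no pooled information and
#' are never merged.
#'
#' @param state a `hac_state`.
#' @return data frame with integer columns `i`, `j` (`i < j`), one row per
#'   candidate pair.
#' @export
candidate_pairs <- function(state) {
  stopifnot(inherits(state, "hac_state"))
  K <- state$K
  conn <- matrix(FALSE, K, K)
  if (K >= 2L) {
    any_e <- apply(state$e_cross, c(1, 2), function(x) any(x > 0))
    conn <- any_e
    ## shared neighbouring cluster
    for (k in seq_len(K)) {
      nb <- which(any_e[k, ])
      if (length(nb) >= 2L)
        for (a in seq_len(length(nb) - 1L)) for (b in seq(a + 1L, length(nb)))
          conn[nb[a], nb[b]] <- conn[nb[b], nb[a]] <- TRUE
    }
  }
  idx <- which(upper.tri(conn) & conn, arr.ind = TRUE)
  data.frame(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
}
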