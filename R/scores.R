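#' Edge density between two clusters
#'
#' `rho_e(i, j) = e_ij / (n_i n_j)`, the fraction of realized edges among
#' all pairs crossing between the clusters; the HAC-E merge score.  Layers
#' of a multi-layer state contribute additively.
#'
#' @inheritParams merge_score_ml
#' @return density in `[0, 1]` per layer, summed over layers.
#' @export
rho_e <- function(state, i, j) {
  .check_state_pair(state, i, j)
  tt <- state$sizes[i] * state$sizes[j]
  if (tt == 0) return(0)
  sum(state$e_cross[i, j, ] / tt)
}

#' Shared-neighbour density between two clusters
#'
#' The fraction of outside vertices adjacent to at least one member of
#' each cluster: `rho_s(i, j) = #{u not in i or j : u ~ i and u ~ j} /
#' (|V| - n_i - n_j)`, 0 when no outside vertex exists.  Together with
#' [rho_e()] this is the HAC-ES merge score `rho_e + rho_s`; shared
#' neighbours are what let density-blind methods still work on
#' disassortative structure.
#'
#' @inheritParams merge_score_ml
#' @return density in `[0, 1]` per layer, summed over layers.
#' @export
rho_s <- function(state, i, j) {
  .check_state_pair(state, i, j)
  mi <- state$members[[i]]
  mj <- state$members[[j]]
  outside <- state$nv - length(mi) - length(mj)
  if (outside == 0) return(0)
  inside <- logical(state$nv)
  inside[c(mi, mj)] <- TRUE
  s <- 0
  for (l in seq_len(state$L)) {
    adj <- state$adj[[l]]
    nb_i <- unique(unlist(adj[mi], use.names = FALSE))
    nb_j <- unique(unlist(adj[mj], use.names = FALSE))
    shared <- intersect(nb_i, nb_j)
    s <- s + sum(!inside[shared]) / outside
  }
  s
}

#' Modularity change of a merge
#'
#' The decomposed Newman modularity increment for merging clusters `i` and
#' `j`: `dQ = e_ij / E - D_i D_j / (2 E^2)` where `D_i` is the sum of
#' (full-network) degrees of the members of `i` and `E` the total edge
#' count.  Summing accepted increments reproduces the global modularity of
#' the resulting partition; the HAC-Q merge score.
#'
#' @inheritParams merge_score_ml
#' @return modularity change in `[-1, 1]` per layer, summed over layers.
#' @export
delta_q <- function(state, i, j) {
  .check_state_pair(state, i, j)
  if (any(state$E == 0)) stop("delta_q is undefined on an empty layer")
  sum(state$e_cross[i, j, ] / state$E -
        state$deg_sum[i, ] * state$deg_sum[j, ] / (2 * state$E^2))
}
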