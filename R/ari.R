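#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used here to score recovery of planted blocks.  1 means identical
#' partitions (up to label names), 0 is the expectation under independent
#' random partitions with the same margins.
#'
#' @param a,b label vectors; if both are named they are aligned by name,
#'   otherwise by position.
#' @return the adjusted Rand index (scalar).
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions cover different item sets")
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("partitions differ in length")
  n <- length(a)
  tab <- table(as.character(a), as.character(b))
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)      # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Convert a cluster list to a membership vector
#'
#' @param clusters list of character vectors (e.g. `top_level` from
#'   [run_hac()]).
#' @return integer membership vector named by vertex id.
#' @export
membership_vector <- function(clusters) {
  out <- integer(0)
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  out
}
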