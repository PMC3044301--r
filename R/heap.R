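## Internal binary max-heap with lazy invalidation, used by the merge loop.
## Entries carry the two cluster ids, their version stamps at score time and
## a canonical tie-break key; ordering is by score (descending) then key
## (ascending), which makes the merge sequence deterministic.

.heap_new <- function(cap = 256L) {
  h <- new.env(parent = emptyenv())
  h$score <- numeric(cap)
  h$i <- integer(cap)
  h$j <- integer(cap)
  h$vi <- integer(cap)
  h$vj <- integer(cap)
  h$gv <- integer(cap)
  h$key <- character(cap)
  h$n <- 0L
  h
}

## is entry a strictly worse than entry b?
.heap_lt <- function(h, a, b) {
  if (h$score[a] != h$score[b]) return(h$score[a] < h$score[b])
  h$key[a] > h$key[b]
}

.heap_swap <- function(h, a, b) {
  for (f in c("score", "i", "j", "vi", "vj", "gv", "key")) {
    tmp <- h[[f]][a]
    h[[f]][a] <- h[[f]][b]
    h[[f]][b] <- tmp
  }
}

.heap_push <- function(h, score, i, j, vi, vj, gv, key) {
  n <- h$n + 1L
  if (n > length(h$score)) {
    for (f in c("score", "i", "j", "vi", "vj", "gv"))
      h[[f]] <- c(h[[f]], h[[f]])
    h$key <- c(h$key, h$key)
  }
  h$score[n] <- score; h$i[n] <- i; h$j[n] <- j
  h$vi[n] <- vi; h$vj[n] <- vj; h$gv[n] <- gv; h$key[n] <- key
  h$n <- n
  while (n > 1L) {
    p <- n %/% 2L
    if (.heap_lt(h, p, n)) { .heap_swap(h, p, n); n <- p } else break
  }
  invisible(h)
}

.heap_pop <- function(h) {
  if (h$n == 0L) return(NULL)
  top <- list(score = h$score[1L], i = h$i[1L], j = h$j[1L],
              vi = h$vi[1L], vj = h$vj[1L], gv = h$gv[1L], key = h$key[1L])
  .heap_swap(h, 1L, h$n)
  h$n <- h$n - 1L
  k <- 1L
  repeat {
    l <- 2L * k; r <- l + 1L
    big <- k
    if (l <= h$n && .heap_lt(h, big, l)) big <- l
    if (r <= h$n && .heap_lt(h, big, r)) big <- r
    if (big == k) break
    .heap_swap(h, k, big)
    k <- big
  }
  top
}
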