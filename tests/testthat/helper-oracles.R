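# Independent oracles, written from the definitions, kept deliberately
# naive (loops, exhaustive enumeration) and separate from the implementation.

# NODF by literal pairwise enumeration.
nodf_oracle <- function(M) {
  score_pairs <- function(M) {
    f <- rowSums(M); total <- 0
    for (u in seq_len(nrow(M) - 1)) {
      for (v in (u + 1):nrow(M)) {
        if (f[u] > f[v]) total <- total + 100 * sum(M[u, ] & M[v, ]) / f[v]
      }
    }
    total
  }
  (score_pairs(M) + score_pairs(t(M))) /
    (choose(nrow(M), 2) + choose(ncol(M), 2))
}

# Decode a Pruefer sequence into tree edges; every labelled tree on n nodes
# corresponds to exactly one sequence, giving exhaustive spanning-tree
# enumeration for the minimax-edge oracle.
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 0L
  for (v in seq) {
    leaf <- which(degree == 1L)[1]
    k <- k + 1L
    edges[k, ] <- c(leaf, v)
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}
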