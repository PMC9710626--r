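# Independent oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and distribution functions)
# they are checking.

# One-sided overrepresentation p for a 2x2 table by explicit enumeration
# of the margin-fixed tables: p = sum over x >= a of
# C(K, x) C(N-K, n-x) / C(N, n), with K = a+b, n = a+c.
oracleFisherTail <- function(a, b, c, d) {
  N <- a + b + c + d
  if (N == 0) return(1)
  K <- a + b
  n <- a + c
  xs <- max(a, 0, K + n - N):min(K, n)
  xs <- xs[xs >= a]
  if (length(xs) == 0) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# Maximal cliques of size >= minSize by exhaustive 2^n subset search on
# an adjacency matrix (n <= ~14). Returns a canonical list of sorted
# name vectors, ordered by size then lexicographically.
oracleMaxCliques <- function(adj, minSize = 2L) {
  n <- nrow(adj)
  stopifnot(n <= 14L)
  nodes <- rownames(adj)
  isClique <- function(idx) {
    if (length(idx) < 2L) return(FALSE)
    all(adj[idx, idx][upper.tri(diag(length(idx)))] == 1)
  }
  out <- list()
  for (code in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < minSize) next
    if (!isClique(idx)) next
    # maximal iff no outside vertex is adjacent to all members
    outside <- setdiff(seq_len(n), idx)
    extendable <- any(vapply(outside, function(v)
      all(adj[v, idx] == 1), TRUE))
    if (!extendable) out[[length(out) + 1L]] <- sort(nodes[idx])
  }
  out[order(lengths(out), vapply(out, paste, "", collapse = "\r"))]
}

# quadratic brute-force count of SNPs covered by >= 1 half-open region
oracleCoveredCount <- function(snpChrom, snpPos0, regChrom, regStart0,
                               regEnd0) {
  covered <- vapply(seq_along(snpPos0), function(i) {
    any(regChrom == snpChrom[i] & regStart0 <= snpPos0[i] &
          snpPos0[i] < regEnd0)
  }, TRUE)
  sum(covered)
}

# Benjamini-Hochberg step-up from first principles
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

randomGraph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n, dimnames = list(sprintf("v%02d", 1:n),
                                          sprintf("v%02d", 1:n)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  adj
}

graphFromAdj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
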