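# Independent oracles used to validate the package's computations.
# Each is a direct, unoptimized restatement of the underlying definition
# and shares no code with the implementation it checks.

# Betweenness by explicit all-pairs shortest-path enumeration:
# Floyd-Warshall distances + path counting, then the pair-dependency
# definition summed over unordered pairs with endpoints excluded.
bruteBetweenness <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- matrix(0, n, n); diag(S) <- 1        # number of shortest paths
  S[adj == 1] <- 1
  D[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || i == k || j == k) next
    via <- D[i, k] + D[k, j]
    if (via < D[i, j]) { D[i, j] <- via; S[i, j] <- S[i, k] * S[k, j] }
    else if (via == D[i, j] && is.finite(via))
      S[i, j] <- S[i, j] + S[i, k] * S[k, j]
  }
  B <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (s == v || t == v || !is.finite(D[s, t])) next
    if (D[s, v] + D[v, t] == D[s, t])
      B[v] <- B[v] + S[s, v] * S[v, t] / S[s, t]
  }
  B
}

adjacencyOf <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# Fisher upper tail by enumerating every table with the observed margins
# and at least `a` study genes in the term, point masses from the printed
# factorial formula.
enumFisherTail <- function(a, b, c, d) {
  pt <- function(a2, b2, c2, d2) {
    n <- a2 + b2 + c2 + d2
    exp(lfactorial(a2 + b2) + lfactorial(c2 + d2) + lfactorial(a2 + c2) +
          lfactorial(b2 + d2) - lfactorial(n) - lfactorial(a2) -
          lfactorial(b2) - lfactorial(c2) - lfactorial(d2))
  }
  amax <- min(a + b, a + c)
  sum(vapply(a:amax, function(a2)
    pt(a2, a + b - a2, a + c - a2, d - a + a2), 0))
}

# Hypergeometric over-representation by exhaustive enumeration of every
# possible prediction set of size nPred out of M candidates (m of which
# are seeds): the exact fraction of sets containing >= nHit seeds.
enumHypergeom <- function(M, nPred, m, nHit) {
  sets <- combn(M, nPred)
  hits <- colSums(sets <= m)  # w.l.o.g. items 1..m are the seeds
  mean(hits >= nHit)
}

# Monte-Carlo estimate of P(U_(j) <= r_(j) for all j) for N iid uniforms,
# with its standard error.
mcOrderStatQ <- function(ratios, nDraws = 1e5) {
  N <- length(ratios)
  r <- sort(ratios)
  U <- matrix(runif(nDraws * N), ncol = N)
  Us <- if (N == 1) U else t(apply(U, 1, sort))
  ok <- rowSums(sweep(Us, 2, r, `<=`)) == N
  p <- mean(ok)
  list(p = p, se = sqrt(max(p * (1 - p), 1 / nDraws) / nDraws))
}

writeTempTSV <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
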