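# Independent oracles used across the suite. These re-derive expected values
# from first principles and deliberately share no code with the package
# internals they check.

# IUPAC base sets, hardcoded
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# exhaustive-window subsumption oracle: does some window of the longer
# pattern consist of position-wise subsets of the shorter pattern?
oracleOverlap <- function(p1, p2) {
  s1 <- strsplit(p1, "")[[1]]
  s2 <- strsplit(p2, "")[[1]]
  if (length(s1) < length(s2)) { tmp <- s1; s1 <- s2; s2 <- tmp }
  subsumedAt <- function(offset) {
    all(vapply(seq_along(s2), function(i) {
      all(ORACLE_IUPAC[[s1[offset + i]]] %in% ORACLE_IUPAC[[s2[i]]])
    }, logical(1)))
  }
  windows <- 0:(length(s1) - length(s2))
  eq <- length(s1) == length(s2)
  hit <- any(vapply(windows, subsumedAt, logical(1)))
  if (!hit && eq) {
    # equal lengths: other subset direction
    hit <- all(vapply(seq_along(s1), function(i) {
      all(ORACLE_IUPAC[[s2[i]]] %in% ORACLE_IUPAC[[s1[i]]])
    }, logical(1)))
  }
  hit
}

randomIupacPattern <- function(len, alphabet = names(ORACLE_IUPAC)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# closed-form combinatorial sum for the upper-tail hypergeometric
oracleHyperUpper <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# correlation-of-residuals oracle for the first-order partial correlation
oraclePartial <- function(x, y, z) {
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  cor(rx, ry)
}

# hand-coded dense MCL iteration, independent of the package implementation
oracleMcl <- function(A, inflation = 2, prune = 1e-5, tol = 1e-8,
                      maxIter = 100) {
  diag(A) <- 0
  loops <- apply(A, 2, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(maxIter)) {
    M2 <- (M %*% M)^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < prune] <- 0
    z <- colSums(M2) == 0
    if (any(z)) M2[cbind(which(z), which(z))] <- 1
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  supp <- (M > 0) | t(M > 0)
  g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# plain Rand index between two labelings of the same items
randIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sameA <- a[i] == a[j]
      sameB <- b[i] == b[j]
      if (sameA == sameB) agree <- agree + 1
    }
  }
  agree / choose(n, 2)
}

smallCommunity <- function(seed = 7L, nPhages = 10L, nBacteria = 10L,
                           nSamples = 20L) {
  simulateCommunity(
    CommunityConfig(nPhages = nPhages, nBacteria = nBacteria,
                    nSamples = nSamples),
    seed = seed)
}
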