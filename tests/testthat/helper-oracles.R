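# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately share no code with the package:
# neighbor sets are enumerated naively, Katz walks are counted by
# recursive extension, PPR is a direct linear solve, and the ranking
# metrics enumerate pairs / walk down the ranked list.

naiveNeighbors <- function(A, v) which(A[v, ] > 0)

naiveAA <- function(A, i, j) {
  common <- intersect(naiveNeighbors(A, i), naiveNeighbors(A, j))
  s <- 0
  for (u in common) {
    du <- length(naiveNeighbors(A, u))
    if (du > 1) s <- s + 1 / log(du)
  }
  s
}

naiveRA <- function(A, i, j) {
  common <- intersect(naiveNeighbors(A, i), naiveNeighbors(A, j))
  s <- 0
  for (u in common) s <- s + 1 / length(naiveNeighbors(A, u))
  s
}

naivePA <- function(A, i, j) {
  length(naiveNeighbors(A, i)) * length(naiveNeighbors(A, j))
}

# count walks of every length 1..maxLen from i to j by recursive extension
naiveWalkCounts <- function(A, i, j, maxLen) {
  counts <- numeric(maxLen)
  recurse <- function(v, len) {
    if (len > maxLen) return()
    for (u in naiveNeighbors(A, v)) {
      if (u == j) counts[len] <<- counts[len] + 1
      recurse(u, len + 1)
    }
  }
  recurse(i, 1)
  counts
}

naiveKatz <- function(A, i, j, beta, maxLen) {
  counts <- naiveWalkCounts(A, i, j, maxLen)
  sum(beta^seq_len(maxLen) * counts)
}

# direct solve of p = omega (Acs p + dangling-to-source) + (1-omega) e_s
solvePPR <- function(A, source, omega) {
  A <- as.matrix(A)
  N <- nrow(A)
  deg <- colSums(A)
  Acs <- sweep(A, 2, pmax(deg, 1), "/")
  Acs[, deg == 0] <- 0
  M <- Acs
  M[source, deg == 0] <- M[source, deg == 0] + 1
  e <- numeric(N); e[source] <- 1
  solve(diag(N) - omega * M, (1 - omega) * e)
}

naiveAUROC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# ranked-list step summation: walk down the unique thresholds, accumulate
# precision times the recall increment
naiveAUPR <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  area <- 0; prevRecall <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / P
    area <- area + (rec - prevRecall) * prec
    prevRecall <- rec
  }
  area
}

# Erdos-Renyi adjacency, symmetric, no self loops
randomAdjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(runif(sum(up)) < p)
  A + t(A)
}
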