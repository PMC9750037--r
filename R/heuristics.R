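# Closed-form link-prediction indices computed on the combined
# heterogeneous graph: the undirected, unweighted union of the bipartite
# association edges and the (binarized) drug-drug similarity edges. On a
# pure bipartite graph a drug and a side effect can never share a common
# neighbor, so the similarity edges are what gives Adamic-Adar and
# resource allocation nonzero drug/effect scores.

#' Combined adjacency matrix for the heuristic indices
#'
#' Binary symmetric (m+n) x (m+n) adjacency: bipartite links (drugs 1..m,
#' effects m+1..m+n) plus similarity edges with weight at or above
#' \code{simThreshold}. No self-loops.
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @param pairs bipartite links to include (default: all positives; pass a
#'   training set to avoid test leakage).
#' @param simThreshold minimum similarity binarized into an edge;
#'   \code{NULL} (default) keeps every stored positive similarity.
#' @return sparse pattern-symmetric \code{dgCMatrix} with node names.
#' @export
heteroAdjacency <- function(graph, pairs = positivePairs(graph),
                            simThreshold = NULL) {
  m <- nDrugs(graph); n <- nEffects(graph)
  N <- m + n
  S <- as(graph@similarity, "TsparseMatrix")
  keep <- S@i != S@j & S@x > 0
  if (!is.null(simThreshold)) keep <- keep & S@x >= simThreshold
  i <- c(pairs[, 1L], m + pairs[, 2L], S@i[keep] + 1L)
  j <- c(m + pairs[, 2L], pairs[, 1L], S@j[keep] + 1L)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(N, N),
                            use.last.ij = TRUE)
  dimnames(A) <- list(c(drugNames(graph), effectNames(graph)),
                      c(drugNames(graph), effectNames(graph)))
  A
}

resolveNode <- function(A, node) {
  if (is.character(node)) {
    idx <- match(node, rownames(A))
    if (is.na(idx)) stop("unknown node '", node, "'")
    idx
  } else {
    if (node < 1L || node > nrow(A)) stop("node index out of range: ", node)
    as.integer(node)
  }
}

commonNeighbors <- function(A, i, j) {
  which(A[i, ] > 0 & A[j, ] > 0)
}

#' Adamic-Adar index
#'
#' Sum over common neighbors u of 1 / log |N(u)| (natural log). A common
#' neighbor necessarily has degree >= 2, so the logarithm is positive.
#'
#' @param A adjacency from [heteroAdjacency()] (any binary symmetric
#'   matrix works).
#' @param i,j node indices or names.
#' @return numeric score.
#' @export
adamicAdar <- function(A, i, j) {
  i <- resolveNode(A, i); j <- resolveNode(A, j)
  u <- commonNeighbors(A, i, j)
  deg <- Matrix::colSums(A > 0)[u]
  sum(ifelse(deg > 1, 1 / log(deg), 0))
}

#' Resource-allocation index
#'
#' Sum over common neighbors u of 1 / |N(u)|.
#'
#' @inheritParams adamicAdar
#' @export
resourceAllocation <- function(A, i, j) {
  i <- resolveNode(A, i); j <- resolveNode(A, j)
  u <- commonNeighbors(A, i, j)
  sum(1 / Matrix::colSums(A > 0)[u])
}

#' Preferential-attachment index
#'
#' Product of the endpoint degrees |N(i)| * |N(j)|.
#'
#' @inheritParams adamicAdar
#' @export
preferentialAttachment <- function(A, i, j) {
  i <- resolveNode(A, i); j <- resolveNode(A, j)
  deg <- Matrix::colSums(A > 0)
  unname(deg[i] * deg[j])
}

#' Katz index
#'
#' Attenuated walk count sum_l beta^l (A^l)_{ij}, either truncated at
#' \code{maxLen} or in closed form (I - beta A)^{-1} - I. The closed form
#' requires beta < 1 / lambda_max(A), checked numerically.
#'
#' @param A adjacency matrix.
#' @param beta attenuation factor > 0 (default 0.005, favoring short
#'   paths).
#' @param maxLen truncation length for the walk sum (default 5).
#' @param closedForm use the matrix-inverse form instead of truncation.
#' @return full score matrix (extract \code{[i, j]} for a pair).
#' @export
katzMatrix <- function(A, beta = 0.005, maxLen = 5L, closedForm = FALSE) {
  if (beta <= 0) stop("beta must be positive")
  Ad <- as.matrix(A)
  if (closedForm) {
    lmax <- max(abs(eigen(Ad, only.values = TRUE)$values))
    if (beta >= 1 / lmax)
      stop("Katz series diverges: beta >= 1/lambda_max = ",
           signif(1 / lmax, 6))
    K <- solve(diag(nrow(Ad)) - beta * Ad) - diag(nrow(Ad))
  } else {
    K <- matrix(0, nrow(Ad), ncol(Ad))
    P <- diag(nrow(Ad))
    for (l in seq_len(maxLen)) {
      P <- P %*% Ad
      K <- K + beta^l * P
    }
  }
  dimnames(K) <- dimnames(A)
  K
}

#' @rdname katzMatrix
#' @param i,j node indices or names.
#' @export
katz <- function(A, i, j, beta = 0.005, maxLen = 5L, closedForm = FALSE) {
  i <- resolveNode(A, i); j <- resolveNode(A, j)
  katzMatrix(A, beta = beta, maxLen = maxLen, closedForm = closedForm)[i, j]
}

#' Personalized PageRank
#'
#' Power iteration on p = omega * A_cs p + (1 - omega) e_source with
#' column-stochastic A_cs; mass reaching a dangling node is returned to the
#' source. The converged vector sums to one; entry v is the pair score
#' (source, v).
#'
#' @param A adjacency matrix.
#' @param source source node index or name.
#' @param omega walk-continuation probability in (0, 1), default 0.85.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param maxIter iteration cap (default 1000).
#' @return named probability vector over all nodes.
#' @export
personalizedPageRank <- function(A, source, omega = 0.85, tol = 1e-10,
                                 maxIter = 1000L) {
  if (omega <= 0 || omega >= 1) stop("omega must lie strictly in (0, 1)")
  source <- resolveNode(A, source)
  N <- nrow(A)
  deg <- Matrix::colSums(A)
  Acs <- A %*% Matrix::Diagonal(N, x = ifelse(deg > 0, 1 / deg, 0))
  e <- numeric(N); e[source] <- 1
  p <- e
  for (it in seq_len(maxIter)) {
    walk <- as.numeric(Acs %*% p)
    dangling <- sum(p[deg == 0])
    walk[source] <- walk[source] + dangling
    pNew <- omega * walk + (1 - omega) * e
    if (sum(abs(pNew - p)) < tol) {
      names(pNew) <- rownames(A)
      return(pNew)
    }
    p <- pNew
  }
  stop("personalized PageRank did not converge in ", maxIter,
       " iterations (residual ", signif(sum(abs(pNew - p)), 3), ")")
}

#' Score candidate pairs with a heuristic index
#'
#' Vectorized scoring of drug/side-effect candidate pairs on the combined
#' heterogeneous adjacency. Raw scores are min-max normalized to [0, 1]
#' for threshold metrics (a constant score vector maps to 0.5); the raw
#' order is preserved for AUROC/AUPR.
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @param method one of \code{"aa"}, \code{"ra"}, \code{"pa"},
#'   \code{"katz"}, \code{"ppr"}.
#' @param pairs two-column (drug index, effect index) matrix.
#' @param trainPairs bipartite edges visible to the index (default: all
#'   positives).
#' @param beta,maxLen Katz parameters.
#' @param omega PPR continuation probability.
#' @param simThreshold binarization threshold for similarity edges.
#' @return data.frame with \code{raw} and \code{prob} columns, one row per
#'   candidate pair.
#' @export
scoreAllPairs <- function(graph, method = c("aa", "ra", "pa", "katz", "ppr"),
                          pairs, trainPairs = positivePairs(graph),
                          beta = 0.005, maxLen = 5L, omega = 0.85,
                          simThreshold = NULL) {
  method <- match.arg(method)
  if (nrow(pairs) == 0L)
    return(data.frame(raw = numeric(), prob = numeric()))
  A <- heteroAdjacency(graph, pairs = trainPairs, simThreshold = simThreshold)
  m <- nDrugs(graph)
  iIdx <- pairs[, 1L]
  jIdx <- m + pairs[, 2L]
  deg <- Matrix::colSums(A > 0)
  raw <- switch(method,
    aa = {
      wgt <- ifelse(deg > 1, 1 / log(deg), 0)
      Sm <- A %*% Matrix::Diagonal(length(deg), x = wgt) %*% A
      as.numeric(Sm[cbind(iIdx, jIdx)])
    },
    ra = {
      wgt <- ifelse(deg > 0, 1 / deg, 0)
      Sm <- A %*% Matrix::Diagonal(length(deg), x = wgt) %*% A
      as.numeric(Sm[cbind(iIdx, jIdx)])
    },
    pa = deg[iIdx] * deg[jIdx],
    katz = {
      K <- katzMatrix(A, beta = beta, maxLen = maxLen)
      K[cbind(iIdx, jIdx)]
    },
    ppr = {
      out <- numeric(nrow(pairs))
      for (s in unique(iIdx)) {
        sel <- iIdx == s
        p <- personalizedPageRank(A, s, omega = omega)
        out[sel] <- p[jIdx[sel]]
      }
      out
    })
  raw <- unname(as.numeric(raw))
  rng <- range(raw)
  prob <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
          else rep(0.5, length(raw))
  data.frame(raw = raw, prob = prob)
}
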