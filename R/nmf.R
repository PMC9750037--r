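# Matrix-completion baselines: non-negative matrix factorization of the
# drug-by-effect association matrix, optionally preceded by heat diffusion
# of that matrix along the drug-drug similarity graph.

#' Association matrix of a graph or split
#'
#' Dense m x n 0/1 matrix of the given positive links (defaults to all of
#' the graph's positives).
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @param pairs two-column (drug, effect) index matrix.
#' @return base matrix, drugs in rows.
#' @export
associationMatrix <- function(graph, pairs = positivePairs(graph)) {
  V <- matrix(0, nDrugs(graph), nEffects(graph),
              dimnames = list(drugNames(graph), effectNames(graph)))
  if (nrow(pairs)) V[pairs] <- 1
  V
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the squared Frobenius error ||V - W H||_F^2 with the classic
#' multiplicative update rules, which keep W and H entrywise non-negative
#' and make the objective non-increasing at every iteration. Factors are
#' initialized uniform-random under \code{seed}.
#'
#' @param V non-negative m x n matrix.
#' @param rank factorization rank (default 64, capped at min(m, n) must not
#'   be exceeded).
#' @param iters maximum iterations (default 500).
#' @param tol stop when the relative objective change drops below this
#'   (default 1e-6).
#' @param seed RNG seed for the initialization.
#' @return list of class \code{nmfFactors}: W (m x rank), H (rank x n),
#'   rank, and \code{trace}, the Frobenius objective after each update.
#' @export
nmfFactorize <- function(V, rank = 64L, iters = 500L, tol = 1e-6, seed = 1L) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be entrywise non-negative")
  m <- nrow(V); n <- ncol(V)
  if (rank < 1L || rank > min(m, n))
    stop("rank must lie in [1, min(m, n)] = [1, ", min(m, n), "]")
  eps <- 1e-12
  init <- withSeed(seed, list(W = matrix(runif(m * rank), m, rank),
                              H = matrix(runif(rank * n), rank, n)))
  W <- init$W; H <- init$H
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(iters)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    obj <- norm(V - W %*% H, "F")
    trace <- c(trace, obj)
    if (is.finite(prev) && prev > 0 && abs(prev - obj) / prev < tol) break
    prev <- obj
  }
  structure(list(W = W, H = H, rank = as.integer(rank), trace = trace),
            class = "nmfFactors")
}

#' Link scores from NMF factors
#'
#' The reconstructed cell (W H)_{p,q} is the link score. Raw scores are kept
#' for ranking; the probability column clips them to [0, 1].
#'
#' @param factors result of [nmfFactorize()].
#' @param pairs optional two-column (drug, effect) index matrix; when
#'   \code{NULL} the full reconstructed matrix is returned.
#' @return for pairs, a data.frame with \code{raw} and \code{prob} columns;
#'   otherwise the m x n reconstruction.
#' @export
nmfScores <- function(factors, pairs = NULL) {
  R <- factors$W %*% factors$H
  if (is.null(pairs)) return(R)
  raw <- R[pairs]
  data.frame(raw = raw, prob = pmin(pmax(raw, 0), 1))
}

#' Heat-diffusion matrix of the drug-similarity graph
#'
#' Builds the generator D with, for an edge (i, j), \code{D[i,j] =
#' s[j,i]/deg(j)} and diagonal \code{D[i,i] = -(tau[i]/deg(i)) * sum_k
#' s[i,k]}, zero elsewhere; tau in [0, 1] is the per-node outflow flag.
#' With tau = 1 and a symmetric similarity every column sums to zero, so
#' diffusion conserves total mass. Isolated drugs (no similarity edge) get
#' a zero row and column.
#'
#' @param similarity symmetric m x m matrix of weights in [0, 1] (diagonal
#'   ignored).
#' @param tau scalar or length-m vector of outflow flags (default 1).
#' @param weightedDegree if \code{TRUE} use the similarity-weighted degree
#'   instead of the unweighted neighbor count.
#' @return list of class \code{diffusionMatrix}: \code{D} (m x m),
#'   \code{tau}, \code{deg}.
#' @export
diffusionMatrix <- function(similarity, tau = 1, weightedDegree = FALSE) {
  S <- as.matrix(similarity)
  m <- nrow(S)
  if (ncol(S) != m) stop("similarity matrix must be square")
  if (max(abs(S - t(S))) > 1e-8)
    stop("similarity matrix is asymmetric beyond tolerance")
  diag(S) <- 0
  if (any(S < 0) || any(S > 1)) stop("similarity entries must lie in [0, 1]")
  tau <- rep_len(tau, m)
  if (any(tau < 0) || any(tau > 1)) stop("tau must lie in [0, 1]")
  deg <- if (weightedDegree) rowSums(S) else rowSums(S > 0)
  D <- sweep(S, 2L, pmax(deg, 1), "/")       # D[i,j] = s[i,j]/deg(j), sym s
  D[, deg == 0] <- 0
  diag(D) <- ifelse(deg > 0, -(tau / pmax(deg, 1)) * rowSums(S), 0)
  structure(list(D = D, tau = tau, deg = deg), class = "diffusionMatrix")
}

#' Propagate heat along the similarity graph
#'
#' Computes exp(alphaT * D) f0 (matrix exponential); alphaT = 0 returns the
#' input unchanged. Only the product of conductivity and time matters, so a
#' single parameter alphaT is exposed. Tiny negative entries produced by
#' the exponential of the (entrywise non-negative) propagator are clipped
#' at zero.
#'
#' @param f0 length-m vector or m x n matrix (drugs in rows).
#' @param D a \code{diffusionMatrix} (or plain m x m generator matrix).
#' @param alphaT non-negative diffusion extent.
#' @return same shape as \code{f0}.
#' @export
heatPropagate <- function(f0, D, alphaT) {
  if (alphaT < 0) stop("alphaT must be non-negative")
  Dm <- if (inherits(D, "diffusionMatrix")) D$D else as.matrix(D)
  vec <- is.null(dim(f0))
  F0 <- if (vec) matrix(f0, ncol = 1L) else as.matrix(f0)
  if (nrow(F0) != nrow(Dm)) stop("shape mismatch: f0 has ", nrow(F0),
                                 " rows but D is ", nrow(Dm), " x ", ncol(Dm))
  if (alphaT == 0) return(f0)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(alphaT * Dm)))
  out <- pmax(P %*% F0, 0)
  if (vec) as.numeric(out) else out
}

#' NMF with heat diffusion (NMFHD) link scores
#'
#' Diffuses the 0/1 association matrix down the drug dimension with
#' exp(alphaT * D), then factorizes the diffused matrix and scores links
#' from the reconstruction. \code{order = "post"} instead factorizes first
#' and diffuses the reconstructed score matrix, kept for comparison. With
#' alphaT = 0 (or an empty similarity graph) the result is identical to
#' plain NMF under the same seed.
#'
#' @param V non-negative m x n association matrix.
#' @param similarity symmetric m x m drug-similarity matrix.
#' @param rank,iters,tol,seed passed to [nmfFactorize()].
#' @param alphaT diffusion extent (default 1).
#' @param tau outflow flags, see [diffusionMatrix()].
#' @param pairs optional (drug, effect) pairs to score; \code{NULL} returns
#'   the full score matrix.
#' @param order \code{"pre"} (diffuse then factorize, default) or
#'   \code{"post"}.
#' @return as [nmfScores()].
#' @export
nmfhdScores <- function(V, similarity, rank = 64L, alphaT = 1, tau = 1,
                        iters = 500L, tol = 1e-6, seed = 1L, pairs = NULL,
                        order = c("pre", "post")) {
  order <- match.arg(order)
  V <- as.matrix(V)
  D <- diffusionMatrix(similarity, tau = tau)
  if (order == "pre") {
    Vd <- heatPropagate(V, D, alphaT)
    factors <- nmfFactorize(Vd, rank = rank, iters = iters, tol = tol,
                            seed = seed)
    nmfScores(factors, pairs)
  } else {
    factors <- nmfFactorize(V, rank = rank, iters = iters, tol = tol,
                            seed = seed)
    R <- heatPropagate(nmfScores(factors), D, alphaT)
    if (is.null(pairs)) return(R)
    raw <- R[pairs]
    data.frame(raw = raw, prob = pmin(pmax(raw, 0), 1))
  }
}
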