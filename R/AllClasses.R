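#' Heterogeneous drug/side-effect graph
#'
#' Bipartite drug-to-side-effect association network plus a symmetric
#' weighted drug-drug similarity matrix. Drugs are indexed 1..m and side
#' effects 1..n in the order of \code{drugNames()} / \code{effectNames()};
#' positive links are stored as a two-column integer matrix of (drug index,
#' effect index). Similarity entries below \code{simThreshold} are zeroed at
#' construction time, so every stored nonzero is an edge of the similarity
#' layer.
#'
#' @slot drugNames character vector, one name per drug node.
#' @slot effectNames character vector, one name per side-effect node.
#' @slot positivePairs two-column integer matrix (drug, effect), one row per
#'   observed association.
#' @slot similarity sparse symmetric m-by-m \linkS4class{dgCMatrix} of
#'   cosine-similarity weights in [0, 1], zero diagonal.
#' @slot simThreshold numeric scalar; entries strictly below it were dropped.
#'
#' @seealso [buildHeteroGraph()], [readAssociations()], [readSimilarity()]
#' @export
setClass("HeteroGraph",
  representation(
    drugNames = "character",
    effectNames = "character",
    positivePairs = "matrix",
    similarity = "Matrix",
    simThreshold = "numeric"
  )
)

setValidity("HeteroGraph", function(object) {
  m <- length(object@drugNames)
  n <- length(object@effectNames)
  pp <- object@positivePairs
  msgs <- character()
  if (m < 1L) msgs <- c(msgs, "graph has zero drugs")
  if (n < 1L) msgs <- c(msgs, "graph has zero side effects")
  if (ncol(pp) != 2L) msgs <- c(msgs, "positivePairs must have two columns")
  if (nrow(pp) > 0) {
    if (min(pp[, 1L]) < 1L || max(pp[, 1L]) > m)
      msgs <- c(msgs, "drug index out of range in positivePairs")
    if (min(pp[, 2L]) < 1L || max(pp[, 2L]) > n)
      msgs <- c(msgs, "effect index out of range in positivePairs")
  }
  S <- object@similarity
  if (nrow(S) != m || ncol(S) != m)
    msgs <- c(msgs, "similarity matrix must be m x m")
  else {
    x <- S@x
    if (length(x) && (min(x) < -1e-12 || max(x) > 1 + 1e-12))
      msgs <- c(msgs, "similarity entries must lie in [0, 1]")
    asym <- max(abs(S - Matrix::t(S)))
    if (asym > 1e-12)
      msgs <- c(msgs, sprintf("similarity matrix asymmetric (max dev %.3g)", asym))
  }
  if (length(msgs)) msgs else TRUE
})

#' One fold of a link-prediction evaluation split
#'
#' Holds the train/test partition of positive links and the sampled negative
#' links for one cross-validation fold. All four sets are two-column integer
#' matrices of (drug index, effect index); the positive sets are disjoint,
#' the negative sets are disjoint from each other and from every positive
#' link of the parent graph.
#'
#' @slot trainPos,testPos,trainNeg,testNeg two-column integer matrices.
#' @slot foldId integer fold number (1-based).
#' @slot seed integer seed that produced the fold's negative sample.
#' @export
setClass("EvalSplit",
  representation(
    trainPos = "matrix", testPos = "matrix",
    trainNeg = "matrix", testNeg = "matrix",
    foldId = "integer", seed = "integer"
  )
)

setValidity("EvalSplit", function(object) {
  key <- function(mat) paste(mat[, 1L], mat[, 2L])
  msgs <- character()
  if (length(intersect(key(object@trainPos), key(object@testPos))))
    msgs <- c(msgs, "train and test positives overlap")
  if (length(intersect(key(object@trainNeg), key(object@testNeg))))
    msgs <- c(msgs, "train and test negatives overlap")
  if (length(msgs)) msgs else TRUE
})

#' Trained GCN link-prediction model
#'
#' Container for the graph-convolutional encoder and link scorer: free node
#' embeddings h0 for all m+n nodes, one (W, B, bias) triple per aggregation
#' layer, the scorer parameters, the configuration that produced them, and
#' the bipartite edges used for message passing (training positives only, so
#' held-out links never leak into the encoder).
#'
#' @slot params list of numeric arrays: \code{E} (node embeddings),
#'   \code{layers} (per-layer W, B, b), \code{scorer}.
#' @slot config the [gcnConfig()] list used for training.
#' @slot drugNames,effectNames node name vectors, fixing the index maps.
#' @slot msgPairs two-column integer matrix of bipartite edges visible to
#'   message passing.
#' @slot loss numeric vector, per-epoch training loss.
#' @export
setClass("GcnModel",
  representation(
    params = "list", config = "list",
    drugNames = "character", effectNames = "character",
    msgPairs = "matrix", loss = "numeric"
  )
)

#' Cross-validation metrics report
#'
#' Per-fold Precision, Recall, F1, AUROC and AUPR for one method, plus the
#' protocol parameters needed to reproduce them. Aggregation (mean and
#' sample standard deviation, both across all folds and across per-repeat
#' means) is done by the accessors and by \code{show}.
#'
#' @slot method method label.
#' @slot perFold data.frame with columns repeat_, fold, seed, precision,
#'   recall, f1, auroc, aupr.
#' @slot k,nRepeats,baseSeed protocol parameters.
#' @slot testFraction,negRatio protocol parameters.
#' @export
setClass("MetricsReport",
  representation(
    method = "character", perFold = "data.frame",
    k = "integer", nRepeats = "integer", baseSeed = "integer",
    testFraction = "numeric", negRatio = "numeric"
  )
)
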