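# Graph-convolutional encoder with an MLP (or dot-product) link scorer.
#
# Each aggregation layer computes, for every node v,
#   h_v' = l2norm( relu( B h_v + W (mean_{u in N(v)} w_uv h_u
#                                   + max_{u in N(v)} h_u) + b ) )
# i.e. a dense map of concat(self, mean + max) split into its two weight
# blocks, followed by row-wise L2 normalization (which bounds the
# representation scale and is what keeps the free input embeddings from
# memorizing the training links). Message passing runs over the bipartite
# training links (weight 1) and the drug-drug similarity edges (weight =
# similarity, count degree). Training is full-batch Adam on the binary
# cross-entropy of scored positive vs negative pairs, the negatives
# resampled every epoch from the complement of the training positives so
# no finite negative set can be memorized; gradients are analytic.

#' GCN training configuration
#'
#' @param depth number of aggregation layers (>= 1; default 3, the depth at
#'   which the model performs best in practice).
#' @param hiddenDim node embedding / layer width (default 64).
#' @param scorer link scorer: \code{"mlp"} (one hidden layer on the
#'   concatenated pair embedding) or \code{"dot"} (sigmoid of the dot
#'   product).
#' @param mlpHidden hidden width of the MLP scorer (default 64).
#' @param epochs full-batch training epochs (default 400, where the
#'   training loss has plateaued under per-epoch negative resampling at
#'   desk scale).
#' @param learningRate Adam step size (default 3e-3; 0 freezes the model at
#'   its initialization).
#' @param seed RNG seed for initialization and negative sampling.
#' @param negRatio negatives sampled per positive when training without a
#'   prebuilt split (default 1).
#' @return a validated config list of class \code{gcnConfig}.
#' @export
gcnConfig <- function(depth = 3L, hiddenDim = 64L, scorer = c("mlp", "dot"),
                      mlpHidden = 64L, epochs = 400L, learningRate = 3e-3,
                      seed = 1L, negRatio = 1) {
  scorer <- match.arg(scorer)
  if (depth < 1L) stop("config error: depth must be >= 1")
  if (hiddenDim < 1L) stop("config error: hiddenDim must be >= 1")
  if (mlpHidden < 1L) stop("config error: mlpHidden must be >= 1")
  if (epochs < 1L) stop("config error: epochs must be >= 1")
  if (learningRate < 0) stop("config error: learningRate must be >= 0")
  if (negRatio <= 0) stop("config error: negRatio must be positive")
  structure(list(depth = as.integer(depth), hiddenDim = as.integer(hiddenDim),
                 scorer = scorer, mlpHidden = as.integer(mlpHidden),
                 epochs = as.integer(epochs), learningRate = learningRate,
                 seed = as.integer(seed), negRatio = negRatio),
            class = "gcnConfig")
}

# Message-passing structure over training bipartite edges + similarity
# edges. Effects occupy node ids m+1 .. m+n.
buildPropagation <- function(graph, bipartitePairs) {
  m <- nDrugs(graph); n <- nEffects(graph)
  N <- m + n
  src <- integer(0); tgt <- integer(0); w <- numeric(0)
  if (nrow(bipartitePairs) > 0L) {
    p <- bipartitePairs[, 1L]; q <- m + bipartitePairs[, 2L]
    src <- c(src, p, q); tgt <- c(tgt, q, p)
    w <- c(w, rep(1, 2L * nrow(bipartitePairs)))
  }
  S <- as(graph@similarity, "TsparseMatrix")
  keep <- S@i != S@j
  if (any(keep)) {
    src <- c(src, S@i[keep] + 1L)
    tgt <- c(tgt, S@j[keep] + 1L)
    w <- c(w, S@x[keep])
  }
  deg <- tabulate(tgt, nbins = N)
  meanOp <- Matrix::sparseMatrix(i = tgt, j = src,
                                 x = w / pmax(deg[tgt], 1L), dims = c(N, N))
  ord <- order(tgt)
  list(N = N, m = m, n = n, meanOp = meanOp,
       indptr = c(0L, cumsum(tabulate(tgt, nbins = N))),
       indices = src[ord] - 1L, deg = deg)
}

# mean + max neighborhood term of one aggregation layer (before weights
# and nonlinearity); isolated nodes get the zero vector. The C++ kernel
# works feature-major, hence the transposes.
aggregateTerm <- function(prop, H) {
  Mn <- as.matrix(prop$meanOp %*% H)
  mx <- neighbor_max_fwd(prop$indptr, prop$indices, t(H))
  list(A = Mn + t(mx$max), amax = mx$amax)
}

# Initial node representations: a seeded random projection of each node's
# structural profile. A drug's profile is its similarity row concatenated
# with its training-link indicator row; an effect's profile is the
# indicator of its linked drugs. Random projection approximately preserves
# profile inner products, so even before training, neighborhood
# aggregation of these features scores a candidate pair roughly by its
# similarity-weighted path count; training then refines the features
# (they stay learnable parameters).
initFeatures <- function(graph, trainPos, d, seed) {
  m <- nDrugs(graph); n <- nEffects(graph)
  V <- Matrix::sparseMatrix(i = trainPos[, 1L], j = trainPos[, 2L], x = 1,
                            dims = c(m, n))
  X <- rbind(cbind(graph@similarity + Matrix::Diagonal(m), V),
             cbind(Matrix::t(V),
                   Matrix::sparseMatrix(i = integer(), j = integer(),
                                        dims = c(n, n))))
  P <- withSeed(seed + 1L,
                matrix(rnorm((m + n) * d, sd = sqrt(1 / d)), m + n, d))
  E <- as.matrix(X %*% P)
  E / (sqrt(rowSums(E^2)) + 1e-8)
}

initParams <- function(N, config, E0 = NULL) {
  d <- config$hiddenDim
  withSeed(config$seed, {
    layers <- lapply(seq_len(config$depth), function(k) list(
      W = matrix(rnorm(d * d, sd = sqrt(1 / d)), d, d),
      B = matrix(rnorm(d * d, sd = sqrt(1 / d)), d, d),
      b = numeric(d)))
    scorer <- if (config$scorer == "mlp") {
      mh <- config$mlpHidden
      list(W1 = matrix(rnorm(2 * d * mh, sd = sqrt(1 / d)), 2 * d, mh),
           b1 = numeric(mh),
           w2 = matrix(rnorm(mh, sd = sqrt(1 / mh)), mh, 1),
           b2 = 0)
    } else list()
    list(E = if (is.null(E0)) matrix(rnorm(N * d, sd = 0.1), N, d) else E0,
         layers = layers, scorer = scorer)
  })
}

addRowVec <- function(Z, b) Z + rep(b, each = nrow(Z))

gcnForward <- function(params, prop) {
  H <- params$E
  depth <- length(params$layers)
  caches <- vector("list", depth)
  for (k in seq_len(depth)) {
    L <- params$layers[[k]]
    ag <- aggregateTerm(prop, H)
    Z <- addRowVec(H %*% L$B + ag$A %*% L$W, L$b)
    R <- relu(Z)
    nrm <- sqrt(rowSums(R^2)) + 1e-8      # zero rows stay zero
    Hn <- R / nrm
    caches[[k]] <- list(H = H, A = ag$A, Z = Z, amax = ag$amax,
                        nrm = nrm, Hn = Hn)
    H <- Hn
  }
  list(H = H, caches = caches)
}

gcnBackward <- function(params, prop, caches, dH) {
  depth <- length(caches)
  gl <- vector("list", depth)
  for (k in rev(seq_len(depth))) {
    cc <- caches[[k]]
    L <- params$layers[[k]]
    dR <- (dH - cc$Hn * rowSums(dH * cc$Hn)) / cc$nrm
    dZ <- dR * (cc$Z > 0)
    gl[[k]] <- list(W = crossprod(cc$A, dZ), B = crossprod(cc$H, dZ),
                    b = colSums(dZ))
    dA <- dZ %*% t(L$W)
    dH <- dZ %*% t(L$B) +
      as.matrix(Matrix::crossprod(prop$meanOp, dA)) +
      t(neighbor_max_bwd(cc$amax, t(dA)))
  }
  list(E = dH, layers = gl)
}

scorerForward <- function(params, H, iIdx, jIdx, scorer) {
  if (scorer == "dot") {
    list(logit = rowSums(H[iIdx, , drop = FALSE] * H[jIdx, , drop = FALSE]))
  } else {
    sp <- params$scorer
    S <- cbind(H[iIdx, , drop = FALSE], H[jIdx, , drop = FALSE])
    Z1 <- addRowVec(S %*% sp$W1, sp$b1)
    A1 <- relu(Z1)
    list(logit = as.numeric(A1 %*% sp$w2) + sp$b2, S = S, Z1 = Z1, A1 = A1)
  }
}

# returns list(dH = N x d gradient wrt node representations, scorer = grads)
scorerBackward <- function(params, H, iIdx, jIdx, scorer, fw, dlogit) {
  d <- ncol(H)
  if (scorer == "dot") {
    dSi <- dlogit * H[jIdx, , drop = FALSE]
    dSj <- dlogit * H[iIdx, , drop = FALSE]
    sg <- list()
  } else {
    sp <- params$scorer
    gw2 <- crossprod(fw$A1, dlogit)
    gb2 <- sum(dlogit)
    dA1 <- tcrossprod(dlogit, sp$w2[, 1L])
    dZ1 <- dA1 * (fw$Z1 > 0)
    sg <- list(W1 = crossprod(fw$S, dZ1), b1 = colSums(dZ1),
               w2 = gw2, b2 = gb2)
    dS <- dZ1 %*% t(sp$W1)
    dSi <- dS[, seq_len(d), drop = FALSE]
    dSj <- dS[, d + seq_len(d), drop = FALSE]
  }
  dH <- matrix(0, nrow(H), d)
  agg <- rowsum(rbind(dSi, dSj), c(iIdx, jIdx))
  rows <- as.integer(rownames(agg))
  dH[rows, ] <- dH[rows, ] + agg
  list(dH = dH, scorer = sg)
}

bceWithLogits <- function(logit, y) {
  mean(pmax(logit, 0) - y * logit + log1p(exp(-abs(logit))))
}

# recursive Adam step over a nested parameter list
adamInit <- function(p) {
  if (is.list(p)) lapply(p, adamInit)
  else list(m = p * 0, v = p * 0)
}

adamStep <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  if (is.list(p) && !identical(names(p), c("m", "v"))) {
    for (idx in seq_along(p)) {
      res <- adamStep(p[[idx]], g[[idx]], st[[idx]], lr, t, beta1, beta2, eps)
      p[[idx]] <- res$p
      st[[idx]] <- res$st
    }
    return(list(p = p, st = st))
  }
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Train the GCN link predictor
#'
#' Full-batch Adam on the binary cross-entropy separating positive links
#' (label 1) from sampled negative links (label 0). Message passing sees
#' only the training positives plus the similarity edges; held-out test
#' links never enter the encoder.
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @param split optional \linkS4class{EvalSplit}; when \code{NULL} the model
#'   trains on all positive links against \code{negRatio} freshly sampled
#'   negatives.
#' @param config a [gcnConfig()].
#' @return a \linkS4class{GcnModel}; the per-epoch loss trace is in slot
#'   \code{loss}.
#' @export
trainGcn <- function(graph, split = NULL, config = gcnConfig()) {
  stopifnot(inherits(config, "gcnConfig"))
  m <- nDrugs(graph)
  if (is.null(split)) {
    trainPos <- positivePairs(graph)
    trainNeg <- sampleNegatives(graph, round(config$negRatio * nrow(trainPos)),
                                seed = config$seed)
  } else {
    trainPos <- split@trainPos
    trainNeg <- split@trainNeg
  }
  if (nrow(trainPos) == 0L || nrow(trainNeg) == 0L)
    stop("training requires non-empty positive and negative sets")
  prop <- buildPropagation(graph, trainPos)
  params <- initParams(prop$N, config,
                       E0 = initFeatures(graph, trainPos,
                                         config$hiddenDim, config$seed))
  iPos <- trainPos[, 1L]; jPos <- m + trainPos[, 2L]
  nNegEpoch <- round(config$negRatio * nrow(trainPos))
  y <- c(rep(1, nrow(trainPos)), rep(0, nrow(trainNeg)))
  state <- adamInit(params)
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    if (epoch == 1L) {
      neg <- trainNeg                      # the split's own negative set
    } else {                               # fresh negatives, train-pos complement
      neg <- samplePairComplement(m, nEffects(graph), trainPos, nNegEpoch,
                                  seed = config$seed + 7919L * epoch)
      y <- c(rep(1, nrow(trainPos)), rep(0, nNegEpoch))
    }
    iIdx <- c(iPos, neg[, 1L])
    jIdx <- c(jPos, m + neg[, 2L])
    fw <- gcnForward(params, prop)
    sc <- scorerForward(params, fw$H, iIdx, jIdx, config$scorer)
    loss <- bceWithLogits(sc$logit, y)
    if (!is.finite(loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    trace[epoch] <- loss
    dlogit <- (sigmoid(sc$logit) - y) / length(y)
    sb <- scorerBackward(params, fw$H, iIdx, jIdx, config$scorer, sc, dlogit)
    gb <- gcnBackward(params, prop, fw$caches, sb$dH)
    grads <- list(E = gb$E, layers = gb$layers, scorer = sb$scorer)
    res <- adamStep(params, grads, state, config$learningRate, epoch)
    params <- res$p
    state <- res$st
  }
  new("GcnModel", params = params, config = unclass(config),
      drugNames = drugNames(graph), effectNames = effectNames(graph),
      msgPairs = trainPos, loss = trace)
}

setMethod("show", "GcnModel", function(object) {
  cat(sprintf(
    "GcnModel: depth %d, dim %d, %s scorer, %d epochs (final loss %.4f), %d message edges\n",
    object@config$depth, object@config$hiddenDim, object@config$scorer,
    length(object@loss),
    if (length(object@loss)) object@loss[length(object@loss)] else NA_real_,
    nrow(object@msgPairs)))
})

checkModelGraph <- function(model, graph) {
  if (!identical(model@drugNames, drugNames(graph)) ||
      !identical(model@effectNames, effectNames(graph)))
    stop("model was trained on a graph with different node names")
}

#' Encode all nodes with a trained model
#'
#' Applies the model's aggregation layers over its training edge set and
#' the graph's similarity edges.
#'
#' @param graph the \linkS4class{HeteroGraph} the model was trained on.
#' @param model a \linkS4class{GcnModel}.
#' @return (m+n) x hiddenDim matrix of node representations, drugs first;
#'   rownames are node names.
#' @export
encodeNodes <- function(graph, model) {
  checkModelGraph(model, graph)
  prop <- buildPropagation(graph, model@msgPairs)
  H <- gcnForward(model@params, prop)$H
  rownames(H) <- c(drugNames(graph), effectNames(graph))
  H
}

#' Score drug/side-effect pairs with a trained model
#'
#' @param graph the training \linkS4class{HeteroGraph}.
#' @param model a \linkS4class{GcnModel}.
#' @param pairs two-column matrix of (drug index, effect index).
#' @return data.frame with drug, side_effect_name and probability in (0, 1).
#' @export
scoreLinks <- function(graph, model, pairs) {
  checkModelGraph(model, graph)
  H <- encodeNodes(graph, model)
  prob <- sigmoid(scorerForward(model@params, H, pairs[, 1L],
                                nDrugs(graph) + pairs[, 2L],
                                model@config$scorer)$logit)
  data.frame(drug = drugNames(graph)[pairs[, 1L]],
             side_effect_name = effectNames(graph)[pairs[, 2L]],
             probability = prob, stringsAsFactors = FALSE)
}

#' Top-k predicted side effects for a drug
#'
#' Scores one drug against every side effect and returns the k highest
#' probabilities in descending order (ties broken by effect index). With
#' \code{excludeKnown = TRUE} (default) side effects already associated
#' with the drug in the graph are dropped first, so the result is the
#' ranked list of new predictions.
#'
#' @param model a \linkS4class{GcnModel}.
#' @param graph the training \linkS4class{HeteroGraph}.
#' @param drug drug name.
#' @param k number of side effects to return (default 10).
#' @param excludeKnown drop known associations before ranking.
#' @return data.frame with side_effect_name, probability, rank.
#' @export
predictTopK <- function(model, graph, drug, k = 10L, excludeKnown = TRUE) {
  if (k < 1L) stop("k must be >= 1")
  p <- match(drug, drugNames(graph))
  if (is.na(p)) {
    near <- agrep(drug, drugNames(graph), max.distance = 0.3, value = TRUE)
    stop("unknown drug '", drug, "'",
         if (length(near)) paste0("; nearest matches: ",
                                  paste(head(near, 5L), collapse = ", "))
         else "")
  }
  n <- nEffects(graph)
  cand <- seq_len(n)
  if (excludeKnown) {
    pp <- positivePairs(graph)
    known <- pp[pp[, 1L] == p, 2L]
    cand <- setdiff(cand, known)
  }
  if (length(cand) == 0L) {
    warning("no candidate side effects left for ", drug)
    return(data.frame(side_effect_name = character(), probability = numeric(),
                      rank = integer()))
  }
  scored <- scoreLinks(graph, model, asPairMatrix(rep(p, length(cand)), cand))
  ord <- order(-scored$probability, cand)
  keep <- head(ord, k)
  if (length(keep) < k)
    warning("only ", length(keep), " candidate side effects available (k = ",
            k, ")")
  data.frame(side_effect_name = scored$side_effect_name[keep],
             probability = scored$probability[keep],
             rank = seq_along(keep), stringsAsFactors = FALSE)
}

#' Save / load a GCN model checkpoint
#'
#' Checkpoints are JSON with a schema version, the full configuration, all
#' weight arrays, the node-name index maps, and the message-passing edges.
#'
#' @param model a \linkS4class{GcnModel}.
#' @param path checkpoint path.
#' @return \code{saveGcnModel} the path, invisibly; \code{loadGcnModel} the
#'   restored model.
#' @export
saveGcnModel <- function(model, path) {
  ser <- list(
    schema = "adrgraph-gcn-1",
    config = model@config,
    config_hash = configHash(model@config),
    drugNames = model@drugNames,
    effectNames = model@effectNames,
    msgPairs = as.numeric(model@msgPairs),
    loss = model@loss,
    E = as.numeric(model@params$E),
    layers = lapply(model@params$layers, function(L)
      list(W = as.numeric(L$W), B = as.numeric(L$B), b = as.numeric(L$b))),
    scorer = lapply(model@params$scorer, as.numeric))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveGcnModel
#' @export
loadGcnModel <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(ser$schema, "adrgraph-gcn-1"))
    stop("unrecognized checkpoint schema: ", ser$schema)
  cfg <- ser$config
  d <- cfg$hiddenDim
  N <- length(ser$drugNames) + length(ser$effectNames)
  layers <- lapply(ser$layers, function(L)
    list(W = matrix(L$W, d, d), B = matrix(L$B, d, d), b = as.numeric(L$b)))
  scorer <- if (identical(cfg$scorer, "mlp")) {
    list(W1 = matrix(ser$scorer$W1, 2L * d, cfg$mlpHidden),
         b1 = as.numeric(ser$scorer$b1),
         w2 = matrix(ser$scorer$w2, ncol = 1L),
         b2 = as.numeric(ser$scorer$b2))
  } else list()
  new("GcnModel",
      params = list(E = matrix(ser$E, N, d), layers = layers,
                    scorer = scorer),
      config = cfg,
      drugNames = ser$drugNames, effectNames = ser$effectNames,
      msgPairs = matrix(as.integer(ser$msgPairs), ncol = 2L,
                        dimnames = list(NULL, c("drug", "effect"))),
      loss = as.numeric(ser$loss))
}
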