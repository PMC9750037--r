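# Evaluation harness: threshold metrics, ROC/PR areas and curves,
# repeated cross-validation with mean +/- sd aggregation, and Welch t-tests
# between methods.

#' Precision, recall and F1 at a probability threshold
#'
#' Positive-class metrics: a pair is predicted positive when its score is
#' at or above the threshold. When nothing is predicted positive the
#' precision is reported as 0 with a warning.
#'
#' @param scores numeric scores/probabilities.
#' @param labels 0/1 labels, same length.
#' @param threshold decision threshold (default 0.5).
#' @return named numeric vector (precision, recall, f1).
#' @export
thresholdMetrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (sum(labels) == 0L) warning("degenerate labels: no positives present")
  if (sum(labels) == length(labels))
    warning("degenerate labels: no negatives present")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (tp + fp == 0L) {
    warning("no predicted positives at threshold ", threshold,
            "; precision reported as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimate: the probability that a random
#' positive outscores a random negative, ties counted one half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return scalar in [0, 1].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# PR / ROC curve points at the distinct score thresholds, descending.
curvePoints <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y == 1)
  cum_fp <- cumsum(y == 0)
  last <- which(diff(s) != 0)            # block ends of distinct thresholds
  last <- c(last, length(s))
  P <- sum(labels == 1); Nn <- sum(labels == 0)
  data.frame(threshold = s[last],
             tp = cum_tp[last], fp = cum_fp[last],
             tpr = if (P > 0) cum_tp[last] / P else 0,
             fpr = if (Nn > 0) cum_fp[last] / Nn else 0,
             precision = cum_tp[last] / (cum_tp[last] + cum_fp[last]),
             recall = if (P > 0) cum_tp[last] / P else 0)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over the distinct score thresholds:
#' sum of (recall step) x (precision at that threshold). No interpolation
#' is applied, so a constant score vector yields the positive prevalence.
#'
#' @inheritParams auroc
#' @return scalar in [0, 1].
#' @export
aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (sum(labels == 1) == 0L) stop("AUPR undefined: no positives present")
  if (sum(labels == 0) == 0L) stop("AUPR undefined: no negatives present")
  cp <- curvePoints(scores, labels)
  sum(diff(c(0, cp$recall)) * cp$precision)
}

#' Export ROC and PR curve tables
#'
#' Writes two TSVs, \code{<path>_roc.tsv} (fpr, tpr) and
#' \code{<path>_pr.tsv} (recall, precision), one row per distinct
#' threshold; the ROC table is anchored at (0,0) and (1,1). Trapezoidal
#' integration of the ROC table reproduces [auroc()], and the step sum over
#' the PR table reproduces [aupr()].
#'
#' @inheritParams auroc
#' @param path output path prefix, or \code{NULL} to skip writing.
#' @return invisibly, list(roc=, pr=) of data.frames.
#' @export
exportCurves <- function(scores, labels, path = NULL) {
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L)
    stop("curves undefined: both classes must be present")
  cp <- curvePoints(scores, labels)
  roc <- rbind(data.frame(fpr = 0, tpr = 0),
               cp[, c("fpr", "tpr")])
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  pr <- cp[, c("recall", "precision")]
  if (!is.null(path)) {
    write.table(roc, paste0(path, "_roc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(pr, paste0(path, "_pr.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(roc = roc, pr = pr))
}

allMetrics <- function(probs, raws, labels, threshold = 0.5) {
  tm <- thresholdMetrics(probs, labels, threshold)
  c(tm, auroc = auroc(raws, labels), aupr = aupr(raws, labels))
}

# Built-in method scorers behind the uniform cross-validation interface.
# Each returns data.frame(raw, prob) for rbind(testPos, testNeg).
methodScorer <- function(method, params = list()) {
  if (is.function(method)) return(method)
  stopifnot(is.character(method), length(method) == 1L)
  known <- c("gcnmlp", "nmf", "nmfhd", "aa", "ra", "pa", "katz", "ppr",
             "oracle", "random")
  if (!method %in% known)
    stop("unknown method '", method, "'; valid methods: ",
         paste(known, collapse = ", "))
  arg <- function(name, default) if (!is.null(params[[name]]))
    params[[name]] else default
  switch(method,
    gcnmlp = function(graph, split, seed) {
      cfgArgs <- params[intersect(names(params),
                                  names(formals(gcnConfig)))]
      cfgArgs$seed <- seed
      config <- do.call(gcnConfig, cfgArgs)
      model <- trainGcn(graph, split, config)
      pairs <- rbind(split@testPos, split@testNeg)
      prob <- scoreLinks(graph, model, pairs)$probability
      data.frame(raw = prob, prob = prob)
    },
    nmf = function(graph, split, seed) {
      V <- associationMatrix(graph, split@trainPos)
      rank <- min(arg("rank", 64L), nDrugs(graph), nEffects(graph))
      f <- nmfFactorize(V, rank = rank, iters = arg("iters", 200L),
                        seed = seed)
      nmfScores(f, rbind(split@testPos, split@testNeg))
    },
    nmfhd = function(graph, split, seed) {
      V <- associationMatrix(graph, split@trainPos)
      rank <- min(arg("rank", 64L), nDrugs(graph), nEffects(graph))
      nmfhdScores(V, as.matrix(drugSimilarity(graph)), rank = rank,
                  alphaT = arg("alphaT", 1), tau = arg("tau", 1),
                  iters = arg("iters", 200L), seed = seed,
                  pairs = rbind(split@testPos, split@testNeg))
    },
    oracle = function(graph, split, seed) {
      lab <- c(rep(1, nrow(split@testPos)), rep(0, nrow(split@testNeg)))
      data.frame(raw = lab, prob = lab)
    },
    random = function(graph, split, seed) {
      u <- withSeed(seed + 10007L,
                    runif(nrow(split@testPos) + nrow(split@testNeg)))
      data.frame(raw = u, prob = u)
    },
    # remaining: heuristic indices
    function(graph, split, seed) {
      scoreAllPairs(graph, method, rbind(split@testPos, split@testNeg),
                    trainPairs = split@trainPos,
                    beta = arg("beta", 0.005), maxLen = arg("maxLen", 5L),
                    omega = arg("omega", 0.85))
    })
}

#' Repeated cross-validation of a link-prediction method
#'
#' For each repeat the positives are reshuffled and split into k folds; for
#' each fold the method is fit on the training sets only and its scores on
#' the held-out positives plus sampled negatives are summarized by the five
#' metrics. Fold seeds are \code{baseSeed + (r-1)*k + f}, so two methods
#' evaluated with the same protocol parameters see identical splits.
#'
#' @param method a built-in method name (\code{"gcnmlp"}, \code{"nmf"},
#'   \code{"nmfhd"}, \code{"aa"}, \code{"ra"}, \code{"pa"}, \code{"katz"},
#'   \code{"ppr"}, \code{"oracle"}, \code{"random"}) or a function
#'   \code{(graph, split, seed) -> data.frame(raw, prob)}.
#' @param graph a \linkS4class{HeteroGraph}.
#' @param k folds per repeat (default 10).
#' @param testFraction held-out positive fraction (default 0.1).
#' @param negRatio negatives per positive (default 1).
#' @param nRepeats repeats (default 1).
#' @param baseSeed base RNG seed.
#' @param params method hyperparameters (list), passed through.
#' @param threshold decision threshold for precision/recall/F1.
#' @return a \linkS4class{MetricsReport}.
#' @export
crossValidate <- function(method, graph, k = 10L, testFraction = 0.1,
                          negRatio = 1, nRepeats = 1L, baseSeed = 1L,
                          params = list(), threshold = 0.5) {
  scorer <- methodScorer(method, params)
  label <- if (is.character(method)) method else "custom"
  rows <- list()
  for (r in seq_len(nRepeats)) {
    repSeed <- baseSeed + (r - 1L) * k
    splits <- kfoldSplits(graph, k = k, testFraction = testFraction,
                          negRatio = negRatio, seed = repSeed)
    for (f in seq_len(k)) {
      split <- splits[[f]]
      res <- tryCatch(scorer(graph, split, split@seed), error = function(e)
        stop("method '", label, "' failed in repeat ", r, ", fold ", f,
             ": ", conditionMessage(e)))
      lab <- c(rep(1, nrow(split@testPos)), rep(0, nrow(split@testNeg)))
      if (all(lab == 1) || all(lab == 0))
        stop("degenerate test set (single class) in repeat ", r,
             ", fold ", f)
      mets <- allMetrics(res$prob, res$raw, lab, threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, seed = split@seed, t(mets))
    }
  }
  new("MetricsReport", method = label, perFold = do.call(rbind, rows),
      k = as.integer(k), nRepeats = as.integer(nRepeats),
      baseSeed = as.integer(baseSeed), testFraction = testFraction,
      negRatio = negRatio)
}

metricNames <- c("precision", "recall", "f1", "auroc", "aupr")

#' Aggregate a metrics report
#'
#' @param report a \linkS4class{MetricsReport}.
#' @param by \code{"fold"}: mean and sample sd across all k x nRepeats
#'   folds; \code{"repeat"}: across the nRepeats per-repeat means.
#' @return data.frame with metric, mean, sd, formatted.
#' @export
aggregateMetrics <- function(report, by = c("fold", "repeat")) {
  by <- match.arg(by)
  pf <- report@perFold
  vals <- if (by == "fold") pf[, metricNames, drop = FALSE]
  else do.call(rbind, lapply(split(pf, pf$repeat_), function(d)
    colMeans(d[, metricNames, drop = FALSE])))
  mu <- colMeans(as.matrix(vals))
  sdev <- apply(as.matrix(vals), 2L, sd)
  sdev[is.na(sdev)] <- 0
  data.frame(metric = metricNames, mean = mu, sd = sdev,
             formatted = sprintf("%.3f±%.3f", mu, sdev),
             row.names = NULL)
}

setMethod("show", "MetricsReport", function(object) {
  agg <- aggregateMetrics(object)
  cat(sprintf("MetricsReport for '%s' (%d folds x %d repeats):\n",
              object@method, object@k, object@nRepeats))
  cat(paste(sprintf("  %-9s %s", agg$metric, agg$formatted),
            collapse = "\n"), "\n")
})

#' Welch t-test between two methods' per-fold metrics
#'
#' Two-sided Welch two-sample t-test on the per-fold values of one metric
#' (n = k x nRepeats per method); the null is rejected at alpha = 0.05.
#' Identical fold vectors give t = 0, p = 1.
#'
#' @param reportA,reportB \linkS4class{MetricsReport} objects.
#' @param metric one of precision, recall, f1, auroc, aupr.
#' @param alpha significance level (default 0.05).
#' @return list with method_a, method_b, metric, t, p_value, alpha, reject.
#' @export
compareMethods <- function(reportA, reportB, metric = "aupr", alpha = 0.05) {
  stopifnot(metric %in% metricNames)
  a <- reportA@perFold[[metric]]
  b <- reportB@perFold[[metric]]
  if (length(a) < 2L || length(b) < 2L)
    stop("insufficient data: need at least 2 folds per method")
  if (isTRUE(all.equal(var(a) + var(b), 0)) &&
      isTRUE(all.equal(mean(a), mean(b)))) {
    tstat <- 0; pval <- 1
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    tstat <- unname(tt$statistic); pval <- tt$p.value
  }
  list(method_a = reportA@method, method_b = reportB@method,
       metric = metric, t = tstat, p_value = pval, alpha = alpha,
       reject = pval < alpha)
}
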