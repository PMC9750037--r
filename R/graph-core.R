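# Readers for the two input dialects, heterogeneous-graph construction,
# negative-link sampling, and cross-validation splitting.

ASSOC_COLUMNS <- c("drugbank_id", "drugbank name", "umls cui from meddra",
                   "side_effect_name")

normalizeHeader <- function(x) gsub("[ _]+", " ", trimws(tolower(x)))

detectSep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a drug/side-effect association table
#'
#' Parses a delimited file with the four columns \code{drugbank_id},
#' \code{drugbank name}, \code{umls cui from meddra} and
#' \code{side_effect_name} (matched case-insensitively, tolerant of
#' underscore/space variation; column order is free). Fully duplicated
#' (drug name, side effect) pairs are collapsed and the number dropped is
#' reported.
#'
#' @param path path to a TSV or CSV file with a header row.
#' @param sep field separator; \code{NULL} (default) auto-detects tab vs
#'   comma from the header line.
#' @return A data.frame with columns \code{drug_id}, \code{drug_name},
#'   \code{umls_cui}, \code{side_effect_name}; attribute
#'   \code{duplicates_dropped} carries the dedup count.
#' @export
readAssociations <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("association file not found: ", path)
  sep <- detectSep(path, sep)
  df <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   comment.char = "", check.names = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L) stop("association file is empty: ", path)
  have <- normalizeHeader(colnames(df))
  want <- normalizeHeader(ASSOC_COLUMNS)
  idx <- match(want, have)
  if (anyNA(idx)) {
    stop("association file missing required column(s): ",
         paste(sQuote(ASSOC_COLUMNS[is.na(idx)]), collapse = ", "))
  }
  out <- df[, idx]
  colnames(out) <- c("drug_id", "drug_name", "umls_cui", "side_effect_name")
  out[] <- lapply(out, trimws)
  blank <- rowSums(out == "" | is.na(out)) > 0
  if (any(blank)) {
    warning(sum(blank), " row(s) with empty fields dropped")
    out <- out[!blank, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("association file has no usable rows: ", path)
  dup <- duplicated(out[, c("drug_name", "side_effect_name")])
  if (any(dup)) adrMessage("collapsed ", sum(dup), " duplicate association row(s)")
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "duplicates_dropped") <- sum(dup)
  out
}

#' Write an association table in the four-column input dialect
#'
#' Inverse of [readAssociations()] on deduplicated tables.
#'
#' @param assoc data.frame as returned by [readAssociations()].
#' @param path output path.
#' @param sep field separator, default tab.
#' @export
writeAssociations <- function(assoc, path, sep = "\t") {
  out <- assoc[, c("drug_id", "drug_name", "umls_cui", "side_effect_name")]
  colnames(out) <- ASSOC_COLUMNS
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug-drug similarity table
#'
#' Parses a three-column file (drug name, drug name, cosine similarity).
#' Pair order is normalized so each unordered pair appears once; duplicate
#' rows for the same pair are averaged. Scores outside [0, 1] by at most
#' 1e-6 are clamped with a warning; larger violations are an error.
#' Self-similarity rows are retained in the output (they are ignored at
#' graph construction).
#'
#' @param path path to a TSV or CSV file. A header row is detected by a
#'   non-numeric third field on line one.
#' @param sep field separator; \code{NULL} auto-detects.
#' @return data.frame with columns \code{drug1}, \code{drug2}, \code{score},
#'   with \code{drug1 <= drug2} lexicographically.
#' @export
readSimilarity <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("similarity file not found: ", path)
  sep <- detectSep(path, sep)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  hasHeader <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
  df <- read.table(path, header = hasHeader, sep = sep, quote = "\"",
                   comment.char = "", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 3L) stop("similarity file must have three columns")
  if (nrow(df) == 0L) stop("similarity file is empty: ", path)
  score <- suppressWarnings(as.numeric(df[[3L]]))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1L] + as.integer(hasHeader)
    stop("non-numeric similarity score at row ", bad)
  }
  low <- score < 0; high <- score > 1
  if (any(score < -1e-6) || any(score > 1 + 1e-6))
    stop("similarity score outside [0, 1] beyond tolerance at row ",
         which(score < -1e-6 | score > 1 + 1e-6)[1L] + as.integer(hasHeader))
  if (any(low | high)) {
    warning(sum(low | high), " similarity score(s) clamped to [0, 1]")
    score <- pmin(pmax(score, 0), 1)
  }
  a <- trimws(df[[1L]]); b <- trimws(df[[2L]])
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(drug1 = a, drug2 = b, score = score,
                    stringsAsFactors = FALSE)
  key <- paste(out$drug1, out$drug2, sep = "\r")
  if (anyDuplicated(key)) {
    out <- aggregate(score ~ drug1 + drug2, data = out, FUN = mean)
  }
  out <- out[order(out$drug1, out$drug2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the heterogeneous graph
#'
#' Assembles a \linkS4class{HeteroGraph} from an association table and
#' (optionally) drug-drug similarity pairs. Drug and effect indices are
#' assigned in sorted name order; similarity rows naming a drug absent from
#' the association table are dropped with a message; entries strictly below
#' \code{simThreshold} are zeroed; the matrix is symmetrized by construction
#' and self-similarities are discarded.
#'
#' @param assoc association data.frame from [readAssociations()].
#' @param sim optional similarity data.frame from [readSimilarity()].
#' @param simThreshold minimum similarity retained as an edge weight
#'   (default 0: every positive similarity becomes a weighted edge).
#' @return A \linkS4class{HeteroGraph}.
#' @export
buildHeteroGraph <- function(assoc, sim = NULL, simThreshold = 0) {
  stopifnot(is.numeric(simThreshold), length(simThreshold) == 1L,
            simThreshold >= 0, simThreshold <= 1)
  drugs <- sort(unique(assoc$drug_name))
  effects <- sort(unique(assoc$side_effect_name))
  if (length(drugs) == 0L || length(effects) == 0L)
    stop("empty graph: no drugs or no side effects after filtering")
  m <- length(drugs)
  pp <- asPairMatrix(match(assoc$drug_name, drugs),
                     match(assoc$side_effect_name, effects))
  pp <- pp[!duplicated(pairKey(pp)), , drop = FALSE]
  S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(m, m))
  if (!is.null(sim) && nrow(sim) > 0L) {
    i <- match(sim$drug1, drugs)
    j <- match(sim$drug2, drugs)
    known <- !is.na(i) & !is.na(j)
    if (any(!known))
      adrMessage("dropped ", sum(!known),
                 " similarity row(s) naming drugs absent from associations")
    keep <- known & i != j & sim$score >= simThreshold & sim$score > 0
    if (any(keep)) {
      S <- Matrix::sparseMatrix(i = c(i[keep], j[keep]),
                                j = c(j[keep], i[keep]),
                                x = rep(sim$score[keep], 2L),
                                dims = c(m, m), use.last.ij = TRUE)
    }
  }
  new("HeteroGraph", drugNames = drugs, effectNames = effects,
      positivePairs = pp, similarity = S, simThreshold = simThreshold)
}

#' @describeIn HeteroGraph-accessors number of drugs
#' @export
nDrugs <- function(graph) length(graph@drugNames)

#' @describeIn HeteroGraph-accessors number of side effects
#' @export
nEffects <- function(graph) length(graph@effectNames)

#' Accessors for HeteroGraph
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @name HeteroGraph-accessors
NULL

#' @describeIn HeteroGraph-accessors drug name vector
#' @export
drugNames <- function(graph) graph@drugNames

#' @describeIn HeteroGraph-accessors side-effect name vector
#' @export
effectNames <- function(graph) graph@effectNames

#' @describeIn HeteroGraph-accessors two-column (drug, effect) index matrix
#'   of observed associations
#' @export
positivePairs <- function(graph) graph@positivePairs

#' @describeIn HeteroGraph-accessors sparse symmetric drug-drug similarity
#'   matrix
#' @export
drugSimilarity <- function(graph) graph@similarity

setMethod("show", "HeteroGraph", function(object) {
  cat(sprintf(
    "HeteroGraph: %d drugs x %d side effects, %d positive links, %d similarity edges (threshold %.3g)\n",
    nDrugs(object), nEffects(object), nrow(object@positivePairs),
    Matrix::nnzero(object@similarity) / 2L, object@simThreshold))
})

#' Size of the negative-link universe
#'
#' Number of drug/side-effect cells not observed as associations:
#' \eqn{m \cdot n - |positives|}. Callable either on a
#' \linkS4class{HeteroGraph} or directly on printed dataset counts.
#'
#' @param graph a \linkS4class{HeteroGraph}, or the number of drugs m when
#'   \code{n} and \code{nPositives} are given.
#' @param n,nPositives number of side effects and of positive associations,
#'   used when \code{graph} is a plain count.
#' @return numeric scalar (exact; may exceed integer range).
#' @export
negativeUniverseSize <- function(graph, n = NULL, nPositives = NULL) {
  if (is(graph, "HeteroGraph")) {
    m <- nDrugs(graph); n <- nEffects(graph)
    nPositives <- nrow(positivePairs(graph))
  } else {
    m <- graph
    stopifnot(is.numeric(m), is.numeric(n), is.numeric(nPositives))
  }
  as.double(m) * as.double(n) - as.double(nPositives)
}

#' Sample negative links uniformly without replacement
#'
#' Draws \code{count} (drug, effect) cells uniformly from the complement of
#' the graph's positive links and of \code{exclude}. Reproducible for a
#' fixed seed.
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @param count number of negatives to draw.
#' @param seed integer RNG seed.
#' @param exclude optional two-column matrix of additional forbidden pairs.
#' @return two-column integer matrix (drug, effect).
#' @export
sampleNegatives <- function(graph, count, seed, exclude = NULL) {
  forbidden <- rbind(graph@positivePairs,
                     if (!is.null(exclude)) exclude[, 1:2, drop = FALSE])
  samplePairComplement(nDrugs(graph), nEffects(graph), forbidden, count,
                       seed)
}

# uniform sample of `count` (p, q) cells of the m x n grid avoiding the
# `forbidden` pair matrix; shared by negative sampling and GCN training.
samplePairComplement <- function(m, n, forbidden, count, seed) {
  mn <- as.double(m) * n
  forbidIds <- unique((as.double(forbidden[, 1L]) - 1) * n +
                        forbidden[, 2L])
  avail <- mn - length(forbidIds)
  if (count > avail)
    stop("cannot sample ", count, " negatives: only ", avail,
         " cells available in the negative universe")
  if (count == 0L) return(emptyPairs())
  ids <- withSeed(seed, {
    if (mn <= 2e6 || count > 0.25 * avail) {
      pool <- setdiff(seq_len(mn), forbidIds)
      pool[sample.int(length(pool), count)]
    } else {
      got <- numeric(0)
      while (length(got) < count) {
        need <- count - length(got)
        cand <- ceiling(runif(max(2L * need, 32L)) * mn)
        cand <- setdiff(unique(cand), forbidIds)
        got <- unique(c(got, cand))
      }
      got[seq_len(count)]
    }
  })
  asPairMatrix((ids - 1) %/% n + 1, (ids - 1) %% n + 1)
}

#' Cross-validation splits of the positive links
#'
#' Shuffles the positive links once under \code{seed}, then forms \code{k}
#' folds. When \code{testFraction} equals 1/k the folds partition the
#' positives exactly (standard k-fold CV); otherwise each fold holds out a
#' circular block of \code{ceiling(testFraction * N)} shuffled positives
#' starting at k evenly spaced offsets, so k and the held-out percentage can
#' be varied independently. Negatives are sampled per fold at
#' \code{negRatio} times the positive counts, train and test negatives
#' disjoint, with per-fold seed \code{seed + fold}.
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @param k number of folds (>= 2).
#' @param testFraction fraction of positives held out per fold (default 1/k).
#' @param negRatio negatives sampled per positive (default 1).
#' @param seed integer shuffle seed.
#' @return list of \linkS4class{EvalSplit}, length k.
#' @export
kfoldSplits <- function(graph, k = 10L, testFraction = 1 / k, negRatio = 1,
                        seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  if (negRatio <= 0) stop("negRatio must be positive")
  pp <- graph@positivePairs
  N <- nrow(pp)
  perm <- withSeed(seed, sample.int(N))
  h <- ceiling(testFraction * N)
  if (h < 1L || h >= N)
    stop("split would leave an empty train or test set (N = ", N, ")")
  exact <- abs(testFraction - 1 / k) < 1e-9
  lapply(seq_len(k), function(f) {
    testIdx <- if (exact) {
      perm[(floor((f - 1) * N / k) + 1):floor(f * N / k)]
    } else {
      start <- floor((f - 1) * N / k)
      perm[(start + seq_len(h) - 1L) %% N + 1L]
    }
    if (length(testIdx) == 0L || length(testIdx) == N)
      stop("fold ", f, " would be empty")
    testPos <- pp[testIdx, , drop = FALSE]
    trainPos <- pp[-testIdx, , drop = FALSE]
    nTr <- round(negRatio * nrow(trainPos))
    nTe <- round(negRatio * nrow(testPos))
    neg <- sampleNegatives(graph, nTr + nTe, seed = seed + f)
    new("EvalSplit",
        trainPos = trainPos, testPos = testPos,
        trainNeg = neg[seq_len(nTr), , drop = FALSE],
        testNeg = neg[nTr + seq_len(nTe), , drop = FALSE],
        foldId = as.integer(f), seed = as.integer(seed + f))
  })
}

setMethod("show", "EvalSplit", function(object) {
  cat(sprintf(
    "EvalSplit fold %d (seed %d): %d/%d train/test positives, %d/%d negatives\n",
    object@foldId, object@seed, nrow(object@trainPos), nrow(object@testPos),
    nrow(object@trainNeg), nrow(object@testNeg)))
})

#' Serialize splits to JSON lines
#'
#' One edge per line: fold, role (train/test), label (1 positive, 0
#' negative), drug name, side-effect name.
#'
#' @param splits list of \linkS4class{EvalSplit} from [kfoldSplits()].
#' @param graph the parent \linkS4class{HeteroGraph} (for names).
#' @param path output path.
#' @export
writeSplits <- function(splits, graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in splits) {
    sets <- list(list(s@trainPos, "train", 1L), list(s@testPos, "test", 1L),
                 list(s@trainNeg, "train", 0L), list(s@testNeg, "test", 0L))
    for (set in sets) {
      mat <- set[[1L]]
      if (nrow(mat) == 0L) next
      for (r in seq_len(nrow(mat))) {
        writeLines(jsonlite::toJSON(list(
          fold = s@foldId, role = set[[2L]], label = set[[3L]],
          drug = graph@drugNames[mat[r, 1L]],
          effect = graph@effectNames[mat[r, 2L]]), auto_unbox = TRUE), con)
      }
    }
  }
  invisible(path)
}
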