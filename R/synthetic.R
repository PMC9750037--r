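# Synthetic heterogeneous graphs with planted latent-factor structure.
# The ground truth is a logistic latent-factor model: drug factors U and
# effect factors E drawn standard normal, link probability
# sigma(U E' + bias) with the bias tuned by bisection so the expected link
# density matches the target. The emitted files use exactly the two input
# dialects the readers consume, so the whole pipeline runs with no
# external download.

#' Specification of a synthetic drug/side-effect dataset
#'
#' @param m number of drugs (default 100).
#' @param n number of side effects (default 200).
#' @param latentRank rank of the planted factors (default 5).
#' @param density target positive-link fraction in (0, 1) (default 0.05,
#'   about 1000 links at the default size).
#' @param noise probability of flipping a cell after sampling, in
#'   [0, 0.5) (default 0: clean links).
#' @param signal variance of the latent factor entries (default 2). This
#'   sets how bimodal the planted link probabilities are: at the default
#'   roughly a third of realized links have true probability above 0.9,
#'   emulating the reproducible (not coin-flip) nature of reported
#'   drug/ADE associations while leaving a substantial noisy margin.
#' @param simInformative if \code{TRUE} (default) the drug-drug similarity
#'   is the cosine similarity of the drug factor rows (negative cosines
#'   clipped at 0), so similar drugs genuinely share side effects; if
#'   \code{FALSE} it is an independent random symmetric matrix in [0, 1],
#'   a negative control.
#' @param seed RNG seed; the emitted files are byte-identical for a fixed
#'   spec.
#' @return validated spec list of class \code{syntheticSpec}.
#' @export
syntheticSpec <- function(m = 100L, n = 200L, latentRank = 5L,
                          density = 0.05, noise = 0, signal = 2,
                          simInformative = TRUE, seed = 1L) {
  if (density <= 0 || density >= 1) stop("density must lie in (0, 1)")
  if (noise < 0 || noise >= 0.5) stop("noise must lie in [0, 0.5)")
  if (latentRank > min(m, n)) stop("latentRank must not exceed min(m, n)")
  if (signal <= 0) stop("signal must be positive")
  structure(list(m = as.integer(m), n = as.integer(n),
                 latentRank = as.integer(latentRank), density = density,
                 noise = noise, signal = signal,
                 simInformative = isTRUE(simInformative),
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

cosineRows <- function(U) {
  nrm <- sqrt(rowSums(U^2))
  C <- tcrossprod(U / pmax(nrm, 1e-12))
  pmin(pmax(C, -1), 1)
}

#' Generate a synthetic heterogeneous dataset
#'
#' Samples the latent-factor ground truth, realizes the association links,
#' and writes the four-column association file and three-column similarity
#' file in the dialects [readAssociations()] and [readSimilarity()] parse.
#'
#' @param spec a [syntheticSpec()].
#' @param dir output directory (created if needed).
#' @return list of class \code{syntheticData}: \code{spec}, \code{files}
#'   (assoc, sim), \code{truth} (U, E, bias, P, links, heldOut), and
#'   \code{graph}, the [buildHeteroGraph()] of the emitted files.
#' @export
generateSynthetic <- function(spec, dir = tempfile("synthetic")) {
  stopifnot(inherits(spec, "syntheticSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- spec$m; n <- spec$n; r <- spec$latentRank
  out <- withSeed(spec$seed, {
    U <- matrix(rnorm(m * r, sd = sqrt(spec$signal)), m, r)
    E <- matrix(rnorm(n * r, sd = sqrt(spec$signal)), n, r)
    logits <- tcrossprod(U, E)
    # bisection on the intercept: mean link probability = target density
    lo <- -50; hi <- 50
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (mean(plogis(logits + mid)) < spec$density) lo <- mid else hi <- mid
    }
    bias <- (lo + hi) / 2
    P <- plogis(logits + bias)
    links <- matrix(runif(m * n) < P, m, n)
    if (spec$noise > 0)
      links <- xor(links, matrix(runif(m * n) < spec$noise, m, n))
    sim <- if (spec$simInformative) pmax(cosineRows(U), 0) else {
      R <- matrix(runif(m * m), m, m)
      (R + t(R)) / 2
    }
    diag(sim) <- 1
    list(U = U, E = E, bias = bias, P = P, links = links, sim = sim)
  })
  if (!any(out$links))
    stop("infeasible density: no positive links realized")
  writeSyntheticFiles(spec, out, dir)
}

syntheticNames <- function(spec) {
  list(drug = sprintf("DRUG%04d", seq_len(spec$m)),
       id = sprintf("DB%05d", seq_len(spec$m)),
       effect = sprintf("effect_%04d", seq_len(spec$n)),
       cui = sprintf("C%07d", seq_len(spec$n)))
}

writeSyntheticFiles <- function(spec, out, dir, heldOut = NULL) {
  nm <- syntheticNames(spec)
  idx <- which(out$links, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  if (!is.null(heldOut)) {
    drop <- pairKey(idx) %in% pairKey(heldOut)
    idx <- idx[!drop, , drop = FALSE]
  }
  assoc <- data.frame(nm$id[idx[, 1L]], nm$drug[idx[, 1L]],
                      nm$cui[idx[, 2L]], nm$effect[idx[, 2L]])
  colnames(assoc) <- ASSOC_COLUMNS
  assocFile <- file.path(dir, "associations.tsv")
  write.table(assoc, assocFile, sep = "\t", quote = FALSE, row.names = FALSE)
  # only drugs that appear in the association file: the emitted pair of
  # files must round-trip through the readers with no dropped rows
  present <- sort(unique(idx[, 1L]))
  keepSim <- matrix(FALSE, nrow(out$sim), ncol(out$sim))
  keepSim[present, present] <- TRUE
  up <- which(upper.tri(out$sim) & out$sim > 0 & keepSim, arr.ind = TRUE)
  up <- up[order(up[, 1L], up[, 2L]), , drop = FALSE]
  simdf <- data.frame(drug1 = nm$drug[up[, 1L]], drug2 = nm$drug[up[, 2L]],
                      score = sprintf("%.10g", out$sim[up]))
  simFile <- file.path(dir, "semantic_similarity_drugs.tsv")
  write.table(simdf, simFile, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  graph <- buildHeteroGraph(readAssociations(assocFile),
                            readSimilarity(simFile))
  structure(list(spec = spec, dir = dir,
                 files = list(assoc = assocFile, sim = simFile),
                 truth = list(U = out$U, E = out$E, bias = out$bias,
                              P = out$P, links = out$links,
                              heldOut = heldOut),
                 graph = graph, raw = out),
            class = "syntheticData")
}

#' Hold out realized true links from an emitted dataset
#'
#' Removes \code{count} randomly chosen realized positive links from the
#' emitted association file (rewriting it) while recording them as
#' ground-truth ranking targets in \code{truth$heldOut}. The regenerated
#' graph no longer contains them.
#'
#' @param synth a \code{syntheticData} from [generateSynthetic()].
#' @param count number of links to hold out.
#' @param seed RNG seed for the selection.
#' @return updated \code{syntheticData}.
#' @export
holdoutTrueLinks <- function(synth, count, seed = 1L) {
  stopifnot(inherits(synth, "syntheticData"))
  if (count == 0L) return(synth)
  idx <- which(synth$raw$links, arr.ind = TRUE)
  if (count > nrow(idx))
    stop("cannot hold out ", count, " links: only ", nrow(idx), " realized")
  sel <- withSeed(seed, sample.int(nrow(idx), count))
  heldOut <- asPairMatrix(idx[sel, 1L], idx[sel, 2L])
  writeSyntheticFiles(synth$spec, synth$raw, synth$dir, heldOut = heldOut)
}
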