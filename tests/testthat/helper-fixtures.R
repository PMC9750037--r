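# Small graphs built in code, shared across test files.

# deduplicatable association table: 3 rows, one (drug, effect) duplicate
writeAssocFixture <- function(path, sep = "\t") {
  lines <- c(
    paste(c("drugbank_id", "drugbank name", "umls cui from meddra",
            "side_effect_name"), collapse = sep),
    paste(c("DB00001", "alphadrug", "C0001", "headache"), collapse = sep),
    paste(c("DB00001", "alphadrug", "C0001", "headache"), collapse = sep),
    paste(c("DB00002", "betadrug", "C0002", "nausea"), collapse = sep))
  writeLines(lines, path)
  path
}

# 2 drugs x 2 effects with positives {(a,x),(b,y)} and sim(a,b) = 0.8
tinyGraph <- function(simThreshold = 0) {
  assoc <- data.frame(
    drug_id = c("DB1", "DB2"), drug_name = c("adrug", "bdrug"),
    umls_cui = c("C1", "C2"), side_effect_name = c("xeffect", "yeffect"),
    stringsAsFactors = FALSE)
  sim <- data.frame(drug1 = "adrug", drug2 = "bdrug", score = 0.8,
                    stringsAsFactors = FALSE)
  buildHeteroGraph(assoc, sim, simThreshold = simThreshold)
}

# m x n graph with `npos` random positives and random similarity; every
# drug and effect is covered so the index maps span exactly [1,m] x [1,n]
randomGraph <- function(m = 20, n = 30, npos = 100, seed = 1,
                        simDensity = 0.3) {
  stopifnot(npos >= max(m, n))
  set.seed(seed)
  coverDrugs <- (seq_len(m) - 1) * n + ((seq_len(m) - 1) %% n) + 1
  coverEffects <- (sample(m, n, replace = TRUE) - 1) * n + seq_len(n)
  forced <- unique(c(coverDrugs, coverEffects))
  pool <- setdiff(seq_len(m * n), forced)
  extra <- if (npos > length(forced))
    sample(pool, npos - length(forced)) else integer()
  cells <- c(forced, extra)[seq_len(max(npos, length(forced)))]
  p <- (cells - 1) %/% n + 1
  q <- (cells - 1) %% n + 1
  assoc <- data.frame(
    drug_id = sprintf("DB%03d", p), drug_name = sprintf("drug%03d", p),
    umls_cui = sprintf("C%03d", q), side_effect_name = sprintf("eff%03d", q),
    stringsAsFactors = FALSE)
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < simDensity
  sim <- data.frame(drug1 = sprintf("drug%03d", pairs[keep, 1]),
                    drug2 = sprintf("drug%03d", pairs[keep, 2]),
                    score = round(runif(sum(keep)), 4),
                    stringsAsFactors = FALSE)
  buildHeteroGraph(assoc, sim)
}
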