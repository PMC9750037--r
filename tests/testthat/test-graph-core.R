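# Readers, graph construction, negative sampling and CV splitting.

test_that("association reader parses the four-column dialect and collapses duplicates", {
  f <- writeAssocFixture(tempfile(fileext = ".tsv"))
  tab <- suppressMessages(readAssociations(f))
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "duplicates_dropped"), 1L)
  expect_named(tab, c("drug_id", "drug_name", "umls_cui", "side_effect_name"))

  # comma dialect, auto-detected; header tolerant of case and underscores
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("DRUGBANK_ID,Drugbank Name,UMLS CUI from MedDRA,Side_Effect_Name",
               "DB1,a,C1,nausea"), f2)
  expect_equal(nrow(readAssociations(f2)), 1L)
})

test_that("association reader reports schema and empty-input errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("drugbank_id\tdrugbank name\tumls cui from meddra",
               "DB1\ta\tC1"), f)
  expect_error(readAssociations(f), "side_effect_name")
  f2 <- tempfile(fileext = ".tsv")
  writeLines("drugbank_id\tdrugbank name\tumls cui from meddra\tside_effect_name",
             f2)
  expect_error(readAssociations(f2), "empty")
  expect_error(readAssociations(tempfile()), "not found")
})

test_that("similarity reader normalizes pair order, keeps self-pairs, checks scores", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.8", "b\ta\t0.8", "a\ta\t1.0"), f)
  sim <- readSimilarity(f)
  expect_equal(nrow(sim), 2L)                       # {a,b} once + self-pair
  expect_equal(sim$score[sim$drug1 == "a" & sim$drug2 == "b"], 0.8)
  expect_true(any(sim$drug1 == sim$drug2))

  fBad <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.8", "a\tc\tx"), fBad)
  expect_error(readSimilarity(fBad), "row 2")

  fClamp <- tempfile(fileext = ".tsv")
  writeLines(sprintf("a\tb\t%.9f", 1 + 5e-7), fClamp)
  expect_warning(simC <- readSimilarity(fClamp), "clamped")
  expect_equal(simC$score, 1)
  fFar <- tempfile(fileext = ".tsv")
  writeLines("a\tb\t1.5", fFar)
  expect_error(readSimilarity(fFar), "outside")
})

test_that("graph construction thresholds similarity edges and drops unknown drugs", {
  g <- tinyGraph(simThreshold = 0.5)
  expect_equal(nDrugs(g), 2L)
  expect_equal(nEffects(g), 2L)
  expect_equal(nrow(positivePairs(g)), 2L)
  expect_equal(Matrix::nnzero(drugSimilarity(g)), 2L)  # one undirected edge
  expect_equal(drugSimilarity(g)[1, 2], 0.8)

  gHigh <- tinyGraph(simThreshold = 0.9)
  expect_equal(Matrix::nnzero(drugSimilarity(gHigh)), 0L)

  # similarity naming a foreign drug is dropped with a message
  assoc <- data.frame(drug_id = "DB1", drug_name = "adrug", umls_cui = "C1",
                      side_effect_name = "xeffect")
  sim <- data.frame(drug1 = "adrug", drug2 = "ghost", score = 0.9)
  expect_message(g2 <- buildHeteroGraph(assoc, sim), "dropped 1")
  expect_equal(Matrix::nnzero(drugSimilarity(g2)), 0L)

  expect_error(buildHeteroGraph(assoc[0, ], NULL), "empty graph")
})

test_that("similarity matrix is validated as symmetric and in [0, 1]", {
  g <- tinyGraph()
  bad <- g
  bad@similarity[1, 2] <- 0.9          # breaks symmetry
  expect_error(validObject(bad), "asymmetric")
})

# 3 drugs x 4 effects with exactly the 5 positives used in the worked
# complement enumeration
grid3x4 <- function() {
  p <- c(1, 1, 2, 2, 3); q <- c(1, 2, 2, 3, 4)
  buildHeteroGraph(data.frame(
    drug_id = sprintf("DB%d", p), drug_name = sprintf("drug%d", p),
    umls_cui = sprintf("C%d", q), side_effect_name = sprintf("eff%d", q)))
}

test_that("negative universe arithmetic is exact, including saturated and tiny graphs", {
  expect_identical(negativeUniverseSize(4245, 17671, 3766382), 71247013)
  g <- grid3x4()
  expect_equal(negativeUniverseSize(g), 3 * 4 - 5)
  expect_equal(negativeUniverseSize(g) + nrow(positivePairs(g)),
               nDrugs(g) * nEffects(g))
  expect_equal(negativeUniverseSize(2, 2, 4), 0)
})

test_that("negative sampling is uniform over the complement, seeded, capacity-checked", {
  g <- grid3x4()
  # asking for the whole 7-cell complement returns exactly the non-positive cells
  neg <- sampleNegatives(g, 7, seed = 5)
  allCells <- expand.grid(drug = 1:3, effect = 1:4)
  posKey <- paste(positivePairs(g)[, 1], positivePairs(g)[, 2])
  negKey <- paste(neg[, 1], neg[, 2])
  expect_setequal(negKey, setdiff(paste(allCells$drug, allCells$effect), posKey))

  expect_identical(sampleNegatives(g, 4, seed = 9),
                   sampleNegatives(g, 4, seed = 9))
  expect_error(sampleNegatives(g, 8, seed = 1), "only 7")

  # saturated 2x2 graph has an empty universe
  gSat <- randomGraph(m = 2, n = 2, npos = 4, seed = 3)
  expect_error(sampleNegatives(gSat, 1, seed = 1), "only 0")

  # exclude shrinks the universe
  neg2 <- sampleNegatives(g, 5, seed = 5, exclude = neg[1:2, , drop = FALSE])
  expect_false(any(paste(neg2[, 1], neg2[, 2]) %in% negKey[1:2]))
})

test_that("k-fold splits have the protocol shape and partition when testFraction = 1/k", {
  g <- randomGraph(m = 20, n = 20, npos = 100, seed = 4)
  splits <- kfoldSplits(g, k = 10, testFraction = 0.1, negRatio = 1, seed = 11)
  expect_length(splits, 10L)
  for (s in splits) {
    expect_equal(nrow(s@trainPos), 90L)
    expect_equal(nrow(s@testPos), 10L)
    expect_equal(nrow(s@trainNeg), 90L)
    expect_equal(nrow(s@testNeg), 10L)
    expect_true(validObject(s))
    # negatives disjoint from every positive of the graph
    posKey <- paste(positivePairs(g)[, 1], positivePairs(g)[, 2])
    expect_false(any(paste(s@trainNeg[, 1], s@trainNeg[, 2]) %in% posKey))
    expect_false(any(paste(s@testNeg[, 1], s@testNeg[, 2]) %in% posKey))
  }
  # the k test sets partition the positives exactly
  testKeys <- unlist(lapply(splits, function(s)
    paste(s@testPos[, 1], s@testPos[, 2])))
  expect_equal(sort(testKeys),
               sort(paste(positivePairs(g)[, 1], positivePairs(g)[, 2])))

  # partition also holds when k does not divide the positive count
  g2 <- randomGraph(m = 20, n = 20, npos = 97, seed = 6)
  splits2 <- kfoldSplits(g2, k = 10, testFraction = 1 / 10, seed = 3)
  keys2 <- unlist(lapply(splits2, function(s)
    paste(s@testPos[, 1], s@testPos[, 2])))
  expect_equal(sort(keys2),
               sort(paste(positivePairs(g2)[, 1], positivePairs(g2)[, 2])))

  # test fraction decoupled from k: 20% held out with k = 6 repetitions
  splits3 <- kfoldSplits(g, k = 6, testFraction = 0.2, seed = 2)
  expect_length(splits3, 6L)
  expect_true(all(vapply(splits3, function(s) nrow(s@testPos), 0L) == 20L))

  expect_error(kfoldSplits(g, k = 1), "at least 2")
  expect_error(kfoldSplits(g, k = 5, testFraction = 0), "strictly between")
})

test_that("association write/read round-trips deduplicated tables", {
  f <- writeAssocFixture(tempfile(fileext = ".tsv"))
  tab <- suppressMessages(readAssociations(f))
  f2 <- tempfile(fileext = ".tsv")
  writeAssociations(tab, f2)
  tab2 <- readAssociations(f2)
  attr(tab, "duplicates_dropped") <- NULL
  attr(tab2, "duplicates_dropped") <- NULL
  expect_identical(tab, tab2)
})

test_that("splits serialize to JSON lines carrying names, roles and labels", {
  g <- randomGraph(m = 5, n = 6, npos = 12, seed = 8)
  splits <- kfoldSplits(g, k = 3, testFraction = 1 / 3, seed = 2)
  f <- tempfile(fileext = ".jsonl")
  writeSplits(splits, g, f)
  rows <- lapply(readLines(f), jsonlite::fromJSON)
  expect_equal(length(rows), sum(vapply(splits, function(s)
    nrow(s@trainPos) + nrow(s@testPos) + nrow(s@trainNeg) + nrow(s@testNeg),
    0L)))
  expect_setequal(unique(vapply(rows, `[[`, "", "role")), c("train", "test"))
  expect_true(all(vapply(rows, `[[`, 0, "label") %in% c(0, 1)))
  expect_true(all(vapply(rows, `[[`, "", "drug") %in% drugNames(g)))
})
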