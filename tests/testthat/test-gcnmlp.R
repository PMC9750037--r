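# GCN encoder, scorer, training loop and ranked prediction.

smallGraph <- function() randomGraph(m = 8, n = 10, npos = 30, seed = 21)

smallConfig <- function(...) {
  args <- list(depth = 2L, hiddenDim = 8L, mlpHidden = 6L, epochs = 5L,
               seed = 3L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(gcnConfig, args)
}

test_that("configuration contracts are enforced", {
  expect_error(gcnConfig(hiddenDim = 0), "config error")
  expect_error(gcnConfig(depth = 0), "config error")
  expect_error(gcnConfig(learningRate = -1), "config error")
  expect_error(gcnConfig(scorer = "bilinear"))
  cfg <- gcnConfig(depth = 3)
  expect_equal(cfg$depth, 3L)
})

test_that("a trained model carries one weight triple per aggregation layer", {
  g <- smallGraph()
  model <- trainGcn(g, config = smallConfig(depth = 3L))
  expect_length(model@params$layers, 3L)
  for (L in model@params$layers) {
    expect_equal(dim(L$W), c(8, 8))
    expect_equal(dim(L$B), c(8, 8))
    expect_true(all(is.finite(L$W)) && all(is.finite(L$B)))
  }
  expect_true(all(is.finite(model@params$E)))
})

test_that("neighborhood aggregation computes mean plus elementwise max", {
  # star: node d1 linked to effects e1, e2 with hand-set features
  assoc <- data.frame(drug_id = c("D1", "D1"), drug_name = c("d1", "d1"),
                      umls_cui = c("C1", "C2"),
                      side_effect_name = c("e1", "e2"))
  g <- buildHeteroGraph(assoc, NULL)
  prop <- adrgraph:::buildPropagation(g, positivePairs(g))
  H <- rbind(c(5, 5), c(1, 0), c(0, 1))   # d1, e1, e2
  ag <- adrgraph:::aggregateTerm(prop, H)
  # d1 has neighbors (1,0) and (0,1): mean (0.5,0.5) + max (1,1) = (1.5,1.5)
  expect_equal(ag$A[1, ], c(1.5, 1.5))
  # each effect has the single neighbor d1: mean + max = 2 * h_d1
  expect_equal(ag$A[2, ], c(10, 10))
  expect_equal(ag$A[3, ], c(10, 10))
})

test_that("isolated nodes aggregate the zero vector", {
  g <- randomGraph(m = 4, n = 5, npos = 6, seed = 9, simDensity = 0)
  # restrict message passing to one edge so most nodes are isolated
  prop <- adrgraph:::buildPropagation(g, positivePairs(g)[1, , drop = FALSE])
  set.seed(1)
  H <- matrix(rnorm(9 * 3), 9, 3)
  ag <- adrgraph:::aggregateTerm(prop, H)
  touched <- c(positivePairs(g)[1, 1], 4 + positivePairs(g)[1, 2])
  expect_true(all(ag$A[-touched, ] == 0))
})

test_that("link scorers behave at their fixed points", {
  g <- smallGraph()
  model <- trainGcn(g, config = smallConfig(scorer = "dot"))
  # orthogonal representations score exactly 1/2 under the dot scorer
  H <- matrix(0, 18, 8)
  H[1, 1] <- 1; H[10, 2] <- 1
  sc <- adrgraph:::scorerForward(model@params, H, 1L, 10L, "dot")
  expect_equal(adrgraph:::sigmoid(sc$logit), 0.5)
  # h_i = h_j = (1,1,...) over two active dims gives sigmoid(2)
  H2 <- matrix(0, 18, 8)
  H2[1, 1:2] <- 1; H2[10, 1:2] <- 1
  sc2 <- adrgraph:::scorerForward(model@params, H2, 1L, 10L, "dot")
  expect_equal(adrgraph:::sigmoid(sc2$logit), 1 / (1 + exp(-2)))
  # MLP with zeroed output layer is indifferent: probability 1/2 everywhere
  m2 <- trainGcn(g, config = smallConfig())
  m2@params$scorer$w2[] <- 0
  m2@params$scorer$b2 <- 0
  probs <- scoreLinks(g, m2, positivePairs(g))$probability
  expect_true(all(probs == 0.5))
})

test_that("training is seeded-deterministic and frozen at zero learning rate", {
  g <- smallGraph()
  m1 <- trainGcn(g, config = smallConfig(epochs = 8L))
  m2 <- trainGcn(g, config = smallConfig(epochs = 8L))
  expect_identical(m1@loss, m2@loss)
  expect_identical(m1@params, m2@params)

  frozen <- trainGcn(g, config = smallConfig(learningRate = 0))
  init <- adrgraph:::initParams(
    18L, smallConfig(learningRate = 0),
    E0 = adrgraph:::initFeatures(g, positivePairs(g), 8L, 3L))
  expect_identical(frozen@params, init)
})

test_that("analytic gradients match finite differences", {
  g <- smallGraph()
  cfg <- smallConfig()
  prop <- adrgraph:::buildPropagation(g, positivePairs(g))
  params <- adrgraph:::initParams(prop$N, cfg)
  iIdx <- c(1L, 3L, 5L); jIdx <- c(9L, 12L, 15L); y <- c(1, 0, 1)
  lossFn <- function(p) {
    fw <- adrgraph:::gcnForward(p, prop)
    sc <- adrgraph:::scorerForward(p, fw$H, iIdx, jIdx, "mlp")
    adrgraph:::bceWithLogits(sc$logit, y)
  }
  fw <- adrgraph:::gcnForward(params, prop)
  sc <- adrgraph:::scorerForward(params, fw$H, iIdx, jIdx, "mlp")
  dlogit <- (adrgraph:::sigmoid(sc$logit) - y) / 3
  sb <- adrgraph:::scorerBackward(params, fw$H, iIdx, jIdx, "mlp", sc, dlogit)
  gb <- adrgraph:::gcnBackward(params, prop, fw$caches, sb$dH)
  numGrad <- function(setter) {
    eps <- 1e-6
    (lossFn(setter(params, eps)) - lossFn(setter(params, -eps))) / (2 * eps)
  }
  cases <- list(
    list(gb$E[2, 1], function(p, e) { p$E[2, 1] <- p$E[2, 1] + e; p }),
    list(gb$E[12, 5], function(p, e) { p$E[12, 5] <- p$E[12, 5] + e; p }),
    list(gb$layers[[1]]$W[1, 2],
         function(p, e) { p$layers[[1]]$W[1, 2] <- p$layers[[1]]$W[1, 2] + e; p }),
    list(gb$layers[[2]]$B[3, 1],
         function(p, e) { p$layers[[2]]$B[3, 1] <- p$layers[[2]]$B[3, 1] + e; p }),
    list(gb$layers[[1]]$b[2],
         function(p, e) { p$layers[[1]]$b[2] <- p$layers[[1]]$b[2] + e; p }),
    list(sb$scorer$W1[2, 3],
         function(p, e) { p$scorer$W1[2, 3] <- p$scorer$W1[2, 3] + e; p }),
    list(sb$scorer$w2[4, 1],
         function(p, e) { p$scorer$w2[4, 1] <- p$scorer$w2[4, 1] + e; p }),
    list(sb$scorer$b2, function(p, e) { p$scorer$b2 <- p$scorer$b2 + e; p }))
  for (cs in cases)
    expect_equal(cs[[1]], numGrad(cs[[2]]), tolerance = 1e-5)
})

test_that("encoding is equivariant to node relabeling", {
  # same structure under two drug orderings; permute h0 accordingly
  mkGraph <- function(names) {
    assoc <- data.frame(
      drug_id = c("D1", "D2", "D3"), drug_name = names,
      umls_cui = c("C1", "C2", "C2"),
      side_effect_name = c("e1", "e2", "e2"))
    sim <- data.frame(drug1 = names[1], drug2 = names[2], score = 0.6)
    buildHeteroGraph(assoc, sim)
  }
  g1 <- mkGraph(c("aaa", "bbb", "ccc"))   # sorted order = given order
  g2 <- mkGraph(c("zzz", "bbb", "ccc"))   # first drug sorts last
  perm <- c(3, 1, 2)                      # g1 drug i sits at perm[i] in g2
  prop1 <- adrgraph:::buildPropagation(g1, positivePairs(g1))
  prop2 <- adrgraph:::buildPropagation(g2, positivePairs(g2))
  cfg <- smallConfig(depth = 2L)
  set.seed(7)
  params1 <- adrgraph:::initParams(prop1$N, cfg)
  params2 <- params1
  fullPerm <- c(perm, 3 + 1:2)            # effects keep their order
  params2$E[fullPerm, ] <- params1$E
  H1 <- adrgraph:::gcnForward(params1, prop1)$H
  H2 <- adrgraph:::gcnForward(params2, prop2)$H
  expect_equal(H2[fullPerm, ], H1, tolerance = 1e-12)
})

test_that("training reduces the loss on the synthetic default structure", {
  synth <- generateSynthetic(syntheticSpec(m = 40, n = 60, density = 0.08,
                                           seed = 5))
  g <- synth$graph
  model <- trainGcn(g, config = gcnConfig(hiddenDim = 16L, mlpHidden = 16L,
                                          epochs = 60L, seed = 2L))
  expect_true(all(is.finite(model@loss)))
  expect_lt(model@loss[length(model@loss)], model@loss[1])
})

test_that("top-k prediction ranks, excludes known links, and handles exhaustion", {
  g <- smallGraph()
  model <- trainGcn(g, config = smallConfig())
  drug <- drugNames(g)[1]
  top <- predictTopK(model, g, drug, k = 5)
  expect_equal(nrow(top), 5L)
  expect_true(all(diff(top$probability) <= 0))
  expect_equal(top$rank, 1:5)
  known <- effectNames(g)[positivePairs(g)[positivePairs(g)[, 1] == 1, 2]]
  expect_false(any(top$side_effect_name %in% known))

  withKnown <- predictTopK(model, g, drug, k = 10, excludeKnown = FALSE)
  expect_equal(nrow(withKnown), 10L)

  expect_warning(predictTopK(model, g, drug, k = 50), "only")
  err <- tryCatch(predictTopK(model, g, "drug0x1"), error = conditionMessage)
  expect_match(err, "unknown drug")
  expect_match(err, "drug0")               # suggests near matches
})

test_that("model checkpoints round-trip through JSON", {
  g <- smallGraph()
  model <- trainGcn(g, config = smallConfig())
  f <- tempfile(fileext = ".json")
  saveGcnModel(model, f)
  back <- loadGcnModel(f)
  pairs <- positivePairs(g)
  expect_equal(scoreLinks(g, back, pairs)$probability,
               scoreLinks(g, model, pairs)$probability, tolerance = 1e-12)
  expect_identical(back@msgPairs, model@msgPairs)
  f2 <- tempfile(fileext = ".json")
  writeLines("{\"schema\":\"x\"}", f2)
  expect_error(loadGcnModel(f2), "schema")
})
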