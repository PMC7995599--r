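test_that("negative sampling draws distinct zero cells reproducibly", {
  a <- matrix(0, 4, 5, dimnames = list(sprintf("m%d", 1:4),
                                       sprintf("d%d", 1:5)))
  a[cbind(1:4, 1:4)] <- 1
  am <- AssociationMatrix(a)
  s1 <- sampleNegatives(am, ratio = 2, seed = 7)
  s2 <- sampleNegatives(am, ratio = 2, seed = 7)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 8)
  expect_false(anyDuplicated(paste(s1$miRNA, s1$disease)) > 0)
  expect_true(all(a[cbind(s1$miRNA, s1$disease)] == 0))

  dense <- AssociationMatrix(matrix(1, 2, 2,
                                    dimnames = list(c("a", "b"),
                                                    c("x", "y"))))
  expect_error(sampleNegatives(dense), "zero cells")
})

test_that("the node-embedding loss has its closed forms", {
  ## all logits zero: log(2) per sample
  expect_equal(nodeEmbeddingLoss(c(0, 0), c(0, 0)), log(2),
               tolerance = 1e-12)
  ## perfect separation drives the loss to zero
  expect_lt(nodeEmbeddingLoss(rep(40, 3), rep(-40, 3)), 1e-12)
  ## duplicating the batch leaves the mean unchanged
  sp <- c(1.2, -0.3); sn <- c(0.1, -2)
  expect_equal(nodeEmbeddingLoss(c(sp, sp), c(sn, sn)),
               nodeEmbeddingLoss(sp, sn), tolerance = 1e-12)
  expect_error(nodeEmbeddingLoss(numeric(), c(1)), "empty")
})

test_that("the total loss combines its components as stated", {
  expect_equal(totalLoss(0.2, 0.4, 0.1, 0.5), 0.45)
  expect_equal(totalLoss(1, 2, 3, 1), 3)       # lambda = 1 drops reg
  ## monotone in each component
  expect_gt(totalLoss(0.3, 0.4, 0.1, 0.5), totalLoss(0.2, 0.4, 0.1, 0.5))
  expect_error(totalLoss(1, 1, 1, 2))
})

test_that("the association score is a sigmoid head over the
          concatenation", {
  head0 <- list(w = numeric(6), b = 0)
  expect_equal(associationScore(rnorm(3), rnorm(3), head0), 0.5)
  headUp <- list(w = c(1, 0, 0, 0, 0, 0), b = 0)
  s1 <- associationScore(c(1, 0, 0), numeric(3), headUp)
  s2 <- associationScore(c(2, 0, 0), numeric(3), headUp)
  expect_gt(s2, s1)
})

test_that("training is seed-reproducible and a zero learning rate
          freezes the parameters", {
  b <- generatePlantedBenchmark(m = 6, n = 5, nBlocks = 2, pIn = 0.7,
                                pOut = 0.1, noise = 0, seed = 2)
  sims <- buildIntegratedSimilarity(b@assoc, b@dags, b@fs)
  cfg <- modelConfig(Z = 4, X = 4, K = 2, q = 0.2, hiddenPair = 6,
                     hiddenValidity = 4, epochs = 5, batchSize = 16,
                     lr = 0, k = 2, seed = 3)
  m0 <- trainModel(b@assoc, sims$SM, sims$SD, cfg)
  cfg0 <- cfg; cfg0$epochs <- 0
  mInit <- trainModel(b@assoc, sims$SM, sims$SD, cfg0)
  expect_identical(modelParams(m0), modelParams(mInit))

  cfg$lr <- 5e-3
  mA <- trainModel(b@assoc, sims$SM, sims$SD, cfg)
  mB <- trainModel(b@assoc, sims$SM, sims$SD, cfg)
  expect_identical(trainLog(mA), trainLog(mB))
  expect_identical(modelParams(mA), modelParams(mB))
})

test_that("a short smoke run reduces the total loss on a toy problem", {
  b <- generatePlantedBenchmark(m = 6, n = 5, nBlocks = 2, pIn = 0.7,
                                pOut = 0.05, noise = 0, seed = 4)
  sims <- buildIntegratedSimilarity(b@assoc, b@dags, b@fs)
  cfg <- modelConfig(Z = 6, X = 6, K = 2, q = 0, hiddenPair = 8,
                     hiddenValidity = 6, epochs = 50, batchSize = 32,
                     lr = 5e-3, weightDecay = 1e-4, k = 2, seed = 5)
  mod <- trainModel(b@assoc, sims$SM, sims$SD, cfg)
  lg <- trainLog(mod)
  expect_equal(nrow(lg), 50)
  expect_lt(lg$total[50], lg$total[1])
  ## trained model separates the classes it saw
  a <- assocMatrix(b)
  pos <- which(a == 1, arr.ind = TRUE)
  neg <- which(a == 0, arr.ind = TRUE)
  sp <- predictPairScores(mod, pos)
  sn <- predictPairScores(mod, neg)
  expect_gt(mean(sp), mean(sn))
})

test_that("candidate ranking respects the mode contracts", {
  b <- generatePlantedBenchmark(m = 8, n = 6, nBlocks = 2, pIn = 0.6,
                                pOut = 0.1, noise = 0, seed = 6)
  a <- assocMatrix(b)
  cfg <- modelConfig(Z = 4, X = 4, K = 2, q = 0, hiddenPair = 6,
                     hiddenValidity = 4, epochs = 3, batchSize = 32,
                     k = 2, seed = 7)
  target <- colnames(a)[1]
  rk <- rankCandidates(target, b@assoc, b@dags, b@fs, cfg)
  ## standard mode excludes confirmed pairs and ranks without gaps
  expect_true(all(a[cbind(rk$miRNA, rk$disease)] == 0))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$score) <= 0))

  ## new-disease mode: the target column contributes no MD edges
  a2 <- a; a2[, target] <- 0
  sims2 <- buildIntegratedSimilarity(AssociationMatrix(a2), b@dags, b@fs)
  net2 <- buildHetNet(AssociationMatrix(a2), sims2$SM, sims2$SD,
                      cfg$edgeRule, cfg$k)
  dIdx <- nrow(a) + match(target, colnames(a))
  md2 <- subset(netEdges(net2), type == "MD")
  expect_false(any(md2$from == dIdx | md2$to == dIdx))
  rkNew <- rankCandidates(target, b@assoc, b@dags, b@fs, cfg,
                          mode = "new_disease")
  expect_equal(nrow(rkNew), nrow(a))   # every miRNA is ranked

  expect_error(rankCandidates("nope", b@assoc, b@dags, b@fs, cfg),
               "unknown")
})
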