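test_that("variant-1 contributions match hand recursion", {
  solo <- DiseaseDAG("D")
  c0 <- d1Contributions(solo)
  expect_equal(c0$contrib, c(D = 1))
  expect_equal(c0$semanticValue, 1)

  chain <- DiseaseDAG("D", cbind(parent = c("A", "B"),
                                 child = c("B", "D")))
  cc <- d1Contributions(chain, delta = 0.5)
  expect_equal(unname(cc$contrib[c("D", "B", "A")]), c(1, 0.5, 0.25))
  expect_equal(cc$semanticValue, 1.75, tolerance = 1e-15)

  diamond <- DiseaseDAG("D", cbind(parent = c("A", "A", "B", "C"),
                                   child = c("B", "C", "D", "D")))
  cd <- d1Contributions(diamond, delta = 0.5)
  expect_equal(unname(cd$contrib["A"]), 0.25)
  expect_equal(cd$semanticValue, 2.25, tolerance = 1e-15)
})

test_that("variant-2 contributions follow the information-content form", {
  dags <- lapply(sprintf("D%02d", 1:10), function(d)
    DiseaseDAG(d, cbind(parent = "shared", child = d)))
  dc <- DAGCollection(dags)
  g <- d2Contributions(dc)
  expect_equal(unname(g["shared"]), 0)            # in all 10 DAGs
  expect_equal(unname(g["D01"]), -log(0.1), tolerance = 1e-12)

  two <- DAGCollection(list(DiseaseDAG("A"), DiseaseDAG("B")))
  g2 <- d2Contributions(two)
  expect_equal(unname(g2[c("A", "B")]), rep(-log(0.5), 2))
})

test_that("semantic similarity has the shared-ancestor closed forms", {
  chain <- DiseaseDAG("D", cbind(parent = "A", child = "D"))
  cD <- d1Contributions(chain)
  expect_equal(semanticSimilarity(cD, cD), 1)

  other <- d1Contributions(DiseaseDAG("E", cbind(parent = "F",
                                                 child = "E")))
  expect_equal(semanticSimilarity(cD, other), 0)

  di <- d1Contributions(DiseaseDAG("Di", cbind(parent = "A",
                                               child = "Di")))
  dj <- d1Contributions(DiseaseDAG("Dj", cbind(parent = "A",
                                               child = "Dj")))
  expect_equal(semanticSimilarity(di, dj), 1 / 3, tolerance = 1e-15)

  zero <- list(contrib = c(x = 0), semanticValue = 0)
  expect_error(semanticSimilarity(zero, zero), "zero")
})

test_that("contributions and pairwise similarity match the brute-force
          oracle on random DAGs", {
  set.seed(42)
  for (i in 1:200) {
    dag <- randomDag(sample(3:12, 1))
    mine <- d1Contributions(dag)
    orc <- oracleD1(dag)
    expect_lt(max(abs(mine$contrib[names(orc$contrib)] - orc$contrib)),
              1e-12)
  }
  ## pairwise similarity on random pairs, both variants' algebraic form
  set.seed(43)
  for (i in 1:50) {
    d1 <- randomDag(sample(3:10, 1), target = "T1")
    d2 <- randomDag(sample(3:10, 1), target = "T2")
    c1 <- d1Contributions(d1); c2 <- d1Contributions(d2)
    expect_equal(semanticSimilarity(c1, c2), oracleSS(c1, c2),
                 tolerance = 1e-12)
  }
})

test_that("combined semantic similarity averages both variants", {
  ## direct arithmetic-mean contract
  expect_equal((0.4 + 0.6) / 2, 0.5)
  set.seed(7)
  dc <- generateDagCollection(5, maxDepth = 3, branching = 2, seed = 7)
  ss <- simValues(combinedSemanticSimilarity(dc))
  expect_true(all(diag(ss) == 1))
  ## independent recomputation from the exported constituents
  g2 <- d2Contributions(dc)
  for (i in 1:4) for (j in (i + 1):5) {
    di <- dc[[i]]; dj <- dc[[j]]
    s1 <- oracleSS(oracleD1(di), oracleD1(dj))
    t2i <- list(contrib = g2[dagNodes(di)],
                semanticValue = sum(g2[dagNodes(di)]))
    t2j <- list(contrib = g2[dagNodes(dj)],
                semanticValue = sum(g2[dagNodes(dj)]))
    s2 <- if (t2i$semanticValue + t2j$semanticValue > 0)
      oracleSS(t2i, t2j) else 0
    expect_equal(ss[i, j], (s1 + s2) / 2, tolerance = 1e-12)
  }
})

test_that("variant-2 similarity is invariant to the logarithm base", {
  dc <- generateDagCollection(6, maxDepth = 3, seed = 11)
  gNat <- d2Contributions(dc)
  gTen <- gNat / log(10)    # -log10(x) = -ln(x)/ln(10)
  tab <- function(g, dag) list(contrib = g[dagNodes(dag)],
                               semanticValue = sum(g[dagNodes(dag)]))
  for (i in 1:5) for (j in (i + 1):6) {
    ti <- tab(gNat, dc[[i]]); tj <- tab(gNat, dc[[j]])
    ui <- tab(gTen, dc[[i]]); uj <- tab(gTen, dc[[j]])
    if (ti$semanticValue + tj$semanticValue > 0 &&
        ui$semanticValue + uj$semanticValue > 0)
      expect_equal(semanticSimilarity(ti, tj),
                   semanticSimilarity(ui, uj), tolerance = 1e-12)
  }
})

test_that("adding a shared ancestor never decreases similarity", {
  set.seed(13)
  for (i in 1:30) {
    d1 <- randomDag(sample(3:8, 1), target = "T1")
    d2 <- randomDag(sample(3:8, 1), target = "T2")
    before <- semanticSimilarity(d1Contributions(d1),
                                 d1Contributions(d2))
    addRoot <- function(dag) {
      root <- dagNodes(dag)[1L]   # first node is a source by construction
      DiseaseDAG(dagTarget(dag),
                 rbind(dagEdges(dag),
                       cbind(parent = "SHARED", child = root)))
    }
    after <- semanticSimilarity(d1Contributions(addRoot(d1)),
                                d1Contributions(addRoot(d2)))
    expect_gte(after, before - 1e-12)
  }
})

test_that("the Gaussian profile kernel matches its closed form", {
  p <- rbind(a = c(1, 0), b = c(0, 1))
  k <- simValues(gaussianProfileKernel(p, alpha0 = 1))
  expect_equal(unname(diag(k)), c(1, 1))
  expect_equal(k["a", "b"], exp(-2), tolerance = 1e-15)

  set.seed(21)
  q <- matrix(rbinom(40, 1, 0.4), 8)
  rownames(q) <- sprintf("r%d", 1:8)
  kq <- simValues(gaussianProfileKernel(q))
  expect_lt(max(abs(kq - t(kq))), 1e-15)
  expect_true(all(kq >= 0 & kq <= 1))

  ## permutation consistency
  perm <- sample(8)
  kp <- simValues(gaussianProfileKernel(q[perm, ]))
  expect_equal(kp, kq[perm, perm], tolerance = 1e-15)

  expect_error(gaussianProfileKernel(matrix(0, 2, 3)), "bandwidth")
})

test_that("similarity integration selects by mask entrywise", {
  nm <- letters[1:3]
  p <- matrix(0.8, 3, 3, dimnames = list(nm, nm)); diag(p) <- 1
  f <- matrix(0.2, 3, 3, dimnames = list(nm, nm)); diag(f) <- 1
  P <- SimilarityMatrix(p); F <- SimilarityMatrix(f)
  expect_equal(simValues(integrateSimilarity(P, F, matrix(TRUE, 3, 3))), p)
  expect_equal(simValues(integrateSimilarity(P, F, matrix(FALSE, 3, 3))), f)
  mask <- matrix(c(TRUE, FALSE, TRUE,
                   FALSE, TRUE, TRUE,
                   TRUE, TRUE, FALSE), 3, byrow = TRUE)
  mask <- mask | t(mask); mask <- mask & t(mask)
  got <- simValues(integrateSimilarity(P, F, mask))
  expect_equal(got, ifelse(mask, p, f), ignore_attr = TRUE)
  f2 <- SimilarityMatrix(matrix(1, 2, 2,
                                dimnames = list(nm[1:2], nm[1:2])))
  expect_error(integrateSimilarity(P, f2, mask), "share")
})

test_that("integrated SD/SM networks have unit diagonal and valid range", {
  b <- generatePlantedBenchmark(m = 12, n = 10, nBlocks = 2, seed = 5)
  sims <- buildIntegratedSimilarity(b@assoc, b@dags, b@fs)
  for (s in sims) {
    v <- simValues(s)
    expect_true(all(abs(diag(v) - 1) < 1e-12))
    expect_true(all(v >= 0 & v <= 1 + 1e-12))
    expect_lt(max(abs(v - t(v))), 1e-9)
  }
})
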