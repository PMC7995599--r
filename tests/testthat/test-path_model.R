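zeroGru <- function(Z, X, q = 0) {
  list(Wzx = matrix(0, Z, X), Wrx = matrix(0, Z, X),
       Whx = matrix(0, Z, X), Wzh = matrix(0, X, X),
       Wrh = matrix(0, X, X), Whh = matrix(0, X, X),
       bz = numeric(X), br = numeric(X), bh = numeric(X), q = q)
}

randGru <- function(Z, X, q = 0, seed = 1) {
  set.seed(seed)
  p <- zeroGru(Z, X, q)
  for (nm in c("Wzx", "Wrx", "Whx"))
    p[[nm]] <- matrix(rnorm(Z * X, sd = 0.5), Z, X)
  for (nm in c("Wzh", "Wrh", "Whh"))
    p[[nm]] <- matrix(rnorm(X * X, sd = 0.5), X, X)
  for (nm in c("bz", "br", "bh")) p[[nm]] <- rnorm(X, sd = 0.2)
  p
}

## manual recursion of the gate equations for one step
manualStep <- function(x, h, p, evalScale = 1) {
  sg <- function(v) 1 / (1 + exp(-v))
  z <- sg(as.numeric(x %*% p$Wzx) + as.numeric(h %*% p$Wzh) + p$bz)
  r <- sg(as.numeric(x %*% p$Wrx) + as.numeric(h %*% p$Wrh) + p$br)
  g <- tanh(as.numeric(x %*% p$Whx) + as.numeric((r * h) %*% p$Whh) +
            p$bh)
  z * h + (1 - z) * evalScale * g
}

test_that("the GRU step follows its gate equations", {
  ## all-zero parameters: gates 0.5, candidate 0, state stays 0
  p <- zeroGru(2, 2)
  expect_equal(gruStep(c(1, 1), c(0, 0), p), c(0, 0))

  ## a huge update-gate bias freezes the state
  p2 <- zeroGru(2, 2)
  p2$bz <- c(50, 50)
  h <- c(0.3, -0.4)
  expect_equal(gruStep(c(1, 2), h, p2), h, tolerance = 1e-12)

  ## eval mode with q = 0.5 scales the update term by (1 - q)
  p3 <- randGru(2, 2, q = 0.5, seed = 4)
  h0 <- c(0.1, 0.2); x <- c(1, -1)
  expect_equal(gruStep(x, h0, p3, train = FALSE),
               manualStep(x, h0, p3, evalScale = 0.5), tolerance = 1e-12)
})

test_that("instance encoding matches step-by-step manual recursion", {
  p <- randGru(2, 2, seed = 8)
  feats <- rbind(c(0.5, -1), c(1, 0.2), c(-0.3, 0.8))
  enc <- encodeInstance(feats, p)
  h <- c(0, 0)
  for (t in 1:3) {
    h <- manualStep(feats[t, ], h, p)
    expect_equal(enc[t, ], h, tolerance = 1e-12)
  }
  ## determinism in eval mode
  expect_identical(enc, encodeInstance(feats, p))
  expect_error(encodeInstance(feats[0, , drop = FALSE], p), "empty")
})

test_that("GRU states stay bounded without dropout", {
  p <- randGru(3, 3, seed = 9)
  h <- rnorm(3)
  for (i in 1:20) {
    h2 <- gruStep(rnorm(3), h, p)
    expect_lte(max(abs(h2)), max(max(abs(h)), 1) + 1e-12)
    h <- h2
  }
})

test_that("attentive pooling reduces to the expected special cases", {
  M <- matrix(rnorm(6), 3, 2)
  ## single row: softmax of a singleton is 1 for any M, K
  h1 <- matrix(c(1, -2, 0.5), 1)
  expect_equal(attentivePool(h1, M), as.numeric(h1))
  ## equal logits: arithmetic mean of the rows
  h2 <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 2, 1))
  Mz <- matrix(0, 3, 2)
  expect_equal(attentivePool(h2, Mz), colMeans(h2))
  ## K = 1 equals the single-head definition
  set.seed(5)
  h3 <- matrix(rnorm(12), 4)
  m1 <- matrix(rnorm(3), 3, 1)
  lg <- as.numeric(h3 %*% m1)
  a <- exp(lg - max(lg)); a <- a / sum(a)
  expect_equal(attentivePool(h3, m1), colSums(a * h3), tolerance = 1e-12)
})

test_that("instance fusion weights are softmax-normalized and the single
          case is the sigmoid", {
  att <- c(0.5, -1)
  single <- list(c(0.3, 0.7))
  expect_equal(fuseInstances(single, att),
               1 / (1 + exp(-single[[1]])), tolerance = 1e-12)
  ## all contributions clamped to zero -> uniform weights
  pooled <- list(c(-1, 0), c(-2, 0), c(-3, 0))
  attNeg <- c(1, 0)   # att . h^p < 0 for all
  mean3 <- Reduce(`+`, pooled) / 3
  expect_equal(fuseInstances(pooled, attNeg),
               1 / (1 + exp(-mean3)), tolerance = 1e-12)
  expect_error(fuseInstances(list(), att), "empty")
})

test_that("type fusion is a softmax-weighted sum with hand-checkable
          two-type case", {
  v1 <- c(0.2, 0.8); v2 <- c(0.9, 0.1)
  atts <- list(A = c(1, 0), B = c(0, 1))
  w1 <- max(0, sum(atts$A * v1)); w2 <- max(0, sum(atts$B * v2))
  sm <- exp(c(w1, w2)); sm <- sm / sum(sm)
  expect_equal(fuseTypes(list(A = v1, B = v2), atts),
               sm[1] * v1 + sm[2] * v2, tolerance = 1e-12)
  ## singleton: identity
  expect_equal(fuseTypes(list(A = v1), atts), v1)
  ## empty map: zero vector of the requested width
  expect_equal(fuseTypes(list(), atts, X = 2), c(0, 0))
})

test_that("instance order within a type does not change the fused
          embedding", {
  set.seed(17)
  pooled <- lapply(1:5, function(i) rnorm(3))
  att <- rnorm(3)
  ref <- fuseInstances(pooled, att)
  for (i in 1:5) {
    perm <- sample(5)
    expect_equal(fuseInstances(pooled[perm], att), ref,
                 tolerance = 1e-12)
  }
})
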