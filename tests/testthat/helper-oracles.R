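## Independent oracles and fixture builders shared across the suite.
## All oracles are deliberately naive (plain recursion / exhaustive
## enumeration) and never call the code paths they check.

## --- disease DAG generators -----------------------------------------------

## random DAG with <= nNodes nodes: nodes are laid out in a random
## topological order ending at the target, each non-target node gets >= 1
## child drawn from later positions
randomDag <- function(nNodes, target = "T", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- max(2L, nNodes)
  nodes <- c(sprintf("n%02d", seq_len(n - 1L)), target)
  edges <- NULL
  for (i in seq_len(n - 1L)) {
    cand <- seq(i + 1L, n)
    kids <- cand[sample.int(length(cand),
                            min(sample.int(2L, 1L), length(cand)))]
    edges <- rbind(edges, cbind(parent = nodes[i], child = nodes[kids]))
  }
  DiseaseDAG(target, edges, nodes)
}

## --- semantic similarity oracles ------------------------------------------

## memoization-free exhaustive recursion for the variant-1 contribution
oracleD1 <- function(dag, delta = 0.5) {
  edges <- dagEdges(dag)
  tgt <- dagTarget(dag)
  rec <- function(d) {
    if (d == tgt) return(1)
    kids <- edges[edges[, "parent"] == d, "child"]
    max(vapply(kids, function(k) delta * rec(k), numeric(1)))
  }
  contrib <- vapply(dagNodes(dag), rec, numeric(1))
  list(contrib = contrib, semanticValue = sum(contrib))
}

oracleSS <- function(ci, cj) {
  shared <- intersect(names(ci$contrib), names(cj$contrib))
  (sum(ci$contrib[shared]) + sum(cj$contrib[shared])) /
    (ci$semanticValue + cj$semanticValue)
}

## --- meta-path enumeration oracle -----------------------------------------

## plain recursive DFS over bounded walks; revisit policy as flagged
oracleMetaPaths <- function(net, r, d, lMax, allowRevisit = FALSE,
                            mdIntermediate = TRUE) {
  nodeNames <- net@nodeNames
  ri <- match(r, nodeNames); di <- match(d, nodeNames)
  adjOf <- function(v) net@adj[[v]]
  found <- list()
  dfs <- function(path) {
    last <- path[length(path)]
    if (length(path) > 1L && last == di) {
      tys <- net@nodeType[path]
      ok <- mdIntermediate ||
        !any(tys[-length(tys)] == "D" & tys[-1L] == "M")
      if (ok)
        found[[length(found) + 1L]] <<- list(
          nodes = nodeNames[path], length = length(path) - 1L,
          type = paste(tys, collapse = ","))
    }
    if (length(path) - 1L >= lMax) return()
    for (nb in adjOf(last)) {
      if (!allowRevisit && nb %in% path) next
      dfs(c(path, nb))
    }
  }
  dfs(ri)
  ## deterministic order: length, then lexicographic node sequence
  if (!length(found)) return(found)
  key <- vapply(found, function(x)
    sprintf("%02d|%s", x$length, paste(x$nodes, collapse = "\r")),
    character(1))
  found[order(key)]
}

## random typed network with nM miRNAs / nD diseases and edge density p
randomHetNet <- function(nM, nD, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nv <- nM + nD
  nodeNames <- c(sprintf("m%d", seq_len(nM)), sprintf("d%d", seq_len(nD)))
  nodeType <- c(rep("M", nM), rep("D", nD))
  cand <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
  sel <- cand[stats::runif(nrow(cand)) < p, , drop = FALSE]
  tp <- paste0(nodeType[sel[, 1]], nodeType[sel[, 2]])
  tp[tp == "DM"] <- "MD"
  edges <- data.frame(from = sel[, 1], to = sel[, 2], type = tp,
                      weight = 1)
  mdembed:::.makeHetNet(nodeNames, nodeType, edges)
}

## --- AUC oracle ------------------------------------------------------------

## exhaustive pairwise comparison with half-credit ties
oracleAUC <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

## --- tiny training setup ---------------------------------------------------

## small planted problem + everything needed to call the engine directly
tinySetup <- function(seed = 5, cfg = NULL) {
  b <- generatePlantedBenchmark(m = 8, n = 6, nBlocks = 2, pIn = 0.6,
                                pOut = 0.1, noise = 0, seed = 3)
  if (is.null(cfg))
    cfg <- modelConfig(Z = 3, X = 3, K = 2, q = 0, hiddenPair = 4,
                       hiddenValidity = 3, lMax = 3, k = 2, epochs = 0,
                       weightDecay = 1e-3, seed = seed)
  sims <- buildIntegratedSimilarity(b@assoc, b@dags, b@fs)
  a <- assocMatrix(b@assoc)
  net <- buildHetNet(b@assoc, sims$SM, sims$SD, cfg$edgeRule, cfg$k)
  pc <- mdembed:::.buildPathCache(net, cfg)
  fd <- list(SM = simValues(sims$SM), SD = simValues(sims$SD),
             m = nrow(a), n = ncol(a))
  set.seed(seed)
  params <- initModelParams(cfg, nrow(a), ncol(a))
  pos <- which(a == 1, arr.ind = TRUE)
  r <- pos[1:6, 1]; d <- pos[1:6, 2]; y <- c(1, 1, 1, 0, 0, 0)
  asm <- mdembed:::.assembleBatch(pc, r, d, nrow(a))
  list(b = b, cfg = cfg, sims = sims, a = a, net = net, pc = pc,
       fd = fd, params = params,
       batch = list(r = r, d = d, y = y, groups = asm$groups))
}

## norm-based relative error between analytic and numerical gradients
gradRelErr <- function(params, fd, batch, cfg) {
  fb <- mdembed:::.forwardBackward(params, fd, batch, cfg,
                                   train = TRUE, wantGrads = TRUE)
  h <- 1e-5
  worst <- 0
  for (nm in names(params)) {
    p <- params[[nm]]
    gnum <- p * 0
    for (i in seq_along(p)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      up <- mdembed:::.forwardBackward(pp, fd, batch, cfg,
                                       train = TRUE, wantGrads = FALSE)$total
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h
      dn <- mdembed:::.forwardBackward(pp, fd, batch, cfg,
                                       train = TRUE, wantGrads = FALSE)$total
      gnum[i] <- (up - dn) / (2 * h)
    }
    ga <- fb$grads[[nm]]
    re <- sqrt(sum((gnum - ga)^2)) /
      max(sqrt(sum(gnum^2)) + sqrt(sum(ga^2)), 1e-8)
    worst <- max(worst, re)
  }
  worst
}
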