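## Synthetic fixtures: a hand-checked toy network for enumeration
## regression, random layered DAG collections emulating MeSH ancestor
## structure, and the planted block-structured benchmark that stands in
## for the HMDD / MeSH / functional-similarity inputs.

#' Hand-checked toy heterogeneous network
#'
#' A fixed 4-miRNA / 4-disease network with all three edge types and,
#' for the designated confirmed pair (m2, d2), the hand-enumerated set
#' of meta-path instances up to length 3. Used as the enumeration
#' regression fixture; identical across runs.
#'
#' @return list with \code{net} (a \linkS4class{HetNet}), \code{pair}
#'   (miRNA, disease names) and \code{expected} (instance list in the
#'   deterministic output order of \code{\link{enumerateMetaPaths}}).
#' @export
makeToyNetworkFixture <- function() {
  nodeNames <- c("m1", "m2", "m3", "m4", "d1", "d2", "d3", "d4")
  nodeType <- c(rep("M", 4), rep("D", 4))
  ed <- function(a, b, type) data.frame(
    from = match(a, nodeNames), to = match(b, nodeNames),
    type = type, weight = 1)
  edges <- rbind(
    ed("m1", "d1", "MD"), ed("m2", "d2", "MD"), ed("m2", "d1", "MD"),
    ed("m3", "d2", "MD"), ed("m4", "d4", "MD"),
    ed("m1", "m2", "MM"), ed("m2", "m3", "MM"),
    ed("d1", "d2", "DD"), ed("d2", "d3", "DD"), ed("d1", "d4", "DD"))
  net <- .makeHetNet(nodeNames, nodeType, edges)
  ## hand enumeration for (m2, d2), simple paths, <= 3 edges:
  ##   length 1: m2-d2
  ##   length 2: m2-d1-d2, m2-m3-d2
  ##   length 3: m2-m1-d1-d2
  expected <- list(
    list(nodes = c("m2", "d2"), length = 1L, type = "M,D"),
    list(nodes = c("m2", "d1", "d2"), length = 2L, type = "M,D,D"),
    list(nodes = c("m2", "m3", "d2"), length = 2L, type = "M,M,D"),
    list(nodes = c("m2", "m1", "d1", "d2"), length = 3L,
         type = "M,M,D,D"))
  list(net = net, pair = c("m2", "d2"), expected = expected)
}

#' Generate a random layered DAG collection
#'
#' Emulates MeSH ancestor structure: diseases draw ancestor chains from
#' a shared layered pool (one node pool per depth level), so distinct
#' diseases share ancestors and semantic similarities are non-trivial.
#' \code{maxDepth = 1} yields target-only DAGs. Acyclic by construction
#' (edges only point from shallower to deeper layers).
#'
#' @param nDiseases number of diseases (>= 2).
#' @param maxDepth maximum chain depth including the target.
#' @param branching ancestor pool size per layer.
#' @param seed integer seed.
#' @param diseaseNames optional disease names.
#' @return a \linkS4class{DAGCollection}
#' @export
generateDagCollection <- function(nDiseases, maxDepth = 3, branching = 2,
                                  seed = 1,
                                  diseaseNames = sprintf("dis-%03d",
                                                         seq_len(nDiseases))) {
  stopifnot(nDiseases >= 2, maxDepth >= 1)
  set.seed(seed)
  dags <- lapply(diseaseNames, function(d) {
    depth <- sample.int(maxDepth, 1L)
    if (depth == 1L) return(DiseaseDAG(d))
    anc <- vapply(seq_len(depth - 1L), function(l)
      sprintf("anc-%d-%d", l, sample.int(branching, 1L)), character(1))
    chain <- c(anc, d)
    edges <- cbind(parent = chain[-length(chain)], child = chain[-1L])
    DiseaseDAG(d, edges)
  })
  DAGCollection(dags)
}

#' Generate the planted block-structured benchmark
#'
#' miRNAs and diseases are split into matched blocks. Associations are
#' Bernoulli(pIn) within matched blocks and Bernoulli(pOut) otherwise,
#' then a \code{noise} fraction of cells is flipped. Functional
#' similarity is high within miRNA blocks and low between, with a
#' random fraction of pairs left undefined (entry 0) so both branches
#' of the similarity integration are exercised. Disease DAGs share a
#' global root plus block-specific ancestor chains, so semantic
#' similarity is high within disease blocks. Regeneration under the
#' same seed is bitwise identical.
#'
#' @param m,n miRNA and disease counts.
#' @param nBlocks number of matched blocks.
#' @param pIn,pOut within- / between-block association probabilities
#'   (pIn > pOut required).
#' @param noise fraction of association cells flipped.
#' @param seed integer seed.
#' @param fsDefinedFrac fraction of miRNA pairs with defined functional
#'   similarity.
#' @return a \linkS4class{PlantedBenchmark}
#' @export
generatePlantedBenchmark <- function(m = 60, n = 40, nBlocks = 4,
                                     pIn = 0.35, pOut = 0.02,
                                     noise = 0.01, seed = 1,
                                     fsDefinedFrac = 0.7) {
  if (pIn <= pOut) stop("pIn must exceed pOut", call. = FALSE)
  stopifnot(m >= nBlocks, n >= nBlocks)
  set.seed(seed)
  mirNames <- sprintf("mir-%03d", seq_len(m))
  disNames <- sprintf("dis-%03d", seq_len(n))
  mirBlock <- sort(rep_len(seq_len(nBlocks), m))
  disBlock <- sort(rep_len(seq_len(nBlocks), n))

  probs <- ifelse(outer(mirBlock, disBlock, `==`), pIn, pOut)
  a <- matrix(as.numeric(stats::runif(m * n) < probs), m, n,
              dimnames = list(mirNames, disNames))
  if (noise > 0) {
    flip <- stats::runif(m * n) < noise
    a[flip] <- 1 - a[flip]
  }

  ## functional similarity: block structure + undefined pairs
  fs <- matrix(0, m, m, dimnames = list(mirNames, mirNames))
  same <- outer(mirBlock, mirBlock, `==`)
  up <- upper.tri(fs)
  vals <- ifelse(same[up],
                 0.75 + stats::runif(sum(up), -0.15, 0.15),
                 0.10 + stats::runif(sum(up), 0, 0.15))
  defined <- stats::runif(sum(up)) < fsDefinedFrac
  vals[!defined] <- 0
  fs[up] <- pmin(pmax(vals, 0), 1)
  fs <- fs + t(fs)
  diag(fs) <- 1

  ## disease DAGs: global root + block ancestor chain
  dags <- lapply(seq_len(n), function(j) {
    b <- disBlock[j]
    depth <- sample(2:3, 1L)
    anc <- c("root", sprintf("blk%d-anc%d", b, seq_len(depth - 1L)))
    chain <- c(anc, disNames[j])
    DiseaseDAG(disNames[j],
               cbind(parent = chain[-length(chain)], child = chain[-1L]))
  })

  new("PlantedBenchmark",
      assoc = AssociationMatrix(a),
      fs = SimilarityMatrix(fs),
      dags = DAGCollection(dags),
      mirnaBlock = stats::setNames(as.integer(mirBlock), mirNames),
      diseaseBlock = stats::setNames(as.integer(disBlock), disNames),
      noise = noise, seed = as.integer(seed))
}

#' Write a benchmark to the standard input files
#'
#' Emits the three input files in the package's file dialects:
#' \code{pairs.tsv} (2-column association pairs), \code{dags.tsv}
#' (3-column DAG edge list, with node-only rows for root-only DAGs) and
#' \code{fs.tsv} (dense functional similarity). Entities with no
#' associations do not appear in the pair file.
#'
#' @param bench a \linkS4class{PlantedBenchmark}.
#' @param dir output directory (created if missing).
#' @return named character vector of the three paths, invisibly.
#' @export
writeBenchmarkFiles <- function(bench, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- positivePairs(bench@assoc)
  pairsPath <- file.path(dir, "pairs.tsv")
  utils::write.table(pp, pairsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  dagRows <- do.call(rbind, lapply(bench@dags@dags, function(dg) {
    e <- dagEdges(dg)
    if (!nrow(e))
      data.frame(disease = dagTarget(dg), parent = ".", child = ".")
    else
      data.frame(disease = dagTarget(dg), parent = e[, "parent"],
                 child = e[, "child"])
  }))
  dagsPath <- file.path(dir, "dags.tsv")
  utils::write.table(dagRows, dagsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fsPath <- file.path(dir, "fs.tsv")
  writeSimilarityMatrix(bench@fs, fsPath)
  invisible(c(pairs = pairsPath, dags = dagsPath, fs = fsPath))
}
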