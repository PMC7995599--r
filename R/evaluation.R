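## Global LOOCV, repeated k-fold cross-validation, and Mann-Whitney AUC.

#' Mann-Whitney AUC of scores against binary labels
#'
#' Probability that a random positive outscores a random negative, with
#' half-credit for ties (computed via average ranks).
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

## derive a fold-specific training seed below 2^31
.foldSeed <- function(seed, rep, fold)
  as.integer((seed + 7919 * rep + 104729 * fold) %% 2147483647)

## train on a zeroed-out copy of A and score the requested cells
.trainAndScore <- function(aTrain, dags, fs, config, cells) {
  assocT <- AssociationMatrix(aTrain)
  sims <- buildIntegratedSimilarity(assocT, dags, fs,
                                    config$delta, config$alpha0)
  model <- trainModel(assocT, sims$SM, sims$SD, config)
  predictPairScores(model, cells)
}

#' Repeated k-fold cross-validation
#'
#' Positives are partitioned randomly into k near-equal groups per
#' repeat; each group is held out once, zeroed from the training matrix
#' before similarity computation, network construction, meta-path
#' extraction and training (leakage-safe), and scored together with all
#' unconfirmed pairs of the full matrix. One Mann-Whitney AUC per fold.
#'
#' @param assoc an \linkS4class{AssociationMatrix} (full data).
#' @param dags a \linkS4class{DAGCollection}.
#' @param fs optional functional \linkS4class{SimilarityMatrix}.
#' @param config a \code{\link{modelConfig}} list; each fold trains
#'   under a seed derived from \code{seed}, the repeat and the fold.
#' @param k fold count (>= 2, <= positive count).
#' @param repeats repeat count.
#' @param seed integer seed for the partitions.
#' @return a \linkS4class{CVReport}
#' @export
kfoldCV <- function(assoc, dags, fs = NULL, config = benchmarkConfig(),
                    k = 5, repeats = 1, seed = 1) {
  a <- assocMatrix(assoc)
  pos <- which(a == 1)
  np <- length(pos)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > np) stop("more folds than positives", call. = FALSE)
  set.seed(seed)
  folds <- replicate(repeats, sample(rep_len(seq_len(k), np)),
                     simplify = FALSE)
  neg <- which(a == 0)
  negCells <- cbind((neg - 1L) %% nrow(a) + 1L,
                    (neg - 1L) %/% nrow(a) + 1L)
  aucs <- numeric(0)
  for (rep0 in seq_len(repeats)) {
    for (f in seq_len(k)) {
      held <- pos[folds[[rep0]] == f]
      aTrain <- a
      aTrain[held] <- 0
      heldCells <- cbind((held - 1L) %% nrow(a) + 1L,
                         (held - 1L) %/% nrow(a) + 1L)
      cfg <- config
      cfg$seed <- .foldSeed(seed, rep0, f)
      sc <- .trainAndScore(aTrain, dags, fs, cfg,
                           rbind(heldCells, negCells))
      lab <- c(rep(1, nrow(heldCells)), rep(0, nrow(negCells)))
      aucs <- c(aucs, aucScore(sc, lab))
    }
  }
  new("CVReport", scheme = "kfold", folds = as.integer(k),
      repeats = as.integer(repeats), aucs = aucs, seed = as.integer(seed))
}

#' Global leave-one-out cross-validation (block-scaled)
#'
#' Every verified pair in the evaluation set is held out and ranked,
#' under the model trained without it, against all unconfirmed pairs of
#' the full matrix; the report carries one AUC entry per held-out
#' positive. Retraining once per held-out pair is quadratic in the data,
#' so held-out positives are grouped into \code{blocks} disjoint blocks
#' and the model is retrained once per block with the whole block
#' zeroed; each held-out pair is still scored by a model that never saw
#' it. \code{nHeldOut} restricts evaluation to a random subsample of
#' positives.
#'
#' @param assoc,dags,fs,config as in \code{\link{kfoldCV}}.
#' @param nHeldOut optional number of positives to evaluate
#'   (default: all).
#' @param blocks retraining block count.
#' @param seed integer seed (subsample, blocks, fold seeds).
#' @return a \linkS4class{CVReport} with one AUC per held-out positive.
#' @export
globalLOOCV <- function(assoc, dags, fs = NULL,
                        config = benchmarkConfig(), nHeldOut = NULL,
                        blocks = 5, seed = 1) {
  a <- assocMatrix(assoc)
  pos <- which(a == 1)
  set.seed(seed)
  if (!is.null(nHeldOut) && nHeldOut < length(pos))
    pos <- sample(pos, nHeldOut)
  blocks <- min(blocks, length(pos))
  assign0 <- sample(rep_len(seq_len(blocks), length(pos)))
  neg <- which(a == 0)
  negCells <- cbind((neg - 1L) %% nrow(a) + 1L,
                    (neg - 1L) %/% nrow(a) + 1L)
  aucs <- numeric(0)
  for (b in seq_len(blocks)) {
    held <- pos[assign0 == b]
    aTrain <- a
    aTrain[held] <- 0
    heldCells <- cbind((held - 1L) %% nrow(a) + 1L,
                       (held - 1L) %/% nrow(a) + 1L)
    cfg <- config
    cfg$seed <- .foldSeed(seed, 1L, b)
    sc <- .trainAndScore(aTrain, dags, fs, cfg,
                         rbind(heldCells, negCells))
    sPos <- sc[seq_len(nrow(heldCells))]
    sNeg <- sc[-seq_len(nrow(heldCells))]
    aucs <- c(aucs, vapply(sPos, function(sp)
      (sum(sNeg < sp) + 0.5 * sum(sNeg == sp)) / length(sNeg),
      numeric(1)))
  }
  new("CVReport", scheme = "loocv", folds = length(aucs),
      repeats = 1L, aucs = aucs, seed = as.integer(seed))
}
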