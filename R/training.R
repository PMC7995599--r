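## Loss assembly, negative sampling, the Adam training loop, and ranked
## prediction.

.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Negative-sampling loss of the node-embedding branch
#'
#' Standard negative-sampling binary cross-entropy over pre-sigmoid
#' logits: \code{-log sigma(s)} for positive pairs and
#' \code{-log sigma(-s)} for sampled negatives, mean-normalized over the
#' batch.
#'
#' @param scoresPos,scoresNeg numeric logit vectors for positive and
#'   negative pairs.
#' @return nonnegative scalar loss.
#' @export
nodeEmbeddingLoss <- function(scoresPos, scoresNeg) {
  if (!length(scoresPos)) stop("empty positive batch", call. = FALSE)
  (sum(.softplus(-scoresPos)) + sum(.softplus(scoresNeg))) /
    (length(scoresPos) + length(scoresNeg))
}

#' Combined training loss
#'
#' \code{Loss_N + lambda * Loss_M + (1 - lambda) * Loss_reg}: the pair
#' validity loss, the mixed-in node-embedding loss, and the weight-decay
#' regularizer (its sign is positive, so large weights are penalized).
#'
#' @param lossN,lossM,lossReg the three components.
#' @param lambda mixing weight in [0, 1].
#' @return scalar total loss.
#' @export
totalLoss <- function(lossN, lossM, lossReg, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  lossN + lambda * lossM + (1 - lambda) * lossReg
}

#' Combined association score
#'
#' Sigmoid of a trainable linear head over the concatenated node
#' embedding and pair embedding, \code{sigma(w . [h_node; g] + b)}. A
#' zero node embedding is allowed (pairs with no meta-path instances).
#'
#' @param hNode node-embedding vector (length X).
#' @param gPair pair-embedding vector (length X).
#' @param head list with \code{w} (length 2X) and \code{b} (scalar).
#' @return probability in [0, 1].
#' @export
associationScore <- function(hNode, gPair, head) {
  stopifnot(length(hNode) == length(gPair),
            length(head$w) == 2 * length(hNode))
  .sigmoid(sum(head$w * c(hNode, gPair)) + head$b)
}

#' Sample negative miRNA-disease pairs
#'
#' Uniform without-replacement draw from the zero cells of the
#' association matrix, of size \code{ratio} times the positive count;
#' reproducible under \code{seed}.
#'
#' @param assoc an \linkS4class{AssociationMatrix}
#' @param ratio negatives per positive (>= 1).
#' @param seed optional integer; when given, seeds the draw locally.
#' @return data.frame with columns miRNA, disease.
#' @export
sampleNegatives <- function(assoc, ratio = 1, seed = NULL) {
  stopifnot(ratio >= 1)
  a <- assocMatrix(assoc)
  zeros <- which(a == 0)
  want <- round(ratio * sum(a))
  if (want > length(zeros))
    stop("requested ", want, " negatives but only ", length(zeros),
         " zero cells exist", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cells <- sample(zeros, want)
  data.frame(miRNA = rownames(a)[(cells - 1L) %% nrow(a) + 1L],
             disease = colnames(a)[(cells - 1L) %/% nrow(a) + 1L],
             stringsAsFactors = FALSE)
}

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train the combined-embedding association model
#'
#' Builds the heterogeneous network and its meta-path cache, samples
#' negatives, initializes all tensors, and minimizes the combined loss
#' (pair validity + lambda * node-embedding + (1 - lambda) * weight
#' decay) with Adam. Every stochastic draw (initialization, negative
#' sampling, shuffling, dropout masks) flows from \code{config$seed}, so
#' identical seeds reproduce identical loss logs bitwise.
#'
#' @param assoc an \linkS4class{AssociationMatrix} (the training matrix).
#' @param sm,sd integrated similarity matrices
#'   (\linkS4class{SimilarityMatrix}) whose rows double as the raw
#'   miRNA / disease features.
#' @param config a \code{\link{modelConfig}} list.
#' @param verbose print per-epoch losses.
#' @return an \linkS4class{MDAModel}
#' @export
trainModel <- function(assoc, sm, sd, config = modelConfig(),
                       verbose = FALSE) {
  set.seed(config$seed)
  a <- assocMatrix(assoc)
  m <- nrow(a); n <- ncol(a)
  net <- buildHetNet(assoc, sm, sd, config$edgeRule, config$k, config$tau)
  pathCache <- .buildPathCache(net, config)
  fd <- list(SM = simValues(sm), SD = simValues(sd), m = m, n = n)

  pos <- which(a == 1, arr.ind = TRUE)
  negs <- sampleNegatives(assoc, config$negRatio)
  negR <- match(negs$miRNA, rownames(a))
  negD <- match(negs$disease, colnames(a))
  allR <- c(pos[, 1], negR)
  allD <- c(pos[, 2], negD)
  allY <- c(rep(1, nrow(pos)), rep(0, length(negR)))
  nPairs <- length(allY)

  params <- initModelParams(config, m, n)
  adam <- .adamInit(params)
  logRows <- vector("list", config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nPairs)
    starts <- seq(1L, nPairs, by = config$batchSize)
    acc <- c(lossN = 0, lossM = 0, lossReg = 0, total = 0)
    for (s in starts) {
      sel <- ord[s:min(s + config$batchSize - 1L, nPairs)]
      asm <- .assembleBatch(pathCache, allR[sel], allD[sel], m)
      batch <- list(r = allR[sel], d = allD[sel], y = allY[sel],
                    groups = asm$groups)
      fb <- .forwardBackward(params, fd, batch, config,
                             train = TRUE, wantGrads = TRUE)
      if (!is.finite(fb$total))
        stop("non-finite loss at epoch ", ep, call. = FALSE)
      upd <- .adamStep(params, fb$grads, adam, config$lr)
      params <- upd$params
      adam <- upd$state
      w <- length(sel) / nPairs
      acc <- acc + w * c(fb$lossN, fb$lossM, fb$lossReg, fb$total)
    }
    logRows[[ep]] <- data.frame(epoch = ep, loss_N = acc[["lossN"]],
                                loss_M = acc[["lossM"]],
                                loss_reg = acc[["lossReg"]],
                                total = acc[["total"]])
    if (verbose)
      message(sprintf("epoch %3d  total %.5f", ep, acc[["total"]]))
  }
  log <- if (config$epochs) do.call(rbind, logRows) else
    data.frame(epoch = integer(), loss_N = numeric(), loss_M = numeric(),
               loss_reg = numeric(), total = numeric())
  new("MDAModel", params = params, config = config,
      types = pathCache$types, log = log,
      cache = list(fd = fd, pathCache = pathCache, net = net,
                   mirna = rownames(a), disease = colnames(a)))
}

#' Score miRNA-disease pairs with a trained model
#'
#' Evaluation-mode forward pass of the combined head over arbitrary
#' pairs; pairs without meta-path instances are scored through the pair
#' branch alone (zero node embedding).
#'
#' @param model a trained \linkS4class{MDAModel}.
#' @param pairs data.frame with columns miRNA, disease (names), or a
#'   2-column integer matrix of indices.
#' @param chunkSize pairs scored per forward pass.
#' @return numeric vector of probabilities.
#' @export
predictPairScores <- function(model, pairs, chunkSize = 512L) {
  cache <- model@cache
  if (is.data.frame(pairs)) {
    r <- match(pairs$miRNA, cache$mirna)
    d <- match(pairs$disease, cache$disease)
    if (anyNA(r) || anyNA(d))
      stop("unknown miRNA or disease name", call. = FALSE)
  } else {
    r <- pairs[, 1]; d <- pairs[, 2]
  }
  out <- numeric(length(r))
  for (s in seq(1L, length(r), by = chunkSize)) {
    sel <- s:min(s + chunkSize - 1L, length(r))
    asm <- .assembleBatch(cache$pathCache, r[sel], d[sel], cache$fd$m)
    batch <- list(r = r[sel], d = d[sel], y = numeric(length(sel)),
                  groups = asm$groups)
    fb <- .forwardBackward(model@params, cache$fd, batch, model@config,
                           train = FALSE, wantGrads = FALSE)
    out[sel] <- fb$scores
  }
  out
}

#' Rank candidate miRNAs for a target disease
#'
#' Trains on the supplied data and scores every candidate miRNA for the
#' target. In \code{standard} mode, confirmed pairs are excluded from
#' the candidate set. In \code{new_disease} mode the target's column of
#' the association matrix is zeroed before similarity computation,
#' network construction and training, simulating a disease with no known
#' miRNAs; all miRNAs are then ranked.
#'
#' @param target disease name.
#' @param assoc an \linkS4class{AssociationMatrix}.
#' @param dags a \linkS4class{DAGCollection}.
#' @param fs optional functional \linkS4class{SimilarityMatrix}.
#' @param config a \code{\link{modelConfig}} list.
#' @param mode "standard" or "new_disease".
#' @param top optional row cap on the returned table.
#' @param model optional pre-trained \linkS4class{MDAModel} (standard
#'   mode only; must have been trained on \code{assoc}).
#' @return data.frame with columns miRNA, disease, score, rank, ordered
#'   by decreasing score (ties broken by miRNA id).
#' @export
rankCandidates <- function(target, assoc, dags, fs = NULL,
                           config = modelConfig(),
                           mode = c("standard", "new_disease"),
                           top = NULL, model = NULL) {
  mode <- match.arg(mode)
  a <- assocMatrix(assoc)
  if (!target %in% colnames(a))
    stop("unknown disease: ", target, call. = FALSE)
  if (mode == "new_disease") {
    a[, target] <- 0
    assoc <- AssociationMatrix(a)
    model <- NULL
  }
  if (is.null(model)) {
    sims <- buildIntegratedSimilarity(assoc, dags, fs,
                                      config$delta, config$alpha0)
    model <- trainModel(assoc, sims$SM, sims$SD, config)
  }
  cand <- if (mode == "standard") rownames(a)[a[, target] == 0]
          else rownames(a)
  if (!length(cand))
    return(data.frame(miRNA = character(), disease = character(),
                      score = numeric(), rank = integer()))
  df <- data.frame(miRNA = cand, disease = target,
                   stringsAsFactors = FALSE)
  df$score <- predictPairScores(model, df)
  o <- order(-df$score, df$miRNA)
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  if (!is.null(top)) df <- df[seq_len(min(top, nrow(df))), , drop = FALSE]
  df
}
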