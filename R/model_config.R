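## Hyperparameter container and parameter initialization.

#' Model and training configuration
#'
#' Collects every tunable constant of the combined-embedding model. The
#' stated defaults target the curated-database scale of the method (projection
#' width 256, attenuation 0.5, initial kernel bandwidth 1, loss mixing 0.5,
#' meta-path length cap 3); the optimizer settings are package choices.
#'
#' @param Z projection width of the miRNA/disease features.
#' @param X embedding width of the pair/GRU outputs (defaults to Z, which
#'   keeps every attention product dimensionally consistent).
#' @param K attention head count for meta-path pooling.
#' @param q dropout rate, shared by the pair MLP hidden layers and the
#'   GRU state update (non-inverted: Bernoulli(1-q) mask at train time,
#'   (1-q) scaling at evaluation).
#' @param hiddenPair hidden width of the pair MLP.
#' @param hiddenValidity hidden width of the pair validity head.
#' @param delta semantic attenuation factor for disease DAG similarity.
#' @param alpha0 initial Gaussian kernel bandwidth.
#' @param lambda mixing weight of the node-embedding loss; the
#'   regularizer enters with weight (1 - lambda).
#' @param lMax maximum meta-path edge count.
#' @param edgeRule,k,tau similarity-to-edge rule for the network (see
#'   \code{\link{buildHetNet}}).
#' @param allowRevisit,mdIntermediate meta-path traversal policy (see
#'   \code{\link{enumerateMetaPaths}}).
#' @param lr,epochs,batchSize,negRatio,weightDecay optimizer settings
#'   (Adam learning rate, epoch count, minibatch size, negatives drawn
#'   per positive, weight-decay coefficient).
#' @param usePair include the pair-embedding branch (FALSE gives the
#'   node-embedding-only ablation).
#' @param seed integer seed fixing every stochastic draw of a run.
#' @return named list of settings.
#' @export
modelConfig <- function(Z = 256, X = Z, K = 4, q = 0.5,
                        hiddenPair = 100, hiddenValidity = 100,
                        delta = 0.5, alpha0 = 1, lambda = 0.5,
                        lMax = 3, edgeRule = "topk", k = 5, tau = 0.5,
                        allowRevisit = FALSE, mdIntermediate = TRUE,
                        lr = 1e-3, epochs = 100, batchSize = 128,
                        negRatio = 1, weightDecay = 1e-4,
                        usePair = TRUE, seed = 1L) {
  stopifnot(Z > 0, X > 0, K >= 1, q >= 0, q < 1, delta > 0, delta < 1,
            lambda >= 0, lambda <= 1, lMax >= 1, lr >= 0, epochs >= 0,
            batchSize >= 1, negRatio >= 1, weightDecay >= 0)
  list(Z = Z, X = X, K = K, q = q, hiddenPair = hiddenPair,
       hiddenValidity = hiddenValidity, delta = delta, alpha0 = alpha0,
       lambda = lambda, lMax = lMax, edgeRule = edgeRule, k = k,
       tau = tau, allowRevisit = allowRevisit,
       mdIntermediate = mdIntermediate, lr = lr, epochs = epochs,
       batchSize = batchSize, negRatio = negRatio,
       weightDecay = weightDecay, usePair = usePair,
       seed = as.integer(seed))
}

#' Desk-scale configuration for the planted benchmark
#'
#' A compact configuration sized for the default synthetic benchmark
#' (60 miRNAs x 40 diseases): narrower embeddings, two attention heads,
#' light dropout and a short Adam schedule. Used by the package's own
#' cross-validation experiments.
#'
#' @param ... overrides passed to \code{\link{modelConfig}}.
#' @return named list of settings.
#' @export
benchmarkConfig <- function(...) {
  defaults <- list(Z = 32, X = 32, K = 2, q = 0.2, hiddenPair = 48,
                   hiddenValidity = 24, lr = 5e-3, epochs = 30,
                   batchSize = 128, weightDecay = 1e-2, k = 5)
  over <- list(...)
  do.call(modelConfig, utils::modifyList(defaults, over))
}

#' Meta-path type vocabulary
#'
#' All node-type strings a meta-path instance can realize under the
#' configured length cap: strings over \{M, D\} that start with M and end
#' with D, of 2 to lMax+1 nodes. With interior association edges
#' disallowed only the monotone strings (M...MD...D) remain.
#'
#' @param lMax maximum edge count.
#' @param mdIntermediate permit interior MD edges.
#' @return character vector of type strings (no separators, e.g. "MMD").
#' @export
typeVocabulary <- function(lMax = 3, mdIntermediate = TRUE) {
  out <- character()
  for (nn in seq(2L, lMax + 1L)) {
    if (nn == 2L) { out <- c(out, "MD"); next }
    mids <- expand.grid(rep(list(c("M", "D")), nn - 2L),
                        stringsAsFactors = FALSE)
    strs <- apply(mids, 1L, function(x)
      paste0("M", paste(x, collapse = ""), "D"))
    out <- c(out, sort(strs))
  }
  if (!mdIntermediate)
    out <- out[!grepl("DM", out)]
  out
}

.decayedParams <- c("Wr", "Wd", "W1", "W2", "V1", "v2", "Wzx", "Wrx",
                    "Whx", "Wzh", "Wrh", "Whh", "M", "attp", "attP", "wc")

#' Initialize model parameters
#'
#' Glorot-uniform weights (drawn from the current RNG state) and zero
#' biases for every trainable tensor: the feature projections, the pair
#' MLP and validity head, the GRU, the multi-head pooling vectors, the
#' per-type fusion vectors and the scoring head.
#'
#' @param config a \code{\link{modelConfig}} list.
#' @param m,n miRNA and disease counts (projection input widths).
#' @return named list of numeric arrays.
#' @export
initModelParams <- function(config, m, n) {
  Z <- config$Z; X <- config$X; K <- config$K
  H1 <- config$hiddenPair; H2 <- config$hiddenValidity
  types <- typeVocabulary(config$lMax, config$mdIntermediate)
  nT <- length(types)
  list(
    Wr = .glorot(m, Z, c(Z, m)),
    Wd = .glorot(n, Z, c(Z, n)),
    W1 = .glorot(4 * Z, H1), b1 = numeric(H1),
    W2 = .glorot(H1, X), b2 = numeric(X),
    V1 = .glorot(X, H2), c1 = numeric(H2),
    v2 = .glorot(H2, 1)[, 1L], c2 = 0,
    Wzx = .glorot(Z, X), Wrx = .glorot(Z, X), Whx = .glorot(Z, X),
    Wzh = .glorot(X, X), Wrh = .glorot(X, X), Whh = .glorot(X, X),
    bz = numeric(X), br = numeric(X), bh = numeric(X),
    M = .glorot(X, K),
    attp = .glorot(X, nT), attP = .glorot(X, nT),
    wc = .glorot(2 * X, 1)[, 1L], bc = 0
  )
}
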