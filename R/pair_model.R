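## Pair-embedding branch: feature projection, pair composition, the pair
## MLP and the validity head. These are the single-sample reference
## implementations; training uses the batched engine, which is tested for
## agreement with these.

## non-inverted dropout (Bernoulli(1-q) mask at train, (1-q) scaling at
## evaluation); masks draw from the current RNG
.dropout <- function(x, q, train) {
  if (q <= 0) return(x)
  if (train) x * stats::rbinom(length(x), 1L, 1 - q) else (1 - q) * x
}

#' Project a raw feature vector into the shared space
#'
#' Exact matrix-vector product \code{W \%*\% x}: miRNA features (rows of
#' SM) are projected by W^R and disease features (rows of SD) by W^D into
#' the common Z-dimensional space.
#'
#' @param x raw feature vector.
#' @param W projection matrix, Z x length(x).
#' @return numeric vector of length Z.
#' @export
projectNode <- function(x, W) {
  if (ncol(W) != length(x))
    stop("feature length does not match projection", call. = FALSE)
  as.numeric(W %*% x)
}

#' Compose a miRNA/disease embedding pair
#'
#' Concatenation of the two embeddings, their elementwise product and
#' their sum, in that order: \code{[h_r; h_d; h_r * h_d; h_r + h_d]},
#' giving a 4Z-length composite.
#'
#' @param hR,hD projected embeddings of equal length.
#' @return numeric vector of length 4Z.
#' @export
combinePair <- function(hR, hD) {
  if (length(hR) != length(hD))
    stop("embeddings must have equal length", call. = FALSE)
  c(hR, hD, hR * hD, hR + hD)
}

#' Pair embedding via the MLP
#'
#' Hidden layers apply affine + ReLU (with dropout after each hidden
#' activation in train mode); the final layer is affine only, and its
#' output is the pair embedding g(r, d).
#'
#' @param h0 composite input vector (length 4Z).
#' @param params list with W1, b1, W2, b2 (weights column-oriented: the
#'   layer computes \code{x \%*\% W + b}).
#' @param train logical; apply dropout masks.
#' @param q dropout rate.
#' @return numeric vector of length X.
#' @export
pairEmbed <- function(h0, params, train = FALSE, q = 0) {
  a1 <- as.numeric(h0 %*% params$W1) + params$b1
  h1 <- .dropout(.relu(a1), q, train)
  as.numeric(h1 %*% params$W2) + params$b2
}

.validityLogit <- function(g, params) {
  p1 <- .relu(as.numeric(g %*% params$V1) + params$c1)
  sum(p1 * params$v2) + params$c2
}

#' Pair validity loss
#'
#' Binary cross-entropy of the validity classifier pi (a 2-layer
#' perceptron with ReLU) applied to the pair embedding:
#' \code{-[y log sigma(pi(g)) + (1-y) log(1 - sigma(pi(g)))]}.
#'
#' @param g pair embedding.
#' @param y binary label (1 = associated).
#' @param params list with V1, c1, v2, c2.
#' @return nonnegative scalar loss.
#' @export
validityLoss <- function(g, y, params) {
  stopifnot(y %in% c(0, 1))
  .bceFromLogits(.validityLogit(g, params), y)
}
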