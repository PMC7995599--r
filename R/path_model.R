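## Meta-path branch, single-instance reference implementations: GRU step,
## instance encoding, multi-head attentive pooling, and the two attention
## fusions (instances within a type, then across types).

#' One GRU step
#'
#' Update and reset gates via sigmoid, candidate state via tanh with the
#' reset gate applied to the previous state, then
#' \code{h_t = z_t * h_prev + (1 - z_t) * d(g_t)} where d() is the
#' non-inverted dropout (mask in train mode, (1-q) scaling otherwise).
#'
#' @param xT input vector (length Z).
#' @param hPrev previous hidden state (length X); the initial state is
#'   the zero vector.
#' @param params list with Wzx, Wrx, Whx (Z x X), Wzh, Wrh, Whh (X x X),
#'   bz, br, bh (length X), q.
#' @param train logical; sample a dropout mask.
#' @return hidden state vector of length X.
#' @export
gruStep <- function(xT, hPrev, params, train = FALSE) {
  z <- .sigmoid(as.numeric(xT %*% params$Wzx) +
                as.numeric(hPrev %*% params$Wzh) + params$bz)
  r <- .sigmoid(as.numeric(xT %*% params$Wrx) +
                as.numeric(hPrev %*% params$Wrh) + params$br)
  g <- tanh(as.numeric(xT %*% params$Whx) +
            as.numeric((r * hPrev) %*% params$Whh) + params$bh)
  z * hPrev + (1 - z) * .dropout(g, params$q, train)
}

#' Encode a meta-path instance with the GRU
#'
#' Runs sequential GRU steps over the instance's projected node features
#' (first node = h_r, last node = h_d) from a zero initial state and
#' returns the full state matrix.
#'
#' @param features numeric matrix, one projected node feature per row.
#' @param params GRU parameter list (see \code{\link{gruStep}}).
#' @param train logical.
#' @return state matrix (n_nodes x X).
#' @export
encodeInstance <- function(features, params, train = FALSE) {
  if (!nrow(features)) stop("empty instance", call. = FALSE)
  X <- ncol(params$Wzx)
  h <- numeric(X)
  out <- matrix(0, nrow(features), X)
  for (t in seq_len(nrow(features))) {
    h <- gruStep(features[t, ], h, params, train)
    out[t, ] <- h
  }
  out
}

#' Multi-head attentive pooling of GRU states
#'
#' Per head k, node weights are the softmax over positions of
#' \code{M^(k) . h_i}; the pooled vector is the average over the K heads
#' of the weighted sums.
#'
#' @param h state matrix (n_nodes x X).
#' @param M attention matrix (X x K), one pooling vector per head.
#' @return pooled vector of length X.
#' @export
attentivePool <- function(h, M) {
  stopifnot(nrow(h) >= 1, ncol(h) == nrow(M))
  K <- ncol(M)
  pooled <- numeric(ncol(h))
  for (k in seq_len(K)) {
    logits <- as.numeric(h %*% M[, k])
    a <- exp(logits - max(logits))
    a <- a / sum(a)
    pooled <- pooled + colSums(a * h)
  }
  pooled / K
}

#' Fuse the instances of one meta-path type
#'
#' Per instance, a scalar contribution \code{e = ReLU(att_p . h^p)};
#' the instance weights are the softmax of these contributions, and the
#' fused type vector is the elementwise sigmoid of the weighted sum.
#'
#' @param pooled list of pooled instance vectors of one type.
#' @param attP type-shared attention vector (length X).
#' @return fused vector of length X, entries in (0, 1).
#' @export
fuseInstances <- function(pooled, attP) {
  if (!length(pooled)) stop("empty instance list", call. = FALSE)
  e <- vapply(pooled, function(p) .relu(sum(attP * p)), numeric(1))
  w <- exp(e - max(e))
  w <- w / sum(w)
  .sigmoid(Reduce(`+`, Map(`*`, w, pooled)))
}

#' Fuse across meta-path types
#'
#' Per type, a scalar contribution \code{ReLU(att_Pi . h^Pi)}; weights
#' are softmax-normalized across the types present, and the pair's node
#' embedding is their weighted sum. An empty map yields the zero vector
#' (the pair then contributes through the pair branch only).
#'
#' @param typeVectors named list of fused type vectors.
#' @param attPList named list (or X x nTypes matrix with column names) of
#'   per-type attention vectors.
#' @param X embedding width, used when \code{typeVectors} is empty.
#' @return node-embedding vector of length X.
#' @export
fuseTypes <- function(typeVectors, attPList, X = NULL) {
  if (!length(typeVectors)) {
    if (is.null(X)) stop("X required for the empty case", call. = FALSE)
    return(numeric(X))
  }
  getAtt <- function(ty)
    if (is.matrix(attPList)) attPList[, ty] else attPList[[ty]]
  w <- vapply(names(typeVectors), function(ty)
    .relu(sum(getAtt(ty) * typeVectors[[ty]])), numeric(1))
  ww <- exp(w - max(w))
  ww <- ww / sum(ww)
  Reduce(`+`, Map(`*`, ww, typeVectors))
}
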