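## Internal numerical helpers shared by the model code.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.relu <- function(x) pmax(x, 0)

## numerically stable mean binary cross-entropy from logits;
## gradient wrt logits is (sigmoid(l) - y) / length(l)
.bceFromLogits <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

## row-wise softmax of a matrix, max-shifted for stability
.rowSoftmax <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

## softmax within contiguous-by-value segments; `group` is an integer id
## per element (need not be contiguous). Returns weights summing to 1
## within each segment.
.segmentSoftmax <- function(x, group) {
  g <- as.integer(factor(group))
  mx <- as.numeric(tapply(x, g, max))[g]
  e <- exp(as.numeric(x) - mx)
  tot <- rowsum(e, g)[g, 1L]
  as.numeric(e / tot)
}

## backward of .segmentSoftmax: given weights w and upstream dW, return dx
.segmentSoftmaxGrad <- function(w, dW, group) {
  g <- as.integer(factor(group))
  s <- rowsum(as.numeric(w * dW), g)[g, 1L]
  as.numeric(w * (dW - s))
}

## accumulate rows of `dRows` into rows `idx` of an accumulator matrix,
## handling repeated indices
.scatterAddRows <- function(acc, idx, dRows) {
  agg <- rowsum(dRows, idx)
  rows <- as.integer(rownames(agg))
  acc[rows, ] <- acc[rows, , drop = FALSE] + agg
  acc
}

## Glorot-uniform initial weights
.glorot <- function(nin, nout, dim = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dim), -lim, lim), dim = dim)
}

.stopifnotFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}
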