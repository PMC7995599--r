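## Assembly of the typed miRNA-disease heterogeneous network and
## enumeration of bounded-length meta-path instances.

## internal constructor: build a HetNet from an explicit edge table
.makeHetNet <- function(nodeNames, nodeType, edges) {
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nv <- length(nodeNames)
  adj <- vector("list", nv)
  for (v in seq_len(nv)) adj[[v]] <- integer()
  if (nrow(edges)) {
    fwd <- split(edges$to, factor(edges$from, levels = seq_len(nv)))
    bwd <- split(edges$from, factor(edges$to, levels = seq_len(nv)))
    for (v in seq_len(nv))
      adj[[v]] <- sort(unique(c(fwd[[v]], bwd[[v]])))
  }
  new("HetNet", nodeNames = nodeNames, nodeType = nodeType,
      edges = edges, adj = adj)
}

## per-node top-k strongest neighbors, union-symmetrized
.topkEdges <- function(sim, k, offset) {
  nn <- nrow(sim)
  s <- sim
  diag(s) <- -Inf
  pairs <- NULL
  for (i in seq_len(nn)) {
    o <- order(s[i, ], decreasing = TRUE)
    keep <- o[seq_len(min(k, nn - 1L))]
    keep <- keep[is.finite(s[i, keep]) & s[i, keep] > 0]
    if (length(keep))
      pairs <- rbind(pairs, cbind(i, keep, s[i, keep]))
  }
  if (is.null(pairs)) return(NULL)
  data.frame(from = as.integer(pairs[, 1]) + offset,
             to = as.integer(pairs[, 2]) + offset,
             weight = pairs[, 3])
}

.thresholdEdges <- function(sim, tau, offset) {
  s <- sim
  diag(s) <- -Inf
  idx <- which(s >= tau & upper.tri(s), arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  data.frame(from = idx[, 1] + offset, to = idx[, 2] + offset,
             weight = s[idx])
}

#' Build the miRNA-disease heterogeneous network
#'
#' MD association edges are placed exactly where the association matrix
#' is 1. The integrated similarity matrices are dense (Gaussian kernels
#' are everywhere positive), so MM and DD similarity edges are admitted
#' by an edge rule: per-node top-k strongest neighbors union-symmetrized
#' (default), or a plain similarity threshold.
#'
#' @param assoc an \linkS4class{AssociationMatrix}
#' @param sm,sd integrated miRNA / disease \linkS4class{SimilarityMatrix}
#'   objects with names matching the association axes.
#' @param edgeRule "topk" or "threshold".
#' @param k neighbors kept per node under the top-k rule; default 5.
#' @param tau similarity cutoff under the threshold rule.
#' @return a \linkS4class{HetNet}
#' @export
buildHetNet <- function(assoc, sm, sd, edgeRule = c("topk", "threshold"),
                        k = 5, tau = 0.5) {
  edgeRule <- match.arg(edgeRule)
  a <- assocMatrix(assoc)
  if (!identical(entityNames(sm), rownames(a)) ||
      !identical(entityNames(sd), colnames(a)))
    stop("similarity names inconsistent with association axes",
         call. = FALSE)
  m <- nrow(a); n <- ncol(a)
  nodeNames <- c(rownames(a), colnames(a))
  nodeType <- c(rep("M", m), rep("D", n))

  md <- which(a == 1, arr.ind = TRUE)
  edges <- data.frame(from = as.integer(md[, 1]),
                      to = as.integer(md[, 2]) + m,
                      type = rep("MD", nrow(md)),
                      weight = rep(1, nrow(md)))
  mkSim <- function(sim, offset, label) {
    e <- if (edgeRule == "topk") .topkEdges(simValues(sim), k, offset)
         else .thresholdEdges(simValues(sim), tau, offset)
    if (is.null(e)) return(NULL)
    e$type <- label
    e[, c("from", "to", "type", "weight")]
  }
  edges <- rbind(edges, mkSim(sm, 0L, "MM"), mkSim(sd, m, "DD"))
  .makeHetNet(nodeNames, nodeType, edges)
}

## all simple paths starting at node `start`, up to lMax edges;
## returns a list indexed by length whose elements are integer matrices
## with length+1 columns (one path per row)
.pathsFrom <- function(net, start, lMax, allowRevisit = FALSE) {
  adj <- net@adj
  out <- vector("list", lMax)
  if (!length(adj[[start]])) return(out)
  cur <- cbind(start, adj[[start]])
  out[[1L]] <- cur
  l <- 1L
  while (l < lMax && !is.null(cur) && nrow(cur)) {
    last <- cur[, l + 1L]
    counts <- lengths(adj[last])
    if (sum(counts) == 0L) break
    rows <- rep.int(seq_len(nrow(cur)), counts)
    tails <- unlist(adj[last], use.names = FALSE)
    cand <- cbind(cur[rows, , drop = FALSE], tails)
    if (!allowRevisit) {
      dup <- cand[, 1L] == tails
      for (c0 in seq(2L, l + 1L)) dup <- dup | cand[, c0] == tails
      cand <- cand[!dup, , drop = FALSE]
    }
    l <- l + 1L
    out[[l]] <- cand
    cur <- cand
  }
  out
}

## keep only paths whose node-type string is admissible: start M, and
## when mdIntermediate is FALSE the string must be monotone (M+D+, a
## single association crossing)
.typeStringOf <- function(net, rowIds) {
  paste(net@nodeType[rowIds], collapse = "")
}

.admissibleRows <- function(net, mat, mdIntermediate) {
  if (mdIntermediate || is.null(mat) || !nrow(mat)) return(mat)
  tl <- matrix(net@nodeType[mat], nrow(mat))
  ok <- rep(TRUE, nrow(mat))
  for (c0 in seq_len(ncol(tl) - 1L))
    ok <- ok & !(tl[, c0] == "D" & tl[, c0 + 1L] == "M")
  mat[ok, , drop = FALSE]
}

#' Enumerate meta-path instances between a miRNA and a disease
#'
#' Returns every simple path from \code{r} to \code{d} with at most
#' \code{lMax} edges, as instances carrying the node sequence, the edge
#' count, and the node-type string (e.g. "M,M,D,D"). Ordering is
#' deterministic: by length, then lexicographically by node sequence.
#'
#' @param net a \linkS4class{HetNet}
#' @param r miRNA node name; @param d disease node name.
#' @param lMax maximum edge count; default 3.
#' @param allowRevisit permit node repetition within an instance
#'   (default FALSE: simple paths only).
#' @param mdIntermediate permit association (MD) edges in the interior of
#'   a path (default TRUE); if FALSE only one M-to-D crossing is allowed.
#' @return list of instances, each
#'   \code{list(nodes, length, type)}.
#' @export
enumerateMetaPaths <- function(net, r, d, lMax = 3, allowRevisit = FALSE,
                               mdIntermediate = TRUE) {
  ri <- match(r, net@nodeNames)
  di <- match(d, net@nodeNames)
  if (is.na(ri) || is.na(di))
    stop("node '", if (is.na(ri)) r else d, "' not in network",
         call. = FALSE)
  if (net@nodeType[ri] != "M" || net@nodeType[di] != "D")
    stop("r must be a miRNA node and d a disease node", call. = FALSE)
  stopifnot(lMax >= 1)
  paths <- .pathsFrom(net, ri, lMax, allowRevisit)
  inst <- list()
  for (l in seq_len(lMax)) {
    p <- paths[[l]]
    if (is.null(p) || !nrow(p)) next
    p <- p[p[, l + 1L] == di, , drop = FALSE]
    p <- .admissibleRows(net, p, mdIntermediate)
    if (!nrow(p)) next
    key <- apply(p, 1L, function(rw)
      paste(net@nodeNames[rw], collapse = "\r"))
    p <- p[order(key), , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      ids <- p[i, ]
      inst[[length(inst) + 1L]] <- list(
        nodes = net@nodeNames[ids],
        ids = unname(ids),
        length = l,
        type = paste(net@nodeType[ids], collapse = ","))
    }
  }
  inst
}

#' Group meta-path instances by type
#'
#' Partitions an instance list by its node-type string (the meta-path
#' type); the union of the groups is the input and every group is
#' non-empty.
#'
#' @param instances list of instances from
#'   \code{\link{enumerateMetaPaths}}.
#' @return named list of instance lists, one per type string.
#' @export
groupByType <- function(instances) {
  if (!length(instances)) return(structure(list(), names = character()))
  types <- vapply(instances, `[[`, character(1), "type")
  split(instances, types)
}
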