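## Disease semantic similarity (two variants and their average), Gaussian
## interaction-profile kernels, and the integrated SD / SM networks.

#' Semantic contributions of DAG nodes, variant 1
#'
#' The target disease contributes 1; every ancestor d contributes the
#' maximum of delta times the contributions of its children, so the
#' contribution decays with the attenuation factor delta along the
#' ancestor chain. The semantic value DV1 is the sum over T(D).
#'
#' @param dag a \linkS4class{DiseaseDAG}
#' @param delta semantic attenuation factor in (0, 1); default 0.5.
#' @return list with \code{contrib} (named numeric over T(D)) and
#'   \code{semanticValue} (their sum).
#' @examples
#' dag <- DiseaseDAG("D", cbind(parent = c("A", "B"), child = c("B", "D")))
#' d1Contributions(dag)$semanticValue  # 1 + 0.5 + 0.25 = 1.75
#' @export
d1Contributions <- function(dag, delta = 0.5) {
  stopifnot(delta > 0, delta < 1)
  validObject(dag)
  nodes <- dagNodes(dag)
  edges <- dagEdges(dag)
  childrenOf <- split(edges[, "child"], factor(edges[, "parent"],
                                               levels = nodes))
  contrib <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  visit <- function(d) {
    if (!is.na(contrib[[d]])) return(contrib[[d]])
    val <- if (d == dagTarget(dag)) 1 else {
      ch <- childrenOf[[d]]
      if (!length(ch))
        stop("node '", d, "' cannot reach the target", call. = FALSE)
      max(delta * vapply(ch, visit, numeric(1)))
    }
    contrib[[d]] <<- val
    val
  }
  for (d in nodes) visit(d)
  list(contrib = contrib, semanticValue = sum(contrib))
}

#' Semantic contributions, variant 2 (information content)
#'
#' A node's contribution is \code{-log(count of DAGs containing it /
#' number of diseases in the collection)}: headings shared by few diseases
#' carry more information. One global table serves every target disease.
#'
#' @param collection a \linkS4class{DAGCollection}
#' @return named numeric vector over all nodes occurring in the collection.
#' @export
d2Contributions <- function(collection) {
  if (!length(collection@dags)) stop("empty DAG collection", call. = FALSE)
  nDiseases <- length(collection@dags)
  counts <- table(unlist(lapply(collection@dags, dagNodes)))
  stats::setNames(-log(as.numeric(counts) / nDiseases), names(counts))
}

#' Semantic similarity of two contribution tables
#'
#' Shared-ancestor similarity: the contributions of nodes common to both
#' DAGs, summed from both sides, over the sum of the two semantic values.
#' The same algebraic form serves both contribution variants.
#'
#' @param contribI,contribJ lists with \code{contrib} and
#'   \code{semanticValue}, as returned by \code{\link{d1Contributions}}.
#' @return similarity in [0, 1], symmetric in its arguments.
#' @export
semanticSimilarity <- function(contribI, contribJ) {
  vi <- contribI$semanticValue
  vj <- contribJ$semanticValue
  if (vi + vj <= 0)
    stop("both semantic values are zero", call. = FALSE)
  shared <- intersect(names(contribI$contrib), names(contribJ$contrib))
  num <- sum(contribI$contrib[shared]) + sum(contribJ$contrib[shared])
  min(max(num / (vi + vj), 0), 1)
}

## per-disease variant-2 contribution table restricted to its DAG nodes
.d2Table <- function(dag, globalContrib) {
  contrib <- globalContrib[dagNodes(dag)]
  list(contrib = contrib, semanticValue = sum(contrib))
}

#' Combined disease semantic similarity matrix (SS)
#'
#' Entrywise arithmetic mean of the two semantic similarity variants over
#' the diseases possessing DAGs; the diagonal is 1. Variant 2 can be
#' globally degenerate (all its contributions are zero when every heading
#' occurs in every DAG); such pairs fall back to 0 off the diagonal.
#'
#' @param collection a \linkS4class{DAGCollection}
#' @param delta attenuation factor for variant 1; default 0.5.
#' @return a \linkS4class{SimilarityMatrix} over the collection's diseases.
#' @export
combinedSemanticSimilarity <- function(collection, delta = 0.5) {
  dis <- diseaseNames(collection)
  t1 <- lapply(collection@dags, d1Contributions, delta = delta)
  g2 <- d2Contributions(collection)
  t2 <- lapply(collection@dags, .d2Table, globalContrib = g2)
  n <- length(dis)
  ss <- matrix(1, n, n, dimnames = list(dis, dis))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      s1 <- semanticSimilarity(t1[[i]], t1[[j]])
      s2 <- if (t2[[i]]$semanticValue + t2[[j]]$semanticValue > 0)
        semanticSimilarity(t2[[i]], t2[[j]]) else 0
      ss[i, j] <- ss[j, i] <- (s1 + s2) / 2
    }
  }
  SimilarityMatrix(ss)
}

#' Gaussian interaction-profile kernel similarity
#'
#' \code{K(i, j) = exp(-alpha * ||profile_i - profile_j||^2)} with the
#' data-adaptive bandwidth \code{alpha = alpha0 / mean(||profile_i||^2)}.
#' Applied to the rows of the association matrix for miRNAs (GM) and to
#' its columns for diseases (GD).
#'
#' @param profiles numeric matrix, one binary interaction profile per row,
#'   with row names.
#' @param alpha0 initial bandwidth parameter; default 1.
#' @return a \linkS4class{SimilarityMatrix}
#' @export
gaussianProfileKernel <- function(profiles, alpha0 = 1) {
  sq <- rowSums(profiles^2)
  if (all(sq == 0))
    stop("all-zero profile matrix: bandwidth undefined", call. = FALSE)
  alpha <- alpha0 / mean(sq)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  k <- exp(-alpha * d2)
  dimnames(k) <- list(rownames(profiles), rownames(profiles))
  SimilarityMatrix((k + t(k)) / 2)
}

#' Entrywise integration of two similarity sources
#'
#' Selects the primary similarity where the pair is defined by the mask
#' and the fallback elsewhere. Used to form SD (semantic similarity over
#' the disease Gaussian kernel) and SM (functional similarity over the
#' miRNA Gaussian kernel).
#'
#' @param primary,fallback \linkS4class{SimilarityMatrix} objects sharing
#'   entity names.
#' @param definedMask symmetric logical matrix; TRUE picks the primary.
#' @return a \linkS4class{SimilarityMatrix}
#' @export
integrateSimilarity <- function(primary, fallback, definedMask) {
  p <- simValues(primary)
  f <- simValues(fallback)
  if (!identical(dim(p), dim(f)) ||
      !identical(rownames(p), rownames(f)))
    stop("similarity matrices must share names and shape", call. = FALSE)
  stopifnot(identical(dim(definedMask), dim(p)))
  out <- ifelse(definedMask, p, f)
  dimnames(out) <- dimnames(p)
  SimilarityMatrix(out)
}

#' Integrated SM and SD similarity networks
#'
#' Computes the miRNA and disease Gaussian profile kernels from the
#' association matrix, the combined disease semantic similarity from the
#' DAG collection, and integrates: SD uses semantic similarity where both
#' diseases possess DAG records (GD otherwise); SM uses functional
#' similarity where both miRNAs appear in FS with a positive entry (GM
#' otherwise).
#'
#' @param assoc an \linkS4class{AssociationMatrix}
#' @param dags a \linkS4class{DAGCollection} (may cover a subset of the
#'   diseases)
#' @param fs optional \linkS4class{SimilarityMatrix} of miRNA functional
#'   similarity; entries of 0 mark undefined pairs.
#' @param delta,alpha0 parameters passed to the constituents.
#' @return list with elements \code{SM} and \code{SD}
#'   (\linkS4class{SimilarityMatrix}).
#' @export
buildIntegratedSimilarity <- function(assoc, dags, fs = NULL,
                                      delta = 0.5, alpha0 = 1) {
  a <- assocMatrix(assoc)
  gm <- gaussianProfileKernel(a, alpha0)
  gd <- gaussianProfileKernel(t(a), alpha0)

  ## disease axis: semantic similarity where both diseases have DAGs
  dis <- diseaseNames(assoc)
  withDag <- intersect(dis, diseaseNames(dags))
  sdv <- simValues(gd)
  if (length(withDag)) {
    sub <- DAGCollection(lapply(withDag, function(d) dags[[d]]))
    ssv <- simValues(combinedSemanticSimilarity(sub, delta))
    sdv[withDag, withDag] <- ssv[withDag, withDag]
  }
  sd <- SimilarityMatrix(sdv)

  ## miRNA axis: functional similarity where defined and positive
  if (is.null(fs)) {
    sm <- gm
  } else {
    mir <- mirnaNames(assoc)
    fsFull <- matrix(0, length(mir), length(mir),
                     dimnames = list(mir, mir))
    common <- intersect(mir, entityNames(fs))
    fsFull[common, common] <- simValues(fs)[common, common]
    mask <- fsFull > 0
    diag(mask) <- TRUE
    diag(fsFull) <- 1
    sm <- integrateSimilarity(SimilarityMatrix(fsFull), gm, mask)
  }
  list(SM = sm, SD = sd)
}
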