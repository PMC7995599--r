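#' @import methods
#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## AssociationMatrix
## ---------------------------------------------------------------------------

#' Binary miRNA-disease association matrix
#'
#' An m x n binary matrix A with miRNA row names and disease column names.
#' \code{A[i, j] == 1} records an experimentally supported association
#' between miRNA i and disease j. Rows double as miRNA interaction profiles
#' IV(r_i) and columns as disease interaction profiles for the Gaussian
#' profile kernels.
#'
#' @slot assoc numeric matrix with entries in \{0, 1\} and unique dimnames.
#'
#' @exportClass AssociationMatrix
setClass("AssociationMatrix", representation(assoc = "matrix"))

setValidity("AssociationMatrix", function(object) {
  a <- object@assoc
  msg <- character()
  if (nrow(a) < 1L || ncol(a) < 1L)
    msg <- c(msg, "association matrix must be at least 1 x 1")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "association matrix must have row and column names")
  else {
    if (anyDuplicated(rownames(a))) msg <- c(msg, "duplicated miRNA names")
    if (anyDuplicated(colnames(a))) msg <- c(msg, "duplicated disease names")
  }
  if (!all(a %in% c(0, 1)))
    msg <- c(msg, "association entries must all be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct an AssociationMatrix
#'
#' @param assoc binary matrix with miRNA row names and disease column names.
#' @return an \linkS4class{AssociationMatrix}
#' @examples
#' a <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("mir-a", "mir-b"), c("dis-x", "dis-y")))
#' AssociationMatrix(a)
#' @export
AssociationMatrix <- function(assoc) {
  storage.mode(assoc) <- "double"
  new("AssociationMatrix", assoc = assoc)
}

#' @rdname accessors
#' @export
setMethod("mirnaNames", "AssociationMatrix", function(x) rownames(x@assoc))

#' @rdname accessors
#' @export
setMethod("diseaseNames", "AssociationMatrix", function(x) colnames(x@assoc))

#' @rdname accessors
#' @export
setMethod("assocMatrix", "AssociationMatrix", function(x) x@assoc)

#' @rdname accessors
#' @export
setMethod("positivePairs", "AssociationMatrix", function(x) {
  idx <- which(x@assoc == 1, arr.ind = TRUE)
  data.frame(miRNA = rownames(x@assoc)[idx[, 1]],
             disease = colnames(x@assoc)[idx[, 2]],
             stringsAsFactors = FALSE)
})

setMethod("show", "AssociationMatrix", function(object) {
  a <- object@assoc
  cat(sprintf("AssociationMatrix: %d miRNAs x %d diseases, %d associations\n",
              nrow(a), ncol(a), sum(a)))
})

## ---------------------------------------------------------------------------
## SimilarityMatrix
## ---------------------------------------------------------------------------

#' Dense symmetric similarity matrix
#'
#' Square symmetric matrix of unitless similarities in [0, 1] over one
#' entity axis (miRNAs or diseases). Houses the semantic similarities
#' (SS1, SS2, SS), the Gaussian profile kernels (GM, GD), the functional
#' similarity FS, and the integrated networks SD and SM.
#'
#' @slot values numeric matrix, symmetric within 1e-9, entries in [0, 1],
#'   matching row/column names.
#'
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "matrix must have dimnames")
  else if (!identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column names must match")
  if (anyNA(v)) msg <- c(msg, "NA entries not allowed")
  else {
    if (max(abs(v - t(v))) > 1e-9) msg <- c(msg, "matrix not symmetric")
    if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
      msg <- c(msg, "entries must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values square symmetric matrix in [0, 1] with matching dimnames.
#' @return a \linkS4class{SimilarityMatrix}
#' @export
SimilarityMatrix <- function(values) {
  storage.mode(values) <- "double"
  new("SimilarityMatrix", values = values)
}

#' @rdname accessors
#' @export
setMethod("entityNames", "SimilarityMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("simValues", "SimilarityMatrix", function(x) x@values)

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  cat(sprintf("SimilarityMatrix: %d entities, range [%.3f, %.3f]\n",
              nrow(v), min(v), max(v)))
})

## ---------------------------------------------------------------------------
## DiseaseDAG / DAGCollection
## ---------------------------------------------------------------------------

#' MeSH-style ancestor DAG of one disease
#'
#' Directed acyclic graph DAG(D) of a target disease D: the node set T(D)
#' contains D and all its ancestor headings, and each edge points from a
#' parent heading to a child heading. Every node must reach the target by
#' following edges in the child direction.
#'
#' @slot target character(1), the disease the DAG belongs to.
#' @slot nodes character vector T(D), includes the target.
#' @slot edges character matrix with columns "parent" and "child"
#'   (zero rows for a root-only DAG).
#'
#' @exportClass DiseaseDAG
setClass("DiseaseDAG",
         representation(target = "character", nodes = "character",
                        edges = "matrix"))

.dagReachesTarget <- function(target, nodes, edges) {
  ## reverse-BFS from the target along parent->child edges
  reached <- target
  frontier <- target
  while (length(frontier)) {
    parents <- edges[edges[, "child"] %in% frontier, "parent"]
    frontier <- setdiff(parents, reached)
    reached <- c(reached, frontier)
  }
  all(nodes %in% reached)
}

.dagIsAcyclic <- function(nodes, edges) {
  if (nrow(edges) == 0L) return(TRUE)
  remaining <- edges
  repeat {
    if (nrow(remaining) == 0L) return(TRUE)
    srcs <- unique(remaining[, "parent"])
    sinks <- setdiff(unique(c(remaining)), srcs)  # nodes with no outgoing
    drop <- remaining[, "child"] %in% sinks
    if (!any(drop)) return(FALSE)
    remaining <- remaining[!drop, , drop = FALSE]
  }
}

setValidity("DiseaseDAG", function(object) {
  msg <- character()
  e <- object@edges
  if (length(object@target) != 1L) msg <- c(msg, "one target required")
  if (!object@target %in% object@nodes)
    msg <- c(msg, "target must be a node")
  if (ncol(e) != 2L || !identical(colnames(e), c("parent", "child")))
    msg <- c(msg, "edges must have columns parent, child")
  else {
    if (!all(c(e) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    if (!.dagIsAcyclic(object@nodes, e))
      msg <- c(msg, sprintf("cycle detected in DAG of '%s'", object@target))
    else if (!.dagReachesTarget(object@target, object@nodes, e))
      msg <- c(msg, "every node must reach the target")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DiseaseDAG
#'
#' @param target disease identifier.
#' @param edges two-column character matrix (parent, child); may have zero
#'   rows for a DAG consisting of the target alone.
#' @param nodes optional node set; defaults to the union of the target and
#'   all edge endpoints.
#' @return a \linkS4class{DiseaseDAG}
#' @export
DiseaseDAG <- function(target, edges = NULL, nodes = NULL) {
  if (is.null(edges))
    edges <- matrix(character(), 0, 2)
  edges <- as.matrix(edges)
  colnames(edges) <- c("parent", "child")
  if (is.null(nodes)) nodes <- unique(c(target, c(edges)))
  new("DiseaseDAG", target = target, nodes = nodes, edges = edges)
}

#' @rdname accessors
#' @export
setMethod("dagTarget", "DiseaseDAG", function(x) x@target)

#' @rdname accessors
#' @export
setMethod("dagNodes", "DiseaseDAG", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("dagEdges", "DiseaseDAG", function(x) x@edges)

setMethod("show", "DiseaseDAG", function(object) {
  cat(sprintf("DiseaseDAG '%s': %d nodes, %d edges\n", object@target,
              length(object@nodes), nrow(object@edges)))
})

#' Collection of per-disease ancestor DAGs
#'
#' Named list of \linkS4class{DiseaseDAG} objects, one per disease that
#' possesses a MeSH-style record. Diseases absent from the collection fall
#' back to the Gaussian profile kernel in the integrated disease network.
#'
#' @slot dags named list of \linkS4class{DiseaseDAG}; names equal targets.
#'
#' @exportClass DAGCollection
setClass("DAGCollection", representation(dags = "list"))

setValidity("DAGCollection", function(object) {
  msg <- character()
  if (length(object@dags)) {
    ok <- vapply(object@dags, function(d) is(d, "DiseaseDAG"), logical(1))
    if (!all(ok)) msg <- c(msg, "all elements must be DiseaseDAG")
    else {
      targets <- vapply(object@dags, dagTarget, character(1))
      if (!identical(unname(targets), unname(names(object@dags))))
        msg <- c(msg, "list names must equal DAG targets")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DAGCollection
#'
#' @param dags list of \linkS4class{DiseaseDAG} objects.
#' @return a \linkS4class{DAGCollection}
#' @export
DAGCollection <- function(dags = list()) {
  if (length(dags))
    names(dags) <- vapply(dags, dagTarget, character(1))
  new("DAGCollection", dags = dags)
}

#' @rdname accessors
#' @export
setMethod("diseaseNames", "DAGCollection", function(x) names(x@dags))

setMethod("show", "DAGCollection", function(object) {
  cat(sprintf("DAGCollection: %d disease DAGs\n", length(object@dags)))
})

setMethod("length", "DAGCollection", function(x) length(x@dags))

#' Extract one DAG from a collection
#' @param x a \linkS4class{DAGCollection}
#' @param i disease name or index
#' @param j,... unused
#' @export
setMethod("[[", "DAGCollection", function(x, i, j, ...) x@dags[[i]])

## ---------------------------------------------------------------------------
## HetNet
## ---------------------------------------------------------------------------

#' Typed miRNA-disease heterogeneous network
#'
#' Undirected graph over m miRNA nodes (type "M") and n disease nodes
#' (type "D") with three edge types: MD association edges (exactly the
#' 1-entries of A), and MM / DD similarity edges admitted by the chosen
#' edge rule. Node ids are integers 1..m for miRNAs and m+1..m+n for
#' diseases; an adjacency list is cached for meta-path enumeration.
#'
#' @slot nodeNames character vector of length m+n.
#' @slot nodeType character vector, "M" or "D" per node.
#' @slot edges data.frame(from, to, type, weight) with from < to.
#' @slot adj list of integer neighbor vectors, one per node.
#'
#' @exportClass HetNet
setClass("HetNet",
         representation(nodeNames = "character", nodeType = "character",
                        edges = "data.frame", adj = "list"))

setValidity("HetNet", function(object) {
  msg <- character()
  nv <- length(object@nodeNames)
  if (length(object@nodeType) != nv)
    msg <- c(msg, "nodeType length must match nodeNames")
  if (!all(object@nodeType %in% c("M", "D")))
    msg <- c(msg, "node types must be 'M' or 'D'")
  e <- object@edges
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-edges not allowed")
    if (any(e$from < 1L | e$to > nv)) msg <- c(msg, "edge index out of range")
  }
  if (length(object@adj) != nv)
    msg <- c(msg, "adjacency list length must match node count")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("netEdges", "HetNet", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("nodeTypes", "HetNet", function(x) {
  structure(x@nodeType, names = x@nodeNames)
})

#' @rdname accessors
#' @export
setMethod("mirnaNames", "HetNet", function(x) x@nodeNames[x@nodeType == "M"])

#' @rdname accessors
#' @export
setMethod("diseaseNames", "HetNet", function(x) x@nodeNames[x@nodeType == "D"])

setMethod("show", "HetNet", function(object) {
  tab <- table(factor(object@edges$type, levels = c("MM", "DD", "MD")))
  cat(sprintf(
    "HetNet: %d miRNAs + %d diseases; edges MM=%d DD=%d MD=%d\n",
    sum(object@nodeType == "M"), sum(object@nodeType == "D"),
    tab["MM"], tab["DD"], tab["MD"]))
})

## ---------------------------------------------------------------------------
## MDAModel
## ---------------------------------------------------------------------------

#' Trained combined-embedding association model
#'
#' Bundles the trained tensors (projections W^R/W^D, pair MLP, validity
#' head, GRU, attention pooling heads, per-type fusion vectors, scoring
#' head), the configuration they were trained under, the meta-path type
#' vocabulary, and the per-epoch loss log.
#'
#' @slot params named list of numeric arrays.
#' @slot config named list, see \code{\link{modelConfig}}.
#' @slot types character vector of meta-path type strings (e.g. "MMD").
#' @slot log data.frame with one row per epoch
#'   (epoch, loss_N, loss_M, loss_reg, total).
#' @slot cache list holding the training-time feature matrices, network
#'   and meta-path cache so prediction does not recompute them.
#'
#' @exportClass MDAModel
setClass("MDAModel",
         representation(params = "list", config = "list",
                        types = "character", log = "data.frame",
                        cache = "list"))

#' @rdname accessors
#' @export
setMethod("modelParams", "MDAModel", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("modelConfigOf", "MDAModel", function(x) x@config)

#' @rdname accessors
#' @export
setMethod("trainLog", "MDAModel", function(x) x@log)

setMethod("show", "MDAModel", function(object) {
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("MDAModel: %d parameters, %d meta-path types, %d epochs\n",
              np, length(object@types), nrow(object@log)))
  if (nrow(object@log))
    cat(sprintf("  final total loss: %.5f\n",
                object@log$total[nrow(object@log)]))
})

## ---------------------------------------------------------------------------
## CVReport
## ---------------------------------------------------------------------------

#' Cross-validation report
#'
#' Per-fold Mann-Whitney AUCs and their arithmetic mean for either global
#' leave-one-out (one entry per held-out positive) or repeated k-fold
#' cross-validation (one entry per fold x repeat).
#'
#' @slot scheme "loocv" or "kfold".
#' @slot folds integer fold count (k; for LOOCV the number of held-out
#'   positives).
#' @slot repeats integer repeat count.
#' @slot aucs numeric vector of per-fold AUCs in [0, 1].
#' @slot seed integer seed the partition was drawn under.
#'
#' @exportClass CVReport
setClass("CVReport",
         representation(scheme = "character", folds = "integer",
                        repeats = "integer", aucs = "numeric",
                        seed = "integer"))

setValidity("CVReport", function(object) {
  msg <- character()
  if (!object@scheme %in% c("loocv", "kfold"))
    msg <- c(msg, "scheme must be 'loocv' or 'kfold'")
  if (length(object@aucs) &&
      (min(object@aucs) < 0 || max(object@aucs) > 1))
    msg <- c(msg, "AUCs must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("cvAUCs", "CVReport", function(x) x@aucs)

#' @rdname accessors
#' @export
setMethod("meanAUC", "CVReport", function(x) mean(x@aucs))

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport [%s]: %d folds x %d repeats, mean AUC %.4f\n",
              object@scheme, object@folds, object@repeats,
              mean(object@aucs)))
})

## ---------------------------------------------------------------------------
## PlantedBenchmark
## ---------------------------------------------------------------------------

#' Planted block-structured synthetic benchmark
#'
#' Synthetic stand-in for the HMDD / MeSH / functional-similarity inputs:
#' miRNAs and diseases are assigned to matched blocks; associations are
#' denser within matched blocks, functional similarity is higher within
#' miRNA blocks, and disease DAGs share ancestors within disease blocks.
#'
#' @slot assoc \linkS4class{AssociationMatrix}
#' @slot fs \linkS4class{SimilarityMatrix} (functional similarity; 0 marks
#'   an undefined pair)
#' @slot dags \linkS4class{DAGCollection}
#' @slot mirnaBlock named integer block label per miRNA
#' @slot diseaseBlock named integer block label per disease
#' @slot noise numeric flip rate applied to the association cells
#' @slot seed integer generation seed
#'
#' @exportClass PlantedBenchmark
setClass("PlantedBenchmark",
         representation(assoc = "AssociationMatrix", fs = "SimilarityMatrix",
                        dags = "DAGCollection", mirnaBlock = "integer",
                        diseaseBlock = "integer", noise = "numeric",
                        seed = "integer"))

#' @rdname accessors
#' @export
setMethod("assocMatrix", "PlantedBenchmark", function(x) x@assoc@assoc)

#' @rdname accessors
#' @export
setMethod("mirnaNames", "PlantedBenchmark", function(x) mirnaNames(x@assoc))

#' @rdname accessors
#' @export
setMethod("diseaseNames", "PlantedBenchmark", function(x) diseaseNames(x@assoc))

setMethod("show", "PlantedBenchmark", function(object) {
  cat(sprintf(
    "PlantedBenchmark: %d x %d, %d blocks, noise %.3f, seed %d\n",
    nrow(object@assoc@assoc), ncol(object@assoc@assoc),
    length(unique(object@mirnaBlock)), object@noise, object@seed))
})
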