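#' @title Accessor generics
#' @description Accessors for the core S4 containers: entity names,
#'   underlying matrices, positive pairs, DAG structure, network structure,
#'   model parameters and cross-validation results.
#' @param x an object
#' @param ... further arguments for methods
#' @return the slot content documented on each method
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mirnaNames", function(x) standardGeneric("mirnaNames"))

#' @rdname accessors
#' @export
setGeneric("diseaseNames", function(x) standardGeneric("diseaseNames"))

#' @rdname accessors
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))

#' @rdname accessors
#' @export
setGeneric("positivePairs", function(x) standardGeneric("positivePairs"))

#' @rdname accessors
#' @export
setGeneric("entityNames", function(x) standardGeneric("entityNames"))

#' @rdname accessors
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' @rdname accessors
#' @export
setGeneric("dagTarget", function(x) standardGeneric("dagTarget"))

#' @rdname accessors
#' @export
setGeneric("dagNodes", function(x) standardGeneric("dagNodes"))

#' @rdname accessors
#' @export
setGeneric("dagEdges", function(x) standardGeneric("dagEdges"))

#' @rdname accessors
#' @export
setGeneric("netEdges", function(x) standardGeneric("netEdges"))

#' @rdname accessors
#' @export
setGeneric("nodeTypes", function(x) standardGeneric("nodeTypes"))

#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname accessors
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

#' @rdname accessors
#' @export
setGeneric("trainLog", function(x) standardGeneric("trainLog"))

#' @rdname accessors
#' @export
setGeneric("cvAUCs", function(x) standardGeneric("cvAUCs"))

#' @rdname accessors
#' @export
setGeneric("meanAUC", function(x) standardGeneric("meanAUC"))
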