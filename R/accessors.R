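#' @rdname ConditionExpression-class
#' @aliases geneIds,ConditionExpression-method
setMethod("geneIds", "ConditionExpression", function(x)
  rownames(SummarizedExperiment::assay(x, "normcounts")))

#' @rdname ConditionExpression-class
#' @aliases cellIds,ConditionExpression-method
setMethod("cellIds", "ConditionExpression", function(x)
  colnames(SummarizedExperiment::assay(x, "normcounts")))

#' @rdname ConditionExpression-class
#' @aliases exprValues,ConditionExpression-method
setMethod("exprValues", "ConditionExpression", function(x)
  SummarizedExperiment::assay(x, "normcounts"))

#' @rdname ConditionExpression-class
#' @aliases conditionLabel,ConditionExpression-method
setMethod("conditionLabel", "ConditionExpression", function(x)
  sprintf("%s_d%d", metadata(x)$line, metadata(x)$day))

#' @rdname InteractionNetwork-class
#' @aliases networkKind,InteractionNetwork-method
setMethod("networkKind", "InteractionNetwork", function(x) x@kind)

#' @rdname InteractionNetwork-class
#' @aliases networkNodes,InteractionNetwork-method
setMethod("networkNodes", "InteractionNetwork", function(x) x@nodes)

#' @rdname InteractionNetwork-class
#' @aliases networkEdges,InteractionNetwork-method
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

#' @rdname adjacencyMatrix
#' @aliases adjacencyMatrix,InteractionNetwork-method
setMethod("adjacencyMatrix", "InteractionNetwork", function(x, order) {
  stopifnot(!anyDuplicated(order))
  n <- length(order)
  A <- matrix(0, n, n, dimnames = list(order, order))
  e <- x@edges
  if (nrow(e)) {
    keep <- e[, 1L] %in% order & e[, 2L] %in% order
    e <- e[keep, , drop = FALSE]
    i <- match(e[, 1L], order); j <- match(e[, 2L], order)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
})

#' @rdname GeneSets-class
#' @aliases geneSetList,GeneSets-method
setMethod("geneSetList", "GeneSets", function(x) x@sets)

#' @rdname GeneSets-class
#' @aliases geneUniverse,GeneSets-method
setMethod("geneUniverse", "GeneSets", function(x) x@universe)

#' @rdname GeneSets-class
#' @aliases length,GeneSets-method
#' @export
setMethod("length", "GeneSets", function(x) length(x@sets))

#' @rdname GeneSets-class
#' @aliases names,GeneSets-method
#' @export
setMethod("names", "GeneSets", function(x) names(x@sets))

#' @rdname ConditionInputs-class
#' @param x a \linkS4class{ConditionInputs}
#' @export
conditionExpression <- function(x) x@expression

#' @rdname ConditionInputs-class
#' @export
conditionNetworks <- function(x) x@networks

#' Adjacency matrices of a condition, aligned to the expression rows
#'
#' @param x a \linkS4class{ConditionInputs}
#' @return named list of four dense symmetric 0/1 matrices in the row
#'   order of the expression matrix.
#' @export
adjacencyList <- function(x) {
  genes <- geneIds(x@expression)
  lapply(x@networks, adjacencyMatrix, order = genes)
}

#' @rdname NmtfFit-class
#' @param x an \linkS4class{NmtfFit}
#' @export
fittedFactors <- function(x) x@factors

#' @rdname NmtfFit-class
#' @export
objectiveHistory <- function(x) x@objective

#' @rdname NmtfFit-class
#' @export
isConverged <- function(x) x@converged

#' @rdname DimensionSelection-class
#' @param x a \linkS4class{DimensionSelection}
#' @export
chosenK <- function(x) x@chosenK

#' @rdname SyntheticStudy-class
#' @param x a \linkS4class{SyntheticStudy}
#' @export
studyConditions <- function(x) x@conditions

#' @rdname SyntheticStudy-class
#' @export
studyTruth <- function(x) x@truth

#' @rdname SyntheticStudy-class
#' @export
studyAnnotations <- function(x) x@annotations

setMethod("show", "ConditionExpression", function(object) {
  v <- exprValues(object)
  cat(sprintf("ConditionExpression: %d genes x %d cells (%s)\n",
              nrow(v), ncol(v), conditionLabel(object)))
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork [%s]: %d nodes, %d edges\n",
              object@kind, length(object@nodes), nrow(object@edges)))
})

setMethod("show", "GeneSets", function(object) {
  cat(sprintf("GeneSets: %d sets%s\n", length(object@sets),
              if (length(object@universe))
                sprintf(", universe of %d genes", length(object@universe)) else ""))
})

setMethod("show", "ConditionInputs", function(object) {
  cat(sprintf("ConditionInputs (%s): %d genes, %d cells\n",
              conditionLabel(object@expression),
              length(geneIds(object@expression)),
              length(cellIds(object@expression))))
  for (net in object@networks)
    cat(sprintf("  %-4s %d edges\n", net@kind, nrow(net@edges)))
})

setMethod("show", "NmtfFactors", function(object) {
  cat(sprintf("NmtfFactors: G1 %d x %d, G2 %d x %d\n",
              nrow(object@G1), ncol(object@G1),
              nrow(object@G2), ncol(object@G2)))
})

setMethod("show", "NmtfFit", function(object) {
  cat(sprintf("NmtfFit: k1=%d k2=%d, %d iterations, %s (final objective %.6g)\n",
              object@config@k1, object@config@k2, object@iterations,
              if (object@converged) "converged" else "not converged",
              utils::tail(object@objective, 1L)))
})

setMethod("show", "DimensionSelection", function(object) {
  cat("DimensionSelection:\n")
  for (i in seq_along(object@candidates))
    cat(sprintf("  k=%d  dispersion=%.4f%s\n", object@candidates[i],
                object@dispersion[i],
                if (object@candidates[i] == object@chosenK) "  <- chosen" else ""))
})

setMethod("show", "SyntheticStudy", function(object) {
  cfg <- object@config
  cat(sprintf("SyntheticStudy: %d conditions, %d genes, %d planted disease genes\n",
              length(object@conditions), cfg$n_genes, cfg$n_disease_genes))
})
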