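#' @rdname ConditionExpression-class
#' @param x a \linkS4class{ConditionExpression}
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ConditionExpression-class
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname ConditionExpression-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ConditionExpression-class
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname InteractionNetwork-class
#' @param x an \linkS4class{InteractionNetwork}
#' @export
setGeneric("networkKind", function(x) standardGeneric("networkKind"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Dense adjacency matrix of a network in a given gene order
#'
#' Genes in \code{order} that are absent from the network contribute
#' all-zero rows/columns, so the adjacency always materializes in the
#' row order of the expression matrix it accompanies.
#'
#' @param x an \linkS4class{InteractionNetwork}
#' @param order character vector of gene identifiers defining row/column
#'   order; defaults to the network node set.
#' @return symmetric 0/1 numeric matrix with dimnames \code{order}.
#' @export
setGeneric("adjacencyMatrix",
  function(x, order = networkNodes(x)) standardGeneric("adjacencyMatrix"))

#' @rdname GeneSets-class
#' @param x a \linkS4class{GeneSets}
#' @export
setGeneric("geneSetList", function(x) standardGeneric("geneSetList"))

#' @rdname GeneSets-class
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' Objective of the joint tri-factorization
#'
#' The sum of the five squared Frobenius residuals: one per network
#' (\eqn{\|A_i - G_1 S_i G_1^T\|_F^2}) plus the expression term
#' (\eqn{\|E - G_1 S_5 G_2^T\|_F^2}).
#'
#' @param factors an \linkS4class{NmtfFactors}
#' @param inputs a \linkS4class{ConditionInputs}
#' @return a single non-negative number.
#' @export
setGeneric("objectiveValue",
  function(factors, inputs) standardGeneric("objectiveValue"))

#' Gene embeddings in the cell-factor coordinate system
#'
#' Projects the shared gene factor into the space spanned by the cell
#' factor: \eqn{U = G_1 S_5}.  Rows of U are the gene embeddings used for
#' the gene-mapping-matrix and gene-movement analyses.
#'
#' @param factors an \linkS4class{NmtfFactors} or \linkS4class{NmtfFit}
#' @return an n x k2 non-negative matrix with gene row names.
#' @export
setGeneric("computeU", function(factors) standardGeneric("computeU"))
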