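#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.NETWORK_KINDS <- c("PPI", "GI", "COEX", "MI")

#' Expression matrix for one cell condition
#'
#' A non-negative normalized gene-by-cell expression matrix for a single
#' cell condition (one cell line at one differentiation day), stored as a
#' \linkS4class{SummarizedExperiment} with a single \code{"normcounts"}
#' assay.  The condition (line and day) lives in the object metadata.
#'
#' @slot .. inherited from \code{SummarizedExperiment}; the single assay is
#'   the normalized count matrix with genes in rows, cells in columns.
#'
#' @seealso [ConditionExpression()] for the constructor,
#'   [geneIds()], [cellIds()], [exprValues()] for accessors.
#' @export
setClass("ConditionExpression", contains = "SummarizedExperiment")

setValidity("ConditionExpression", function(object) {
  a <- SummarizedExperiment::assays(object)
  if (length(a) != 1L || !identical(names(a), "normcounts"))
    return("must hold exactly one assay named 'normcounts'")
  v <- a[["normcounts"]]
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("gene and cell identifiers are required as dimnames")
  if (anyDuplicated(rownames(v))) return("duplicate gene identifiers")
  if (anyDuplicated(colnames(v))) return("duplicate cell identifiers")
  if (!is.numeric(v) || anyNA(v)) return("values must be numeric and non-missing")
  if (any(v < 0)) return("expression values must be non-negative")
  md <- metadata(object)
  if (!is.character(md$line) || !md$line %in% c("control", "disease"))
    return("metadata 'line' must be 'control' or 'disease'")
  if (!is.numeric(md$day) || length(md$day) != 1L || md$day < 0)
    return("metadata 'day' must be a single non-negative number")
  TRUE
})

#' Undirected gene-gene interaction network
#'
#' A simple undirected graph over gene identifiers: one of the four
#' molecular network kinds (protein-protein, genetic, co-expression,
#' metabolic co-pathway).  Edges are stored canonically (lexicographically
#' smaller endpoint first), with no self-loops or duplicates.
#'
#' @slot kind one of \code{"PPI"}, \code{"GI"}, \code{"COEX"}, \code{"MI"}.
#' @slot nodes character vector of gene identifiers.
#' @slot edges two-column character matrix of gene-id pairs.
#'
#' @seealso [InteractionNetwork()], [readEdgeList()], [adjacencyMatrix()]
#' @export
setClass("InteractionNetwork",
  representation(kind = "character", nodes = "character", edges = "matrix"))

setValidity("InteractionNetwork", function(object) {
  if (length(object@kind) != 1L || !object@kind %in% .NETWORK_KINDS)
    return(sprintf("kind must be one of %s", paste(.NETWORK_KINDS, collapse = ", ")))
  if (anyDuplicated(object@nodes)) return("duplicate node identifiers")
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have two columns")
  if (nrow(e)) {
    if (!is.character(e)) return("edges must be a character matrix")
    if (any(e[, 1L] == e[, 2L])) return("self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L])) return("edges must be stored canonically (u < v)")
    if (anyDuplicated(paste(e[, 1L], e[, 2L]))) return("duplicate edges")
    if (!all(c(e) %in% object@nodes)) return("edge endpoint not in node set")
  }
  TRUE
})

#' Named gene-set collection
#'
#' A collection of named gene sets (GMT-style), with an optional explicit
#' universe of gene identifiers.
#'
#' @slot sets named list of character vectors (unique set names,
#'   non-empty members).
#' @slot universe character vector; may be empty when no universe is
#'   declared.
#'
#' @seealso [GeneSets()], [readGmt()]
#' @export
setClass("GeneSets",
  representation(sets = "list", universe = "character"))

setValidity("GeneSets", function(object) {
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      return("every gene set must be named")
    if (anyDuplicated(names(s))) return("duplicate gene-set names")
    ok <- vapply(s, function(g) is.character(g) && length(g) > 0L && all(nzchar(g)),
                 logical(1))
    if (!all(ok)) return("gene sets must be non-empty character vectors")
  }
  TRUE
})

#' Aligned inputs for one cell condition
#'
#' The expression matrix of one cell condition together with the four
#' molecular networks induced on its gene set, i.e. everything the joint
#' tri-factorization of that condition consumes.
#'
#' @slot expression a \linkS4class{ConditionExpression}.
#' @slot networks named list of four \linkS4class{InteractionNetwork}
#'   objects (PPI, GI, COEX, MI), each with node set contained in the
#'   expression gene set.
#'
#' @seealso [conditionInputs()], [adjacencyList()]
#' @export
setClass("ConditionInputs",
  representation(expression = "ConditionExpression", networks = "list"))

setValidity("ConditionInputs", function(object) {
  nets <- object@networks
  if (!identical(sort(names(nets)), sort(.NETWORK_KINDS)))
    return("networks must be a named list with kinds PPI, GI, COEX, MI")
  genes <- rownames(SummarizedExperiment::assay(object@expression))
  for (kind in .NETWORK_KINDS) {
    net <- nets[[kind]]
    if (!is(net, "InteractionNetwork")) return("networks must be InteractionNetwork")
    if (!identical(net@kind, kind))
      return(sprintf("network stored under '%s' has kind '%s'", kind, net@kind))
    if (!all(net@nodes %in% genes))
      return(sprintf("%s network has nodes outside the expression gene set", kind))
  }
  TRUE
})

#' Solver configuration for the joint tri-factorization
#'
#' @slot k1 gene-space latent rank.
#' @slot k2 cell-space latent rank.
#' @slot maxIter iteration cap for the multiplicative-update solver.
#' @slot checkEvery objective recording/convergence-check period (iterations).
#' @slot relTol relative-change convergence threshold.
#' @slot epsilon denominator safeguard added in every update.
#' @slot seed integer seed carried along for downstream stochastic steps.
#'
#' @seealso [nmtfConfig()], [nmtfFit()]
#' @export
setClass("NmtfConfig",
  representation(k1 = "integer", k2 = "integer", maxIter = "integer",
                 checkEvery = "integer", relTol = "numeric",
                 epsilon = "numeric", seed = "integer"))

setValidity("NmtfConfig", function(object) {
  if (object@k1 < 1L || object@k2 < 1L) return("k1 and k2 must be positive")
  if (object@maxIter < 1L) return("maxIter must be positive")
  if (object@checkEvery < 1L) return("checkEvery must be positive")
  if (object@relTol <= 0) return("relTol must be positive")
  if (object@epsilon <= 0) return("epsilon must be positive")
  TRUE
})

#' Factor set of the joint tri-factorization
#'
#' Holds the shared gene factor G1 (n x k1), the cell factor G2 (m x k2),
#' the four network middle factors S[[i]] (k1 x k1) and the expression
#' middle factor S5 (k1 x k2), so that each network adjacency is
#' approximated by G1 S_i G1' and the expression matrix by G1 S5 G2'.
#'
#' @slot G1 non-negative gene factor, rows named by gene.
#' @slot G2 non-negative cell factor, rows named by cell.
#' @slot S list of four non-negative k1 x k1 matrices, named by network kind.
#' @slot S5 non-negative k1 x k2 matrix.
#'
#' @seealso [nmtfFit()], [computeU()]
#' @export
setClass("NmtfFactors",
  representation(G1 = "matrix", G2 = "matrix", S = "list", S5 = "matrix"))

setValidity("NmtfFactors", function(object) {
  k1 <- ncol(object@G1); k2 <- ncol(object@G2)
  if (length(object@S) != 4L) return("S must hold four matrices")
  if (any(object@G1 < 0) || any(object@G2 < 0)) return("G1 and G2 must be non-negative")
  for (Si in object@S)
    if (!all(dim(Si) == c(k1, k1))) return("each S factor must be k1 x k1")
  if (!all(dim(object@S5) == c(k1, k2))) return("S5 must be k1 x k2")
  TRUE
})

#' Fitted joint tri-factorization
#'
#' @slot factors the final \linkS4class{NmtfFactors}.
#' @slot objective objective values recorded at iteration 0 and every
#'   \code{checkEvery} iterations thereafter.
#' @slot iterations number of multiplicative sweeps performed.
#' @slot converged whether the relative-change stopping rule fired before
#'   the iteration cap.
#' @slot config the \linkS4class{NmtfConfig} used.
#'
#' @seealso [nmtfFit()]
#' @export
setClass("NmtfFit",
  representation(factors = "NmtfFactors", objective = "numeric",
                 iterations = "integer", converged = "logical",
                 config = "NmtfConfig"))

setValidity("NmtfFit", function(object) {
  if (!length(object@objective)) return("objective history must be non-empty")
  if (utils::tail(object@objective, 1L) < 0) return("objective must be non-negative")
  TRUE
})

#' Dispersion-based latent-rank selection result
#'
#' @slot candidates candidate ranks, in the order evaluated.
#' @slot dispersion consensus dispersion coefficient per candidate, in [0,1].
#' @slot chosenK the candidate attaining the maximum dispersion (smallest
#'   such candidate on ties).
#'
#' @seealso [selectDimension()], [dispersionCoefficient()]
#' @export
setClass("DimensionSelection",
  representation(candidates = "integer", dispersion = "numeric",
                 chosenK = "integer"))

setValidity("DimensionSelection", function(object) {
  if (length(object@candidates) != length(object@dispersion))
    return("one dispersion value per candidate is required")
  if (any(object@dispersion < -1e-12 | object@dispersion > 1 + 1e-12))
    return("dispersion must lie in [0, 1]")
  best <- max(object@dispersion)
  if (!object@chosenK %in% object@candidates[object@dispersion >= best - 1e-12])
    return("chosenK must attain the maximum dispersion")
  TRUE
})

#' Synthetic paired control/disease study
#'
#' A generated multi-timepoint study: per-condition aligned inputs, the
#' planted ground truth (gene blocks, disease genes, the designated
#' perturbation block) and the annotation gene sets, as produced by
#' [generateStudy()].
#'
#' @slot conditions named list of \linkS4class{ConditionInputs}, names of
#'   the form \code{control_d0}, \code{disease_d0}, ...
#' @slot truth list with elements \code{geneBlocks} (named integer),
#'   \code{cellBlocks} (named integer), \code{plantedGenes},
#'   \code{annotatedPlanted}, \code{diseaseBlock}.
#' @slot annotations a \linkS4class{GeneSets} holding the
#'   \code{disease_genes} annotation set and per-block pathway sets.
#' @slot config the study configuration list (see [studyConfig()]).
#'
#' @seealso [generateStudy()], [runPipeline()]
#' @export
setClass("SyntheticStudy",
  representation(conditions = "list", truth = "list",
                 annotations = "GeneSets", config = "list"))

setValidity("SyntheticStudy", function(object) {
  if (!length(object@conditions)) return("study must hold at least one condition")
  ok <- vapply(object@conditions, is, logical(1), "ConditionInputs")
  if (!all(ok)) return("conditions must be ConditionInputs objects")
  TRUE
})
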