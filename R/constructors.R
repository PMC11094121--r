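#' Construct a ConditionExpression
#'
#' @param values non-negative numeric matrix, genes in rows, cells in
#'   columns, with unique dimnames.
#' @param line `"control"` or `"disease"`.
#' @param day non-negative integer differentiation day.
#' @return a \linkS4class{ConditionExpression}
#' @examples
#' e <- ConditionExpression(matrix(1:6, 3, 2,
#'        dimnames = list(c("g1","g2","g3"), c("c1","c2"))), "control", 0)
#' geneIds(e)
#' @export
ConditionExpression <- function(values, line = c("control", "disease"), day = 0L) {
  line <- match.arg(line)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(normcounts = values),
    metadata = list(line = line, day = as.integer(day)))
  methods::new("ConditionExpression", se)
}

#' Construct an InteractionNetwork
#'
#' Edges are canonicalized (unordered pairs), self-loops dropped and
#' duplicates collapsed; the node set defaults to the union of edge
#' endpoints but may be extended with isolated nodes.
#'
#' @param kind one of `"PPI"`, `"GI"`, `"COEX"`, `"MI"`.
#' @param from,to character vectors of edge endpoints (may be empty).
#' @param nodes optional character vector of node identifiers; the union
#'   of endpoints is always included.
#' @return an \linkS4class{InteractionNetwork}
#' @examples
#' net <- InteractionNetwork("PPI", c("a","b","c"), c("b","a","c"))
#' networkEdges(net)   # single canonical edge a-b; the self-loop is dropped
#' @export
InteractionNetwork <- function(kind, from = character(), to = character(),
                               nodes = NULL) {
  stopifnot(length(from) == length(to))
  from <- as.character(from); to <- as.character(to)
  endpoints <- c(from, to)  # self-loop endpoints stay in the node set
  keep <- from != to
  u <- pmin(from[keep], to[keep])
  v <- pmax(from[keep], to[keep])
  key <- !duplicated(paste(u, v))
  edges <- cbind(u[key], v[key])
  if (!nrow(edges)) edges <- matrix(character(), 0L, 2L)
  colnames(edges) <- c("from", "to")
  allnodes <- unique(c(nodes, endpoints))
  methods::new("InteractionNetwork", kind = kind,
               nodes = as.character(allnodes), edges = edges)
}

#' Construct a GeneSets collection
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param universe optional character vector of the gene universe.
#' @return a \linkS4class{GeneSets}
#' @export
GeneSets <- function(sets = list(), universe = character()) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  methods::new("GeneSets", sets = sets, universe = as.character(universe))
}

#' Bundle an expression matrix with its four condition-specific networks
#'
#' Each network is induced on the expression gene set, so the stored
#' networks are aligned with the expression rows by construction.
#'
#' @param expression a \linkS4class{ConditionExpression}
#' @param ppi,gi,coex,mi the four \linkS4class{InteractionNetwork}s
#'   (kinds are checked).
#' @return a \linkS4class{ConditionInputs}
#' @seealso [induceNetwork()]
#' @export
conditionInputs <- function(expression, ppi, gi, coex, mi) {
  nets <- list(PPI = ppi, GI = gi, COEX = coex, MI = mi)
  genes <- geneIds(expression)
  nets <- lapply(nets, induceNetwork, genes = genes)
  methods::new("ConditionInputs", expression = expression, networks = nets)
}

#' Solver configuration
#'
#' Defaults follow the method's stated protocol: the objective is checked
#' every 10 iterations and iteration stops when the relative change over
#' one check period drops to `1e-3` or below.
#'
#' @param k1,k2 latent ranks of the gene and cell embedding spaces.
#' @param maxIter iteration cap (default 1000).
#' @param checkEvery check period in iterations (default 10).
#' @param relTol relative-change stopping threshold (default 1e-3).
#' @param epsilon denominator safeguard (default 1e-10).
#' @param seed integer seed used by stochastic downstream steps.
#' @return an \linkS4class{NmtfConfig}
#' @export
nmtfConfig <- function(k1, k2, maxIter = 1000L, checkEvery = 10L,
                       relTol = 1e-3, epsilon = 1e-10, seed = 1L) {
  methods::new("NmtfConfig", k1 = as.integer(k1), k2 = as.integer(k2),
               maxIter = as.integer(maxIter), checkEvery = as.integer(checkEvery),
               relTol = as.numeric(relTol), epsilon = as.numeric(epsilon),
               seed = as.integer(seed))
}

#' Assemble an NmtfFactors object
#'
#' @param G1,G2,S,S5 the factor matrices (see
#'   \linkS4class{NmtfFactors}); `S` is a list of four k1 x k1 matrices.
#' @return an \linkS4class{NmtfFactors}
#' @export
NmtfFactors <- function(G1, G2, S, S5) {
  if (is.null(names(S))) names(S) <- .NETWORK_KINDS
  methods::new("NmtfFactors", G1 = G1, G2 = G2, S = S, S5 = S5)
}
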