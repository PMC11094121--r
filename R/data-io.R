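#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported.  `"dense_table"` is a tab-separated
#' table with gene identifiers in the first column and cell identifiers in
#' the header.  `"mtx_triplet"` is a MatrixMarket file (1-based triplet
#' indices) accompanied by `genes.tsv` and `cells.tsv` label files in the
#' same directory (one identifier per line).
#'
#' @param path file path (the `.mtx` file for the triplet layout).
#' @param format `"dense_table"` or `"mtx_triplet"`.
#' @param line,day condition attached to the returned object.
#' @return a \linkS4class{ConditionExpression}
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, format = c("dense_table", "mtx_triplet"),
                           line = "control", day = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense_table") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("parse error in ", path, ": need gene column plus cells")
    genes <- as.character(tab[[1L]])
    if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
    values <- as.matrix(tab[, -1L, drop = FALSE])
    if (anyDuplicated(colnames(values))) stop("duplicate cell identifiers in ", path)
    storage.mode(values) <- "double"
    rownames(values) <- genes
  } else {
    m <- Matrix::readMM(path)
    dir <- dirname(path)
    gfile <- file.path(dir, "genes.tsv"); cfile <- file.path(dir, "cells.tsv")
    if (!file.exists(gfile) || !file.exists(cfile))
      stop("MTX layout requires genes.tsv and cells.tsv next to ", path)
    genes <- readLines(gfile); cells <- readLines(cfile)
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("label files do not match matrix dimensions for ", path)
    values <- as.matrix(m)
    dimnames(values) <- list(genes, cells)
  }
  if (anyNA(values)) stop("missing values in ", path)
  if (any(values < 0)) stop("negative expression values in ", path)
  ConditionExpression(values, line = line, day = day)
}

#' Write an expression matrix to disk
#'
#' @param e a \linkS4class{ConditionExpression}
#' @param path output path (the `.mtx` file for the triplet layout).
#' @param format `"dense_table"` or `"mtx_triplet"`.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(e, path, format = c("dense_table", "mtx_triplet")) {
  format <- match.arg(format)
  v <- exprValues(e)
  if (format == "dense_table") {
    tab <- data.frame(gene = rownames(v), v, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(v, sparse = TRUE), "generalMatrix"),
                    path)
    writeLines(rownames(v), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(v), file.path(dirname(path), "cells.tsv"))
  }
  invisible(path)
}

#' Read an undirected edge list
#'
#' Expects a headerless two-column (optionally weighted; extra columns are
#' ignored) tab-separated file of gene pairs.  Self-loops are dropped and
#' duplicate or reversed-duplicate edges collapsed.
#'
#' @param path file path.
#' @param kind network kind (`"PPI"`, `"GI"`, `"COEX"`, `"MI"`).
#' @return an \linkS4class{InteractionNetwork}
#' @seealso [writeEdgeList()]
#' @export
readEdgeList <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L)
    return(InteractionNetwork(kind))
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("parse error in ", path, ": need two columns")
  InteractionNetwork(kind, as.character(tab[[1L]]), as.character(tab[[2L]]))
}

#' @rdname readEdgeList
#' @param net an \linkS4class{InteractionNetwork}
#' @export
writeEdgeList <- function(net, path) {
  utils::write.table(networkEdges(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`.  Sets without members and
#' duplicated set names are rejected.
#'
#' @param path file path.
#' @return a \linkS4class{GeneSets}
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("parse error in ", path, " line ", i, ": set has no members")
    nm <- f[1L]
    if (nm %in% names(sets)) stop("duplicate gene-set name '", nm, "' in ", path)
    sets[[nm]] <- f[-(1:2)]
  }
  GeneSets(sets)
}

#' @rdname readGmt
#' @param gs a \linkS4class{GeneSets}
#' @export
writeGmt <- function(gs, path) {
  sets <- geneSetList(gs)
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter an expression matrix to usable genes
#'
#' Retains exactly the genes that are (a) protein-coding per the supplied
#' list, (b) have at least one interaction in the reference PPI network,
#' and (c) show at least one strictly positive count in this condition.
#' Row order of surviving genes is preserved.
#'
#' @param e a \linkS4class{ConditionExpression}
#' @param proteinCoding character vector of protein-coding gene ids.
#' @param ppi the reference PPI \linkS4class{InteractionNetwork}.
#' @return the filtered \linkS4class{ConditionExpression}
#' @export
filterExpressedGenes <- function(e, proteinCoding, ppi) {
  v <- exprValues(e)
  deg <- table(factor(c(networkEdges(ppi)), levels = rownames(v)))
  keep <- rownames(v) %in% proteinCoding &
    as.integer(deg[rownames(v)]) >= 1L &
    rowSums(v > 0) > 0L
  if (!any(keep))
    stop("no genes survive the coding/PPI/expression filters")
  ConditionExpression(v[keep, , drop = FALSE],
                      line = metadata(e)$line, day = metadata(e)$day)
}

#' Induce a network on a gene set
#'
#' Restricts the node set to `nodes(net)` intersected with `genes` and
#' keeps only edges with both endpoints retained.  Idempotent; inducing
#' on a subset never adds edges.
#'
#' @param net an \linkS4class{InteractionNetwork}
#' @param genes character vector of gene identifiers to keep.
#' @return an \linkS4class{InteractionNetwork}
#' @export
induceNetwork <- function(net, genes) {
  nodes <- intersect(networkNodes(net), genes)
  e <- networkEdges(net)
  keep <- e[, 1L] %in% nodes & e[, 2L] %in% nodes
  e <- e[keep, , drop = FALSE]
  InteractionNetwork(networkKind(net), e[, 1L], e[, 2L], nodes = nodes)
}

#' Build a metabolic co-pathway network
#'
#' Connects two genes whenever some pathway in the collection contains
#' both, mirroring the construction of a metabolic interaction network
#' from pathway membership.
#'
#' @param pathways a \linkS4class{GeneSets} of pathway memberships.
#' @return an \linkS4class{InteractionNetwork} of kind `"MI"`.
#' @export
buildPathwayNetwork <- function(pathways) {
  from <- character(); to <- character(); nodes <- character()
  for (members in geneSetList(pathways)) {
    members <- unique(members)
    nodes <- c(nodes, members)
    if (length(members) >= 2L) {
      pr <- utils::combn(sort(members), 2L)
      from <- c(from, pr[1L, ]); to <- c(to, pr[2L, ])
    }
  }
  InteractionNetwork("MI", from, to, nodes = unique(nodes))
}

#' Build a co-expression network from a correlation matrix
#'
#' Keeps the `ceiling(topFraction * P)` unordered gene pairs with the
#' largest absolute correlation among all `P = n(n-1)/2` pairs (diagonal
#' ignored).  Ties at the cutoff are broken by lexicographic pair order so
#' the result is deterministic.
#'
#' @param corr symmetric numeric matrix with gene dimnames.
#' @param topFraction fraction of pairs to keep, in (0, 1].
#' @return an \linkS4class{InteractionNetwork} of kind `"COEX"`.
#' @export
buildCoexpressionNetwork <- function(corr, topFraction) {
  if (!is.numeric(topFraction) || topFraction <= 0 || topFraction > 1)
    stop("topFraction must lie in (0, 1]")
  genes <- rownames(corr)
  if (is.null(genes) || !identical(genes, colnames(corr)))
    stop("corr must have matching gene dimnames")
  n <- length(genes)
  idx <- which(upper.tri(corr), arr.ind = TRUE)
  u <- pmin(genes[idx[, 1L]], genes[idx[, 2L]])
  v <- pmax(genes[idx[, 1L]], genes[idx[, 2L]])
  strength <- abs(corr[idx])
  ord <- order(-strength, u, v)
  keep <- ord[seq_len(min(length(ord), ceiling(topFraction * nrow(idx))))]
  InteractionNetwork("COEX", u[keep], v[keep], nodes = genes)
}
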