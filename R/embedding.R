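#' Gene mapping matrix: norm-scaled pairwise embedding distances
#'
#' Entry (i, j) is the Euclidean distance between gene embeddings u_i and
#' u_j divided by the Frobenius norm of U.  The result is symmetric with
#' zero diagonal, invariant to multiplying U by a positive scalar and to
#' any orthogonal rotation of the embedding coordinates.
#'
#' @param U numeric matrix of gene embeddings (rows named by gene).
#' @return square symmetric matrix with gene dimnames.
#' @export
computeGeneMapping <- function(U) {
  fro <- sqrt(sum(U * U))
  if (fro == 0) stop("degenerate input: all-zero embedding matrix")
  D <- as.matrix(stats::dist(U)) / fro
  dimnames(D) <- list(rownames(U), rownames(U))
  D
}

#' Cross-condition gene movement
#'
#' Restricts both gene mapping matrices to their shared genes (rows and
#' columns, in a canonical sorted order) and returns, per shared gene, the
#' Euclidean distance between its restricted row in the two conditions.
#' Zero iff the gene's relative position (to all shared genes) is
#' unchanged; symmetric in its arguments.
#'
#' @param gmmA,gmmB gene mapping matrices with gene dimnames
#'   (see [computeGeneMapping()]).
#' @return named non-negative numeric vector over the shared genes.
#' @export
geneMovement <- function(gmmA, gmmB) {
  shared <- sort(intersect(rownames(gmmA), rownames(gmmB)))
  if (!length(shared)) stop("no shared genes between the two conditions")
  a <- gmmA[shared, shared, drop = FALSE]
  b <- gmmB[shared, shared, drop = FALSE]
  mv <- sqrt(rowSums((a - b)^2))
  names(mv) <- shared
  mv
}

## k-means++ seeding: spread initial centers with probability
## proportional to squared distance from the nearest chosen center.
.kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[centers[1L], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = probs)
    nd <- rowSums((X - matrix(X[centers[j + 1L], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  X[centers, , drop = FALSE]
}

#' Cluster genes by k-means on factor rows
#'
#' Runs k-means (squared-Euclidean objective) on the rows of a factor
#' matrix, with k-means++ seeding, keeping the best of `restarts`
#' initializations.  Deterministic given `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param X numeric matrix whose rows are clustered (typically the shared
#'   gene factor G1).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts number of random initializations (default 10).
#' @return named integer vector of labels in `1..k`, with attributes
#'   `k`, `seed` and `restarts`.
#' @export
clusterGenes <- function(X, k, seed = 1L, restarts = 10L) {
  if (k > nrow(X)) stop("more clusters than rows requested")
  if (k < 1L) stop("k must be positive")
  labels <- .withSeed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- .kmeansppCenters(X, k)
      centers <- centers + 1e-9 * (seq_len(k) - 1)  # guard duplicate centers
      km <- suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best$cluster
  })
  names(labels) <- rownames(X)
  attr(labels, "k") <- as.integer(k)
  attr(labels, "seed") <- as.integer(seed)
  attr(labels, "restarts") <- as.integer(restarts)
  labels
}

#' Hypergeometric cluster enrichment
#'
#' Per cluster, tests over-representation of an annotated gene set with a
#' one-sided hypergeometric upper tail \eqn{P(X \ge x)} where N is the
#' universe size, K the annotated genes in the universe, c the cluster
#' size and x the overlap.  Fold enrichment is `(x/c) / (K/N)`.  No
#' multiple-testing correction is applied here (the cluster screen uses a
#' raw p-value threshold); see [pathwayEnrichment()] for the BH-corrected
#' variant.
#'
#' @param labels named integer cluster labels (see [clusterGenes()]).
#' @param annotated character vector of annotated gene ids.
#' @param universe character vector of the gene universe; must contain
#'   all clustered genes.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @return `data.frame` with columns `cluster`, `size`, `overlap`,
#'   `p_value`, `fold_enrichment`, `significant`.
#' @export
clusterEnrichment <- function(labels, annotated, universe, alpha = 0.05) {
  genes <- names(labels)
  if (!all(genes %in% universe)) stop("clustered genes must lie in the universe")
  annotated <- intersect(annotated, universe)
  N <- length(universe); K <- length(annotated)
  if (K == 0L) warning("no annotated genes in the universe; all p-values are 1")
  cl <- sort(unique(labels))
  res <- lapply(cl, function(ci) {
    members <- genes[labels == ci]
    cs <- length(members)
    x <- length(intersect(members, annotated))
    p <- if (K == 0L) 1 else stats::phyper(x - 1L, K, N - K, cs, lower.tail = FALSE)
    fold <- if (K == 0L || cs == 0L) 0 else (x / cs) / (K / N)
    data.frame(cluster = ci, size = cs, overlap = x, p_value = p,
               fold_enrichment = fold, significant = p <= alpha)
  })
  do.call(rbind, res)
}

#' Percentage of significantly enriched clusters
#'
#' @param enrichment result of [clusterEnrichment()].
#' @return a number in \[0, 100\].
#' @export
percentEnrichedClusters <- function(enrichment) {
  100 * sum(enrichment$significant) / nrow(enrichment)
}
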