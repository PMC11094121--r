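#' One-sided Mann-Whitney U test
#'
#' Wrapper around the rank-sum machinery of [stats::wilcox.test()]: the
#' p-value is exact whenever both samples have fewer than 50 observations
#' and there are no ties, and otherwise uses the normal approximation with
#' continuity and tie correction.
#'
#' @param x,y numeric samples.
#' @param alternative `"greater"` tests whether `x` is stochastically
#'   larger than `y`; `"less"` the reverse.
#' @return list with `statistic` (the U statistic for `x`), `p.value`,
#'   `alternative`, `n1`, `n2` and `exact` (whether the exact path was
#'   used).
#' @export
mwuTest <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  pooled <- c(x, y)
  if (all(pooled == pooled[1L]))  # degenerate zero-variance case
    return(list(statistic = length(x) * length(y) / 2, p.value = 0.5,
                alternative = alternative, n1 = length(x), n2 = length(y),
                exact = FALSE))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) < 50 && length(y) < 50
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 0.5  # zero-variance degenerate case (all values tied)
  list(statistic = unname(wt$statistic), p.value = p,
       alternative = alternative, n1 = length(x), n2 = length(y),
       exact = exact)
}

#' Overlap significance by resampling
#'
#' Null model for the multi-way overlap of several observed gene sets:
#' per repetition, draw `|set_i|` genes uniformly *with replacement* from
#' each universe, reduce to distinct members, and record the size of the
#' multi-way intersection.  The empirical p-value uses the standard +1
#' pseudo-count, `(#{null >= observed} + 1) / (repetitions + 1)`, so it is
#' never exactly zero.  A without-replacement variant is available for
#' sensitivity analysis.
#'
#' @param observedSets list of character vectors (the observed gene sets).
#' @param universes list of character vectors, one universe per set (a
#'   single universe is recycled).
#' @param repetitions number of null draws (default 10000).
#' @param seed integer seed; the result is deterministic given it.
#' @param replace draw with replacement (default TRUE, the reference
#'   null); FALSE switches to plain subsampling.
#' @return list with `observed`, `null` (integer vector of null overlap
#'   sizes), `p.value` and `repetitions`.
#' @export
overlapResampling <- function(observedSets, universes, repetitions = 10000L,
                              seed = 1L, replace = TRUE) {
  if (repetitions < 100L) warning("fewer than 100 repetitions; p is unstable")
  if (length(universes) == 1L)
    universes <- rep(universes, length(observedSets))
  stopifnot(length(universes) == length(observedSets))
  for (i in seq_along(observedSets))
    if (!all(observedSets[[i]] %in% universes[[i]]))
      stop("observed set ", i, " is not contained in its universe")
  observed <- length(Reduce(intersect, observedSets))
  sizes <- lengths(observedSets)
  null <- .withSeed(seed, {
    vapply(seq_len(repetitions), function(r) {
      draws <- lapply(seq_along(sizes), function(i)
        unique(sample(universes[[i]], sizes[i], replace = replace)))
      length(Reduce(intersect, draws))
    }, integer(1))
  })
  p <- (sum(null >= observed) + 1) / (repetitions + 1)
  list(observed = observed, null = null, p.value = p,
       repetitions = as.integer(repetitions))
}

#' Shortest-path distances from gene groups to a target gene
#'
#' Breadth-first unweighted shortest paths in an interaction network from
#' a target gene; reports per-group distance vectors and means.  The
#' target itself is excluded from every group; unreachable genes are
#' listed separately and excluded from the means.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param target gene identifier; must be a network node.
#' @param groups named list of character vectors of gene ids.
#' @return named list, per group: `distances` (named numeric),
#'   `unreachable` (character), `mean`.
#' @export
shortestPathsToTarget <- function(net, target, groups) {
  nodes <- networkNodes(net)
  if (!target %in% nodes) stop("target gene '", target, "' is not in the network")
  e <- networkEdges(net)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e[, 1L], to = e[, 2L]),
    directed = FALSE, vertices = data.frame(name = nodes))
  d <- igraph::distances(g, v = target, mode = "all")[1L, ]
  lapply(groups, function(members) {
    members <- setdiff(intersect(members, nodes), target)
    dm <- d[members]
    reach <- is.finite(dm)
    list(distances = dm[reach], unreachable = members[!reach],
         mean = if (any(reach)) mean(dm[reach]) else NaN)
  })
}

#' Hypergeometric enrichment of a prediction set in an annotated set
#'
#' Upper-tail hypergeometric test over the universe formed by the union
#' of predictions and background; also reports the fraction of
#' predictions that are annotated.
#'
#' @param predictions,annotated,background character vectors of gene ids.
#' @return list with `p.value`, `fraction`, `overlap`, `universe_size`,
#'   `annotated_in_universe`.
#' @export
geneSetEnrichment <- function(predictions, annotated, background) {
  universe <- union(predictions, background)
  annotated <- intersect(annotated, universe)
  N <- length(universe); K <- length(annotated)
  drawn <- length(predictions)
  x <- length(intersect(predictions, annotated))
  p <- if (K == 0L) 1 else stats::phyper(x - 1L, K, N - K, drawn, lower.tail = FALSE)
  list(p.value = p,
       fraction = if (drawn) x / drawn else 0,
       overlap = x, universe_size = N, annotated_in_universe = K)
}

#' BH-corrected pathway enrichment of a prediction set
#'
#' One hypergeometric upper-tail test per pathway over the universe
#' `union(predictions, background)`, followed by Benjamini-Hochberg
#' step-up adjustment across all tested pathways.  Rows are ordered by
#' adjusted p-value (smallest first), ties by raw p then pathway name.
#'
#' @param predictions character vector of predicted gene ids.
#' @param pathways a \linkS4class{GeneSets} of pathway memberships.
#' @param background character vector of background gene ids.
#' @param alpha significance threshold on the adjusted p-value.
#' @return `data.frame` with columns `pathway`, `overlap`, `pathway_size`,
#'   `p_value`, `p_adjusted`, `fold_enrichment`, `significant`.
#' @export
pathwayEnrichment <- function(predictions, pathways, background, alpha = 0.05) {
  universe <- union(predictions, background)
  drawn <- length(predictions)
  N <- length(universe)
  sets <- geneSetList(pathways)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    x <- length(intersect(predictions, members))
    p <- if (K == 0L) 1 else stats::phyper(x - 1L, K, N - K, drawn,
                                           lower.tail = FALSE)
    fold <- if (K == 0L || drawn == 0L) 0 else (x / drawn) / (K / N)
    data.frame(pathway = nm, overlap = x, pathway_size = K,
               p_value = p, fold_enrichment = fold)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted <= alpha
  out <- out[order(out$p_adjusted, out$p_value, out$pathway), ]
  rownames(out) <- NULL
  out[, c("pathway", "overlap", "pathway_size", "p_value", "p_adjusted",
          "fold_enrichment", "significant")]
}
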