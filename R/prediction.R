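#' Stage-specific disease-gene predictions
#'
#' Step one of the two-step downstream method: take the union of genes in
#' clusters significantly enriched in the known disease-gene set, drop
#' genes already labelled as disease genes, and keep only genes expressed
#' in the time-matched control condition.
#'
#' @param enrichment result of [clusterEnrichment()] for this condition's
#'   clustering.
#' @param labels the cluster labels the enrichment refers to.
#' @param diseaseGenes character vector of known disease-gene ids.
#' @param controlExpressed character vector of genes expressed in the
#'   matched control condition.
#' @param day the time point (carried through for bookkeeping).
#' @return list with elements `day`, `genes` (sorted character vector)
#'   and `clusters` (labels of the contributing enriched clusters).
#' @export
stagePredictions <- function(enrichment, labels, diseaseGenes,
                             controlExpressed, day = NA_integer_) {
  sig <- enrichment$cluster[enrichment$significant]
  candidates <- names(labels)[labels %in% sig]
  genes <- setdiff(candidates, diseaseGenes)
  genes <- intersect(genes, controlExpressed)
  list(day = as.integer(day), genes = sort(genes), clusters = sig)
}

#' Core predictions: intersect stages and rank by average movement
#'
#' Step two: intersect the stage-specific prediction sets across all time
#' points and rank the surviving genes by their average movement across
#' time points, largest first.  Ties are broken lexicographically by gene
#' identifier so the ranking is reproducible.
#'
#' @param stages list of stage-prediction results (see
#'   [stagePredictions()]); at least two.
#' @param movements named list of per-day movement vectors (see
#'   [geneMovement()]), one per stage, in stage order.
#' @return `data.frame` with columns `gene`, `avg_movement`, one
#'   `movement_d<day>` column per stage, and `rank`.
#' @export
corePredictions <- function(stages, movements) {
  if (length(stages) < 2L) stop("at least two stages are required")
  if (length(movements) != length(stages))
    stop("one movement vector per stage is required")
  core <- Reduce(intersect, lapply(stages, `[[`, "genes"))
  days <- vapply(stages, `[[`, integer(1), "day")
  cols <- sprintf("movement_d%d", days)
  if (!length(core)) {
    out <- data.frame(gene = character(), avg_movement = numeric())
    for (cn in cols) out[[cn]] <- numeric()
    out$rank <- integer()
    return(out)
  }
  per <- vapply(seq_along(movements), function(i) {
    mv <- movements[[i]]
    missing <- setdiff(core, names(mv))
    if (length(missing))
      stop("gene ", missing[1L], " has no movement value at day ", days[i])
    mv[core]
  }, numeric(length(core)))
  per <- matrix(per, nrow = length(core),
                dimnames = list(core, cols))
  avg <- rowMeans(per)
  ord <- order(-avg, core)
  out <- data.frame(gene = core[ord], avg_movement = avg[ord],
                    per[ord, , drop = FALSE], row.names = NULL,
                    check.names = FALSE)
  out$rank <- seq_len(nrow(out))
  out
}

#' Pairwise and global overlap of stage predictions
#'
#' @param stages list of stage-prediction results.
#' @return list with `pairwise` (symmetric matrix of intersection sizes,
#'   diagonal = set sizes) and `global` (size of the all-way
#'   intersection).
#' @export
stageOverlap <- function(stages) {
  sets <- lapply(stages, `[[`, "genes")
  ns <- length(sets)
  M <- matrix(0L, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns))
    M[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  days <- vapply(stages, `[[`, integer(1), "day")
  dimnames(M) <- list(sprintf("d%d", days), sprintf("d%d", days))
  list(pairwise = M, global = length(Reduce(intersect, sets)))
}
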