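#' Run the full integration and prediction pipeline on a study
#'
#' For each time point: fits the joint tri-factorization of the control
#' and disease conditions, projects gene embeddings (`U = G1 S5`),
#' computes the two gene mapping matrices and the cross-condition gene
#' movement; clusters the disease gene factor G1 into k1 clusters,
#' screens the clusters for enrichment in the known disease-gene set,
#' and extracts the stage-specific predictions.  Finally intersects the
#' stages into the core predictions ranked by average movement.
#'
#' @param study a \linkS4class{SyntheticStudy} (or any object with the
#'   same condition layout).
#' @param k1,k2 latent ranks; default to the study's planted block
#'   counts.
#' @param alpha raw p-value threshold of the cluster enrichment screen.
#' @param maxIter,seed passed to the solver configuration.
#' @return list with elements `fits` (per condition), `movements`
#'   (per day, named `d<day>`), `clusterings`, `enrichments`,
#'   `stages`, `core` (the ranked core-prediction table),
#'   `overlap` (stage overlap summary).
#' @export
runPipeline <- function(study, k1 = study@config$k_true,
                        k2 = study@config$k2_true, alpha = 0.05,
                        maxIter = 1000L, seed = study@config$seed) {
  conds <- studyConditions(study)
  labels <- names(conds)
  days <- sort(unique(as.integer(sub("^.*_d", "", labels))))
  diseaseGenes <- geneSetList(studyAnnotations(study))$disease_genes

  fits <- list(); movements <- list()
  clusterings <- list(); enrichments <- list(); stages <- list()
  for (d in days) {
    cn <- sprintf("control_d%d", d); dn <- sprintf("disease_d%d", d)
    cfg <- nmtfConfig(k1, k2, maxIter = maxIter, seed = seed)
    fits[[cn]] <- nmtfFit(conds[[cn]], cfg)
    fits[[dn]] <- nmtfFit(conds[[dn]], cfg)
    gmmC <- computeGeneMapping(computeU(fits[[cn]]))
    gmmD <- computeGeneMapping(computeU(fits[[dn]]))
    movements[[sprintf("d%d", d)]] <- geneMovement(gmmC, gmmD)

    G1d <- fittedFactors(fits[[dn]])@G1
    labs <- clusterGenes(G1d, k1, seed = seed + d)
    clusterings[[dn]] <- labs
    universe <- geneIds(conditionExpression(conds[[dn]]))
    enr <- clusterEnrichment(labs, diseaseGenes, universe, alpha = alpha)
    enrichments[[dn]] <- enr
    vc <- exprValues(conditionExpression(conds[[cn]]))
    controlExpressed <- rownames(vc)[rowSums(vc > 0) > 0L]
    stages[[sprintf("d%d", d)]] <-
      stagePredictions(enr, labs, diseaseGenes, controlExpressed, day = d)
  }
  core <- corePredictions(stages, movements)
  list(fits = fits, movements = movements, clusterings = clusterings,
       enrichments = enrichments, stages = stages, core = core,
       overlap = stageOverlap(stages))
}

#' Write the pipeline's result tables
#'
#' Emits, per day, the movement table (`gene`, `movement`), cluster table
#' (`gene`, `label`) and enrichment table, plus the per-stage prediction
#' lists and the ranked core-prediction table.  All outputs are UTF-8
#' tab-separated.
#'
#' @param result a [runPipeline()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writePipelineResults <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  for (dn in names(result$movements)) {
    mv <- result$movements[[dn]]
    wt(data.frame(gene = names(mv), movement = unname(mv)),
       sprintf("movement_%s.tsv", dn))
  }
  for (cn in names(result$clusterings)) {
    labs <- result$clusterings[[cn]]
    wt(data.frame(gene = names(labs), label = unname(labs)),
       sprintf("clusters_%s.tsv", cn))
    wt(result$enrichments[[cn]], sprintf("enrichment_%s.tsv", cn))
  }
  for (dn in names(result$stages))
    writeLines(result$stages[[dn]]$genes,
               file.path(dir, sprintf("stage_predictions_%s.tsv", dn)))
  wt(result$core, "core_predictions.tsv")
  invisible(dir)
}
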