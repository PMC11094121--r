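#' Configuration for a synthetic paired control/disease study
#'
#' The generator plants k_true gene blocks and k2_true cell blocks in a
#' non-negative factor model, draws four stochastic-block-model networks
#' aligned to the gene blocks, and, in disease conditions, mixes a set of
#' planted disease genes toward a designated perturbation block so that
#' their relative embedding geometry shifts between the two lines.
#'
#' @param n_genes,n_cells study dimensions.
#' @param n_timepoints number of paired time points (default 4; days are
#'   labelled 0, 6, 15, 21 for a four-stage design).
#' @param k_true,k2_true planted gene- and cell-block counts.
#' @param noise_sd standard deviation of the half-normal expression noise.
#' @param n_disease_genes number of planted disease genes.
#' @param perturbation_strength mixing weight toward the perturbation
#'   block in disease conditions (0 = none; values above 1 saturate).
#' @param within_block_edge_prob,between_block_edge_prob SBM edge
#'   probabilities (within must not be smaller than between).
#' @param fraction_annotated_disease fraction of planted genes included
#'   in the `disease_genes` annotation set.
#' @param dropout_fraction fraction of genes silenced (all-zero rows) in
#'   disease conditions only; off by default, used to exercise the
#'   control-expression filters.
#' @param seed integer seed; [generateStudy()] is deterministic given it.
#' @return a validated configuration list of class `studyConfig`.
#' @export
studyConfig <- function(n_genes = 200L, n_cells = 100L, n_timepoints = 4L,
                        k_true = 5L, k2_true = 4L, noise_sd = 0.01,
                        n_disease_genes = 20L, perturbation_strength = 1.0,
                        within_block_edge_prob = 0.3,
                        between_block_edge_prob = 0.02,
                        fraction_annotated_disease = 0.5,
                        dropout_fraction = 0, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
              n_timepoints = as.integer(n_timepoints),
              k_true = as.integer(k_true), k2_true = as.integer(k2_true),
              noise_sd = noise_sd, n_disease_genes = as.integer(n_disease_genes),
              perturbation_strength = perturbation_strength,
              within_block_edge_prob = within_block_edge_prob,
              between_block_edge_prob = between_block_edge_prob,
              fraction_annotated_disease = fraction_annotated_disease,
              dropout_fraction = dropout_fraction, seed = as.integer(seed))
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$perturbation_strength < 0) stop("perturbation_strength must be non-negative")
  probs <- c(cfg$within_block_edge_prob, cfg$between_block_edge_prob,
             cfg$fraction_annotated_disease, cfg$dropout_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$within_block_edge_prob < cfg$between_block_edge_prob)
    stop("within-block edge probability must be at least the between-block one")
  if (cfg$n_disease_genes > cfg$n_genes)
    stop("more disease genes than genes")
  if (cfg$k_true > cfg$n_genes || cfg$k2_true > cfg$n_cells)
    stop("block counts exceed study dimensions")
  class(cfg) <- "studyConfig"
  cfg
}

.dayLabels <- function(nt) {
  std <- c(0L, 6L, 15L, 21L)
  if (nt <= 4L) std[seq_len(nt)] else c(std, seq(28L, by = 7L,
                                                 length.out = nt - 4L))
}

## Block-structured non-negative factor: baseline Unif(0, 0.1) plus a
## dominant Unif(0.8, 1.2) entry in the assigned block column.
.blockFactor <- function(blocks, k) {
  n <- length(blocks)
  M <- matrix(stats::runif(n * k, 0, 0.1), n, k)
  M[cbind(seq_len(n), blocks)] <- stats::runif(n, 0.8, 1.2)
  M
}

## Symmetric SBM adjacency given block labels; upper triangle drawn,
## mirrored, zero diagonal.
.sbmAdjacency <- function(blocks, pWithin, pBetween) {
  n <- length(blocks)
  same <- outer(blocks, blocks, "==")
  P <- ifelse(same, pWithin, pBetween)
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  A[ut] <- as.numeric(stats::runif(sum(ut)) < P[ut])
  A + t(A)
}

#' Generate a synthetic paired control/disease study
#'
#' For each time point, control and disease share the same planted
#' factors and networks except that planted disease genes are mixed
#' toward a designated perturbation block (rows of the gene factor
#' re-drawn, incident network edges re-drawn with the same mixing
#' probability).  At `perturbation_strength = 0` and `noise_sd = 0` the
#' two lines are identical by construction.  Expression noise is
#' half-normal so matrices stay non-negative without clipping.
#'
#' @param config a [studyConfig()].
#' @return a \linkS4class{SyntheticStudy}
#' @export
generateStudy <- function(config) {
  stopifnot(inherits(config, "studyConfig"))
  .withSeed(config$seed, .generateStudyImpl(config))
}

.generateStudyImpl <- function(cfg) {
  n <- cfg$n_genes; m <- cfg$n_cells
  k1 <- cfg$k_true; k2 <- cfg$k2_true
  genes <- sprintf("g%04d", seq_len(n))
  cells <- sprintf("c%04d", seq_len(m))
  geneBlocks <- sample(rep_len(seq_len(k1), n))
  names(geneBlocks) <- genes
  cellBlocks <- sample(rep_len(seq_len(k2), m))
  names(cellBlocks) <- cells
  planted <- sample(genes, cfg$n_disease_genes)
  diseaseBlock <- sample.int(k1, 1L)
  lambda <- min(1, cfg$perturbation_strength)

  ## perturbed block labels: planted genes adopt the perturbation block
  diseaseLabels <- geneBlocks
  diseaseLabels[planted] <- diseaseBlock

  ## shared base networks; disease variant re-draws only planted-incident
  ## pairs, with probability lambda, under the perturbed labels
  perturbPair <- outer(genes %in% planted, genes %in% planted, "|")
  nets <- list(); netsD <- list()
  for (kind in .NETWORK_KINDS) {
    A <- .sbmAdjacency(geneBlocks, cfg$within_block_edge_prob,
                       cfg$between_block_edge_prob)
    Ad <- A
    if (lambda > 0 && length(planted)) {
      sameD <- outer(diseaseLabels, diseaseLabels, "==")
      Pd <- ifelse(sameD, cfg$within_block_edge_prob, cfg$between_block_edge_prob)
      ut <- upper.tri(A) & perturbPair
      redraw <- stats::runif(sum(ut)) < lambda
      newEdges <- as.numeric(stats::runif(sum(ut)) < Pd[ut])
      vals <- Ad[ut]
      vals[redraw] <- newEdges[redraw]
      Ad[ut] <- vals
      Ad[lower.tri(Ad)] <- t(Ad)[lower.tri(Ad)]
    }
    dimnames(A) <- dimnames(Ad) <- list(genes, genes)
    nets[[kind]] <- .adjacencyToNetwork(A, kind)
    netsD[[kind]] <- .adjacencyToNetwork(Ad, kind)
  }

  days <- .dayLabels(cfg$n_timepoints)
  conditions <- list()
  for (t in seq_along(days)) {
    G1c <- .blockFactor(geneBlocks, k1)
    G2 <- .blockFactor(cellBlocks, k2)
    S5 <- diag(stats::runif(min(k1, k2), 0.8, 1.2), k1, k2) +
      matrix(stats::runif(k1 * k2, 0, 0.05), k1, k2)
    ## disease gene factor: planted rows mixed toward the perturbation block
    G1d <- G1c
    if (lambda > 0 && length(planted)) {
      target <- .blockFactor(diseaseLabels[planted], k1)
      pi <- match(planted, genes)
      G1d[pi, ] <- (1 - lambda) * G1c[pi, , drop = FALSE] + lambda * target
    }
    Ec <- G1c %*% S5 %*% t(G2)
    Ed <- G1d %*% S5 %*% t(G2)
    if (cfg$noise_sd > 0) {
      Ec <- Ec + abs(matrix(stats::rnorm(n * m, 0, cfg$noise_sd), n, m))
      Ed <- Ed + abs(matrix(stats::rnorm(n * m, 0, cfg$noise_sd), n, m))
    }
    dimnames(Ec) <- dimnames(Ed) <- list(genes, cells)
    if (cfg$dropout_fraction > 0) {
      silenced <- sample(genes, round(cfg$dropout_fraction * n))
      Ed[silenced, ] <- 0
    }
    ec <- ConditionExpression(Ec, "control", days[t])
    ed <- ConditionExpression(Ed, "disease", days[t])
    conditions[[sprintf("control_d%d", days[t])]] <-
      conditionInputs(ec, nets$PPI, nets$GI, nets$COEX, nets$MI)
    conditions[[sprintf("disease_d%d", days[t])]] <-
      conditionInputs(ed, netsD$PPI, netsD$GI, netsD$COEX, netsD$MI)
  }

  nAnn <- round(cfg$fraction_annotated_disease * length(planted))
  annotatedPlanted <- sample(planted, nAnn)
  decoys <- sample(setdiff(genes, planted), nAnn)
  sets <- list(disease_genes = sort(c(annotatedPlanted, decoys)))
  for (b in seq_len(k1))
    sets[[sprintf("block_%d", b)]] <- genes[geneBlocks == b]
  annotations <- GeneSets(sets, universe = genes)

  methods::new("SyntheticStudy", conditions = conditions,
               truth = list(geneBlocks = geneBlocks, cellBlocks = cellBlocks,
                            plantedGenes = planted,
                            annotatedPlanted = annotatedPlanted,
                            diseaseBlock = diseaseBlock,
                            diseaseLabels = diseaseLabels),
               annotations = annotations, config = unclass(cfg))
}

.adjacencyToNetwork <- function(A, kind) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  InteractionNetwork(kind, rownames(A)[idx[, 1L]], colnames(A)[idx[, 2L]],
                     nodes = rownames(A))
}

#' Write a synthetic study to disk in the standard exchange formats
#'
#' Per condition: a dense expression TSV and four edge-list TSVs; plus
#' the annotation sets as GMT, a ground-truth TSV (gene, block, planted,
#' annotated) and the configuration echoed as a tab-separated key-value
#' file.
#'
#' @param study a \linkS4class{SyntheticStudy}.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study@conditions)) {
    ci <- study@conditions[[nm]]
    writeExpression(conditionExpression(ci),
                    file.path(dir, sprintf("%s_expression.tsv", nm)))
    for (kind in .NETWORK_KINDS)
      writeEdgeList(conditionNetworks(ci)[[kind]],
                    file.path(dir, sprintf("%s_%s.tsv", nm, tolower(kind))))
  }
  writeGmt(study@annotations, file.path(dir, "annotations.gmt"))
  tr <- study@truth
  truthTab <- data.frame(gene = names(tr$geneBlocks),
                         block = unname(tr$geneBlocks),
                         planted = names(tr$geneBlocks) %in% tr$plantedGenes,
                         annotated = names(tr$geneBlocks) %in% tr$annotatedPlanted)
  utils::write.table(truthTab, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- study@config
  utils::write.table(data.frame(key = names(cfg),
                                value = vapply(cfg, as.character, character(1))),
                     file.path(dir, "config.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Movement separation of planted genes, per time point
#'
#' For each time point, compares the movement (between the time-matched
#' control and disease conditions) of the planted disease genes against
#' all other genes with a one-sided rank-sum test (planted greater).
#'
#' @param study a \linkS4class{SyntheticStudy}.
#' @param movements named list of per-day movement vectors, as produced
#'   by [runPipeline()] (names `d<day>`).
#' @return `data.frame` with columns `day`, `p_value`, `median_planted`,
#'   `median_background`.
#' @export
movementEffectCheck <- function(study, movements) {
  planted <- study@truth$plantedGenes
  rows <- lapply(names(movements), function(dn) {
    mv <- movements[[dn]]
    pm <- mv[names(mv) %in% planted]
    bg <- mv[!names(mv) %in% planted]
    p <- mwuTest(pm, bg, "greater")$p.value
    data.frame(day = as.integer(sub("^d", "", dn)), p_value = p,
               median_planted = stats::median(pm),
               median_background = stats::median(bg))
  })
  do.call(rbind, rows)
}

#' Exact factor-model inputs for solver checks
#'
#' Draws non-negative factors at given ranks (symmetric S factors for the
#' adjacencies, so the networks are symmetric as real adjacency matrices
#' are) and returns the noiseless inputs they generate exactly:
#' `A_i = G1 S_i G1'`, `E = G1 S5 G2'`.  Useful for testing recovery in
#' the noiseless limit.
#'
#' @param n,m,k1,k2 dimensions and ranks.
#' @param seed integer seed.
#' @return list with `A`, `E` and the generating `factors`.
#' @export
makeFactorModelInputs <- function(n, m, k1, k2, seed = 1L) {
  .withSeed(seed, {
    G1 <- matrix(stats::rexp(n * k1), n,
                 dimnames = list(sprintf("g%04d", seq_len(n)), NULL))
    G2 <- matrix(stats::rexp(m * k2), m,
                 dimnames = list(sprintf("c%04d", seq_len(m)), NULL))
    S <- lapply(seq_len(4L), function(i) {
      M <- matrix(stats::rexp(k1 * k1), k1); (M + t(M)) / 2
    })
    S5 <- matrix(stats::rexp(k1 * k2), k1)
    A <- lapply(S, function(Si) G1 %*% Si %*% t(G1))
    A <- lapply(A, function(Ai) { dimnames(Ai) <- list(rownames(G1), rownames(G1)); Ai })
    E <- G1 %*% S5 %*% t(G2)
    dimnames(E) <- list(rownames(G1), rownames(G2))
    list(A = A, E = E, factors = NmtfFactors(G1, G2, S, S5))
  })
}
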