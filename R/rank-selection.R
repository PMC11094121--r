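#' Consensus connectivity matrix of repeated clusterings
#'
#' Entry (i, j) is the fraction of clustering runs in which items i and j
#' share a cluster.  Symmetric with unit diagonal.
#'
#' @param labelRuns list of cluster-label vectors over the same items.
#' @return square numeric matrix.
#' @export
consensusConnectivity <- function(labelRuns) {
  stopifnot(length(labelRuns) >= 1L)
  n <- length(labelRuns[[1L]])
  C <- matrix(0, n, n)
  for (lab in labelRuns) {
    if (length(lab) != n) stop("all label runs must cover the same items")
    C <- C + outer(lab, lab, "==")
  }
  C / length(labelRuns)
}

#' Dispersion coefficient of a consensus matrix
#'
#' \eqn{\rho = (1/n^2) \sum_{ij} 4 (C_{ij} - 1/2)^2}: 1 for a perfectly
#' reproducible clustering (all entries 0 or 1), 0 when every pair
#' co-clusters in exactly half of the runs.
#'
#' @param consensus square numeric matrix with entries in \[0, 1\].
#' @return a number in \[0, 1\].
#' @export
dispersionCoefficient <- function(consensus) {
  stopifnot(nrow(consensus) == ncol(consensus))
  mean(4 * (consensus - 0.5)^2)
}

#' Select a latent rank by consensus-clustering dispersion
#'
#' For each candidate rank k, obtains an embedding via `embedFun(k)` and
#' measures how reproducibly its rows cluster into k groups: each of
#' `runs` repetitions draws a random subsample of the rows (fraction
#' `subsample`) and clusters it under a distinct seed; the consensus
#' connectivity of each row pair is averaged over the runs in which both
#' rows were sampled, and summarized by the dispersion coefficient.
#' Subsampling perturbs the clustered cohort so that a rank whose
#' clusters are only an artifact of a particular merge of finer structure
#' loses stability, while a rank matching the data's block structure
#' stays reproducible.  The chosen rank maximizes dispersion; ties go to
#' the smallest candidate.
#'
#' @param embedFun function of one argument k returning a numeric matrix
#'   whose rows are clustered (the embedding itself is deterministic for
#'   a fixed k since the solver uses an SVD start).
#' @param candidates integer vector of candidate ranks.
#' @param runs number of clustering repetitions per candidate (default 20).
#' @param seed base seed; run r of candidate k uses a seed derived from it.
#' @param subsample fraction of rows clustered per run (default 0.8); 1
#'   disables subsampling so every run clusters the full cohort.
#' @return a \linkS4class{DimensionSelection}
#' @export
selectDimension <- function(embedFun, candidates, runs = 20L, seed = 1L,
                            subsample = 0.8) {
  if (runs < 2L) stop("at least two clustering runs are required")
  if (subsample <= 0 || subsample > 1) stop("subsample must lie in (0, 1]")
  candidates <- as.integer(candidates)
  rho <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    k <- candidates[ci]
    M <- embedFun(k)
    n <- nrow(M)
    agree <- matrix(0, n, n)
    seen <- matrix(0, n, n)
    for (r in seq_len(runs)) {
      runSeed <- seed + 1000L * ci + r
      idx <- .withSeed(runSeed, sample(n, round(subsample * n)))
      labs <- clusterGenes(M[idx, , drop = FALSE], k, seed = runSeed,
                           restarts = 1L)
      agree[idx, idx] <- agree[idx, idx] + outer(labs, labs, "==")
      seen[idx, idx] <- seen[idx, idx] + 1
    }
    C <- ifelse(seen > 0, agree / seen, 0.5)  # never-co-sampled: no evidence
    diag(C) <- 1
    rho[ci] <- dispersionCoefficient(C)
  }
  best <- max(rho)
  chosen <- min(candidates[rho >= best - 1e-12])
  methods::new("DimensionSelection", candidates = candidates,
               dispersion = rho, chosenK = as.integer(chosen))
}
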