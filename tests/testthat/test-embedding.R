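test_that("gene mapping matrices have the documented geometry", {
  U <- diag(2)
  rownames(U) <- c("g1", "g2")
  G <- computeGeneMapping(U)
  expect_equal(G["g1", "g2"], 1)  # sqrt(2) distance over sqrt(2) norm
  expect_equal(diag(G), c(g1 = 0, g2 = 0))

  set.seed(21)
  for (i in 1:20) {
    U <- matrix(rnorm(8 * 3), 8, dimnames = list(paste0("g", 1:8), NULL))
    G <- computeGeneMapping(U)
    expect_equal(G, t(G), tolerance = 1e-12)
    expect_equal(max(abs(diag(G))), 0)
    expect_true(all(G >= 0))
    expect_equal(computeGeneMapping(3.7 * U), G, tolerance = 1e-12)
    Q <- randomOrthogonal(3)
    expect_equal(computeGeneMapping(U %*% Q), G, tolerance = 1e-12)
  }

  U2 <- matrix(c(1, 1, 2, 2), 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(computeGeneMapping(U2)["a", "b"], 0)
  expect_error(computeGeneMapping(matrix(0, 3, 2)), "degenerate")
})

test_that("gene movement is symmetric, rotation-blind and hand-checkable", {
  set.seed(31)
  U <- matrix(rexp(12), 6, dimnames = list(paste0("g", 1:6), NULL))
  gA <- computeGeneMapping(U)
  expect_equal(unname(geneMovement(gA, gA)), rep(0, 6))
  gB <- computeGeneMapping(U %*% randomOrthogonal(2))
  expect_equal(max(geneMovement(gA, gB)), 0, tolerance = 1e-12)

  # hand-written 3x3 mapping matrices differing in gene c's row/column
  mk <- function(ac, bc) {
    M <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    M["a", "b"] <- M["b", "a"] <- 0.2
    M["a", "c"] <- M["c", "a"] <- ac
    M["b", "c"] <- M["c", "b"] <- bc
    M
  }
  g1 <- mk(0.3, 0.4); g2 <- mk(0.6, 0.8)
  mv <- geneMovement(g1, g2)
  expect_equal(unname(mv["a"]), 0.3)
  expect_equal(unname(mv["b"]), 0.4)
  expect_equal(unname(mv["c"]), sqrt(0.3^2 + 0.4^2))
  expect_equal(geneMovement(g2, g1), mv)

  # restriction to the shared gene set
  g3 <- computeGeneMapping(
    matrix(rexp(8), 4, dimnames = list(c("g2", "g4", "g5", "g6"), NULL)))
  expect_setequal(names(geneMovement(gA, g3)), c("g2", "g4", "g5", "g6"))
  expect_error(geneMovement(g1, gA), "shared")
})

test_that("k-means clustering is deterministic and recovers separated blobs", {
  set.seed(41)
  X <- rbind(matrix(rnorm(30, 0, .1), 15), matrix(rnorm(30, 6, .1), 15))
  rownames(X) <- paste0("g", 1:30)
  labs <- clusterGenes(X, 2, seed = 7)
  expect_identical(labs, clusterGenes(X, 2, seed = 7))
  expect_equal(ari(labs, rep(1:2, each = 15)), 1)
  expect_true(all(clusterGenes(X, 1, seed = 1) == 1L))
  expect_error(clusterGenes(X, 31, seed = 1), "more clusters")
})

test_that("cluster enrichment matches the combinatorial oracle exactly", {
  universe <- paste0("g", 1:20)
  annotated <- paste0("g", 1:5)
  labels <- setNames(c(rep(1L, 4), rep(2L, 16)), c(paste0("g", c(1, 2, 3, 6)),
                                                   paste0("g", c(4, 5, 7:20))))
  enr <- clusterEnrichment(labels, annotated, universe)
  r1 <- enr[enr$cluster == 1, ]
  expect_equal(r1$p_value, 155 / 4845, tolerance = 1e-12)
  expect_equal(r1$fold_enrichment, 3.0)
  expect_true(r1$significant)

  # exhaustive agreement for all configurations with N <= 25
  for (N in c(5, 12, 25)) {
    for (K in c(0, 2, N %/% 2, N)) {
      for (c_ in c(1, N %/% 3, N)) {
        for (x in unique(c(0, min(K, c_)))) {
          p <- if (K == 0) 1 else
            stats::phyper(x - 1, K, N - K, c_, lower.tail = FALSE)
          expect_equal(p, hyperUpperOracle(x, N, K, c_), tolerance = 1e-12,
                       label = sprintf("N=%d K=%d c=%d x=%d", N, K, c_, x))
        }
      }
    }
  }

  # forced outcomes
  all_in_one <- setNames(rep(1L, 20), universe)
  expect_equal(clusterEnrichment(all_in_one, annotated, universe)$p_value, 1)
  expect_warning(noK <- clusterEnrichment(labels, character(), universe),
                 "no annotated")
  expect_true(all(noK$p_value == 1))
})

test_that("a planted annotated-gene concentration yields the minimum p", {
  set.seed(51)
  universe <- paste0("g", 1:60)
  labels <- setNames(sample(rep(1:4, each = 15)), universe)
  annotated <- names(labels)[labels == 2][1:10]
  enr <- clusterEnrichment(labels, annotated, universe)
  expect_identical(enr$cluster[which.min(enr$p_value)], 2L)
})

test_that("percentage of enriched clusters is plain arithmetic on the screen", {
  enr <- data.frame(significant = c(rep(TRUE, 2), rep(FALSE, 9)))
  expect_equal(percentEnrichedClusters(enr), 200 / 11)
  expect_equal(percentEnrichedClusters(data.frame(significant = rep(FALSE, 4))), 0)
  expect_equal(percentEnrichedClusters(data.frame(significant = rep(TRUE, 3))), 100)
})
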