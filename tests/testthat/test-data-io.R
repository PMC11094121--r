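test_that("expression matrices round-trip through both on-disk layouts", {
  e <- toyExpression()
  for (fmt in c("dense_table", "mtx_triplet")) {
    dir <- withr::local_tempdir()
    path <- file.path(dir, if (fmt == "dense_table") "e.tsv" else "e.mtx")
    writeExpression(e, path, format = fmt)
    back <- readExpression(path, format = fmt)
    expect_identical(geneIds(back), geneIds(e))
    expect_identical(cellIds(back), cellIds(e))
    expect_equal(exprValues(back), exprValues(e))
  }
})

test_that("malformed expression inputs are rejected with clear errors", {
  dir <- withr::local_tempdir()
  neg <- file.path(dir, "neg.tsv")
  writeLines(c("gene\tc1\tc2", "g1\t-1\t2", "g2\t0\t1"), neg)
  expect_error(readExpression(neg), "negative")
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("gene\tc1\tc2", "g1\t1\t2", "g1\t0\t1"), dup)
  expect_error(readExpression(dup), "duplicate")
  expect_error(ConditionExpression(matrix(1, 1, 1), line = "control"),
               "identifiers")
})

test_that("edge lists collapse duplicates and drop self-loops on read", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "edges.tsv")
  writeLines(c("a\tb", "b\ta", "c\tc"), path)
  net <- readEdgeList(path, "PPI")
  expect_identical(unname(networkEdges(net)), matrix(c("a", "b"), 1))
  expect_setequal(networkNodes(net), c("a", "b", "c"))

  writeLines(character(), path)
  empty <- readEdgeList(path, "GI")
  expect_identical(nrow(networkEdges(empty)), 0L)

  writeEdgeList(pathNetwork(), path)
  back <- readEdgeList(path, "PPI")
  expect_equal(networkEdges(back), networkEdges(pathNetwork()))
  deg <- table(c(networkEdges(back)))
  expect_setequal(as.integer(deg), c(1L, 2L, 2L, 1L))

  onecol <- file.path(dir, "bad.tsv")
  writeLines(c("a", "b"), onecol)
  expect_error(readEdgeList(onecol, "PPI"), "two columns")
})

test_that("GMT collections round-trip and reject degenerate lines", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  writeLines("S1\tdesc\tg1\tg2", path)
  gs <- readGmt(path)
  expect_identical(geneSetList(gs), list(S1 = c("g1", "g2")))

  gs2 <- GeneSets(list(A = c("x", "y"), B = "z"))
  writeGmt(gs2, path)
  expect_identical(geneSetList(readGmt(path)), geneSetList(gs2))

  writeLines("S1\tonly-name", path)
  expect_error(readGmt(path), "no members")
  writeLines(c("S1\td\tg1", "S1\td\tg2"), path)
  expect_error(readGmt(path), "duplicate")
})

test_that("the coding/PPI/expression gene filter keeps exactly the right genes", {
  # g1 passes all three filters; g2 is non-coding; g3 has no PPI edge;
  # g4 is never expressed.
  v <- matrix(c(1, 2, 0.5, 0, 1, 0, 0, 0), nrow = 4,
              dimnames = list(paste0("g", 1:4), c("c1", "c2")))
  e <- ConditionExpression(v, "control", 0L)
  ppi <- InteractionNetwork("PPI", c("g1", "g2", "g1"), c("g2", "g1", "g4"))
  coding <- c("g1", "g3", "g4")
  kept <- filterExpressedGenes(e, coding, ppi)
  expect_identical(geneIds(kept), "g1")

  # identity when everything passes
  all_ok <- filterExpressedGenes(
    ConditionExpression(v[1:2, ], "control", 0L), c("g1", "g2"), ppi)
  expect_identical(geneIds(all_ok), c("g1", "g2"))

  # surviving set does not depend on input row order
  perm <- c(3, 1, 4, 2)
  kept2 <- filterExpressedGenes(ConditionExpression(v[perm, ], "control", 0L),
                                coding, ppi)
  expect_setequal(geneIds(kept2), geneIds(kept))

  empty_ppi <- InteractionNetwork("PPI")
  expect_error(filterExpressedGenes(e, coding, empty_ppi), "no genes")
})

test_that("network induction restricts nodes and edges and is idempotent", {
  net <- pathNetwork()
  sub <- induceNetwork(net, c("a", "b", "d"))
  expect_setequal(networkNodes(sub), c("a", "b", "d"))
  expect_identical(unname(networkEdges(sub)), matrix(c("a", "b"), 1))
  expect_equal(induceNetwork(sub, c("a", "b", "d")), sub)
  expect_identical(networkEdges(induceNetwork(net, networkNodes(net))),
                   networkEdges(net))
  none <- induceNetwork(net, c("x", "y"))
  expect_identical(length(networkNodes(none)), 0L)

  # monotone: inducing on a subset never adds edges
  set.seed(42)
  for (i in 1:10) {
    genes <- paste0("g", 1:12)
    net <- randomNetwork(genes, 0.4)
    keep <- sample(genes, 7)
    expect_lte(nrow(networkEdges(induceNetwork(net, keep))),
               nrow(networkEdges(net)))
  }
})

test_that("co-pathway and co-expression network builders count pairs correctly", {
  tri <- buildPathwayNetwork(GeneSets(list(P = c("a", "b", "c"))))
  expect_identical(nrow(networkEdges(tri)), 3L)
  two <- buildPathwayNetwork(GeneSets(list(P1 = c("a", "b"),
                                           P2 = c("x", "y", "z"))))
  expect_identical(nrow(networkEdges(two)), 4L)
  single <- buildPathwayNetwork(GeneSets(list(P1 = "a", P2 = "b")))
  expect_identical(nrow(networkEdges(single)), 0L)
  expect_setequal(networkNodes(single), c("a", "b"))

  corr <- matrix(c(1, .9, .1, .9, 1, .5, .1, .5, 1), 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  top1 <- buildCoexpressionNetwork(corr, 1 / 3)
  expect_identical(unname(networkEdges(top1)), matrix(c("a", "b"), 1))
  full <- buildCoexpressionNetwork(corr, 1)
  expect_identical(nrow(networkEdges(full)), 3L)
  expect_error(buildCoexpressionNetwork(corr, 0), "topFraction")
})

test_that("condition inputs align every network to the expression gene order", {
  e <- toyExpression()
  net <- InteractionNetwork("PPI", c("g1", "g2", "zz"), c("g2", "g3", "g1"))
  ci <- conditionInputs(e, net,
                        InteractionNetwork("GI", "g1", "g3"),
                        InteractionNetwork("COEX"),
                        InteractionNetwork("MI"))
  A <- adjacencyList(ci)
  expect_identical(rownames(A$PPI), geneIds(e))  # zz dropped by induction
  expect_equal(A$PPI["g1", "g2"], 1)
  expect_equal(A$PPI["g1", "g3"], 0)
  expect_equal(A$PPI, t(A$PPI))
  expect_equal(diag(A$PPI), c(g1 = 0, g2 = 0, g3 = 0))
  expect_equal(sum(A$COEX), 0)
})
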