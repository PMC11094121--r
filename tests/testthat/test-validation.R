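test_that("one-sided rank-sum p-values match full permutation enumeration", {
  r <- mwuTest(c(1, 2), c(3, 4), "less")
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1 / 6, tolerance = 1e-12)

  set.seed(71)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- sample(100, n1 + n2)  # distinct, no ties
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    alt <- sample(c("greater", "less"), 1)
    expect_equal(mwuTest(x, y, alt)$p.value, mwuEnumOracle(x, y, alt),
                 tolerance = 1e-12)
  }

  same <- mwuTest(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_gte(same$p.value, 0.5)
  const <- mwuTest(rep(2, 5), rep(2, 5), "greater")
  expect_equal(const$p.value, 0.5)

  set.seed(72)
  big <- mwuTest(rnorm(100, 5), rnorm(100, 0), "greater")
  expect_lt(big$p.value, 1e-6)
  expect_error(mwuTest(numeric(), 1:3), "non-empty")
})

test_that("exact and approximate rank-sum paths agree at moderate n", {
  set.seed(73)
  for (i in 1:10) {
    vals <- sample(1000, 12)
    x <- vals[1:6]; y <- vals[7:12]
    pe <- mwuTest(x, y, "greater")$p.value
    wa <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                              exact = FALSE, correct = TRUE))
    expect_lt(abs(pe - wa$p.value), 0.02)
  }
})

test_that("overlap resampling has the documented null and determinism", {
  # sets equal to their tiny universes: without replacement every draw
  # covers the universe, so no null overlap can beat the observed one
  u <- list(letters[1:3], letters[1:3])
  r <- overlapResampling(u, u, repetitions = 200, seed = 1, replace = FALSE)
  expect_equal(r$p.value, 1)
  expect_true(all(r$null >= r$observed))
  # with replacement, repeated draws shrink the distinct sets, so the
  # null can fall below the observed full overlap
  rw <- overlapResampling(u, u, repetitions = 200, seed = 1)
  expect_true(any(rw$null < rw$observed))

  # disjoint observed sets: observed overlap 0 can never be beaten
  r0 <- overlapResampling(list(c("a", "b"), c("c", "d")),
                          list(letters[1:10]), repetitions = 200, seed = 1)
  expect_identical(r0$observed, 0L)
  expect_equal(r0$p.value, 1)

  # a large overlap from big universes attains the minimum attainable p
  set.seed(2)
  universe <- paste0("g", 1:10000)
  shared <- paste0("g", 1:50)
  sets <- replicate(4, c(shared, sample(universe[51:10000], 50)),
                    simplify = FALSE)
  rr <- overlapResampling(sets, list(universe), repetitions = 500, seed = 3)
  expect_equal(rr$p.value, 1 / 501)

  # invariance to gene relabeling: only sizes matter
  relabel <- function(s) chartr("g", "h", s)
  rA <- overlapResampling(sets, list(universe), repetitions = 300, seed = 9)
  rB <- overlapResampling(lapply(sets, relabel), list(relabel(universe)),
                          repetitions = 300, seed = 9)
  expect_identical(rA$null, rB$null)
  expect_identical(rA$p.value, rB$p.value)

  expect_warning(overlapResampling(u, u, repetitions = 10, seed = 1), "100")
  expect_error(overlapResampling(list("zz"), list(letters)), "universe")
})

test_that("shortest-path distances follow breadth-first geometry", {
  net <- InteractionNetwork("PPI", c("a", "b", "c"), c("b", "c", "d"),
                            nodes = c("a", "b", "c", "d", "iso"))
  res <- shortestPathsToTarget(net, "a",
                               list(grp = c("b", "c", "d"), nb = "b",
                                    far = "iso"))
  expect_equal(unname(res$grp$distances), c(1, 2, 3))
  expect_equal(res$grp$mean, 2)
  expect_equal(unname(res$nb$distances), 1)
  expect_identical(res$far$unreachable, "iso")
  expect_true(is.nan(res$far$mean))
  expect_error(shortestPathsToTarget(net, "nope", list()), "not in the network")

  # every edge satisfies |d(u) - d(v)| <= 1
  set.seed(81)
  genes <- paste0("g", 1:30)
  rnet <- randomNetwork(genes, 0.15)
  target <- networkEdges(rnet)[1, 1]
  d <- shortestPathsToTarget(rnet, target, list(all = genes))$all$distances
  d <- c(d, setNames(0, target))
  e <- networkEdges(rnet)
  both <- e[, 1] %in% names(d) & e[, 2] %in% names(d)
  expect_true(all(abs(d[e[both, 1]] - d[e[both, 2]]) <= 1))
})

test_that("prediction-set enrichment shares the hypergeometric oracle", {
  # same configuration as the cluster-level oracle check
  predictions <- paste0("g", c(1, 2, 3, 6))
  annotated <- paste0("g", 1:5)
  background <- paste0("g", 1:20)
  r <- geneSetEnrichment(predictions, annotated, background)
  expect_equal(r$p.value, 155 / 4845, tolerance = 1e-12)
  expect_equal(r$fraction, 3 / 4)

  rin <- geneSetEnrichment(letters[1:3], letters[1:5], letters[1:10])
  expect_equal(rin$fraction, 1)
  rout <- geneSetEnrichment(letters[1:3], letters[6:9], letters[1:10])
  expect_equal(rout$fraction, 0)
  expect_equal(rout$p.value, 1)
})

test_that("pathway enrichment applies monotone BH adjustment and ranking", {
  # spot-check the step-up formula on a known vector
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))

  set.seed(91)
  universe <- paste0("g", 1:50)
  predictions <- universe[1:10]
  pw <- GeneSets(list(hit = universe[1:12], miss = universe[40:50],
                      part = universe[c(1:3, 20:28)], single = universe[30]))
  tab <- pathwayEnrichment(predictions, pw, universe)
  expect_true(all(tab$p_adjusted >= tab$p_value))
  expect_false(is.unsorted(tab$p_adjusted))
  expect_identical(tab$pathway[1], "hit")
  zero <- tab[tab$pathway == "miss", ]
  expect_equal(zero$p_value, 1)

  one <- pathwayEnrichment(predictions, GeneSets(list(only = universe[1:12])),
                           universe)
  expect_equal(one$p_adjusted, one$p_value)

  # BH never reorders: larger raw p never gets a smaller adjusted p
  set.seed(92)
  p <- runif(20)
  adj <- stats::p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})
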