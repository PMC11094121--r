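# Programmatic fixtures shared across the suite.

toyExpression <- function(line = "control", day = 0L) {
  ConditionExpression(
    matrix(c(0, 1.5, 2, 1, 0.5, 3), nrow = 3,
           dimnames = list(c("g1", "g2", "g3"), c("c1", "c2"))),
    line = line, day = day)
}

pathNetwork <- function(kind = "PPI", nodes = c("a", "b", "c", "d")) {
  InteractionNetwork(kind, nodes[-length(nodes)], nodes[-1L])
}

# Random simple undirected network over given genes.
randomNetwork <- function(genes, p = 0.3, kind = "PPI") {
  pr <- t(combn(genes, 2L))
  keep <- runif(nrow(pr)) < p
  InteractionNetwork(kind, pr[keep, 1L], pr[keep, 2L], nodes = genes)
}

# Upper-tail hypergeometric by direct combinatorial counting (independent
# of phyper): P(X >= x) with N items, K annotated, c drawn.
hyperUpperOracle <- function(x, N, K, c) {
  jmax <- min(K, c)
  if (x > jmax) return(0)
  num <- sum(vapply(x:jmax, function(j) choose(K, j) * choose(N - K, c - j),
                    numeric(1)))
  num / choose(N, c)
}

# One-sided MWU p by full enumeration over all splits of the pooled sample
# (assumes no ties).  U counts pairs (x_i > y_j).
mwuEnumOracle <- function(x, y, alternative) {
  pool <- c(x, y)
  n1 <- length(x)
  uStat <- function(xs, ys) sum(outer(xs, ys, ">"))
  uObs <- uStat(x, y)
  splits <- combn(length(pool), n1)
  us <- apply(splits, 2L, function(ix) uStat(pool[ix], pool[-ix]))
  if (alternative == "greater") mean(us >= uObs) else mean(us <= uObs)
}

# Adjusted Rand index between two label vectors.
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Random orthogonal matrix via QR with positive-diagonal fix.
randomOrthogonal <- function(k) {
  qr <- qr(matrix(rnorm(k * k), k))
  Q <- qr.Q(qr)
  Q %*% diag(sign(diag(qr.R(qr))), k)
}
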