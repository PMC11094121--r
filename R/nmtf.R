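## Core joint tri-factorization solver.
##
## Minimizes  sum_i ||A_i - G1 S_i G1'||_F^2 + ||E - G1 S5 G2'||_F^2
## over non-negative factors, by multiplicative update rules from the
## standard KKT construction, starting from a deterministic abs-SVD
## initialization.

.objectiveRaw <- function(f, A, E) {
  total <- 0
  for (i in seq_along(A)) {
    R <- A[[i]] - f$G1 %*% f$S[[i]] %*% t(f$G1)
    total <- total + sum(R * R)
  }
  R5 <- E - f$G1 %*% f$S5 %*% t(f$G2)
  total + sum(R5 * R5)
}

.inputNorm2 <- function(A, E) {
  sum(vapply(A, function(x) sum(x * x), numeric(1))) + sum(E * E)
}

.checkShapes <- function(f, A, E) {
  n <- nrow(f$G1); m <- nrow(f$G2)
  k1 <- ncol(f$G1); k2 <- ncol(f$G2)
  if (length(A) != 4L) stop("expected four network adjacency matrices")
  for (Ai in A)
    if (!all(dim(Ai) == c(n, n))) stop("adjacency shape does not match G1")
  if (!all(dim(E) == c(n, m))) stop("expression shape does not match G1/G2")
  for (Si in f$S)
    if (!all(dim(Si) == c(k1, k1))) stop("S factor shape mismatch")
  if (!all(dim(f$S5) == c(k1, k2))) stop("S5 shape mismatch")
  invisible(TRUE)
}

#' @rdname objectiveValue
#' @aliases objectiveValue,NmtfFactors,ConditionInputs-method
setMethod("objectiveValue", signature("NmtfFactors", "ConditionInputs"),
  function(factors, inputs) {
    A <- adjacencyList(inputs)
    E <- exprValues(conditionExpression(inputs))
    f <- .asList(factors)
    .checkShapes(f, A, E)
    .objectiveRaw(f, A, E)
  })

#' @rdname objectiveValue
#' @aliases objectiveValue,NmtfFactors,list-method
#' @param inputs a \linkS4class{ConditionInputs}, or a list with elements
#'   `A` (list of four adjacency matrices) and `E` (expression matrix).
setMethod("objectiveValue", signature("NmtfFactors", "list"),
  function(factors, inputs) {
    f <- .asList(factors)
    .checkShapes(f, inputs$A, inputs$E)
    .objectiveRaw(f, inputs$A, inputs$E)
  })

.asList <- function(factors)
  list(G1 = factors@G1, G2 = factors@G2, S = factors@S, S5 = factors@S5)

.asFactors <- function(f, genes = NULL, cells = NULL) {
  if (!is.null(genes)) rownames(f$G1) <- genes
  if (!is.null(cells)) rownames(f$G2) <- cells
  NmtfFactors(f$G1, f$G2, f$S, f$S5)
}

.inputsOf <- function(inputs) {
  if (is(inputs, "ConditionInputs")) {
    list(A = adjacencyList(inputs),
         E = exprValues(conditionExpression(inputs)),
         genes = geneIds(conditionExpression(inputs)),
         cells = cellIds(conditionExpression(inputs)))
  } else {
    list(A = inputs$A, E = inputs$E,
         genes = rownames(inputs$E), cells = colnames(inputs$E))
  }
}

## Fix each singular vector's sign so that its largest-magnitude entry is
## positive; keeps the SVD (and hence the whole fit) deterministic across
## LAPACK implementations.
.fixSigns <- function(M) {
  for (j in seq_len(ncol(M))) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  M
}

#' Deterministic SVD-based initialization
#'
#' The shared gene factor G1 is the element-wise absolute value of the
#' top-k1 left singular vectors of the column-wise concatenation
#' `[A1 | A2 | A3 | A4 | E]`, so that it reflects all five inputs; G2 is
#' the absolute value of the top-k2 right singular vectors of E; S5 is a
#' diagonal of E's top singular values padded to k1 x k2; each S_i is
#' `|G1' A_i G1|`.  Fully deterministic for fixed inputs.
#'
#' @param inputs a \linkS4class{ConditionInputs} or a list with elements
#'   `A` and `E`.
#' @param config an \linkS4class{NmtfConfig}.
#' @return an \linkS4class{NmtfFactors}
#' @export
svdInitialize <- function(inputs, config) {
  x <- .inputsOf(inputs)
  n <- nrow(x$E); m <- ncol(x$E)
  k1 <- config@k1; k2 <- config@k2
  if (k1 > n || k2 > m) stop("latent rank exceeds input dimension")
  if (.inputNorm2(x$A, x$E) == 0)
    stop("all-zero inputs have no top-k singular vectors; use smaller k or fix inputs")
  C <- do.call(cbind, c(x$A, list(x$E)))
  G1 <- abs(.fixSigns(svd(C, nu = k1, nv = 0)$u))
  se <- svd(x$E, nu = 0, nv = k2)
  G2 <- abs(.fixSigns(se$v))
  S5 <- matrix(0, k1, k2)
  d <- se$d[seq_len(min(k1, k2))]
  S5[cbind(seq_along(d), seq_along(d))] <- d
  S <- lapply(x$A, function(Ai) abs(t(G1) %*% Ai %*% G1))
  .asFactors(list(G1 = G1, G2 = G2, S = S, S5 = S5), x$genes, x$cells)
}

.murSweep <- function(f, A, E, eps) {
  G1 <- f$G1; G2 <- f$G2; S <- f$S; S5 <- f$S5
  ## G1: positive and negative parts of the gradient of all five terms.
  ## For symmetric A the network terms reduce to A G1 (S + S'); the
  ## general form below is the exact gradient either way.
  num <- E %*% G2 %*% t(S5)
  den <- G1 %*% S5 %*% crossprod(G2) %*% t(S5)
  GtG <- crossprod(G1)
  for (i in seq_along(A)) {
    num <- num + A[[i]] %*% G1 %*% t(S[[i]]) + t(A[[i]]) %*% G1 %*% S[[i]]
    den <- den + G1 %*% (S[[i]] %*% GtG %*% t(S[[i]]) +
                         t(S[[i]]) %*% GtG %*% S[[i]])
  }
  G1 <- G1 * num / (den + eps)
  GtG <- crossprod(G1)
  G2 <- G2 * (crossprod(E, G1) %*% S5) /
    (G2 %*% t(S5) %*% GtG %*% S5 + eps)
  for (i in seq_along(A))
    S[[i]] <- S[[i]] * (t(G1) %*% A[[i]] %*% G1) / (GtG %*% S[[i]] %*% GtG + eps)
  S5 <- S5 * (t(G1) %*% E %*% G2) / (GtG %*% S5 %*% crossprod(G2) + eps)
  list(G1 = G1, G2 = G2, S = S, S5 = S5)
}

.assertFinite <- function(f, iter) {
  if (!all(is.finite(f$G1)) || !all(is.finite(f$G2)) ||
      !all(is.finite(f$S5)) || !all(vapply(f$S, function(s) all(is.finite(s)),
                                           logical(1))))
    stop("numerical failure (NaN/Inf in factors) at iteration ", iter)
  invisible(TRUE)
}

#' One multiplicative-update sweep
#'
#' Updates G1, G2, each S_i and S5 once, in that order, each update using
#' the already-updated factors.  Non-negativity is preserved and exact
#' zeros stay zero (multiplicative rule).
#'
#' @param factors an \linkS4class{NmtfFactors}
#' @param inputs a \linkS4class{ConditionInputs} or list with `A`, `E`.
#' @param epsilon denominator safeguard (default 1e-10).
#' @return the updated \linkS4class{NmtfFactors}
#' @export
murUpdate <- function(factors, inputs, epsilon = 1e-10) {
  x <- .inputsOf(inputs)
  f <- .asList(factors)
  .checkShapes(f, x$A, x$E)
  f <- .murSweep(f, x$A, x$E, epsilon)
  .assertFinite(f, 1L)
  .asFactors(f, x$genes, x$cells)
}

#' Fit the joint tri-factorization
#'
#' Initializes with [svdInitialize()] and iterates multiplicative-update
#' sweeps.  The objective is recorded at iteration 0 and every
#' `checkEvery` iterations; iteration stops when the relative change over
#' one check period is at most `relTol` (or the objective hits exactly
#' zero), or when `maxIter` is reached.  Deterministic for fixed inputs
#' and configuration.
#'
#' @param inputs a \linkS4class{ConditionInputs} or a list with elements
#'   `A` (four adjacency matrices) and `E` (expression matrix).
#' @param config an \linkS4class{NmtfConfig}
#' @return an \linkS4class{NmtfFit}
#' @examples
#' set.seed(1)
#' n <- 20; m <- 10
#' G1 <- matrix(rexp(n * 2), n); G2 <- matrix(rexp(m * 2), m)
#' S  <- replicate(4, { M <- matrix(rexp(4), 2); (M + t(M)) / 2 },
#'                 simplify = FALSE)
#' S5 <- matrix(rexp(4), 2)
#' inp <- list(A = lapply(S, function(Si) G1 %*% Si %*% t(G1)),
#'             E = G1 %*% S5 %*% t(G2))
#' fit <- nmtfFit(inp, nmtfConfig(k1 = 2, k2 = 2))
#' isConverged(fit)
#' @export
nmtfFit <- function(inputs, config) {
  x <- .inputsOf(inputs)
  f <- .asList(svdInitialize(inputs, config))
  history <- .objectiveRaw(f, x$A, x$E)
  prev <- history[1L]
  converged <- prev == 0
  iter <- 0L
  while (!converged && iter < config@maxIter) {
    f <- .murSweep(f, x$A, x$E, config@epsilon)
    iter <- iter + 1L
    if (iter %% config@checkEvery == 0L) {
      .assertFinite(f, iter)
      cur <- .objectiveRaw(f, x$A, x$E)
      history <- c(history, cur)
      if (cur == 0 || abs((prev - cur) / cur) <= config@relTol)
        converged <- TRUE
      prev <- cur
    }
  }
  if (iter %% config@checkEvery != 0L)
    history <- c(history, .objectiveRaw(f, x$A, x$E))
  methods::new("NmtfFit", factors = .asFactors(f, x$genes, x$cells),
               objective = history, iterations = iter,
               converged = converged, config = config)
}

#' Relative residual of a fit
#'
#' Final objective divided by the squared Frobenius norm of the inputs.
#'
#' @param fit an \linkS4class{NmtfFit}
#' @param inputs the inputs it was fitted to.
#' @return a number in \[0, 1\] for any non-trivial input.
#' @export
relativeResidual <- function(fit, inputs) {
  x <- .inputsOf(inputs)
  utils::tail(fit@objective, 1L) / .inputNorm2(x$A, x$E)
}

#' @rdname computeU
#' @aliases computeU,NmtfFactors-method
setMethod("computeU", "NmtfFactors", function(factors) {
  U <- factors@G1 %*% factors@S5
  rownames(U) <- rownames(factors@G1)
  U
})

#' @rdname computeU
#' @aliases computeU,NmtfFit-method
setMethod("computeU", "NmtfFit", function(factors) computeU(factors@factors))
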