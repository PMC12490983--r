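## Independent brute-force oracles. Everything here recomputes the
## package's quantities from first principles (dense matrices, explicit
## double loops, exhaustive pair counting) and must stay independent of
## the implementation paths it checks.

reluRef <- function(x) pmax(x, 0)

randomGeneSetList <- function(nGenes, nSets, sizeRange = c(2L, 6L),
                              seed = 1L) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(nGenes))
    members <- lapply(seq_len(nSets), function(i) {
      sample(genes, sample(seq(sizeRange[1L], sizeRange[2L]), 1L))
    })
    GeneSetList(sprintf("set%03d", seq_len(nSets)), members)
  })
}

randomHypergraph <- function(nGenes, nSets, seed = 1L) {
  buildHypergraph(randomGeneSetList(nGenes, nSets, seed = seed))
}

## Eq-by-definition degrees: explicit double loops over the incidence.
oracleDegrees <- function(H, w) {
  node <- numeric(nrow(H))
  for (a in seq_len(nrow(H))) {
    for (b in seq_len(ncol(H))) node[a] <- node[a] + w[b] * H[a, b]
  }
  edge <- numeric(ncol(H))
  for (b in seq_len(ncol(H))) edge[b] <- sum(H[, b])
  list(node = node, edge = edge)
}

## w(e) = (# positive members) / (# members), per hyperedge loop.
oracleEdgeWeights <- function(H, posIdx) {
  vapply(seq_len(ncol(H)), function(b) {
    members <- which(H[, b] == 1)
    sum(members %in% posIdx) / length(members)
  }, numeric(1))
}

## Laplacian entrywise: Delta_ij = 1{i==j} - sum_e w_e H_ie H_je /
## (sqrt(d_i d_j) * delta_e), with d computed under the same weights.
oracleLaplacian <- function(H, w) {
  d <- as.numeric(H %*% w)
  de <- colSums(H)
  n <- nrow(H)
  lap <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (e in seq_len(ncol(H))) {
        s <- s + w[e] * H[i, e] * H[j, e] / (sqrt(d[i] * d[j]) * de[e])
      }
      lap[i, j] <- (i == j) - s
    }
  }
  lap
}

## Per-hyperedge aggregation loop (node-to-edge stage).
oracleNodeToEdge <- function(X, H, dv, Theta) {
  M <- ncol(H)
  out <- matrix(0, M, ncol(Theta))
  for (e in seq_len(M)) {
    acc <- matrix(0, 1L, ncol(X))
    for (v in which(H[, e] == 1)) acc <- acc + X[v, , drop = FALSE] / dv[v]
    out[e, ] <- reluRef(acc %*% Theta)
  }
  out
}

## Per-node weighted aggregation + residual loop (edge-to-node stage).
oracleEdgeToNode <- function(Y, X, H, w, Theta) {
  N <- nrow(H)
  out <- matrix(0, N, ncol(X))
  for (v in seq_len(N)) {
    acc <- matrix(0, 1L, ncol(Y))
    for (e in which(H[v, ] == 1)) acc <- acc + w[e] * Y[e, , drop = FALSE]
    out[v, ] <- reluRef(acc %*% Theta + X[v, , drop = FALSE])
  }
  out
}

## Classical hypergraph convolution via explicit diagonal matrices.
oracleHGNN <- function(X, H, w, Theta) {
  dv <- as.numeric(H %*% w)
  de <- colSums(H)
  Dvis <- diag(1 / sqrt(dv), nrow(H))
  Deinv <- diag(1 / de, ncol(H))
  W <- diag(w, ncol(H))
  reluRef(Dvis %*% H %*% W %*% Deinv %*% t(H) %*% Dvis %*% X %*% Theta)
}

## Full forward pass with the one-hot input matrix materialized and the
## two stages expanded as loops.
oracleForward <- function(H, w, params, nBlocks, degreeNormMode) {
  N <- nrow(H)
  oneHot <- diag(N)
  X <- reluRef(oneHot %*% params$E +
                 matrix(params$b0, N, length(params$b0), byrow = TRUE))
  dv <- switch(degreeNormMode,
               unweighted = rowSums(H),
               weighted = as.numeric(H %*% w))
  for (l in seq_len(nBlocks)) {
    Y <- oracleNodeToEdge(X, H, dv, params$Tve[[l]])
    X <- oracleEdgeToNode(Y, X, H, w, params$Tev[[l]])
  }
  logits <- X %*% params$Th1 +
    matrix(params$b1, N, 2L, byrow = TRUE)
  Z <- t(apply(logits, 1L, function(r) {
    ex <- exp(r - max(r)); ex / sum(ex)
  }))
  Z
}

## AUROC by exhaustive positive-negative pair counting.
oracleAUROC <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

## Average precision by explicit threshold sweep over distinct scores.
oracleAveragePrecision <- function(scores, labels) {
  labels <- as.logical(labels)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prevRecall <- 0
  ap <- 0
  for (t in thresholds) {
    sel <- scores >= t
    precision <- sum(labels[sel]) / sum(sel)
    recall <- sum(labels[sel]) / sum(labels)
    ap <- ap + (recall - prevRecall) * precision
    prevRecall <- recall
  }
  ap
}

## Tie-corrected Kendall tau-b with the normal-approximation p-value,
## from exhaustive concordant/discordant pair counting.
oracleTauB <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  S <- C - D
  tx <- as.numeric(table(x)); tx <- tx[tx > 1]
  ty <- as.numeric(table(y)); ty <- ty[ty > 1]
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(varS)
  list(tau = tau, p = 2 * stats::pnorm(-abs(z)))
}

## Exact hypergeometric upper tail P(X >= k) by term-by-term summation.
oracleHyperTail <- function(k, termSize, universe, binSize) {
  kk <- k:min(termSize, binSize)
  sum(choose(termSize, kk) * choose(universe - termSize, binSize - kk)) /
    choose(universe, binSize)
}

## Shared small model configuration for fast unit tests.
tinyConfig <- function(seed, epochs = 30L, ...) {
  hyperADConfig(seed = seed, embedDim = 8L, nBlocks = 2L,
                epochs = epochs, ...)
}
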