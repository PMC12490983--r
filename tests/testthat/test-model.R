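test_that("initial embeddings are the ReLU'd one-hot projection", {
  params <- list(E = matrix(c(-1, 2), 1, 2), b0 = c(0, 0))
  expect_equal(initEmbeddings(params), matrix(c(0, 2), 1, 2))
  paramsZero <- list(E = matrix(0, 3, 2), b0 = c(0, 0))
  expect_equal(initEmbeddings(paramsZero), matrix(0, 3, 2))
  ## random 5-gene state vs explicit one-hot matrix product
  cfg <- hyperADConfig(seed = 5, embedDim = 4)
  params5 <- withr::with_seed(5, initHyperADState(5, cfg))
  oneHot <- diag(5)
  ref <- reluRef(oneHot %*% params5$E +
                   matrix(params5$b0, 5, 4, byrow = TRUE))
  expect_equal(initEmbeddings(params5), ref, tolerance = 1e-12)
})

test_that("node-to-edge aggregation matches its defining sum", {
  ## singleton hyperedge with identity transform passes features through
  hg1 <- buildHypergraph(GeneSetList("e", list("g1")), minSize = 1)
  X <- matrix(c(2, -3), 1, 2)
  y <- nodeToEdge(X, hg1, nodeDegree = 1, Theta = diag(2),
                  activation = identity)
  expect_equal(unname(as.matrix(y)), X)
  ## two degree-1 nodes sum before the activation
  hg2 <- buildHypergraph(GeneSetList("e", list(c("g1", "g2"))))
  X2 <- matrix(c(1, -4, 2, 1), 2, 2, byrow = TRUE)
  expect_equal(unname(as.matrix(
                 nodeToEdge(X2, hg2, nodeDegree = c(1, 1),
                            Theta = diag(2)))),
               reluRef(matrix(colSums(X2), 1, 2)))
  ## random instance vs per-hyperedge brute force
  hgR <- randomHypergraph(20, 10, seed = 21)
  N <- nGenes(hgR)
  dv <- unname(degrees(hgR)$node)
  XR <- withr::with_seed(21, matrix(rnorm(N * 3), N, 3))
  Theta <- withr::with_seed(22, matrix(rnorm(9), 3, 3))
  expect_equal(unname(as.matrix(nodeToEdge(XR, hgR, dv, Theta))),
               oracleNodeToEdge(XR, as.matrix(incidenceMatrix(hgR)),
                                dv, Theta),
               tolerance = 1e-6)
  expect_error(nodeToEdge(XR, hgR, rep(0, N), Theta), "unweighted")
})

test_that("edge-to-node aggregation is weighted, residual, and inert at w=0", {
  hg <- buildHypergraph(GeneSetList("e", list(c("g1", "g2"))))
  X <- matrix(c(-1, 2, 3, -4), 2, 2, byrow = TRUE)
  Y <- matrix(c(5, 7), 1, 2)
  ## zero-weight hyperedge: message vanishes, residual survives the ReLU
  expect_equal(unname(as.matrix(edgeToNode(Y, X, hg, w = 0,
                                           Theta = diag(2)))),
               reluRef(X))
  ## perturbing features of a zero-weight hyperedge changes nothing
  expect_equal(edgeToNode(Y + 100, X, hg, w = 0, Theta = diag(2)),
               edgeToNode(Y, X, hg, w = 0, Theta = diag(2)))
  ## random instance vs per-node brute force
  hgR <- randomHypergraph(20, 10, seed = 31)
  H <- as.matrix(incidenceMatrix(hgR))
  N <- nGenes(hgR); M <- nHyperedges(hgR)
  XR <- withr::with_seed(31, matrix(rnorm(N * 3), N, 3))
  YR <- withr::with_seed(32, matrix(rnorm(M * 3), M, 3))
  wR <- withr::with_seed(33, runif(M))
  Theta <- withr::with_seed(34, matrix(rnorm(9), 3, 3))
  expect_equal(unname(as.matrix(edgeToNode(YR, XR, hgR, wR, Theta))),
               oracleEdgeToNode(YR, XR, H, wR, Theta), tolerance = 1e-6)
})

test_that("classical hypergraph convolution layer matches the dense chain", {
  hg <- buildHypergraph(GeneSetList("e", list(c("g1", "g2"))))
  X <- matrix(c(1, 3, 2, 5), 2, 2, byrow = TRUE)
  out <- hgnnLayer(X, hg, w = 1, Theta = diag(2), activation = identity)
  avg <- (X[1, ] + X[2, ]) / 2
  expect_equal(out, rbind(avg, avg), ignore_attr = TRUE)
  ## annihilation at zero weights happens before degree normalization
  hgR <- randomHypergraph(15, 8, seed = 41)
  XR <- withr::with_seed(41, matrix(rnorm(15 * 3), 15, 3))
  Theta <- withr::with_seed(42, matrix(rnorm(9), 3, 3))
  expect_error(hgnnLayer(XR, hgR, w = rep(0, 8), Theta = Theta), "zero")
  wR <- withr::with_seed(43, runif(8, 0.1, 1))
  expect_equal(unname(hgnnLayer(XR, hgR, wR, Theta)),
               oracleHGNN(XR, as.matrix(incidenceMatrix(hgR)), wR, Theta),
               tolerance = 1e-6)
})

test_that("forward pass composes the stages exactly", {
  hg <- randomHypergraph(10, 6, seed = 51)
  cfg <- hyperADConfig(seed = 51, embedDim = 5, nBlocks = 2)
  params <- withr::with_seed(51, initHyperADState(nGenes(hg), cfg))
  w <- withr::with_seed(52, runif(nHyperedges(hg)))
  Z <- forwardHyperAD(hg, w, params, cfg)
  expect_equal(unname(rowSums(Z)), rep(1, nGenes(hg)), tolerance = 1e-6)
  expect_true(all(Z >= 0 & Z <= 1))
  ref <- oracleForward(as.matrix(incidenceMatrix(hg)), w, params, 2,
                       "unweighted")
  expect_equal(unname(Z), ref, tolerance = 1e-6)
})

test_that("all-zero parameters give uninformative 0.5/0.5 scores", {
  hg <- randomHypergraph(8, 5, seed = 61)
  cfg <- hyperADConfig(seed = 61, embedDim = 3, nBlocks = 1)
  params <- withr::with_seed(61, initHyperADState(nGenes(hg), cfg))
  params <- lapply(params, function(p) {
    if (is.list(p)) lapply(p, function(q) q * 0) else p * 0
  })
  Z <- forwardHyperAD(hg, rep(1, nHyperedges(hg)), params, cfg)
  expect_equal(unname(Z), matrix(0.5, nGenes(hg), 2))
})

test_that("scores are equivariant to gene permutation and invariant to set ids", {
  gsl <- randomGeneSetList(12, 7, seed = 71)
  hg <- buildHypergraph(gsl)
  cfg <- hyperADConfig(seed = 71, embedDim = 4, nBlocks = 2)
  params <- withr::with_seed(71, initHyperADState(nGenes(hg), cfg))
  w <- withr::with_seed(72, runif(nHyperedges(hg)))
  Z <- forwardHyperAD(hg, w, params, cfg)
  ## renaming hyperedges changes nothing
  gsl2 <- GeneSetList(paste0("renamed_", seq_along(gsl@setIds)),
                      gsl@members)
  Z2 <- forwardHyperAD(buildHypergraph(gsl2), w, params, cfg)
  expect_equal(unname(Z), unname(Z2))
  ## renaming genes with an order-reversing map permutes the rows;
  ## permute the embedding rows the same way and scores must follow
  old <- hgGenes(hg)
  newNames <- setNames(sprintf("z%02d", rev(seq_along(old))), old)
  gsl3 <- GeneSetList(gsl@setIds,
                      lapply(gsl@members, function(m) unname(newNames[m])))
  hg3 <- buildHypergraph(gsl3)
  perm <- match(hgGenes(hg3), unname(newNames[old]))
  params3 <- params
  params3$E <- params$E[perm, , drop = FALSE]
  Z3 <- forwardHyperAD(hg3, w, params3, cfg)
  expect_equal(unname(Z3), unname(Z)[perm, ], tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  hg <- randomHypergraph(8, 5, seed = 81)
  cfg <- hyperADConfig(seed = 81, embedDim = 3, nBlocks = 2)
  params <- withr::with_seed(81, initHyperADState(nGenes(hg), cfg))
  w <- unname(hyperedgeWeights(hg, hgGenes(hg)[1:3]))
  ops <- hyperAD:::.denseOperators(hg, w, "unweighted")
  trainIdx <- c(1L, 3L, 5L, 7L)
  classIdx <- c(2L, 2L, 1L, 1L)
  lg <- hyperAD:::.lossGrads(ops, params, 2L, trainIdx, classIdx)
  numGrad <- function(mutate) {
    eps <- 1e-6
    up <- hyperAD:::.lossGrads(ops, mutate(params, eps), 2L,
                               trainIdx, classIdx)$loss
    dn <- hyperAD:::.lossGrads(ops, mutate(params, -eps), 2L,
                               trainIdx, classIdx)$loss
    (up - dn) / (2 * eps)
  }
  checks <- c(
    abs(numGrad(function(p, e) { p$E[2, 3] <- p$E[2, 3] + e; p }) -
          lg$grads$E[2, 3]),
    abs(numGrad(function(p, e) { p$b0[1] <- p$b0[1] + e; p }) -
          lg$grads$b0[1]),
    abs(numGrad(function(p, e) { p$Tve[[1]][1, 2] <- p$Tve[[1]][1, 2] + e; p }) -
          lg$grads$Tve[[1]][1, 2]),
    abs(numGrad(function(p, e) { p$Tev[[2]][3, 1] <- p$Tev[[2]][3, 1] + e; p }) -
          lg$grads$Tev[[2]][3, 1]),
    abs(numGrad(function(p, e) { p$Th1[2, 1] <- p$Th1[2, 1] + e; p }) -
          lg$grads$Th1[2, 1]),
    abs(numGrad(function(p, e) { p$b1[2] <- p$b1[2] + e; p }) -
          lg$grads$gb1[2]))
  expect_lt(max(checks), 1e-6)
})

test_that("training reduces the loss and is reproducible bit-for-bit", {
  sim <- generatePlantedHypergraph(plantedHypergraphSpec(
    nGenes = 80, nDiseaseGenes = 12, nRelevantSets = 12,
    nBackgroundSets = 25, nNegatives = 40, seed = 91))
  fit1 <- trainHyperAD(sim$hypergraph, sim$labels, tinyConfig(seed = 91))
  lt <- lossTrace(fit1)
  expect_lt(lt[length(lt)], lt[1])
  fit2 <- trainHyperAD(sim$hypergraph, sim$labels, tinyConfig(seed = 91))
  expect_identical(lossTrace(fit1), lossTrace(fit2))
  expect_identical(riskScores(fit1), riskScores(fit2))
  ## a different seed gives a different trajectory
  fit3 <- trainHyperAD(sim$hypergraph, sim$labels, tinyConfig(seed = 92))
  expect_false(identical(lossTrace(fit1), lossTrace(fit3)))
})

test_that("training uses only the provided labels: no held-out leakage", {
  sim <- generatePlantedHypergraph(plantedHypergraphSpec(
    nGenes = 80, nDiseaseGenes = 12, nRelevantSets = 12,
    nBackgroundSets = 25, nNegatives = 40, seed = 101))
  trainLabels <- sim$labels
  fit <- trainHyperAD(sim$hypergraph, trainLabels, tinyConfig(seed = 101))
  ## hyperedge weights derive from the training positives alone...
  expect_equal(fit@edgeWeights,
               unname(hyperedgeWeights(sim$hypergraph,
                                       trainLabels@positives)))
  ## ...and differ from weights that would leak the held-out positives
  leaky <- unname(hyperedgeWeights(sim$hypergraph, sim$diseaseGenes))
  expect_false(isTRUE(all.equal(fit@edgeWeights, leaky)))
  ## relabeling held-out genes in any external annotation cannot move
  ## the trained scores, because they never reach the training call
  mutatedHeldout <- sample(sim$heldoutPositives)
  fitAgain <- trainHyperAD(sim$hypergraph, trainLabels,
                           tinyConfig(seed = 101))
  expect_identical(riskScores(fit), riskScores(fitAgain))
})

test_that("degenerate label sets are rejected", {
  hg <- randomHypergraph(10, 6, seed = 111)
  expect_error(
    trainHyperAD(hg, LabelSet(hgGenes(hg)[1], character()),
                 tinyConfig(seed = 1)),
    "both positive and negative")
  expect_warning(
    trainHyperAD(hg, LabelSet(c(hgGenes(hg)[1], "ABSENT"),
                              hgGenes(hg)[2:4]),
                 tinyConfig(seed = 1)),
    "dropped")
})

test_that("model checkpoints save and load", {
  sim <- generatePlantedHypergraph(plantedHypergraphSpec(
    nGenes = 60, nDiseaseGenes = 10, nRelevantSets = 10,
    nBackgroundSets = 20, nNegatives = 30, seed = 121))
  fit <- trainHyperAD(sim$hypergraph, sim$labels,
                      tinyConfig(seed = 121, epochs = 10L))
  f <- withr::local_tempfile(fileext = ".rds")
  saveModelState(fit, f)
  back <- loadModelState(f)
  expect_identical(riskScores(back), riskScores(fit))
})
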