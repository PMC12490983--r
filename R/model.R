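## Two-stage message-passing network over the gene-set hypergraph.
##
## One block = node-to-hyperedge aggregation (member node features,
## degree-normalized, linearly transformed, ReLU) followed by
## hyperedge-to-node aggregation (incident hyperedge features scaled by
## the disease-specific weight w(e), transformed, residual added inside
## the activation). Gradients are computed by hand-written reverse-mode
## differentiation of this exact composition; optimization is full-batch
## Adam on a cross-entropy restricted to the labeled training genes
## (transductive learning: unlabeled genes participate in every forward
## pass but never in the loss).

.relu <- function(x) x * (x > 0)

.softmaxRows <- function(x) {
    x <- x - apply(x, 1L, max)
    ex <- exp(x)
    ex / rowSums(ex)
}

.xavier <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

## Dense operators used by the forward/backward pass:
##   A (M x N): row e = 1/d(v) over members v of e  -> node-to-edge
##   B (N x M): column e scaled by w(e)             -> edge-to-node
.denseOperators <- function(hg, w, degreeNormMode) {
    H <- as.matrix(hg@incidence)
    dv <- switch(degreeNormMode,
        unweighted = rowSums(H),
        weighted = as.numeric(H %*% w))
    if (any(dv <= 0)) {
        stop("zero node degree under degreeNormMode='", degreeNormMode,
             "'; use degreeNormMode='unweighted' or restrict the hypergraph")
    }
    list(H = H, A = t(H / dv), B = t(t(H) * w), dv = dv)
}

#' Initialize model parameters
#'
#' Xavier-uniform initialization of the embedding table (the one-hot
#' input projection), the per-block node-to-edge and edge-to-node
#' matrices, and the 2-class output head. Biases start at zero. Uses the
#' current RNG state; [trainHyperAD()] seeds it from the configuration.
#'
#' @param nGenes number of genes N.
#' @param config a [HyperADConfig-class].
#' @return named list of parameter matrices/vectors.
#' @export
initHyperADState <- function(nGenes, config) {
    d <- config@embedDim
    L <- config@nBlocks
    params <- list(
        E = .xavier(nGenes, d),
        b0 = rep(0, d),
        Tve = lapply(seq_len(L), function(l) .xavier(d, d)),
        Tev = lapply(seq_len(L), function(l) .xavier(d, d)),
        Th1 = .xavier(d, 2L),
        b1 = rep(0, 2L))
    params
}

#' Initial gene embeddings
#'
#' Projects the (implicit) one-hot gene features into the embedding
#' space: `X0 = relu(E + b0)`. Because the input is one-hot, the N x N
#' input matrix never needs to be materialized; the projection reduces to
#' a row lookup in the embedding table `E`.
#'
#' @param params parameter list from [initHyperADState()] (uses `E`, `b0`).
#' @return N x d matrix of initial embeddings.
#' @export
initEmbeddings <- function(params) {
    .relu(sweep(params$E, 2L, params$b0, "+"))
}

#' Node-to-hyperedge aggregation
#'
#' Each hyperedge aggregates the degree-normalized features of its member
#' nodes: `y_e = relu( sum_{v in e} (x_v / d(v)) %*% Theta )`.
#'
#' @param X N x d node feature matrix.
#' @param hg a [Hypergraph-class].
#' @param nodeDegree length-N node degree vector d(v) used for
#'   normalization (see [degrees()]).
#' @param Theta d x d transform matrix.
#' @param activation activation function (default ReLU).
#' @return M x d hyperedge feature matrix.
#' @export
nodeToEdge <- function(X, hg, nodeDegree, Theta, activation = .relu) {
    H <- as.matrix(hg@incidence)
    incident <- rowSums(H) > 0
    if (any(nodeDegree[incident] <= 0)) {
        stop("a node incident to a hyperedge has zero degree; ",
             "use degreeNormMode='unweighted'")
    }
    Xn <- X / nodeDegree
    Xn[!incident, ] <- 0
    activation(t(H) %*% Xn %*% Theta)
}

#' Hyperedge-to-node aggregation with residual
#'
#' Each node aggregates the features of its incident hyperedges scaled by
#' the disease-specific weight, adds its own previous features, then
#' applies the activation:
#' `x_v' = relu( sum_{e : v in e} w(e) * y_e %*% Theta + x_v )`.
#' Hyperedges with weight zero are inert: their features cannot influence
#' any node.
#'
#' @param Y M x d hyperedge feature matrix.
#' @param X N x d node feature matrix (residual input).
#' @param hg a [Hypergraph-class].
#' @param w length-M hyperedge weight vector.
#' @param Theta d x d transform matrix.
#' @param activation activation function (default ReLU).
#' @return N x d updated node feature matrix.
#' @export
edgeToNode <- function(Y, X, hg, w, Theta, activation = .relu) {
    H <- as.matrix(hg@incidence)
    if (length(w) != ncol(H)) stop("weight vector must have length ", ncol(H))
    activation(H %*% (Y * w) %*% Theta + X)
}

#' Classical hypergraph convolution layer
#'
#' The spectral-approximation baseline layer
#' `relu(Dv^(-1/2) H W De^(-1) H^T Dv^(-1/2) X Theta)`, provided for
#' architecture-comparison experiments against the two-stage blocks.
#'
#' @param X N x d node feature matrix.
#' @param hg a [Hypergraph-class].
#' @param w length-M hyperedge weight vector (identity when `NULL`).
#' @param Theta d x d transform matrix.
#' @param activation activation function (default ReLU).
#' @return N x d matrix.
#' @export
hgnnLayer <- function(X, hg, w = NULL, Theta, activation = .relu) {
    H <- as.matrix(hg@incidence)
    if (is.null(w)) w <- rep(1, ncol(H))
    dv <- as.numeric(H %*% w)
    if (any(dv <= 0)) {
        stop("zero node degree under these weights; restrict the ",
             "hypergraph or use identity weights")
    }
    de <- colSums(H)
    Hn <- H / sqrt(dv)
    activation(Hn %*% ((t(Hn) %*% X) * (w / de)) %*% Theta)
}

## Forward pass keeping the intermediates needed for backprop.
.forwardCache <- function(ops, params, L) {
    pre0 <- sweep(params$E, 2L, params$b0, "+")
    X <- .relu(pre0)
    Vs <- Ss <- Us <- Ts <- Xs <- vector("list", L)
    Xprev <- X
    for (l in seq_len(L)) {
        V <- ops$A %*% Xprev
        S <- V %*% params$Tve[[l]]
        Y <- .relu(S)
        U <- ops$B %*% Y
        Tm <- U %*% params$Tev[[l]] + Xprev
        Xl <- .relu(Tm)
        if (!all(is.finite(Xl))) {
            stop("non-finite node features in message-passing block ", l)
        }
        Vs[[l]] <- V; Ss[[l]] <- S; Us[[l]] <- U; Ts[[l]] <- Tm
        Xs[[l]] <- Xl
        Xprev <- Xl
    }
    logits <- sweep(Xprev %*% params$Th1, 2L, params$b1, "+")
    list(pre0 = pre0, X0 = X, Vs = Vs, Ss = Ss, Us = Us, Ts = Ts, Xs = Xs,
         logits = logits, Z = .softmaxRows(logits))
}

#' Full forward pass
#'
#' Initial embedding, `nBlocks` two-stage message-passing blocks, then a
#' softmax head producing one row of class probabilities per gene (second
#' column = risk score). Rows sum to 1.
#'
#' @param hg a [Hypergraph-class].
#' @param w length-M hyperedge weight vector.
#' @param params parameter list (see [initHyperADState()]).
#' @param config a [HyperADConfig-class].
#' @return N x 2 probability matrix with gene rownames.
#' @export
forwardHyperAD <- function(hg, w, params, config) {
    ops <- .denseOperators(hg, w, config@degreeNormMode)
    Z <- .forwardCache(ops, params, config@nBlocks)$Z
    rownames(Z) <- hg@genes
    colnames(Z) <- c("nonrisk", "risk")
    Z
}

## Mean cross-entropy over training rows + gradients for every parameter.
.lossGrads <- function(ops, params, L, trainIdx, classIdx) {
    fc <- .forwardCache(ops, params, L)
    n <- length(trainIdx)
    p <- fc$Z[cbind(trainIdx, classIdx)]
    loss <- -mean(log(pmax(p, 1e-300)))

    dlogits <- matrix(0, nrow(fc$Z), 2L)
    dlogits[trainIdx, ] <- fc$Z[trainIdx, , drop = FALSE] / n
    dlogits[cbind(trainIdx, classIdx)] <-
        dlogits[cbind(trainIdx, classIdx)] - 1 / n

    XL <- if (L > 0) fc$Xs[[L]] else fc$X0
    gTh1 <- t(XL) %*% dlogits
    gb1 <- colSums(dlogits)
    dX <- dlogits %*% t(params$Th1)

    gTve <- gTev <- vector("list", L)
    for (l in rev(seq_len(L))) {
        dT <- dX * (fc$Ts[[l]] > 0)
        gTev[[l]] <- t(fc$Us[[l]]) %*% dT
        dU <- dT %*% t(params$Tev[[l]])
        dY <- t(ops$B) %*% dU
        dS <- dY * (fc$Ss[[l]] > 0)
        gTve[[l]] <- t(fc$Vs[[l]]) %*% dS
        dV <- dS %*% t(params$Tve[[l]])
        dX <- dT + t(ops$A) %*% dV      # residual path + aggregation path
    }
    dPre0 <- dX * (fc$pre0 > 0)
    list(loss = loss,
         grads = list(E = dPre0, b0 = colSums(dPre0),
                      Tve = gTve, Tev = gTev, Th1 = gTh1, gb1 = gb1),
         Z = fc$Z)
}

## Adam state/update over the flat list of parameter arrays.
.flatten <- function(params) {
    c(list(E = params$E, b0 = params$b0),
      stats::setNames(params$Tve, paste0("Tve", seq_along(params$Tve))),
      stats::setNames(params$Tev, paste0("Tev", seq_along(params$Tev))),
      list(Th1 = params$Th1, b1 = params$b1))
}

.unflatten <- function(flat, L) {
    list(E = flat$E, b0 = flat$b0,
         Tve = unname(flat[paste0("Tve", seq_len(L))]),
         Tev = unname(flat[paste0("Tev", seq_len(L))]),
         Th1 = flat$Th1, b1 = flat$b1)
}

.adamStep <- function(flat, gflat, m, v, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    for (k in names(flat)) {
        m[[k]] <- beta1 * m[[k]] + (1 - beta1) * gflat[[k]]
        v[[k]] <- beta2 * v[[k]] + (1 - beta2) * gflat[[k]]^2
        mhat <- m[[k]] / (1 - beta1^t)
        vhat <- v[[k]] / (1 - beta2^t)
        flat[[k]] <- flat[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(flat = flat, m = m, v = v)
}

#' Train the risk-gene model
#'
#' Transductive full-batch training: every forward pass covers the whole
#' hypergraph, the cross-entropy covers only the labeled genes in
#' `labels`. When `weightMode = "ad_weighted"` the hyperedge weights are
#' computed from the positives in `labels` (in cross-validation these are
#' the training-fold positives only, so held-out labels can never leak
#' into the weights). With a fixed configuration seed the loss trace and
#' final scores are bit-for-bit reproducible.
#'
#' @param hg a [Hypergraph-class].
#' @param labels a [LabelSet-class]; labeled genes outside the hypergraph
#'   are dropped with a warning.
#' @param config a [HyperADConfig-class].
#' @return A [HyperADFit-class].
#' @examples
#' sim <- generatePlantedHypergraph(plantedHypergraphSpec(
#'     nGenes = 60, nDiseaseGenes = 10, nRelevantSets = 10,
#'     nBackgroundSets = 20, nNegatives = 30, seed = 1))
#' fit <- trainHyperAD(sim$hypergraph, sim$labels,
#'                     hyperADConfig(seed = 1, embedDim = 16, epochs = 30))
#' head(sort(riskScores(fit), decreasing = TRUE))
#' @export
trainHyperAD <- function(hg, labels, config) {
    stopifnot(is(hg, "Hypergraph"), is(labels, "LabelSet"),
              is(config, "HyperADConfig"))
    pos <- intersect(labels@positives, hg@genes)
    neg <- intersect(labels@negatives, hg@genes)
    nDropped <- length(labels@positives) + length(labels@negatives) -
        length(pos) - length(neg)
    if (nDropped > 0) {
        warning(nDropped, " labeled gene(s) not in the hypergraph were dropped")
    }
    if (!length(pos) || !length(neg)) {
        stop("both positive and negative labels are required for training")
    }
    M <- nHyperedges(hg)
    w <- switch(config@weightMode,
        ad_weighted = unname(hyperedgeWeights(hg, pos)),
        unweighted = rep(1, M))
    ops <- .denseOperators(hg, w, config@degreeNormMode)
    L <- config@nBlocks

    params <- withr::with_seed(config@seed,
                               initHyperADState(nGenes(hg), config))

    trainIdx <- match(c(pos, neg), hg@genes)
    classIdx <- c(rep(2L, length(pos)), rep(1L, length(neg)))

    flat <- .flatten(params)
    m <- lapply(flat, function(p) p * 0)
    v <- m
    lossTrace <- numeric(config@epochs + 1L)
    for (epoch in seq_len(config@epochs)) {
        params <- .unflatten(flat, L)
        lg <- .lossGrads(ops, params, L, trainIdx, classIdx)
        if (!is.finite(lg$loss)) {
            stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        lossTrace[epoch] <- lg$loss
        gflat <- .flatten(list(E = lg$grads$E, b0 = lg$grads$b0,
                               Tve = lg$grads$Tve, Tev = lg$grads$Tev,
                               Th1 = lg$grads$Th1, b1 = lg$grads$gb1))
        st <- .adamStep(flat, gflat, m, v, epoch, config@learningRate)
        flat <- st$flat; m <- st$m; v <- st$v
    }
    params <- .unflatten(flat, L)
    fc <- .forwardCache(ops, params, L)
    p <- fc$Z[cbind(trainIdx, classIdx)]
    lossTrace[config@epochs + 1L] <- -mean(log(pmax(p, 1e-300)))
    Z <- fc$Z
    rownames(Z) <- hg@genes
    colnames(Z) <- c("nonrisk", "risk")
    new("HyperADFit",
        config = config, params = params, edgeWeights = w,
        lossTrace = lossTrace, scores = Z,
        trainLabels = LabelSet(pos, neg))
}

#' @rdname riskScores
#' @export
setMethod("riskScores", "HyperADFit", function(object) {
    stats::setNames(object@scores[, 2L], rownames(object@scores))
})

#' @rdname lossTrace
#' @export
setMethod("lossTrace", "HyperADFit", function(object) object@lossTrace)

setMethod("show", "HyperADFit", function(object) {
    cat(sprintf(
        "HyperADFit: %d genes, %d block(s), embedDim %d, weightMode '%s'\n",
        nrow(object@scores), object@config@nBlocks, object@config@embedDim,
        object@config@weightMode))
    lt <- object@lossTrace
    cat(sprintf("training loss %.4f -> %.4f over %d epochs\n",
                lt[1L], lt[length(lt)], object@config@epochs))
})

#' Save / load a fitted model
#'
#' Thin checkpoint wrappers around [saveRDS()]/[readRDS()].
#'
#' @param fit a [HyperADFit-class].
#' @param path file path.
#' @return `loadModelState` returns the [HyperADFit-class];
#'   `saveModelState` returns `path` invisibly.
#' @export
saveModelState <- function(fit, path) {
    stopifnot(is(fit, "HyperADFit"))
    saveRDS(fit, path)
    invisible(path)
}

#' @rdname saveModelState
#' @export
loadModelState <- function(path) {
    fit <- readRDS(path)
    stopifnot(is(fit, "HyperADFit"))
    fit
}

#' Write ranked risk scores as TSV
#'
#' Columns: gene, risk_score, rank (1 = highest risk; ties broken
#' lexicographically by symbol).
#'
#' @param fit a [HyperADFit-class].
#' @param path output TSV path.
#' @param exclude genes to drop before ranking (e.g. known positives).
#' @return the written data.frame, invisibly.
#' @export
writeScores <- function(fit, path, exclude = character()) {
    s <- riskScores(fit)
    ranked <- prioritizeGenes(s, exclude = exclude)
    df <- data.frame(gene = ranked,
                     risk_score = unname(s[ranked]),
                     rank = seq_along(ranked))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(df)
}
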