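#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random
#' positive outscores a random negative, counting ties as 1/2.
#'
#' @param scores numeric vector.
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive; both classes
#'   must be present.
#' @return AUROC in \[0, 1\].
#' @examples
#' aurocScore(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' @export
aurocScore <- function(scores, labels) {
    labels <- as.logical(labels)
    if (length(scores) != length(labels)) stop("length mismatch")
    nPos <- sum(labels)
    nNeg <- sum(!labels)
    if (nPos == 0L || nNeg == 0L) {
        stop("AUROC requires both classes to be present")
    }
    r <- rank(scores)
    (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-rule average precision: AP = sum_k (R_k - R_{k-1}) * P_k over the
#' distinct score thresholds in decreasing order (no trapezoidal
#' interpolation, which is optimistic for PR curves). Tied scores enter
#' as one threshold.
#'
#' @param scores numeric vector.
#' @param labels logical or 0/1 vector; at least one positive required.
#' @return AUPRC in (0, 1\].
#' @examples
#' auprcScore(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
#' @export
auprcScore <- function(scores, labels) {
    labels <- as.logical(labels)
    if (length(scores) != length(labels)) stop("length mismatch")
    nPos <- sum(labels)
    if (nPos == 0L) stop("AUPRC requires at least one positive")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]
    y <- labels[o]
    tp <- cumsum(y)
    fp <- cumsum(!y)
    last <- which(s != c(s[-1L], NA) | seq_along(s) == length(s))
    prec <- tp[last] / (tp[last] + fp[last])
    rec <- tp[last] / nPos
    sum(diff(c(0, rec)) * prec)
}

#' Cross-validation configuration
#'
#' @param nRepetitions number of CV repetitions (default 10).
#' @param nFolds folds per repetition (default 5).
#' @param seed integer seed controlling negative sampling, fold
#'   assignment and per-fold model initialization.
#' @param nNegatives negatives sampled from the pool per repetition
#'   (default 1000; capped at the pool size).
#' @param resampleNegatives resample negatives each repetition (default
#'   `TRUE`); if `FALSE` a single draw is reused across repetitions.
#' @return list of class `cvConfig`.
#' @export
cvConfig <- function(nRepetitions = 10L, nFolds = 5L, seed,
                     nNegatives = 1000L, resampleNegatives = TRUE) {
    if (missing(seed)) stop("a seed is mandatory in the CV configuration")
    if (nFolds < 2L) stop("nFolds must be >= 2")
    structure(list(nRepetitions = as.integer(nRepetitions),
                   nFolds = as.integer(nFolds), seed = as.integer(seed),
                   nNegatives = as.integer(nNegatives),
                   resampleNegatives = isTRUE(resampleNegatives)),
              class = "cvConfig")
}

## Stratified fold ids: each class split as evenly as possible.
.stratifiedFolds <- function(n, k) {
    if (n < k) stop("cannot stratify ", n, " observations into ", k, " folds")
    sample(rep(seq_len(k), length.out = n))
}

#' Repeated stratified cross-validation
#'
#' For each repetition: negatives are drawn (seeded) from the pool,
#' positives and negatives are split into stratified folds, and for each
#' fold a model is trained on the remaining labeled genes — with
#' hyperedge weights recomputed from the training-fold positives only —
#' and scored on the held-out genes. AUROC and AUPRC are recorded per
#' fold. Fully deterministic under a fixed seed.
#'
#' @param hg a [Hypergraph-class].
#' @param positives character vector of known risk genes.
#' @param negativePool character vector of candidate negatives (disjoint
#'   from `positives`).
#' @param modelConfig a [HyperADConfig-class]; its seed is re-derived per
#'   fold from the CV seed.
#' @param cv a [cvConfig()] list.
#' @return A [CVResult-class].
#' @export
crossValidate <- function(hg, positives, negativePool, modelConfig, cv) {
    stopifnot(is(hg, "Hypergraph"), inherits(cv, "cvConfig"))
    if (length(intersect(positives, negativePool))) {
        stop("positives and negative pool must be disjoint")
    }
    pos <- intersect(unique(positives), hg@genes)
    pool <- intersect(unique(negativePool), hg@genes)
    dropped <- length(unique(positives)) - length(pos) +
        length(unique(negativePool)) - length(pool)
    if (dropped > 0) {
        message(dropped, " labeled gene(s) outside the hypergraph dropped")
    }
    if (length(pos) < cv$nFolds) {
        stop("need at least one positive per fold")
    }
    nNeg <- min(cv$nNegatives, length(pool))
    if (nNeg < cv$nFolds) stop("need at least one negative per fold")

    auroc <- auprc <- matrix(NA_real_, cv$nRepetitions, cv$nFolds,
        dimnames = list(paste0("rep", seq_len(cv$nRepetitions)),
                        paste0("fold", seq_len(cv$nFolds))))
    negFixed <- NULL
    for (r in seq_len(cv$nRepetitions)) {
        repSeed <- cv$seed + 1009L * r
        drawn <- withr::with_seed(repSeed, {
            neg <- sample(pool, nNeg)
            list(neg = neg,
                 foldPos = .stratifiedFolds(length(pos), cv$nFolds),
                 foldNeg = .stratifiedFolds(nNeg, cv$nFolds))
        })
        if (!cv$resampleNegatives) {
            if (is.null(negFixed)) negFixed <- drawn$neg
            drawn$neg <- negFixed
        }
        for (f in seq_len(cv$nFolds)) {
            trainPos <- pos[drawn$foldPos != f]
            trainNeg <- drawn$neg[drawn$foldNeg != f]
            testPos <- pos[drawn$foldPos == f]
            testNeg <- drawn$neg[drawn$foldNeg == f]
            if (!length(testPos) || !length(testNeg)) {
                stop("fold ", f, " of repetition ", r,
                     " contains a single class")
            }
            cfg <- modelConfig
            cfg@seed <- (repSeed + 17L * f) %% .Machine$integer.max
            fit <- trainHyperAD(hg, LabelSet(trainPos, trainNeg), cfg)
            s <- riskScores(fit)[c(testPos, testNeg)]
            y <- c(rep(1L, length(testPos)), rep(0L, length(testNeg)))
            auroc[r, f] <- aurocScore(s, y)
            auprc[r, f] <- auprcScore(s, y)
        }
    }
    new("CVResult", auroc = auroc, auprc = auprc,
        nRepetitions = cv$nRepetitions, nFolds = cv$nFolds,
        seed = cv$seed)
}

#' @rdname cvSummary
#' @export
setMethod("cvSummary", "CVResult", function(object) {
    data.frame(
        metric = c("AUROC", "AUPRC"),
        mean = c(mean(object@auroc), mean(object@auprc)),
        sd = c(stats::sd(as.numeric(object@auroc)),
               stats::sd(as.numeric(object@auprc))),
        nFolds = length(object@auroc))
})

setMethod("show", "CVResult", function(object) {
    s <- cvSummary(object)
    cat(sprintf("CVResult: %d repetition(s) x %d fold(s), seed %d\n",
                object@nRepetitions, object@nFolds, object@seed))
    cat(sprintf("  AUROC %.3f +/- %.3f   AUPRC %.3f +/- %.3f\n",
                s$mean[1], s$sd[1], s$mean[2], s$sd[2]))
})

#' Rank genes by risk score
#'
#' Genes in `exclude` (typically the known positives) are removed; the
#' rest are sorted by score descending, ties broken lexicographically by
#' gene symbol so the ranking is deterministic.
#'
#' @param scores named numeric vector of risk scores.
#' @param exclude character vector of genes to drop before ranking.
#' @return character vector of gene symbols in rank order.
#' @examples
#' prioritizeGenes(c(A = 0.2, B = 0.9, C = 0.9), exclude = "A")
#' @export
prioritizeGenes <- function(scores, exclude = character()) {
    if (is.null(names(scores))) stop("scores must be named by gene symbol")
    keep <- !(names(scores) %in% exclude)
    s <- scores[keep]
    names(s)[order(-s, names(s), method = "radix")]
}
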