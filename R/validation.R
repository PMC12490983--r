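#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()]), with input
#' validation: p-values must lie in \[0, 1\].
#'
#' @param pvalues numeric vector of raw p-values.
#' @return adjusted p-values, capped at 1.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(pvalues) {
    if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
        stop("p-values must lie in [0, 1]")
    }
    stats::p.adjust(pvalues, method = "BH")
}

#' Decile enrichment of term sets in a ranked gene list
#'
#' Splits the ranking into `nBins` near-equal contiguous bins (the
#' remainder genes go to the earlier bins) and asks, per term, whether
#' its members concentrate in the first bin (the top tier of the
#' ranking). The first-bin p-value is the hypergeometric upper tail
#' P(X >= overlap) over the ranking universe; FDR is controlled by
#' Benjamini-Hochberg across terms. Terms with no member in the universe
#' are skipped with a warning.
#'
#' @param ranking ordered character vector of genes (best first),
#'   typically from [prioritizeGenes()].
#' @param termSets a [GeneSetList-class] of annotation terms.
#' @param nBins number of bins (default 10, i.e. deciles).
#' @return list with `summary` (data.frame: setId, nUniverse,
#'   firstBinCount, pValue, fdr) and `binFractions` (terms x bins matrix
#'   of per-bin member fractions, rows summing to 1).
#' @export
decileEnrichment <- function(ranking, termSets, nBins = 10L) {
    stopifnot(is(termSets, "GeneSetList"))
    n <- length(ranking)
    if (!n) stop("ranking is empty")
    if (anyDuplicated(ranking)) stop("ranking contains duplicate genes")
    binSizes <- rep(n %/% nBins, nBins)
    extra <- n %% nBins
    if (extra) binSizes[seq_len(extra)] <- binSizes[seq_len(extra)] + 1L
    binOf <- rep(seq_len(nBins), binSizes)
    names(binOf) <- ranking

    ids <- termSets@setIds
    keep <- logical(length(ids))
    frac <- matrix(NA_real_, length(ids), nBins,
                   dimnames = list(ids, paste0("bin", seq_len(nBins))))
    sizes <- integer(length(ids))
    overlap1 <- integer(length(ids))
    pvals <- rep(NA_real_, length(ids))
    for (i in seq_along(ids)) {
        inUniv <- intersect(termSets@members[[i]], ranking)
        if (!length(inUniv)) {
            warning("term '", ids[i], "' has no member in the ranking; skipped")
            next
        }
        keep[i] <- TRUE
        sizes[i] <- length(inUniv)
        counts <- tabulate(binOf[inUniv], nbins = nBins)
        frac[i, ] <- counts / length(inUniv)
        overlap1[i] <- counts[1L]
        pvals[i] <- stats::phyper(counts[1L] - 1L, length(inUniv),
                                  n - length(inUniv), binSizes[1L],
                                  lower.tail = FALSE)
    }
    if (!any(keep)) stop("no term overlaps the ranking universe")
    summary <- data.frame(
        setId = ids[keep], nUniverse = sizes[keep],
        firstBinCount = overlap1[keep], pValue = pvals[keep])
    summary$fdr <- benjaminiHochberg(summary$pValue)
    list(summary = summary, binFractions = frac[keep, , drop = FALSE])
}

#' Permutation test of network association with known genes
#'
#' Counts edges joining the candidate set to the known set, then compares
#' against a null of size-matched gene sets drawn uniformly from the
#' network genes excluding the known set. The empirical p-value is
#' `(1 + #{null >= observed}) / (1 + nPerm)`, so its resolution is
#' `1/(nPerm + 1)`.
#'
#' @param candidates character vector (e.g. the top 50 novel genes);
#'   must be disjoint from `known`. Candidates absent from the network
#'   are dropped and reported in the result.
#' @param known character vector of established disease genes.
#' @param edges two-column data.frame/matrix of undirected edges (gene
#'   symbols); duplicate and self edges are removed.
#' @param nPerm number of permutations (default 10000, resolution 1e-4).
#' @param seed integer seed for the null draws.
#' @return list: `observed`, `nullMean`, `nullSd`, `pValue`,
#'   `nCandidatesUsed`, `nPerm`.
#' @export
networkAssociationTest <- function(candidates, known, edges,
                                   nPerm = 10000L, seed) {
    if (missing(seed)) stop("a seed is mandatory for the permutation test")
    if (nPerm < 1L) stop("nPerm must be >= 1")
    candidates <- unique(as.character(candidates))
    known <- unique(as.character(known))
    if (length(intersect(candidates, known))) {
        stop("candidates and known genes must be disjoint")
    }
    edges <- as.data.frame(edges)[, 1:2]
    a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
    ok <- a != b
    a <- a[ok]; b <- b[ok]
    key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
    dup <- duplicated(key)
    a <- a[!dup]; b <- b[!dup]
    netGenes <- sort(unique(c(a, b)))

    ## edges-to-known count per non-known network gene; the statistic for
    ## any candidate set is then a fast sum over this lookup
    cnt <- numeric(length(netGenes))
    names(cnt) <- netGenes
    ends <- c(a[b %in% known & !(a %in% known)],
              b[a %in% known & !(b %in% known)])
    if (length(ends)) {
        tt <- table(ends)
        cnt[names(tt)] <- cnt[names(tt)] + as.numeric(tt)
    }

    candUsed <- intersect(candidates, netGenes)
    if (!length(candUsed)) stop("no candidate gene is present in the network")
    observed <- sum(cnt[candUsed])
    pool <- setdiff(netGenes, known)
    if (length(pool) < length(candUsed)) {
        stop("network too small to draw size-matched null sets")
    }
    nullStats <- withr::with_seed(seed, {
        vapply(seq_len(nPerm), function(i) {
            sum(cnt[sample(pool, length(candUsed))])
        }, numeric(1))
    })
    list(observed = observed,
         nullMean = mean(nullStats), nullSd = stats::sd(nullStats),
         pValue = (1 + sum(nullStats >= observed)) / (1 + nPerm),
         nCandidatesUsed = length(candUsed), nPerm = as.integer(nPerm))
}

#' Kendall tau-b monotone trend test across ordinal stages
#'
#' Per gene, tests whether expression changes monotonically with an
#' ordinal stage variable (e.g. cognitively normal, mild impairment,
#' disease) using the tie-corrected Kendall tau-b statistic with a
#' normal-approximation p-value; FDR across genes is controlled by
#' Benjamini-Hochberg. Missing expression values are handled
#' pairwise-complete (samples with `NA` dropped per gene); genes with
#' constant (or fewer than two finite) values get tau `NA`, p 1 and
#' direction `"none"`.
#'
#' @param expression numeric gene x sample matrix with gene rownames.
#' @param stage ordinal sample stage vector (numeric or ordered factor),
#'   length `ncol(expression)`, at least two distinct values, no missing
#'   entries.
#' @param fdrThreshold FDR level below which a direction is called
#'   (default 0.05).
#' @return data.frame: gene, tau, pValue, fdr, direction
#'   (`"increasing"`, `"decreasing"`, `"none"`).
#' @export
kendallTaubTrend <- function(expression, stage, fdrThreshold = 0.05) {
    expression <- as.matrix(expression)
    if (is.ordered(stage) || is.factor(stage)) stage <- as.integer(stage)
    if (length(stage) != ncol(expression)) {
        stop("stage length must equal the number of samples")
    }
    if (anyNA(stage)) stop("missing stage labels are not allowed")
    if (length(unique(stage)) < 2L) {
        stop("at least two distinct stages are required")
    }
    genes <- rownames(expression)
    if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(expression)))
    tau <- rep(NA_real_, nrow(expression))
    pval <- rep(1, nrow(expression))
    for (i in seq_len(nrow(expression))) {
        x <- expression[i, ]
        ok <- is.finite(x)
        if (sum(ok) < 2L || length(unique(x[ok])) < 2L ||
            length(unique(stage[ok])) < 2L) next
        ct <- suppressWarnings(
            stats::cor.test(x[ok], stage[ok], method = "kendall",
                            exact = FALSE))
        tau[i] <- unname(ct$estimate)
        pval[i] <- ct$p.value
    }
    fdr <- benjaminiHochberg(pval)
    direction <- rep("none", length(tau))
    sig <- !is.na(tau) & fdr < fdrThreshold
    direction[sig & tau > 0] <- "increasing"
    direction[sig & tau < 0] <- "decreasing"
    data.frame(gene = genes, tau = tau, pValue = pval, fdr = fdr,
               direction = direction)
}
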