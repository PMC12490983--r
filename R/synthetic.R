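#' Specification for a planted-module hypergraph
#'
#' Describes a synthetic gene-set hypergraph in which a designated group
#' of disease genes co-occurs in "relevant" hyperedges — the structure a
#' functional gene-set collection exhibits when a coherent disease module
#' is annotated across many sets — while background hyperedges sample
#' genes uniformly.
#'
#' @param nGenes total genes (default 300).
#' @param nDiseaseGenes planted disease genes (default 30).
#' @param nRelevantSets hyperedges enriched for disease genes (default 40).
#' @param nBackgroundSets uniform hyperedges (default 120).
#' @param pDiseaseInRelevant probability that each member of a relevant
#'   hyperedge is drawn from the disease genes rather than uniformly
#'   (default 0.8).
#' @param setSizeRange inclusive size range of hyperedges (default 5-25).
#' @param positiveFraction fraction of disease genes exposed as training
#'   positives; the rest are held out as discoverable (default 0.5).
#' @param nNegatives negatives sampled from the non-disease genes
#'   (default 100, keeping roughly the 1:7 positive:negative ratio used
#'   with curated risk-gene lists).
#' @param seed integer seed (mandatory).
#' @return list of class `plantedHypergraphSpec`.
#' @export
plantedHypergraphSpec <- function(nGenes = 300L, nDiseaseGenes = 30L,
                                  nRelevantSets = 40L, nBackgroundSets = 120L,
                                  pDiseaseInRelevant = 0.8,
                                  setSizeRange = c(5L, 25L),
                                  positiveFraction = 0.5,
                                  nNegatives = 100L, seed) {
    if (missing(seed)) stop("a seed is mandatory")
    if (nDiseaseGenes >= nGenes) stop("nDiseaseGenes must be < nGenes")
    if (pDiseaseInRelevant < 0 || pDiseaseInRelevant > 1) {
        stop("pDiseaseInRelevant must lie in [0, 1]")
    }
    if (setSizeRange[1L] < 2L) stop("minimum set size must be >= 2")
    if (nNegatives > nGenes - nDiseaseGenes) {
        stop("not enough non-disease genes for the requested negatives")
    }
    structure(list(nGenes = as.integer(nGenes),
                   nDiseaseGenes = as.integer(nDiseaseGenes),
                   nRelevantSets = as.integer(nRelevantSets),
                   nBackgroundSets = as.integer(nBackgroundSets),
                   pDiseaseInRelevant = pDiseaseInRelevant,
                   setSizeRange = as.integer(setSizeRange),
                   positiveFraction = positiveFraction,
                   nNegatives = as.integer(nNegatives),
                   seed = as.integer(seed)),
              class = "plantedHypergraphSpec")
}

#' Generate a hypergraph with a planted disease module
#'
#' Relevant hyperedges draw each member from the disease genes with
#' probability `pDiseaseInRelevant`, otherwise uniformly from all genes;
#' background hyperedges draw uniformly. A fraction of the disease genes
#' is exposed as training positives, the rest are held out as the
#' discoverable ground truth; negatives are sampled from the non-disease
#' genes. Bit-for-bit reproducible under the spec seed.
#'
#' @param spec a [plantedHypergraphSpec()].
#' @return list: `hypergraph` ([Hypergraph-class]), `labels`
#'   ([LabelSet-class] of exposed positives and sampled negatives),
#'   `diseaseGenes` (full planted module), `heldoutPositives` (disease
#'   genes not exposed as positives), `geneSets` (the underlying
#'   [GeneSetList-class]).
#' @export
generatePlantedHypergraph <- function(spec) {
    stopifnot(inherits(spec, "plantedHypergraphSpec"))
    withr::with_seed(spec$seed, {
        genes <- sprintf("G%04d", seq_len(spec$nGenes))
        disease <- sort(sample(genes, spec$nDiseaseGenes))
        nSets <- spec$nRelevantSets + spec$nBackgroundSets
        sizes <- sample(seq(spec$setSizeRange[1L], spec$setSizeRange[2L]),
                        nSets, replace = TRUE)
        members <- vector("list", nSets)
        for (s in seq_len(nSets)) {
            if (s <= spec$nRelevantSets) {
                fromDisease <- stats::runif(sizes[s]) < spec$pDiseaseInRelevant
                m <- character(sizes[s])
                if (any(fromDisease)) {
                    m[fromDisease] <- sample(disease, sum(fromDisease),
                                             replace = TRUE)
                }
                if (any(!fromDisease)) {
                    m[!fromDisease] <- sample(genes, sum(!fromDisease),
                                              replace = TRUE)
                }
            } else {
                m <- sample(genes, sizes[s], replace = FALSE)
            }
            members[[s]] <- unique(m)
        }
        tags <- rep(c("relevant", "background"),
                    c(spec$nRelevantSets, spec$nBackgroundSets))
        gsl <- GeneSetList(
            setIds = sprintf("%s_%03d", toupper(tags), seq_len(nSets)),
            members = members,
            descriptions = tags,
            collectionTags = tags)
        hg <- buildHypergraph(gsl, minSize = 2L)
        diseaseInHg <- intersect(disease, hgGenes(hg))
        nExposed <- max(1L, round(spec$positiveFraction * length(diseaseInHg)))
        exposed <- sort(sample(diseaseInHg, nExposed))
        heldout <- setdiff(diseaseInHg, exposed)
        nonDisease <- setdiff(hgGenes(hg), disease)
        negatives <- sort(sample(nonDisease,
                                 min(spec$nNegatives, length(nonDisease))))
        list(hypergraph = hg,
             labels = LabelSet(exposed, negatives),
             diseaseGenes = diseaseInHg,
             heldoutPositives = heldout,
             geneSets = gsl)
    })
}

#' Specification for staged expression data
#'
#' Emulates a proteomic/transcriptomic cohort stratified into ordered
#' clinical stages (e.g. no impairment, mild impairment, disease), with a
#' planted subset of genes whose mean expression shifts monotonically
#' across stages.
#'
#' @param nGenes total genes (default 200).
#' @param nTrendGenes genes with a planted monotone trend (default 40).
#' @param groupSizes samples per stage in stage order (default
#'   `c(174, 100, 104)`).
#' @param effectSize mean shift per stage step in noise-SD-free units
#'   (default 0.5).
#' @param noiseSd Gaussian noise standard deviation (default 1).
#' @param seed integer seed (mandatory).
#' @return list of class `stagedExpressionSpec`.
#' @export
stagedExpressionSpec <- function(nGenes = 200L, nTrendGenes = 40L,
                                 groupSizes = c(174L, 100L, 104L),
                                 effectSize = 0.5, noiseSd = 1, seed) {
    if (missing(seed)) stop("a seed is mandatory")
    if (nTrendGenes > nGenes) stop("nTrendGenes must be <= nGenes")
    if (any(groupSizes < 2L)) stop("each stage needs >= 2 samples")
    structure(list(nGenes = as.integer(nGenes),
                   nTrendGenes = as.integer(nTrendGenes),
                   groupSizes = as.integer(groupSizes),
                   effectSize = effectSize, noiseSd = noiseSd,
                   seed = as.integer(seed)),
              class = "stagedExpressionSpec")
}

#' Generate staged expression with planted monotone trends
#'
#' Trend genes get their stage-group means shifted by `+/- effectSize`
#' per stage step (sign randomized per gene and recorded); all other
#' genes are flat. Gaussian noise with `noiseSd` is added everywhere.
#'
#' @param spec a [stagedExpressionSpec()].
#' @return list: `expression` (gene x sample matrix), `stage` (integer
#'   stage per sample, 1-based), `trendGenes` (character), `trendSign`
#'   (named +1/-1 vector over trend genes).
#' @export
generateStagedExpression <- function(spec) {
    stopifnot(inherits(spec, "stagedExpressionSpec"))
    withr::with_seed(spec$seed, {
        genes <- sprintf("P%04d", seq_len(spec$nGenes))
        stage <- rep(seq_along(spec$groupSizes), spec$groupSizes)
        nSamples <- length(stage)
        trend <- if (spec$nTrendGenes > 0) {
            sort(sample(genes, spec$nTrendGenes))
        } else {
            character()
        }
        sign <- stats::setNames(
            sample(c(-1, 1), length(trend), replace = TRUE), trend)
        mu <- matrix(0, spec$nGenes, nSamples, dimnames = list(genes, NULL))
        if (length(trend)) {
            shift <- outer(sign, (stage - 1) * spec$effectSize)
            mu[trend, ] <- shift
        }
        expr <- mu + matrix(stats::rnorm(spec$nGenes * nSamples,
                                         sd = spec$noiseSd),
                            spec$nGenes, nSamples)
        colnames(expr) <- sprintf("S%04d", seq_len(nSamples))
        list(expression = expr, stage = stage,
             trendGenes = trend, trendSign = sign)
    })
}

#' Generate a toy undirected gene network
#'
#' Inserts the given planted edges, then adds independent background
#' edges between every unordered gene pair with probability
#' `backgroundEdgeProb` (Erdos-Renyi). Deterministic under the seed.
#'
#' @param genes character vector of node names.
#' @param plantedPairs two-column matrix/data.frame of edges to force
#'   into the network (may be `NULL`).
#' @param backgroundEdgeProb background edge probability.
#' @param seed integer seed (mandatory).
#' @return two-column data.frame (`from`, `to`) of unique undirected
#'   edges.
#' @export
generateToyNetwork <- function(genes, plantedPairs = NULL,
                               backgroundEdgeProb = 0, seed) {
    if (missing(seed)) stop("a seed is mandatory")
    genes <- unique(as.character(genes))
    withr::with_seed(seed, {
        pairs <- t(utils::combn(genes, 2L))
        keep <- stats::runif(nrow(pairs)) < backgroundEdgeProb
        edges <- pairs[keep, , drop = FALSE]
        if (!is.null(plantedPairs)) {
            pp <- as.matrix(as.data.frame(plantedPairs)[, 1:2])
            storage.mode(pp) <- "character"
            edges <- rbind(pp, edges)
        }
        if (!nrow(edges)) {
            return(data.frame(from = character(), to = character()))
        }
        a <- pmin(edges[, 1L], edges[, 2L])
        b <- pmax(edges[, 1L], edges[, 2L])
        ok <- a != b
        key <- paste(a, b, sep = "\r")
        dedup <- ok & !duplicated(key)
        out <- data.frame(from = a[dedup], to = b[dedup])
        out[order(out$from, out$to), , drop = FALSE]
    })
}

#' Write a staged expression dataset as TSV files
#'
#' Writes `expression.tsv` (genes x samples, first column `gene`) and
#' `stage.tsv` (sample, stage) into `dir`.
#'
#' @param sim output of [generateStagedExpression()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeStagedExpression <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    df <- data.frame(gene = rownames(sim$expression), sim$expression,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(sample = colnames(sim$expression), stage = sim$stage),
        file.path(dir, "stage.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(dir)
}

#' Read a staged expression dataset written by [writeStagedExpression()]
#'
#' @param dir directory containing `expression.tsv` and `stage.tsv`.
#' @return list with `expression` matrix and `stage` integer vector.
#' @export
readStagedExpression <- function(dir) {
    df <- utils::read.delim(file.path(dir, "expression.tsv"),
                            check.names = FALSE)
    expr <- as.matrix(df[, -1L, drop = FALSE])
    rownames(expr) <- df$gene
    st <- utils::read.delim(file.path(dir, "stage.tsv"))
    list(expression = expr, stage = st$stage[match(colnames(expr),
                                                   st$sample)])
}

#' Write / read an edge list as a two-column TSV
#' @param edges two-column data.frame of edges.
#' @param path TSV path.
#' @return `path` invisibly (write); data.frame (read).
#' @export
writeEdgeList <- function(edges, path) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
    utils::read.delim(path, colClasses = "character")
}
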