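#' Build a hypergraph from gene sets
#'
#' Genes become nodes and gene sets become hyperedges; the sparse binary
#' incidence matrix has `H[a, b] = 1` iff gene `a` is a member of set `b`.
#' Sets whose member count falls outside `[minSize, maxSize]` are dropped
#' before construction. The gene universe is the union of the members of
#' the retained sets, sorted lexicographically; sets keep input order.
#'
#' @param sets a [GeneSetList-class].
#' @param minSize minimum set size retained (default 2; singleton
#'   hyperedges carry no relational information).
#' @param maxSize maximum set size retained (default `Inf`).
#' @return A [Hypergraph-class].
#' @examples
#' gs <- GeneSetList(c("e1", "e2"), list(c("g1", "g2"), c("g2", "g3")))
#' hg <- buildHypergraph(gs)
#' as.matrix(incidenceMatrix(hg))
#' @export
buildHypergraph <- function(sets, minSize = 2L, maxSize = Inf) {
    stopifnot(is(sets, "GeneSetList"))
    sizes <- lengths(sets@members)
    keep <- which(sizes >= minSize & sizes <= maxSize)
    if (!length(keep)) {
        stop(sprintf(
            "no gene sets remain after the size filter [%s, %s]",
            minSize, maxSize))
    }
    members <- sets@members[keep]
    genes <- sort(unique(unlist(members)))
    geneIdx <- seq_along(genes)
    names(geneIdx) <- genes
    i <- unlist(lapply(members, function(m) unname(geneIdx[m])))
    j <- rep(seq_along(members), lengths(members))
    H <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(genes), length(members)),
                              dimnames = list(genes, sets@setIds[keep]))
    new("Hypergraph",
        genes = genes, setIds = sets@setIds[keep], incidence = H,
        collectionTags = sets@collectionTags[keep])
}

#' @describeIn Hypergraph-class number of genes N
#' @param x a Hypergraph
#' @export
setMethod("nGenes", "Hypergraph", function(x) length(x@genes))

#' @describeIn Hypergraph-class number of hyperedges M
#' @export
setMethod("nHyperedges", "Hypergraph", function(x) length(x@setIds))

#' @describeIn Hypergraph-class gene symbols (node order)
#' @export
setMethod("hgGenes", "Hypergraph", function(x) x@genes)

#' @describeIn Hypergraph-class hyperedge ids (column order)
#' @export
setMethod("setIds", "Hypergraph", function(x) x@setIds)

#' @describeIn Hypergraph-class sparse incidence matrix
#' @export
setMethod("incidenceMatrix", "Hypergraph", function(x) x@incidence)

setMethod("show", "Hypergraph", function(object) {
    cat(sprintf("Hypergraph: %d genes x %d hyperedges, %d incidences\n",
                nGenes(object), nHyperedges(object),
                length(object@incidence@x)))
    tags <- unique(object@collectionTags)
    tags <- tags[!is.na(tags)]
    if (length(tags)) cat("collections:", paste(tags, collapse = ", "), "\n")
})

#' @rdname degrees
#' @export
setMethod("degrees", "Hypergraph", function(x, w = NULL) {
    H <- x@incidence
    M <- ncol(H)
    if (is.null(w)) w <- rep(1, M)
    if (length(w) != M) stop("weight vector must have length ", M)
    node <- as.numeric(H %*% w)
    edge <- Matrix::colSums(H)
    list(node = stats::setNames(node, x@genes),
         edge = stats::setNames(as.numeric(edge), x@setIds))
})

#' @rdname hyperedgeWeights
#' @export
setMethod("hyperedgeWeights", "Hypergraph", function(x, positives) {
    positives <- unique(as.character(positives))
    missing <- setdiff(positives, x@genes)
    if (length(missing)) {
        warning(length(missing),
                " positive gene(s) not in the hypergraph were ignored")
    }
    pos <- intersect(positives, x@genes)
    H <- x@incidence
    delta <- Matrix::colSums(H)
    if (any(delta == 0)) stop("internal error: empty hyperedge encountered")
    nPos <- if (length(pos)) {
        Matrix::colSums(H[match(pos, x@genes), , drop = FALSE])
    } else {
        rep(0, ncol(H))
    }
    stats::setNames(as.numeric(nPos) / as.numeric(delta), x@setIds)
})

#' @rdname hypergraphLaplacian
#' @export
setMethod("hypergraphLaplacian", "Hypergraph", function(x, w = NULL) {
    H <- as.matrix(x@incidence)
    M <- ncol(H)
    if (is.null(w)) w <- rep(1, M)
    if (length(w) != M) stop("weight vector must have length ", M)
    dv <- as.numeric(H %*% w)
    if (any(dv <= 0)) {
        stop("some node degrees are zero under these weights; restrict the ",
             "hypergraph to positive-degree nodes or use identity weights")
    }
    de <- colSums(H)
    Hn <- H / sqrt(dv)                      # Dv^{-1/2} H
    theta <- Hn %*% diag(w / de, nrow = M) %*% t(Hn)
    lap <- diag(nrow(H)) - theta
    dimnames(lap) <- list(x@genes, x@genes)
    (lap + t(lap)) / 2
})

#' Restrict a hypergraph to a subset of genes
#'
#' Keeps the given genes (input order ignored; node order stays
#' lexicographic) and drops hyperedges left empty.
#'
#' @param x a [Hypergraph-class].
#' @param genes character vector of gene symbols to keep.
#' @return A [Hypergraph-class].
#' @export
subsetHypergraph <- function(x, genes) {
    stopifnot(is(x, "Hypergraph"))
    keep <- intersect(x@genes, genes)
    if (!length(keep)) stop("no requested genes are present")
    H <- x@incidence[match(keep, x@genes), , drop = FALSE]
    nz <- which(Matrix::colSums(H) > 0)
    if (!length(nz)) stop("all hyperedges empty after gene restriction")
    H <- H[, nz, drop = FALSE]
    lone <- which(Matrix::rowSums(H) == 0)
    if (length(lone)) {
        H <- H[-lone, , drop = FALSE]
        keep <- keep[-lone]
    }
    new("Hypergraph", genes = keep, setIds = x@setIds[nz], incidence = H,
        collectionTags = x@collectionTags[nz])
}

#' Export a hypergraph as MatrixMarket + index files
#'
#' Writes `incidence.mtx` (sparse MatrixMarket), `genes.tsv` and
#' `sets.tsv` (index, id, degree) into `dir`.
#'
#' @param x a [Hypergraph-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @importFrom Matrix writeMM
#' @importFrom utils write.table
#' @export
exportIncidence <- function(x, dir) {
    stopifnot(is(x, "Hypergraph"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(x@incidence, file.path(dir, "incidence.mtx"))
    deg <- degrees(x)
    utils::write.table(
        data.frame(index = seq_len(nGenes(x)), gene = x@genes,
                   degree = as.numeric(deg$node)),
        file.path(dir, "genes.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(index = seq_len(nHyperedges(x)), set_id = x@setIds,
                   collection = x@collectionTags,
                   degree = as.numeric(deg$edge)),
        file.path(dir, "sets.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
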