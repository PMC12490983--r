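#' Number of genes (nodes) in an object
#' @param x a [Hypergraph-class] or [GeneSetList-class].
#' @return integer.
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' Number of hyperedges (gene sets) in an object
#' @param x a [Hypergraph-class] or [GeneSetList-class].
#' @return integer.
#' @export
setGeneric("nHyperedges", function(x) standardGeneric("nHyperedges"))

#' Gene symbols of an object
#' @param x a [Hypergraph-class].
#' @return character vector.
#' @export
setGeneric("hgGenes", function(x) standardGeneric("hgGenes"))

#' Hyperedge (gene set) identifiers
#' @param x a [Hypergraph-class] or [GeneSetList-class].
#' @return character vector.
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' Sparse incidence matrix of a hypergraph
#' @param x a [Hypergraph-class].
#' @return an N x M sparse binary `Matrix`.
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' Node and hyperedge degrees
#'
#' Node degree is the (optionally weighted) number of hyperedges a gene
#' belongs to, d(v) = sum_e w(e) H(v, e); hyperedge degree is its member
#' count, delta(e) = sum_v H(v, e).
#'
#' @param x a [Hypergraph-class].
#' @param w optional length-M hyperedge weight vector; identity weights
#'   (all 1) when omitted.
#' @return list with numeric components `node` (length N, named by gene)
#'   and `edge` (length M, named by set id).
#' @examples
#' gs <- GeneSetList(setIds = c("a", "b"),
#'                   members = list(c("g1", "g2"), c("g2", "g3")))
#' hg <- buildHypergraph(gs)
#' degrees(hg)$node
#' @export
setGeneric("degrees", function(x, w = NULL) standardGeneric("degrees"))

#' Disease-specific hyperedge weights
#'
#' The weight of a hyperedge is the fraction of its members that are known
#' disease genes: w(e) = |members(e) intersect positives| / delta(e).
#' Weights are 0 for hyperedges with no positive member and 1 when every
#' member is positive.
#'
#' @param x a [Hypergraph-class].
#' @param positives character vector of known disease gene symbols;
#'   symbols absent from the hypergraph are ignored with a warning.
#' @return named numeric vector of length M with values in \[0, 1\].
#' @export
setGeneric("hyperedgeWeights",
    function(x, positives) standardGeneric("hyperedgeWeights"))

#' Normalized hypergraph Laplacian
#'
#' Delta = I - Dv^(-1/2) H W De^(-1) H^T Dv^(-1/2), where node degrees are
#' computed under the same weights W. The matrix is symmetric, positive
#' semidefinite, and annihilates Dv^(1/2) 1.
#'
#' @param x a [Hypergraph-class].
#' @param w length-M hyperedge weight vector; identity when omitted.
#' @return dense symmetric N x N matrix.
#' @export
setGeneric("hypergraphLaplacian",
    function(x, w = NULL) standardGeneric("hypergraphLaplacian"))

#' Per-gene risk scores from a fitted model
#' @param object a [HyperADFit-class].
#' @return named numeric vector (second softmax column, one per gene).
#' @export
setGeneric("riskScores", function(object) standardGeneric("riskScores"))

#' Per-epoch training loss trace
#' @param object a [HyperADFit-class].
#' @return numeric vector of cross-entropy values.
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))

#' Summary statistics of a cross-validation run
#' @param object a [CVResult-class].
#' @return data.frame with one row per metric (mean, sd, n folds).
#' @export
setGeneric("cvSummary", function(object) standardGeneric("cvSummary"))
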