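#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums t Diagonal
NULL

#' GeneSetList: an ordered collection of annotated gene sets
#'
#' Container for gene sets as read from GMT files. Each set has a unique
#' identifier, a free-text description, an ordered vector of unique gene
#' symbols, and an optional collection tag (e.g. `"H"`, `"C2"`) recording
#' which collection it came from.
#'
#' @slot setIds character vector of unique set identifiers.
#' @slot descriptions character vector, same length as `setIds`.
#' @slot members list of character vectors; each vector is non-empty and
#'   free of duplicate gene symbols.
#' @slot collectionTags character vector, same length as `setIds`; `NA`
#'   where no tag was assigned.
#'
#' @seealso [readGMT()], [buildHypergraph()]
#' @export
setClass("GeneSetList",
    representation(
        setIds = "character",
        descriptions = "character",
        members = "list",
        collectionTags = "character"
    )
)

setValidity("GeneSetList", function(object) {
    n <- length(object@setIds)
    if (length(object@descriptions) != n || length(object@members) != n ||
        length(object@collectionTags) != n) {
        return("setIds, descriptions, members and collectionTags must have equal length")
    }
    if (anyDuplicated(object@setIds)) {
        return("duplicate set ids")
    }
    for (i in seq_len(n)) {
        m <- object@members[[i]]
        if (!is.character(m) || length(m) == 0L) {
            return(sprintf("set '%s' has no members", object@setIds[i]))
        }
        if (anyDuplicated(m)) {
            return(sprintf("set '%s' has duplicate members", object@setIds[i]))
        }
    }
    TRUE
})

#' Hypergraph of genes (nodes) and gene sets (hyperedges)
#'
#' Sparse binary incidence structure: `incidence[a, b] == 1` iff gene `a`
#' belongs to gene set `b`. Genes are ordered lexicographically and sets
#' keep their input order, so every downstream matrix is deterministic.
#' Construction guarantees every gene appears in at least one hyperedge
#' and every hyperedge is non-empty.
#'
#' @slot genes ordered character vector of N unique gene symbols.
#' @slot setIds ordered character vector of M unique hyperedge ids.
#' @slot incidence N x M sparse binary matrix (`Matrix::dgCMatrix`).
#' @slot collectionTags per-hyperedge collection tag (`NA` allowed).
#'
#' @seealso [buildHypergraph()], [degrees()], [hyperedgeWeights()],
#'   [hypergraphLaplacian()]
#' @export
setClass("Hypergraph",
    representation(
        genes = "character",
        setIds = "character",
        incidence = "Matrix",
        collectionTags = "character"
    )
)

setValidity("Hypergraph", function(object) {
    H <- object@incidence
    if (nrow(H) != length(object@genes) || ncol(H) != length(object@setIds)) {
        return("incidence dimensions do not match gene/set counts")
    }
    if (anyDuplicated(object@genes)) return("duplicate gene symbols")
    if (anyDuplicated(object@setIds)) return("duplicate set ids")
    if (length(object@collectionTags) != length(object@setIds)) {
        return("collectionTags length must equal number of hyperedges")
    }
    x <- H@x
    if (length(x) && !all(x %in% c(0, 1))) return("incidence entries must be 0/1")
    if (nrow(H) > 0 && any(Matrix::rowSums(H) == 0)) {
        return("every gene must appear in at least one hyperedge")
    }
    if (ncol(H) > 0 && any(Matrix::colSums(H) == 0)) {
        return("every hyperedge must contain at least one gene")
    }
    TRUE
})

#' Positive/negative label partition over hypergraph genes
#'
#' Holds the known risk genes (positives) and the sampled non-risk genes
#' (negatives) used for transductive training; all remaining genes are
#' unlabeled. The two sets must be disjoint.
#'
#' @slot positives character vector of known risk gene symbols.
#' @slot negatives character vector of non-risk gene symbols.
#'
#' @export
setClass("LabelSet",
    representation(positives = "character", negatives = "character")
)

setValidity("LabelSet", function(object) {
    if (length(intersect(object@positives, object@negatives))) {
        return("positives and negatives must be disjoint")
    }
    if (anyDuplicated(object@positives)) return("duplicate positives")
    if (anyDuplicated(object@negatives)) return("duplicate negatives")
    TRUE
})

#' Construct a LabelSet
#'
#' @param positives character vector of positive (risk) gene symbols.
#' @param negatives character vector of negative gene symbols.
#' @return A [LabelSet-class] object.
#' @examples
#' LabelSet(c("APP", "PSEN1"), c("ACTB", "GAPDH"))
#' @export
LabelSet <- function(positives, negatives) {
    new("LabelSet",
        positives = unique(as.character(positives)),
        negatives = unique(as.character(negatives)))
}

#' Model hyperparameter configuration
#'
#' All architecture and optimization settings for the two-stage
#' message-passing network. `weightMode` selects between disease-specific
#' hyperedge weights (fraction of members that are training positives) and
#' the unweighted variant used for ablation. `degreeNormMode` controls the
#' node degree d(v) used to normalize node-to-hyperedge messages:
#' `"unweighted"` counts incident hyperedges (numerically safe default),
#' `"weighted"` uses the hyperedge-weighted degree.
#'
#' @slot embedDim embedding dimension d.
#' @slot nBlocks number of stacked message-passing blocks.
#' @slot learningRate Adam learning rate.
#' @slot epochs number of full-batch training epochs.
#' @slot seed integer seed controlling parameter initialization.
#' @slot weightMode `"ad_weighted"` or `"unweighted"`.
#' @slot degreeNormMode `"unweighted"` or `"weighted"`.
#' @slot activation only `"relu"` is supported.
#'
#' @export
setClass("HyperADConfig",
    representation(
        embedDim = "integer",
        nBlocks = "integer",
        learningRate = "numeric",
        epochs = "integer",
        seed = "integer",
        weightMode = "character",
        degreeNormMode = "character",
        activation = "character"
    )
)

setValidity("HyperADConfig", function(object) {
    if (object@embedDim < 1L) return("embedDim must be >= 1")
    if (object@nBlocks < 1L) return("nBlocks must be >= 1")
    if (object@learningRate <= 0) return("learningRate must be positive")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (!object@weightMode %in% c("ad_weighted", "unweighted")) {
        return("weightMode must be 'ad_weighted' or 'unweighted'")
    }
    if (!object@degreeNormMode %in% c("unweighted", "weighted")) {
        return("degreeNormMode must be 'unweighted' or 'weighted'")
    }
    if (!identical(object@activation, "relu")) {
        return("only activation = 'relu' is supported")
    }
    TRUE
})

#' Construct a model configuration
#'
#' @param embedDim embedding dimension (default 128).
#' @param nBlocks number of two-stage message-passing blocks (default 2).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 200).
#' @param seed integer seed for parameter initialization (mandatory).
#' @param weightMode `"ad_weighted"` (default) uses disease-specific
#'   hyperedge weights computed from training positives; `"unweighted"`
#'   sets all hyperedge weights to 1.
#' @param degreeNormMode node-degree normalization mode (default
#'   `"unweighted"`).
#' @param activation activation function; only `"relu"`.
#' @return A [HyperADConfig-class] object.
#' @examples
#' hyperADConfig(seed = 1, embedDim = 32, epochs = 50)
#' @export
hyperADConfig <- function(embedDim = 128L, nBlocks = 2L, learningRate = 1e-3,
                          epochs = 200L, seed,
                          weightMode = c("ad_weighted", "unweighted"),
                          degreeNormMode = c("unweighted", "weighted"),
                          activation = "relu") {
    if (missing(seed)) stop("a seed is mandatory in the model configuration")
    new("HyperADConfig",
        embedDim = as.integer(embedDim), nBlocks = as.integer(nBlocks),
        learningRate = as.numeric(learningRate), epochs = as.integer(epochs),
        seed = as.integer(seed), weightMode = match.arg(weightMode),
        degreeNormMode = match.arg(degreeNormMode),
        activation = activation)
}

#' Fitted HyperAD model
#'
#' Returned by [trainHyperAD()]. Holds the learned parameters, the
#' hyperedge weights used during training, the per-epoch loss trace and
#' the final N x 2 softmax score matrix (second column = risk score).
#'
#' @slot config the [HyperADConfig-class] used.
#' @slot params named list of learned parameter matrices.
#' @slot edgeWeights length-M hyperedge weight vector used in training.
#' @slot lossTrace per-epoch cross-entropy on the training labels.
#' @slot scores N x 2 matrix of class probabilities, rownames = genes.
#' @slot trainLabels the [LabelSet-class] the model was trained on.
#'
#' @export
setClass("HyperADFit",
    representation(
        config = "HyperADConfig",
        params = "list",
        edgeWeights = "numeric",
        lossTrace = "numeric",
        scores = "matrix",
        trainLabels = "LabelSet"
    )
)

#' Cross-validation result
#'
#' Per-fold AUROC and AUPRC matrices (repetitions x folds) from repeated
#' stratified cross-validation, with the configuration used.
#'
#' @slot auroc nRepetitions x nFolds matrix.
#' @slot auprc nRepetitions x nFolds matrix.
#' @slot nRepetitions,nFolds integers.
#' @slot seed integer seed of the run.
#'
#' @seealso [crossValidate()], [cvSummary()]
#' @export
setClass("CVResult",
    representation(
        auroc = "matrix",
        auprc = "matrix",
        nRepetitions = "integer",
        nFolds = "integer",
        seed = "integer"
    )
)

setValidity("CVResult", function(object) {
    ok <- function(m) all(is.na(m) | (m >= 0 & m <= 1))
    if (!ok(object@auroc) || !ok(object@auprc)) {
        return("metrics must lie in [0, 1]")
    }
    TRUE
})
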