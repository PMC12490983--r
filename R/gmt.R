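#' Construct a GeneSetList
#'
#' @param setIds character vector of unique set identifiers.
#' @param members list of character vectors of gene symbols; duplicates
#'   within a set are removed preserving first occurrence.
#' @param descriptions optional character vector (defaults to `""`).
#' @param collectionTags optional character vector of collection labels.
#' @return A [GeneSetList-class].
#' @examples
#' GeneSetList(c("S1", "S2"), list(c("A", "B"), c("B", "C")))
#' @export
GeneSetList <- function(setIds, members, descriptions = NULL,
                        collectionTags = NULL) {
    setIds <- as.character(setIds)
    if (is.null(descriptions)) descriptions <- rep("", length(setIds))
    if (is.null(collectionTags)) {
        collectionTags <- rep(NA_character_, length(setIds))
    }
    members <- lapply(members, function(m) unique(as.character(m)))
    new("GeneSetList",
        setIds = setIds, descriptions = as.character(descriptions),
        members = members, collectionTags = as.character(collectionTags))
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated gene-set exchange format: each line holds a
#' set name, a description, then one or more member gene symbols. Gene
#' symbols are taken verbatim (case preserved); duplicate symbols within a
#' line are removed keeping first occurrence.
#'
#' @param path path to a GMT file.
#' @param collectionTag optional collection label (e.g. `"C2"`) attached
#'   to every set read from this file.
#' @return A [GeneSetList-class], one set per line.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("SETA\turl\tG1\tG2\tG3", f)
#' readGMT(f)
#' @export
readGMT <- function(path, collectionTag = NA_character_) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("GMT file is empty: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L)) {
        bad <- which(nf < 3L)[1L]
        stop(sprintf(
            "malformed GMT line %d in '%s': expected >= 3 tab-separated fields, got %d",
            bad, path, nf[bad]))
    }
    ids <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(ids)) {
        stop("duplicate set id in '", path, "': ",
             ids[duplicated(ids)][1L])
    }
    GeneSetList(
        setIds = ids,
        descriptions = vapply(fields, `[[`, character(1), 2L),
        members = lapply(fields, function(f) f[-(1:2)]),
        collectionTags = rep(as.character(collectionTag), length(ids)))
}

#' Write gene sets to a GMT file
#'
#' @param x a [GeneSetList-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(x, path) {
    stopifnot(is(x, "GeneSetList"))
    lines <- vapply(seq_along(x@setIds), function(i) {
        paste(c(x@setIds[i], x@descriptions[i], x@members[[i]]),
              collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Concatenate gene-set collections
#'
#' @param ... [GeneSetList-class] objects.
#' @return a single [GeneSetList-class]; set ids must stay unique.
#' @export
concatGeneSetLists <- function(...) {
    xs <- list(...)
    GeneSetList(
        setIds = unlist(lapply(xs, function(x) x@setIds)),
        members = do.call(c, lapply(xs, function(x) x@members)),
        descriptions = unlist(lapply(xs, function(x) x@descriptions)),
        collectionTags = unlist(lapply(xs, function(x) x@collectionTags)))
}

#' Restrict a GeneSetList to given collections
#'
#' Used for per-collection ablation runs: gene sets whose collection tag
#' is not in `tags` are dropped.
#'
#' @param x a [GeneSetList-class].
#' @param tags character vector of collection tags to retain.
#' @return a [GeneSetList-class].
#' @export
filterCollections <- function(x, tags) {
    stopifnot(is(x, "GeneSetList"))
    keep <- which(x@collectionTags %in% tags)
    if (!length(keep)) stop("no gene sets carry collection tag(s): ",
                            paste(tags, collapse = ", "))
    GeneSetList(x@setIds[keep], x@members[keep],
                x@descriptions[keep], x@collectionTags[keep])
}

#' Read a one-symbol-per-line gene list
#' @param path text file with one gene symbol per line.
#' @return character vector (empty lines dropped).
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("gene list file not found: ", path)
    x <- trimws(readLines(path, warn = FALSE))
    x[nzchar(x)]
}

#' Write a one-symbol-per-line gene list
#' @param genes character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneList <- function(genes, path) {
    writeLines(as.character(genes), path)
    invisible(path)
}

#' @describeIn GeneSetList-class number of gene sets
#' @param x a GeneSetList
#' @export
setMethod("nHyperedges", "GeneSetList", function(x) length(x@setIds))

#' @describeIn GeneSetList-class set identifiers
#' @export
setMethod("setIds", "GeneSetList", function(x) x@setIds)

#' Gene-set members
#' @param x a [GeneSetList-class].
#' @return named list of character vectors.
#' @export
geneSetMembers <- function(x) {
    stopifnot(is(x, "GeneSetList"))
    stats::setNames(x@members, x@setIds)
}

setMethod("show", "GeneSetList", function(object) {
    cat(sprintf("GeneSetList with %d gene set(s); %d distinct gene(s)\n",
                length(object@setIds),
                length(unique(unlist(object@members)))))
    tags <- unique(object@collectionTags)
    tags <- tags[!is.na(tags)]
    if (length(tags)) cat("collections:", paste(tags, collapse = ", "), "\n")
})
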