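#' Genes of an object
#' @param x an object with a gene universe.
#' @return Character vector of gene identifiers.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Number of genes in a network
#' @param x an [InteractionNetwork-class].
#' @return Integer.
#' @export
setGeneric("numGenes", function(x) standardGeneric("numGenes"))

#' Per-gene interaction count
#' @param x an [InteractionNetwork-class].
#' @return Named integer vector of degrees.
#' @export
setGeneric("geneDegree", function(x) standardGeneric("geneDegree"))

#' Binary adjacency matrix
#' @param x an [InteractionNetwork-class].
#' @return Sparse symmetric binary `dgCMatrix`.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Network interactors of a gene
#' @param x an [InteractionNetwork-class].
#' @param gene a single gene identifier.
#' @return Character vector of direct neighbours (empty if the gene is not in
#'   the network).
#' @export
setGeneric("interactorsOf", function(x, gene) standardGeneric("interactorsOf"))

#' Member lists of a gene set collection
#' @param x a [GeneSetCollection-class].
#' @return Named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Provenance tags of a gene set collection
#' @param x a [GeneSetCollection-class].
#' @return Named character vector, one tag per set.
#' @export
setGeneric("setProvenance", function(x) standardGeneric("setProvenance"))

#' Weight sources
#' @param x a [WeightSet-class].
#' @return Character vector of source names.
#' @export
setGeneric("sources", function(x) standardGeneric("sources"))

#' Weight vector of one source
#' @param x a [WeightSet-class].
#' @param source source name; defaults to the first source.
#' @return Named numeric vector over the weight universe.
#' @export
setGeneric("geneWeights", function(x, source) standardGeneric("geneWeights"))

#' @describeIn InteractionNetwork-class gene identifiers (node order).
#' @param x object.
#' @export
setMethod("genes", "InteractionNetwork", function(x) rownames(x@adjacency))

#' @describeIn InteractionNetwork-class number of genes.
#' @export
setMethod("numGenes", "InteractionNetwork", function(x) nrow(x@adjacency))

#' @describeIn InteractionNetwork-class per-gene degree.
#' @export
setMethod("geneDegree", "InteractionNetwork", function(x) {
    d <- Matrix::colSums(x@adjacency)
    storage.mode(d) <- "integer"
    d
})

#' @describeIn InteractionNetwork-class the adjacency matrix.
#' @export
setMethod("adjacencyMatrix", "InteractionNetwork", function(x) x@adjacency)

#' @describeIn InteractionNetwork-class direct neighbours of `gene`.
#' @param gene single gene identifier.
#' @export
setMethod("interactorsOf", "InteractionNetwork", function(x, gene) {
    stopifnot(length(gene) == 1L)
    g <- genes(x)
    j <- match(gene, g)
    if (is.na(j)) return(character())
    A <- x@adjacency
    g[A@i[seq.int(A@p[j] + 1L, length.out = A@p[j + 1L] - A@p[j])] + 1L]
})

setMethod("show", "InteractionNetwork", function(object) {
    d <- geneDegree(object)
    cat("InteractionNetwork with", numGenes(object), "genes and",
        sum(d) %/% 2L, "interactions\n")
    if (length(d))
        cat("  degree: min", min(d), "/ median", stats::median(d),
            "/ max", max(d), "\n")
})

#' @describeIn GeneSetCollection-class member lists.
#' @param x object.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection-class provenance tags.
#' @export
setMethod("setProvenance", "GeneSetCollection", function(x) x@provenance)

#' @describeIn GeneSetCollection-class number of sets.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class set names.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @describeIn GeneSetCollection-class extract one set's members.
#' @param i set name or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' @describeIn GeneSetCollection-class union of all member genes.
#' @export
setMethod("genes", "GeneSetCollection",
          function(x) sort(unique(unlist(x@sets, use.names = FALSE))))

setMethod("show", "GeneSetCollection", function(object) {
    sz <- vapply(object@sets, length, integer(1L))
    cat("GeneSetCollection with", length(object@sets), "sets\n")
    if (length(sz))
        cat("  sizes: min", min(sz), "/ median", stats::median(sz),
            "/ max", max(sz), "\n")
})

#' @describeIn WeightSet-class source names.
#' @param x object.
#' @export
setMethod("sources", "WeightSet", function(x) colnames(x@weights))

#' @describeIn WeightSet-class gene universe of the weights.
#' @export
setMethod("genes", "WeightSet", function(x) rownames(x@weights))

#' @describeIn WeightSet-class weight vector of one source.
#' @param source source name.
#' @export
setMethod("geneWeights", "WeightSet", function(x, source) {
    if (missing(source)) source <- colnames(x@weights)[1L]
    if (!source %in% colnames(x@weights))
        stop("unknown weight source: ", source)
    x@weights[, source]
})

setMethod("show", "WeightSet", function(object) {
    cat("WeightSet:", nrow(object@weights), "genes x",
        ncol(object@weights), "source(s)\n")
    for (s in colnames(object@weights)) {
        w <- object@weights[, s]
        cat(sprintf("  %s: %d positive weights (max %.3g)\n",
                    s, sum(w > 0), max(w)))
    }
})

setMethod("show", "DegreeBinning", function(object) {
    cat("DegreeBinning:", length(object@genes), "genes in",
        object@nBins, "bins (sizes",
        paste(tabulate(object@bins, object@nBins), collapse = ", "), ")\n")
})
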