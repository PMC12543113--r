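#' @import methods
#' @importFrom Matrix sparseMatrix colSums rowSums
#' @importClassesFrom Matrix dgCMatrix
NULL

#' Gene-centric molecular interaction network
#'
#' An undirected, unweighted ("gene-centric") interaction network stored as a
#' symmetric binary sparse adjacency matrix with a zero diagonal. Node order
#' is deterministic (sorted gene identifiers) and every retained gene has at
#' least one interaction. Edge confidence scores, if any, are used upstream
#' for filtering only (see [filterInteractionsByScore()]); the crosstalk
#' score is defined on the binary adjacency.
#'
#' @slot adjacency symmetric binary `dgCMatrix` with gene identifiers as
#'   dimnames and zero diagonal.
#'
#' @seealso [buildNetwork()], [genes()], [geneDegree()], [adjacencyMatrix()]
#' @export
setClass("InteractionNetwork", slots = c(adjacency = "dgCMatrix"))

setValidity("InteractionNetwork", function(object) {
    A <- object@adjacency
    msg <- character()
    dn <- dimnames(A)
    if (is.null(dn[[1L]]) || is.null(dn[[2L]]) || !identical(dn[[1L]], dn[[2L]]))
        msg <- c(msg, "adjacency must carry identical row/column gene names")
    if (anyDuplicated(dn[[1L]]))
        msg <- c(msg, "gene identifiers must be unique")
    if (length(A@x) && !all(A@x == 1))
        msg <- c(msg, "adjacency must be binary (all stored values 1)")
    if (any(Matrix::diag(A) != 0))
        msg <- c(msg, "adjacency diagonal must be zero (no self-interactions)")
    if (!Matrix::isSymmetric(A))
        msg <- c(msg, "adjacency must be symmetric")
    if (nrow(A) && any(Matrix::colSums(A) < 1))
        msg <- c(msg, "every retained gene must have degree >= 1")
    if (length(msg)) msg else TRUE
})

#' Collection of named gene sets
#'
#' Named gene sets (pathways, protein complexes, cell-type marker sets) with a
#' per-set provenance tag (e.g. the resource or the cell type the set belongs
#' to). In inter-cellular analyses the provenance tag names the weight source
#' (cell type) the set is paired with.
#'
#' @slot sets named list of character vectors (unique member gene IDs).
#' @slot provenance character vector parallel to `sets`.
#'
#' @seealso [readGeneSets()], [geneSets()], [setProvenance()]
#' @export
setClass("GeneSetCollection",
         slots = c(sets = "list", provenance = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (length(object@sets)) {
        if (is.null(nm) || any(!nzchar(nm)))
            msg <- c(msg, "every gene set must be named")
        if (anyDuplicated(nm))
            msg <- c(msg, "gene set names must be unique")
        if (!all(vapply(object@sets, is.character, logical(1L))))
            msg <- c(msg, "gene sets must be character vectors")
        if (any(vapply(object@sets, length, integer(1L)) == 0L))
            msg <- c(msg, "gene sets must be non-empty")
        if (any(vapply(object@sets, anyDuplicated, integer(1L)) > 0L))
            msg <- c(msg, "gene sets must not contain duplicated members")
    }
    if (length(object@provenance) != length(object@sets))
        msg <- c(msg, "provenance must have one tag per set")
    if (length(msg)) msg else TRUE
})

#' Named gene-weight vectors in the unit interval
#'
#' One weight vector per source (condition or cell type), all defined over the
#' same gene universe. Entries lie in [0, 1]; a zero means the gene carries no
#' alteration signal in that source. Each source has at least one strictly
#' positive weight (sources without any significant gene are rejected
#' upstream, see [normalizeWeights()]).
#'
#' @slot weights numeric matrix, genes x sources, with dimnames.
#'
#' @seealso [weightsFromDE()], [geneWeights()], [sources()]
#' @export
setClass("WeightSet", slots = c(weights = "matrix"))

setValidity("WeightSet", function(object) {
    W <- object@weights
    msg <- character()
    if (is.null(rownames(W)) || is.null(colnames(W)))
        msg <- c(msg, "weights must carry gene rownames and source colnames")
    if (anyDuplicated(rownames(W)) || anyDuplicated(colnames(W)))
        msg <- c(msg, "gene and source names must be unique")
    if (!is.numeric(W) || anyNA(W) || any(W < 0) || any(W > 1))
        msg <- c(msg, "all weights must lie in [0, 1]")
    if (ncol(W) && any(apply(W, 2L, max) <= 0))
        msg <- c(msg, "each source needs at least one positive weight")
    if (length(msg)) msg else TRUE
})

#' Degree binning of a network's genes
#'
#' Contiguous, equally sized (+/- 1) groups of the degree-sorted gene list,
#' within which gene labels may be exchanged by the permutation null models
#' so that the association between gene weight and gene degree is
#' approximately preserved.
#'
#' @slot genes gene identifiers in network order.
#' @slot bins integer bin label per gene (1..nBins).
#' @slot nBins number of bins.
#'
#' @seealso [makeDegreeBins()], [permuteWithinBins()]
#' @export
setClass("DegreeBinning",
         slots = c(genes = "character", bins = "integer", nBins = "integer"))

setValidity("DegreeBinning", function(object) {
    msg <- character()
    if (length(object@bins) != length(object@genes))
        msg <- c(msg, "one bin label per gene required")
    if (length(object@nBins) != 1L || object@nBins < 1L)
        msg <- c(msg, "nBins must be a single positive integer")
    tab <- tabulate(object@bins, nbins = object@nBins)
    if (any(tab == 0L))
        msg <- c(msg, "every bin must be non-empty")
    if (length(object@bins) &&
        (min(object@bins) < 1L || max(object@bins) > object@nBins))
        msg <- c(msg, "bin labels out of range")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene IDs. Duplicate members
#'   within a set are collapsed.
#' @param provenance optional character vector (recycled) tagging each set
#'   with its origin (resource name, cell type, ...).
#' @return A [GeneSetCollection-class] object.
#' @examples
#' gsc <- GeneSetCollection(list(P53 = c("TP53", "CDKN2A"), S = c("A", "B")))
#' length(gsc)
#' @export
GeneSetCollection <- function(sets, provenance = NULL) {
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (is.null(provenance)) provenance <- rep("", length(sets))
    provenance <- rep_len(as.character(provenance), length(sets))
    names(provenance) <- names(sets)
    new("GeneSetCollection", sets = sets, provenance = provenance)
}

#' Construct a WeightSet
#'
#' @param weights numeric matrix (genes x sources) with dimnames, or a named
#'   list of named numeric vectors (one per source; gene universes are
#'   unioned, absent genes get weight 0).
#' @return A [WeightSet-class] object.
#' @examples
#' ws <- WeightSet(list(tumour = c(TP53 = 1, MYC = 0.4)))
#' sources(ws)
#' @export
WeightSet <- function(weights) {
    if (is.list(weights)) {
        genes <- sort(unique(unlist(lapply(weights, names))))
        W <- vapply(weights, function(w) {
            v <- w[genes]
            v[is.na(v)] <- 0
            as.numeric(v)
        }, numeric(length(genes)))
        W <- matrix(W, nrow = length(genes),
                    dimnames = list(genes, names(weights)))
        weights <- W
    }
    new("WeightSet", weights = weights)
}
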