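#' Split a network's genes into degree bins
#'
#' Sorts the genes by degree (ties broken by gene ID) and splits the sorted
#' sequence into `k` contiguous, equally sized (+/- 1) bins, within which
#' gene labels may be exchanged by the permutation nulls. When `requested` is
#' not given, `k` is the highest value not exceeding `maxBins` that
#' guarantees non-empty bins; with equal-count bins over the sorted degree
#' sequence this is `min(maxBins, numGenes(net))`.
#'
#' @param net an [InteractionNetwork-class].
#' @param maxBins upper bound on the number of bins (default 15).
#' @param requested explicit number of bins (overrides the automatic rule).
#' @return A [DegreeBinning-class].
#' @examples
#' net <- buildNetwork(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C")))
#' makeDegreeBins(net)
#' @export
makeDegreeBins <- function(net, maxBins = 15L, requested = NULL) {
    g <- genes(net)
    n <- length(g)
    if (!n) stop("network is empty")
    if (!is.null(requested)) {
        requested <- as.integer(requested)
        if (requested < 1L || requested > n)
            stop("requested bin count must lie in [1, ", n, "]")
        k <- requested
    } else {
        k <- min(as.integer(maxBins), n)
    }
    ord <- order(geneDegree(net), g)
    sizes <- rep(n %/% k, k)
    r <- n %% k
    if (r) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
    bins <- integer(n)
    bins[ord] <- rep.int(seq_len(k), sizes)
    new("DegreeBinning", genes = g, bins = bins, nBins = k)
}

#' Draw one within-bin gene-label permutation
#'
#' Returns a bijection on gene indices whose restriction to every degree bin
#' is a permutation of that bin; singleton bins are fixed points. Drawing
#' uses (and advances) R's RNG stream, so results are reproducible under
#' `set.seed()` or an explicit `seed`.
#'
#' @param binning a [DegreeBinning-class].
#' @param seed optional integer seed applied before drawing.
#' @return Integer vector `perm` with `perm[i]` the image of gene `i`.
#' @export
permuteWithinBins <- function(binning, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    perm <- seq_along(binning@bins)
    for (idx in split(perm, binning@bins)) {
        if (length(idx) > 1L)
            perm[idx] <- idx[sample.int(length(idx))]
    }
    perm
}

#' Draw a matrix of within-bin permutations
#'
#' The shared permutation stream used by the null models: one column per
#' permutation, reused across every tested pair of a run (which is
#' statistically valid -- each pair's null distribution is marginally
#' correct -- and considerably faster than per-pair streams).
#'
#' @param binning a [DegreeBinning-class].
#' @param nPerm number of permutations.
#' @param seed optional integer seed.
#' @return Integer matrix (genes x `nPerm`); each column a within-bin
#'   bijection.
#' @export
makePermutations <- function(binning, nPerm, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(binning@bins)
    P <- matrix(rep(seq_len(n), nPerm), nrow = n, ncol = nPerm)
    for (idx in split(seq_len(n), binning@bins)) {
        m <- length(idx)
        if (m > 1L)
            P[idx, ] <- vapply(seq_len(nPerm),
                               function(k) idx[sample.int(m)], integer(m))
    }
    P
}

# Null score samples for one pair under the interaction-randomising model:
# gene labels of the network are permuted within degree bins while set
# memberships and weights stay put, i.e. c_k = sum a[p(i), p(j)] wx(i) wy(j).
.nullSamplesMA <- function(A, ix, wx, iy, wy, perms) {
    nPerm <- ncol(perms)
    n <- nrow(A)
    VX <- Matrix::sparseMatrix(i = as.vector(perms[ix, , drop = FALSE]),
                               j = rep(seq_len(nPerm), each = length(ix)),
                               x = rep(wx, nPerm), dims = c(n, nPerm))
    VY <- Matrix::sparseMatrix(i = as.vector(perms[iy, , drop = FALSE]),
                               j = rep(seq_len(nPerm), each = length(iy)),
                               x = rep(wy, nPerm), dims = c(n, nPerm))
    as.numeric(Matrix::colSums(VX * (A %*% VY)))
}

# Weight-randomising model: the full weight vectors are relocated within
# degree bins while the network and memberships stay put, i.e.
# c_k = sum a[i, j] wfx(p(i)) wfy(p(j)). A gene of X can thus inherit the
# weight of any like-degree gene of the network, inside or outside X.
.nullSamplesMU <- function(A, ix, iy, wfx, wfy, perms) {
    WX <- matrix(wfx[perms[ix, , drop = FALSE]], nrow = length(ix))
    WY <- matrix(wfy[perms[iy, , drop = FALSE]], nrow = length(iy))
    S <- A[ix, iy, drop = FALSE]
    as.numeric(Matrix::colSums(WX * as.matrix(S %*% WY)))
}

#' Null crosstalk score samples for one gene-set pair
#'
#' Generates permutation null samples of the crosstalk score under one of
#' the two degree-binned label-permutation models: `"MA"` relabels the
#' network's genes (probing the dependence of the score on the network
#' proximity of the two sets) and `"MU"` relabels the gene weights (probing
#' the dependence on the weights). Both models preserve gene set size, the
#' degree sequence and, within each degree bin, the association between gene
#' weight and gene degree.
#'
#' @param net an [InteractionNetwork-class].
#' @param x,y gene ID vectors (the pair as scored, i.e. after
#'   [preparePair()]).
#' @param weights a [WeightSet-class].
#' @param sourceX,sourceY weight sources for the two sides (same source in
#'   the intra / integrated scenarios).
#' @param model `"MA"` or `"MU"`.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param binning optional [DegreeBinning-class]; built with the automatic
#'   rule when omitted.
#' @return Numeric vector of `nPerm` null scores (all `>= 0`).
#' @export
nullScores <- function(net, x, y, weights, sourceX,
                       sourceY = sourceX, model = c("MA", "MU"),
                       nPerm = 999L, seed = 1L, binning = NULL) {
    model <- match.arg(model)
    if (is.null(binning)) binning <- makeDegreeBins(net)
    g <- genes(net)
    x <- intersect(unique(x), g)
    y <- intersect(unique(y), g)
    if (!length(x) || !length(y)) return(rep(0, nPerm))
    perms <- makePermutations(binning, nPerm, seed = seed)
    wfx <- .fullWeightVector(weights, sourceX, g)
    wfy <- .fullWeightVector(weights, sourceY, g)
    ix <- match(x, g)
    iy <- match(y, g)
    A <- adjacencyMatrix(net)
    if (model == "MA")
        .nullSamplesMA(A, ix, wfx[ix], iy, wfy[iy], perms)
    else
        .nullSamplesMU(A, ix, iy, wfx, wfy, perms)
}

.fullWeightVector <- function(weights, source, genes) {
    w <- geneWeights(weights, source)
    v <- w[genes]
    v[is.na(v)] <- 0
    stats::setNames(as.numeric(v), genes)
}

#' Empirical tail probability of an observed crosstalk score
#'
#' The add-one permutation probability
#' \eqn{\rho = (1 + \#\{c_{null} \ge c_{obs}\}) / (1 + n_{perm})} of
#' observing a null score equal to or greater than the observed one. Ties
#' count towards the tail, and the add-one convention keeps \eqn{\rho > 0}
#' so the logarithm in the Fisher combination stays finite; with 999
#' permutations the attainable floor is exactly 0.001.
#'
#' @param cObs observed crosstalk score.
#' @param samples numeric vector of null scores.
#' @return Empirical probability in (0, 1].
#' @export
empiricalProb <- function(cObs, samples) {
    if (!length(samples)) stop("no null samples")
    tol <- 1e-9 * max(1, abs(cObs))
    (1 + sum(samples >= cObs - tol)) / (1 + length(samples))
}

#' Fisher product combination of the two null probabilities
#'
#' The tail probability of the product of two independent uniform variates:
#' \eqn{p = P(\hat\rho \le \rho_A \rho_u) = z - z \ln z} with
#' \eqn{z = \rho_A \rho_u}, identical to Fisher's combined probability test
#' on two p-values. Strictly increasing in `z`, with `p = 1` at `z = 1` and
#' `p >= z` always.
#'
#' @param rhoA,rhoU empirical probabilities in (0, 1] (vectorised).
#' @return Combined probability in (0, 1].
#' @examples
#' fisherCombine(0.001, 0.001)
#' @export
fisherCombine <- function(rhoA, rhoU) {
    if (any(rhoA <= 0 | rhoA > 1) || any(rhoU <= 0 | rhoU > 1))
        stop("empirical probabilities must lie in (0, 1]")
    z <- rhoA * rhoU
    z - z * log(z)
}

#' Summary score of a crosstalk
#'
#' Combines effect size and significance for ranking:
#' \eqn{s = -c \log_{10}(p)}. It is 0 exactly when `c = 0` or `p = 1`.
#'
#' @param c crosstalk score (`>= 0`).
#' @param p combined probability in (0, 1] (vectorised).
#' @return Summary score `>= 0`.
#' @export
summaryScore <- function(c, p) {
    if (any(c < 0)) stop("crosstalk scores must be non-negative")
    if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
    -c * log10(p)
}

#' Classify a crosstalk by which null models support it
#'
#' Thresholds each empirical probability at `alpha` and reports the joint
#' outcome: supported by both nulls, by the interaction null only
#' (`MA_only`), by the weight null only (`MU_only`), or by neither.
#'
#' @param rhoA,rhoU empirical probabilities (vectorised).
#' @param alpha significance level in (0, 1), default 0.01.
#' @return Character vector in `{"both", "MA_only", "MU_only", "neither"}`.
#' @export
classifyOutcome <- function(rhoA, rhoU, alpha = 0.01) {
    if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
        stop("alpha must lie in (0, 1)")
    sa <- rhoA <= alpha
    su <- rhoU <= alpha
    ifelse(sa & su, "both",
           ifelse(sa, "MA_only", ifelse(su, "MU_only", "neither")))
}

#' Hypergeometric enrichment of a gene set in a hit list
#'
#' Convenience over-representation test used to contrast crosstalk analysis
#' with classical enrichment: the upper-tail hypergeometric probability of
#' observing at least the realised overlap between `set` and `hits` in a
#' universe of `universeSize` genes.
#'
#' @param set character vector (the gene set).
#' @param hits character vector (e.g. the DEGs).
#' @param universeSize number of genes in the universe.
#' @return Upper-tail probability in (0, 1]; 1 for zero overlap.
#' @export
enrichmentOverlap <- function(set, hits, universeSize) {
    set <- unique(set)
    hits <- unique(hits)
    if (length(set) > universeSize || length(hits) > universeSize)
        stop("set larger than universe")
    k <- length(intersect(set, hits))
    stats::phyper(k - 1, length(hits), universeSize - length(hits),
                  length(set), lower.tail = FALSE)
}

#' Complete screened crosstalk records with the permutation assessment
#'
#' For every screened pair, draws the two null ensembles (shared permutation
#' streams, one per model, both over the same degree binning so the two
#' nulls are strictly complementary), computes the empirical probabilities
#' `rho_a` and `rho_u`, the Fisher-combined `p`, the summary score `s`, a
#' Benjamini-Hochberg adjusted `p_bh` convenience column, and the outcome
#' class; the result is sorted by `s` descending.
#'
#' @param screen a `CrosstalkScreen` from [screenPairs()].
#' @param net the [InteractionNetwork-class] used for screening.
#' @param weights the [WeightSet-class] used for screening.
#' @param nPerm number of label permutations per null model (default 999).
#' @param seed integer seed; the two models draw from independent substreams
#'   derived from it.
#' @param nBins number of degree bins (automatic rule when `NULL`).
#' @param alpha significance level for the outcome classification.
#' @return Data.frame of completed crosstalk records (see
#'   [writeCrosstalkTable()] for the column schema).
#' @export
assessCrosstalks <- function(screen, net, weights, nPerm = 999L, seed = 1L,
                             nBins = NULL, alpha = 0.01) {
    stopifnot(inherits(screen, "CrosstalkScreen"))
    rec <- screen$records
    if (is.null(rec) || !nrow(rec)) stop("no screened pairs to assess")
    binning <- makeDegreeBins(net, requested = nBins)
    set.seed(seed)
    seeds <- sample.int(2147483646L, 2L)
    permsA <- makePermutations(binning, nPerm, seed = seeds[1L])
    permsU <- makePermutations(binning, nPerm, seed = seeds[2L])
    g <- genes(net)
    A <- adjacencyMatrix(net)
    srcs <- screen$sources
    fullW <- lapply(stats::setNames(nm = unique(srcs)),
                    function(s) .fullWeightVector(weights, s, g))
    rhoA <- rhoU <- numeric(nrow(rec))
    for (k in seq_len(nrow(rec))) {
        pg <- screen$pairGenes[[k]]
        ix <- match(pg$x, g)
        iy <- match(pg$y, g)
        wfx <- fullW[[srcs[[rec$set_x[k]]]]]
        wfy <- fullW[[srcs[[rec$set_y[k]]]]]
        sampA <- .nullSamplesMA(A, ix, wfx[ix], iy, wfy[iy], permsA)
        sampU <- .nullSamplesMU(A, ix, iy, wfx, wfy, permsU)
        rhoA[k] <- empiricalProb(rec$c[k], sampA)
        rhoU[k] <- empiricalProb(rec$c[k], sampU)
    }
    rec$rho_a <- rhoA
    rec$rho_u <- rhoU
    rec$p <- fisherCombine(rhoA, rhoU)
    rec$p_bh <- stats::p.adjust(rec$p, method = "BH")
    rec$s <- summaryScore(rec$c, rec$p)
    rec$outcome <- classifyOutcome(rhoA, rhoU, alpha)
    rec <- rec[order(-rec$s, rec$set_x, rec$set_y), , drop = FALSE]
    rownames(rec) <- NULL
    rec
}
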