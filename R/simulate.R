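#' Simulate an interaction network from a configuration-model draw
#'
#' Draws a random multigraph with the requested degree sequence (regular or
#' truncated power-law), removes self-loops and multi-edges, and returns the
#' resulting simple network. Genes that end up isolated after simplification
#' are dropped (so the degree >= 1 invariant holds by construction), and the
#' edge set is reproducible given a seed.
#'
#' @param nGenes number of genes (>= 10).
#' @param degreeDist `"regular"` (every gene targets degree `k`) or
#'   `"powerlaw"` (Pareto tail with exponent `gamma`).
#' @param k target degree for the regular distribution (default 8, a typical
#'   mean degree for confidence-filtered functional interactomes).
#' @param gamma power-law exponent (default 2.5).
#' @param seed optional integer seed.
#' @return An [InteractionNetwork-class].
#' @export
simulateNetwork <- function(nGenes = 500L, degreeDist = c("regular", "powerlaw"),
                            k = 8L, gamma = 2.5, seed = NULL) {
    degreeDist <- match.arg(degreeDist)
    if (!is.null(seed)) set.seed(seed)
    if (nGenes < 10L) stop("nGenes must be at least 10")
    degs <- switch(degreeDist,
        regular = rep(as.integer(k), nGenes),
        powerlaw = {
            d <- floor(stats::runif(nGenes)^(-1 / (gamma - 1)))
            pmax(1L, pmin(as.integer(d), nGenes - 1L))
        })
    if (sum(degs) %% 2L == 1L) degs[1L] <- degs[1L] + 1L
    gr <- NULL
    for (attempt in 1:5) {
        gr <- tryCatch(
            igraph::sample_degseq(degs, method = "configuration"),
            error = function(e) NULL)
        if (!is.null(gr)) break
        warning("infeasible degree sequence, resampling (attempt ",
                attempt, ")")
        degs <- sample(degs)
    }
    if (is.null(gr)) stop("could not realise the degree sequence")
    gr <- igraph::simplify(gr)
    el <- igraph::as_edgelist(gr, names = FALSE)
    if (!nrow(el)) stop("degenerate draw: no edges survived simplification")
    ids <- sprintf("g%04d", seq_len(nGenes))
    buildNetwork(data.frame(gene_a = ids[el[, 1L]], gene_b = ids[el[, 2L]],
                            stringsAsFactors = FALSE))
}

#' Simulate a gene-set collection with controlled pairwise overlap
#'
#' Draws `nSets` sets whose members all have network degree >= 1. With
#' `overlapFrac = 0` the sets are pairwise disjoint; otherwise every set
#' includes a common core of `round(overlapFrac * min(size))` genes, so the
#' pairwise intersection equals the core size, and the remaining members are
#' drawn disjointly.
#'
#' @param net an [InteractionNetwork-class].
#' @param nSets number of sets.
#' @param setSize a single size or a `c(min, max)` range sampled uniformly.
#' @param overlapFrac pairwise overlap fraction in [0, 1].
#' @param seed optional integer seed.
#' @return A [GeneSetCollection-class] with provenance `"synthetic"`.
#' @export
simulateGeneSets <- function(net, nSets = 20L, setSize = 25L,
                             overlapFrac = 0, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(overlapFrac >= 0, overlapFrac <= 1, nSets >= 1L)
    g <- genes(net)
    sizes <- if (length(setSize) == 1L) rep(as.integer(setSize), nSets)
             else sample(seq.int(setSize[1L], setSize[2L]), nSets,
                         replace = TRUE)
    if (max(sizes) > length(g))
        stop("set size exceeds the number of networked genes")
    coreSize <- as.integer(round(overlapFrac * min(sizes)))
    core <- if (coreSize > 0L) sample(g, coreSize) else character()
    pool <- setdiff(g, core)
    need <- sum(sizes) - nSets * coreSize
    if (need > length(pool))
        stop("not enough networked genes for ", nSets, " sets of these sizes")
    uniq <- sample(pool, need)
    stops <- cumsum(sizes - coreSize)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    sets <- lapply(seq_len(nSets), function(i)
        sort(c(core, uniq[starts[i]:stops[i]])))
    names(sets) <- sprintf("S%02d", seq_len(nSets))
    GeneSetCollection(sets, provenance = "synthetic")
}

#' Plant active crosstalks between randomly chosen set pairs
#'
#' Creates the alternative hypothesis the analysis is designed to detect:
#' for each of `nPlanted` randomly chosen set pairs, the endpoints of every
#' cross-link between the two sets receive weight `effect`, so the whole
#' interconnection of the pair is altered. All other genes get a background
#' weight `Bernoulli(backgroundRate) * Uniform(0, effect / 2)`. A planted
#' pair without any cross-link is rewired by adding a few edges between the
#' two sets (logged via a message), so every planted pair has signal.
#'
#' @param net an [InteractionNetwork-class].
#' @param sets a [GeneSetCollection-class] (or named list).
#' @param nPlanted number of planted pairs (`<= choose(nSets, 2)`).
#' @param effect planted weight level in (0, 1].
#' @param backgroundRate probability that a non-planted gene carries a
#'   (small) background weight.
#' @param seed optional integer seed.
#' @param sourceName name of the generated weight source.
#' @param rewireEdges edges added between a planted pair that has no
#'   cross-link (default 3).
#' @return List with `weights` (a single-source [WeightSet-class]), `truth`
#'   (data.frame of planted `set_x`, `set_y` in lexicographic order), and
#'   `network` (the input network, rewired if needed).
#' @export
plantCrosstalks <- function(net, sets, nPlanted = 3L, effect = 1,
                            backgroundRate = 0.05, seed = NULL,
                            sourceName = "s1", rewireEdges = 3L) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(effect > 0, effect <= 1,
              backgroundRate >= 0, backgroundRate <= 1)
    setList <- .asSetList(sets)
    nPairs <- choose(length(setList), 2L)
    if (nPlanted > nPairs)
        stop("nPlanted exceeds the number of set pairs")
    g <- genes(net)
    w <- stats::setNames(numeric(length(g)), g)
    bg <- stats::runif(length(g)) < backgroundRate
    w[bg] <- stats::runif(sum(bg), 0, effect / 2)

    nm <- sort(names(setList))
    allPairs <- t(utils::combn(nm, 2L))
    chosen <- allPairs[sample.int(nrow(allPairs), nPlanted), , drop = FALSE]
    extra <- NULL
    A <- adjacencyMatrix(net)
    for (k in seq_len(nrow(chosen))) {
        x <- setdiff(intersect(setList[[chosen[k, 1L]]], g),
                     setList[[chosen[k, 2L]]])
        y <- setdiff(intersect(setList[[chosen[k, 2L]]], g),
                     setList[[chosen[k, 1L]]])
        sub <- A[match(x, g), match(y, g), drop = FALSE]
        tri <- Matrix::summary(sub)
        if (!nrow(tri)) {
            message("planted pair ", chosen[k, 1L], "/", chosen[k, 2L],
                    " has no cross-link; adding ", rewireEdges, " edge(s)")
            add <- data.frame(gene_a = sample(x, rewireEdges, replace = TRUE),
                              gene_b = sample(y, rewireEdges, replace = TRUE))
            extra <- rbind(extra, add)
            w[unique(c(add$gene_a, add$gene_b))] <- effect
        } else {
            w[unique(c(x[tri$i], y[tri$j]))] <- effect
        }
    }
    if (!is.null(extra)) {
        old <- Matrix::summary(A)
        old <- old[old$i < old$j, , drop = FALSE]
        net <- buildNetwork(rbind(
            data.frame(gene_a = g[old$i], gene_b = g[old$j],
                       stringsAsFactors = FALSE),
            extra))
    }
    truth <- data.frame(set_x = chosen[, 1L], set_y = chosen[, 2L],
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$set_x, truth$set_y), , drop = FALSE]
    rownames(truth) <- NULL
    list(weights = WeightSet(matrix(w, ncol = 1L,
                                    dimnames = list(g, sourceName))),
         truth = truth, network = net)
}

#' One-call synthetic crosstalk study
#'
#' Generates a network, a gene-set collection and a weight source with
#' planted active crosstalks, all driven by a single seed through
#' independent per-stage substreams (bit-reproducible fixtures).
#'
#' @inheritParams simulateNetwork
#' @inheritParams simulateGeneSets
#' @inheritParams plantCrosstalks
#' @param seed single integer seed for the whole fixture.
#' @return List with `network`, `sets`, `weights`, `truth`.
#' @examples
#' sim <- simulateCrosstalkData(nGenes = 60, nSets = 4, setSize = 8,
#'                              nPlanted = 1, seed = 1)
#' sim$truth
#' @export
simulateCrosstalkData <- function(nGenes = 500L, degreeDist = "regular",
                                  k = 8L, gamma = 2.5, nSets = 20L,
                                  setSize = 25L, overlapFrac = 0,
                                  nPlanted = 3L, effect = 1,
                                  backgroundRate = 0.05, seed = 1L) {
    set.seed(seed)
    ss <- sample.int(2147483646L, 3L)
    net <- simulateNetwork(nGenes, degreeDist, k = k, gamma = gamma,
                           seed = ss[1L])
    sets <- simulateGeneSets(net, nSets = nSets, setSize = setSize,
                             overlapFrac = overlapFrac, seed = ss[2L])
    pl <- plantCrosstalks(net, sets, nPlanted = nPlanted, effect = effect,
                          backgroundRate = backgroundRate, seed = ss[3L])
    list(network = pl$network, sets = sets, weights = pl$weights,
         truth = pl$truth)
}
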