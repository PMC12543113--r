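#' Intra-cellular crosstalk analysis
#'
#' End-to-end screen of the crosstalk among intra-cellular gene sets
#' (pathways) under a single weight source: pre-filters, pair enumeration
#' with shared-gene exclusion, permutation assessment with both null models,
#' Fisher combination, outcome classification and mediator-gene scoring.
#'
#' @param net general-purpose [InteractionNetwork-class].
#' @param sets pathway [GeneSetCollection-class] (or named list).
#' @param weights [WeightSet-class]; `source` picks the vector to use.
#' @param source weight source name (default: the first source).
#' @param nPerm permutations per null model (default 999).
#' @param seed integer seed for the permutation streams.
#' @param alpha significance level (default 0.01).
#' @param nBins degree bins (automatic rule when `NULL`).
#' @param minSetSize minimum networked members per set (default 3).
#' @param rule significance rule for mediator scoring (`"any"` / `"both"`).
#' @return A `CrosstalkRun`: list with `crosstalks` (completed records,
#'   sorted by `s`), `geneScores`, `screen` (filters and tested sets) and
#'   `params`.
#' @examples
#' sim <- simulateCrosstalkData(nGenes = 80, nSets = 4, setSize = 10,
#'                              nPlanted = 1, seed = 7)
#' run <- runIntra(sim$network, sim$sets, sim$weights, nPerm = 99, seed = 7)
#' head(run$crosstalks[, c("set_x", "set_y", "c", "p", "s", "outcome")])
#' @export
runIntra <- function(net, sets, weights, source = NULL, nPerm = 999L,
                     seed = 1L, alpha = 0.01, nBins = NULL, minSetSize = 3L,
                     rule = c("any", "both")) {
    rule <- match.arg(rule)
    if (is.null(source)) source <- sources(weights)[1L]
    setNames <- if (is(sets, "GeneSetCollection")) names(sets) else names(sets)
    srcMap <- stats::setNames(rep(source, length(setNames)), setNames)
    screen <- screenPairs(sets, weights, net, mode = "intra",
                          sources = srcMap, minSetSize = minSetSize)
    ct <- assessCrosstalks(screen, net, weights, nPerm = nPerm, seed = seed,
                           nBins = nBins, alpha = alpha)
    gs <- scoreAllGenes(ct, screen$testedSets, net, weights, rule = rule)
    structure(list(crosstalks = ct, geneScores = gs, screen = screen,
                   params = list(mode = "intra", source = source,
                                 nPerm = nPerm, seed = seed, alpha = alpha,
                                 nBins = nBins, rule = rule)),
              class = "CrosstalkRun")
}

#' Inter-cellular crosstalk (cell-cell communication) analysis
#'
#' Screens every cross-source pair of cell-type gene sets over a
#' ligand-receptor style network. Each set must be tagged (via the
#' collection's provenance or the `sources` argument) with the weight source
#' of its cell type; shared genes between two cell types are permitted.
#'
#' @inheritParams runIntra
#' @param sets cell-type DEG sets; provenance tags name each set's weight
#'   source.
#' @param sources optional explicit set-to-source map overriding the
#'   provenance tags.
#' @return A `CrosstalkRun` (see [runIntra()]); `geneScores` ranks the
#'   communication mediators and `d_x` counts cell types.
#' @export
runInter <- function(net, sets, weights, sources = NULL, nPerm = 999L,
                     seed = 1L, alpha = 0.01, nBins = NULL, minSetSize = 3L,
                     rule = c("any", "both")) {
    rule <- match.arg(rule)
    screen <- screenPairs(sets, weights, net, mode = "inter",
                          sources = sources, minSetSize = minSetSize)
    ct <- assessCrosstalks(screen, net, weights, nPerm = nPerm, seed = seed,
                           nBins = nBins, alpha = alpha)
    gs <- scoreAllGenes(ct, screen$testedSets, net, weights, rule = rule)
    structure(list(crosstalks = ct, geneScores = gs, screen = screen,
                   params = list(mode = "inter", nPerm = nPerm, seed = seed,
                                 alpha = alpha, nBins = nBins, rule = rule)),
              class = "CrosstalkRun")
}

#' Integrated crosstalk analysis: communication mediators vs pathways
#'
#' Links a cell type's inter-cellular communications to its intra-cellular
#' states: the mediator genes of the focal cell type's significant
#' communications (see [buildMediatorSet()]) form the `X` set, screened
#' against every pathway of the collection over the general-purpose network,
#' with the intra-cellular shared-gene exclusion and the same permutation
#' machinery.
#'
#' @inheritParams runIntra
#' @param net general-purpose [InteractionNetwork-class].
#' @param pathways pathway [GeneSetCollection-class] (or named list).
#' @param interRun a `CrosstalkRun` from [runInter()] (or its `crosstalks`
#'   data.frame).
#' @param focalType set name of the focal cell type in the inter run.
#' @param partner optional partner cell type restricting the mediator set.
#' @param source weight source of the focal cell type (defaults to
#'   `focalType` when that is a source, else the first source).
#' @return A `CrosstalkRun`; `mediators` carries the `X` gene set.
#' @export
runIntegrated <- function(net, pathways, weights, interRun, focalType,
                          partner = NULL, source = NULL, nPerm = 999L,
                          seed = 1L, alpha = 0.01, nBins = NULL,
                          minSetSize = 3L, rule = c("any", "both")) {
    rule <- match.arg(rule)
    records <- if (inherits(interRun, "CrosstalkRun")) interRun$crosstalks
               else interRun
    med <- buildMediatorSet(records, focalType, partner = partner, rule = rule)
    if (is.null(source))
        source <- if (focalType %in% sources(weights)) focalType
                  else sources(weights)[1L]
    medName <- paste0(focalType, ".mediators")
    pwList <- .asSetList(pathways)
    allSets <- c(stats::setNames(list(med), medName), pwList)
    srcMap <- stats::setNames(rep(source, length(allSets)), names(allSets))
    pairs <- cbind(medName, names(pwList))
    screen <- screenPairs(allSets, weights, net, mode = "integrated",
                          sources = srcMap, pairs = pairs,
                          minSetSize = minSetSize)
    ct <- assessCrosstalks(screen, net, weights, nPerm = nPerm, seed = seed,
                           nBins = nBins, alpha = alpha)
    gs <- scoreAllGenes(ct, screen$testedSets, net, weights, rule = rule)
    structure(list(crosstalks = ct, geneScores = gs, screen = screen,
                   mediators = med,
                   params = list(mode = "integrated", focalType = focalType,
                                 partner = partner, source = source,
                                 nPerm = nPerm, seed = seed, alpha = alpha,
                                 nBins = nBins, rule = rule)),
              class = "CrosstalkRun")
}

#' @export
print.CrosstalkRun <- function(x, ...) {
    ct <- x$crosstalks
    cat("CrosstalkRun (", x$params$mode, " mode)\n", sep = "")
    cat("  ", nrow(ct), " tested pair(s); ",
        sum(ct$outcome != "neither"), " supported by >= 1 null, ",
        sum(ct$outcome == "both"), " by both (alpha = ",
        x$params$alpha, ")\n", sep = "")
    cat("  ", nrow(x$geneScores), " mediator gene(s)\n", sep = "")
    if (nrow(ct)) {
        top <- utils::head(ct, 3L)
        cat("  top pairs by s:\n")
        for (i in seq_len(nrow(top)))
            cat(sprintf("    %s / %s: c = %.3g, p = %.3g, s = %.3g (%s)\n",
                        top$set_x[i], top$set_y[i], top$c[i], top$p[i],
                        top$s[i], top$outcome[i]))
    }
    invisible(x)
}
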