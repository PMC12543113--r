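#' Apply the scenario-specific overlap rule to a gene-set pair
#'
#' In the intra-cellular and integrated scenarios the genes shared between
#' the two sets are excluded from both sides (otherwise intra-set
#' interactions would be counted). In the inter-cellular scenario the sets
#' belong to different cell types, which are expected to express genes in
#' common, so the overlap is permitted and the sets are returned unchanged.
#'
#' @param x,y character vectors of gene IDs (non-empty).
#' @param mode one of `"intra"`, `"inter"`, `"integrated"`.
#' @return List with elements `x`, `y` (the possibly pruned sets), `skip`
#'   (logical: `TRUE` when a side became empty) and `reason`.
#' @examples
#' preparePair(c("A", "B", "C"), c("B", "D"), "intra")
#' @export
preparePair <- function(x, y, mode = c("intra", "inter", "integrated")) {
    mode <- match.arg(mode)
    if (!length(x) || !length(y)) stop("both gene sets must be non-empty")
    if (mode == "inter")
        return(list(x = x, y = y, skip = FALSE, reason = NA_character_))
    px <- setdiff(x, y)
    py <- setdiff(y, x)
    skip <- !length(px) || !length(py)
    list(x = px, y = py, skip = skip,
         reason = if (skip) "set empty after excluding shared genes"
                  else NA_character_)
}

#' Crosstalk score of a gene-set pair
#'
#' Computes the bilinear crosstalk score
#' \eqn{c = \sum_i \sum_j a_{ij}\, u_X(i)\, u_Y(j)} over all network links
#' between `x` and `y`, together with the total link count `l`, the altered
#' link count `delta_l` (links whose two endpoints both carry positive
#' weight), and the contributing genes (the endpoints of altered links).
#' Links are unordered gene pairs; a gene present in both sets (inter-cell
#' scenario) can pair only with a *different* gene through a network edge,
#' never with itself (zero diagonal).
#'
#' @param net an [InteractionNetwork-class].
#' @param x,y character vectors of gene IDs (any genes absent from the
#'   network are ignored).
#' @param weightsX named numeric weight vector; values are looked up by gene
#'   name, absent genes count as 0. Only the restriction to `x` matters.
#' @param weightsY weight vector for the `y` side (defaults to `weightsX`,
#'   the intra-cellular case).
#' @return List with elements `c`, `delta_l`, `l`, `genes_x`, `genes_y`
#'   (contributing genes per side), `wsum_x`, `wsum_y` (sums of
#'   contributing-gene weights).
#' @examples
#' net <- buildNetwork(data.frame(gene_a = "A", gene_b = "B"))
#' crosstalkScore(net, "A", "B", c(A = 0.5, B = 0.4))
#' @export
crosstalkScore <- function(net, x, y, weightsX, weightsY = weightsX) {
    g <- genes(net)
    x <- intersect(unique(x), g)
    y <- intersect(unique(y), g)
    empty <- list(c = 0, delta_l = 0L, l = 0L,
                  genes_x = character(), genes_y = character(),
                  wsum_x = 0, wsum_y = 0)
    if (!length(x) || !length(y)) return(empty)
    wx <- .lookupWeights(weightsX, x)
    wy <- .lookupWeights(weightsY, y)
    sub <- adjacencyMatrix(net)[match(x, g), match(y, g), drop = FALSE]
    tri <- Matrix::summary(sub)
    if (!nrow(tri)) return(empty)
    ga <- x[tri$i]
    gb <- y[tri$j]
    key <- paste(pmin(ga, gb), pmax(ga, gb), sep = "\r")
    contrib <- wx[tri$i] > 0 & wy[tri$j] > 0
    gx <- sort(unique(ga[contrib]))
    gy <- sort(unique(gb[contrib]))
    list(c = sum(wx[tri$i] * wy[tri$j]),
         delta_l = length(unique(key[contrib])),
         l = length(unique(key)),
         genes_x = gx, genes_y = gy,
         wsum_x = sum(wx[match(gx, x)]),
         wsum_y = sum(wy[match(gy, y)]))
}

.lookupWeights <- function(w, genes) {
    if (is.null(names(w))) stop("weight vectors must be named by gene")
    v <- w[genes]
    v[is.na(v)] <- 0
    as.numeric(v)
}

#' Crosstalk saturation
#'
#' The fraction \eqn{r_C = \delta L / L} of existing links between the two
#' sets whose both endpoints carry positive weight; defined as 0 when there
#' are no links. Similar crosstalk scores can reflect a broad or a narrow
#' impairment of the interconnection, which the saturation distinguishes.
#'
#' @param deltaL altered link count (integer, `0 <= deltaL <= l`).
#' @param l total link count.
#' @return Saturation in [0, 1].
#' @examples
#' saturation(19, 101)
#' @export
saturation <- function(deltaL, l) {
    if (any(deltaL < 0) || any(l < 0)) stop("link counts must be non-negative")
    if (any(deltaL > l)) stop("deltaL exceeds l (invariant breach)")
    ifelse(l > 0, deltaL / l, 0)
}

#' Screen all gene-set pairs for non-zero crosstalk
#'
#' Applies the pre-filters of the analysis -- genes without any interaction
#' are dropped from every set; only sets with at least `minSetSize` networked
#' members and a non-null gene weight (in their own source) are retained --
#' then enumerates pairs (all unordered pairs, or all cross-source pairs in
#' the inter scenario, or an explicit `pairs` list), applies the scenario
#' overlap rule, and computes the crosstalk decomposition for each pair.
#' Pairs with `c = 0` are discarded by default to reduce the number of pairs
#' carried into the permutation stage.
#'
#' @param sets a [GeneSetCollection-class] or named list of gene ID vectors.
#' @param weights a [WeightSet-class].
#' @param net an [InteractionNetwork-class].
#' @param mode analysis scenario, see [preparePair()].
#' @param sources named character vector mapping each set name to its weight
#'   source. Defaults: the first source for every set (intra / integrated),
#'   or the collection's provenance tags (inter).
#' @param pairs optional 2-column matrix / data.frame of set-name pairs to
#'   test (rows referencing dropped sets are skipped).
#' @param minSetSize minimum number of networked members per set (default 3).
#' @param dropZero discard pairs with `c = 0` (default `TRUE`). Setting
#'   `FALSE` keeps every evaluated pair, which is what an unconditional
#'   calibration assessment of the null models requires.
#' @return An object of class `CrosstalkScreen`: a list with `records` (one
#'   row per retained pair: `set_x`, `set_y`, contributing genes, sizes,
#'   weight sums, `delta_l`, `l`, `c`, `r_c`), `pairGenes` (the pruned member
#'   lists actually scored, needed by the permutation stage), `testedSets`
#'   (pruned membership of every set that survived the filters), `sources`,
#'   `mode` and `log` (filter attrition counts).
#' @export
screenPairs <- function(sets, weights, net,
                        mode = c("intra", "inter", "integrated"),
                        sources = NULL, pairs = NULL, minSetSize = 3L,
                        dropZero = TRUE) {
    mode <- match.arg(mode)
    if (is(sets, "GeneSetCollection")) {
        if (is.null(sources) && mode == "inter")
            sources <- setProvenance(sets)
        sets <- geneSets(sets)
    }
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
        stop("sets must carry unique names")
    if (is.null(sources))
        sources <- stats::setNames(rep(sources(weights)[1L], length(sets)),
                                   names(sets))
    missingSrc <- setdiff(names(sets), names(sources))
    if (length(missingSrc))
        stop("no weight source mapped for set(s): ",
             paste(missingSrc, collapse = ", "))
    bad <- setdiff(unique(sources[names(sets)]), sources(weights))
    if (length(bad))
        stop("set/source mismatch: unknown weight source(s) ",
             paste(bad, collapse = ", "))

    g <- genes(net)
    pruned <- lapply(sets, function(s) sort(intersect(unique(s), g)))
    nOff <- sum(vapply(sets, length, integer(1L))) -
        sum(vapply(pruned, length, integer(1L)))
    sizeOK <- vapply(pruned, length, integer(1L)) >= minSetSize
    wOK <- vapply(names(pruned), function(nm) {
        w <- geneWeights(weights, sources[[nm]])
        any(.lookupWeights(w, pruned[[nm]]) > 0)
    }, logical(1L))
    tested <- pruned[sizeOK & wOK]
    log <- list(genes_dropped_no_interaction = nOff,
                sets_dropped_size = sum(!sizeOK),
                sets_dropped_zero_weight = sum(sizeOK & !wOK),
                sets_tested = length(tested))
    if (length(tested) < 2L) stop("nothing to screen: fewer than 2 sets survive")

    if (is.null(pairs)) {
        nm <- sort(names(tested))
        pairs <- t(utils::combn(nm, 2L))
        if (mode == "inter")
            pairs <- pairs[sources[pairs[, 1L]] != sources[pairs[, 2L]], ,
                           drop = FALSE]
    } else {
        pairs <- as.matrix(pairs)
        pairs <- pairs[pairs[, 1L] %in% names(tested) &
                       pairs[, 2L] %in% names(tested), , drop = FALSE]
    }
    if (!nrow(pairs)) stop("nothing to screen: no eligible pairs")

    rows <- vector("list", nrow(pairs))
    pairGenes <- vector("list", nrow(pairs))
    nSkipped <- 0L
    nZero <- 0L
    nOverlap <- 0L
    for (k in seq_len(nrow(pairs))) {
        nx <- pairs[k, 1L]; ny <- pairs[k, 2L]
        if (mode == "inter" && length(intersect(tested[[nx]], tested[[ny]])))
            nOverlap <- nOverlap + 1L
        pp <- preparePair(tested[[nx]], tested[[ny]], mode)
        if (pp$skip) { nSkipped <- nSkipped + 1L; next }
        wx <- geneWeights(weights, sources[[nx]])
        wy <- geneWeights(weights, sources[[ny]])
        cs <- crosstalkScore(net, pp$x, pp$y, wx, wy)
        if (dropZero && cs$c == 0) { nZero <- nZero + 1L; next }
        rows[[k]] <- data.frame(
            set_x = nx, set_y = ny,
            genes_x = paste(cs$genes_x, collapse = ";"),
            genes_y = paste(cs$genes_y, collapse = ";"),
            size_x = length(pp$x), size_y = length(pp$y),
            wsum_x = cs$wsum_x, wsum_y = cs$wsum_y,
            delta_l = cs$delta_l, l = cs$l, c = cs$c,
            r_c = saturation(cs$delta_l, cs$l),
            stringsAsFactors = FALSE)
        pairGenes[[k]] <- list(x = pp$x, y = pp$y)
    }
    keep <- !vapply(rows, is.null, logical(1L))
    log$pairs_skipped_empty <- nSkipped
    log$pairs_dropped_zero_score <- nZero
    log$pairs_with_overlap <- nOverlap
    log$pairs_retained <- sum(keep)
    if (nOverlap)
        message(nOverlap, " inter-mode pair(s) have overlapping member sets")
    structure(list(records = do.call(rbind, rows[keep]),
                   pairGenes = pairGenes[keep],
                   testedSets = tested,
                   sources = sources[names(tested)],
                   mode = mode, log = log),
              class = "CrosstalkScreen")
}

#' @export
print.CrosstalkScreen <- function(x, ...) {
    cat("CrosstalkScreen (", x$mode, " mode): ",
        x$log$pairs_retained, " pair(s) over ",
        length(x$testedSets), " tested set(s)\n", sep = "")
    invisible(x)
}

#' Mediator gene set of a cell type's significant communications
#'
#' Collects the cell type's contributing genes across its significant
#' inter-cellular crosstalks (with one named partner, or with all partners),
#' yielding the gene set used as the `X` side of an integrated-scenario
#' screen against the cell type's intra-cellular pathways.
#'
#' @param records completed crosstalk records (inter scenario).
#' @param cellType set name of the focal cell type.
#' @param partner optional set name restricting to one communication partner.
#' @param rule which records count as significant: supported by at least one
#'   null (`"any"`, the default) or by both (`"both"`).
#' @return Sorted character vector of mediator genes.
#' @export
buildMediatorSet <- function(records, cellType, partner = NULL,
                             rule = c("any", "both")) {
    rule <- match.arg(rule)
    sig <- records[.isSignificant(records$outcome, rule), , drop = FALSE]
    selX <- sig$set_x == cellType &
        (if (is.null(partner)) TRUE else sig$set_y == partner)
    selY <- sig$set_y == cellType &
        (if (is.null(partner)) TRUE else sig$set_x == partner)
    med <- sort(unique(c(
        unlist(strsplit(sig$genes_x[selX], ";", fixed = TRUE)),
        unlist(strsplit(sig$genes_y[selY], ";", fixed = TRUE)))))
    med <- med[nzchar(med)]
    if (!length(med))
        stop("no significant communications found for ", cellType)
    med
}

.isSignificant <- function(outcome, rule = c("any", "both")) {
    rule <- match.arg(rule)
    if (rule == "both") outcome == "both" else outcome != "neither"
}
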