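#' Raw per-gene alteration scores from differential-expression statistics
#'
#' Combines each gene's fold change with its adjusted p-value into a raw
#' score \eqn{y_i = -\log_2(x_i)\,\log_{10}(p_i)} for genes passing both the
#' significance and the effect-size threshold; scores associated with
#' marginal significance are set to zero. With the default thresholds a gene
#' scores only when \eqn{p_i < 0.05} and \eqn{\log_2(x_i) \ge 0.5}, so all
#' scores are non-negative.
#'
#' @param de data.frame with columns `gene`, `p_adj`, and `fc` (fold change,
#'   ratio scale) or `log2fc` (already on the log2 scale).
#' @param pThresh adjusted p-value threshold (default 0.05, strict `<`).
#' @param lfcThresh log2 fold-change threshold (default 0.5).
#' @param strict if `TRUE`, require `log2fc > lfcThresh` instead of `>=`.
#' @param logInput if `TRUE` the effect column is already log2 fold change;
#'   if `NULL` (default) it is auto-detected from the column name.
#' @param pFloor adjusted p-values of exactly 0 are clamped to this floor
#'   (with a warning) to keep scores finite.
#' @return Named numeric vector of raw scores `y >= 0`, one per gene.
#' @examples
#' de <- data.frame(gene = c("A", "B"), fc = c(2, 2), p_adj = c(0.01, 0.06))
#' computeRawScores(de)  # B is marginal -> 0
#' @export
computeRawScores <- function(de, pThresh = 0.05, lfcThresh = 0.5,
                             strict = FALSE, logInput = NULL,
                             pFloor = 1e-300) {
    stopifnot(pThresh > 0, lfcThresh > 0, pFloor > 0)
    if (is.null(logInput)) logInput <- "log2fc" %in% names(de)
    lfc <- if (logInput) {
        if (!"log2fc" %in% names(de)) stop("no 'log2fc' column")
        as.numeric(de$log2fc)
    } else {
        if (!"fc" %in% names(de)) stop("no 'fc' column")
        fc <- as.numeric(de$fc)
        if (any(fc <= 0, na.rm = TRUE)) stop("fold changes must be positive")
        log2(fc)
    }
    p <- as.numeric(de$p_adj)
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("adjusted p-values must lie in [0, 1]")
    if (any(p == 0)) {
        warning("adjusted p-values of 0 clamped to ", pFloor)
        p[p == 0] <- pFloor
    }
    pass <- p < pThresh &
        (if (strict) lfc > lfcThresh else lfc >= lfcThresh)
    y <- ifelse(pass, -lfc * log10(p), 0)
    stats::setNames(y, as.character(de$gene))
}

#' Normalise raw scores to unit-interval weights
#'
#' Divides by the maximum so that `max(u) = 1`; zeros are preserved. A source
#' with no significant gene (all-zero scores) is an error, not a silent
#' all-zero weight vector.
#'
#' @param y named numeric vector of raw scores (`>= 0`).
#' @return Named numeric vector of weights in [0, 1] with maximum exactly 1.
#' @export
normalizeWeights <- function(y) {
    if (any(y < 0)) stop("raw scores must be non-negative")
    m <- max(y)
    if (m <= 0) stop("no significant genes for source")
    y / m
}

#' Gene weights from a (multi-source) differential-expression table
#'
#' Applies [computeRawScores()] and [normalizeWeights()] per source and
#' assembles a [WeightSet-class] over a common gene universe. Genes absent
#' from a source's DE table receive weight 0 (downstream filters rely on
#' explicit zeros).
#'
#' @param de DE data.frame (see [readDETable()]); an optional `source` column
#'   separates conditions / cell types.
#' @param genes optional gene universe for the weight vectors (e.g.
#'   `genes(network)`); defaults to the union of genes in `de`.
#' @inheritParams computeRawScores
#' @return A [WeightSet-class] with one source per distinct `source` value.
#' @export
weightsFromDE <- function(de, genes = NULL, pThresh = 0.05, lfcThresh = 0.5,
                          strict = FALSE, logInput = NULL, pFloor = 1e-300) {
    if (!"source" %in% names(de)) de$source <- "source1"
    byS <- split(de, de$source)
    vecs <- lapply(byS, function(d) {
        y <- computeRawScores(d, pThresh = pThresh, lfcThresh = lfcThresh,
                              strict = strict, logInput = logInput,
                              pFloor = pFloor)
        normalizeWeights(y)
    })
    if (!is.null(genes)) {
        vecs <- lapply(vecs, function(u) {
            v <- u[genes]
            v[is.na(v)] <- 0
            stats::setNames(as.numeric(v), genes)
        })
    }
    WeightSet(vecs)
}
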