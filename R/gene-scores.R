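# Shared helper: long table of (gene, partner set, pair id) contributions
# extracted from significant crosstalk records.
.contributionTable <- function(records, rule) {
    sig <- records[.isSignificant(records$outcome, rule), , drop = FALSE]
    if (!nrow(sig)) return(NULL)
    pieces <- lapply(seq_len(nrow(sig)), function(k) {
        gx <- strsplit(sig$genes_x[k], ";", fixed = TRUE)[[1L]]
        gy <- strsplit(sig$genes_y[k], ";", fixed = TRUE)[[1L]]
        gx <- gx[nzchar(gx)]; gy <- gy[nzchar(gy)]
        pair <- paste(sig$set_x[k], sig$set_y[k], sep = "|")
        rbind(
            if (length(gx)) data.frame(gene = gx, partner = sig$set_y[k],
                                       pair = pair, stringsAsFactors = FALSE),
            if (length(gy)) data.frame(gene = gy, partner = sig$set_x[k],
                                       pair = pair, stringsAsFactors = FALSE))
    })
    do.call(rbind, pieces)
}

.asSetList <- function(sets) {
    if (is(sets, "GeneSetCollection")) geneSets(sets) else sets
}

#' Crosstalk diversity of a mediator gene
#'
#' Counts the gene sets that are part of altered (significant) crosstalks
#' and contain interactors of the gene -- i.e. the distinct partner sets of
#' the crosstalks the gene mediates. Its saturation `r_x` divides by the
#' number of *tested* sets containing at least one interactor of the gene,
#' and reaches 1 when every such set is part of an altered crosstalk with
#' the gene. Because the same partner set can appear in several significant
#' pairs, the pair count is returned alongside the set count.
#'
#' @param gene a gene identifier.
#' @param records completed crosstalk records (see [assessCrosstalks()]).
#' @param sets the tested gene sets (named list or
#'   [GeneSetCollection-class]); the saturation denominator counts only this
#'   tested universe.
#' @param net an [InteractionNetwork-class].
#' @param rule significance rule, `"any"` (at least one null, default) or
#'   `"both"`.
#' @return List with `d_x` (distinct partner sets), `d_x_pairs` (significant
#'   pairs mediated), `r_x`; `NULL` when no tested set contains an
#'   interactor of the gene.
#' @export
crosstalkDiversity <- function(gene, records, sets, net,
                               rule = c("any", "both")) {
    sets <- .asSetList(sets)
    contrib <- .contributionTable(records, match.arg(rule))
    inter <- interactorsOf(net, gene)
    denom <- sum(vapply(sets, function(s) any(inter %in% s), logical(1L)))
    if (denom == 0L) return(NULL)
    mine <- contrib[!is.null(contrib) & contrib$gene == gene, , drop = FALSE]
    partners <- unique(mine$partner)
    partners <- partners[vapply(partners,
                                function(p) any(inter %in% sets[[p]]),
                                logical(1L))]
    list(d_x = length(partners),
         d_x_pairs = length(unique(mine$pair)),
         r_x = length(partners) / denom)
}

#' Interactor diversity of a mediator gene
#'
#' Counts the gene's network interactors that belong to partner sets of the
#' significant crosstalks the gene mediates. Its saturation `r_a` divides by
#' the number of interactors belonging to any tested set, and reaches 1 when
#' all of them sit in sets engaged in altered crosstalks with the gene.
#'
#' @inheritParams crosstalkDiversity
#' @return List with `d_a` and `r_a`; `NULL` when none of the gene's
#'   interactors belongs to a tested set.
#' @export
interactorDiversity <- function(gene, records, sets, net,
                                rule = c("any", "both")) {
    sets <- .asSetList(sets)
    contrib <- .contributionTable(records, match.arg(rule))
    inter <- interactorsOf(net, gene)
    allMembers <- unique(unlist(sets, use.names = FALSE))
    denom <- sum(inter %in% allMembers)
    if (denom == 0L) return(NULL)
    mine <- contrib[!is.null(contrib) & contrib$gene == gene, , drop = FALSE]
    partnerMembers <- unique(unlist(sets[unique(mine$partner)],
                                    use.names = FALSE))
    d_a <- sum(inter %in% partnerMembers)
    list(d_a = d_a, r_a = d_a / denom)
}

#' Score every mediator gene of the significant crosstalks
#'
#' One record per gene that appears as a contributing gene in any
#' significant crosstalk, carrying both diversity scores and their
#' saturations, the number of weight sources in which the gene is altered,
#' and the list of mediated pairs; sorted by crosstalk diversity then
#' interactor diversity (descending), ties broken by gene ID.
#'
#' @param records completed crosstalk records.
#' @param sets tested gene sets (named list or [GeneSetCollection-class]).
#' @param net an [InteractionNetwork-class].
#' @param weights optional [WeightSet-class] for the `n_sources` column.
#' @param rule significance rule (`"any"` or `"both"`).
#' @return Data.frame with columns `gene`, `d_x`, `d_x_pairs`, `r_x`, `d_a`,
#'   `r_a`, `n_sources`, `pairs` (empty when nothing is significant).
#' @export
scoreAllGenes <- function(records, sets, net, weights = NULL,
                          rule = c("any", "both")) {
    rule <- match.arg(rule)
    sets <- .asSetList(sets)
    contrib <- .contributionTable(records, rule)
    empty <- data.frame(gene = character(), d_x = integer(),
                        d_x_pairs = integer(), r_x = numeric(),
                        d_a = integer(), r_a = numeric(),
                        n_sources = integer(), pairs = character(),
                        stringsAsFactors = FALSE)
    if (is.null(contrib)) return(empty)
    out <- lapply(sort(unique(contrib$gene)), function(g) {
        cd <- crosstalkDiversity(g, records, sets, net, rule)
        id <- interactorDiversity(g, records, sets, net, rule)
        if (is.null(cd) || is.null(id)) return(NULL)
        mine <- contrib[contrib$gene == g, , drop = FALSE]
        ns <- if (is.null(weights)) NA_integer_ else {
            w <- weights@weights
            if (g %in% rownames(w)) sum(w[g, ] > 0) else 0L
        }
        data.frame(gene = g, d_x = cd$d_x, d_x_pairs = cd$d_x_pairs,
                   r_x = cd$r_x, d_a = id$d_a, r_a = id$r_a,
                   n_sources = as.integer(ns),
                   pairs = paste(sort(unique(mine$pair)), collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
    if (is.null(out)) return(empty)
    out <- out[order(-out$d_x, -out$d_a, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}
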