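#' Read gene sets from a GMT file
#'
#' Parses the tab-separated GMT dialect: set name, description, then member
#' gene IDs. Duplicate members within a set are collapsed; the description
#' field becomes the set's provenance tag.
#'
#' @param path path to a GMT file.
#' @return A [GeneSetCollection-class].
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("P53\thallmark\tTP53\tCDKN2A", f)
#' readGeneSets(f)
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty GMT file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, integer(1L)) < 3L)
    if (length(bad))
        stop("malformed GMT line ", bad[1L], ": fewer than 3 fields")
    nm <- vapply(fields, `[[`, character(1L), 1L)
    if (anyDuplicated(nm))
        stop("duplicate gene set name: ", nm[duplicated(nm)][1L])
    desc <- vapply(fields, `[[`, character(1L), 2L)
    sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
    names(sets) <- nm
    GeneSetCollection(sets, provenance = desc)
}

#' Write gene sets to a GMT file
#'
#' @param gsc a [GeneSetCollection-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGeneSets <- function(gsc, path) {
    stopifnot(is(gsc, "GeneSetCollection"))
    prov <- setProvenance(gsc)
    prov[!nzchar(prov)] <- "."
    lines <- mapply(function(nm, p, members)
        paste(c(nm, p, members), collapse = "\t"),
        names(gsc), prov, geneSets(gsc))
    writeLines(lines, path)
    invisible(path)
}

#' Read a scored or unscored interaction table
#'
#' Reads a tab-separated edge list (header required; the first two columns are
#' gene IDs). Self-pairs are dropped and unordered duplicates collapsed,
#' keeping the highest score where scores are present. Gene pairs are returned
#' in canonical (lexicographically sorted) order.
#'
#' @param path path to a TSV file.
#' @param scoreColumn optional name of a numeric score column (e.g. STRING's
#'   `combined_score`). If `NULL` the table is treated as unscored
#'   (ligand-receptor style).
#' @return A data.frame with columns `gene_a`, `gene_b` and, when scored,
#'   `score`.
#' @export
readInteractions <- function(path, scoreColumn = NULL) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (!nrow(df)) stop("empty interaction file: ", path)
    if (ncol(df) < 2L) stop("interaction file needs two gene ID columns")
    tbl <- data.frame(gene_a = as.character(df[[1L]]),
                      gene_b = as.character(df[[2L]]),
                      stringsAsFactors = FALSE)
    if (!is.null(scoreColumn)) {
        if (!scoreColumn %in% names(df))
            stop("score column not found: ", scoreColumn)
        sc <- df[[scoreColumn]]
        if (!is.numeric(sc)) stop("score column is not numeric: ", scoreColumn)
        if (anyNA(sc) || any(sc < 0)) stop("scores must be non-negative")
        tbl$score <- as.numeric(sc)
    }
    cleanInteractions(tbl)
}

#' Clean an interaction table
#'
#' Drops self-pairs, canonicalises unordered pairs and collapses duplicates
#' keeping the maximum score per pair.
#'
#' @param tbl data.frame with columns `gene_a`, `gene_b` and optionally
#'   `score`.
#' @return The cleaned data.frame, sorted by gene pair.
#' @export
cleanInteractions <- function(tbl) {
    keep <- tbl$gene_a != tbl$gene_b
    tbl <- tbl[keep, , drop = FALSE]
    a <- pmin(tbl$gene_a, tbl$gene_b)
    b <- pmax(tbl$gene_a, tbl$gene_b)
    tbl$gene_a <- a
    tbl$gene_b <- b
    key <- paste(a, b, sep = "\r")
    if ("score" %in% names(tbl)) {
        ord <- order(key, -tbl$score)
        tbl <- tbl[ord, , drop = FALSE]
        key <- key[ord]
    }
    tbl <- tbl[!duplicated(key), , drop = FALSE]
    tbl <- tbl[order(tbl$gene_a, tbl$gene_b), , drop = FALSE]
    rownames(tbl) <- NULL
    tbl
}

#' Confidence filtering of a scored interaction table
#'
#' Retains the union of (i) all high-confidence interactions
#' (`score >= high`) and (ii), for every gene independently, its `topK`
#' highest-scoring medium-confidence interactions (`medium <= score < high`).
#' The kept medium-confidence edge set is the union over genes, and ties at
#' the k-th score of a gene keep all tied edges, so the result does not
#' depend on row order. High-confidence edges do not count towards a gene's
#' `topK` medium slots.
#'
#' @param tbl scored interaction table (see [readInteractions()]).
#' @param high high-confidence score threshold (default 700).
#' @param medium medium-confidence score threshold (default 400).
#' @param topK medium-confidence edges retained per gene (default 3).
#' @return The filtered interaction table (a subset of `tbl`).
#' @export
filterInteractionsByScore <- function(tbl, high = 700, medium = 400,
                                      topK = 3L) {
    if (!"score" %in% names(tbl))
        stop("confidence filtering requires a score column")
    if (topK < 0L) stop("topK must be non-negative")
    hi <- tbl$score >= high
    med <- !hi & tbl$score >= medium
    medTbl <- tbl[med, , drop = FALSE]
    keepMed <- logical(nrow(medTbl))
    if (nrow(medTbl) && topK > 0L) {
        long <- data.frame(gene = c(medTbl$gene_a, medTbl$gene_b),
                           row = rep(seq_len(nrow(medTbl)), 2L),
                           score = rep(medTbl$score, 2L))
        for (rows in split(seq_len(nrow(long)), long$gene)) {
            sc <- long$score[rows]
            thr <- if (length(sc) <= topK) min(sc) else
                sort(sc, decreasing = TRUE)[topK]
            keepMed[long$row[rows][sc >= thr]] <- TRUE
        }
    }
    out <- rbind(tbl[hi, , drop = FALSE], medTbl[keepMed, , drop = FALSE])
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build an interaction network from a cleaned interaction table
#'
#' Constructs the symmetric binary adjacency over the genes appearing in the
#' table; isolated genes are impossible by construction and the node order is
#' deterministic (sorted gene IDs). Scores, if present, are discarded: the
#' crosstalk analysis operates on the binary adjacency.
#'
#' @param tbl interaction table with columns `gene_a`, `gene_b`.
#' @return An [InteractionNetwork-class].
#' @examples
#' net <- buildNetwork(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C")))
#' geneDegree(net)
#' @export
buildNetwork <- function(tbl) {
    if (!nrow(tbl)) stop("cannot build a network from an empty table")
    a <- as.character(tbl$gene_a)
    b <- as.character(tbl$gene_b)
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    if (!length(a)) stop("no non-self interactions in table")
    gs <- sort(unique(c(a, b)))
    i <- match(a, gs); j <- match(b, gs)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(length(gs), length(gs)),
                              dimnames = list(gs, gs))
    A <- as(A, "CsparseMatrix")
    A@x[] <- 1
    new("InteractionNetwork", adjacency = as(A, "dgCMatrix"))
}

#' Export a network as an annotated edge list
#'
#' Writes one row per unordered interaction, optionally flagging altered
#' ("delta") links and the gene sets each endpoint belongs to, in a TSV
#' loadable by standard graph viewers.
#'
#' @param net an [InteractionNetwork-class].
#' @param path output path.
#' @param deltaLinks optional data.frame with columns `gene_a`, `gene_b` of
#'   altered links; matching rows get `delta = TRUE`.
#' @param sets optional [GeneSetCollection-class] used to annotate endpoint
#'   set membership.
#' @return Invisibly, the exported data.frame.
#' @export
writeNetworkEdges <- function(net, path, deltaLinks = NULL, sets = NULL) {
    A <- adjacencyMatrix(net)
    tri <- Matrix::summary(A)
    tri <- tri[tri$i < tri$j, , drop = FALSE]
    g <- genes(net)
    out <- data.frame(gene_a = g[tri$i], gene_b = g[tri$j],
                      stringsAsFactors = FALSE)
    if (!is.null(deltaLinks)) {
        key <- paste(pmin(out$gene_a, out$gene_b),
                     pmax(out$gene_a, out$gene_b))
        dkey <- paste(pmin(deltaLinks$gene_a, deltaLinks$gene_b),
                      pmax(deltaLinks$gene_a, deltaLinks$gene_b))
        out$delta <- key %in% dkey
    }
    if (!is.null(sets)) {
        memberOf <- function(gene) paste(
            names(geneSets(sets))[vapply(geneSets(sets),
                                         function(s) gene %in% s, logical(1L))],
            collapse = ";")
        out$sets_a <- vapply(out$gene_a, memberOf, character(1L))
        out$sets_b <- vapply(out$gene_b, memberOf, character(1L))
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(out)
}

.CROSSTALK_COLUMNS <- c("set_x", "set_y", "genes_x", "genes_y",
                        "size_x", "size_y", "wsum_x", "wsum_y",
                        "delta_l", "l", "c", "r_c",
                        "rho_a", "rho_u", "p", "p_bh", "s", "outcome")

#' Validate a table of crosstalk records
#'
#' Checks the structural invariants of completed crosstalk records:
#' `delta_l <= l`, `r_c = delta_l / l` (0 when `l = 0`), `c = 0` exactly when
#' `delta_l = 0`, `s = -c log10(p)`, and empirical probabilities in (0, 1].
#'
#' @param records crosstalk record data.frame.
#' @param tol numeric tolerance for the arithmetic identities.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validateCrosstalkRecords <- function(records, tol = 1e-8) {
    need <- setdiff(.CROSSTALK_COLUMNS, c("p_bh", names(records)))
    if (length(need)) stop("missing crosstalk columns: ",
                           paste(need, collapse = ", "))
    if (!nrow(records)) return(invisible(TRUE))
    with(records, {
        if (any(delta_l > l)) stop("delta_l exceeds l")
        rc <- ifelse(l > 0, delta_l / l, 0)
        if (any(abs(r_c - rc) > tol)) stop("r_c != delta_l / l")
        if (any((c == 0) != (delta_l == 0))) stop("c = 0 iff delta_l = 0 violated")
        if (any(rho_a <= 0 | rho_a > 1 | rho_u <= 0 | rho_u > 1))
            stop("empirical probabilities must lie in (0, 1]")
        if (any(p <= 0 | p > 1)) stop("combined p must lie in (0, 1]")
        if (any(abs(s - (-c * log10(p))) > tol * pmax(1, abs(s))))
            stop("s != -c log10(p)")
    })
    invisible(TRUE)
}

#' Write a crosstalk result table
#'
#' Validates the record invariants, sorts by summary score `s` (descending),
#' and writes a TSV with the full record schema (pair identity, contributing
#' genes per side, set sizes, contributing weight sums, altered and total
#' link counts, score, saturation, the two empirical probabilities, combined
#' p, summary score and outcome class).
#'
#' @param records crosstalk record data.frame (see [assessCrosstalks()]).
#' @param path output path.
#' @return Invisibly, the sorted data.frame that was written.
#' @export
writeCrosstalkTable <- function(records, path) {
    validateCrosstalkRecords(records)
    cols <- intersect(.CROSSTALK_COLUMNS, names(records))
    records <- records[order(-records$s, records$set_x, records$set_y),
                       cols, drop = FALSE]
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(records)
}

#' Read a crosstalk result table written by [writeCrosstalkTable()]
#'
#' @param path path to the TSV.
#' @return Data.frame of crosstalk records.
#' @export
readCrosstalkTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE)
    for (col in c("set_x", "set_y", "genes_x", "genes_y", "outcome"))
        if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
    df
}

#' Write a gene-score (mediator) table
#'
#' @param scores gene score data.frame (see [scoreAllGenes()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGeneScoreTable <- function(scores, path) {
    utils::write.table(scores, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a long-format weight table
#'
#' Expects columns `gene`, `source`, `weight` (tab-separated, header). Genes
#' absent from a source get weight 0.
#'
#' @param path path to the TSV.
#' @return A [WeightSet-class].
#' @export
readWeightTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- setdiff(c("gene", "source", "weight"), names(df))
    if (length(need)) stop("weight table lacks columns: ",
                           paste(need, collapse = ", "))
    WeightSet(lapply(split(df, df$source), function(d)
        stats::setNames(as.numeric(d$weight), d$gene)))
}

#' Write a WeightSet in long format
#'
#' Only positive weights are written; zeros are implicit.
#'
#' @param ws a [WeightSet-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeWeightTable <- function(ws, path) {
    W <- ws@weights
    long <- do.call(rbind, lapply(colnames(W), function(s) {
        pos <- W[, s] > 0
        data.frame(gene = rownames(W)[pos], source = s,
                   weight = W[pos, s], stringsAsFactors = FALSE)
    }))
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a differential-expression table
#'
#' Expects tab-separated columns `gene`, `p_adj`, and either `fc` (fold
#' change, ratio scale) or `log2fc`; an optional `source` column separates
#' conditions / cell types.
#'
#' @param path path to the TSV.
#' @return Data.frame with the DE statistics.
#' @export
readDETable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!"gene" %in% names(df)) stop("DE table needs a 'gene' column")
    if (!"p_adj" %in% names(df)) stop("DE table needs a 'p_adj' column")
    if (!any(c("fc", "log2fc") %in% names(df)))
        stop("DE table needs a 'fc' or 'log2fc' column")
    if (any(df$p_adj < 0 | df$p_adj > 1, na.rm = TRUE))
        stop("adjusted p-values must lie in [0, 1]")
    if ("fc" %in% names(df) && any(df$fc <= 0, na.rm = TRUE))
        stop("fold changes must be positive (ratio scale)")
    df
}
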