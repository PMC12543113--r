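# Small fixtures and independent oracles shared across the test files.

edgeTable <- function(...) {
    pairs <- list(...)
    data.frame(gene_a = vapply(pairs, `[[`, character(1L), 1L),
               gene_b = vapply(pairs, `[[`, character(1L), 2L),
               stringsAsFactors = FALSE)
}

netFromEdges <- function(...) buildNetwork(edgeTable(...))

completeNet <- function(n, prefix = "g") {
    ids <- paste0(prefix, seq_len(n))
    idx <- t(combn(ids, 2L))
    buildNetwork(data.frame(gene_a = idx[, 1L], gene_b = idx[, 2L],
                            stringsAsFactors = FALSE))
}

# Independent nested-loop oracle for the crosstalk decomposition: the double
# sum over x X y on the dense adjacency, with links counted as unordered
# gene pairs. Deliberately naive; kept free of the package's sparse path.
oracleCrosstalk <- function(net, x, y, wx, wy = wx) {
    A <- as.matrix(adjacencyMatrix(net))
    g <- genes(net)
    x <- intersect(unique(x), g)
    y <- intersect(unique(y), g)
    lookup <- function(w, gene) {
        v <- w[gene]
        if (is.na(v)) 0 else as.numeric(v)
    }
    cval <- 0
    linkKeys <- character()
    deltaKeys <- character()
    for (gx in x) for (gy in y) {
        if (gx == gy) next
        if (A[gx, gy] == 1) {
            wxi <- lookup(wx, gx)
            wyj <- lookup(wy, gy)
            cval <- cval + wxi * wyj
            key <- paste(min(gx, gy), max(gx, gy))
            linkKeys <- c(linkKeys, key)
            if (wxi > 0 && wyj > 0) deltaKeys <- c(deltaKeys, key)
        }
    }
    list(c = cval, l = length(unique(linkKeys)),
         delta_l = length(unique(deltaKeys)))
}

# All permutations of a vector (tiny n only).
allPermutations <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in allPermutations(v[-i]))
            out <- c(out, list(c(v[i], rest)))
    out
}

# Random small test instance: an Erdos-Renyi-ish network built with base R
# plus random (possibly overlapping) gene sets and sparse random weights.
randomInstance <- function(seed, maxGenes = 50L, allowOverlap = TRUE) {
    set.seed(seed)
    n <- sample(6:maxGenes, 1L)
    ids <- sprintf("n%03d", seq_len(n))
    pairs <- t(combn(ids, 2L))
    keep <- runif(nrow(pairs)) < min(1, 3 / n + 0.05)
    if (!any(keep)) keep[sample.int(nrow(pairs), 3L)] <- TRUE
    net <- buildNetwork(data.frame(gene_a = pairs[keep, 1L],
                                   gene_b = pairs[keep, 2L],
                                   stringsAsFactors = FALSE))
    g <- genes(net)
    x <- sample(g, min(length(g), sample(2:8, 1L)))
    y <- if (allowOverlap && runif(1) < 0.5)
        sample(g, min(length(g), sample(2:8, 1L)))
    else sample(setdiff(g, x), min(length(setdiff(g, x)), sample(2:8, 1L)))
    wx <- setNames(ifelse(runif(length(g)) < 0.7, runif(length(g)), 0), g)
    wy <- setNames(ifelse(runif(length(g)) < 0.7, runif(length(g)), 0), g)
    list(net = net, x = x, y = y, wx = wx, wy = wy)
}
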