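test_that("degree binning follows the equal-count rule over the sorted degrees", {
    # 9 genes: the automatic rule caps the bin count at the gene count
    net9 <- completeNet(9)
    b <- makeDegreeBins(net9)
    expect_equal(b@nBins, 9L)
    expect_equal(as.integer(table(b@bins)), rep(1L, 9))

    # 8 same-degree genes, 4 requested bins -> 4 bins of 2
    ring8 <- netFromEdges(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
                          c("e", "f"), c("f", "g"), c("g", "h"), c("h", "a"))
    b4 <- makeDegreeBins(ring8, requested = 4)
    expect_equal(as.integer(table(b4@bins)), rep(2L, 4))

    # bins are contiguous over the degree-sorted order
    set.seed(5)
    net <- simulateNetwork(60, "powerlaw", gamma = 2.2, seed = 5)
    bb <- makeDegreeBins(net, maxBins = 5)
    d <- geneDegree(net)
    ord <- order(d, genes(net))
    expect_true(all(diff(bb@bins[ord]) >= 0))
    expect_error(makeDegreeBins(net9, requested = 100), "must lie in")
})

test_that("within-bin permutations are bin-respecting bijections", {
    net <- simulateNetwork(40, "powerlaw", gamma = 2.3, seed = 8)
    b <- makeDegreeBins(net, maxBins = 5)
    p1 <- permuteWithinBins(b, seed = 1)
    expect_identical(sort(p1), seq_along(b@bins))       # bijection
    expect_identical(b@bins[p1], b@bins)                # bin-preserving
    expect_identical(permuteWithinBins(b, seed = 1), p1) # reproducible
    # relabelling preserves the degree multiset exactly
    expect_identical(sort(unname(geneDegree(net)[p1])),
                     sort(unname(geneDegree(net))))

    # singleton bins are always fixed points
    path3 <- netFromEdges(c("A", "B"), c("B", "C"))
    bs <- makeDegreeBins(path3)  # 3 bins of 1
    expect_identical(permuteWithinBins(bs, seed = 3), 1:3)

    P <- makePermutations(b, 25, seed = 2)
    expect_identical(dim(P), c(40L, 25L))
    for (k in c(1, 13, 25))
        expect_identical(sort(P[, k]), seq_len(40L))
    expect_identical(makePermutations(b, 25, seed = 2), P)
})

test_that("one-bin permutations are uniform over the factorial arrangements", {
    # one bin of 3 genes: 6 arrangements, chi-square GOF on 3000 draws
    tri <- netFromEdges(c("A", "B"), c("B", "C"), c("A", "C"))
    b <- makeDegreeBins(tri, requested = 1)
    P <- makePermutations(b, 3000, seed = 77)
    id <- apply(P, 2, paste, collapse = "")
    counts <- table(id)
    expect_equal(length(counts), 6L)
    gof <- chisq.test(as.numeric(counts))
    expect_gt(gof$p.value, 1e-3)
})

test_that("null score means match exhaustive within-bin enumeration", {
    # 5-node toy, bins of sizes 2 and 3 -> 2! * 3! = 12 permutations
    net <- netFromEdges(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "E"),
                        c("A", "D"))
    g <- genes(net)
    b <- makeDegreeBins(net, requested = 2)
    w <- setNames(c(0.9, 0.7, 0.5, 0.3, 0.2), g)
    ws <- WeightSet(matrix(w, ncol = 1, dimnames = list(g, "s1")))
    x <- c("A", "B"); y <- c("C", "D")
    cobs <- crosstalkScore(net, x, y, w)$c

    # exhaustive enumeration, by composing all within-bin arrangements
    binIdx <- split(seq_along(g), b@bins)
    exactMA <- exactMU <- c()
    A <- as.matrix(adjacencyMatrix(net))
    for (pa in allPermutations(binIdx[[1]])) {
        for (pb in allPermutations(binIdx[[2]])) {
            perm <- integer(5)
            perm[binIdx[[1]]] <- pa
            perm[binIdx[[2]]] <- pb
            ma <- mu <- 0
            for (i in match(x, g)) for (j in match(y, g)) {
                ma <- ma + A[perm[i], perm[j]] * w[i] * w[j]
                mu <- mu + A[i, j] * w[perm[i]] * w[perm[j]]
            }
            exactMA <- c(exactMA, ma)
            exactMU <- c(exactMU, mu)
        }
    }
    for (model in c("MA", "MU")) {
        exact <- if (model == "MA") exactMA else exactMU
        samp <- nullScores(net, x, y, ws, "s1", model = model,
                           nPerm = 999, seed = 42, binning = b)
        se <- sd(exact) / sqrt(999)
        expect_lt(abs(mean(samp) - mean(exact)), 3 * se + 1e-12)
        # every sample is an attainable enumeration value
        expect_true(all(vapply(samp, function(s)
            any(abs(exact - s) < 1e-12), logical(1))))
    }
})

test_that("degenerate nulls are exact: invariant configurations give rho = 1", {
    # interaction null on a complete graph with one bin: relabelling is a
    # graph automorphism, so every sample equals the observed score
    k6 <- completeNet(6)
    g <- genes(k6)
    w <- setNames(runif(6, 0.3, 1), g)
    ws <- WeightSet(matrix(w, ncol = 1, dimnames = list(g, "s1")))
    b1 <- makeDegreeBins(k6, requested = 1)
    cobs <- crosstalkScore(k6, g[1:2], g[3:4], w)$c
    sampA <- nullScores(k6, g[1:2], g[3:4], ws, "s1", model = "MA",
                        nPerm = 199, seed = 9, binning = b1)
    expect_equal(sampA, rep(cobs, 199), tolerance = 1e-12)
    expect_equal(empiricalProb(cobs, sampA), 1)

    # weight null with constant weights within every bin is invariant on any
    # topology
    net <- simulateNetwork(30, "powerlaw", gamma = 2.4, seed = 13)
    b <- makeDegreeBins(net, requested = 3)
    wconst <- setNames(c(0.2, 0.5, 0.9)[b@bins], genes(net))
    wsc <- WeightSet(matrix(wconst, ncol = 1,
                            dimnames = list(genes(net), "s1")))
    gg <- genes(net)
    x <- gg[1:5]; y <- gg[6:10]
    cobs2 <- crosstalkScore(net, x, y, wconst)$c
    sampU <- nullScores(net, x, y, wsc, "s1", model = "MU",
                        nPerm = 199, seed = 10, binning = b)
    expect_equal(sampU, rep(cobs2, 199), tolerance = 1e-12)
    expect_equal(empiricalProb(cobs2, sampU), 1)
})

test_that("empirical probabilities use the add-one convention with >= ties", {
    expect_equal(empiricalProb(5, rep(1, 999)), 0.001)
    expect_equal(empiricalProb(5, c(rep(1, 995), rep(7, 4))), 0.005)
    expect_equal(empiricalProb(0, runif(99)), 1)
    # ties count towards the tail
    expect_equal(empiricalProb(3, c(3, 3, 1)), 0.75)
    expect_error(empiricalProb(1, numeric()), "no null samples")
})

test_that("Fisher combination is the product-tail formula", {
    expect_equal(fisherCombine(1, 1), 1)
    z <- 0.3 * 0.2
    expect_equal(fisherCombine(0.3, 0.2), z - z * log(z))
    # strictly increasing in the product, and never below it
    zs <- sort(runif(50, 1e-8, 1))
    ps <- fisherCombine(zs, 1)
    expect_true(all(diff(ps) > 0))
    expect_true(all(ps >= zs))
    expect_true(all(ps > 0 & ps <= 1))
    expect_error(fisherCombine(0, 0.5), "\\(0, 1\\]")
    expect_error(fisherCombine(0.5, 1.2), "\\(0, 1\\]")
    # agreement with the chi-square form of Fisher's method
    expect_equal(fisherCombine(0.01, 0.03),
                 pchisq(-2 * (log(0.01) + log(0.03)), df = 4,
                        lower.tail = FALSE))
})

test_that("summary score combines effect size and significance", {
    expect_equal(summaryScore(0, 0.5), 0)
    expect_equal(summaryScore(2, 1), 0)
    expect_equal(summaryScore(0.252, 1.4816e-5), -0.252 * log10(1.4816e-5))
    expect_error(summaryScore(-1, 0.5), "non-negative")
    expect_error(summaryScore(1, 0), "\\(0, 1\\]")
})

test_that("outcome classification thresholds each null at alpha", {
    expect_identical(classifyOutcome(0.001, 0.001), "both")
    expect_identical(classifyOutcome(0.5, 0.001), "MU_only")
    expect_identical(classifyOutcome(0.001, 0.5), "MA_only")
    expect_identical(classifyOutcome(0.5, 0.5), "neither")
    expect_identical(classifyOutcome(c(0.01, 0.02), c(0.01, 0.5), 0.01),
                     c("both", "neither"))
    expect_error(classifyOutcome(0.5, 0.5, alpha = 1.5), "alpha")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
    # P(K >= k) by direct summation of choose() terms
    exactUpper <- function(k, setSize, hitSize, N) {
        js <- k:min(setSize, hitSize)
        sum(choose(hitSize, js) * choose(N - hitSize, setSize - js)) /
            choose(N, setSize)
    }
    uni <- sprintf("u%03d", 1:100)
    set <- uni[1:5]
    hits <- uni[c(1, 2, 3, 20, 30, 40, 50, 60, 70, 80)]  # overlap 3
    expect_equal(enrichmentOverlap(set, hits, 100),
                 exactUpper(3, 5, 10, 100), tolerance = 1e-12)
    # zero overlap -> upper tail includes 0 -> p = 1
    expect_equal(enrichmentOverlap(uni[90:95], uni[1:10], 100), 1)
    # boundary: set = hits = universe
    expect_equal(enrichmentOverlap(uni, uni, 100), 1)
    expect_error(enrichmentOverlap(uni, uni[1:5], 50), "universe")
})

test_that("assessment completes records with reproducible probabilities", {
    sim <- simulateCrosstalkData(nGenes = 120, nSets = 6, setSize = 12,
                                 nPlanted = 1, seed = 21)
    scr <- screenPairs(sim$sets, sim$weights, sim$network, mode = "intra")
    r1 <- assessCrosstalks(scr, sim$network, sim$weights, nPerm = 99, seed = 5)
    r2 <- assessCrosstalks(scr, sim$network, sim$weights, nPerm = 99, seed = 5)
    expect_identical(r1, r2)
    validateCrosstalkRecords(r1)
    expect_true(all(diff(r1$s) <= 0))
    expect_true(all(r1$rho_a >= 1 / 100 & r1$rho_a <= 1))
    # the planted pair is ranked first
    expect_identical(unname(unlist(r1[1, c("set_x", "set_y")])),
                     unname(unlist(sim$truth[1, ])))
})

test_that("two seeds give rho values within binomial fluctuation", {
    sim <- simulateCrosstalkData(nGenes = 150, nSets = 8, setSize = 15,
                                 nPlanted = 0, backgroundRate = 0.3, seed = 31)
    scr <- screenPairs(sim$sets, sim$weights, sim$network, mode = "intra")
    n <- 399
    ra <- assessCrosstalks(scr, sim$network, sim$weights, nPerm = n, seed = 1)
    rb <- assessCrosstalks(scr, sim$network, sim$weights, nPerm = n, seed = 2)
    key <- function(r) paste(r$set_x, r$set_y)
    rb <- rb[match(key(ra), key(rb)), ]
    tol <- 3 * sqrt(ra$rho_a * (1 - ra$rho_a) / n) + 1e-9
    expect_gte(mean(abs(ra$rho_a - rb$rho_a) <= tol), 0.95)
    tolu <- 3 * sqrt(ra$rho_u * (1 - ra$rho_u) / n) + 1e-9
    expect_gte(mean(abs(ra$rho_u - rb$rho_u) <= tolu), 0.95)
})
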