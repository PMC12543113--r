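test_that("pair preparation applies the scenario overlap rules", {
    pp <- preparePair(c("A", "B", "C"), c("B", "D"), "intra")
    expect_identical(pp$x, c("A", "C"))
    expect_identical(pp$y, "D")
    expect_false(pp$skip)

    # cell types are expected to share genes: inter mode keeps the overlap
    pp2 <- preparePair(c("A", "B"), c("B", "C"), "inter")
    expect_identical(pp2$x, c("A", "B"))
    expect_identical(pp2$y, c("B", "C"))

    pp3 <- preparePair(c("A", "B"), c("A", "B"), "intra")
    expect_true(pp3$skip)
    expect_error(preparePair(character(), "A", "intra"), "non-empty")
})

test_that("crosstalk score matches hand-computed single-edge cases", {
    net <- netFromEdges(c("A", "B"))
    cs <- crosstalkScore(net, "A", "B", c(A = 0.5, B = 0.4))
    expect_equal(cs$c, 0.2)
    expect_equal(cs$delta_l, 1L)
    expect_equal(cs$l, 1L)
    expect_identical(cs$genes_x, "A")
    expect_equal(cs$wsum_x, 0.5)

    # zero weight on one endpoint: the link exists but is not altered
    cs0 <- crosstalkScore(net, "A", "B", c(A = 0.5, B = 0))
    expect_equal(cs0$c, 0)
    expect_equal(cs0$delta_l, 0L)
    expect_equal(cs0$l, 1L)

    v <- netFromEdges(c("A", "C"), c("B", "C"))
    cs2 <- crosstalkScore(v, c("A", "B"), "C", c(A = 1, B = 1, C = 1))
    expect_equal(cs2$c, 2)
    expect_equal(cs2$delta_l, 2L)
    expect_equal(cs2$l, 2L)
})

test_that("crosstalk score equals the nested-loop oracle on random instances", {
    for (seed in 1:40) {
        inst <- randomInstance(seed)
        cs <- crosstalkScore(inst$net, inst$x, inst$y, inst$wx, inst$wy)
        or <- oracleCrosstalk(inst$net, inst$x, inst$y, inst$wx, inst$wy)
        expect_equal(cs$c, or$c, tolerance = 1e-12)
        expect_identical(cs$l, or$l)
        expect_identical(cs$delta_l, or$delta_l)
        # contributing weights sum to the reported norms
        expect_equal(cs$wsum_x, sum(inst$wx[cs$genes_x]), tolerance = 1e-12)
        expect_equal(cs$wsum_y, sum(inst$wy[cs$genes_y]), tolerance = 1e-12)
    }
})

test_that("crosstalk score is symmetric and monotone", {
    set.seed(99)
    for (rep in 1:10) {
        inst <- randomInstance(rep + 500, allowOverlap = FALSE)
        w <- inst$wx
        a <- crosstalkScore(inst$net, inst$x, inst$y, w)
        b <- crosstalkScore(inst$net, inst$y, inst$x, w)
        expect_equal(a$c, b$c, tolerance = 1e-12)
        expect_identical(a$l, b$l)
        expect_identical(a$delta_l, b$delta_l)

        # increasing a contributing gene's weight never decreases c
        if (length(a$genes_x)) {
            w2 <- w
            w2[a$genes_x[1L]] <- min(1, w2[a$genes_x[1L]] + 0.3)
            expect_gte(crosstalkScore(inst$net, inst$x, inst$y, w2)$c, a$c)
        }
    }

    # adding an edge between weighted members never decreases c or delta_l
    net <- netFromEdges(c("A", "B"), c("C", "D"))
    w <- c(A = 0.5, B = 0.5, C = 0.5, D = 0.5)
    before <- crosstalkScore(net, c("A", "C"), c("B", "D"), w)
    net2 <- netFromEdges(c("A", "B"), c("C", "D"), c("A", "D"))
    after <- crosstalkScore(net2, c("A", "C"), c("B", "D"), w)
    expect_gte(after$c, before$c)
    expect_gte(after$delta_l, before$delta_l)
})

test_that("saturation is the altered-link fraction with guarded edge cases", {
    expect_equal(saturation(0, 7), 0)
    expect_equal(saturation(3, 4), 0.75)
    expect_equal(saturation(0, 0), 0)
    expect_error(saturation(5, 4), "exceeds")
    expect_error(saturation(-1, 4), "non-negative")
})

test_that("screening applies the published pre-filters", {
    # path: A-B-C-D-E plus chord B-E and component F-G; sets over it
    net <- netFromEdges(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E"),
                        c("B", "E"), c("F", "G"))
    sets <- list(S1 = c("A", "B", "H"),       # only 2 networked genes
                 S2 = c("A", "B", "C"),
                 S3 = c("C", "D", "E"),
                 S4 = c("E", "F", "G"))
    w <- WeightSet(list(s1 = c(A = 1, B = 0.5, C = 0.5, D = 0.5, E = 0.5,
                               F = 0, G = 0)))
    scr <- screenPairs(sets, w, net, mode = "intra")
    # S1 dropped for size (H is off-network); S4 has networked members and E
    # carries weight
    expect_equal(scr$log$sets_dropped_size, 1L)
    expect_false("S1" %in% names(scr$testedSets))
    # all retained pairs have C > 0; S3/S4 (no links after exclusion) is out
    expect_gte(nrow(scr$records), 1L)
    expect_true(all(scr$records$c > 0))
    expect_true(all(scr$records$delta_l <= scr$records$l))
    expect_gte(scr$log$pairs_dropped_zero_score, 1L)

    # a set with all-zero weight is dropped
    w0 <- WeightSet(list(s1 = c(A = 1, B = 0.5, C = 0.5, D = 0.5, E = 0,
                                F = 0, G = 0)))
    scr0 <- screenPairs(sets, w0, net, mode = "intra")
    expect_false("S4" %in% names(scr0$testedSets))
    expect_equal(scr0$log$sets_dropped_zero_weight, 1L)

    # fewer than two surviving sets is an error
    expect_error(screenPairs(sets[1:2], w, net, mode = "intra"),
                 "nothing to screen")
})

test_that("inter-mode screening enumerates cross-source pairs only", {
    net <- completeNet(9)
    g <- genes(net)
    sets <- GeneSetCollection(
        list(ct1 = g[1:4], ct2 = g[4:6], ct3 = g[6:9]),
        provenance = c("ct1", "ct2", "ct3"))
    w <- WeightSet(lapply(setNames(nm = c("ct1", "ct2", "ct3")),
                          function(s) setNames(runif(9, 0.2, 1), g)))
    scr <- screenPairs(sets, w, net, mode = "inter")
    expect_equal(nrow(scr$records), 3L)  # 3 cell types -> 3 pairs max
    expect_gte(scr$log$pairs_with_overlap, 1L)

    # 2 sources -> 1 pair
    scr2 <- screenPairs(GeneSetCollection(list(ct1 = g[1:4], ct2 = g[5:8]),
                                          provenance = c("ct1", "ct2")),
                        w, net, mode = "inter")
    expect_equal(nrow(scr2$records), 1L)
})

test_that("mediator sets collect a cell type's contributing genes", {
    rec <- data.frame(
        set_x = c("cancer", "cancer", "Bcell"),
        set_y = c("CAF", "Tcell", "cancer"),
        genes_x = c("MDK;MFGE8", "LAMP1", "CD19"),
        genes_y = c("ITGB1", "CD3", "RPSA"),
        outcome = c("MU_only", "neither", "both"),
        stringsAsFactors = FALSE)
    expect_identical(buildMediatorSet(rec, "cancer", partner = "CAF"),
                     c("MDK", "MFGE8"))
    # across all partners, both sides and only significant records count
    expect_identical(buildMediatorSet(rec, "cancer"),
                     c("MDK", "MFGE8", "RPSA"))
    expect_identical(buildMediatorSet(rec, "cancer", rule = "both"), "RPSA")
    expect_error(buildMediatorSet(rec, "Tcell"), "no significant")
})
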