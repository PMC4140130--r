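test_that("discretizeFeature maps values to the documented bins", {
    expect_identical(discretizeFeature(rep(2.5, 8)), rep(1L, 8))
    expect_identical(
        discretizeFeature(c(0, 0, 0, 10), "zero_vs_positive"),
        c(0L, 0L, 0L, 1L))
    expect_error(discretizeFeature(numeric()), "empty")
    ## explicit boundary handling: mu +/- sigma fall in the outer bins
    v <- c(0, 5, 10)   # mu = 5, sigma = 5
    expect_identical(discretizeFeature(v), c(0L, 1L, 2L))
})

test_that("three-state bins of a normal sample match the CDF", {
    set.seed(101)
    x <- rnorm(10000)
    b <- discretizeFeature(x)
    p <- tabulate(b + 1L, 3L) / length(x)
    expect_equal(p[1], pnorm(-1), tolerance = 0.02)
    expect_equal(p[2], pnorm(1) - pnorm(-1), tolerance = 0.03)
    expect_equal(p[3], pnorm(-1), tolerance = 0.02)
})

test_that("cramersV agrees with closed forms on 2x2 tables", {
    expect_identical(cramersV(matrix(10, 2, 2)), 0)
    expect_identical(cramersV(matrix(c(20, 0, 0, 20), 2)), 1)
    expect_equal(cramersV(matrix(c(30, 10, 10, 30), 2)),
                 cramer2x2(30, 10, 10, 30), tolerance = 1e-12)
    set.seed(7)
    for (i in 1:20) {
        t <- matrix(rpois(4, 12), 2)
        if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
        expect_equal(cramersV(t),
                     cramer2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                     tolerance = 1e-12)
    }
})

test_that("cramersV stays in [0,1], ignores empty margins, and is permutation invariant", {
    set.seed(21)
    for (i in 1:20) {
        t <- matrix(rpois(6, 5), 3)
        v <- cramersV(t)
        expect_gte(v, 0); expect_lte(v, 1)
        expect_equal(cramersV(t[sample(3), sample(2)]), v,
                     tolerance = 1e-12)
    }
    ## zero-margin rows are dropped before computing
    t0 <- rbind(c(10, 2), c(0, 0), c(3, 9))
    expect_equal(cramersV(t0), cramersV(t0[c(1, 3), ]))
    ## a single nonempty row has no association
    expect_identical(cramersV(matrix(c(5, 7), 1)), 0)
})

test_that("filterFeatures keeps V >= threshold, preserving feature order", {
    sim <- simulateDiseaseData(smallSpec(seed = 2L))
    mat <- encodeGenes(c(sim$positives, sim$negatives), sim$network,
                       sim$corpus,
                       labels = c(rep(1L, 10L), rep(0L, 90L)))
    all <- filterFeatures(mat, threshold = 0)
    expect_identical(all$features, termIds(mat))
    none <- filterFeatures(mat, threshold = 1.01)
    expect_length(none$features, 0L)
    some <- filterFeatures(mat, threshold = 0.1)
    expect_identical(some$features,
                     termIds(mat)[some$V >= 0.1])
    ## boundary rule: a feature whose V equals the threshold is kept
    pick <- names(some$V)[some$V > 0][1]
    exact <- filterFeatures(mat, threshold = unname(some$V[pick]))
    expect_true(pick %in% exact$features)
})

test_that("planted features dominate the Cramér ranking across seeds", {
    wins <- 0L
    for (s in 1:10) {
        sim <- simulateDiseaseData(smallSpec(seed = s))
        mat <- encodeGenes(c(sim$positives, sim$negatives),
                           sim$network, sim$corpus,
                           labels = c(rep(1L, 10L), rep(0L, 90L)))
        V <- filterFeatures(mat)$V
        medOther <- median(V[setdiff(names(V), sim$plantedTerms)])
        wins <- wins +
            all(V[sim$plantedTerms] > medOther)
    }
    expect_gte(wins, 6L)   # majority criterion over 10 seeds
})

test_that("a null run filters out some features at the 0.1 threshold", {
    keptFrac <- vapply(1:10, function(s) {
        sim <- simulateDiseaseData(smallSpec(seed = 100L + s,
                                             signal = 0))
        mat <- encodeGenes(c(sim$positives, sim$negatives),
                           sim$network, sim$corpus,
                           labels = c(rep(1L, 10L), rep(0L, 90L)))
        f <- filterFeatures(mat, threshold = 0.1)
        length(f$features) / length(termIds(mat))
    }, numeric(1))
    expect_true(all(keptFrac < 1))   # survivors strictly fewer than total
})
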