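test_that("geneNeighborhood returns the closed neighborhood", {
    fix <- toyFixture()
    expect_setequal(geneNeighborhood("hub", fix$network),
                    c("hub", "l1", "l2", "l3", "l4"))
    expect_identical(geneNeighborhood("l5", fix$network), "l5")
    expect_identical(geneNeighborhood("absent", fix$network),
                     "absent")
    ## open-neighborhood variant drops the gene itself
    expect_setequal(geneNeighborhood("l1", fix$network, open = TRUE),
                    "hub")
    expect_length(geneNeighborhood("l5", fix$network, open = TRUE), 0L)
})

test_that("|closed neighborhood| = degree + 1 on a random graph", {
    set.seed(9)
    g <- igraph::sample_gnp(40, 0.1)
    igraph::V(g)$name <- paste0("v", 1:40)
    deg <- igraph::degree(g)
    for (v in igraph::V(g)$name)
        expect_length(geneNeighborhood(v, g), deg[[v]] + 1L)
})

test_that("hypergeomUpperTail matches the exact combinatorial sum", {
    expect_identical(hypergeomUpperTail(20, 5, 6, 0), 1)
    expect_identical(hypergeomUpperTail(10, 10, 4, 4), 1)  # N = M forces m = n
    expect_equal(hypergeomUpperTail(20, 5, 6, 3),
                 exactUpperTail(20, 5, 6, 3), tolerance = 1e-14)
    ## spot lattice at unit-test scale; the full N <= 30 sweep runs in
    ## the acceptance suite
    for (N in c(5L, 9L, 12L)) {
        for (M in 0:N) for (n in 0:N) for (m in 0:min(n, M)) {
            p <- hypergeomUpperTail(N, M, n, m)
            e <- exactUpperTail(N, M, n, m)
            expect_equal(p, e, tolerance = 1e-12)
        }
    }
    expect_error(hypergeomUpperTail(10, 11, 3, 1), "invalid")
    expect_error(hypergeomUpperTail(10, 5, 3, 4), "invalid")
})

test_that("the tail probability is monotone in m", {
    for (m in 1:6)
        expect_lte(hypergeomUpperTail(20, 8, 6, m),
                   hypergeomUpperTail(20, 8, 6, m - 1))
})

test_that("enrichmentScore is -log10 of the neighborhood tail", {
    fix <- toyFixture()
    ## hub's closed neighborhood {hub,l1..l4}: T1 hits m=3 of M=3
    p <- exactUpperTail(6, 3, 5, 3)
    expect_equal(enrichmentScore("hub", "T1", fix$network,
                                 fix$corpus), -log10(p))
    ## no neighborhood member annotated: score 0
    expect_identical(enrichmentScore("l5", "T1", fix$network,
                                     fix$corpus), 0)
    ## tail of exactly 10^-k maps to k
    expect_equal(-log10(1e-3), 3)
    expect_error(enrichmentScore("nope", "T1", fix$network,
                                 fix$corpus), "background")
})

test_that("scores are capped and finite", {
    ## a huge -log10 p cannot occur at toy sizes; exercise the cap arg
    fix <- toyFixture()
    s <- enrichmentScore("hub", "T1", fix$network, fix$corpus,
                         cap = 0.1)
    expect_identical(s, 0.1)
})

test_that("encodeGenes lays out genes x (GO ++ KEGG) deterministically", {
    fix <- toyFixture()
    genes <- c("hub", "l3", "l5")
    m <- encodeGenes(genes, fix$network, fix$corpus)
    expect_identical(geneIds(m), genes)
    expect_identical(termIds(m), c("T1", "T2", "P1"))
    expect_true(all(is.finite(scoreMatrix(m))) &&
                all(scoreMatrix(m) >= 0))
    ## row permutation equivariance
    m2 <- encodeGenes(rev(genes), fix$network, fix$corpus)
    expect_identical(scoreMatrix(m2), scoreMatrix(m)[3:1, ])
    ## per-entry agreement with the scalar path
    for (g in genes) for (t in termIds(m))
        expect_equal(scoreMatrix(m)[g, t],
                     enrichmentScore(g, t, fix$network, fix$corpus))
})

test_that("encodeGenes handles empty input and foreign genes", {
    fix <- toyFixture()
    m0 <- encodeGenes(character(), fix$network, fix$corpus)
    expect_equal(dim(scoreMatrix(m0)), c(0L, 3L))
    expect_warning(m1 <- encodeGenes(c("hub", "alien"), fix$network,
                                     fix$corpus,
                                     labels = c(1L, 0L)),
                   "dropped")
    expect_identical(geneIds(m1), "hub")
    expect_identical(unname(geneLabels(m1)), 1L)
})
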