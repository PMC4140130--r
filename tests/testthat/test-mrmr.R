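test_that("mutualInformation matches direct summation", {
    expect_identical(mutualInformation(rep(1L, 30), rep(0:2, 10)), 0)
    expect_equal(mutualInformation(rep(0:1, 50), rep(0:1, 50)), 1)
    expect_error(mutualInformation(1:3, 1:4), "length")
    set.seed(31)
    for (i in 1:10) {
        x <- sample(0:2, 60, replace = TRUE)
        y <- sample(0:1, 60, replace = TRUE)
        expect_equal(mutualInformation(x, y), miOracle(x, y),
                     tolerance = 1e-12)
    }
})

## binary matrices + the zero_vs_positive scheme make the package see
## exactly the discrete values the oracle sees
binaryMatrix <- function(n, p, labels) {
    m <- matrix(rbinom(n * p, 1, 0.4), n,
                dimnames = list(paste0("g", seq_len(n)),
                                paste0("T", seq_len(p))))
    EnrichmentMatrix(m, rep("GO", p), labels)
}

test_that("a single survivor yields singleton lists", {
    set.seed(5)
    x <- binaryMatrix(20, 3, rep(0:1, 10))
    r <- rankFeatures(x, "T2", scheme = "zero_vs_positive")
    expect_identical(maxrelList(r), "T2")
    expect_identical(mrmrList(r), "T2")
    expect_error(rankFeatures(x, character()), "lower the")
})

test_that("mRMR penalizes redundant duplicates", {
    set.seed(8)
    lab <- rep(0:1, each = 20)
    strong <- as.integer(lab == 1L)
    strong[c(2, 39)] <- 1L - strong[c(2, 39)]   # strong but imperfect
    weak <- as.integer(runif(40) < ifelse(lab == 1L, 0.7, 0.3))
    m <- cbind(A = strong, B = strong, C = weak)
    rownames(m) <- paste0("g", 1:40)
    x <- EnrichmentMatrix(m, rep("GO", 3), lab)
    r <- rankFeatures(x, c("A", "B", "C"),
                      scheme = "zero_vs_positive")
    ## MaxRel ranks the duplicates 1st-2nd
    expect_setequal(maxrelList(r)[1:2], c("A", "B"))
    ## mRMR promotes the independent weaker feature to 2nd place
    expect_identical(mrmrList(r)[1], "A")
    expect_identical(mrmrList(r)[2], "C")
})

test_that("rankFeatures equals the brute-force greedy MID oracle", {
    set.seed(17)
    for (rep in 1:8) {
        n <- sample(20:60, 1)
        p <- sample(3:8, 1)
        lab <- rbinom(n, 1, 0.5)
        if (length(unique(lab)) < 2) lab[1:2] <- 0:1
        x <- binaryMatrix(n, p, lab)
        r <- rankFeatures(x, paste0("T", 1:p),
                          scheme = "zero_vs_positive")
        oracle <- bruteMrmr(scoreMatrix(x), lab)
        expect_identical(mrmrList(r), colnames(scoreMatrix(x))[oracle])
    }
})

test_that("both lists are deterministic and share their first element", {
    set.seed(23)
    x <- binaryMatrix(40, 6, rbinom(40, 1, 0.5))
    r1 <- rankFeatures(x, paste0("T", 1:6),
                       scheme = "zero_vs_positive")
    r2 <- rankFeatures(x, paste0("T", 1:6),
                       scheme = "zero_vs_positive")
    expect_identical(mrmrList(r1), mrmrList(r2))
    expect_identical(maxrelList(r1), maxrelList(r2))
    expect_identical(mrmrList(r1)[1], maxrelList(r1)[1])
    ## truncation to k applies to both lists
    r3 <- rankFeatures(x, paste0("T", 1:6), k = 4L,
                       scheme = "zero_vs_positive")
    expect_length(mrmrList(r3), 4L)
    expect_length(maxrelList(r3), 4L)
})

test_that("planted terms rank near the top with signal, centrally without", {
    relRanks <- function(spec) {
        sim <- simulateDiseaseData(spec)
        nPos <- length(sim$positives)
        nNeg <- length(sim$negatives)
        mat <- encodeGenes(c(sim$positives, sim$negatives),
                           sim$network, sim$corpus,
                           labels = c(rep(1L, nPos), rep(0L, nNeg)))
        r <- rankFeatures(mat, termIds(mat), k = 10L)
        rnk <- rank(-featureRelevance(r), ties.method = "average")
        rnk[sim$plantedTerms] / length(rnk)
    }
    ## reference benchmark: 20 planted among 340 features
    sig <- unlist(lapply(1:3, function(s)
        relRanks(syntheticSpec(seed = s))))
    expect_lte(median(sig), 0.10)   # median planted rank in top decile
    nul <- unlist(lapply(11:15, function(s)
        relRanks(smallSpec(seed = s, signal = 0))))
    ## no systematic top-ranking under the null
    expect_gt(median(nul), 0.20)
})
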