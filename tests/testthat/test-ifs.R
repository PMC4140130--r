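test_that("confusionMetrics implements the four formulas", {
    perfect <- confusionMetrics(TP = 39, TN = 195, FP = 0, FN = 0)
    expect_equal(perfect, c(ACC = 1, SP = 1, SN = 1, MCC = 1))
    worst <- confusionMetrics(TP = 0, TN = 0, FP = 7, FN = 3)
    expect_equal(worst[["ACC"]], 0)
    expect_equal(worst[["MCC"]], -1)
    direct <- confusionMetrics(TP = 30, FN = 9, TN = 160, FP = 35)
    expect_equal(direct, metricsOracle(TP = 30, TN = 160, FP = 35,
                                       FN = 9), tolerance = 1e-12)
})

test_that("metric identities hold on random confusion counts", {
    set.seed(77)
    for (i in 1:200) {
        cc <- rpois(4, 20)
        m <- confusionMetrics(cc[1], cc[2], cc[3], cc[4])
        expect_gte(m[["MCC"]], -1); expect_lte(m[["MCC"]], 1)
        P <- cc[1] + cc[4]; N <- cc[2] + cc[3]
        if (P > 0 && N > 0)
            expect_equal(m[["ACC"]],
                         (m[["SN"]] * P + m[["SP"]] * N) / (P + N),
                         tolerance = 1e-12)
        ## class swap flips the MCC sign at most
        sw <- confusionMetrics(cc[2], cc[1], cc[4], cc[3])
        expect_equal(abs(sw[["MCC"]]), abs(m[["MCC"]]),
                     tolerance = 1e-12)
    }
    ## denominator-zero convention: all-one-class predictions
    expect_equal(confusionMetrics(0, 10, 0, 5)[["MCC"]], 0)
    expect_equal(confusionMetrics(0, 0, 0, 0)[["ACC"]], 0)
})

test_that("stratified folds balance classes and cover every sample once", {
    lab <- c(rep(1L, 39), rep(0L, 195))
    foldId <- enrichIFS:::stratifiedFolds(lab, 10L, seed = 4L)
    expect_length(foldId, 234L)
    sizes <- tabulate(foldId, 10L)
    expect_true(all(sizes %in% c(23L, 24L)))
    posPerFold <- tabulate(foldId[lab == 1L], 10L)
    expect_true(all(posPerFold %in% c(3L, 4L)))
    ## deterministic under seed
    expect_identical(foldId,
                     enrichIFS:::stratifiedFolds(lab, 10L, 4L))
})

trivialMatrix <- function(n = 40, sep = 10) {
    lab <- rep(c(1L, 0L), each = n / 2)
    m <- cbind(S = ifelse(lab == 1L, sep, 0) + rnorm(n, sd = 0.01),
               J = rnorm(n))
    rownames(m) <- paste0("g", seq_len(n))
    m[m < 0] <- 0
    EnrichmentMatrix(m, c("GO", "GO"), lab)
}

test_that("cross-validation is perfect on a separable toy and pools all samples", {
    set.seed(12)
    x <- trivialMatrix()
    cc <- crossValidate(x, c("S", "J"), folds = 10L, seed = 1L)
    expect_equal(sum(cc), 40)
    expect_equal(cc[["FP"]] + cc[["FN"]], 0)
    expect_error(crossValidate(x, "S", folds = 30L), "per fold")
})

test_that("label permutation drives pooled MCC toward zero", {
    set.seed(99)
    mccs <- vapply(1:20, function(s) {
        x <- trivialMatrix(n = 60)
        geneLabels(x) <- sample(unname(geneLabels(x)))
        cc <- crossValidate(x, c("S", "J"), folds = 10L, seed = s)
        confusionMetrics(cc[["TP"]], cc[["TN"]], cc[["FP"]],
                         cc[["FN"]])[["MCC"]]
    }, numeric(1))
    expect_true(mean(abs(mccs) <= 0.25) >= 0.9)
})

test_that("the classifier separates a linear toy and is deterministic", {
    set.seed(3)
    n <- 30
    lab <- rep(c(1L, 0L), each = n / 2)
    x <- cbind(a = lab * 4 + rnorm(n, sd = 0.1),
               b = rnorm(n))
    clf <- trainClassifier(x, lab)
    expect_equal(predictClassifier(clf, x), lab)
    clf2 <- trainClassifier(x, lab)
    expect_identical(predictClassifier(clf2, x),
                     predictClassifier(clf, x))
    expect_error(trainClassifier(x, rep(1L, n)), "both classes")
})

test_that("duplicating every sample leaves the decision rule unchanged", {
    set.seed(14)
    n <- 24
    lab <- rep(c(1L, 0L), each = n / 2)
    x <- cbind(a = lab * 2 + rnorm(n), b = rnorm(n))
    probe <- cbind(a = seq(-2, 4, length.out = 25),
                   b = seq(-2, 2, length.out = 25))
    clf1 <- trainClassifier(x, lab)
    clf2 <- trainClassifier(rbind(x, x), c(lab, lab))
    ## identical up to solver tolerance: probe points on the decision
    ## boundary may flip
    agree <- mean(predictClassifier(clf1, probe) ==
                  predictClassifier(clf2, probe))
    expect_gte(agree, 0.96)
})

test_that("runIFS records the curve and extracts the first-maximum prefix", {
    set.seed(6)
    x <- trivialMatrix()
    one <- runIFS(x, "S", folds = 5L, seed = 2L)
    expect_equal(nrow(ifsCurve(one)), 1L)
    expect_equal(optimalSize(one), 1L)

    res <- runIFS(x, c("S", "J"), folds = 5L, seed = 2L)
    cv <- ifsCurve(res)
    expect_equal(nrow(cv), 2L)
    ## the perfectly separating feature alone reaches MCC 1, so the
    ## first maximum is the singleton prefix even though the pair ties
    expect_equal(maxMCC(res), 1)
    expect_equal(optimalSize(res), 1L)
    expect_identical(optimalFeatures(res), "S")
    ## optimal size is always the first index attaining the maximum
    expect_equal(optimalSize(res),
                 cv$i[[which(cv$MCC == max(cv$MCC))[1]]])
    ## same seed, same curve
    res2 <- runIFS(x, c("S", "J"), folds = 5L, seed = 2L)
    expect_identical(ifsCurve(res2), ifsCurve(res))
    expect_error(runIFS(x, character()), "empty")
})
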