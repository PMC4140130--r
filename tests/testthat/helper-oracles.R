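## Independent oracles used to pin down expected values. These are
## deliberately naive implementations that share no code with the
## package internals.

## Hypergeometric upper tail by direct summation of the defining
## formula. For N <= 30 every binomial coefficient and every partial
## product is an integer below 2^53, so the sum is exact rational
## arithmetic carried in doubles.
exactUpperTail <- function(N, M, n, m) {
    ks <- seq(from = m, to = min(n, M), length.out = max(0, min(n, M) - m + 1))
    if (!length(ks)) return(0)
    sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

## Closed-form Cramer's V for a 2x2 table [[a,b],[c,d]].
cramer2x2 <- function(a, b, c, d) {
    abs(a * d - b * c) /
        sqrt((a + b) * (c + d) * (a + c) * (b + d))
}

## Plug-in mutual information (bits) by direct summation over the
## joint table.
miOracle <- function(x, y) {
    tab <- table(x, y)
    n <- sum(tab)
    out <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
        pxy <- tab[i, j] / n
        if (pxy > 0)
            out <- out + pxy *
                log2(pxy / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
    }
    out
}

## Brute-force greedy mRMR (MID criterion) over an already-discrete
## feature matrix: recomputes every mutual information from scratch at
## every step. Ties broken by column order.
bruteMrmr <- function(disc, labels, k = ncol(disc)) {
    p <- ncol(disc)
    rel <- vapply(seq_len(p), function(j) miOracle(disc[, j], labels),
                  numeric(1))
    selected <- which.max(rel)
    while (length(selected) < min(k, p)) {
        rest <- setdiff(seq_len(p), selected)
        crit <- vapply(rest, function(j) {
            red <- mean(vapply(selected, function(s)
                miOracle(disc[, j], disc[, s]), numeric(1)))
            rel[j] - red
        }, numeric(1))
        selected <- c(selected, rest[which.max(crit)])
    }
    selected
}

## Direct-formula classification metrics, spreadsheet style.
metricsOracle <- function(TP, TN, FP, FN) {
    div <- function(a, b) if (b == 0) 0 else a / b
    c(ACC = div(TP + TN, TP + TN + FP + FN),
      SP = div(TN, TN + FP),
      SN = div(TP, TP + FN),
      MCC = div(TP * TN - FP * FN,
                sqrt(TN + FN) * sqrt(TN + FP) * sqrt(TP + FN) *
                    sqrt(TP + FP)))
}

## Tiny deterministic fixture shared by several files: a 6-gene star
## network plus a 3-term corpus.
toyFixture <- function() {
    net <- igraph::graph_from_literal(
        hub - l1, hub - l2, hub - l3, hub - l4, l5)
    corpus <- AnnotationCorpus(
        termGenes = list(
            T1 = c("hub", "l1", "l2"),
            T2 = c("l3", "l5"),
            P1 = c("hub", "l4", "l5")),
        termNamespace = c(T1 = "GO", T2 = "GO", P1 = "KEGG"),
        background = c("hub", "l1", "l2", "l3", "l4", "l5"))
    list(network = net, corpus = corpus)
}

## Small synthetic spec for fast pipeline-level tests.
smallSpec <- function(seed, signal = 0.5) {
    syntheticSpec(nGenes = 100L, nGoTerms = 60L, nKeggTerms = 10L,
                  edgeProb = 0.05, nPositives = 10L,
                  nInformativeTerms = 10L, signalStrength = signal,
                  baseAnnotProb = 0.05, seed = seed)
}

smallConfig <- function(seed) {
    runConfig(seed = seed, negativeRatio = 5L, nSplits = 2L,
              maxRankedFeatures = 30L, cvFolds = 5L)
}
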