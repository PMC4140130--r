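#' @include AllClasses.R accessors.R
NULL

#' Discretize a continuous feature
#'
#' Two schemes are offered for turning continuous enrichment scores
#' into the discrete states used by both the Cramér filter and the
#' mutual-information machinery, so the two selection stages see the
#' same view of the data:
#'
#' * `"three_state_mean_sd"` (default, the canonical mRMR
#'   preprocessing): bins (-Inf, mu-sigma], (mu-sigma, mu+sigma),
#'   \[mu+sigma, Inf) mapped to states 0/1/2, with mu and sigma
#'   computed over the supplied values (i.e., over the current
#'   dataset).
#' * `"zero_vs_positive"`: state 1 for strictly positive values, 0
#'   otherwise — natural for zero-inflated enrichment scores.
#'
#' Constant vectors map to the single middle state.
#'
#' @param values numeric vector (non-empty).
#' @param scheme `"three_state_mean_sd"` or `"zero_vs_positive"`.
#' @return integer vector of bin states.
#' @export
discretizeFeature <- function(values,
                              scheme = c("three_state_mean_sd",
                                         "zero_vs_positive")) {
    scheme <- match.arg(scheme)
    if (!length(values)) stop("cannot discretize an empty vector")
    if (scheme == "zero_vs_positive")
        return(as.integer(values > 0))
    mu <- mean(values)
    sig <- stats::sd(values)
    if (!is.finite(sig) || sig == 0)
        return(rep(1L, length(values)))
    ifelse(values <= mu - sig, 0L,
           ifelse(values >= mu + sig, 2L, 1L))
}

#' Cramér's V of a contingency table
#'
#' V = sqrt(chi^2 / (n (min(r, c) - 1))) with the plain Pearson
#' chi-square statistic (no continuity correction — the coefficient is
#' used as a ranking/filtering device, not an inference). Rows and
#' columns with zero marginals are dropped first; if fewer than two
#' non-empty rows or columns remain the association is undefined and V
#' is 0.
#'
#' @param table non-negative integer matrix of counts (feature bins by
#'   classes).
#' @return V in \[0, 1\].
#' @examples
#' cramersV(matrix(c(20, 0, 0, 20), 2))   # perfect association: 1
#' @export
cramersV <- function(table) {
    table <- as.matrix(table)
    n <- sum(table)
    if (n < 1) stop("contingency table must have positive total")
    table <- table[rowSums(table) > 0, , drop = FALSE]
    table <- table[, colSums(table) > 0, drop = FALSE]
    if (nrow(table) < 2L || ncol(table) < 2L) return(0)
    expected <- outer(rowSums(table), colSums(table)) / n
    chi2 <- sum((table - expected)^2 / expected)
    v2 <- chi2 / (n * (min(dim(table)) - 1L))
    sqrt(max(0, min(1, v2)))
}

#' Filter features by Cramér association with the class label
#'
#' Stage-1 selection: each feature is discretized (see
#' [discretizeFeature()]), cross-tabulated against the binary label,
#' and kept iff its Cramér's V is at least `threshold` (a coefficient
#' exactly equal to the threshold is kept; only strictly lower values
#' are excluded). Feature order is preserved.
#'
#' @param x an [EnrichmentMatrix-class] with binary labels on every
#'   gene.
#' @param threshold minimum Cramér's V (default 0.1).
#' @param scheme discretization scheme, see [discretizeFeature()].
#' @return a list with `features` (surviving term ids, in feature
#'   order) and `V` (named numeric, the coefficient of every feature).
#' @export
filterFeatures <- function(x, threshold = 0.1,
                           scheme = "three_state_mean_sd") {
    stopifnot(is(x, "EnrichmentMatrix"))
    lab <- geneLabels(x)
    if (any(is.na(lab)))
        stop("all genes must carry a binary label")
    m <- scoreMatrix(x)
    V <- vapply(seq_len(ncol(m)), function(j) {
        b <- discretizeFeature(m[, j], scheme)
        cramersV(table(factor(b), factor(lab)))
    }, numeric(1))
    names(V) <- colnames(m)
    list(features = colnames(m)[V >= threshold], V = V)
}
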