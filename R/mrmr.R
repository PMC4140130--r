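#' @include AllClasses.R cramer.R
NULL

#' Mutual information of two discrete vectors
#'
#' Plug-in estimate in bits: I(X;Y) = sum p(x,y) log2( p(x,y) / (p(x)
#' p(y)) ), with 0 log 0 := 0, over the empirical joint distribution.
#'
#' @param x,y equal-length vectors over discrete alphabets.
#' @return mutual information in bits (>= 0 up to floating point).
#' @examples
#' mutualInformation(rep(0:1, 50), rep(0:1, 50))   # 1 bit
#' @export
mutualInformation <- function(x, y) {
    if (length(x) != length(y))
        stop("length mismatch between x and y")
    joint <- table(x, y) / length(x)
    px <- rowSums(joint)
    py <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

## Fast MI between one discretized column and many, via joint tabulate.
miColumns <- function(target, mat, nlev = 3L) {
    n <- length(target)
    pt <- tabulate(target + 1L, nlev) / n
    vapply(seq_len(ncol(mat)), function(j) {
        x <- mat[, j]
        joint <- tabulate(x * nlev + target + 1L, nlev * nlev) / n
        px <- tabulate(x + 1L, nlev) / n
        pj <- as.vector(outer(pt, px))
        nz <- joint > 0
        sum(joint[nz] * log2(joint[nz] / pj[nz]))
    }, numeric(1))
}

#' MaxRel and mRMR feature ranking
#'
#' Stage-2 selection over the Cramér survivors. Features are
#' discretized with the same scheme as the filter; the MaxRel list
#' sorts them by mutual information with the class label
#' (non-increasing, ties broken by feature order) and the mRMR list is
#' built greedily under the mutual-information-difference (MID)
#' criterion: after seeding with the most relevant feature, each step
#' adds the candidate maximizing
#' relevance - mean(MI with the already-selected features),
#' ties again broken by feature order. Both lists are truncated to
#' `k` entries and necessarily begin with the same feature.
#'
#' @param x an [EnrichmentMatrix-class] with binary labels.
#' @param survivors character vector of term ids to rank (the Cramér
#'   survivors), in feature order.
#' @param k maximum list length (default 500).
#' @param scheme discretization scheme, see [discretizeFeature()].
#' @return a [RankedFeatures-class].
#' @export
rankFeatures <- function(x, survivors, k = 500L,
                         scheme = "three_state_mean_sd") {
    stopifnot(is(x, "EnrichmentMatrix"))
    if (!length(survivors))
        stop("no surviving features to rank; lower the Cramér ",
             "threshold")
    lab <- geneLabels(x)
    if (any(is.na(lab)))
        stop("all genes must carry a binary label")
    survivors <- intersect(termIds(x), survivors)  # keep feature order
    m <- scoreMatrix(x)[, survivors, drop = FALSE]
    disc <- vapply(seq_len(ncol(m)),
                   function(j) discretizeFeature(m[, j], scheme),
                   integer(nrow(m)))
    if (is.null(dim(disc))) disc <- matrix(disc, nrow = nrow(m))
    colnames(disc) <- survivors
    labInt <- as.integer(lab)
    rel <- miColumns(labInt, disc)
    names(rel) <- survivors
    k <- min(as.integer(k), length(survivors))

    ## MaxRel: stable sort keeps feature order on ties
    maxrel <- survivors[order(-rel)][seq_len(k)]

    ## greedy mRMR/MID with incremental redundancy sums
    selected <- integer(0)
    remaining <- seq_along(survivors)
    redSum <- numeric(length(survivors))
    first <- remaining[which.max(rel[remaining])]
    selected <- first
    remaining <- setdiff(remaining, first)
    while (length(selected) < k && length(remaining)) {
        lastIdx <- selected[[length(selected)]]
        redSum[remaining] <- redSum[remaining] +
            miColumns(disc[, lastIdx],
                      disc[, remaining, drop = FALSE])
        crit <- rel[remaining] - redSum[remaining] / length(selected)
        pick <- remaining[which.max(crit)]
        selected <- c(selected, pick)
        remaining <- setdiff(remaining, pick)
    }
    new("RankedFeatures",
        maxrel = maxrel,
        mrmr = survivors[selected],
        relevance = rel)
}
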