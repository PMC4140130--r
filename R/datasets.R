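#' @include AllClasses.R synthetic.R
NULL

#' Sample negative genes from a universe
#'
#' Uniform sample without replacement of `ratio` times the number of
#' positives, drawn from the universe after removing all positives.
#' Deterministic under `seed`.
#'
#' @param universe character vector of candidate gene ids.
#' @param positives character vector of positive gene ids.
#' @param ratio integer; negatives per positive (the reference design
#'   uses 50).
#' @param seed integer RNG seed.
#' @return character vector of sampled negative gene ids.
#' @export
sampleNegatives <- function(universe, positives, ratio = 50L,
                            seed = 1L) {
    pool <- setdiff(unique(universe), positives)
    need <- as.integer(ratio) * length(unique(positives))
    if (length(pool) < need)
        stop("negative universe too small: need ", need,
             " non-positive genes, have ", length(pool))
    withSeed(seed, sample(pool, need))
}

#' Partition negatives into balanced datasets
#'
#' Randomly permutes the negatives and deals them round-robin into `k`
#' disjoint portions whose sizes differ by at most one; dataset i is
#' the full positive set plus portion i. With 1,950 negatives and
#' k = 10, every portion has 195 genes and each dataset carries a 5:1
#' negative:positive ratio over 39 positives.
#'
#' @param negatives character vector of sampled negative gene ids.
#' @param positives character vector of positive gene ids.
#' @param k number of portions/datasets.
#' @param seed integer RNG seed.
#' @return a [DatasetSplit-class].
#' @export
splitNegatives <- function(negatives, positives, k = 10L, seed = 1L) {
    k <- as.integer(k)
    if (k <= 0L) stop("k must be positive")
    if (length(negatives) < k)
        stop("fewer negatives than portions")
    perm <- withSeed(seed, sample(negatives))
    portions <- split(perm, rep_len(seq_len(k), length(perm)))
    names(portions) <- NULL
    new("DatasetSplit", positives = as.character(positives),
        portions = portions, seed = as.integer(seed))
}

#' Subset an EnrichmentMatrix to one balanced dataset
#'
#' @param x an [EnrichmentMatrix-class] covering all dataset genes.
#' @param split a [DatasetSplit-class].
#' @param i dataset index.
#' @return an [EnrichmentMatrix-class] restricted to dataset i's genes
#'   with labels set (1 = positive, 0 = negative).
#' @export
datasetMatrix <- function(x, split, i) {
    g <- datasetGenes(split, i)
    missing <- setdiff(g, geneIds(x))
    if (length(missing))
        stop(length(missing), " dataset gene(s) absent from the ",
             "feature matrix, e.g. ", missing[[1L]])
    out <- x[, g]
    geneLabels(out) <- datasetLabels(split, i)
    out
}
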