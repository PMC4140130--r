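#' @include AllClasses.R accessors.R
NULL

#' Combine per-dataset optimal feature sets
#'
#' The final optimal feature set is the union of the per-dataset
#' optimal sets; each member's multiplicity is the number of optimal
#' sets containing it. Features are reported in order of first
#' appearance across the input sets.
#'
#' @param sets list of character vectors (the per-dataset optimal
#'   feature sets).
#' @param corpus optional [AnnotationCorpus-class] supplying term
#'   namespaces for the GO/KEGG breakdown.
#' @return a [FinalOptimalSet-class].
#' @examples
#' fs <- combineOptimalSets(list(c("A", "B"), c("B", "C")))
#' featureMultiplicity(fs)   # A=1 B=2 C=1
#' @export
combineOptimalSets <- function(sets, corpus = NULL) {
    stopifnot(is.list(sets), length(sets) >= 1L)
    sets <- lapply(sets, unique)
    all <- unlist(sets, use.names = FALSE)
    features <- unique(all)
    mult <- setNames(vapply(features, function(f)
        sum(vapply(sets, function(s) f %in% s, logical(1))),
        integer(1)), features)
    ns <- if (is.null(corpus))
        setNames(rep(NA_character_, length(features)), features)
    else termNamespace(corpus)[features]
    new("FinalOptimalSet", features = features, multiplicity = mult,
        nSets = length(sets), namespace = setNames(ns, features))
}

#' Multiplicity histogram of a final optimal set
#'
#' For each multiplicity value 1..nSets, the number of features
#' contained in exactly that many optimal sets.
#'
#' @param x a [FinalOptimalSet-class].
#' @return named integer vector over multiplicities `1..nSets`.
#' @export
multiplicityHistogram <- function(x) {
    stopifnot(is(x, "FinalOptimalSet"))
    tabulate(x@multiplicity, nbins = x@nSets) |>
        setNames(seq_len(x@nSets))
}

#' Fraction of features shared by at least k optimal sets
#'
#' @param x a [FinalOptimalSet-class] (non-empty).
#' @param minMultiplicity integer k >= 1.
#' @return |features with multiplicity >= k| / |features|.
#' @examples
#' fs <- combineOptimalSets(list(c("A", "B"), c("B", "C")))
#' fractionShared(fs, 2)   # only B: 1/3
#' @export
fractionShared <- function(x, minMultiplicity = 2L) {
    stopifnot(is(x, "FinalOptimalSet"), minMultiplicity >= 1L)
    if (!length(x@features)) stop("final optimal set is empty")
    mean(x@multiplicity >= minMultiplicity)
}

#' Category-level frequency and percentage of the final optimal set
#'
#' For each category term c (a direct child of a hierarchy root), let
#' S(c) be the descendant closure of c. The frequency of c is
#' |final set ∩ S(c)| and its percentage is that count divided by
#' |S(c)|. Terms reachable from several categories (DAG
#' multi-parentage) count in every one. Final-set terms not covered by
#' the hierarchy are reported in the `unmapped` attribute rather than
#' raising an error.
#'
#' @param x a [FinalOptimalSet-class].
#' @param hierarchy a [TermHierarchy-class].
#' @return data.frame with columns `category`, `root`, `size`
#'   (|S(c)|), `frequency` and `percentage`, sorted by decreasing
#'   frequency; attribute `unmapped` lists uncovered GO members.
#' @export
categorySummary <- function(x, hierarchy) {
    stopifnot(is(x, "FinalOptimalSet"), is(hierarchy, "TermHierarchy"))
    rows <- do.call(rbind, lapply(hierarchyRoots(hierarchy),
        function(r) {
            cats <- hierarchy@children[[r]]
            if (is.null(cats)) return(NULL)
            do.call(rbind, lapply(cats, function(cc) {
                S <- termDescendants(hierarchy, cc)
                freq <- length(intersect(x@features, S))
                data.frame(category = cc, root = r,
                           size = length(S), frequency = freq,
                           percentage = if (length(S)) freq /
                               length(S) else 0)
            }))
        }))
    if (is.null(rows))
        rows <- data.frame(category = character(), root = character(),
                           size = integer(), frequency = integer(),
                           percentage = numeric())
    rows <- rows[order(-rows$frequency), , drop = FALSE]
    rownames(rows) <- NULL
    covered <- unique(unlist(lapply(categoryTerms(hierarchy),
        function(cc) termDescendants(hierarchy, cc)),
        use.names = FALSE))
    go <- x@features[is.na(x@namespace) | x@namespace == "GO"]
    attr(rows, "unmapped") <- setdiff(go, covered)
    rows
}

#' Bar chart of category frequencies or percentages
#'
#' @param summary a data.frame from [categorySummary()].
#' @param measure `"frequency"` or `"percentage"`.
#' @param top number of categories to display (default all).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted subset.
#' @export
plotCategorySummary <- function(summary,
                                measure = c("frequency",
                                            "percentage"),
                                top = nrow(summary), ...) {
    measure <- match.arg(measure)
    d <- summary[order(-summary[[measure]]), , drop = FALSE]
    d <- utils::head(d, top)
    graphics::barplot(d[[measure]], names.arg = d$category,
                      las = 2, ylab = measure, ...)
    invisible(d)
}
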