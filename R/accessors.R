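#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname termIds
#' @export
setMethod("termIds", "AnnotationCorpus", function(x) names(x@termGenes))

#' @rdname termIds
#' @export
setMethod("termIds", "EnrichmentMatrix", function(x) rownames(x))

#' @rdname termNamespace
#' @export
setMethod("termNamespace", "AnnotationCorpus",
          function(x) x@termNamespace)

#' @rdname termNamespace
#' @export
setMethod("termNamespace", "EnrichmentMatrix", function(x)
    setNames(SummarizedExperiment::rowData(x)$namespace, rownames(x)))

#' @rdname geneIds
#' @export
setMethod("geneIds", "EnrichmentMatrix", function(x) colnames(x))

#' Background gene universe of a corpus
#'
#' @param x an [AnnotationCorpus-class].
#' @return character vector of background gene ids; `nBackground()`
#'   returns its length, the hypergeometric population size N.
#' @export
backgroundGenes <- function(x) {
    stopifnot(is(x, "AnnotationCorpus"))
    x@background
}

#' @rdname backgroundGenes
#' @export
nBackground <- function(x) length(backgroundGenes(x))

#' Number of background genes annotated to each term
#'
#' @param x an [AnnotationCorpus-class].
#' @return named integer vector M over terms, in feature order.
#' @export
termSizes <- function(x) {
    stopifnot(is(x, "AnnotationCorpus"))
    setNames(lengths(x@termGenes), names(x@termGenes))
}

#' Genes annotated to one term
#'
#' @param x an [AnnotationCorpus-class].
#' @param term a term id present in the corpus.
#' @return character vector of annotated gene ids.
#' @export
genesForTerm <- function(x, term) {
    stopifnot(is(x, "AnnotationCorpus"))
    if (!term %in% names(x@termGenes))
        stop("unknown term: ", term)
    x@termGenes[[term]]
}

#' Genes-by-terms score matrix of an EnrichmentMatrix
#'
#' Returns the dense score matrix in the external orientation: one row
#' per gene, one column per term (the transpose of the internal assay).
#'
#' @param x an [EnrichmentMatrix-class].
#' @return numeric matrix, genes x terms.
#' @export
scoreMatrix <- function(x) {
    stopifnot(is(x, "EnrichmentMatrix"))
    t(SummarizedExperiment::assay(x, "score"))
}

#' Binary class labels of an EnrichmentMatrix
#'
#' @param x an [EnrichmentMatrix-class].
#' @return named integer vector (1 positive, 0 negative, `NA`
#'   unlabeled) over genes.
#' @export
geneLabels <- function(x) {
    stopifnot(is(x, "EnrichmentMatrix"))
    setNames(SummarizedExperiment::colData(x)$label, colnames(x))
}

#' Replace the class labels of an EnrichmentMatrix
#'
#' @param x an [EnrichmentMatrix-class].
#' @param value integer vector over genes (1/0/`NA`), optionally named
#'   by gene id.
#' @return the modified object.
#' @export
`geneLabels<-` <- function(x, value) {
    stopifnot(is(x, "EnrichmentMatrix"))
    if (!is.null(names(value)))
        value <- value[colnames(x)]
    SummarizedExperiment::colData(x)$label <- as.integer(value)
    x
}

#' Number of datasets in a split
#'
#' @param x a [DatasetSplit-class].
#' @return integer k.
#' @export
nDatasets <- function(x) {
    stopifnot(is(x, "DatasetSplit"))
    length(x@portions)
}

#' Genes of one balanced dataset
#'
#' Dataset i is the full positive set followed by negative portion i.
#'
#' @param x a [DatasetSplit-class].
#' @param i dataset index in 1..k.
#' @return character vector of gene ids, positives first.
#' @export
datasetGenes <- function(x, i) {
    stopifnot(is(x, "DatasetSplit"))
    i <- as.integer(i)
    if (i < 1L || i > nDatasets(x)) stop("dataset index out of range")
    c(x@positives, x@portions[[i]])
}

#' Labels of one balanced dataset
#'
#' @inheritParams datasetGenes
#' @return named integer vector: 1 for positives, 0 for the portion's
#'   negatives, parallel to [datasetGenes()].
#' @export
datasetLabels <- function(x, i) {
    g <- datasetGenes(x, i)
    setNames(c(rep(1L, length(x@positives)),
               rep(0L, length(g) - length(x@positives))), g)
}

#' Accessors for ranked feature lists
#'
#' @param x a [RankedFeatures-class].
#' @return `maxrelList()` and `mrmrList()` return the respective
#'   ordered character vectors of term ids; `featureRelevance()` the
#'   named mutual-information values (bits).
#' @export
mrmrList <- function(x) {
    stopifnot(is(x, "RankedFeatures"))
    x@mrmr
}

#' @rdname mrmrList
#' @export
maxrelList <- function(x) {
    stopifnot(is(x, "RankedFeatures"))
    x@maxrel
}

#' @rdname mrmrList
#' @export
featureRelevance <- function(x) {
    stopifnot(is(x, "RankedFeatures"))
    x@relevance
}

#' Accessors for IFS results
#'
#' @param x an [IFSResult-class].
#' @return `ifsCurve()` returns the per-prefix metric data.frame;
#'   `optimalFeatures()` the MCC-maximizing feature prefix;
#'   `optimalSize()` its length; `maxMCC()` the maximum MCC.
#' @export
ifsCurve <- function(x) {
    stopifnot(is(x, "IFSResult"))
    x@curve
}

#' @rdname ifsCurve
#' @export
optimalFeatures <- function(x) {
    stopifnot(is(x, "IFSResult"))
    x@optimalFeatures
}

#' @rdname ifsCurve
#' @export
optimalSize <- function(x) {
    stopifnot(is(x, "IFSResult"))
    x@optimalSize
}

#' @rdname ifsCurve
#' @export
maxMCC <- function(x) {
    stopifnot(is(x, "IFSResult"))
    x@maxMCC
}

#' Accessors for the final optimal feature set
#'
#' @param x a [FinalOptimalSet-class].
#' @return `finalFeatures()` returns the member term ids;
#'   `featureMultiplicity()` the named count of optimal sets containing
#'   each member; `featureNamespaceCounts()` the number of GO vs KEGG
#'   members.
#' @export
finalFeatures <- function(x) {
    stopifnot(is(x, "FinalOptimalSet"))
    x@features
}

#' @rdname finalFeatures
#' @export
featureMultiplicity <- function(x) {
    stopifnot(is(x, "FinalOptimalSet"))
    x@multiplicity
}

#' @rdname finalFeatures
#' @export
featureNamespaceCounts <- function(x) {
    stopifnot(is(x, "FinalOptimalSet"))
    ns <- x@namespace
    c(GO = sum(ns == "GO", na.rm = TRUE),
      KEGG = sum(ns == "KEGG", na.rm = TRUE))
}

#' Roots and category terms of a hierarchy
#'
#' Category terms are the direct children of the namespace roots; they
#' are the units of the frequency/percentage reporting.
#'
#' @param x a [TermHierarchy-class].
#' @return character vector of term ids.
#' @export
hierarchyRoots <- function(x) {
    stopifnot(is(x, "TermHierarchy"))
    x@roots
}

#' @rdname hierarchyRoots
#' @export
categoryTerms <- function(x) {
    stopifnot(is(x, "TermHierarchy"))
    unique(unlist(x@children[x@roots], use.names = FALSE))
}

#' All descendants of a term
#'
#' Descendant closure (children, children of children, ...), excluding
#' the term itself.
#'
#' @param x a [TermHierarchy-class].
#' @param term a term id.
#' @return character vector of descendant term ids (possibly empty).
#' @export
termDescendants <- function(x, term) {
    stopifnot(is(x, "TermHierarchy"))
    out <- character()
    frontier <- x@children[[term]]
    while (length(frontier)) {
        frontier <- setdiff(frontier, out)
        out <- c(out, frontier)
        frontier <- unique(unlist(x@children[frontier],
                                  use.names = FALSE))
    }
    out
}
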