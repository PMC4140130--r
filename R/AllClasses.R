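#' @import methods
#' @importFrom stats phyper sd setNames
#' @importFrom utils head
NULL

## Central data containers. Genes and terms are opaque string tokens;
## all set operations are exact string matches.

#' AnnotationCorpus: term-to-gene annotation maps over a fixed background
#'
#' Holds the gene sets annotated to each functional term in two
#' namespaces (GO terms and KEGG pathways) together with the background
#' gene universe of size `N`. The slot order of `termGenes` — all GO
#' terms first, then all KEGG pathways, each in first-appearance file
#' order — is the fixed feature ordering used for every feature vector
#' downstream.
#'
#' @slot termGenes named list; one character vector of annotated genes
#'   per term, in feature order.
#' @slot termNamespace named character vector parallel to `termGenes`;
#'   `"GO"` or `"KEGG"`.
#' @slot background character vector of background gene ids; its length
#'   is the hypergeometric population size `N`.
#'
#' @seealso [readAnnotations()], [termIds()], [termSizes()],
#'   [enrichmentScore()]
#' @export
setClass("AnnotationCorpus",
    slots = c(
        termGenes = "list",
        termNamespace = "character",
        background = "character"
    )
)

setValidity("AnnotationCorpus", function(object) {
    tg <- object@termGenes
    ns <- object@termNamespace
    bg <- object@background
    msg <- character()
    if (is.null(names(tg)) || anyDuplicated(names(tg)))
        msg <- c(msg, "termGenes must be uniquely named by term id")
    if (length(ns) != length(tg) || !identical(names(ns), names(tg)))
        msg <- c(msg, "termNamespace must be named parallel to termGenes")
    if (!all(ns %in% c("GO", "KEGG")))
        msg <- c(msg, "termNamespace entries must be 'GO' or 'KEGG'")
    if (length(bg) < 1L)
        msg <- c(msg, "background must contain at least one gene (N >= 1)")
    if (anyDuplicated(bg))
        msg <- c(msg, "background gene ids must be unique")
    annotated <- unique(unlist(tg, use.names = FALSE))
    if (length(annotated) && !all(annotated %in% bg))
        msg <- c(msg, "every annotated gene must belong to the background")
    ## GO block must precede KEGG block: ordering defines coordinates
    if (length(ns) && is.unsorted(match(ns, c("GO", "KEGG"))))
        msg <- c(msg, "terms must be ordered GO first, then KEGG")
    if (length(msg)) msg else TRUE
})

#' Construct an AnnotationCorpus
#'
#' @param termGenes named list of character vectors (annotated genes per
#'   term); GO terms must precede KEGG terms.
#' @param termNamespace character vector (`"GO"`/`"KEGG"`), either named
#'   parallel to `termGenes` or unnamed in the same order.
#' @param background character vector of background gene ids. Defaults
#'   to the union of all annotated genes.
#' @return an [AnnotationCorpus-class] object.
#' @examples
#' corpus <- AnnotationCorpus(
#'     termGenes = list(T1 = c("g1", "g2"), T2 = "g2", P1 = "g1"),
#'     termNamespace = c("GO", "GO", "KEGG")
#' )
#' termSizes(corpus)
#' @export
AnnotationCorpus <- function(termGenes, termNamespace,
                             background = NULL) {
    termGenes <- lapply(termGenes, function(g) unique(as.character(g)))
    if (is.null(names(termNamespace)))
        names(termNamespace) <- names(termGenes)
    if (is.null(background))
        background <- unique(unlist(termGenes, use.names = FALSE))
    new("AnnotationCorpus",
        termGenes = termGenes,
        termNamespace = termNamespace,
        background = as.character(background))
}

#' TermHierarchy: parent links between functional terms
#'
#' A rooted, acyclic child-to-parent map used for category-level
#' reporting: the children of the three namespace roots (the biological
#' process, cellular component and molecular function analogues) act as
#' categories, and membership of a term in a category is decided by
#' descendant closure.
#'
#' @slot parents named list; for each child term, the character vector
#'   of its parent terms (multi-parentage allowed, as in the GO DAG).
#' @slot children named list; inverse map, parent to children.
#' @slot roots character vector of root terms (appear as parents, never
#'   as children).
#' @seealso [readTermHierarchy()], [termDescendants()],
#'   [categorySummary()]
#' @export
setClass("TermHierarchy",
    slots = c(parents = "list", children = "list", roots = "character")
)

setValidity("TermHierarchy", function(object) {
    msg <- character()
    ch <- object@children
    ## cycle check by iterative leaf stripping (Kahn)
    allTerms <- unique(c(names(object@parents), names(ch),
                         unlist(ch, use.names = FALSE),
                         unlist(object@parents, use.names = FALSE)))
    indeg <- setNames(integer(length(allTerms)), allTerms)
    for (p in names(ch)) indeg[ch[[p]]] <- indeg[ch[[p]]] + 1L
    queue <- allTerms[indeg == 0L]
    seen <- 0L
    while (length(queue)) {
        t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
        kids <- ch[[t]]
        if (!is.null(kids)) {
            indeg[kids] <- indeg[kids] - 1L
            queue <- c(queue, kids[indeg[kids] == 0L])
        }
    }
    if (seen != length(allTerms))
        msg <- c(msg, "hierarchy contains a cycle")
    if (any(object@roots %in% names(object@parents)))
        msg <- c(msg, "roots must not have parents")
    if (length(msg)) msg else TRUE
})

#' Construct a TermHierarchy from child-parent pairs
#'
#' @param child,parent parallel character vectors of term ids; each pair
#'   records one child-of link.
#' @return a [TermHierarchy-class] object. Roots are the terms that
#'   appear as parents but never as children.
#' @examples
#' h <- TermHierarchy(child = c("a", "b"), parent = c("root", "root"))
#' termDescendants(h, "root")
#' @export
TermHierarchy <- function(child, parent) {
    child <- as.character(child)
    parent <- as.character(parent)
    stopifnot(length(child) == length(parent))
    parents <- split(parent, child)
    parents <- lapply(parents, unique)
    children <- split(child, parent)
    children <- lapply(children, unique)
    roots <- setdiff(unique(parent), unique(child))
    new("TermHierarchy", parents = parents, children = children,
        roots = roots)
}

#' EnrichmentMatrix: genes-by-terms enrichment scores
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay,
#' `"score"`, with functional terms as rows (features) and genes as
#' columns (samples): entry (j, g) is the -log10 hypergeometric
#' upper-tail probability that gene g's closed network neighborhood
#' contains as many members annotated to term j as observed. `rowData`
#' carries the term namespace; `colData` may carry a binary class
#' `label` (1 = disease-related positive, 0 = negative). The external
#' (file) representation is transposed: one row per gene.
#'
#' All scores are finite and non-negative (the underflow cap guarantees
#' finiteness).
#'
#' @seealso [encodeGenes()], [scoreMatrix()], [writeFeatureMatrix()]
#' @export
setClass("EnrichmentMatrix",
    contains = "SummarizedExperiment"
)

setValidity("EnrichmentMatrix", function(object) {
    msg <- character()
    if (!"score" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "must contain an assay named 'score'")
    else {
        a <- SummarizedExperiment::assay(object, "score")
        if (length(a) && (!all(is.finite(a)) || any(a < 0)))
            msg <- c(msg, "scores must be finite and >= 0")
    }
    if (!"namespace" %in%
            colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData must contain a 'namespace' column")
    if (length(msg)) msg else TRUE
})

#' Construct an EnrichmentMatrix from a genes-by-terms score matrix
#'
#' @param scores numeric matrix, one row per gene and one column per
#'   term, with gene ids as rownames and term ids as colnames.
#' @param namespace character vector (`"GO"`/`"KEGG"`) parallel to the
#'   columns of `scores`.
#' @param labels optional numeric/integer vector of binary class labels
#'   (1 positive, 0 negative), parallel to the rows of `scores`; `NA`
#'   allowed for unlabeled genes.
#' @return an [EnrichmentMatrix-class].
#' @export
EnrichmentMatrix <- function(scores, namespace, labels = NULL) {
    scores <- as.matrix(scores)
    if (is.null(labels)) labels <- rep(NA_integer_, nrow(scores))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(score = t(scores)),
        rowData = S4Vectors::DataFrame(
            namespace = as.character(namespace),
            row.names = colnames(scores)),
        colData = S4Vectors::DataFrame(
            label = as.integer(labels),
            row.names = rownames(scores))
    )
    new("EnrichmentMatrix", se)
}

#' DatasetSplit: balanced datasets from a negative-sample partition
#'
#' Records the random partition of the sampled negative genes into k
#' disjoint portions of near-equal size. Dataset i combines the full
#' positive set with portion i, so every dataset carries all positives
#' and exactly one negative portion.
#'
#' @slot positives character vector of positive gene ids (class 1).
#' @slot portions list of k disjoint character vectors whose union is
#'   the sampled negative set (class 0); sizes differ by at most one.
#' @slot seed integer seed that produced the partition.
#' @seealso [splitNegatives()], [datasetGenes()]
#' @export
setClass("DatasetSplit",
    slots = c(positives = "character", portions = "list",
              seed = "integer")
)

setValidity("DatasetSplit", function(object) {
    msg <- character()
    neg <- unlist(object@portions, use.names = FALSE)
    if (anyDuplicated(neg))
        msg <- c(msg, "portions must be pairwise disjoint")
    if (length(intersect(object@positives, neg)))
        msg <- c(msg, "positives and negatives must be disjoint")
    sizes <- lengths(object@portions)
    if (length(sizes) && diff(range(sizes)) > 1L)
        msg <- c(msg, "portion sizes must differ by at most 1")
    if (length(msg)) msg else TRUE
})

#' RankedFeatures: MaxRel and mRMR feature orderings
#'
#' The two orderings of the Cramer-filtered surviving features: MaxRel
#' sorts by mutual information with the class label alone; mRMR is the
#' greedy ordering that trades relevance against redundancy with the
#' already-selected features. Both lists are truncated to the same
#' length and begin with the same (most relevant) feature.
#'
#' @slot maxrel character vector of term ids, non-increasing relevance.
#' @slot mrmr character vector of term ids, greedy mRMR order.
#' @slot relevance named numeric; mutual information (bits) between
#'   each surviving feature and the label.
#' @seealso [rankFeatures()]
#' @export
setClass("RankedFeatures",
    slots = c(maxrel = "character", mrmr = "character",
              relevance = "numeric")
)

setValidity("RankedFeatures", function(object) {
    msg <- character()
    if (anyDuplicated(object@maxrel) || anyDuplicated(object@mrmr))
        msg <- c(msg, "ranked lists must be duplicate-free")
    if (length(object@maxrel) != length(object@mrmr))
        msg <- c(msg, "maxrel and mrmr lists must have equal length")
    if (length(object@maxrel) &&
        object@maxrel[[1L]] != object@mrmr[[1L]])
        msg <- c(msg, "both lists must start with the most relevant feature")
    if (length(msg)) msg else TRUE
})

#' IFSResult: incremental-feature-selection curve and optimal set
#'
#' For each prefix length i of the mRMR list, the pooled
#' cross-validation confusion counts and derived metrics (ACC, SP, SN,
#' MCC). The optimal feature set is the shortest prefix attaining the
#' maximum MCC on the curve.
#'
#' @slot curve data.frame with columns `i, TP, TN, FP, FN, ACC, SP, SN,
#'   MCC`, one row per prefix size.
#' @slot optimalSize integer; smallest i attaining the maximum MCC.
#' @slot optimalFeatures character; the first `optimalSize` features of
#'   the mRMR list.
#' @slot maxMCC numeric; the maximum MCC over the curve.
#' @seealso [runIFS()], [plotIFSCurve()]
#' @export
setClass("IFSResult",
    slots = c(curve = "data.frame", optimalSize = "integer",
              optimalFeatures = "character", maxMCC = "numeric")
)

setValidity("IFSResult", function(object) {
    msg <- character()
    cv <- object@curve
    need <- c("i", "TP", "TN", "FP", "FN", "ACC", "SP", "SN", "MCC")
    if (!all(need %in% colnames(cv)))
        msg <- c(msg, "curve must have columns i, TP, TN, FP, FN, ACC, SP, SN, MCC")
    else if (nrow(cv)) {
        if (length(object@optimalFeatures) != object@optimalSize)
            msg <- c(msg, "optimalFeatures length must equal optimalSize")
        best <- max(cv$MCC)
        if (abs(object@maxMCC - best) > 1e-12)
            msg <- c(msg, "maxMCC must equal the curve maximum")
        if (object@optimalSize != cv$i[[which.max(cv$MCC)]])
            msg <- c(msg, "optimalSize must be the smallest i attaining maxMCC")
    }
    if (length(msg)) msg else TRUE
})

#' FinalOptimalSet: union of per-dataset optimal feature sets
#'
#' The final optimal feature set is the union of the per-dataset optimal
#' sets; each member's multiplicity counts how many optimal sets contain
#' it (between 1 and the number of datasets).
#'
#' @slot features character vector of member term ids.
#' @slot multiplicity named integer vector over `features`.
#' @slot nSets integer; number of optimal sets combined.
#' @slot namespace named character (`"GO"`/`"KEGG"`) over `features`;
#'   may be `NA` when no corpus was attached.
#' @seealso [combineOptimalSets()], [fractionShared()],
#'   [multiplicityHistogram()]
#' @export
setClass("FinalOptimalSet",
    slots = c(features = "character", multiplicity = "integer",
              nSets = "integer", namespace = "character")
)

setValidity("FinalOptimalSet", function(object) {
    msg <- character()
    m <- object@multiplicity
    if (!identical(names(m), object@features))
        msg <- c(msg, "multiplicity must be named by features, in order")
    if (length(m) && (any(m < 1L) || any(m > object@nSets)))
        msg <- c(msg, "multiplicities must lie in [1, nSets]")
    if (length(msg)) msg else TRUE
})
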