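#' @include AllClasses.R accessors.R
NULL

setMethod("show", "AnnotationCorpus", function(object) {
    ns <- table(factor(object@termNamespace, c("GO", "KEGG")))
    cat("AnnotationCorpus with", length(object@termGenes), "terms (",
        ns[["GO"]], "GO,", ns[["KEGG"]], "KEGG ) over a background of",
        length(object@background), "genes\n")
    m <- termSizes(object)
    if (length(m))
        cat("  annotated genes per term: median", stats::median(m),
            " range [", min(m), ",", max(m), "]\n")
})

setMethod("show", "TermHierarchy", function(object) {
    cat("TermHierarchy:", length(unique(c(names(object@parents),
        unlist(object@parents, use.names = FALSE)))), "terms,",
        length(object@roots), "roots (",
        paste(object@roots, collapse = ", "), ")\n")
})

setMethod("show", "EnrichmentMatrix", function(object) {
    cat("EnrichmentMatrix:", ncol(object), "genes x", nrow(object),
        "terms\n")
    ns <- table(factor(
        SummarizedExperiment::rowData(object)$namespace,
        c("GO", "KEGG")))
    cat("  features:", ns[["GO"]], "GO terms,", ns[["KEGG"]],
        "KEGG pathways\n")
    lab <- geneLabels(object)
    if (any(!is.na(lab)))
        cat("  labels:", sum(lab == 1L, na.rm = TRUE), "positive,",
            sum(lab == 0L, na.rm = TRUE), "negative,",
            sum(is.na(lab)), "unlabeled\n")
})

setMethod("show", "DatasetSplit", function(object) {
    cat("DatasetSplit:", length(object@positives), "positives +",
        length(unlist(object@portions)), "negatives in",
        length(object@portions), "portions (sizes",
        paste(lengths(object@portions), collapse = "/"), "), seed",
        object@seed, "\n")
})

setMethod("show", "RankedFeatures", function(object) {
    cat("RankedFeatures:", length(object@mrmr), "features ranked\n")
    cat("  top mRMR:", paste(head(object@mrmr, 5L), collapse = ", "),
        "\n")
})

setMethod("show", "IFSResult", function(object) {
    cat("IFSResult: curve over", nrow(object@curve),
        "prefix sizes; max MCC", format(object@maxMCC, digits = 4),
        "at", object@optimalSize, "features\n")
})

setMethod("show", "FinalOptimalSet", function(object) {
    nsc <- featureNamespaceCounts(object)
    cat("FinalOptimalSet:", length(object@features), "features (",
        nsc[["GO"]], "GO,", nsc[["KEGG"]], "KEGG ) from",
        object@nSets, "optimal sets\n")
    if (length(object@features))
        cat("  shared by >= 2 sets:",
            format(100 * fractionShared(object, 2L), digits = 4),
            "%\n")
})
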