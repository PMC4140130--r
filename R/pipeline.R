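#' @include AllClasses.R enrichment.R datasets.R cramer.R mrmr.R ifs.R aggregate.R
NULL

#' Pipeline run configuration
#'
#' Collects every tunable of the classification pipeline in one
#' validated list. The reference design is `negativeRatio = 50`
#' negatives per positive split into `nSplits = 10` balanced datasets
#' (a 5:1 within-dataset ratio), a Cramér threshold of 0.1, ranked
#' lists truncated at 500 features, 10-fold cross-validation, and a
#' linear-kernel soft-margin SVM with C = 1.
#'
#' @param seed master integer seed; all per-stage seeds (negative
#'   sampling, portion split, fold assignment) are derived from it
#'   deterministically, so one number reproduces a whole run.
#' @param negativeRatio negatives sampled per positive.
#' @param nSplits number of negative portions / balanced datasets.
#' @param cramerThreshold minimum Cramér's V for a feature to survive
#'   stage-1 filtering.
#' @param maxRankedFeatures truncation length of the MaxRel/mRMR
#'   lists.
#' @param cvFolds cross-validation folds.
#' @param kernel,cost,degree,gamma classifier settings, see
#'   [trainClassifier()].
#' @param scheme discretization scheme, see [discretizeFeature()].
#' @param openNeighborhood logical; encode with the open (exclusive)
#'   neighborhood instead of the closed one.
#' @param scoreCap enrichment-score underflow cap.
#' @return a validated `runConfig` list.
#' @export
runConfig <- function(seed = 1L, negativeRatio = 50L, nSplits = 10L,
                      cramerThreshold = 0.1,
                      maxRankedFeatures = 500L, cvFolds = 10L,
                      kernel = "linear", cost = 1, degree = 3L,
                      gamma = NULL, scheme = "three_state_mean_sd",
                      openNeighborhood = FALSE, scoreCap = 300) {
    cfg <- list(seed = as.integer(seed),
                negativeRatio = as.integer(negativeRatio),
                nSplits = as.integer(nSplits),
                cramerThreshold = cramerThreshold,
                maxRankedFeatures = as.integer(maxRankedFeatures),
                cvFolds = as.integer(cvFolds), kernel = kernel,
                cost = cost, degree = as.integer(degree),
                gamma = gamma, scheme = scheme,
                openNeighborhood = isTRUE(openNeighborhood),
                scoreCap = scoreCap)
    with(cfg, {
        if (negativeRatio < 1L || nSplits < 1L || cvFolds < 2L ||
            maxRankedFeatures < 1L)
            stop("counts in the run configuration must be >= 1 ",
                 "(cvFolds >= 2)")
        if (cramerThreshold < 0 || cramerThreshold > 1)
            stop("cramerThreshold must lie in [0, 1]")
    })
    structure(cfg, class = "runConfig")
}

## Derived per-stage seeds: fixed offsets from the master seed, kept
## within the 32-bit integer range.
stageSeed <- function(config, offset) {
    as.integer((as.numeric(config$seed) * 101 + offset) %% 2147483647)
}

#' Desk-scale benchmark configuration
#'
#' The run configuration used with the package's reference synthetic
#' benchmark ([syntheticSpec()] defaults, a 200-gene universe with 15
#' positives): the 10-way negative split of the reference design is
#' kept, the negative ratio is 12 so the sample exhausts the 185-gene
#' negative universe (the desk-scale analogue of a large negative
#' pool), and the ranked lists are truncated at 100 features — the
#' same computation-bounding truncation the reference design applies
#' at 500 — with the standard Cramér threshold 0.1, 10-fold
#' cross-validation and a linear-kernel SVM at C = 1.
#'
#' @param seed master integer seed.
#' @return a [runConfig()].
#' @export
benchmarkConfig <- function(seed = 1L) {
    runConfig(seed = seed, negativeRatio = 12L, nSplits = 10L,
              maxRankedFeatures = 100L)
}

#' Run the full disease-gene classification pipeline
#'
#' Executes every stage on in-memory inputs: encode the positives and
#' a sampled negative set as neighborhood-enrichment vectors, split
#' the negatives into balanced datasets, then per dataset run the
#' Cramér filter, mRMR ranking and SVM-driven incremental feature
#' selection, and finally combine the per-dataset optimal feature sets
#' into the final optimal set (with category summaries when a
#' hierarchy is supplied).
#'
#' Positive or universe genes missing from the corpus background are
#' dropped with a warning before encoding.
#'
#' @param network an [igraph::igraph] interaction network.
#' @param corpus an [AnnotationCorpus-class].
#' @param positives character vector of known disease-gene ids.
#' @param universe character vector of candidate negative gene ids
#'   (positives are removed internally).
#' @param config a [runConfig()].
#' @param hierarchy optional [TermHierarchy-class] for category
#'   reporting.
#' @return a list with components `matrix` (the labeled
#'   [EnrichmentMatrix-class] over all pipeline genes), `split` (the
#'   [DatasetSplit-class]), `datasets` (per-dataset lists holding
#'   `survivors`, `V`, `ranking`, `ifs`), `finalSet` (the
#'   [FinalOptimalSet-class]), `categories` (data.frame or `NULL`) and
#'   `config`.
#' @seealso The stage functions: [encodeGenes()], [sampleNegatives()],
#'   [splitNegatives()], [filterFeatures()], [rankFeatures()],
#'   [runIFS()], [combineOptimalSets()].
#' @export
runIfsPipeline <- function(network, corpus, positives, universe,
                           config = runConfig(), hierarchy = NULL) {
    stopifnot(inherits(config, "runConfig"))
    bg <- backgroundGenes(corpus)
    dropP <- setdiff(positives, bg)
    if (length(dropP)) {
        warning(length(dropP), " positive gene(s) not in the ",
                "annotation background were dropped")
        positives <- intersect(positives, bg)
    }
    universe <- intersect(unique(universe), bg)
    if (!length(positives)) stop("no positive genes left to analyze")

    negatives <- sampleNegatives(universe, positives,
                                 ratio = config$negativeRatio,
                                 seed = stageSeed(config, 1L))
    split <- splitNegatives(negatives, positives,
                            k = config$nSplits,
                            seed = stageSeed(config, 2L))
    allGenes <- c(positives, negatives)
    mat <- encodeGenes(allGenes, network, corpus,
                       labels = c(rep(1L, length(positives)),
                                  rep(0L, length(negatives))),
                       open = config$openNeighborhood,
                       cap = config$scoreCap)

    datasets <- vector("list", nDatasets(split))
    for (i in seq_along(datasets)) {
        di <- datasetMatrix(mat, split, i)
        filt <- filterFeatures(di, threshold = config$cramerThreshold,
                               scheme = config$scheme)
        ranking <- rankFeatures(di, filt$features,
                                k = config$maxRankedFeatures,
                                scheme = config$scheme)
        ifs <- runIFS(di, mrmrList(ranking), folds = config$cvFolds,
                      seed = stageSeed(config, 10L + i),
                      kernel = config$kernel, cost = config$cost,
                      degree = config$degree, gamma = config$gamma)
        datasets[[i]] <- list(survivors = filt$features, V = filt$V,
                              ranking = ranking, ifs = ifs)
    }
    finalSet <- combineOptimalSets(
        lapply(datasets, function(d) optimalFeatures(d$ifs)), corpus)
    categories <- if (!is.null(hierarchy))
        categorySummary(finalSet, hierarchy)
    list(matrix = mat, split = split, datasets = datasets,
         finalSet = finalSet, categories = categories,
         config = config)
}

#' Run the pipeline from input files
#'
#' Thin wrapper over [runIfsPipeline()] that reads the five standard
#' input files (edge-list network, GO and KEGG annotation tables,
#' positive gene list, optional negative-universe list and term
#' hierarchy) with the package readers. When `universePath` is `NULL`
#' the universe is the corpus background minus the positives.
#'
#' @param networkPath,goPath,keggPath,positivesPath input file paths.
#' @param universePath,hierarchyPath,backgroundPath optional input
#'   file paths.
#' @param config a [runConfig()].
#' @param outDir optional directory; when set, the per-dataset IFS
#'   curves (TSV), the final-set TSV and the category summary TSV are
#'   written there.
#' @return as [runIfsPipeline()].
#' @export
runPipelineFromFiles <- function(networkPath, goPath, keggPath,
                                 positivesPath, universePath = NULL,
                                 hierarchyPath = NULL,
                                 backgroundPath = NULL,
                                 config = runConfig(),
                                 outDir = NULL) {
    net <- readNetwork(networkPath)
    corpus <- readAnnotations(goPath, keggPath,
                              backgroundPath = backgroundPath,
                              network = net)
    positives <- readGeneList(positivesPath)
    universe <- if (is.null(universePath))
        setdiff(backgroundGenes(corpus), positives)
    else readGeneList(universePath)
    hierarchy <- if (!is.null(hierarchyPath))
        readTermHierarchy(hierarchyPath)
    res <- runIfsPipeline(net, corpus, positives, universe,
                          config = config, hierarchy = hierarchy)
    if (!is.null(outDir)) {
        if (!dir.exists(outDir))
            dir.create(outDir, recursive = TRUE)
        for (i in seq_along(res$datasets)) {
            utils::write.table(
                ifsCurve(res$datasets[[i]]$ifs),
                file.path(outDir, sprintf("ifs_curve_D%02d.tsv", i)),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }
        writeFinalSet(res$finalSet,
                      file.path(outDir, "final_optimal_set.tsv"))
        if (!is.null(res$categories))
            utils::write.table(
                res$categories,
                file.path(outDir, "category_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res
}
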