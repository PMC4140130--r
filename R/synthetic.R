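#' @include AllClasses.R io.R
NULL

## Run an expression under a fixed RNG state without disturbing the
## caller's stream.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit(
        if (is.null(old))
            suppressWarnings(rm(".Random.seed", envir = globalenv()))
        else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}

#' Specification of a synthetic disease-gene benchmark
#'
#' Defines the generative model for a benchmark instance: an
#' Erdős–Rényi interaction network, per-term Bernoulli annotations, and
#' a planted enrichment signal. Genes within distance 1 of a positive
#' gene (the closed neighborhoods of the positives — the structure the
#' neighborhood encoder can detect) are annotated to each planted term
#' with probability `min(1, baseAnnotProb + signalStrength)` instead of
#' `baseAnnotProb`.
#'
#' The defaults describe the package's reference benchmark: 200 genes
#' with mean degree ~5, a 300-term GO vocabulary plus 40 KEGG
#' pathways, 15 positives, and 20 planted terms carrying an excess
#' annotation probability of 0.5 over a 0.05 base rate.
#'
#' @param nGenes number of genes.
#' @param nGoTerms,nKeggTerms vocabulary sizes of the two namespaces.
#' @param edgeProb Erdős–Rényi edge probability.
#' @param nPositives number of disease-related (positive) genes.
#' @param nInformativeTerms number of planted (signal-carrying) terms,
#'   drawn from the joint GO+KEGG vocabulary.
#' @param signalStrength excess annotation probability for planted
#'   terms within positive neighborhoods (0 = null model).
#' @param baseAnnotProb background annotation probability per
#'   gene-term pair.
#' @param seed integer RNG seed; the same seed reproduces the instance
#'   bit-for-bit.
#' @return a `syntheticSpec` list.
#' @seealso [simulateDiseaseData()]
#' @export
syntheticSpec <- function(nGenes = 200L, nGoTerms = 300L,
                          nKeggTerms = 40L, edgeProb = 0.025,
                          nPositives = 15L, nInformativeTerms = 20L,
                          signalStrength = 0.5, baseAnnotProb = 0.05,
                          seed = 1L) {
    spec <- list(nGenes = as.integer(nGenes),
                 nGoTerms = as.integer(nGoTerms),
                 nKeggTerms = as.integer(nKeggTerms),
                 edgeProb = edgeProb,
                 nPositives = as.integer(nPositives),
                 nInformativeTerms = as.integer(nInformativeTerms),
                 signalStrength = signalStrength,
                 baseAnnotProb = baseAnnotProb,
                 seed = as.integer(seed))
    with(spec, {
        if (nGenes < 2L || nGoTerms < 1L || nKeggTerms < 0L)
            stop("degenerate spec: counts too small")
        if (edgeProb <= 0 || edgeProb >= 1)
            stop("edgeProb must lie in (0,1)")
        if (baseAnnotProb <= 0 || baseAnnotProb >= 1)
            stop("baseAnnotProb must lie in (0,1)")
        if (signalStrength < 0)
            stop("signalStrength must be >= 0")
        if (nPositives >= nGenes)
            stop("nPositives must be smaller than nGenes")
        if (nInformativeTerms > nGoTerms + nKeggTerms)
            stop("more informative terms than vocabulary")
    })
    structure(spec, class = "syntheticSpec")
}

#' Simulate a disease-gene benchmark with planted enrichment signal
#'
#' Draws an instance from a [syntheticSpec()]: an Erdős–Rényi network
#' over the genes, independent Bernoulli annotations per gene-term
#' pair, a randomly chosen positive gene set, and a planted subset of
#' terms whose annotation probability is raised inside the closed
#' neighborhoods of the positives. A three-category toy hierarchy
#' (biological process / cellular component / molecular function
#' analogues) assigns GO terms round-robin to the three category terms
#' so category-level reporting is exercisable.
#'
#' @param spec a [syntheticSpec()].
#' @return a list with components `network` (igraph, all genes as
#'   vertices), `corpus` ([AnnotationCorpus-class], background = all
#'   genes), `hierarchy` ([TermHierarchy-class]), `positives`,
#'   `negatives` (the remaining gene universe), and `plantedTerms`.
#' @examples
#' sim <- simulateDiseaseData(syntheticSpec(nGenes = 50, seed = 7))
#' length(sim$positives)
#' @export
simulateDiseaseData <- function(spec) {
    stopifnot(inherits(spec, "syntheticSpec"))
    withSeed(spec$seed, {
        genes <- sprintf("G%04d", seq_len(spec$nGenes))
        ## Erdős–Rényi edges over all unordered pairs
        pairIdx <- which(upper.tri(diag(spec$nGenes)), arr.ind = TRUE)
        on <- stats::runif(nrow(pairIdx)) < spec$edgeProb
        net <- igraph::make_empty_graph(0, directed = FALSE)
        net <- igraph::add_vertices(net, spec$nGenes, name = genes)
        if (any(on))
            net <- igraph::add_edges(net,
                rbind(pairIdx[on, 1L], pairIdx[on, 2L]))
        positives <- sample(genes, spec$nPositives)

        goIds <- sprintf("GO:%07d", seq_len(spec$nGoTerms))
        keggIds <- sprintf("hsa%05d", seq_len(spec$nKeggTerms))
        termIds <- c(goIds, keggIds)
        planted <- sample(termIds, spec$nInformativeTerms)

        ## genes within distance 1 of a positive (closed neighborhoods)
        zone <- genes[unique(unlist(igraph::ego(net, 1L, positives),
                                    use.names = FALSE))]
        inZone <- genes %in% zone
        pSignal <- min(1, spec$baseAnnotProb + spec$signalStrength)

        termGenes <- vector("list", length(termIds))
        names(termGenes) <- termIds
        for (j in seq_along(termIds)) {
            p <- rep(spec$baseAnnotProb, spec$nGenes)
            if (termIds[[j]] %in% planted) p[inZone] <- pSignal
            ann <- genes[stats::runif(spec$nGenes) < p]
            ## a term catalog only lists terms annotating >= 1 gene;
            ## back an empty draw with one random gene
            if (!length(ann)) ann <- sample(genes, 1L)
            termGenes[[j]] <- ann
        }
        corpus <- AnnotationCorpus(
            termGenes,
            setNames(rep(c("GO", "KEGG"),
                         c(spec$nGoTerms, spec$nKeggTerms)), termIds),
            background = genes)

        cats <- c("GO:catBP", "GO:catCC", "GO:catMF")
        roots <- c("GO:rootBP", "GO:rootCC", "GO:rootMF")
        hier <- TermHierarchy(
            child = c(goIds, cats),
            parent = c(cats[((seq_len(spec$nGoTerms) - 1L) %% 3L) + 1L],
                       roots))
        list(network = net, corpus = corpus, hierarchy = hier,
             positives = positives,
             negatives = setdiff(genes, positives),
             plantedTerms = planted)
    })
}

#' Write a simulated benchmark to disk
#'
#' Emits the five pipeline input files in the package's TSV dialects:
#' `network.tsv` (edge list), `annotations_go.tsv` and
#' `annotations_kegg.tsv` (gene, term), `hierarchy.tsv` (child,
#' parent) and `positives.txt` (one gene per line). The negative
#' universe is recoverable as background minus positives.
#'
#' @param spec a [syntheticSpec()].
#' @param outDir output directory (created if missing).
#' @return invisibly, the [simulateDiseaseData()] result that was
#'   written, with an added `paths` component.
#' @export
emitSyntheticData <- function(spec, outDir) {
    sim <- simulateDiseaseData(spec)
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    paths <- file.path(outDir, c(
        network = "network.tsv", go = "annotations_go.tsv",
        kegg = "annotations_kegg.tsv", hierarchy = "hierarchy.tsv",
        positives = "positives.txt"))
    names(paths) <- c("network", "go", "kegg", "hierarchy",
                      "positives")
    el <- igraph::as_edgelist(sim$network)
    writeLines(paste(el[, 1L], el[, 2L], sep = "\t"),
               paths[["network"]])
    ns <- termNamespace(sim$corpus)
    writeAnnot <- function(which, path) {
        ids <- names(ns)[ns == which]
        rows <- unlist(lapply(ids, function(t)
            paste(genesForTerm(sim$corpus, t), t, sep = "\t")),
            use.names = FALSE)
        writeLines(rows, path)
    }
    writeAnnot("GO", paths[["go"]])
    writeAnnot("KEGG", paths[["kegg"]])
    h <- sim$hierarchy
    rows <- unlist(lapply(names(h@parents), function(ch)
        paste(ch, h@parents[[ch]], sep = "\t")), use.names = FALSE)
    writeLines(rows, paths[["hierarchy"]])
    writeLines(sim$positives, paths[["positives"]])
    sim$paths <- paths
    invisible(sim)
}
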