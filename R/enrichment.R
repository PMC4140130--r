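#' @include AllClasses.R accessors.R
NULL

#' Closed network neighborhood of a gene
#'
#' The evaluated gene set G for the enrichment test: the gene itself
#' together with its direct interaction partners. A gene absent from
#' the network has the singleton neighborhood `{gene}`, which keeps the
#' hypergeometric draw size n >= 1 well defined. With
#' `open = TRUE` the gene itself is excluded (direct neighbors only),
#' so an absent or isolated gene yields the empty set.
#'
#' @param gene a gene id.
#' @param network an undirected [igraph::igraph] with gene-id vertex
#'   names.
#' @param open logical; drop the gene itself from G.
#' @return character vector of gene ids.
#' @export
geneNeighborhood <- function(gene, network, open = FALSE) {
    stopifnot(length(gene) == 1L)
    idx <- match(gene, igraph::V(network)$name)
    nb <- if (is.na(idx)) character() else
        igraph::V(network)$name[
            as.integer(igraph::neighbors(network, idx))]
    if (open) setdiff(nb, gene) else unique(c(gene, nb))
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= m) for X ~ hypergeometric(N, M, n): the probability that a
#' uniformly drawn n-subset of an N-gene background contains at least m
#' of the M genes annotated to a term,
#' \deqn{\sum_{k=m}^{n} \binom{M}{k}\binom{N-M}{n-k} / \binom{N}{n},}
#' with terms where k > M or n-k > N-M contributing zero. Computed via
#' the stable distribution-function routine rather than naive
#' summation. Vectorized over its arguments.
#'
#' @param N background (population) size.
#' @param M number of background genes annotated to the term.
#' @param n size of the evaluated gene set G.
#' @param m number of members of G annotated to the term.
#' @return probability in (0, 1]; exactly 1 when `m == 0`.
#' @examples
#' hypergeomUpperTail(20, 5, 6, 3)
#' @export
hypergeomUpperTail <- function(N, M, n, m) {
    bad <- M > N | n > N | m > pmin(n, M) | N < 1 | M < 0 | n < 0 |
        m < 0
    if (any(bad))
        stop("invalid hypergeometric parameters: need 0 <= m <= ",
             "min(n, M), n <= N, M <= N")
    stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Neighborhood enrichment score of a gene for one term
#'
#' The score is `-log10` of [hypergeomUpperTail()] evaluated on the
#' gene's closed neighborhood G: N is the background size, M the
#' term's annotation count, n = |G| (restricted to the background) and
#' m = |G ∩ annotated genes|. The score is 0 whenever m = 0 (the tail
#' probability is then 1) and is capped at `cap` when the tail
#' underflows, so scores are always finite and non-negative.
#'
#' @param gene a gene id; must belong to the corpus background.
#' @param term a term id present in the corpus.
#' @param network an [igraph::igraph] interaction network.
#' @param corpus an [AnnotationCorpus-class].
#' @param open logical; use the open neighborhood (direct neighbors
#'   only, excluding the gene).
#' @param cap upper bound applied to the score (default 300,
#'   corresponding to tail probabilities below 1e-300).
#' @return a single non-negative enrichment score.
#' @export
enrichmentScore <- function(gene, term, network, corpus,
                            open = FALSE, cap = 300) {
    stopifnot(is(corpus, "AnnotationCorpus"))
    bg <- backgroundGenes(corpus)
    if (!gene %in% bg)
        stop("gene not in annotation background: ", gene)
    G <- intersect(geneNeighborhood(gene, network, open = open), bg)
    ann <- genesForTerm(corpus, term)
    m <- length(intersect(G, ann))
    if (m == 0L) return(0)
    p <- hypergeomUpperTail(length(bg), length(ann), length(G), m)
    min(-log10(p), cap)
}

#' Encode genes as neighborhood-enrichment feature vectors
#'
#' Builds the genes-by-terms [EnrichmentMatrix-class]: one row per
#' input gene, one column per term in corpus feature order (all GO
#' terms, then all KEGG pathways), each entry the neighborhood
#' enrichment score of that gene for that term. Deterministic;
#' permuting the input gene order permutes rows only.
#'
#' Genes missing from the annotation background are dropped with a
#' warning (their evaluated set G cannot be defined consistently).
#'
#' @param genes ordered character vector of gene ids.
#' @param network an [igraph::igraph] interaction network.
#' @param corpus an [AnnotationCorpus-class].
#' @param labels optional binary labels parallel to `genes` (kept for
#'   the retained genes).
#' @inheritParams enrichmentScore
#' @return an [EnrichmentMatrix-class] with `length(genes)` columns
#'   dropped to those in the background.
#' @export
encodeGenes <- function(genes, network, corpus, labels = NULL,
                        open = FALSE, cap = 300) {
    stopifnot(is(corpus, "AnnotationCorpus"))
    bg <- backgroundGenes(corpus)
    keep <- genes %in% bg
    if (!all(keep)) {
        warning(sum(!keep), " gene(s) not in the annotation ",
                "background were dropped")
        genes <- genes[keep]
        if (!is.null(labels)) labels <- labels[keep]
    }
    terms <- termIds(corpus)
    N <- length(bg)
    M <- unname(termSizes(corpus))
    ## sparse background-by-term membership for fast m counting
    gi <- unlist(lapply(corpus@termGenes, match, table = bg),
                 use.names = FALSE)
    ti <- rep.int(seq_along(terms), M)
    A <- Matrix::sparseMatrix(i = gi, j = ti,
                              dims = c(N, length(terms)))
    scores <- matrix(0, nrow = length(genes), ncol = length(terms),
                     dimnames = list(genes, terms))
    for (r in seq_along(genes)) {
        G <- intersect(geneNeighborhood(genes[[r]], network,
                                        open = open), bg)
        n <- length(G)
        if (n == 0L) next
        m <- Matrix::colSums(A[match(G, bg), , drop = FALSE])
        pos <- which(m > 0)
        if (!length(pos)) next
        p <- stats::phyper(m[pos] - 1, M[pos], N - M[pos], n,
                           lower.tail = FALSE)
        scores[r, pos] <- pmin(-log10(p), cap)
    }
    EnrichmentMatrix(scores, termNamespace(corpus), labels)
}
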