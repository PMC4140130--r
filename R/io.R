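#' @include AllClasses.R
NULL

## Simple whitespace/TAB-delimited dialects; deliberately not the native
## STRING/OBO/GAF/KGML formats (inputs are assumed pre-harmonized).

splitFields <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read an interaction network from a two-column edge list
#'
#' Each non-empty line holds `geneA geneB` (TAB- or space-separated)
#' with an optional third numeric column carrying an interaction
#' confidence score. Duplicate rows and reversed duplicates collapse to
#' a single undirected edge; self-loop rows are dropped with a warning.
#'
#' @param path path to the edge-list file.
#' @param minScore optional numeric; when set, rows whose third column
#'   is below it are dropped (rows without a score are kept).
#' @return an undirected [igraph::igraph] graph whose vertex names are
#'   gene ids.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "A\tA"), f)
#' g <- readNetwork(f)   # one edge {A,B}; the self-loop is dropped
#' igraph::gsize(g)
#' @export
readNetwork <- function(path, minScore = NULL) {
    if (!file.exists(path)) stop("network file not found: ", path)
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    fields <- splitFields(lines[keep])
    lineNo <- which(keep)
    nf <- lengths(fields)
    bad <- which(nf < 2L | nf > 3L)
    if (length(bad))
        stop("malformed network row at line ", lineNo[bad[[1L]]],
             ": expected 2-3 columns, got ", nf[bad[[1L]]])
    if (!length(fields))
        return(igraph::make_empty_graph(0, directed = FALSE))
    a <- vapply(fields, `[[`, character(1), 1L)
    b <- vapply(fields, `[[`, character(1), 2L)
    if (!is.null(minScore)) {
        score <- vapply(fields, function(f)
            if (length(f) >= 3L) suppressWarnings(as.numeric(f[[3L]]))
            else NA_real_, numeric(1))
        drop <- !is.na(score) & score < minScore
        a <- a[!drop]; b <- b[!drop]
    }
    self <- a == b
    if (any(self))
        warning(sum(self), " self-loop row(s) dropped")
    a2 <- pmin(a[!self], b[!self])
    b2 <- pmax(a[!self], b[!self])
    keyed <- !duplicated(paste(a2, b2, sep = "\r"))
    nodes <- unique(c(a, b))
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    if (any(keyed))
        g <- igraph::add_edges(
            g, rbind(match(a2[keyed], nodes), match(b2[keyed], nodes)))
    g
}

readTwoColumn <- function(path, what) {
    if (!file.exists(path)) stop(what, " file not found: ", path)
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    fields <- splitFields(lines[keep])
    lineNo <- which(keep)
    nf <- lengths(fields)
    bad <- which(nf != 2L)
    if (length(bad))
        stop("malformed ", what, " row at line ", lineNo[bad[[1L]]],
             ": expected 2 columns, got ", nf[bad[[1L]]])
    list(first = vapply(fields, `[[`, character(1), 1L),
         second = if (length(fields))
             vapply(fields, `[[`, character(1), 2L) else character())
}

#' Read GO and KEGG annotation tables into an AnnotationCorpus
#'
#' Each annotation file is a two-column `gene term` table; a gene
#' annotated twice to the same term is counted once. Feature order is
#' GO terms in first-appearance order, then KEGG terms in
#' first-appearance order.
#'
#' When no explicit background file is given, the background is the
#' union of all genes seen in the two annotation files and (if
#' supplied) the vertices of `network`, so the hypergeometric
#' population size N is self-contained and reproducible.
#'
#' @param goPath,keggPath paths to the GO and KEGG annotation tables.
#' @param backgroundPath optional path to a one-gene-per-line
#'   background file.
#' @param network optional [igraph::igraph] whose vertices join the
#'   background.
#' @return an [AnnotationCorpus-class].
#' @export
readAnnotations <- function(goPath, keggPath, backgroundPath = NULL,
                            network = NULL) {
    go <- readTwoColumn(goPath, "GO annotation")
    kegg <- readTwoColumn(keggPath, "KEGG annotation")
    if (!length(go$first) || !length(kegg$first))
        stop("empty annotation file: no features would exist")
    goTerms <- lapply(split(go$first, factor(go$second,
        levels = unique(go$second))), unique)
    keggTerms <- lapply(split(kegg$first, factor(kegg$second,
        levels = unique(kegg$second))), unique)
    if (length(intersect(names(goTerms), names(keggTerms))))
        stop("a term id appears in both the GO and KEGG tables")
    termGenes <- c(goTerms, keggTerms)
    ns <- setNames(rep(c("GO", "KEGG"),
                       c(length(goTerms), length(keggTerms))),
                   names(termGenes))
    if (!is.null(backgroundPath)) {
        background <- readGeneList(backgroundPath)
    } else {
        background <- unique(c(go$first, kegg$first,
            if (!is.null(network)) igraph::V(network)$name))
    }
    AnnotationCorpus(termGenes, ns, background)
}

#' Read a one-gene-per-line list
#'
#' Lines starting with `#` are comments; order is preserved and
#' duplicates are removed keeping the first occurrence (with a
#' warning).
#'
#' @param path path to the gene-list file.
#' @return character vector of gene ids (never empty).
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("gene list file not found: ", path)
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("gene list is empty: ", path)
    if (anyDuplicated(lines))
        warning(sum(duplicated(lines)),
                " duplicate gene id(s) removed, keeping first occurrence")
    unique(lines)
}

#' Read a term hierarchy from a child-parent table
#'
#' Two-column `child parent` table; roots are inferred as terms that
#' appear as parents but never as children.
#'
#' @param path path to the hierarchy file.
#' @return a [TermHierarchy-class].
#' @export
readTermHierarchy <- function(path) {
    d <- readTwoColumn(path, "hierarchy")
    if (!length(d$first)) stop("hierarchy file is empty: ", path)
    TermHierarchy(child = d$first, parent = d$second)
}

#' Write / read an enrichment feature matrix as TSV
#'
#' The file has one header row (`gene`, then the term ids, then
#' optionally `label`) and one row per gene. Values round-trip
#' losslessly to 12 significant digits. The `label` column is written
#' whenever any gene carries a non-`NA` label.
#'
#' @param x an [EnrichmentMatrix-class].
#' @param path output (input) file path.
#' @return `writeFeatureMatrix` returns `path` invisibly;
#'   `readFeatureMatrix` returns an [EnrichmentMatrix-class]. Term
#'   namespaces are re-derived on read from the id prefix when
#'   possible; supply `namespace` to override.
#' @param namespace optional character vector of `"GO"`/`"KEGG"` for
#'   the read matrix's columns; default classifies ids starting with
#'   `"KEGG"`/`"hsa"`/`"path"` as KEGG and the rest as GO.
#' @export
writeFeatureMatrix <- function(x, path) {
    stopifnot(is(x, "EnrichmentMatrix"))
    m <- scoreMatrix(x)
    lab <- geneLabels(x)
    hasLab <- any(!is.na(lab))
    header <- c("gene", colnames(m), if (hasLab) "label")
    body <- cbind(rownames(m),
                  matrix(sprintf("%.12g", m), nrow = nrow(m)),
                  if (hasLab) ifelse(is.na(lab), "NA", lab))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(header, collapse = "\t"), con)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path, namespace = NULL) {
    if (!file.exists(path)) stop("feature matrix file not found: ", path)
    lines <- readLines(path)
    if (!length(lines)) stop("feature matrix file is empty")
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (header[[1L]] != "gene")
        stop("feature matrix header must start with 'gene'")
    hasLab <- header[[length(header)]] == "label"
    terms <- header[-c(1L, if (hasLab) length(header))]
    rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
    bad <- which(lengths(rows) != length(header))
    if (length(bad))
        stop("feature matrix width mismatch at line ", bad[[1L]] + 1L)
    genes <- vapply(rows, `[[`, character(1), 1L)
    vals <- t(vapply(rows, function(r)
        as.numeric(r[1L + seq_along(terms)]),
        numeric(length(terms))))
    if (length(terms) == 1L) vals <- matrix(vals, ncol = 1L)
    dimnames(vals) <- list(genes, terms)
    labels <- if (hasLab)
        suppressWarnings(as.integer(
            vapply(rows, `[[`, character(1), length(header))))
    if (is.null(namespace))
        namespace <- ifelse(
            grepl("^(KEGG|hsa|path)", terms), "KEGG", "GO")
    EnrichmentMatrix(vals, namespace, labels)
}

#' Write a final optimal feature set as TSV
#'
#' Columns: term, namespace, multiplicity — one row per member of the
#' final optimal set, in feature order.
#'
#' @param x a [FinalOptimalSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFinalSet <- function(x, path) {
    stopifnot(is(x, "FinalOptimalSet"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("term\tnamespace\tmultiplicity", con)
    if (length(x@features))
        writeLines(paste(x@features, x@namespace,
                         x@multiplicity, sep = "\t"), con)
    invisible(path)
}
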