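#' @include AllClasses.R
NULL

#' Term identifiers of an object
#'
#' Returns the ordered vector of functional-term identifiers (GO terms
#' first, then KEGG pathways) carried by an [AnnotationCorpus] or an
#' [EnrichmentMatrix]. This ordering defines feature-vector coordinates
#' and is stable across a run.
#'
#' @param x an `AnnotationCorpus` or `EnrichmentMatrix`.
#' @return character vector of term identifiers.
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' Namespace of each term
#'
#' @param x an `AnnotationCorpus` or `EnrichmentMatrix`.
#' @return character vector, `"GO"` or `"KEGG"`, named by term id and
#'   parallel to [termIds()].
#' @export
setGeneric("termNamespace", function(x) standardGeneric("termNamespace"))

#' Gene identifiers of an object
#'
#' @param x an `EnrichmentMatrix`.
#' @return character vector of gene identifiers, in row order of the
#'   genes-by-terms score matrix.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
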