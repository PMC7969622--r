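#' Accessors for aopminer classes
#'
#' Small accessor generics: `corpusRecords()` returns the record
#' `data.frame` of a [DocumentCorpus-class]; `pmids()` its document ids;
#' `corpusProvenance()` its provenance notes. `incidenceMatrix()` /
#' `mentionCounts()` / `droppedGenes()` expose the slots of a
#' [TermDocumentMatrix-class]; `cosineScores()` / `jointCounts()` /
#' `docCounts()` those of a [CosineMatrix-class]. `setName()`, `geneIds()`,
#' `geneCategories()` and `geneProvenance()` read a [Geneset-class];
#' `pcaScores()`, `pcaLoadings()` and `varianceExplained()` a
#' [PCAModel-class].
#'
#' @param x an aopminer object.
#' @return The slot contents (see above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("corpusRecords", function(x) standardGeneric("corpusRecords"))
#' @rdname accessors
#' @export
setGeneric("pmids", function(x) standardGeneric("pmids"))
#' @rdname accessors
#' @export
setGeneric("corpusProvenance",
           function(x) standardGeneric("corpusProvenance"))
#' @rdname accessors
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))
#' @rdname accessors
#' @export
setGeneric("mentionCounts", function(x) standardGeneric("mentionCounts"))
#' @rdname accessors
#' @export
setGeneric("droppedGenes", function(x) standardGeneric("droppedGenes"))
#' @rdname accessors
#' @export
setGeneric("cosineScores", function(x) standardGeneric("cosineScores"))
#' @rdname accessors
#' @export
setGeneric("jointCounts", function(x) standardGeneric("jointCounts"))
#' @rdname accessors
#' @export
setGeneric("docCounts", function(x) standardGeneric("docCounts"))
#' @rdname accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("geneCategories", function(x) standardGeneric("geneCategories"))
#' @rdname accessors
#' @export
setGeneric("geneProvenance", function(x) standardGeneric("geneProvenance"))
#' @rdname accessors
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))
#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))
#' @rdname accessors
#' @export
setGeneric("varianceExplained",
           function(x) standardGeneric("varianceExplained"))

#' @rdname topPairs
#' @export
setGeneric("topPairs",
           function(x, n = 60L, minJoint = 1L, ...) standardGeneric("topPairs"))

## ---- accessor methods -----------------------------------------------------

#' @rdname accessors
setMethod("corpusRecords", "DocumentCorpus", function(x) x@records)
#' @rdname accessors
setMethod("pmids", "DocumentCorpus", function(x) x@records$pmid)
#' @rdname accessors
setMethod("corpusProvenance", "DocumentCorpus", function(x) x@provenance)
#' @rdname accessors
setMethod("incidenceMatrix", "TermDocumentMatrix", function(x) x@incidence)
#' @rdname accessors
setMethod("mentionCounts", "TermDocumentMatrix", function(x) x@counts)
#' @rdname accessors
setMethod("droppedGenes", "TermDocumentMatrix", function(x) x@dropped)
#' @rdname accessors
setMethod("cosineScores", "CosineMatrix", function(x) x@scores)
#' @rdname accessors
setMethod("jointCounts", "CosineMatrix", function(x) x@nJoint)
#' @rdname accessors
setMethod("docCounts", "CosineMatrix", function(x) x@nDocs)
#' @rdname accessors
setMethod("setName", "Geneset", function(x) x@name)
#' @rdname accessors
setMethod("geneIds", "Geneset", function(x) x@members)
#' @rdname accessors
setMethod("geneCategories", "Geneset",
          function(x) structure(x@category, names = x@members))
#' @rdname accessors
setMethod("geneProvenance", "Geneset", function(x) x@provenance)
#' @rdname accessors
setMethod("pcaScores", "PCAModel", function(x) x@scores)
#' @rdname accessors
setMethod("pcaLoadings", "PCAModel", function(x) x@loadings)
#' @rdname accessors
setMethod("varianceExplained", "PCAModel", function(x) x@varianceExplained)

## ---- length / dim / show --------------------------------------------------

#' @describeIn DocumentCorpus-class number of records.
#' @param x a DocumentCorpus.
#' @export
setMethod("length", "DocumentCorpus", function(x) nrow(x@records))

#' @describeIn TermDocumentMatrix-class genes x documents dimensions.
#' @param x a TermDocumentMatrix.
#' @export
setMethod("dim", "TermDocumentMatrix", function(x) dim(x@incidence))

#' @describeIn Geneset-class number of member genes.
#' @param x a Geneset.
#' @export
setMethod("length", "Geneset", function(x) length(x@members))

setMethod("show", "DocumentCorpus", function(object) {
    cat(sprintf("DocumentCorpus with %d record(s)\n", nrow(object@records)))
    n <- sum(!is.na(object@records$impact_factor))
    cat(sprintf("  impact factor annotated: %d/%d\n", n, nrow(object@records)))
    if (length(object@provenance))
        cat("  provenance:", paste(utils::head(object@provenance, 3),
                                   collapse = "; "),
            if (length(object@provenance) > 3) "..." else "", "\n")
})

setMethod("show", "GeneDictionary", function(object) {
    cat(sprintf("GeneDictionary: %d symbol(s), %d alias(es), %d exclusion(s)\n",
                length(object@symbols), length(object@aliases),
                length(object@exclusions)))
})

setMethod("show", "TermDocumentMatrix", function(object) {
    cat(sprintf("TermDocumentMatrix: %d gene(s) x %d document(s), %d nonzero\n",
                nrow(object@incidence), ncol(object@incidence),
                length(object@incidence@x)))
    if (length(object@dropped))
        cat(sprintf("  %d dictionary symbol(s) never mentioned (dropped)\n",
                    length(object@dropped)))
})

setMethod("show", "CosineMatrix", function(object) {
    cat(sprintf("CosineMatrix over %d gene(s)\n", nrow(object@scores)))
})

setMethod("show", "Geneset", function(object) {
    tab <- table(factor(object@category, levels = c("S", "R", "A", "U")))
    cat(sprintf("Geneset '%s': %d gene(s) [S:%d R:%d A:%d U:%d]\n",
                object@name, length(object@members),
                tab[["S"]], tab[["R"]], tab[["A"]], tab[["U"]]))
})

setMethod("show", "PCAModel", function(object) {
    cat(sprintf("PCAModel: %d sample(s), %d component(s)\n",
                nrow(object@scores), ncol(object@scores)))
    cat("  variance explained:",
        paste(sprintf("%.3f", utils::head(object@varianceExplained, 5)),
              collapse = " "), "\n")
})
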