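#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

.CORPUS_COLS <- c("pmid", "title", "abstract", "journal", "year",
                  "impact_factor")

#' DocumentCorpus: a collection of literature abstract records
#'
#' A `DocumentCorpus` holds the evidence units of a literature-mining run:
#' one record per PubMed-style abstract with its title, journal, year and
#' (once annotated) journal impact factor. Records are stored in a
#' `data.frame` with columns `pmid`, `title`, `abstract`, `journal`, `year`
#' and `impact_factor`; `pmid`s are unique within a corpus and record order
#' is stable under round-trip I/O.
#'
#' @slot records data.frame of abstract records (see above).
#' @slot provenance character vector of query strings / source notes
#'   accumulated as the corpus is built, merged and filtered.
#'
#' @seealso [readCorpus()], [writeCorpus()], [mergeCorpora()],
#'   [annotateImpactFactor()], [filterByImpactFactor()]
#' @export
setClass("DocumentCorpus",
         representation(records = "data.frame", provenance = "character"))

setValidity("DocumentCorpus", function(object) {
    rec <- object@records
    miss <- setdiff(.CORPUS_COLS, names(rec))
    if (length(miss))
        return(paste("records missing columns:", paste(miss, collapse = ", ")))
    if (nrow(rec)) {
        if (any(is.na(rec$pmid)) || any(!nzchar(rec$pmid)))
            return("every record needs a non-empty pmid")
        if (anyDuplicated(rec$pmid))
            return("duplicate pmids in corpus")
        iff <- rec$impact_factor
        if (any(!is.na(iff) & iff < 0))
            return("impact_factor must be >= 0 when present")
    }
    TRUE
})

#' Construct a DocumentCorpus
#'
#' @param records data.frame with at least `pmid`, `title`, `abstract`,
#'   `journal`, `year`; an `impact_factor` column is added (as `NA`) when
#'   absent.
#' @param provenance character vector of free-text provenance notes.
#' @return A [DocumentCorpus-class] object.
#' @examples
#' DocumentCorpus(data.frame(pmid = "1", title = "t", abstract = "a",
#'                           journal = "J", year = 2020L))
#' @export
DocumentCorpus <- function(records = data.frame(), provenance = character()) {
    if (!nrow(records) && !length(records))
        records <- data.frame(pmid = character(), title = character(),
                              abstract = character(), journal = character(),
                              year = integer(), impact_factor = double())
    if (!"impact_factor" %in% names(records))
        records$impact_factor <- NA_real_
    records$pmid <- as.character(records$pmid)
    records$title <- as.character(records$title)
    records$abstract <- as.character(records$abstract)
    records$journal <- as.character(records$journal)
    records$year <- as.integer(records$year)
    records$impact_factor <- as.numeric(records$impact_factor)
    records <- records[, .CORPUS_COLS, drop = FALSE]
    rownames(records) <- NULL
    new("DocumentCorpus", records = records,
        provenance = as.character(provenance))
}

#' GeneDictionary: HGNC symbols, aliases and banned acronyms
#'
#' Dictionary driving gene named-entity recognition. Matching is
#' case-sensitive and token-exact; `aliases` map alternative surface forms
#' to their approved symbol; `exclusions` are surface forms (or symbols)
#' that must never be reported because they collide with common laboratory
#' acronyms (e.g. "CBF", ciliary beat frequency). Exclusions are applied at
#' match time, so an excluded symbol stays in the dictionary.
#'
#' @slot symbols character vector of approved symbols.
#' @slot aliases named character vector, `names()` are the aliases and the
#'   values the approved symbol each maps to.
#' @slot exclusions character vector of banned tokens.
#' @seealso [recognizeGenes()], [buildTDM()], [defaultExclusions()]
#' @export
setClass("GeneDictionary",
         representation(symbols = "character", aliases = "character",
                        exclusions = "character"))

setValidity("GeneDictionary", function(object) {
    if (!length(object@symbols)) return("dictionary has no symbols")
    if (any(is.na(object@symbols)) || any(!nzchar(object@symbols)))
        return("symbols must be non-empty strings")
    if (anyDuplicated(object@symbols)) return("duplicate symbols")
    if (length(object@aliases) && is.null(names(object@aliases)))
        return("aliases must be a named character vector (alias -> symbol)")
    TRUE
})

#' Construct a GeneDictionary
#'
#' @param symbols character vector of approved (HGNC-style) symbols.
#' @param aliases named character vector mapping alias -> approved symbol.
#' @param exclusions character vector of banned tokens (never reported).
#' @return A [GeneDictionary-class] object.
#' @examples
#' geneDictionary(c("EGFR", "MUC5AC"), aliases = c(HER1 = "EGFR"))
#' @export
geneDictionary <- function(symbols, aliases = character(),
                           exclusions = character()) {
    symbols <- unique(as.character(symbols))
    symbols <- symbols[!is.na(symbols) & nzchar(symbols)]
    if (!length(symbols)) stop("empty gene dictionary")
    aliases <- if (length(aliases)) {
        stopifnot(!is.null(names(aliases)))
        vapply(aliases, as.character, "")
    } else {
        structure(character(), names = character())
    }
    new("GeneDictionary", symbols = symbols, aliases = aliases,
        exclusions = unique(as.character(exclusions)))
}

#' TermDocumentMatrix: gene-by-document incidence from dictionary NER
#'
#' Sparse gene x document matrices produced by [buildTDM()]. `incidence` is
#' binary (gene mentioned at least once in the document's title+abstract);
#' `counts` holds raw mention counts, and `incidence == (counts >= 1)`
#' always. Rows and columns are sorted canonically (alphabetically) so that
#' the matrix is invariant to record order. Genes from the dictionary that
#' were never mentioned are dropped and listed in `dropped`.
#'
#' @slot incidence dgCMatrix, binary gene x document incidence.
#' @slot counts dgCMatrix of mention counts, same dimnames.
#' @slot dropped character, dictionary symbols with no mention in the corpus.
#' @seealso [buildTDM()], [cosineMatrix()], [uniqueGenes()]
#' @export
setClass("TermDocumentMatrix",
         representation(incidence = "dgCMatrix", counts = "dgCMatrix",
                        dropped = "character"))

setValidity("TermDocumentMatrix", function(object) {
    inc <- object@incidence; cnt <- object@counts
    if (!identical(dim(inc), dim(cnt))) return("incidence/counts dim mismatch")
    if (!identical(dimnames(inc), dimnames(cnt)))
        return("incidence/counts dimnames mismatch")
    if (is.null(rownames(inc)) || is.null(colnames(inc)))
        return("gene and document names are required")
    if (anyDuplicated(rownames(inc))) return("duplicate gene rows")
    if (anyDuplicated(colnames(inc))) return("duplicate document columns")
    if (length(inc@x) && !all(inc@x %in% c(0, 1)))
        return("incidence entries must be 0/1")
    if (!isTRUE(all(as.logical(inc != 0) == as.logical(cnt != 0))))
        return("incidence must equal (counts >= 1)")
    TRUE
})

#' CosineMatrix: pairwise gene co-occurrence scores
#'
#' Symmetric gene x gene matrix of cosine similarities
#' \eqn{c(g,h) = n_{gh} / \sqrt{n_g n_h}} over binary document-incidence
#' vectors: 0 means the two genes are never co-mentioned in an abstract, 1
#' means their abstract sets are identical.
#'
#' @slot scores symmetric numeric matrix in \[0,1\], unit diagonal.
#' @slot nDocs named numeric, documents per gene (\eqn{n_g}).
#' @slot nJoint numeric matrix of joint document counts (\eqn{n_{gh}}).
#' @seealso [cosineMatrix()], [topPairs()]
#' @export
setClass("CosineMatrix",
         representation(scores = "matrix", nDocs = "numeric",
                        nJoint = "matrix"))

setValidity("CosineMatrix", function(object) {
    s <- object@scores
    if (!isTRUE(all.equal(s, t(s), tolerance = 1e-12)))
        return("scores must be symmetric")
    if (any(s < -1e-12 | s > 1 + 1e-12)) return("scores must lie in [0,1]")
    if (!identical(dimnames(s), dimnames(object@nJoint)))
        return("scores/nJoint dimnames mismatch")
    if (!identical(rownames(s), names(object@nDocs)))
        return("nDocs names must match score rows")
    TRUE
})

#' Geneset: a named gene collection with S/R/A provenance categories
#'
#' Key-event genesets pool seed genes (category "S"), relevant genes from
#' curated co-occurring pairs ("R") and additional genes from manual
#' citation chasing ("A"); category precedence on overlap is S > R > A.
#' Genesets imported from plain GMT files with no category metadata carry
#' category "U" (uncategorized). Each member can carry provenance
#' references (pmids or citation keys).
#'
#' @slot name geneset (key event) identifier.
#' @slot members character vector of unique gene symbols.
#' @slot category character vector parallel to `members`, in
#'   \{"S","R","A","U"\}.
#' @slot provenance named list (by member) of character reference vectors.
#' @seealso [assembleGeneset()], [mergeGenesets()], [readGMT()], [writeGMT()]
#' @export
setClass("Geneset",
         representation(name = "character", members = "character",
                        category = "character", provenance = "list"))

setValidity("Geneset", function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
        return("name must be a single non-empty string")
    if (anyDuplicated(object@members)) return("duplicate members")
    if (length(object@category) != length(object@members))
        return("one category per member required")
    if (length(object@members) && !all(object@category %in% c("S", "R", "A", "U")))
        return("categories must be S, R, A or U")
    if (length(object@provenance) &&
        !all(names(object@provenance) %in% object@members))
        return("provenance keys must be members")
    TRUE
})

#' PCAModel: principal component analysis of an expression matrix
#'
#' Samples are observations, genes are variables. `scores` are sample x
#' component coordinates, `loadings` gene x component orthonormal axes, and
#' `varianceExplained` the per-component fraction of total variance
#' (non-increasing, summing to <= 1 when truncated).
#'
#' @slot scores numeric matrix, samples x components.
#' @slot loadings numeric matrix, genes x components (orthonormal columns).
#' @slot varianceExplained numeric, fraction of variance per component.
#' @slot center numeric, per-gene means removed before the SVD.
#' @slot scaled logical flag, whether rows were Z-scored first.
#' @seealso [pcaFit()], [associatePCs()]
#' @export
setClass("PCAModel",
         representation(scores = "matrix", loadings = "matrix",
                        varianceExplained = "numeric", center = "numeric",
                        scaled = "logical"))

setValidity("PCAModel", function(object) {
    k <- ncol(object@scores)
    if (ncol(object@loadings) != k) return("scores/loadings component mismatch")
    if (length(object@varianceExplained) != k)
        return("one varianceExplained entry per component")
    ve <- object@varianceExplained
    if (any(diff(ve) > 1e-10)) return("varianceExplained must be non-increasing")
    if (sum(ve) > 1 + 1e-8) return("varianceExplained must sum to <= 1")
    TRUE
})
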