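#' Load a gene dictionary from TSV
#'
#' The TSV needs a `symbol` column and may carry an `alias` column; rows
#' with a non-empty alias add an alias -> symbol mapping (the symbol itself
#' is always included). An optional exclusion file lists one banned token
#' per line (`#` comments allowed); exclusions are applied at match time by
#' [recognizeGenes()], not at load time, so excluded symbols stay in the
#' dictionary.
#'
#' @param path dictionary TSV.
#' @param exclusionPath optional exclusion list file.
#' @return a [GeneDictionary-class].
#' @export
loadGeneDictionary <- function(path, exclusionPath = NULL) {
    df <- .read_tsv(path)
    if (!"symbol" %in% names(df)) stop("dictionary TSV needs a 'symbol' column")
    symbols <- unique(as.character(df$symbol))
    symbols <- symbols[!is.na(symbols) & nzchar(symbols)]
    if (!length(symbols)) stop("empty gene dictionary: ", path)
    aliases <- character()
    if ("alias" %in% names(df)) {
        ok <- !is.na(df$alias) & nzchar(df$alias)
        aliases <- structure(as.character(df$symbol[ok]),
                             names = as.character(df$alias[ok]))
        aliases <- aliases[!duplicated(names(aliases))]
    }
    exclusions <- if (!is.null(exclusionPath))
        .read_exclusions(exclusionPath) else character()
    geneDictionary(symbols, aliases = aliases, exclusions = exclusions)
}

.read_exclusions <- function(path) {
    x <- readLines(path, encoding = "UTF-8", warn = FALSE)
    x <- trimws(sub("#.*$", "", x))
    unique(x[nzchar(x)])
}

#' Default false-acronym exclusion list
#'
#' Laboratory/measurement acronyms (CBF, TEER, LDH, ...) that collide with
#' gene-symbol-shaped tokens in abstracts and are excluded from NER by
#' default. Shipped with the package; extend or replace it with your own
#' curated list.
#'
#' @return character vector of banned tokens.
#' @export
defaultExclusions <- function() {
    .read_exclusions(system.file("extdata", "default_exclusions.txt",
                                 package = "aopminer", mustWork = TRUE))
}

#' Recognize gene symbols in free text
#'
#' Dictionary NER: the text is split into maximal alphanumeric tokens (so
#' "EGFR-dependent" yields the token "EGFR") and each token is compared
#' case-sensitively against the approved symbols and aliases. Aliases are
#' reported under their approved symbol. A match whose surface token or
#' mapped symbol is on the exclusion list is never reported. Symbols that
#' themselves contain non-alphanumeric characters (e.g. "HLA-A") are
#' matched as exact substrings bounded by non-alphanumerics.
#'
#' @param text a single character string.
#' @param dictionary a [GeneDictionary-class].
#' @return data.frame with columns `symbol`, `start`, `end`,
#'   `matched_text`, ordered by `start` (zero rows when nothing matches).
#' @examples
#' d <- geneDictionary(c("EGFR", "MUC5AC"))
#' recognizeGenes("EGFR activation by tobacco smoke", d)
#' @export
recognizeGenes <- function(text, dictionary) {
    stopifnot(is(dictionary, "GeneDictionary"))
    if (is.null(text)) stop("text must not be NULL")
    text <- as.character(text)
    stopifnot(length(text) == 1L)
    if (is.na(text) || !nzchar(text)) return(.empty_mentions())

    simple <- dictionary@symbols[grepl("^[A-Za-z0-9]+$", dictionary@symbols)]
    special <- setdiff(dictionary@symbols, simple)
    out <- list()

    m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
    if (m[1] != -1L) {
        starts <- as.integer(m)
        lens <- attr(m, "match.length")
        toks <- substring(text, starts, starts + lens - 1L)
        sym <- ifelse(toks %in% simple, toks,
                      unname(dictionary@aliases[toks]))
        hit <- !is.na(sym)
        if (any(hit))
            out[[1]] <- data.frame(symbol = sym[hit], start = starts[hit],
                                   end = starts[hit] + lens[hit] - 1L,
                                   matched_text = toks[hit],
                                   stringsAsFactors = FALSE)
    }
    for (s in special) {
        pat <- sprintf("(?<![A-Za-z0-9])\\Q%s\\E(?![A-Za-z0-9])", s)
        mm <- gregexpr(pat, text, perl = TRUE)[[1]]
        if (mm[1] == -1L) next
        starts <- as.integer(mm)
        lens <- attr(mm, "match.length")
        out[[length(out) + 1L]] <- data.frame(
            symbol = s, start = starts, end = starts + lens - 1L,
            matched_text = substring(text, starts, starts + lens - 1L),
            stringsAsFactors = FALSE)
    }
    if (!length(out)) return(.empty_mentions())
    res <- do.call(rbind, out)
    excl <- dictionary@exclusions
    res <- res[!(res$matched_text %in% excl | res$symbol %in% excl), ,
               drop = FALSE]
    res <- res[order(res$start), , drop = FALSE]
    rownames(res) <- NULL
    res
}

.empty_mentions <- function() {
    data.frame(symbol = character(), start = integer(), end = integer(),
               matched_text = character(), stringsAsFactors = FALSE)
}

#' Build the gene x document term-document matrix
#'
#' Runs [recognizeGenes()] over the title+abstract of every record and
#' assembles sparse mention-count and binary incidence matrices
#' (`incidence(g, d) = 1` iff gene g is mentioned at least once in document
#' d). Rows and columns are sorted alphabetically so the result does not
#' depend on record order. Dictionary symbols never mentioned are dropped
#' (and reported in the `dropped` slot).
#'
#' @param corpus a non-empty [DocumentCorpus-class].
#' @param dictionary a [GeneDictionary-class].
#' @return a [TermDocumentMatrix-class].
#' @export
buildTDM <- function(corpus, dictionary) {
    stopifnot(is(corpus, "DocumentCorpus"), is(dictionary, "GeneDictionary"))
    if (!length(corpus)) stop("corpus is empty")
    rec <- corpus@records
    docs <- sort(rec$pmid)
    triplets <- list()
    for (i in seq_len(nrow(rec))) {
        text <- paste(rec$title[i], rec$abstract[i])
        men <- recognizeGenes(text, dictionary)
        if (!nrow(men)) next
        tab <- table(men$symbol)
        triplets[[length(triplets) + 1L]] <- data.frame(
            gene = names(tab), pmid = rec$pmid[i],
            n = as.integer(tab), stringsAsFactors = FALSE)
    }
    if (!length(triplets)) {
        genes <- character()
        cnt <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                    x = double(), dims = c(0L, length(docs)),
                                    dimnames = list(genes, docs))
    } else {
        tri <- do.call(rbind, triplets)
        genes <- sort(unique(tri$gene))
        cnt <- Matrix::sparseMatrix(
            i = match(tri$gene, genes), j = match(tri$pmid, docs),
            x = as.double(tri$n), dims = c(length(genes), length(docs)),
            dimnames = list(genes, docs))
    }
    dropped <- setdiff(sort(dictionary@symbols), genes)
    if (length(dropped))
        message(sprintf("%d dictionary symbol(s) had no mention and were dropped",
                        length(dropped)))
    cnt <- .as_dgc(cnt)
    inc <- cnt
    inc@x <- rep(1, length(inc@x))
    new("TermDocumentMatrix", incidence = inc, counts = cnt,
        dropped = dropped)
}

#' Unique genes mentioned in a corpus
#'
#' The sorted symbols with at least one mention (i.e. the non-zero rows of
#' the term-document matrix) and their count.
#'
#' @param tdm a [TermDocumentMatrix-class].
#' @return list with elements `genes` (sorted character) and `n` (integer).
#' @export
uniqueGenes <- function(tdm) {
    stopifnot(is(tdm, "TermDocumentMatrix"))
    keep <- Matrix::rowSums(tdm@incidence) > 0
    genes <- sort(rownames(tdm@incidence)[keep])
    list(genes = genes, n = length(genes))
}
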