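#' Key terms for tobacco-exposure literature queries
#'
#' The default oxidative-stress / tobacco-exposure key terms combined with
#' each seed gene when querying an abstract database: smoke, tobacco,
#' acrolein, acetaldehyde, peroxide, H2O2, reactive oxygen species.
#'
#' @format character vector of 7 terms.
#' @export
aopKeyTerms <- c("smoke", "tobacco", "acrolein", "acetaldehyde",
                 "peroxide", "H2O2", "reactive oxygen species")

#' Build a seed-gene + key-term boolean query string
#'
#' Queries take the form `SEED AND (t1 OR t2 OR ...)`; multi-word terms are
#' quoted. With no key terms the query is the bare seed symbol.
#'
#' @param seedGene a single non-empty HGNC symbol.
#' @param keyTerms character vector of key terms (may be empty); defaults to
#'   [aopKeyTerms].
#' @return a single query string.
#' @examples
#' buildQuery("EGFR")
#' buildQuery("MUC5AC", "smoke")
#' @export
buildQuery <- function(seedGene, keyTerms = aopKeyTerms) {
    if (!.is_string(seedGene) || !nzchar(trimws(seedGene)))
        stop("seedGene must be a single non-empty string")
    seedGene <- trimws(seedGene)
    keyTerms <- as.character(keyTerms)
    if (!length(keyTerms)) return(seedGene)
    quoted <- ifelse(grepl("[[:space:]]", keyTerms),
                     paste0('"', keyTerms, '"'), keyTerms)
    sprintf("%s AND (%s)", seedGene, paste(quoted, collapse = " OR "))
}

#' Build queries for a whole key event
#'
#' One query per seed gene, all sharing the same key terms.
#'
#' @param seedGenes character vector of seed symbols (non-empty).
#' @param keyTerms character vector of key terms; defaults to [aopKeyTerms].
#' @return named character vector of query strings (names = seed genes).
#' @export
buildQueries <- function(seedGenes, keyTerms = aopKeyTerms) {
    seedGenes <- as.character(seedGenes)
    if (!length(seedGenes)) stop("seedGenes must be non-empty")
    vapply(seedGenes, buildQuery, "", keyTerms = keyTerms)
}

## ---- dialects -------------------------------------------------------------

.record_to_jsonl <- function(rec) {
    x <- list(pmid = rec$pmid, title = rec$title, abstract = rec$abstract,
              journal = rec$journal, year = rec$year)
    if (!is.na(rec$impact_factor)) x$impact_factor <- rec$impact_factor
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

.read_jsonl <- function(path) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(NULL)
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        x <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stop(sprintf(
                          "parse error in %s at line %d: %s", path, i,
                          conditionMessage(e)), call. = FALSE))
        if (is.null(x$pmid))
            stop(sprintf("parse error in %s at line %d: missing pmid",
                         path, i), call. = FALSE)
        recs[[i]] <- data.frame(
            pmid = as.character(x$pmid), title = as.character(x$title %||% ""),
            abstract = as.character(x$abstract %||% ""),
            journal = as.character(x$journal %||% ""),
            year = as.integer(x$year %||% NA),
            impact_factor = as.numeric(x$impact_factor %||% NA),
            stringsAsFactors = FALSE)
    }
    do.call(rbind, recs)
}

.read_tsv_corpus <- function(path) {
    df <- .read_tsv(path)
    need <- c("pmid", "title", "abstract", "journal", "year")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("parse error in %s: missing column(s) %s", path,
                     paste(miss, collapse = ", ")), call. = FALSE)
    if (!"impact_factor" %in% names(df)) df$impact_factor <- NA_real_
    df
}

# MEDLINE tagged format: "TAG - value", continuation lines indented;
# records separated by blank lines. Tags used: PMID, TI, AB, TA, DP.
.read_medline <- function(path) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    blank <- !nzchar(trimws(lines))
    grp <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1]))
    grp[blank] <- NA
    recs <- list()
    for (g in unique(stats::na.omit(grp))) {
        chunk <- lines[which(grp == g)]
        fields <- list(); tag <- NULL
        for (ln in chunk) {
            m <- regmatches(ln, regexec("^([A-Z0-9]{1,4})\\s*- ?(.*)$", ln))[[1]]
            if (length(m) == 3) {
                tag <- m[2]
                fields[[tag]] <- c(fields[[tag]], m[3])
            } else if (grepl("^\\s+", ln) && !is.null(tag)) {
                n <- length(fields[[tag]])
                fields[[tag]][n] <- paste(fields[[tag]][n], trimws(ln))
            } else {
                stop(sprintf("parse error in %s: unparseable MEDLINE line %s",
                             path, dQuote(ln)), call. = FALSE)
            }
        }
        if (is.null(fields$PMID))
            stop(sprintf("parse error in %s: MEDLINE record %d lacks PMID",
                         path, g), call. = FALSE)
        dp <- fields$DP[1] %||% NA_character_
        yr <- if (is.na(dp)) NA_integer_ else
            as.integer(regmatches(dp, regexpr("\\d{4}", dp)))
        recs[[length(recs) + 1L]] <- data.frame(
            pmid = fields$PMID[1],
            title = paste(fields$TI %||% "", collapse = " "),
            abstract = paste(fields$AB %||% "", collapse = " "),
            journal = fields$TA[1] %||% "",
            year = yr, impact_factor = NA_real_, stringsAsFactors = FALSE)
    }
    if (!length(recs)) return(NULL)
    do.call(rbind, recs)
}

#' Read an abstract corpus from disk
#'
#' Supported dialects: `"jsonl"` (canonical; one JSON object per line with
#' fields pmid/title/abstract/journal/year/impact_factor), `"tsv"` (header
#' with the same columns), and `"medline"` (PMID-/TI-/AB-/TA-/DP- tagged
#' records). Duplicate pmids are collapsed to the first occurrence with a
#' warning.
#'
#' @param path file to read.
#' @param dialect one of `"jsonl"`, `"tsv"`, `"medline"`.
#' @return a [DocumentCorpus-class].
#' @seealso [writeCorpus()]
#' @export
readCorpus <- function(path, dialect = c("jsonl", "tsv", "medline")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("no such file: ", path)
    df <- switch(dialect,
                 jsonl = .read_jsonl(path),
                 tsv = .read_tsv_corpus(path),
                 medline = .read_medline(path))
    if (is.null(df) || !nrow(df))
        return(DocumentCorpus(provenance = paste0("read:", path)))
    dup <- duplicated(df$pmid)
    if (any(dup)) {
        warning(sprintf("%d duplicate pmid(s) collapsed to first occurrence",
                        sum(dup)))
        df <- df[!dup, , drop = FALSE]
    }
    DocumentCorpus(df, provenance = paste0("read:", path))
}

#' Write an abstract corpus to disk
#'
#' Round-trips with [readCorpus()]: `readCorpus(writeCorpus(x))` reproduces
#' the records for every dialect (the MEDLINE dialect has no impact-factor
#' tag, so annotation is lost there; JSONL is the canonical lossless
#' dialect). The TSV dialect refuses fields containing tabs or newlines.
#'
#' @param corpus a [DocumentCorpus-class].
#' @param path output file.
#' @param dialect one of `"jsonl"`, `"tsv"`, `"medline"`.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path, dialect = c("jsonl", "tsv", "medline")) {
    stopifnot(is(corpus, "DocumentCorpus"))
    dialect <- match.arg(dialect)
    rec <- corpus@records
    con <- file(path, open = "wb")
    on.exit(close(con))
    out <- switch(dialect,
        jsonl = if (nrow(rec))
            vapply(seq_len(nrow(rec)),
                   function(i) .record_to_jsonl(rec[i, ]), "") else character(),
        tsv = {
            txt <- c(rec$title, rec$abstract, rec$journal)
            if (any(grepl("[\t\n\r]", txt)))
                stop("TSV dialect cannot hold tabs/newlines in fields; ",
                     "use jsonl")
            c(paste(.CORPUS_COLS, collapse = "\t"),
              if (nrow(rec)) vapply(seq_len(nrow(rec)), function(i) {
                  paste(c(rec$pmid[i], rec$title[i], rec$abstract[i],
                          rec$journal[i],
                          ifelse(is.na(rec$year[i]), "NA", rec$year[i]),
                          ifelse(is.na(rec$impact_factor[i]), "NA",
                                 format(rec$impact_factor[i], digits = 15))),
                        collapse = "\t")
              }, "") else character())
        },
        medline = if (nrow(rec)) unlist(lapply(seq_len(nrow(rec)), function(i) {
            c(paste0("PMID- ", rec$pmid[i]),
              paste0("TI  - ", rec$title[i]),
              paste0("AB  - ", rec$abstract[i]),
              paste0("TA  - ", rec$journal[i]),
              if (!is.na(rec$year[i])) paste0("DP  - ", rec$year[i]),
              "")
        })) else character())
    writeLines(enc2utf8(out), con, useBytes = TRUE)
    invisible(path)
}

#' Merge several corpora into one (union by pmid)
#'
#' Per-seed-gene searches are pooled into one per-key-event corpus: records
#' are unioned by pmid (first occurrence wins) and provenance notes are
#' concatenated. Idempotent and order-insensitive at the pmid-set level.
#'
#' @param corpora a list of [DocumentCorpus-class] objects (>= 1).
#' @return a [DocumentCorpus-class].
#' @export
mergeCorpora <- function(corpora) {
    if (is(corpora, "DocumentCorpus")) corpora <- list(corpora)
    if (!length(corpora)) stop("need at least one corpus")
    stopifnot(all(vapply(corpora, is, TRUE, "DocumentCorpus")))
    rec <- do.call(rbind, lapply(corpora, corpusRecords))
    rec <- rec[!duplicated(rec$pmid), , drop = FALSE]
    DocumentCorpus(rec,
                   provenance = unlist(lapply(corpora, corpusProvenance)))
}

#' Annotate records with journal impact factors
#'
#' Joins the corpus to a journal -> impact-factor table. Journal names are
#' matched after [normalizeJournal()] (lowercase, trimmed, internal
#' whitespace collapsed); there is no fuzzy matching. Unmatched journals
#' leave `impact_factor` missing and are counted in a message.
#'
#' @param corpus a [DocumentCorpus-class].
#' @param ifTable data.frame with columns `journal` and `impact_factor`, or
#'   the path of a TSV with those columns.
#' @return the annotated [DocumentCorpus-class].
#' @export
annotateImpactFactor <- function(corpus, ifTable) {
    stopifnot(is(corpus, "DocumentCorpus"))
    if (.is_string(ifTable)) ifTable <- .read_tsv(ifTable)
    stopifnot(all(c("journal", "impact_factor") %in% names(ifTable)))
    key <- normalizeJournal(ifTable$journal)
    if (anyDuplicated(key)) stop("duplicate journals in impact-factor table")
    iff <- structure(as.numeric(ifTable$impact_factor), names = key)
    if (any(!is.na(iff) & iff < 0)) stop("impact factors must be >= 0")
    rec <- corpus@records
    hit <- iff[normalizeJournal(rec$journal)]
    rec$impact_factor <- unname(hit)
    n_un <- sum(is.na(hit))
    if (n_un) message(sprintf("%d record(s) with journal not in IF table", n_un))
    DocumentCorpus(rec, provenance = c(corpus@provenance,
                                       sprintf("if_annotated unmatched=%d", n_un)))
}

#' Filter a corpus by journal impact factor
#'
#' Keeps records whose impact factor is greater than or equal to
#' `threshold` (the cut is inclusive: an IF of exactly 3.0 survives the
#' default filter). Records with a missing impact factor are dropped and
#' counted; run [annotateImpactFactor()] first.
#'
#' @param corpus an annotated [DocumentCorpus-class].
#' @param threshold minimum impact factor retained (default 3.0).
#' @return the filtered [DocumentCorpus-class]; the numbers of records
#'   dropped for a missing / below-threshold IF are appended to its
#'   provenance and available as `attr(, "dropped")`.
#' @export
filterByImpactFactor <- function(corpus, threshold = 3.0) {
    stopifnot(is(corpus, "DocumentCorpus"),
              is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
    rec <- corpus@records
    missing_if <- is.na(rec$impact_factor)
    keep <- !missing_if & rec$impact_factor >= threshold
    out <- DocumentCorpus(
        rec[keep, , drop = FALSE],
        provenance = c(corpus@provenance,
                       sprintf("if_filter>=%s kept=%d dropped_missing=%d dropped_below=%d",
                               format(threshold), sum(keep), sum(missing_if),
                               sum(!keep) - sum(missing_if))))
    attr(out, "dropped") <- c(missing = sum(missing_if),
                              below = sum(!keep) - sum(missing_if))
    out
}

#' Summarize per-key-event corpora
#'
#' One row per key event with seed-gene, abstract and unique-gene counts,
#' plus a TOTAL row whose abstract count is the plain sum of the per-KE
#' (already internally deduplicated) corpora.
#'
#' @param corpora named list of [DocumentCorpus-class], one per key event.
#' @param seedGenes optional named list of per-KE seed symbol vectors.
#' @param tdms optional named list of per-KE [TermDocumentMatrix-class]
#'   (for unique mentioned-gene counts).
#' @return data.frame with columns `ke`, `n_seed_genes`, `n_abstracts`,
#'   `n_unique_genes`.
#' @export
corpusSummary <- function(corpora, seedGenes = NULL, tdms = NULL) {
    stopifnot(is.list(corpora), length(corpora) >= 1L)
    kes <- names(corpora) %||% paste0("KE", seq_along(corpora))
    rows <- data.frame(
        ke = kes,
        n_seed_genes = if (is.null(seedGenes)) NA_integer_ else
            vapply(kes, function(k) length(seedGenes[[k]]), 1L),
        n_abstracts = vapply(corpora, length, 1L),
        n_unique_genes = if (is.null(tdms)) NA_integer_ else
            vapply(kes, function(k)
                if (is.null(tdms[[k]])) NA_integer_ else
                    nrow(incidenceMatrix(tdms[[k]])), 1L),
        row.names = NULL, stringsAsFactors = FALSE)
    total <- data.frame(
        ke = "TOTAL",
        n_seed_genes = if (is.null(seedGenes)) NA_integer_ else
            sum(rows$n_seed_genes),
        n_abstracts = sum(rows$n_abstracts),
        n_unique_genes = NA_integer_, stringsAsFactors = FALSE)
    rbind(rows, total)
}
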