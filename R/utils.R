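# internal helpers

#' Normalize a journal name for matching
#'
#' Lowercases, trims, and collapses internal whitespace. This deterministic
#' normalization (no fuzzy matching) is used when joining corpora to an
#' impact-factor table.
#'
#' @param x character vector of journal names.
#' @return normalized character vector.
#' @examples normalizeJournal("  Am  J   Respir ") # "am j respir"
#' @export
normalizeJournal <- function(x) {
    gsub("[[:space:]]+", " ", trimws(tolower(as.character(x))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# read a 2+-column TSV with header, tolerant of quotes in text fields
.read_tsv <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                      comment.char = "", check.names = FALSE,
                      fileEncoding = "UTF-8")
}

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# canonical numeric general sparse form (Matrix() may auto-pick
# triangular/symmetric classes)
.as_dgc <- function(m) {
    methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                "CsparseMatrix")
}
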