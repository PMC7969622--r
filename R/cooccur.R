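#' Cosine similarity matrix of gene co-occurrence
#'
#' Scores every gene pair by the cosine similarity of their binary
#' document-incidence vectors, \eqn{c(g,h) = n_{gh} / \sqrt{n_g n_h}} where
#' \eqn{n_g} is the number of abstracts mentioning g and \eqn{n_{gh}} the
#' number mentioning both. 0 means the genes are never co-mentioned; 1
#' means their abstract sets are identical. Computed on binary incidence
#' (not mention counts), which is what makes the 0/1 endpoints
#' interpretable; set `useCounts = TRUE` for a count-weighted variant.
#'
#' @param tdm a [TermDocumentMatrix-class] with at least 2 genes.
#' @param useCounts use mention counts instead of binary incidence
#'   (off by default).
#' @return a [CosineMatrix-class].
#' @export
cosineMatrix <- function(tdm, useCounts = FALSE) {
    stopifnot(is(tdm, "TermDocumentMatrix"))
    X <- if (useCounts) tdm@counts else tdm@incidence
    if (nrow(X) < 2L) stop("need at least 2 genes to score pairs")
    rs <- Matrix::rowSums(X^2)
    if (any(rs == 0)) stop("term-document matrix has all-zero gene rows")
    J <- as.matrix(Matrix::tcrossprod(X))
    S <- J / sqrt(outer(rs, rs))
    S[S > 1] <- 1  # guard FP overshoot
    nJoint <- as.matrix(Matrix::tcrossprod(tdm@incidence))
    new("CosineMatrix", scores = S,
        nDocs = structure(Matrix::rowSums(tdm@incidence),
                          names = rownames(X)),
        nJoint = nJoint)
}

.pairs_from_cosine <- function(cm) {
    s <- cm@scores
    idx <- which(upper.tri(s), arr.ind = TRUE)
    g <- rownames(s)
    a <- g[idx[, 1]]; b <- g[idx[, 2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    data.frame(gene_a = a, gene_b = b,
               score = s[idx], n_joint = cm@nJoint[idx],
               stringsAsFactors = FALSE)
}

.rank_pairs <- function(df, n, tieKeyScore = TRUE) {
    ord <- order(-df$score, -df$n_joint, df$gene_a, df$gene_b)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    df$tie_at_cutoff <- FALSE
    if (nrow(df) > n) {
        cut_score <- df$score[n]
        keep <- seq_len(nrow(df)) <= n | df$score == cut_score
        df <- df[keep, , drop = FALSE]
        df$tie_at_cutoff <- seq_len(nrow(df)) > n
        if (any(df$tie_at_cutoff))
            message(sprintf("%d pair(s) tied with the rank-%d score included",
                            sum(df$tie_at_cutoff), n))
    }
    df
}

#' Top-ranked co-occurring gene pairs
#'
#' Ranks all unordered gene pairs by (cosine score desc, joint document
#' count desc, lexicographic pair asc) and returns the top `n`. Pairs whose
#' score ties the rank-`n` score are all included and flagged in
#' `tie_at_cutoff` rather than truncated arbitrarily. The
#' [TermDocumentMatrix-class] method also attaches the evidence pmids
#' (the documents mentioning both genes) as a list-column.
#'
#' @param x a [TermDocumentMatrix-class] or [CosineMatrix-class].
#' @param n number of pairs to keep (default 60).
#' @param minJoint minimum joint document count (default 1; pairs that are
#'   never co-mentioned are not ranked).
#' @param ... unused.
#' @return data.frame with columns `gene_a`, `gene_b` (canonically ordered
#'   `gene_a < gene_b`), `score`, `n_joint`, `tie_at_cutoff` and — for the
#'   TDM method — list-column `evidence_pmids`.
#' @name topPairs
NULL

#' @rdname topPairs
#' @export
setMethod("topPairs", "CosineMatrix", function(x, n = 60L, minJoint = 1L, ...) {
    stopifnot(n >= 1L)
    df <- .pairs_from_cosine(x)
    df <- df[df$n_joint >= minJoint, , drop = FALSE]
    .rank_pairs(df, n)
})

#' @rdname topPairs
#' @export
setMethod("topPairs", "TermDocumentMatrix",
          function(x, n = 60L, minJoint = 1L, ...) {
    cm <- cosineMatrix(x)
    df <- topPairs(cm, n = n, minJoint = minJoint)
    inc <- x@incidence
    df$evidence_pmids <- lapply(seq_len(nrow(df)), function(i) {
        both <- inc[df$gene_a[i], ] * inc[df$gene_b[i], ]
        colnames(inc)[both > 0]
    })
    df
})

#' Evidence table for one gene pair
#'
#' The abstracts in which both genes of a pair are mentioned, joined to the
#' corpus metadata — the per-pair audit trail behind a co-occurrence edge.
#'
#' @param geneA,geneB gene symbols present in `tdm`.
#' @param tdm the [TermDocumentMatrix-class] the pair was scored on.
#' @param corpus the [DocumentCorpus-class] holding record metadata.
#' @return data.frame with columns `pmid`, `journal`, `impact_factor`,
#'   `year`, ordered by pmid (zero rows if the genes never co-occur).
#' @export
pairEvidence <- function(geneA, geneB, tdm, corpus) {
    stopifnot(is(tdm, "TermDocumentMatrix"), is(corpus, "DocumentCorpus"))
    inc <- tdm@incidence
    if (!all(c(geneA, geneB) %in% rownames(inc)))
        stop("both genes must be present in the term-document matrix")
    both <- inc[geneA, ] * inc[geneB, ]
    ids <- sort(colnames(inc)[both > 0])
    rec <- corpus@records
    out <- rec[match(ids, rec$pmid), c("pmid", "journal", "impact_factor",
                                       "year"), drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build a thresholded gene co-occurrence network
#'
#' Keeps pairs whose cosine score exceeds `threshold` (strictly, by
#' default: a score of exactly 0.1 is excluded at the default threshold;
#' set `strict = FALSE` for an inclusive cut in sensitivity analyses).
#' Seed nodes are always present, even when isolated. Node categories
#' (S/R/A) can be attached via `categories` once curation has assigned
#' them; other nodes are "uncategorized".
#'
#' @param pairs data.frame from [topPairs()] (columns `gene_a`, `gene_b`,
#'   `score`, `n_joint`).
#' @param threshold cosine threshold in \[0,1\] (default 0.1).
#' @param seedNodes symbols to include as vertices regardless of edges.
#' @param strict if `TRUE` (default) keep edges with score > threshold,
#'   else score >= threshold.
#' @param categories optional named character vector symbol -> category.
#' @return an [igraph::igraph] with edge attributes `score`, `n_joint` and
#'   vertex attribute `category`.
#' @export
buildNetwork <- function(pairs, threshold = 0.1, seedNodes = character(),
                         strict = TRUE, categories = NULL) {
    stopifnot(is.data.frame(pairs),
              all(c("gene_a", "gene_b", "score", "n_joint") %in% names(pairs)),
              is.numeric(threshold), length(threshold) == 1L,
              threshold >= 0, threshold <= 1)
    keep <- if (strict) pairs$score > threshold else pairs$score >= threshold
    edges <- pairs[keep, c("gene_a", "gene_b", "score", "n_joint"),
                   drop = FALSE]
    nodes <- sort(unique(c(seedNodes, edges$gene_a, edges$gene_b)))
    cat_vec <- rep("uncategorized", length(nodes))
    if (!is.null(categories)) {
        hit <- match(nodes, names(categories))
        cat_vec[!is.na(hit)] <- unname(categories[hit[!is.na(hit)]])
    }
    igraph::graph_from_data_frame(
        edges, directed = FALSE,
        vertices = data.frame(name = nodes, category = cat_vec,
                              stringsAsFactors = FALSE))
}

#' Export a gene network
#'
#' Formats: `"graphml"` (lossless for nodes, edges, scores and categories;
#' re-importable with [igraph::read_graph()]), `"sif"`
#' (`geneA<TAB>cooccur<TAB>geneB`, isolated nodes as single-column lines)
#' and `"edge_tsv"` (edge list with score/n_joint columns).
#'
#' @param net an igraph network from [buildNetwork()].
#' @param path output file.
#' @param format one of `"graphml"`, `"sif"`, `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "sif", "edge_tsv")) {
    stopifnot(igraph::is_igraph(net))
    format <- match.arg(format)
    if (format == "graphml") {
        igraph::write_graph(net, path, format = "graphml")
        return(invisible(path))
    }
    el <- igraph::as_data_frame(net, what = "edges")
    if (format == "sif") {
        lines <- if (nrow(el))
            paste(el$from, "cooccur", el$to, sep = "\t") else character()
        iso <- setdiff(igraph::V(net)$name, c(el$from, el$to))
        writeLines(c(lines, iso), path)
    } else {
        header <- "gene_a\tgene_b\tscore\tn_joint"
        lines <- if (nrow(el))
            sprintf("%s\t%s\t%.15g\t%d", el$from, el$to, el$score,
                    as.integer(el$n_joint)) else character()
        writeLines(c(header, lines), path)
    }
    invisible(path)
}
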