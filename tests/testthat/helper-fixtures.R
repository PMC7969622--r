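# shared fixtures and independent oracles (brute-force, enumeration)

toy_records <- function() {
    data.frame(
        pmid = c("p1", "p2", "p3"),
        title = c("EGFR activation by tobacco smoke",
                  "MUC5AC and EGFR in airway mucus",
                  "TGFA signalling after peroxide"),
        abstract = c("EGFR was induced twice: EGFR-dependent growth.",
                     "MUC5AC increased alongside EGFR in goblet cells.",
                     "TGFA rose while egfr stayed flat. CBF was measured."),
        journal = c("J X", "Resp J", "J X"),
        year = c(2019L, 2020L, 2021L),
        stringsAsFactors = FALSE)
}

toy_corpus <- function() DocumentCorpus(toy_records())

toy_dict <- function(exclusions = "CBF")
    geneDictionary(c("EGFR", "MUC5AC", "TGFA"), exclusions = exclusions)

# brute-force cosine from per-gene document-id sets
oracle_cosine <- function(docs_a, docs_b) {
    if (!length(docs_a) || !length(docs_b)) return(0)
    length(intersect(docs_a, docs_b)) / sqrt(length(docs_a) * length(docs_b))
}

# brute-force per-document token scan (independent of recognizeGenes)
oracle_mentioned <- function(text, symbols) {
    toks <- strsplit(text, "[^A-Za-z0-9]+")[[1]]
    symbols[symbols %in% toks]
}

as_dgc <- function(x) {
    methods::as(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                        "dMatrix"), "generalMatrix"),
                "CsparseMatrix")
}

# random TDM over random document sets; no all-zero rows
random_tdm <- function(nGenes, nDocs, p = 0.4) {
    inc <- matrix(as.numeric(stats::runif(nGenes * nDocs) < p), nGenes, nDocs)
    zero <- rowSums(inc) == 0
    if (any(zero))
        inc[cbind(which(zero), sample.int(nDocs, sum(zero), replace = TRUE))] <- 1
    dimnames(inc) <- list(sprintf("G%02d", seq_len(nGenes)),
                          sprintf("d%03d", seq_len(nDocs)))
    m <- as_dgc(inc)
    methods::new("TermDocumentMatrix", incidence = m, counts = m,
                 dropped = character())
}

# exhaustive greedy Ward: at each step merge the pair of clusters with the
# smallest increase in within-cluster sum of squares
ward_oracle_merges <- function(X) {
    clusters <- as.list(seq_len(nrow(X)))
    merges <- list()
    while (length(clusters) > 1L) {
        best <- NULL; bestd <- Inf
        for (i in 2:length(clusters)) for (j in 1:(i - 1)) {
            ci <- clusters[[i]]; cj <- clusters[[j]]
            mi <- colMeans(X[ci, , drop = FALSE])
            mj <- colMeans(X[cj, , drop = FALSE])
            d <- length(ci) * length(cj) / (length(ci) + length(cj)) *
                sum((mi - mj)^2)
            if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
        }
        merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
        clusters[[best[1]]] <- NULL
        clusters[[best[2]]] <- merged
        merges[[length(merges) + 1L]] <- merged
    }
    merges
}

# the member sets created by each hclust merge step
hclust_merge_sets <- function(hc) {
    sets <- vector("list", nrow(hc$merge))
    expand <- function(v) if (v < 0) -v else sets[[v]]
    for (k in seq_len(nrow(hc$merge)))
        sets[[k]] <- sort(c(expand(hc$merge[k, 1]), expand(hc$merge[k, 2])))
    sets
}

# brute-force adjusted Rand index by pair enumeration (independent of the
# contingency-table implementation)
oracle_ari <- function(x, y) {
    n <- length(x)
    n11 <- n00 <- n10 <- n01 <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
        sx <- x[i] == x[j]; sy <- y[i] == y[j]
        if (sx && sy) n11 <- n11 + 1
        else if (sx && !sy) n10 <- n10 + 1
        else if (!sx && sy) n01 <- n01 + 1
        else n00 <- n00 + 1
    }
    den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
    if (den == 0) return(1)
    2 * (n11 * n00 - n10 * n01) / den
}
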