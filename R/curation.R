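.REASONS <- c("low_if", "false_acronym", "irrelevant", "non_hgnc", "other")

#' Read a curation decision ledger
#'
#' Manual curation is externalized as a machine-readable ledger so the
#' human filtering step is reproducible and auditable. Each decision
#' targets either a gene pair (`target_type = "pair"`, target written
#' `"GENEA|GENEB"`) or an abstract (`target_type = "pmid"`), with a
#' `verdict` of `keep` or `discard`, a `reason` code for every discard
#' (one of `low_if`, `false_acronym`, `irrelevant`, `non_hgnc`, `other`),
#' a free-text `note`, and a `source` (`auto` or `manual`).
#'
#' @param path a JSON file (array of decision objects) or a TSV with
#'   columns `target_type`, `target`, `verdict`, `reason`, `note`, `source`.
#' @return data.frame of decisions.
#' @export
readCurationLedger <- function(path) {
    df <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::fromJSON(path) else .read_tsv(path)
    need <- c("target_type", "target", "verdict")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("curation ledger missing column(s): ", paste(miss, collapse = ", "))
    for (col in c("reason", "note", "source"))
        if (!col %in% names(df)) df[[col]] <- NA_character_
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    .validate_ledger(df)
    df
}

.validate_ledger <- function(decisions) {
    stopifnot(all(decisions$target_type %in% c("pair", "pmid")),
              all(decisions$verdict %in% c("keep", "discard")))
    disc <- decisions$verdict == "discard"
    bad <- disc & (is.na(decisions$reason) |
                   !decisions$reason %in% .REASONS)
    if (any(bad))
        stop("every discard needs a reason code in {",
             paste(.REASONS, collapse = ", "), "}; offending target(s): ",
             paste(decisions$target[bad], collapse = ", "))
    invisible(TRUE)
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Apply impact-factor filtering and curation decisions to ranked pairs
#'
#' Replays the curation stage: the corpus is restricted to records with
#' impact factor >= `ifThreshold` (see [filterByImpactFactor()]), abstracts
#' with a discard verdict are removed, and each pair keeps only the
#' evidence pmids that survive. A pair is retained iff it has no
#' pair-level discard verdict and at least one surviving evidence abstract.
#' The genes of the kept pairs, minus the seed genes, form the R-genes
#' ("relevant genes") of the key event. Every removal is logged with its
#' reason.
#'
#' @param pairs data.frame from [topPairs()] on a TDM (must carry the
#'   `evidence_pmids` list-column).
#' @param corpus the annotated [DocumentCorpus-class] behind the pairs.
#' @param decisions decision data.frame (see [readCurationLedger()]); may
#'   have zero rows.
#' @param seedGenes character vector of seed (S) genes.
#' @param ifThreshold impact-factor cut, default 3.0 (inclusive).
#' @return list with elements `pairs` (kept pairs, evidence restricted to
#'   surviving pmids), `corpus` (curated corpus), `rGenes` (sorted R-gene
#'   symbols) and `log` (data.frame of removals with reasons).
#' @export
applyCuration <- function(pairs, corpus, decisions, seedGenes,
                          ifThreshold = 3.0) {
    stopifnot(is.data.frame(pairs), is(corpus, "DocumentCorpus"),
              "evidence_pmids" %in% names(pairs))
    if (is.null(decisions) || !nrow(decisions))
        decisions <- data.frame(target_type = character(),
                                target = character(), verdict = character(),
                                reason = character(), note = character(),
                                source = character(), stringsAsFactors = FALSE)
    .validate_ledger(decisions)

    keys <- .pair_key(pairs$gene_a, pairs$gene_b)
    pd <- decisions[decisions$target_type == "pair", , drop = FALSE]
    pd_keys <- vapply(strsplit(pd$target, "|", fixed = TRUE), function(x) {
        if (length(x) != 2L) return(NA_character_)
        .pair_key(x[1], x[2])
    }, "")
    unknown <- pd$target[is.na(pd_keys) | !pd_keys %in% keys]
    md <- decisions[decisions$target_type == "pmid", , drop = FALSE]
    unknown <- c(unknown, md$target[!md$target %in% pmids(corpus)])
    if (length(unknown))
        stop("curation decisions reference unknown target(s): ",
             paste(unknown, collapse = ", "))

    curated <- filterByImpactFactor(corpus, ifThreshold)
    discarded_pmids <- md$target[md$verdict == "discard"]
    rec <- corpusRecords(curated)
    curated <- DocumentCorpus(
        rec[!rec$pmid %in% discarded_pmids, , drop = FALSE],
        provenance = c(corpusProvenance(curated),
                       sprintf("curation: %d pmid discard(s), %d pair decision(s)",
                               length(discarded_pmids), nrow(pd))))
    alive <- pmids(curated)

    discarded_pairs <- pd_keys[pd$verdict == "discard"]
    reason_of <- structure(pd$reason[pd$verdict == "discard"],
                           names = discarded_pairs)
    surviving <- lapply(pairs$evidence_pmids, intersect, alive)

    keep <- !(keys %in% discarded_pairs) & lengths(surviving) > 0L
    log <- data.frame(
        pair = keys[!keep],
        reason = ifelse(keys[!keep] %in% discarded_pairs,
                        unname(reason_of[keys[!keep]]),
                        "no_surviving_evidence"),
        stringsAsFactors = FALSE)
    kept <- pairs[keep, , drop = FALSE]
    kept$evidence_pmids <- surviving[keep]
    rownames(kept) <- NULL
    rGenes <- sort(setdiff(unique(c(kept$gene_a, kept$gene_b)), seedGenes))
    list(pairs = kept, corpus = curated, rGenes = rGenes, log = log)
}

#' Record additional (A) genes with their provenance
#'
#' A-genes come from manual citation chasing after curation; each one must
#' carry at least one literature reference.
#'
#' @param genes character vector of symbols (may be empty).
#' @param references list (parallel to `genes`, or named by them) of
#'   character reference vectors (pmids or citation keys).
#' @return data.frame with columns `symbol` and list-column `references`.
#' @export
addAGenes <- function(genes, references) {
    genes <- as.character(genes)
    if (!length(genes))
        return(data.frame(symbol = character(),
                          references = I(list()), stringsAsFactors = FALSE))
    if (!is.list(references)) references <- as.list(references)
    if (!is.null(names(references))) references <- references[genes]
    if (length(references) != length(genes))
        stop("one reference vector per gene required")
    nref <- vapply(references, function(r)
        sum(!is.na(r) & nzchar(as.character(r))), 1L)
    if (any(nref == 0L))
        stop("A-gene(s) without a reference: ",
             paste(genes[nref == 0L], collapse = ", "))
    if (anyDuplicated(genes)) {
        warning("duplicate A-genes collapsed")
        keep <- !duplicated(genes)
        references <- references[keep]; genes <- genes[keep]
    }
    data.frame(symbol = genes, references = I(unname(references)),
               stringsAsFactors = FALSE)
}

#' Assemble a key-event geneset from S-, R- and A-genes
#'
#' Pools seed genes (S), relevant genes from curated pairs (R) and
#' additional genes from manual follow-up (A) into one geneset. Duplicates
#' within a list are collapsed with a warning; genes appearing in more
#' than one category are kept once, under category precedence S > R > A.
#'
#' @param name geneset (key event) identifier.
#' @param S,R,A character vectors of symbols (R and A default empty). `A`
#'   may also be the data.frame returned by [addAGenes()].
#' @param provenance optional named list of per-gene reference vectors.
#' @return a [Geneset-class]; its Table-1-style counts are available via
#'   [accountingRow()].
#' @examples
#' gs <- assembleGeneset("KE1", S = "EGFR",
#'                       R = paste0("R", 1:18), A = paste0("A", 1:6))
#' length(gs)  # 25
#' @export
assembleGeneset <- function(name, S, R = character(), A = character(),
                            provenance = list()) {
    if (is.data.frame(A)) {
        prov_a <- structure(A$references, names = A$symbol)
        provenance <- utils::modifyList(as.list(prov_a), provenance)
        A <- A$symbol
    }
    dedupe <- function(x, lab) {
        x <- as.character(x)
        if (anyDuplicated(x)) {
            warning(sprintf("%d duplicate(s) removed from %s-genes",
                            sum(duplicated(x)), lab))
            x <- unique(x)
        }
        x
    }
    S <- dedupe(S, "S"); R <- dedupe(R, "R"); A <- dedupe(A, "A")
    members <- c(S, setdiff(R, S), setdiff(A, c(S, R)))
    category <- c(rep("S", length(S)),
                  rep("R", length(setdiff(R, S))),
                  rep("A", length(setdiff(A, c(S, R)))))
    prov <- provenance[intersect(names(provenance), members)]
    new("Geneset", name = as.character(name), members = members,
        category = category,
        provenance = lapply(prov, as.character))
}

#' Table-1-style accounting for a geneset
#'
#' Category counts and the accounting identity `n_total = |S u R u A|`
#' (always <= n_S + n_R + n_A, with equality iff the categories are
#' disjoint). Corpus-level counts can be supplied to fill the remaining
#' columns.
#'
#' @param geneset a [Geneset-class].
#' @param n_abstracts,n_abstracts_curated,n_unique_genes optional corpus
#'   metrics for the row.
#' @return one-row data.frame with columns `ke`, `n_seed`, `n_abstracts`,
#'   `n_unique_genes`, `n_abstracts_curated`, `n_S`, `n_R`, `n_A`,
#'   `n_total`.
#' @export
accountingRow <- function(geneset, n_abstracts = NA_integer_,
                          n_abstracts_curated = NA_integer_,
                          n_unique_genes = NA_integer_) {
    stopifnot(is(geneset, "Geneset"))
    tab <- table(factor(geneset@category, levels = c("S", "R", "A", "U")))
    data.frame(ke = geneset@name, n_seed = unname(tab[["S"]]),
               n_abstracts = as.integer(n_abstracts),
               n_unique_genes = as.integer(n_unique_genes),
               n_abstracts_curated = as.integer(n_abstracts_curated),
               n_S = unname(tab[["S"]]), n_R = unname(tab[["R"]]),
               n_A = unname(tab[["A"]]),
               n_total = length(geneset@members),
               stringsAsFactors = FALSE)
}

#' Stack accounting rows and append a TOTAL row
#'
#' @param rows a list of one-row data.frames from [accountingRow()] (or a
#'   single stacked data.frame).
#' @return data.frame with one row per key event plus a `TOTAL` row whose
#'   numeric columns are sums (NA-tolerant).
#' @export
accountingTable <- function(rows) {
    df <- if (is.data.frame(rows)) rows else do.call(rbind, rows)
    total <- df[1, , drop = FALSE]
    total$ke <- "TOTAL"
    for (col in setdiff(names(df), "ke"))
        total[[col]] <- if (all(is.na(df[[col]]))) NA_integer_ else
            as.integer(sum(df[[col]], na.rm = TRUE))
    rbind(df, total)
}

#' Merge two genesets
#'
#' Used when two key events overlap so much that their gene lists are
#' pooled. Members are unioned; a gene present in both keeps the
#' higher-precedence category (S > R > A > U); provenance references are
#' concatenated and deduplicated.
#'
#' @param g1,g2 [Geneset-class] objects.
#' @param mergedName name for the merged geneset.
#' @return a [Geneset-class].
#' @export
mergeGenesets <- function(g1, g2, mergedName) {
    stopifnot(is(g1, "Geneset"), is(g2, "Geneset"))
    prec <- c(S = 1L, R = 2L, A = 3L, U = 4L)
    members <- c(g1@members, setdiff(g2@members, g1@members))
    cat1 <- structure(g1@category, names = g1@members)
    cat2 <- structure(g2@category, names = g2@members)
    category <- vapply(members, function(m) {
        cc <- c(cat1[m], cat2[m])
        cc <- cc[!is.na(cc)]
        names(prec)[min(prec[cc])]
    }, "")
    prov <- lapply(members, function(m)
        unique(c(g1@provenance[[m]], g2@provenance[[m]])))
    names(prov) <- members
    prov <- prov[lengths(prov) > 0]
    new("Geneset", name = as.character(mergedName), members = members,
        category = unname(category), provenance = prov)
}

#' Overlap of a geneset with user-supplied reference gene lists
#'
#' Exact set intersections against external genesets (e.g. published COPD
#' or asthma lists, supplied as files or vectors by the user — never
#' fetched).
#'
#' @param geneset a [Geneset-class] (or plain character vector).
#' @param referenceLists named list of character symbol vectors.
#' @return data.frame with columns `reference`, `n_reference`, `n_overlap`
#'   and list-column `overlap` (the intersecting symbols, sorted).
#' @export
overlapReport <- function(geneset, referenceLists) {
    genes <- if (is(geneset, "Geneset")) geneIds(geneset) else
        as.character(geneset)
    stopifnot(is.list(referenceLists), length(names(referenceLists)) ==
                  length(referenceLists))
    ov <- lapply(referenceLists, function(r)
        sort(intersect(genes, as.character(r))))
    data.frame(reference = names(referenceLists),
               n_reference = vapply(referenceLists, function(r)
                   length(unique(r)), 1L),
               n_overlap = lengths(ov),
               overlap = I(unname(ov)),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate gene pairs with shared attributes
#'
#' Joins each pair against user-supplied gene -> attribute tables (e.g.
#' exports from KEGG, Reactome, IntAct, Human Protein Atlas) and reports,
#' per resource, the attributes shared by both members of the pair. Pairs
#' without shared attributes are retained with an empty annotation.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param annotationTables named list of data.frames with columns `gene`
#'   and `attribute`.
#' @return `pairs` with one list-column `shared_<resource>` per table.
#' @export
annotatePairs <- function(pairs, annotationTables) {
    stopifnot(is.data.frame(pairs), is.list(annotationTables),
              length(names(annotationTables)) == length(annotationTables))
    for (nm in names(annotationTables)) {
        tab <- annotationTables[[nm]]
        stopifnot(all(c("gene", "attribute") %in% names(tab)))
        attrs <- split(as.character(tab$attribute), as.character(tab$gene))
        pairs[[paste0("shared_", nm)]] <- lapply(seq_len(nrow(pairs)),
            function(i) sort(intersect(attrs[[pairs$gene_a[i]]] %||% character(),
                                       attrs[[pairs$gene_b[i]]] %||% character())))
    }
    pairs
}

## ---- GMT ------------------------------------------------------------------

#' Read / write genesets in GMT format
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`. aopminer
#' serializes the S/R/A categories and per-gene provenance as minified JSON
#' in the description field, so its own files round-trip losslessly;
#' foreign GMT files (plain description) import with category "U"
#' (uncategorized).
#'
#' @param genesets a [Geneset-class] or list of them.
#' @param path GMT file.
#' @return `writeGMT()` returns `path` invisibly; `readGMT()` a list of
#'   [Geneset-class] objects named by geneset.
#' @export
writeGMT <- function(genesets, path) {
    if (is(genesets, "Geneset")) genesets <- list(genesets)
    lines <- vapply(genesets, function(g) {
        stopifnot(is(g, "Geneset"))
        meta <- list(category = as.list(structure(g@category,
                                                  names = g@members)),
                     provenance = g@provenance)
        desc <- as.character(jsonlite::toJSON(meta, auto_unbox = TRUE))
        paste(c(g@name, desc, g@members), collapse = "\t")
    }, "")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
    invisible(path)
}

#' @rdname writeGMT
#' @export
readGMT <- function(path) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (i in seq_along(lines)) {
        parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3L)
            stop(sprintf("malformed GMT line %d in %s (need name, description, >=1 gene)",
                         i, path))
        name <- parts[1]; desc <- parts[2]
        members <- parts[-(1:2)]
        members <- members[nzchar(members)]
        category <- rep("U", length(members))
        provenance <- list()
        if (startsWith(desc, "{")) {
            meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
            if (!is.null(meta$category)) {
                cc <- unlist(meta$category)
                hit <- match(members, names(cc))
                category[!is.na(hit)] <- unname(cc[hit[!is.na(hit)]])
            }
            if (!is.null(meta$provenance) && length(meta$provenance))
                provenance <- lapply(meta$provenance, as.character)
        }
        out[[name]] <- new("Geneset", name = name, members = members,
                           category = category, provenance = provenance)
    }
    out
}
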