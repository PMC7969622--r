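# small curated world: 4 pmids, 3 pairs, IF-annotated
.curation_world <- function() {
    corpus <- DocumentCorpus(data.frame(
        pmid = c("m1", "m2", "m3", "m4"), title = "t", abstract = "a",
        journal = "J", year = 2000L,
        impact_factor = c(5.0, 3.0, 2.0, 6.0)))
    pairs <- data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "C", "C"),
                        score = c(0.9, 0.5, 0.4), n_joint = c(2L, 1L, 1L),
                        stringsAsFactors = FALSE)
    pairs$evidence_pmids <- list(c("m1", "m3"), "m2", "m4")
    list(corpus = corpus, pairs = pairs)
}

test_that("curation ledgers parse and demand reasons for discards", {
    path <- withr::local_tempfile(fileext = ".json")
    writeLines(jsonlite::toJSON(data.frame(
        target_type = c("pair", "pmid"), target = c("A|B", "m2"),
        verdict = c("keep", "discard"),
        reason = c(NA, "irrelevant"), note = NA, source = "manual")), path)
    led <- readCurationLedger(path)
    expect_identical(nrow(led), 2L)
    writeLines(jsonlite::toJSON(data.frame(
        target_type = "pmid", target = "m2", verdict = "discard",
        reason = NA_character_)), path)
    expect_error(readCurationLedger(path), "reason")
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("target_type\ttarget\tverdict\treason\tnote\tsource",
                 "pair\tA|B\tdiscard\tfalse_acronym\t\tmanual"), tsv)
    expect_identical(readCurationLedger(tsv)$reason, "false_acronym")
})

test_that("applyCuration replays IF filter + verdicts and derives R-genes", {
    w <- .curation_world()
    # no decisions: pair (B,C) evidence m2 survives at IF 3.0 (inclusive);
    # (A,B) keeps m1 only (m3 IF 2.0 < 3.0)
    out <- applyCuration(w$pairs, w$corpus, NULL, seedGenes = "A")
    expect_identical(nrow(out$pairs), 3L)
    expect_identical(out$pairs$evidence_pmids[[1]], "m1")
    expect_identical(out$rGenes, c("B", "C"))   # kept-pair genes minus seeds
    expect_setequal(pmids(out$corpus), c("m1", "m2", "m4"))
    # discarding the only evidence abstract of (B,C) removes the pair
    dec <- data.frame(target_type = "pmid", target = "m2",
                      verdict = "discard", reason = "false_acronym",
                      note = NA, source = "manual")
    out2 <- applyCuration(w$pairs, w$corpus, dec, seedGenes = "A")
    expect_identical(nrow(out2$pairs), 2L)
    expect_identical(out2$log$pair, "B|C")
    expect_identical(out2$log$reason, "no_surviving_evidence")
    # pair-level discard logs its own reason code
    dec2 <- data.frame(target_type = "pair", target = "C|A",
                       verdict = "discard", reason = "irrelevant",
                       note = NA, source = "manual")
    out3 <- applyCuration(w$pairs, w$corpus, dec2, seedGenes = "A")
    expect_identical(out3$log$reason, "irrelevant")
    expect_identical(out3$rGenes, c("B", "C"))
    # unknown targets are rejected with the offender named
    bad <- data.frame(target_type = "pair", target = "X|Y",
                      verdict = "discard", reason = "other",
                      note = NA, source = "auto")
    expect_error(applyCuration(w$pairs, w$corpus, bad, "A"), "X\\|Y")
})

test_that("ledger replay is deterministic and matches a brute-force replay", {
    set.seed(41)
    genes <- sprintf("G%02d", 1:15)
    pairs <- do.call(rbind, lapply(1:40, function(i) {
        ab <- sort(sample(genes, 2))
        data.frame(gene_a = ab[1], gene_b = ab[2], score = runif(1),
                   n_joint = 1L, stringsAsFactors = FALSE)
    }))
    pairs <- pairs[!duplicated(paste(pairs$gene_a, pairs$gene_b)), ]
    ids <- sprintf("pm%02d", 1:30)
    corpus <- DocumentCorpus(data.frame(
        pmid = ids, title = "t", abstract = "a", journal = "J", year = 2000L,
        impact_factor = runif(30, 1, 8)))
    pairs$evidence_pmids <- lapply(seq_len(nrow(pairs)), function(i)
        sample(ids, sample(1:4, 1)))
    disc <- sample(seq_len(nrow(pairs)), 10)
    dec <- data.frame(
        target_type = "pair",
        target = paste(pairs$gene_a[disc], pairs$gene_b[disc], sep = "|"),
        verdict = "discard", reason = "irrelevant", note = NA, source = "auto")
    out1 <- applyCuration(pairs, corpus, dec, seedGenes = "G01")
    out2 <- applyCuration(pairs, corpus, dec, seedGenes = "G01")
    expect_identical(out1, out2)
    # brute force: replay by hand
    alive <- ids[corpusRecords(corpus)$impact_factor >= 3.0]
    keep <- vapply(seq_len(nrow(pairs)), function(i) {
        !(i %in% disc) && length(intersect(pairs$evidence_pmids[[i]], alive)) > 0
    }, TRUE)
    expect_identical(paste(out1$pairs$gene_a, out1$pairs$gene_b),
                     paste(pairs$gene_a[keep], pairs$gene_b[keep]))
    expect_identical(out1$rGenes,
                     sort(setdiff(unique(c(pairs$gene_a[keep],
                                           pairs$gene_b[keep])), "G01")))
})

test_that("A-genes require provenance references", {
    a <- addAGenes(paste0("A", 1:6),
                   references = unname(split(paste0("ref", 1:12), rep(1:6, 2))))
    expect_identical(nrow(a), 6L)
    expect_identical(length(unlist(a$references)), 12L)
    expect_identical(nrow(addAGenes(character(), list())), 0L)
    expect_error(addAGenes("X", list(character())), "without a reference")
})

test_that("geneset assembly applies S > R > A precedence and counts members", {
    gs <- assembleGeneset("KE1", S = "EGFR", R = paste0("R", 1:18),
                          A = paste0("A", 1:6))
    expect_identical(length(gs), 25L)
    row <- accountingRow(gs)
    expect_identical(row[, c("n_S", "n_R", "n_A", "n_total")],
                     data.frame(n_S = 1L, n_R = 18L, n_A = 6L, n_total = 25L))
    # precedence: a gene in S and R stays S; totals use the union
    gs2 <- assembleGeneset("KEx", S = "X", R = c("X", "Y"))
    expect_identical(length(gs2), 2L)
    expect_identical(unname(geneCategories(gs2)["X"]), "S")
    r2 <- accountingRow(gs2)
    expect_identical(r2$n_total, 2L)
    expect_lte(r2$n_total, r2$n_S + r2$n_R + r2$n_A)
    # duplicates within a list collapse with a warning
    expect_warning(gs3 <- assembleGeneset("KE5", S = c(paste0("S", 1:42), "S1"),
                                          A = paste0("A", 1:9)), "duplicate")
    expect_identical(length(gs3), 51L)
    # A-gene provenance flows from addAGenes
    gs4 <- assembleGeneset("KEp", S = "S1",
                           A = addAGenes("A1", list("pm9")))
    expect_identical(geneProvenance(gs4)$A1, "pm9")
})

test_that("merging genesets unions members under category precedence", {
    g1 <- assembleGeneset("KE2", S = c("A", "B"), R = "C")
    g2 <- assembleGeneset("KE3", S = "D", R = c("B", "E"), A = "C")
    m <- mergeGenesets(g1, g2, "KE2-3")
    expect_setequal(geneIds(m), c("A", "B", "C", "D", "E"))
    expect_identical(unname(geneCategories(m)[c("B", "C")]), c("S", "R"))
    # merging with an empty-overlap set follows inclusion-exclusion
    set.seed(8)
    for (i in 1:5) {
        s1 <- sample(paste0("g", 1:40), 15)
        s2 <- sample(paste0("g", 1:40), 12)
        k <- length(intersect(s1, s2))
        mm <- mergeGenesets(assembleGeneset("a", S = s1),
                            assembleGeneset("b", S = s2), "ab")
        expect_identical(length(mm), 15L + 12L - k)
    }
})

test_that("overlapReport computes exact intersections", {
    gs <- assembleGeneset("KE", S = c("A", "B", "C"))
    rep <- overlapReport(gs, list(copd = c("B", "C", "D"),
                                  asthma = character()))
    expect_identical(rep$n_overlap, c(2L, 0L))
    expect_identical(rep$overlap[[1]], c("B", "C"))
    set.seed(3)
    for (i in 1:5) {
        ref <- sample(letters, 10)
        got <- overlapReport(assembleGeneset("x", S = sample(letters, 12)),
                             list(r = ref))
        expect_identical(got$n_overlap,
                         length(intersect(got$overlap[[1]], ref)))
    }
})

test_that("annotatePairs reports attributes shared by both pair members", {
    pairs <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"),
                        stringsAsFactors = FALSE)
    tabs <- list(kegg = data.frame(gene = c("A", "A", "B", "C"),
                                   attribute = c("p1", "p2", "p2", "p9")))
    ann <- annotatePairs(pairs, tabs)
    expect_identical(ann$shared_kegg[[1]], "p2")
    expect_identical(ann$shared_kegg[[2]], character(0))  # pair retained
    # randomized: shared sets equal brute-force intersections
    set.seed(12)
    tab <- data.frame(gene = sample(c("A", "B"), 30, TRUE),
                      attribute = sample(paste0("t", 1:8), 30, TRUE))
    got <- annotatePairs(data.frame(gene_a = "A", gene_b = "B"),
                         list(x = tab))$shared_x[[1]]
    expect_identical(got, sort(intersect(tab$attribute[tab$gene == "A"],
                                         tab$attribute[tab$gene == "B"])))
})

test_that("GMT round-trips members, categories and provenance", {
    gs1 <- assembleGeneset("KE1", S = "EGFR", R = paste0("R", 1:18),
                           A = addAGenes(paste0("A", 1:6),
                                         as.list(paste0("pm", 1:6))))
    gs2 <- assembleGeneset("KE4", S = paste0("S", 1:34), R = paste0("R", 1:13),
                           A = paste0("X", 1:3))
    path <- withr::local_tempfile(fileext = ".gmt")
    writeGMT(list(gs1, gs2), path)
    expect_identical(length(readLines(path)), 2L)
    back <- readGMT(path)
    expect_identical(geneIds(back$KE1), geneIds(gs1))
    expect_identical(geneCategories(back$KE1), geneCategories(gs1))
    expect_identical(geneProvenance(back$KE1)$A3, "pm3")
    expect_identical(geneIds(back$KE4), geneIds(gs2))
    # a foreign GMT line imports with category "U"
    writeLines("bosse\tCOPD list\tIL13\tMMP9\tTLR4", path)
    plain <- readGMT(path)$bosse
    expect_identical(geneIds(plain), c("IL13", "MMP9", "TLR4"))
    expect_true(all(geneCategories(plain) == "U"))
    writeLines("broken\tonly-two-fields", path)
    expect_error(readGMT(path), "line 1")
})
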