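## synthetic corpora and expression data with known ground truth

.default_journals <- function() {
    data.frame(journal = c("J Airway Biol", "Respir Mucus Res",
                           "Lung Cell Rep", "Epithelial Signal J",
                           "Tob Toxicol Lett"),
               impact_factor = c(8.5, 4.2, 3.0, 2.9, 1.5),
               stringsAsFactors = FALSE)
}

#' Configuration for a synthetic abstract corpus
#'
#' The generative model: each document is assigned to one block uniformly
#' at random; gene `g` is then mentioned in document `d` independently with
#' probability `q * pIn` when `g` belongs to `d`'s block and `q * pOut`
#' otherwise. With a single block and `pIn = 1` mentions are independent
#' Bernoulli(q); with `pOut = 0` genes in different blocks are never
#' co-mentioned, so cross-block cosine similarity is exactly 0.
#'
#' @param genes character vector of symbols to plant.
#' @param blocks list of character vectors partitioning `genes` (default:
#'   one block holding all genes).
#' @param nDocs number of documents (>= 1).
#' @param q per-gene marginal mention probability scale, in \[0,1\].
#' @param pIn,pOut within-/between-block co-mention probabilities,
#'   `0 <= pOut <= pIn <= 1`.
#' @param keyTerms terms embedded in the document text ([aopKeyTerms]).
#' @param journals data.frame with `journal` and `impact_factor` columns.
#' @param seed integer seed.
#' @return a validated config list for [simulateCorpus()] /
#'   [expectedCosine()].
#' @export
corpusSimConfig <- function(genes, blocks = NULL, nDocs = 200L, q = 0.5,
                            pIn = 0.8, pOut = 0.1,
                            keyTerms = aopKeyTerms,
                            journals = .default_journals(), seed = 1L) {
    genes <- as.character(genes)
    if (is.null(blocks)) blocks <- list(genes)
    stopifnot(length(genes) >= 1L, nDocs >= 1L,
              q >= 0, q <= 1, pOut >= 0, pOut <= pIn, pIn <= 1,
              setequal(unlist(blocks), genes),
              !anyDuplicated(unlist(blocks)),
              all(c("journal", "impact_factor") %in% names(journals)))
    list(genes = genes, blocks = lapply(blocks, as.character),
         nDocs = as.integer(nDocs), q = q, pIn = pIn, pOut = pOut,
         keyTerms = as.character(keyTerms), journals = journals,
         seed = as.integer(seed))
}

.block_of <- function(config) {
    bl <- integer(length(config$genes))
    names(bl) <- config$genes
    for (b in seq_along(config$blocks)) bl[config$blocks[[b]]] <- b
    bl
}

#' Simulate an abstract corpus with planted gene co-mention blocks
#'
#' Draws gene-document incidence from the block model of
#' [corpusSimConfig()] and renders each document as a templated abstract in
#' which the sampled gene symbols appear as standalone uppercase tokens —
#' so dictionary NER recall is 100% by construction and downstream tests
#' exercise co-occurrence statistics, not tokenizer luck. With
#' `adversarial = TRUE`, some mentions are rendered hyphenated
#' ("SYM-dependent", still a token match), a lowercase decoy of an
#' unmentioned gene is appended (must not match under the case-sensitive
#' policy), and a "CBF was measured" sentence exercises the exclusion
#' list. Reproducible from the config seed.
#'
#' @param config from [corpusSimConfig()].
#' @param adversarial add NER stress-test sentences (default FALSE).
#' @return list with `corpus` (a [DocumentCorpus-class]), `truth` (binary
#'   genes x pmids incidence matrix, rows/columns sorted as [buildTDM()]
#'   sorts them), and `config`.
#' @export
simulateCorpus <- function(config, adversarial = FALSE) {
    set.seed(config$seed)
    n <- config$nDocs
    genes <- sort(config$genes)
    block_of <- .block_of(config)[genes]
    K <- length(config$blocks)
    doc_block <- sample.int(K, n, replace = TRUE)
    pmid <- sprintf("SIM%06d", seq_len(n))
    prob <- matrix(config$q * config$pOut, length(genes), n,
                   dimnames = list(genes, pmid))
    same <- outer(block_of, doc_block, "==")
    prob[same] <- config$q * config$pIn
    truth <- matrix(as.numeric(stats::runif(length(prob)) < prob),
                    length(genes), n, dimnames = dimnames(prob))

    terms <- if (length(config$keyTerms))
        sample(config$keyTerms, n, replace = TRUE) else rep("exposure", n)
    jrow <- sample.int(nrow(config$journals), n, replace = TRUE)
    title <- sprintf("Effects of %s exposure on the airway epithelium (record %d)",
                     terms, seq_len(n))
    abstract <- character(n)
    for (i in seq_len(n)) {
        gs <- genes[truth[, i] > 0]
        body <- if (length(gs)) {
            shown <- gs
            extra <- ""
            if (adversarial && length(gs)) {
                if (stats::runif(1) < 0.3)
                    shown[1] <- paste0(shown[1], "-dependent signalling")
                decoy <- setdiff(genes, gs)
                if (length(decoy) && stats::runif(1) < 0.3)
                    extra <- sprintf(" Levels of %s were not assessed.",
                                     tolower(decoy[1]))
                if (stats::runif(1) < 0.3)
                    extra <- paste0(extra, " CBF was measured after exposure.")
            }
            sprintf("We report that %s expression changed after %s exposure in differentiated cultures.%s",
                    paste(shown, collapse = " and "), terms[i], extra)
        } else {
            sprintf("No candidate transcripts responded to %s exposure in this cohort.",
                    terms[i])
        }
        abstract[i] <- paste("Airway epithelial cells were studied at the",
                             "air liquid interface.", body)
    }
    corpus <- DocumentCorpus(
        data.frame(pmid = pmid, title = title, abstract = abstract,
                   journal = config$journals$journal[jrow],
                   year = sample(2000:2021, n, replace = TRUE),
                   impact_factor = NA_real_, stringsAsFactors = FALSE),
        provenance = sprintf("simulateCorpus seed=%d nDocs=%d", config$seed, n))
    list(corpus = corpus, truth = truth, config = config)
}

#' Expected cosine similarity under the block model
#'
#' Analytic mode evaluates \eqn{E[n_{ab}] / \sqrt{E[n_a] E[n_b]}} in closed
#' form from the block-model probabilities; Monte-Carlo mode averages the
#' empirical cosine over `nSim` simulated corpora (seeds derived from the
#' config seed) and attaches the standard error of the mean as
#' `attr(, "se")`.
#'
#' @param config from [corpusSimConfig()].
#' @param geneA,geneB genes in the config.
#' @param method `"analytic"` (default) or `"mc"`.
#' @param nSim Monte-Carlo replicates (default 50).
#' @return expected cosine in \[0,1\].
#' @export
expectedCosine <- function(config, geneA, geneB,
                           method = c("analytic", "mc"), nSim = 50L) {
    method <- match.arg(method)
    stopifnot(all(c(geneA, geneB) %in% config$genes))
    if (method == "analytic") {
        K <- length(config$blocks)
        block_of <- .block_of(config)
        p_g <- function(g, b)
            config$q * if (block_of[[g]] == b) config$pIn else config$pOut
        marg <- function(g) mean(vapply(seq_len(K), function(b) p_g(g, b), 0))
        joint <- mean(vapply(seq_len(K),
                             function(b) p_g(geneA, b) * p_g(geneB, b), 0))
        den <- sqrt(marg(geneA) * marg(geneB))
        return(if (den == 0) 0 else joint / den)
    }
    vals <- vapply(seq_len(nSim), function(i) {
        cfg <- config
        cfg$seed <- config$seed + i
        truth <- simulateCorpus(cfg)$truth
        na <- sum(truth[geneA, ]); nb <- sum(truth[geneB, ])
        if (na == 0 || nb == 0) return(NA_real_)
        sum(truth[geneA, ] * truth[geneB, ]) / sqrt(na * nb)
    }, 0)
    vals <- vals[!is.na(vals)]
    out <- mean(vals)
    attr(out, "se") <- stats::sd(vals) / sqrt(length(vals))
    out
}

#' Simulate an expression matrix with a planted group effect
#'
#' Control and treated groups of equal size; geneset genes receive a mean
#' shift `delta` (in expression units, on the same log-like scale as the
#' Gaussian baseline) in the treated group; all entries get Gaussian noise
#' with standard deviation `noiseSd`. An optional continuous technical
#' confounder (standard normal per sample) loads with coefficient
#' `confounderLoading` on a disjoint block of `confounderGenes` genes,
#' emulating sequencing-quality covariates that drive their own principal
#' component. Truth (labels, confounder values, planted gene ids) is in
#' the colData / metadata. Reproducible from `seed`.
#'
#' @param nGenes total genes (default 100).
#' @param genesetSize genes carrying the treatment shift (default 25; the
#'   first `genesetSize` gene ids).
#' @param nPerGroup samples per group (default 10).
#' @param delta treated-group mean shift on geneset genes (default
#'   `5 * noiseSd`).
#' @param noiseSd noise standard deviation (default 1).
#' @param baselineMean,baselineSd per-gene baseline level distribution
#'   (defaults 7 and 1, a normalized log2-like scale).
#' @param confounder add the technical confounder (default FALSE).
#' @param confounderGenes size of the confounder-loaded gene block
#'   (default 15, disjoint from the geneset).
#' @param confounderLoading loading of the confounder (default
#'   `2 * noiseSd`).
#' @param seed integer seed.
#' @return a [SummarizedExperiment::SummarizedExperiment] (assay `exprs`)
#'   with colData columns `group` (control/treated) and, if planted,
#'   `confounder`; metadata fields `genesetGenes`, `confounderGenes`,
#'   `delta`, `noiseSd`.
#' @export
simulateExpression <- function(nGenes = 100L, genesetSize = 25L,
                               nPerGroup = 10L, delta = 5 * noiseSd,
                               noiseSd = 1, baselineMean = 7,
                               baselineSd = 1, confounder = FALSE,
                               confounderGenes = 15L,
                               confounderLoading = 2 * noiseSd, seed = 1L) {
    stopifnot(noiseSd > 0, is.finite(delta), nPerGroup >= 1L,
              genesetSize <= nGenes,
              !confounder || genesetSize + confounderGenes <= nGenes)
    set.seed(seed)
    genes <- sprintf("G%04d", seq_len(nGenes))
    gset <- genes[seq_len(genesetSize)]
    cset <- if (confounder)
        genes[genesetSize + seq_len(confounderGenes)] else character()
    n <- 2L * nPerGroup
    samples <- c(sprintf("ctrl_%02d", seq_len(nPerGroup)),
                 sprintf("trt_%02d", seq_len(nPerGroup)))
    group <- factor(rep(c("control", "treated"), each = nPerGroup),
                    levels = c("control", "treated"))
    conf <- if (confounder) stats::rnorm(n) else NULL

    baseline <- stats::rnorm(nGenes, baselineMean, baselineSd)
    mat <- matrix(baseline, nGenes, n, dimnames = list(genes, samples))
    mat[gset, group == "treated"] <- mat[gset, group == "treated"] + delta
    if (confounder)
        mat[cset, ] <- mat[cset, ] +
            confounderLoading * matrix(conf, length(cset), n, byrow = TRUE)
    mat <- mat + matrix(stats::rnorm(nGenes * n, sd = noiseSd), nGenes, n)

    cd <- S4Vectors::DataFrame(group = group, row.names = samples)
    if (confounder) cd$confounder <- conf
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = mat), colData = cd)
    S4Vectors::metadata(se) <- list(genesetGenes = gset,
                                    confounderGenes = cset,
                                    delta = delta, noiseSd = noiseSd,
                                    seed = as.integer(seed))
    se
}

#' Write an expression SummarizedExperiment as TSV
#'
#' The on-disk dialect [readExpression()] consumes: an expression TSV
#' (gene column + one column per sample) and a metadata TSV keyed by
#' `sample`.
#'
#' @param se a SummarizedExperiment with assay `exprs`.
#' @param exprPath,metaPath output files (metadata skipped when
#'   `metaPath` is NULL).
#' @return `exprPath`, invisibly.
#' @export
writeExpression <- function(se, exprPath, metaPath = NULL) {
    mat <- .expr_matrix(se)
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(metaPath) && is(se, "SummarizedExperiment")) {
        cd <- as.data.frame(SummarizedExperiment::colData(se))
        meta <- data.frame(sample = rownames(cd), cd, check.names = FALSE,
                           stringsAsFactors = FALSE)
        utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(exprPath)
}
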