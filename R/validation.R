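## geneset validation against expression data

.expr_matrix <- function(x) {
    if (is(x, "SummarizedExperiment"))
        as.matrix(SummarizedExperiment::assay(x))
    else as.matrix(x)
}

.as_se <- function(mat, template = NULL) {
    cd <- if (is(template, "SummarizedExperiment"))
        SummarizedExperiment::colData(template)[colnames(mat), , drop = FALSE]
    else S4Vectors::DataFrame(row.names = colnames(mat))
    md <- if (is(template, "SummarizedExperiment"))
        S4Vectors::metadata(template) else list()
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = mat), colData = cd)
    S4Vectors::metadata(se) <- md
    se
}

#' Read an expression matrix and sample metadata from TSV
#'
#' The expression TSV has genes as rows (first column = gene id, header =
#' sample ids); the metadata TSV is keyed by a `sample` column. Metadata
#' columns parse as numeric where possible (continuous covariates),
#' otherwise stay categorical.
#'
#' @param exprPath expression TSV.
#' @param metaPath optional sample-metadata TSV.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs` and the metadata as `colData`.
#' @export
readExpression <- function(exprPath, metaPath = NULL) {
    df <- .read_tsv(exprPath)
    genes <- as.character(df[[1]])
    if (anyDuplicated(genes)) stop("duplicate gene ids in ", exprPath)
    mat <- as.matrix(df[, -1, drop = FALSE])
    mode(mat) <- "numeric"
    rownames(mat) <- genes
    se <- .as_se(mat)
    if (!is.null(metaPath)) {
        meta <- .read_tsv(metaPath)
        if (!"sample" %in% names(meta)) stop("metadata needs a 'sample' column")
        if (anyDuplicated(meta$sample)) stop("duplicate sample ids in metadata")
        miss <- setdiff(colnames(mat), meta$sample)
        if (length(miss))
            stop("metadata missing sample(s): ", paste(miss, collapse = ", "))
        meta <- meta[match(colnames(mat), meta$sample), , drop = FALSE]
        SummarizedExperiment::colData(se) <-
            S4Vectors::DataFrame(meta[, setdiff(names(meta), "sample"),
                                      drop = FALSE],
                                 row.names = colnames(mat))
    }
    se
}

#' Subset an expression matrix to a geneset
#'
#' Restricts rows to the intersection of the geneset with the measured
#' genes; members absent from the matrix are reported (message + attribute
#' `missing`). An empty intersection is an error.
#'
#' @param expr a SummarizedExperiment (assay genes x samples) or matrix.
#' @param geneset a [Geneset-class] or character vector of symbols.
#' @return the subset object (same class as the relevant input container),
#'   with `attr(, "missing")` listing absent members.
#' @export
subsetByGeneset <- function(expr, geneset) {
    genes <- if (is(geneset, "Geneset")) geneIds(geneset) else
        as.character(geneset)
    mat <- .expr_matrix(expr)
    present <- intersect(genes, rownames(mat))
    missing <- setdiff(genes, rownames(mat))
    if (!length(present))
        stop("no geneset member is present in the expression matrix")
    if (length(missing))
        message(sprintf("%d geneset member(s) absent from the matrix",
                        length(missing)))
    out <- if (is(expr, "SummarizedExperiment")) expr[present, ]
           else mat[present, , drop = FALSE]
    attr(out, "missing") <- missing
    out
}

#' Z-score expression rows
#'
#' Mean-centers and scales each gene row to unit variance (sample standard
#' deviation, n-1 denominator). Zero-variance rows cannot be scaled; they
#' are dropped with a warning, and an all-constant matrix is an error.
#' Idempotent up to floating point.
#'
#' @param expr SummarizedExperiment or numeric matrix with >= 2 samples.
#' @return same container class, rows Z-scored, with `attr(, "dropped")`
#'   naming removed constant rows.
#' @export
zscoreRows <- function(expr) {
    mat <- .expr_matrix(expr)
    if (ncol(mat) < 2L) stop("need at least 2 samples to Z-score")
    mu <- rowMeans(mat)
    sd <- apply(mat, 1L, stats::sd)
    const <- sd < 1e-12
    if (all(const)) stop("all rows have zero variance")
    if (any(const))
        warning(sprintf("%d zero-variance row(s) dropped", sum(const)))
    z <- (mat[!const, , drop = FALSE] - mu[!const]) / sd[!const]
    out <- if (is(expr, "SummarizedExperiment")) {
        se <- expr[!const, ]
        SummarizedExperiment::assay(se) <- z
        se
    } else z
    attr(out, "dropped") <- rownames(mat)[const]
    out
}

#' Hierarchical clustering with Euclidean distance and Ward linkage
#'
#' Agglomerative clustering of samples (or genes) on pairwise Euclidean
#' distances under the Ward minimum-variance criterion — `stats::hclust`
#' with `method = "ward.D2"`, the variant whose merge heights equal
#' \eqn{\sqrt{2\,\Delta SS}} so each merge minimizes the increase in
#' within-cluster variance. Ties are resolved deterministically by input
#' order. Cut the tree with [stats::cutree()]; export with
#' [exportNewick()].
#'
#' @param expr SummarizedExperiment or numeric matrix (genes x samples),
#'   typically Z-scored first ([zscoreRows()]).
#' @param axis cluster `"samples"` (default) or `"genes"`.
#' @return an object of class [stats::hclust].
#' @export
hierarchicalCluster <- function(expr, axis = c("samples", "genes")) {
    axis <- match.arg(axis)
    mat <- .expr_matrix(expr)
    obs <- if (axis == "samples") t(mat) else mat
    if (nrow(obs) < 2L) stop("need at least 2 items to cluster")
    stats::hclust(stats::dist(obs, method = "euclidean"), method = "ward.D2")
}

#' Export a dendrogram as Newick
#'
#' Branch lengths encode the merge heights (via [ape::as.phylo()]).
#'
#' @param hc an [stats::hclust] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportNewick <- function(hc, path) {
    stopifnot(inherits(hc, "hclust"))
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items:
#' 1 for identical partitions, ~0 at chance level (can be negative).
#'
#' @param x,y label vectors of equal length.
#' @return a single number in \[-1, 1\].
#' @export
adjustedRandIndex <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 2L)
    tab <- table(x, y)
    a <- rowSums(tab); b <- colSums(tab); n <- sum(tab)
    sum_ij <- sum(choose(tab, 2))
    sum_a <- sum(choose(a, 2)); sum_b <- sum(choose(b, 2))
    expected <- sum_a * sum_b / choose(n, 2)
    maximum <- (sum_a + sum_b) / 2
    if (abs(maximum - expected) < .Machine$double.eps^0.5)
        return(if (abs(sum_ij - expected) < .Machine$double.eps^0.5) 1 else 0)
    (sum_ij - expected) / (maximum - expected)
}

#' Agreement between a clustering and known sample labels
#'
#' Cuts the dendrogram at `k` clusters and quantifies agreement with
#' reference labels by the adjusted Rand index plus per-cluster purity
#' (the modal label's share of each cluster).
#'
#' @param result an [stats::hclust] from [hierarchicalCluster()].
#' @param labels reference labels, aligned with the clustered items (same
#'   order; a named vector is reordered by the hclust labels).
#' @param k number of clusters (>= 2).
#' @return list with `ari`, `purity` (per-cluster named vector),
#'   `assignments`, and the cluster x label `table`.
#' @export
clusterLabelAgreement <- function(result, labels, k = 2L) {
    stopifnot(inherits(result, "hclust"), k >= 2L)
    if (!is.null(names(labels)) && !is.null(result$labels))
        labels <- labels[result$labels]
    stopifnot(length(labels) == length(result$order))
    assignments <- stats::cutree(result, k = k)
    tab <- table(cluster = assignments, label = labels)
    list(ari = adjustedRandIndex(assignments, labels),
         purity = apply(tab, 1L, max) / rowSums(tab),
         assignments = assignments,
         table = tab)
}

#' Principal component analysis of an expression matrix
#'
#' Samples are observations; the (optionally row-Z-scored) matrix is
#' column-centered and decomposed by SVD. The default `scaleGenes = TRUE`
#' mirrors the clustering preprocessing (gene-wise Z-scores) so clustering
#' and PCA see the same data. Complete data are required.
#'
#' @param expr SummarizedExperiment or numeric matrix (genes x samples).
#' @param nComponents number of components to keep (default
#'   `min(n_samples - 1, n_genes)`).
#' @param scaleGenes Z-score gene rows first (default TRUE); constant rows
#'   are then dropped as in [zscoreRows()].
#' @return a [PCAModel-class].
#' @export
pcaFit <- function(expr, nComponents = NULL, scaleGenes = TRUE) {
    mat <- .expr_matrix(expr)
    if (anyNA(mat)) stop("pcaFit requires complete data (no NA)")
    if (ncol(mat) < 2L) stop("need at least 2 samples")
    if (scaleGenes) mat <- .expr_matrix(zscoreRows(mat))
    X <- t(mat)                             # samples x genes
    kmax <- min(nrow(X) - 1L, ncol(X))
    k <- if (is.null(nComponents)) kmax else min(nComponents, kmax)
    if (k < 1L) stop("no principal components computable")
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    new("PCAModel",
        scores = pc$x[, seq_len(k), drop = FALSE],
        loadings = pc$rotation[, seq_len(k), drop = FALSE],
        varianceExplained = ve[seq_len(k)],
        center = pc$center,
        scaled = isTRUE(scaleGenes))
}

#' Associate principal components with sample covariates
#'
#' One test per (component, covariate) pair: a one-way ANOVA F-test when
#' the covariate is categorical (factor/character/logical), a Spearman
#' rank-correlation test when it is continuous. Categorical covariates
#' with a single level are skipped with a warning. Raw p-values are
#' reported alongside Benjamini-Hochberg adjusted ones.
#'
#' @param pca a [PCAModel-class].
#' @param metadata data.frame (or DataFrame) of per-sample covariates,
#'   rows aligned with (or named by) the score rows.
#' @return data.frame with columns `component`, `covariate`, `test`,
#'   `statistic`, `p_value`, `p_adjusted`.
#' @export
associatePCs <- function(pca, metadata) {
    stopifnot(is(pca, "PCAModel"))
    metadata <- as.data.frame(metadata)
    scores <- pcaScores(pca)
    if (!is.null(rownames(metadata)) && !is.null(rownames(scores)) &&
        all(rownames(scores) %in% rownames(metadata)))
        metadata <- metadata[rownames(scores), , drop = FALSE]
    stopifnot(nrow(metadata) == nrow(scores))
    rows <- list()
    for (cov in names(metadata)) {
        v <- metadata[[cov]]
        categorical <- is.factor(v) || is.character(v) || is.logical(v)
        if (categorical) {
            v <- factor(v)
            if (nlevels(v) < 2L) {
                warning(sprintf("covariate '%s' has a single level; skipped",
                                cov))
                next
            }
        }
        for (j in seq_len(ncol(scores))) {
            pc <- scores[, j]
            if (categorical) {
                fit <- stats::anova(stats::lm(pc ~ v))
                stat <- fit$`F value`[1]; p <- fit$`Pr(>F)`[1]
                test <- "anova"
            } else {
                ct <- suppressWarnings(
                    stats::cor.test(pc, as.numeric(v), method = "spearman",
                                    exact = FALSE))
                stat <- unname(ct$estimate); p <- ct$p.value
                test <- "spearman"
            }
            rows[[length(rows) + 1L]] <- data.frame(
                component = colnames(scores)[j], covariate = cov,
                test = test, statistic = stat, p_value = p,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(component = character(), covariate = character(),
                          test = character(), statistic = double(),
                          p_value = double(), p_adjusted = double()))
    out <- do.call(rbind, rows)
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    rownames(out) <- NULL
    out
}
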