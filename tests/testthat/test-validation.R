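test_that("subsetByGeneset restricts rows and reports missing members", {
    mat <- matrix(rnorm(100 * 6), 100, 6,
                  dimnames = list(sprintf("G%04d", 1:100), paste0("s", 1:6)))
    gs <- assembleGeneset("KE", S = c(sprintf("G%04d", 1:20),
                                      sprintf("ZZ%02d", 1:5)))
    sub <- suppressMessages(subsetByGeneset(mat, gs))
    expect_identical(nrow(sub), 20L)
    expect_identical(length(attr(sub, "missing")), 5L)
    expect_error(subsetByGeneset(mat, c("nope1", "nope2")), "no geneset member")
    # randomized: row set equals brute-force intersection
    set.seed(6)
    for (i in 1:5) {
        genes <- sample(rownames(mat), 30)
        got <- rownames(subsetByGeneset(mat, genes))
        expect_setequal(got, intersect(genes, rownames(mat)))
    }
    # SummarizedExperiment container round-trips through the same op
    se <- simulateExpression(seed = 1)
    sub_se <- subsetByGeneset(se, S4Vectors::metadata(se)$genesetGenes)
    expect_s4_class(sub_se, "SummarizedExperiment")
    expect_identical(nrow(sub_se), 25L)
})

test_that("zscoreRows centers and scales each row; constant rows drop", {
    m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(10, 0, 20))
    colnames(m) <- paste0("s", 1:3)
    expect_warning(z <- zscoreRows(m), "zero-variance")
    expect_equal(z["a", ], c(s1 = -1, s2 = 0, s3 = 1))   # sd = 1 with n-1
    expect_identical(attr(z, "dropped"), "b")
    expect_error(zscoreRows(rbind(c(2, 2, 2))), "zero variance")
    expect_error(zscoreRows(m[, 1, drop = FALSE]), "2 samples")
    # property: all row means ~0, sds ~1; idempotent
    set.seed(14)
    r <- matrix(rnorm(20 * 8, 5, 3), 20, 8,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
    z <- zscoreRows(r)
    expect_true(all(abs(rowMeans(z)) < 1e-10))
    expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-10))
    expect_equal(zscoreRows(z), z, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Ward clustering groups identical samples first", {
    m <- cbind(s1 = c(0, 0), s2 = c(0, 0), s3 = c(10, 10))
    rownames(m) <- c("g1", "g2")
    hc <- hierarchicalCluster(m)
    expect_identical(unname(stats::cutree(hc, 2)[c("s1", "s2")]),
                     c(1L, 1L))
    expect_identical(hclust_merge_sets(hc)[[1]], c(1L, 2L))
    expect_error(hierarchicalCluster(m[, 1, drop = FALSE]), "at least 2")
    # two well-separated planted pairs merge within pairs first (pair
    # diameters differ so the merge order is unambiguous)
    m2 <- cbind(a1 = c(0, 0), a2 = c(0.1, 0), b1 = c(9, 9), b2 = c(9, 9.15))
    rownames(m2) <- c("g1", "g2")
    merges <- hclust_merge_sets(hierarchicalCluster(m2))
    expect_identical(merges[[1]], c(1L, 2L))
    expect_identical(merges[[2]], c(3L, 4L))
    # genes axis clusters rows
    hcg <- hierarchicalCluster(matrix(rnorm(12), 4, 3,
                                      dimnames = list(paste0("g", 1:4),
                                                      paste0("s", 1:3))),
                               axis = "genes")
    expect_identical(hcg$labels, paste0("g", 1:4))
})

test_that("Ward merges minimize the within-cluster variance increase", {
    set.seed(22)
    for (n in 3:5) for (rep in 1:8) {
        X <- matrix(runif(n * 2) * 10, n, 2)
        rownames(X) <- paste0("p", seq_len(n))
        hc <- stats::hclust(stats::dist(X), method = "ward.D2")
        expect_identical(hclust_merge_sets(hc), ward_oracle_merges(X))
    }
})

test_that("dendrogram topology is invariant to sample order", {
    set.seed(33)
    m <- matrix(rnorm(10 * 6), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    h1 <- hierarchicalCluster(m)
    perm <- sample(6)
    h2 <- hierarchicalCluster(m[, perm])
    d1 <- as.matrix(stats::cophenetic(h1))
    d2 <- as.matrix(stats::cophenetic(h2))[colnames(m), colnames(m)]
    expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("adjusted Rand index matches definition and the pair-count oracle", {
    expect_identical(adjustedRandIndex(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
    # one big cluster vs two balanced labels sits at chance
    expect_equal(adjustedRandIndex(rep(1, 20), rep(c("a", "b"), 10)), 0)
    set.seed(44)
    for (i in 1:25) {
        x <- sample(1:3, 12, TRUE); y <- sample(1:4, 12, TRUE)
        expect_equal(adjustedRandIndex(x, y), oracle_ari(x, y),
                     tolerance = 1e-12)
    }
    # permutation null: mean ARI of random labelings ~ 0
    x <- rep(1:2, each = 10)
    null <- replicate(1000, adjustedRandIndex(x, sample(x)))
    expect_lt(abs(mean(null)), 0.05)
})

test_that("clusterLabelAgreement scores a cut against reference labels", {
    se <- simulateExpression(seed = 2)   # delta = 5 * noiseSd
    labels <- SummarizedExperiment::colData(se)$group
    hc <- hierarchicalCluster(zscoreRows(subsetByGeneset(
        se, S4Vectors::metadata(se)$genesetGenes)))
    ag <- clusterLabelAgreement(hc, labels, k = 2)
    expect_identical(ag$ari, 1)
    expect_true(all(ag$purity == 1))
    expect_identical(sort(unique(ag$assignments)), c(1L, 2L))
    expect_error(clusterLabelAgreement(hc, labels, k = 1), "k >= 2")
})

test_that("PCA recovers exact low-rank structure and is rotation-invariant", {
    # samples on a line: PC1 explains everything
    t_ <- seq(-2, 2, length.out = 6)
    mat <- rbind(g1 = 3 * t_, g2 = -1 * t_, g3 = 0.5 * t_)
    colnames(mat) <- paste0("s", 1:6)
    p <- pcaFit(mat, scaleGenes = FALSE)
    expect_equal(varianceExplained(p)[1], 1.0, tolerance = 1e-12)
    # orthogonal rotation of gene space leaves the spectrum unchanged
    set.seed(55)
    X <- matrix(rnorm(8 * 5), 8, 5,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
    Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
    XR <- Q %*% X
    dimnames(XR) <- dimnames(X)
    expect_equal(varianceExplained(pcaFit(X, scaleGenes = FALSE)),
                 varianceExplained(pcaFit(XR, scaleGenes = FALSE)),
                 tolerance = 1e-8)
    # full-rank reconstruction of the centered matrix
    p2 <- pcaFit(X, scaleGenes = FALSE)
    recon <- pcaScores(p2) %*% t(pcaLoadings(p2))
    centered <- t(X) - rep(colMeans(t(X)), each = ncol(X))
    expect_equal(recon, centered, tolerance = 1e-8, ignore_attr = TRUE)
    # loadings are orthonormal
    expect_equal(crossprod(pcaLoadings(p2)), diag(ncol(pcaScores(p2))),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # planted two-group shift separates the groups on PC1
    se <- simulateExpression(seed = 4)
    pp <- pcaFit(se)
    grp <- SummarizedExperiment::colData(se)$group
    s1 <- pcaScores(pp)[, 1]
    expect_gt(abs(mean(s1[grp == "treated"]) - mean(s1[grp == "control"])),
              3 * max(sd(s1[grp == "treated"]), sd(s1[grp == "control"])))
})

test_that("associatePCs picks ANOVA vs Spearman by covariate type", {
    scores <- cbind(PC1 = rep(c(1, 2, 3), 2), PC2 = c(1, 2, 3, 4, 5, 6))
    rownames(scores) <- paste0("s", 1:6)
    pca <- methods::new("PCAModel", scores = scores,
                        loadings = matrix(0, 2, 2), center = c(0, 0),
                        varianceExplained = c(0.6, 0.4), scaled = FALSE)
    meta <- data.frame(group = rep(c("a", "b"), each = 3),
                       depth = c(2, 4, 6, 8, 10, 12),
                       batch = "one",
                       row.names = paste0("s", 1:6))
    expect_warning(tab <- associatePCs(pca, meta), "single level")
    expect_false("batch" %in% tab$covariate)
    # identical PC1 scores across groups: F = 0, p = 1
    r <- tab[tab$component == "PC1" & tab$covariate == "group", ]
    expect_identical(r$test, "anova")
    expect_equal(r$p_value, 1, tolerance = 1e-12)
    # PC2 is a monotone function of depth: |rho| = 1
    r2 <- tab[tab$component == "PC2" & tab$covariate == "depth", ]
    expect_identical(r2$test, "spearman")
    expect_equal(abs(r2$statistic), 1)
    expect_true(all(tab$p_adjusted >= tab$p_value - 1e-12))
})

test_that("a planted technical confounder is flagged on its own component", {
    se <- simulateExpression(confounder = TRUE, seed = 7)
    tab <- associatePCs(pcaFit(se), SummarizedExperiment::colData(se))
    conf <- tab[tab$covariate == "confounder", ]
    grp <- tab[tab$covariate == "group", ]
    expect_identical(conf$component[which.min(conf$p_value)], "PC2")
    expect_identical(grp$component[which.min(grp$p_value)], "PC1")
})

test_that("dendrograms export to Newick with merge heights", {
    m <- matrix(rnorm(8 * 4), 8, 4,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:4)))
    hc <- hierarchicalCluster(m)
    path <- withr::local_tempfile(fileext = ".nwk")
    exportNewick(hc, path)
    tree <- ape::read.tree(path)
    expect_setequal(tree$tip.label, paste0("s", 1:4))
})

test_that("expression TSV and metadata read back into a SummarizedExperiment", {
    se <- simulateExpression(nGenes = 10, genesetSize = 4, nPerGroup = 3,
                             confounder = FALSE, seed = 9)
    ep <- withr::local_tempfile(); mp <- withr::local_tempfile()
    writeExpression(se, ep, mp)
    back <- readExpression(ep, mp)
    expect_equal(SummarizedExperiment::assay(back),
                 SummarizedExperiment::assay(se), tolerance = 1e-10)
    expect_identical(
        as.character(SummarizedExperiment::colData(back)$group),
        as.character(SummarizedExperiment::colData(se)$group))
})
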