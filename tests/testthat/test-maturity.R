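test_that("a two-gene anti-correlated fit puts all variance on PC1, oriented term-high", {
    ids <- sprintf("s%d", 1:8)
    grp <- rep(c("PTC", "Term"), each = 4)
    L <- rbind(gUp = c(1, 1.1, 0.9, 1, 3, 3.1, 2.9, 3),
               gDn = c(3, 2.9, 3.1, 3, 1, 1.1, 0.9, 1))
    colnames(L) <- ids
    em <- ExpressionMatrix(L, "LOG2P1")
    tab <- tinySampleTable(ids, grp)
    mod <- fitRmm(em, tab, c("gUp", "gDn"), minGenes = 2L)
    expect_gt(mod@varExplained, 0.99)
    sc <- scoreRmm(mod, em)
    expect_gt(mean(sc[grp == "Term"]), mean(sc[grp == "PTC"]))
    ## training-matrix scoring reproduces training scores exactly
    expect_equal(unname(sc), mod@training$scores, tolerance = 1e-10)
    ## a sample equal to the training gene-mean profile scores zero
    em0 <- ExpressionMatrix(
        matrix(rowMeans(L), 2, 1, dimnames = list(rownames(L), "mean")),
        "LOG2P1")
    expect_equal(unname(scoreRmm(mod, em0)), 0, tolerance = 1e-12)
})

test_that("PC1 loadings agree with an independent eigendecomposition", {
    proc <- processedTissue("lung")
    co <- defaultCohort()
    sel <- selectDegs(proc$results[proc$results$contrast == "Term_vs_PTC", ],
                      "rmm_lung")
    mod <- fitRmm(proc$filtered, co$samples, c(sel$up, sel$down))
    ## oracle: eigenvector of the training correlation matrix
    st <- co$samples[match(sampleIds(proc$filtered),
                           co$samples$sample_id), ]
    train <- exprValues(proc$filtered)[mod@genes,
                                       st$group %in% c("PTC", "Term")]
    ev <- eigen(stats::cor(t(train)))$vectors[, 1]
    flip <- sign(sum(ev * mod@loadings))
    expect_lt(max(abs(mod@loadings - flip * ev)), 1e-8)
    expect_equal(sqrt(sum(mod@loadings^2)), 1, tolerance = 1e-10)

    ## duplicating every training sample leaves the loadings unchanged
    em2 <- ExpressionMatrix(
        cbind(exprValues(proc$filtered),
              `colnames<-`(exprValues(proc$filtered),
                           paste0(sampleIds(proc$filtered), "_dup"))),
        "LOG2P1")
    tab2 <- rbind(co$samples,
                  transform(co$samples,
                            sample_id = paste0(sample_id, "_dup")))
    mod2 <- fitRmm(em2, tab2, mod@genes)
    expect_equal(mod2@loadings, mod@loadings, tolerance = 1e-8)
})

test_that("scoring degrades gracefully with missing genes and enforces the overlap floor", {
    proc <- processedTissue("lung")
    co <- defaultCohort()
    sel <- selectDegs(proc$results[proc$results$contrast == "Term_vs_PTC", ],
                      "rmm_lung")
    mod <- fitRmm(proc$filtered, co$samples, c(sel$up, sel$down))
    nMiss <- max(1L, floor(0.05 * length(mod@genes)))
    reduced <- proc$filtered[!geneIds(proc$filtered) %in%
                             mod@genes[seq_len(nMiss)], ]
    expect_warning(scReduced <- scoreRmm(mod, reduced), "absent")
    full <- scoreRmm(mod, proc$filtered)
    expect_gt(stats::cor(scReduced, full), 0.98)
    tiny <- proc$filtered[geneIds(proc$filtered) %in%
                          mod@genes[1:3], ]
    expect_error(scoreRmm(mod, tiny), "floor")
    ## gene order is irrelevant
    perm <- sample(nrow(proc$filtered))
    expect_equal(scoreRmm(mod, proc$filtered[perm, ]), full,
                 tolerance = 1e-10)
})

test_that("partial Spearman matches the residualized-rank oracle", {
    set.seed(91)
    for (i in 1:200) {
        x <- stats::rnorm(30)
        y <- 0.5 * x + stats::rnorm(30)
        z <- sample(0:1, 30, replace = TRUE)
        got <- partialSpearman(x, y, z)
        want <- partialSpearmanOracle(x, y, z)
        expect_equal(got$estimate, want$estimate, tolerance = 1e-12)
        expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
    }
})

test_that("partial Spearman reduces to plain Spearman for an orthogonal control", {
    n <- 12
    x <- stats::qnorm((1:n) / (n + 1))         # ranks 1..n
    z <- orthogonalPermutation(rank(x), seed = 5)
    y <- stats::qexp(orthogonalPermutation(z, seed = 9) / (n + 1))
    expect_equal(stats::cor(rank(x), z), 0)
    expect_equal(stats::cor(rank(y), z), 0)
    got <- partialSpearman(x, y, z)
    expect_equal(got$estimate,
                 stats::cor(x, y, method = "spearman"), tolerance = 1e-10)
    ## y identical to x gives rho 1; degenerate inputs error
    expect_equal(partialSpearman(x, x + 0, z)$estimate, 1)
    expect_error(partialSpearman(rep(1, 10), stats::rnorm(10), 1:10),
                 "zero variance")
    expect_error(partialSpearman(1:10, stats::rnorm(10), 1:10),
                 "degenerate")
})

test_that("Dunnett adjustment reduces to the two-sided t with one treatment", {
    set.seed(101)
    y <- stats::rnorm(24)
    g <- rep(c("PTC", "B060"), each = 12)
    dn <- anovaDunnett(y, g, nMC = 1e6)
    tt <- stats::t.test(y[g == "B060"], y[g == "PTC"],
                        var.equal = TRUE)$p.value
    expect_lt(abs(dn$comparisons$p.adj - tt), 1e-3)
    expect_equal(dn$fPvalue, tt, tolerance = 1e-10)
})

test_that("Dunnett agrees with the multivariate-t reference implementation", {
    skip_if_not_installed("multcomp")
    set.seed(103)
    y <- c(stats::rnorm(8), stats::rnorm(8, 0.8), stats::rnorm(8, -0.3),
           stats::rnorm(8, 0.2))
    g <- factor(rep(c("PTC", "A", "B", "C"), each = 8))
    dn <- anovaDunnett(y, g, nMC = 1e6)
    d <- data.frame(y = y, g = stats::relevel(g, "PTC"))
    mc <- summary(multcomp::glht(stats::aov(y ~ g, d),
                                 linfct = multcomp::mcp(g = "Dunnett")))
    ref <- as.numeric(mc$test$pvalues)
    ord <- match(dn$comparisons$group,
                 sub("^(\\S+) - PTC$", "\\1", names(mc$test$coefficients)))
    expect_lt(max(abs(dn$comparisons$p.adj - ref[ord])), 5e-3)
})

test_that("a large planted shift drives its adjusted P to zero, others unharmed", {
    set.seed(107)
    y <- stats::rnorm(40)
    g <- rep(c("PTC", "A", "B", "C"), each = 10)
    y[g == "B"] <- y[g == "B"] + 10 * stats::sd(y)
    dn <- anovaDunnett(y, g, nMC = 2e5)
    cmp <- dn$comparisons
    expect_lt(cmp$p.adj[cmp$group == "B"], 1e-3)
    expect_gt(min(cmp$p.adj[cmp$group != "B"]), 0.05)
    ## control label must exist, groups need n >= 2
    expect_error(anovaDunnett(y, g, control = "Z"), "absent")
    expect_error(anovaDunnett(y[-(1:9)], g[-(1:9)]), "n >= 2")
    ## sex-covariate two-way form runs and returns one row per treatment
    cov <- rep(c("M", "F"), 20)
    dn2 <- anovaDunnett(y, g, covariate = cov, nMC = 1e5)
    expect_setequal(dn2$comparisons$group, c("A", "B", "C"))
})

test_that("the variance homogeneity test is calibrated and powered", {
    set.seed(109)
    ## power: 100x variance ratio is detected
    y <- c(stats::rnorm(20, sd = 1), stats::rnorm(20, sd = 10))
    g <- rep(c("a", "b"), each = 20)
    expect_lt(leveneVarianceTest(y, g)$p.value, 0.01)
    ## permutation invariance
    perm <- sample(40)
    expect_equal(leveneVarianceTest(y[perm], g[perm])$p.value,
                 leveneVarianceTest(y, g)$p.value, tolerance = 1e-12)
    ## null P values are close to uniform
    ps <- vapply(1:400, function(i) {
        yy <- stats::rnorm(120)
        gg <- rep(c("a", "b", "c"), each = 40)
        leveneVarianceTest(yy, gg)$p.value
    }, numeric(1))
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.005)
    ## degenerate zero-spread input
    expect_warning(out <- leveneVarianceTest(rep(c(1, 2), each = 5),
                                             rep(c("a", "b"), each = 5)),
                   "degenerate")
    expect_equal(out$p.value, 1)
})
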