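makeDeFixture <- function(nGenes = 50, groups = c("PTC", "B060", "Term"),
                          n = 4, years = c(2017L, 2018L), sd = 0.2,
                          seed = 31) {
    set.seed(seed)
    nS <- length(groups) * n
    grp <- rep(groups, each = n)
    year <- rep_len(rep(years, each = ceiling(n / 2)), nS)
    ids <- sprintf("s%02d", seq_len(nS))
    L <- matrix(stats::rnorm(nGenes * nS, 5, sd), nGenes, nS,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)), ids))
    list(em = ExpressionMatrix(L, "LOG2P1"),
         tab = tinySampleTable(ids, grp, year = year))
}

test_that("the blocked OLS fit matches the normal equations and is order invariant", {
    fx <- makeDeFixture()
    bfit <- fitBlockedLinearModel(fx$em, fx$tab)
    ## single-gene oracle: explicit normal-equations solve on the design
    X <- bfit$design
    y <- exprValues(fx$em)[1, ]
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(bfit$fit$coefficients[1, ]), unname(drop(beta)),
                 tolerance = 1e-10)
    rss <- sum((y - X %*% beta)^2)
    expect_equal(bfit$s2[1], rss / (length(y) - ncol(X)),
                 tolerance = 1e-10, ignore_attr = TRUE)

    ## permuting sample order leaves every statistic unchanged
    set.seed(1)
    perm <- sample(ncol(fx$em))
    bfit2 <- fitBlockedLinearModel(fx$em[, perm], fx$tab[perm, ])
    L <- treatmentContrasts(bfit)
    r1 <- contrastTest(bfit, L)
    r2 <- contrastTest(bfit2, treatmentContrasts(bfit2))
    expect_equal(r1$t, r2$t, tolerance = 1e-10)
    expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-10)

    ## equal values within cells give the cell means with zero residual
    em0 <- fx$em
    M <- assay(em0, "expr")
    cellMean <- 3 + as.integer(factor(fx$tab$group))
    M[] <- rep(cellMean, each = nrow(M))
    assay(em0, "expr") <- M
    b0 <- fitBlockedLinearModel(em0, fx$tab)
    expect_lt(max(b0$s2), 1e-20)
})

test_that("treatment contrasts compare against contemporary controls", {
    fx <- makeDeFixture(groups = c("PTC", "B060"), n = 6)
    bfit <- fitBlockedLinearModel(fx$em, fx$tab)
    L <- treatmentContrasts(bfit)
    expect_identical(colnames(L), "B060_vs_PTC")
    expect_equal(sum(L), 0)
    ## the contrast averages (treatment - control) over the shared blocks
    expect_equal(sort(unique(round(L[, 1], 6))), c(-0.5, 0.5))
    expect_error(treatmentContrasts(bfit, control = "Term"), "absent")
})

test_that("moderation hyperparameters are recovered from scaled-F variances", {
    set.seed(71)
    d0 <- 4; s02 <- 2; d <- 10; nG <- 5000
    s2 <- s02 * (stats::rchisq(nG, d) / d) / (stats::rchisq(nG, d0) / d0)
    mf <- moderateVariances(s2, d)
    expect_lt(abs(mf$d0 - d0) / d0, 0.25)
    expect_lt(abs(mf$s02 - s02) / s02, 0.10)
    ## the posterior is the precision-weighted combination
    expect_equal(mf$s2post, posteriorVar(s2, d, mf$d0, mf$s02),
                 tolerance = 1e-8)
    expect_error(moderateVariances(rep(0, 20), 5), "degenerate")
})

test_that("posterior variance limits recover ordinary and pooled t", {
    s2 <- c(0.5, 2, 8); d <- 6
    expect_equal(posteriorVar(s2, d, 0, 1), s2)        # no prior: ordinary t
    expect_equal(posteriorVar(s2, d, Inf, 1.3),
                 rep(1.3, 3))                          # infinite prior: pooled
    ## moderated t^2 decreases in the posterior variance at fixed effect
    tsq <- 1 / posteriorVar(s2, d, 4, 1)
    expect_true(all(diff(tsq) < 0))
})

test_that("contrast tests behave under null, zero and scaled effects", {
    fx <- makeDeFixture(nGenes = 400, n = 6)
    bfit <- fitBlockedLinearModel(fx$em, fx$tab)
    L <- treatmentContrasts(bfit)
    res <- contrastTest(bfit, L)
    ## zero contrast gives t = 0, P = 1
    z <- matrix(0, nrow(L), 1, dimnames = list(rownames(L), "null"))
    rz <- contrastTest(bfit, z)
    expect_true(all(rz$t == 0))
    expect_true(all(rz$pvalue == 1))
    ## doubling a gene's data effect at fixed residuals doubles its t:
    ## two genes share the same noise realization, one with twice the shift
    set.seed(3)
    ids <- sprintf("p%02d", 1:12)
    grp <- rep(c("PTC", "Term"), each = 6)
    noise <- stats::rnorm(12, 0, 0.3)
    noise <- noise - stats::ave(noise, grp)  # exact group effects
    shift <- as.numeric(grp == "Term")
    Ld <- rbind(g1 = 5 + 0.5 * shift + noise,
                g2 = 5 + 1.0 * shift + noise,
                g3 = 4 + stats::rnorm(12, 0, 0.3))
    colnames(Ld) <- ids
    bd <- fitBlockedLinearModel(ExpressionMatrix(Ld, "LOG2P1"),
                                tinySampleTable(ids, grp))
    rd <- contrastTest(bd, treatmentContrasts(bd),
                       trend = FALSE, robust = FALSE)
    expect_equal(rd$t[rd$gene == "g2"], 2 * rd$t[rd$gene == "g1"],
                 tolerance = 1e-8)
    expect_error(contrastTest(bfit, L[-1, , drop = FALSE]), "match design")
})

test_that("full DE pipeline recovers planted effects with controlled FDR", {
    set.seed(57)
    nG <- 2000; n <- 6
    grp <- rep(c("PTC", "Term"), each = n)
    year <- rep(rep(c(2017L, 2018L), each = 3), 2)
    ids <- sprintf("s%02d", seq_len(2 * n))
    L <- matrix(stats::rnorm(nG * 2 * n, 5, 0.35), nG, 2 * n,
                dimnames = list(sprintf("g%04d", seq_len(nG)), ids))
    de <- sample(nG, 100)
    L[de, grp == "Term"] <- L[de, grp == "Term"] +
        sample(c(-1, 1), 100, TRUE)
    em <- ExpressionMatrix(L, "LOG2P1")
    tab <- tinySampleTable(ids, grp, year = year)
    bfit <- fitBlockedLinearModel(em, tab)
    res <- contrastTest(bfit, treatmentContrasts(bfit))
    called <- res$gene[res$fdr <= 0.05]
    truth <- rownames(L)[de]
    sens <- mean(truth %in% called)
    fdrObs <- if (length(called)) mean(!called %in% truth) else 0
    expect_gte(sens, 0.8)
    expect_lte(fdrObs, 0.10)
})

test_that("BH adjustment matches hand computations and is monotone", {
    expect_equal(bhAdjust(rep(0.02, 5)), rep(0.02, 5))
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_error(bhAdjust(c(0.5, 0)), "0, 1")
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
    set.seed(6)
    for (i in 1:20) {
        p <- stats::runif(sample(3:40, 1))
        adj <- bhAdjust(p)
        expect_true(all(adj >= p - 1e-15))
        expect_true(all(diff(adj[order(p)]) > -1e-12))
    }
})

test_that("DEG selection rules are boundary exact and brute-force consistent", {
    tab <- data.frame(
        gene = c("gA", "gB", "gC", "gD"),
        contrast = "T_vs_C",
        log2fc = c(log2(1.25), -log2(1.25), 0.1, -2),
        t = c(2, -2, 0.5, -8),
        pvalue = c(0.05, 0.01, 0.2, 0.001),
        fdr = c(0.2, 0.08, 0.5, 0.01))
    sel <- selectDegs(tab, "gsea")
    ## boundary inclusive: exactly log2(1.25) at P = 0.05 is in
    expect_identical(sel$up, "gA")
    expect_identical(sel$down, c("gB", "gD"))
    empty <- selectDegs(tab[0, ], "gsea")
    expect_identical(empty$counts, c(up = 0L, down = 0L))
    expect_error(selectDegs(tab, "nope"), "registered rules")
    ## strict picks rules exclude the boundary
    strict <- selectDegs(data.frame(gene = "gX", contrast = "c",
        log2fc = -0.4, t = -2, pvalue = 0.01, fdr = 0.1),
        "hippocampus_down_picks")
    expect_length(strict$down, 0L)

    set.seed(12)
    rnd <- data.frame(gene = sprintf("g%03d", 1:300), contrast = "c",
                      log2fc = stats::rnorm(300), t = stats::rnorm(300),
                      pvalue = stats::runif(300))
    rnd$fdr <- bhAdjust(rnd$pvalue)
    s2 <- selectDegs(rnd, "rmm_lung")
    oracle <- rnd$gene[rnd$fdr <= 0.05 & abs(rnd$log2fc) >= 1]
    expect_setequal(c(s2$up, s2$down), oracle)
    gsc <- degGeneSets(s2, "lungTerm")
    expect_true(all(lengths(geneSets(gsc)) > 0))
})
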