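makeReference <- function(nGenes = 120, pops = c("A", "B", "C"),
                          nPer = 6, seed = 61, noise = 0.2) {
    set.seed(seed)
    base <- matrix(stats::rnorm(nGenes * length(pops), 5, 2),
                   nGenes, length(pops))
    M <- base[, rep(seq_along(pops), each = nPer)] +
        matrix(stats::rnorm(nGenes * length(pops) * nPer, 0, noise),
               nGenes)
    dimnames(M) <- list(sprintf("g%03d", seq_len(nGenes)),
                        sprintf("c%02d", seq_len(ncol(M))))
    list(M = 2^M, labels = rep(pops, each = nPer))
}

test_that("marker assignment equals the explicit indicator-correlation argmax", {
    ref <- makeReference()
    sig <- markerFinderSignature(ref$M, ref$labels, nMarkers = 15)
    ## oracle: recompute correlations and assignments from scratch
    I <- stats::model.matrix(~ 0 + factor(ref$labels))
    C <- stats::cor(t(ref$M), I)
    colnames(C) <- sort(unique(ref$labels))
    for (p in names(signatureMarkers(sig))) {
        for (g in signatureMarkers(sig)[[p]]) {
            expect_identical(colnames(C)[which.max(C[g, ])], p)
            expect_equal(signatureWeights(sig)[g, p], C[g, p],
                         tolerance = 1e-12)
        }
    }
    ## correlation mode zeros outside the owning population
    W <- signatureWeights(sig)
    for (p in colnames(W))
        expect_true(all(rownames(W)[W[, p] != 0] %in%
                        signatureMarkers(sig)[[p]]))
    ## invariant under sample permutation
    set.seed(1); perm <- sample(ncol(ref$M))
    sig2 <- markerFinderSignature(ref$M[, perm], ref$labels[perm],
                                  nMarkers = 15)
    expect_identical(signatureMarkers(sig2), signatureMarkers(sig))

    ## a gene expressed only in one population is assigned there
    M2 <- ref$M
    M2["g001", ] <- ifelse(ref$labels == "B", 50, 0)
    sigB <- markerFinderSignature(M2, ref$labels, nMarkers = 200)
    expect_true("g001" %in% signatureMarkers(sigB)$B)
    ## a gene symmetric between two populations ties and is broken by
    ## first label order with a warning
    M3 <- ref$M
    M3["g002", ] <- ifelse(ref$labels %in% c("A", "B"), 30, 0)
    expect_warning(sigT <- markerFinderSignature(M3, ref$labels,
                                                 nMarkers = 200), "tie")
    expect_true("g002" %in% signatureMarkers(sigT)$A)
    ## fully duplicated populations leave one with no markers
    M4 <- ref$M[, c(1:6, 1:6)]
    colnames(M4) <- sprintf("d%02d", 1:12)
    expect_error(suppressWarnings(
        markerFinderSignature(M4, rep(c("A", "B"), each = 6),
                              nMarkers = 5)), "no assignable")
})

test_that("centroid signatures are seeded, subsampled and round-trip their log means", {
    ref <- makeReference(nGenes = 150, pops = c("lungish", "brainish"),
                         nPer = 40, seed = 63, noise = 0.15)
    s1 <- centroidSignature(ref$M, ref$labels, nMarkers = 50, seed = 4)
    s2 <- centroidSignature(ref$M, ref$labels, nMarkers = 50, seed = 4)
    s3 <- centroidSignature(ref$M, ref$labels, nMarkers = 50, seed = 5)
    expect_identical(signatureWeights(s1), signatureWeights(s2))
    expect_false(identical(signatureWeights(s1), signatureWeights(s3)))
    expect_identical(s1@mode, "centroid")
    ## log2(1 + centroid TPM) is an exact mean of log-scale values, so the
    ## back-transform round trips
    expect_true(all(signatureWeights(s1) >= 0))
    logW <- log2(1 + signatureWeights(s1))
    expect_lt(max(abs(2^logW - 1 - signatureWeights(s1))), 1e-10)
    ## tissues under the size floor are dropped with a warning
    expect_warning(
        centroidSignature(ref$M, c(rep("lungish", 40), rep("brainish", 36),
                                   rep("rare", 4)),
                          nMarkers = 50, seed = 4), "dropped")

    ## two tissues with disjoint expressed blocks: markers are the blocks
    blockM <- matrix(0.01, 40, 12,
                     dimnames = list(sprintf("b%02d", 1:40),
                                     sprintf("s%02d", 1:12)))
    blockM[1:20, 1:6] <- 100
    blockM[21:40, 7:12] <- 100
    labs2 <- rep(c("T1", "T2"), each = 6)
    sb <- centroidSignature(blockM, labs2, nMarkers = 25, seed = 1)
    expect_setequal(signatureMarkers(sb)$T1, sprintf("b%02d", 1:20))
    expect_setequal(signatureMarkers(sb)$T2, sprintf("b%02d", 21:40))
    expect_equal(unname(signatureWeights(sb)[sprintf("b%02d", 1:20), "T1"]),
                 rep(100, 20), tolerance = 1e-8)
})

test_that("constrained deconvolution matches the exhaustive active-set oracle", {
    set.seed(67)
    W <- matrix(2^stats::rnorm(80 * 4, 5, 2), 80, 4,
                dimnames = list(sprintf("g%03d", 1:80), paste0("P", 1:4)))
    for (i in 1:25) {
        ## half the probes are arbitrary vectors, so some optima sit on
        ## simplex faces and exercise the active-set logic
        x <- if (i %% 2) W %*% {p <- stats::rgamma(4, 1); p / sum(p)} +
                 stats::rnorm(80, 0, 20)
             else stats::rexp(80, 1 / 100)
        mine <- mixProportions(deconvolveConstrained(
            W, matrix(x, dimnames = list(rownames(W), "m")),
            standardize = FALSE))[1, ]
        oracle <- qpSimplexOracle(W, as.numeric(x))
        expect_lt(max(abs(mine - oracle)), 1e-6)
    }
})

test_that("deconvolution recovers known mixtures and stays on the simplex", {
    set.seed(69)
    W <- matrix(2^stats::rnorm(200 * 5, 5, 2), 200, 5,
                dimnames = list(sprintf("g%03d", 1:200), paste0("P", 1:5)))
    P <- t(vapply(1:50, function(i) {
        p <- stats::rgamma(5, 1); p / sum(p)
    }, numeric(5)))
    noiseless <- simulateMixtures(W, P, noiseCv = 0, seed = 2)
    d0 <- deconvolveConstrained(W, noiseless)
    expect_lt(max(abs(mixProportions(d0) - P)), 1e-4)
    noisy <- simulateMixtures(W, P, noiseCv = 0.1, seed = 2)
    d1 <- deconvolveConstrained(W, noisy)
    expect_lt(mean(abs(mixProportions(d1) - P)), 0.05)
    expect_lt(max(abs(rowSums(mixProportions(d1)) - 1)), 1e-8)
    expect_true(all(mixProportions(d1) >= 0))
    ## a pure population column recovers the unit vector in both modes
    for (std in c(TRUE, FALSE)) {
        dI <- deconvolveConstrained(W, W[, 2, drop = FALSE],
                                    standardize = std)
        expect_lt(max(abs(mixProportions(dI)[1, ] -
                          c(0, 1, 0, 0, 0))), 1e-6)
    }
    ## homogeneity: jointly rescaling signature and mixture leaves the
    ## simplex solution unchanged (standardization off, S fixed in shape)
    d2 <- deconvolveConstrained(3 * W, 3 * exprValues(noiseless)[, 1:5],
                                standardize = FALSE)
    d3 <- deconvolveConstrained(W, exprValues(noiseless)[, 1:5],
                                standardize = FALSE)
    expect_equal(mixProportions(d2), mixProportions(d3),
                 tolerance = 1e-8)
    expect_error(deconvolveConstrained(W[, c(1, 1)], noiseless),
                 "rank-deficient")
    expect_error(deconvolveConstrained(W, noiseless[1:20, ]),
                 "shared")
})

test_that("adding a truly present population never raises the noiseless residual", {
    set.seed(73)
    W <- matrix(2^stats::rnorm(100 * 4, 5, 1.5), 100, 4,
                dimnames = list(sprintf("g%03d", 1:100), paste0("P", 1:4)))
    p <- c(0.4, 0.3, 0.2, 0.1)
    x <- W %*% p
    colnames(x) <- "m"
    partial <- deconvolveConstrained(W[, 1:3], x, standardize = FALSE)
    full <- deconvolveConstrained(W, x, standardize = FALSE)
    expect_lte(residualNorms(full)[1], residualNorms(partial)[1] + 1e-10)
    expect_lt(residualNorms(full)[1], 1e-8)
})

test_that("marker Z scores standardize against the reference group exactly", {
    co <- defaultCohort()
    lg <- log2p1Transform(co$expression$lung)
    st <- co$samples[co$samples$tissue == "lung", ]
    sets <- list(oneGene = geneIds(lg)[5],
                 program = co$truth$maturityGenes$lung$gene[1:20])
    mz <- markerZscore(lg, co$samples, sets)
    ## reference group scores are mean 0 by construction
    ref <- zScores(mz)[st$sample_id[st$group == "PTC"], ]
    expect_lt(max(abs(colMeans(ref))), 1e-10)
    ## a single-gene set score is that gene's z exactly
    g <- geneIds(lg)[5]
    refIdx <- st$sample_id[st$group == "PTC"]
    z <- (exprValues(lg)[g, ] - mean(exprValues(lg)[g, refIdx])) /
        stats::sd(exprValues(lg)[g, refIdx])
    expect_equal(zScores(mz)[, "oneGene"], z, tolerance = 1e-10)
    ## maturity program genes track the latent axis by group
    prog <- zScores(mz)[st$sample_id, "program"]
    up <- co$truth$maturityGenes$lung$loading[1:20] > 0
    gm <- tapply(prog, st$group, mean)
    if (mean(up) > 0.5) expect_identical(names(which.max(gm)), "Term")
})

test_that("the gated extremum rule follows ANOVA, Dunnett and the numerical extremum", {
    set.seed(77)
    g <- rep(c("Term", "PTC", "B060", "C1x"), each = 8)
    ## comparator far above everyone: flagged maximum
    y <- stats::rnorm(32, 0, 1)
    y[g == "Term"] <- y[g == "Term"] + 8
    out <- groupwiseExtremumTest(y, g, comparator = "Term")
    expect_identical(out$flag, "maximum")
    ## no group structure: gate almost surely closed
    y0 <- stats::rnorm(32)
    out0 <- groupwiseExtremumTest(y0, g)
    expect_true(out0$flag %in% c("none", "maximum", "minimum"))
    ## comparator numerically max but one comparison not significant
    y2 <- stats::rnorm(32, 0, 0.5)
    y2[g == "Term"] <- y2[g == "Term"] + 3
    y2[g == "B060"] <- y2[g == "B060"] + 2.8
    out2 <- groupwiseExtremumTest(y2, g)
    if (out2$anovaP < 0.05 &&
        any(out2$dunnett$comparisons$p.adj >= 0.05))
        expect_identical(out2$flag, "none")
})
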