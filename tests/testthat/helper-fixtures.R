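## Shared fixtures and independent oracles. Fixtures are built in code;
## the default synthetic cohort (and its preprocessing) is cached per test
## run because several files exercise it.

.cache <- new.env(parent = emptyenv())

defaultCohort <- function() {
    if (is.null(.cache$cohort))
        .cache$cohort <- simulateCohort(cohortConfig())
    .cache$cohort
}

## purge + log transform + batch correction + expression filter for one
## tissue of the default cohort, plus the term-vs-PTC contrast table
processedTissue <- function(tissue = "lung") {
    key <- paste0("proc_", tissue)
    if (is.null(.cache[[key]])) {
        co <- defaultCohort()
        if (is.null(.cache$purge))
            .cache$purge <- suppressWarnings(
                identifySexLinkedGenes(co$expression, co$samples))
        x <- suppressWarnings(dropGenes(co$expression[[tissue]],
                                        .cache$purge$removed))
        x <- ascaBatchCorrect(log2p1Transform(x), co$samples)
        filt <- filterLowExpression(x)
        bfit <- fitBlockedLinearModel(filt, co$samples)
        res <- contrastTest(bfit, treatmentContrasts(bfit))
        .cache[[key]] <- list(corrected = x, filtered = filt,
                              fit = bfit, results = res,
                              purge = .cache$purge)
    }
    .cache[[key]]
}

## small deterministic expression fixture
smallExpr <- function(nGenes = 6, nSamples = 4, scale = "TPM", seed = 11) {
    set.seed(seed)
    m <- matrix(round(2^stats::runif(nGenes * nSamples, 0, 8), 4),
                nGenes, nSamples,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(nSamples))))
    ExpressionMatrix(m, scale)
}

tinySampleTable <- function(ids, groups, tissue = "lung",
                            year = 2017L, sex = "M", pv40 = NA_real_) {
    data.frame(sample_id = ids, animal_id = paste0("an_", ids),
               tissue = tissue, group = groups,
               year = year, sex = rep_len(sex, length(ids)),
               pv40 = pv40, stringsAsFactors = FALSE)
}

## ---- independent oracles ----------------------------------------------

## brute-force step-up BH from the definition: for each i, the minimum
## of m * p_(k) / k over every order statistic k with p_(k) >= p_i
bhDefinition <- function(p) {
    m <- length(p)
    ps <- sort(p)
    ratio <- m * ps / seq_len(m)
    vapply(p, function(pi) min(1, min(ratio[ps >= pi])), numeric(1))
}

## partial Spearman oracle: residualize ranks on the control ranks, then
## Pearson of the residuals; P from the same t transform
partialSpearmanOracle <- function(x, y, z) {
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    ex <- stats::residuals(stats::lm(rx ~ rz))
    ey <- stats::residuals(stats::lm(ry ~ rz))
    r <- stats::cor(ex, ey)
    n <- length(x)
    tstat <- r * sqrt((n - 3) / (1 - r^2))
    list(estimate = r, p.value = 2 * stats::pt(-abs(tstat), n - 3))
}

## two-sided Fisher P by exhaustive hypergeometric enumeration
fisherOracle <- function(r, n, R, N) {
    ks <- max(0, n + R - N):min(n, R)
    probs <- stats::dhyper(ks, R, N - R, n)
    sum(probs[probs <= probs[ks == r] * (1 + 1e-7)])
}

## brute-force GSEA running-sum enrichment score
esOracle <- function(ranking, set, gseaParam = 1) {
    hits <- names(ranking) %in% set
    w <- abs(ranking)^gseaParam
    phit <- cumsum(ifelse(hits, w, 0)) / sum(w[hits])
    pmiss <- cumsum(!hits) / (length(ranking) - sum(hits))
    d <- phit - pmiss
    d[which.max(abs(d))]
}

## global optimum of min ||Sw - x||^2, w >= 0, sum(w) = 1, by exhaustive
## enumeration of active sets (exact for small population counts)
qpSimplexOracle <- function(S, x) {
    k <- ncol(S)
    A <- crossprod(S); b <- crossprod(S, x)
    best <- NULL; bestObj <- Inf
    for (mask in seq_len(2^k - 1)) {
        passive <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
        np <- length(passive)
        K <- rbind(cbind(2 * A[passive, passive, drop = FALSE], rep(1, np)),
                   c(rep(1, np), 0))
        sol <- tryCatch(solve(K, c(2 * b[passive], 1)),
                        error = function(e) NULL)
        if (is.null(sol)) next
        w <- numeric(k); w[passive] <- sol[seq_len(np)]
        if (any(w < -1e-9)) next
        obj <- sum((S %*% w - x)^2)
        if (obj < bestObj - 1e-12) { bestObj <- obj; best <- w }
    }
    pmax(best, 0) / sum(pmax(best, 0))
}

## find a permutation of 1:n whose ranks are exactly uncorrelated with a
## reference rank vector (integer sums make exact zero attainable)
orthogonalPermutation <- function(ref, seed = 1, maxTries = 2e5) {
    n <- length(ref)
    target <- sum(ref) * (n + 1) / 2
    set.seed(seed)
    for (i in seq_len(maxTries)) {
        z <- sample.int(n)
        if (sum(z * ref) == target) return(z)
    }
    stop("no orthogonal permutation found")
}
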