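## Signature construction and bulk deconvolution. Two signature modes:
## "correlation" (single-cell style: each gene assigned to the population
## whose 0/1 indicator profile it best correlates with; entries are those
## correlations, zero elsewhere) and "centroid" (bulk-compendium style:
## per-tissue expression centroids over indicator-correlated markers).
## Mixing proportions are estimated by quadratic programming with the
## nonnegativity and sum-to-one constraints enforced exactly. A marker-set
## Z-score strategy complements the proportion estimates.

.indicatorCorrelations <- function(M, labels) {
    labels <- factor(labels)
    I <- stats::model.matrix(~ 0 + labels)
    colnames(I) <- levels(labels)
    keep <- apply(M, 1L, stats::sd) > 0
    C <- matrix(NA_real_, nrow(M), nlevels(labels),
                dimnames = list(rownames(M), levels(labels)))
    if (any(keep))
        C[keep, ] <- stats::cor(t(M[keep, , drop = FALSE]), I)
    list(cor = C, usable = keep)
}

#' Correlation-mode marker signature from a labeled reference
#'
#' For every gene, the Pearson correlation with each population's 0/1
#' indicator profile is computed; the gene is assigned to its
#' best-correlated population, and each population keeps its top
#' `nMarkers` genes by correlation. Signature entries are those
#' correlations at the owning cells and zero elsewhere.
#'
#' @param reference genes x samples numeric matrix (or
#'   [ExpressionMatrix-class]) of reference profiles.
#' @param labels population label per reference column (>= 2 populations).
#' @param nMarkers markers retained per population (default 100).
#' @return a correlation-mode [SignatureMatrix-class].
#' @export
markerFinderSignature <- function(reference, labels, nMarkers = 100L) {
    M <- if (is(reference, "ExpressionMatrix")) exprValues(reference)
         else as.matrix(reference)
    if (length(labels) != ncol(M))
        stop("one population label per reference column is required")
    if (length(unique(labels)) < 2L)
        stop(">= 2 populations are required")
    ic <- .indicatorCorrelations(M, labels)
    if (any(!ic$usable))
        warning(sum(!ic$usable), " constant gene(s) skipped")
    C <- ic$cor[ic$usable, , drop = FALSE]
    best <- max.col(C, ties.method = "first")
    nTies <- sum(apply(C, 1L, function(r) sum(r == max(r)) > 1L))
    if (nTies > 0L)
        warning(nTies, " assignment tie(s) broken by first label order")
    pops <- colnames(C)
    markers <- list()
    W <- matrix(0, nrow(C), length(pops),
                dimnames = list(rownames(C), pops))
    for (j in seq_along(pops)) {
        own <- which(best == j & C[, j] > 0)
        own <- own[order(C[own, j], decreasing = TRUE)]
        own <- utils::head(own, nMarkers)
        if (!length(own))
            stop("population '", pops[j], "' has no assignable markers")
        markers[[pops[j]]] <- rownames(C)[own]
        W[own, j] <- C[own, j]
    }
    keep <- rowSums(W != 0) > 0
    new("SignatureMatrix", weights = W[keep, , drop = FALSE],
        markers = markers, mode = "correlation",
        valueScale = "correlation")
}

#' Centroid-mode tissue signature from a bulk compendium
#'
#' Tissues with fewer than `minSamples` samples are dropped; the rest are
#' randomly subsampled (seeded) to at most `maxPerTissue` samples. On the
#' log2(1+TPM) scale, each gene is assigned to its best indicator-
#' correlated tissue; per tissue the top `nMarkers` genes with Pearson
#' correlation above `rMin` become markers. Centroids are gene-wise mean
#' log2(1+TPM) profiles over each tissue's subsample, back-transformed to
#' TPM for deconvolution.
#'
#' @param reference genes x samples TPM matrix or [ExpressionMatrix-class].
#' @param labels tissue label per column.
#' @param nMarkers markers per tissue (default 200).
#' @param rMin correlation floor for markers (default 0.5); tissues with
#'   no passing marker are dropped with a warning.
#' @param maxPerTissue subsampling cap (default 30).
#' @param minSamples minimum samples for a tissue to enter (default 5).
#' @param seed RNG seed for the subsampling.
#' @return a centroid-mode [SignatureMatrix-class] (TPM-scale entries over
#'   the union of all marker genes).
#' @export
centroidSignature <- function(reference, labels, nMarkers = 200L,
                              rMin = 0.5, maxPerTissue = 30L,
                              minSamples = 5L, seed = 1L) {
    M <- if (is(reference, "ExpressionMatrix")) {
        if (exprScale(reference) == "TPM") exprValues(reference)
        else 2^exprValues(reference) - 1
    } else as.matrix(reference)
    labels <- as.character(labels)
    if (length(labels) != ncol(M))
        stop("one tissue label per reference column is required")
    sizes <- table(labels)
    small <- names(sizes)[sizes < minSamples]
    if (length(small)) {
        warning("tissue(s) with fewer than ", minSamples,
                " samples dropped: ", paste(small, collapse = ", "))
        keep <- !labels %in% small
        M <- M[, keep, drop = FALSE]; labels <- labels[keep]
    }
    if (length(unique(labels)) < 2L)
        stop(">= 2 tissues are required after size filtering")
    set.seed(seed)
    sel <- unlist(lapply(unique(labels), function(l) {
        idx <- which(labels == l)
        if (length(idx) > maxPerTissue) sort(sample(idx, maxPerTissue))
        else idx
    }), use.names = FALSE)
    M <- M[, sel, drop = FALSE]; labels <- labels[sel]
    L <- log2(1 + M)
    ic <- .indicatorCorrelations(L, labels)
    C <- ic$cor[ic$usable, , drop = FALSE]
    best <- max.col(C, ties.method = "first")
    pops <- colnames(C)
    markers <- list()
    for (j in seq_along(pops)) {
        own <- which(best == j & C[, j] > rMin)
        own <- own[order(C[own, j], decreasing = TRUE)]
        own <- utils::head(own, nMarkers)
        if (length(own))
            markers[[pops[j]]] <- rownames(C)[own]
    }
    dropped <- setdiff(pops, names(markers))
    if (length(dropped))
        warning("tissue(s) with no marker passing r > ", rMin,
                " dropped: ", paste(dropped, collapse = ", "))
    if (length(markers) < 2L)
        stop("fewer than 2 tissues retain markers")
    genes <- unique(unlist(markers, use.names = FALSE))
    W <- vapply(names(markers), function(l)
        rowMeans(L[genes, labels == l, drop = FALSE]),
        numeric(length(genes)))
    W <- 2^W - 1  # back to TPM for deconvolution
    dimnames(W) <- list(genes, names(markers))
    new("SignatureMatrix", weights = W, markers = markers,
        mode = "centroid", valueScale = "TPM")
}

## Exact active-set QP: min ||S w - x||^2 s.t. w >= 0, sum(w) = 1.
## Primal active-set iteration on the bound constraints with the equality
## handled in the KKT system; S must have full column rank.
.qpSimplex <- function(S, x, tol = 1e-10) {
    k <- ncol(S)
    ## the solution is invariant to a joint rescaling of S and x; normalize
    ## so the KKT system mixes comparable magnitudes with the unit row
    sc <- max(abs(S), 1e-300)
    S <- S / sc
    x <- x / sc
    A <- crossprod(S)
    b <- crossprod(S, x)
    scaleTol <- tol * max(1, max(abs(A)))
    solveSubset <- function(passive) {
        np <- length(passive)
        K <- rbind(cbind(2 * A[passive, passive, drop = FALSE],
                         rep(1, np)),
                   c(rep(1, np), 0))
        rhs <- c(2 * b[passive], 1)
        sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
        if (is.null(sol)) return(NULL)
        list(w = sol[seq_len(np)], mu = sol[np + 1L])
    }
    w <- rep(1 / k, k)
    active <- rep(FALSE, k)
    for (iter in seq_len(50L * k)) {
        passive <- which(!active)
        sub <- solveSubset(passive)
        if (is.null(sub))
            stop("singular KKT system; signature is rank-deficient")
        wStar <- numeric(k)
        wStar[passive] <- sub$w
        p <- wStar - w
        if (max(abs(p)) <= tol) {
            grad <- 2 * (A %*% w - b)
            lambda <- grad[active] + sub$mu
            if (!length(lambda) || min(lambda) >= -sqrt(scaleTol)) {
                w[w < 0] <- 0
                return(w / sum(w))
            }
            release <- which(active)[which.min(lambda)]
            active[release] <- FALSE
            next
        }
        blocking <- passive[p[passive] < -tol & w[passive] > -tol]
        alpha <- 1
        hit <- NA_integer_
        for (j in blocking) {
            aj <- -w[j] / p[j]
            if (aj < alpha) { alpha <- aj; hit <- j }
        }
        w <- w + alpha * p
        if (!is.na(hit)) {
            w[hit] <- 0
            active[hit] <- TRUE
        }
    }
    stop("simplex QP did not converge")
}

#' Constrained deconvolution of bulk mixtures
#'
#' Per sample, solves `min_w ||S w - x||^2` subject to `w >= 0` and
#' `sum(w) = 1` over the genes shared between the signature and the
#' mixture matrix, by an exact active-set quadratic program. With
#' `standardize = TRUE` (default) each shared gene of the signature and
#' the mixture profile is centered and scaled by the signature row's mean
#' and SD before fitting, mirroring the scaling convention of reference
#' deconvolution tools; the constraints make the fit invariant to this
#' choice in the noiseless case.
#'
#' @param signature a [SignatureMatrix-class] or genes x populations
#'   matrix.
#' @param mixtures genes x samples [ExpressionMatrix-class] or matrix.
#' @param standardize per-gene standardization flag (default `TRUE`).
#' @param sharedFloor minimum fraction of signature genes that must be
#'   found in the mixtures (default 0.5).
#' @return a [DeconvResult-class] (per-sample proportions on the simplex
#'   and residual norms on the fitting scale).
#' @export
deconvolveConstrained <- function(signature, mixtures, standardize = TRUE,
                                  sharedFloor = 0.5) {
    W <- if (is(signature, "SignatureMatrix")) signatureWeights(signature)
         else as.matrix(signature)
    X <- if (is(mixtures, "ExpressionMatrix")) exprValues(mixtures)
         else as.matrix(mixtures)
    shared <- intersect(rownames(W), rownames(X))
    frac <- length(shared) / nrow(W)
    if (frac < sharedFloor)
        stop(sprintf("only %.1f%% of signature genes shared with mixtures (floor %.0f%%)",
                     100 * frac, 100 * sharedFloor))
    S <- W[shared, , drop = FALSE]
    M <- X[shared, , drop = FALSE]
    if (standardize) {
        mu <- rowMeans(S)
        sdv <- apply(S, 1L, stats::sd)
        usable <- sdv > 0
        S <- (S[usable, , drop = FALSE] - mu[usable]) / sdv[usable]
        M <- (M[usable, , drop = FALSE] - mu[usable]) / sdv[usable]
    }
    ## identifiability is needed on the sum-to-one constraint manifold:
    ## per-gene centering nulls the all-ones direction, which the equality
    ## constraint pins down, so the check augments S with the constraint row
    if (qr(rbind(S, rep(1, ncol(S))))$rank < ncol(S))
        stop("signature is rank-deficient on the shared genes")
    P <- t(apply(M, 2L, function(xcol) .qpSimplex(S, xcol)))
    dimnames(P) <- list(colnames(M), colnames(S))
    resid <- vapply(seq_len(ncol(M)), function(i)
        sqrt(sum((S %*% P[i, ] - M[, i])^2)), numeric(1))
    new("DeconvResult", proportions = P,
        residuals = stats::setNames(resid, colnames(M)))
}

#' Top specific markers per population from a signature
#'
#' @param signature a [SignatureMatrix-class].
#' @param n markers per population (default 20).
#' @return a [GeneSetCollection-class] of per-population marker sets (the
#'   signature's marker lists are already ranked by specificity).
#' @export
topMarkers <- function(signature, n = 20L) {
    stopifnot(is(signature, "SignatureMatrix"))
    GeneSetCollection(lapply(signatureMarkers(signature), utils::head, n))
}

#' Marker-set Z scores against a reference group
#'
#' Each gene is standardized by its mean and SD in the reference treatment
#' group (preterm controls by default); standardized values are averaged
#' over the genes of each marker set, giving one score per sample per
#' set. Genes with zero reference SD are dropped with a warning; sets
#' with no usable genes yield a missing score column with a warning.
#'
#' @param x a [ExpressionMatrix-class] (log scale recommended).
#' @param samples sample metadata data.frame.
#' @param markerSets a [GeneSetCollection-class] or named list of gene
#'   vectors (e.g. [topMarkers()] output).
#' @param referenceGroup standardizing group label (default `"PTC"`,
#'   n >= 2 required).
#' @return a [MarkerZScores-class].
#' @export
markerZscore <- function(x, samples, markerSets, referenceGroup = "PTC") {
    stopifnot(is(x, "ExpressionMatrix"))
    sets <- if (is(markerSets, "GeneSetCollection")) geneSets(markerSets)
            else markerSets
    samples <- validateSampleTable(samples)
    st <- samples[match(sampleIds(x), samples$sample_id), , drop = FALSE]
    refIdx <- which(st$group == referenceGroup)
    if (length(refIdx) < 2L)
        stop("reference group '", referenceGroup, "' needs n >= 2")
    M <- exprValues(x)
    mu <- rowMeans(M[, refIdx, drop = FALSE])
    sdv <- apply(M[, refIdx, drop = FALSE], 1L, stats::sd)
    zero <- names(sdv)[sdv == 0]
    if (length(zero))
        warning(length(zero), " gene(s) with zero reference SD dropped")
    usable <- setdiff(geneIds(x), zero)
    Z <- (M[usable, , drop = FALSE] - mu[usable]) / sdv[usable]
    scores <- vapply(names(sets), function(nm) {
        g <- intersect(sets[[nm]], usable)
        if (!length(g)) {
            warning("marker set '", nm, "' has no usable genes; score missing")
            return(rep(NA_real_, ncol(M)))
        }
        colMeans(Z[g, , drop = FALSE])
    }, numeric(ncol(M)))
    scores <- matrix(scores, nrow = ncol(M),
                     dimnames = list(sampleIds(x), names(sets)))
    new("MarkerZScores", scores = scores, referenceGroup = referenceGroup,
        refMeans = mu, refSds = sdv, dropped = zero)
}

#' Flag a comparator group as the extremum of a per-group response
#'
#' Applies the gated testing rule used for deconvolution proportions and
#' marker Z scores: if the one-way ANOVA F test is significant at
#' `alpha`, Dunnett's test with the comparator (term controls) as the
#' common reference is run, and the comparator is flagged as the maximum
#' (minimum) only when its mean is the numerical extremum among all group
#' means and every Dunnett-adjusted P is below `alpha`.
#'
#' @param values per-sample response (a proportion column or Z score).
#' @param groups treatment group labels.
#' @param comparator the common comparison group (default `"Term"`).
#' @param alpha gate and comparison level (default 0.05).
#' @param nMC,seed,nullDraws passed to [anovaDunnett()].
#' @return list with `flag` (`"maximum"`, `"minimum"` or `"none"`),
#'   `anovaP` and the `DunnettResult` (NULL when the gate fails).
#' @export
groupwiseExtremumTest <- function(values, groups, comparator = "Term",
                                  alpha = 0.05, nMC = 2e5, seed = 1L,
                                  nullDraws = NULL) {
    g <- factor(groups)
    fit <- stats::lm(values ~ g)
    anovaP <- stats::anova(fit)["g", "Pr(>F)"]
    if (!is.finite(anovaP) || anovaP >= alpha)
        return(list(flag = "none", anovaP = anovaP, dunnett = NULL))
    dn <- anovaDunnett(values, groups, control = comparator, nMC = nMC,
                       seed = seed, nullDraws = nullDraws)
    means <- dn$groupMeans
    allSig <- all(dn$comparisons$p.adj < alpha)
    flag <- if (means[comparator] == max(means) && allSig) "maximum"
            else if (means[comparator] == min(means) && allSig) "minimum"
            else "none"
    list(flag = flag, anovaP = anovaP, dunnett = dn)
}
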