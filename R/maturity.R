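## The RNA maturity model: PCA restricted to preterm- and term-control
## samples over term-vs-preterm differential genes, with every sample
## (including other tissues) scored by projection onto the oriented first
## principal component. Validation statistics: partial Spearman correlation
## against the PV40 lung-compliance endpoint, one-way ANOVA with Dunnett
## many-to-one comparisons, and the Brown-Forsythe variance homogeneity
## diagnostic.

#' Fit an RNA maturity model
#'
#' Restricts the matrix to the supplied term-vs-preterm differential genes
#' and to the preterm-control and term-control training samples, centers
#' and scales each gene by its training mean and SD, runs PCA on the
#' standardized training matrix and stores the first-component loadings.
#' The component sign is fixed so the mean term training score exceeds the
#' mean preterm training score (eigenvector sign is otherwise arbitrary).
#'
#' @param x a `LOG2P1` [ExpressionMatrix-class].
#' @param samples sample metadata data.frame.
#' @param genes character vector of selected maturity genes (e.g. from
#'   [selectDegs()] with the tissue's rule).
#' @param control,term training group labels (defaults `"PTC"`, `"Term"`).
#' @param sourceTissue recorded on the model (default from metadata).
#' @param minGenes smallest usable model gene count (default 3; two genes
#'   are enough for a mathematically valid component, but three is the
#'   floor below which a selection rule should be loosened).
#' @return a [MaturityModel-class].
#' @export
fitRmm <- function(x, samples, genes, control = "PTC", term = "Term",
                   sourceTissue = NULL, minGenes = 3L) {
    stopifnot(is(x, "ExpressionMatrix"))
    if (exprScale(x) != "LOG2P1")
        stop("maturity model expects log2(1+TPM) values")
    samples <- validateSampleTable(samples)
    st <- samples[match(sampleIds(x), samples$sample_id), , drop = FALSE]
    trainIdx <- which(st$group %in% c(control, term))
    if (!any(st$group == control) || !any(st$group == term))
        stop("both the '", control, "' and '", term,
             "' groups must be present for training")
    if (sum(st$group == control) < 3L || sum(st$group == term) < 2L)
        stop("training needs >= 3 control and >= 2 term samples")
    genes <- intersect(genes, geneIds(x))
    M <- exprValues(x)[genes, trainIdx, drop = FALSE]
    ctr <- rowMeans(M)
    scl <- apply(M, 1L, stats::sd)
    zero <- scl == 0
    if (any(zero)) {
        warning(sum(zero), " gene(s) with zero training SD dropped")
        M <- M[!zero, , drop = FALSE]
        ctr <- ctr[!zero]; scl <- scl[!zero]
        genes <- genes[!zero]
    }
    if (length(genes) < max(2L, minGenes))
        stop("fewer than ", max(2L, minGenes),
             " usable model genes; loosen the selection rule")
    Z <- (M - ctr) / scl
    pc <- stats::prcomp(t(Z), center = FALSE, scale. = FALSE)
    loadings <- pc$rotation[, 1L]
    scores <- pc$x[, 1L]
    isTerm <- st$group[trainIdx] == term
    orient <- if (mean(scores[isTerm]) >= mean(scores[!isTerm])) 1 else -1
    loadings <- orient * loadings
    scores <- orient * scores
    tissue <- sourceTissue
    if (is.null(tissue)) {
        tissue <- unique(st$tissue[trainIdx])
        tissue <- if (length(tissue) == 1L) tissue else "mixed"
    }
    new("MaturityModel", sourceTissue = tissue, genes = genes,
        center = unname(ctr), scale = unname(scl),
        loadings = unname(loadings),
        varExplained = pc$sdev[1L]^2 / sum(pc$sdev^2),
        training = list(sample_id = sampleIds(x)[trainIdx],
                        group = st$group[trainIdx],
                        scores = unname(scores)))
}

#' Score samples with a maturity model
#'
#' Standardizes the target matrix with the model's training center and
#' scale and projects onto the oriented first-component loadings. Works
#' across tissues: model genes missing from the target contribute zero
#' after standardization (reported with a warning), provided the overlap
#' stays above the floor.
#'
#' @param model a [MaturityModel-class].
#' @param x a `LOG2P1` [ExpressionMatrix-class] (for cross-tissue scoring,
#'   batch-corrected but unfiltered values).
#' @param minOverlap minimum fraction of model genes that must be present
#'   (default 0.9).
#' @return named numeric vector of per-sample maturity scores.
#' @export
scoreRmm <- function(model, x, minOverlap = 0.9) {
    stopifnot(is(model, "MaturityModel"), is(x, "ExpressionMatrix"))
    if (exprScale(x) != "LOG2P1")
        stop("maturity scoring expects log2(1+TPM) values")
    present <- model@genes %in% geneIds(x)
    overlap <- mean(present)
    if (overlap < minOverlap)
        stop(sprintf("only %.1f%% of model genes present (floor %.0f%%)",
                     100 * overlap, 100 * minOverlap))
    if (any(!present))
        warning(sum(!present), " model gene(s) absent; imputed as 0 after standardization")
    Z <- matrix(0, length(model@genes), ncol(x),
                dimnames = list(model@genes, sampleIds(x)))
    gi <- model@genes[present]
    Z[gi, ] <- (exprValues(x)[gi, , drop = FALSE] -
                model@center[present]) / model@scale[present]
    drop(crossprod(Z, model@loadings))[seq_len(ncol(x))] |>
        stats::setNames(sampleIds(x))
}

#' Partial Spearman rank correlation
#'
#' First-order partial correlation of the ranks of `x` and `y` given the
#' ranks of a single control variable `z` (average ranks for ties):
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with a
#' two-sided P value from `t = r sqrt((n - 3) / (1 - r^2))` on `n - 3`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @param z the control variable (e.g. dichotomized collection year).
#' @return list of class `CorrelationResult`: `estimate`, `statistic`,
#'   `p.value`, `n`, `k` (number of controls, 1).
#' @export
partialSpearman <- function(x, y, z) {
    n <- length(x)
    if (length(y) != n || length(z) != n)
        stop("x, y and z must have equal length")
    if (n < 4L)
        stop("partial correlation needs n >= 4")
    ok <- stats::complete.cases(x, y, z)
    x <- x[ok]; y <- y[ok]; z <- z[ok]
    n <- length(x)
    if (n < 4L) stop("fewer than 4 complete observations")
    rx <- rank(x); ry <- rank(y); rz <- rank(as.numeric(factor(z)))
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
        stop("zero variance in x or y")
    rxy <- stats::cor(rx, ry)
    rxz <- stats::cor(rx, rz)
    ryz <- stats::cor(ry, rz)
    if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
        stop("control variable is degenerate with x or y")
    r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    r <- max(-1, min(1, r))
    df <- n - 3L
    tstat <- if (abs(r) >= 1) Inf * sign(r)
             else r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df)
    structure(list(estimate = r, statistic = tstat, p.value = p,
                   n = n, k = 1L),
              class = "CorrelationResult")
}

#' Monte Carlo null draws of the Dunnett max-|T| statistic
#'
#' Draws from the equicorrelated multivariate-t distribution of the
#' largest absolute many-to-one comparison statistic under the global
#' null, with `lambda_i = sqrt(n_i / (n_i + n_0))` and a shared
#' chi-squared denominator on the pooled-error degrees of freedom.
#'
#' @param ns treatment group sizes.
#' @param n0 control group size.
#' @param df pooled residual degrees of freedom.
#' @param nMC number of draws.
#' @param seed RNG seed.
#' @return numeric vector of `nMC` max-|T| draws.
#' @export
dunnettMaxNull <- function(ns, n0, df, nMC = 2e5, seed = 1L) {
    lam <- sqrt(ns / (ns + n0))
    set.seed(seed)
    Z0 <- stats::rnorm(nMC)
    S <- sqrt(stats::rchisq(nMC, df) / df)
    maxT <- numeric(nMC)
    for (j in seq_along(lam)) {
        Tj <- abs(lam[j] * Z0 + sqrt(1 - lam[j]^2) * stats::rnorm(nMC)) / S
        maxT <- pmax(maxT, Tj)
    }
    maxT
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Overall F test of the group factor, then each treatment compared with
#' the common control using pooled-error t statistics. Family-wise
#' adjusted P values are `Pr(max_j |T_j| >= |t_i|)` under the
#' equicorrelated multivariate-t null, estimated by seeded Monte Carlo.
#' An optional categorical covariate (e.g. sex) gives the two-way form
#' with covariate-adjusted effects and error.
#'
#' @param values numeric response (PV40, maturity scores, proportions...).
#' @param groups group labels.
#' @param control control group label (default `"PTC"`).
#' @param covariate optional categorical covariate.
#' @param nMC Monte Carlo draws for the adjusted P (default 2e5).
#' @param seed RNG seed for the null draws.
#' @param nullDraws optional precomputed draws from [dunnettMaxNull()]
#'   (reused across calls with an identical design).
#' @return list of class `DunnettResult`: `fStatistic`, `fPvalue`,
#'   `comparisons` (data.frame with group, estimate, se, t, adjusted P),
#'   `df` and the group means.
#' @export
anovaDunnett <- function(values, groups, control = "PTC", covariate = NULL,
                         nMC = 2e5, seed = 1L, nullDraws = NULL) {
    g <- factor(groups)
    if (!control %in% levels(g))
        stop("control label '", control, "' absent from groups")
    ok <- is.finite(values)
    values <- values[ok]; g <- droplevels(g[ok])
    if (!is.null(covariate)) covariate <- factor(covariate)[ok]
    sizes <- table(g)
    if (any(sizes < 2L))
        stop("every group needs n >= 2")
    g <- stats::relevel(g, ref = control)
    dat <- data.frame(y = values, g = g)
    if (is.null(covariate)) {
        fit <- stats::lm(y ~ g, data = dat)
        av <- stats::anova(fit)
        fRow <- "g"
    } else {
        if (nlevels(droplevels(covariate)) < 2L)
            stop("covariate coding is singular")
        dat$cov <- droplevels(covariate)
        fit <- stats::lm(y ~ cov + g, data = dat)
        av <- stats::anova(fit)
        fRow <- "g"
    }
    nu <- fit$df.residual
    cf <- summary(fit)$coefficients
    rows <- grep("^g", rownames(cf))
    treatments <- sub("^g", "", rownames(cf)[rows])
    tstat <- cf[rows, "t value"]
    est <- cf[rows, "Estimate"]
    se <- cf[rows, "Std. Error"]
    ns <- as.integer(sizes[treatments])
    n0 <- as.integer(sizes[control])
    if (is.null(nullDraws))
        nullDraws <- dunnettMaxNull(ns, n0, nu, nMC = nMC, seed = seed)
    padj <- vapply(abs(tstat), function(tt) mean(nullDraws >= tt),
                   numeric(1))
    means <- tapply(values, g, mean)
    structure(list(
        fStatistic = av[fRow, "F value"],
        fPvalue = av[fRow, "Pr(>F)"],
        comparisons = data.frame(group = treatments, estimate = unname(est),
                                 se = unname(se), t = unname(tstat),
                                 p.adj = unname(padj),
                                 stringsAsFactors = FALSE),
        df = nu, groupMeans = means, control = control),
        class = "DunnettResult")
}

#' Brown-Forsythe test of variance homogeneity
#'
#' Levene's test on absolute deviations from group medians (the
#' Brown-Forsythe variant), via `car::leveneTest`. Degenerate inputs with
#' zero spread in every group return P = 1 with a warning.
#'
#' @param values numeric response.
#' @param groups group labels (each group n >= 2).
#' @return list with `statistic` (F), `p.value`, `df`.
#' @export
leveneVarianceTest <- function(values, groups) {
    g <- droplevels(factor(groups))
    if (nlevels(g) < 2L || any(table(g) < 2L))
        stop(">= 2 groups with n >= 2 each are required")
    med <- tapply(values, g, stats::median)
    dev <- abs(values - med[as.integer(g)])
    if (all(dev == 0)) {
        warning("zero spread in all groups; homogeneity test degenerate")
        return(list(statistic = 0, p.value = 1,
                    df = c(nlevels(g) - 1L, length(values) - nlevels(g))))
    }
    lt <- car::leveneTest(values, g, center = stats::median)
    list(statistic = lt[1, "F value"], p.value = lt[1, "Pr(>F)"],
         df = c(lt[1, "Df"], lt[2, "Df"]))
}
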