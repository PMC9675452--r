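## Moderated differential expression on log2(1+TPM) values: a blocked
## cell-means linear model (treatment groups nested in the dichotomized
## collection year), empirical-Bayes variance moderation with an
## expression trend, contrasts of each treatment against its contemporary
## preterm controls, aggregate BH correction, and threshold rules for DEG
## list construction. The linear modeling machinery is limma's.

#' Dichotomize collection year
#'
#' The blocking variable for differential expression: 2018 versus any
#' other collection year.
#'
#' @param year integer vector of collection years.
#' @return factor with levels `other`, `y2018`.
#' @export
dichotomizeYear <- function(year) {
    factor(ifelse(as.integer(year) == 2018L, "y2018", "other"),
           levels = c("other", "y2018"))
}

#' Fit a blocked cell-means linear model per gene
#'
#' Ordinary least squares per gene on the cell-means design with one cell
#' per (treatment group, year block) combination, so treatments are
#' compared with reasonably contemporary controls and residual year
#' effects are absorbed. Returns a fit object consumed by
#' [treatmentContrasts()] and [contrastTest()].
#'
#' @param x a `LOG2P1` [ExpressionMatrix-class].
#' @param samples sample metadata data.frame covering all matrix columns.
#' @return list of class `BlockedFit`: the limma `MArrayLM` fit, the
#'   design, cell/group/block bookkeeping, per-gene residual variance
#'   `s2` and residual df.
#' @export
fitBlockedLinearModel <- function(x, samples) {
    stopifnot(is(x, "ExpressionMatrix"))
    if (exprScale(x) != "LOG2P1")
        stop("differential expression expects log2(1+TPM) values")
    samples <- validateSampleTable(samples)
    st <- samples[match(sampleIds(x), samples$sample_id), , drop = FALSE]
    if (anyNA(st$sample_id))
        stop("sample(s) missing from metadata: ",
             paste(sampleIds(x)[is.na(st$sample_id)], collapse = ", "))
    block <- dichotomizeYear(st$year)
    cells <- interaction(st$group, block, drop = TRUE, sep = ".")
    design <- stats::model.matrix(~ 0 + cells)
    colnames(design) <- levels(cells)
    qrd <- qr(design)
    if (qrd$rank < ncol(design))
        stop("rank-deficient design; aliased cell(s): ",
             paste(colnames(design)[qrd$pivot[-seq_len(qrd$rank)]],
                   collapse = ", "))
    if (ncol(x) - nlevels(cells) < 1L)
        stop("no residual degrees of freedom (", ncol(x), " samples, ",
             nlevels(cells), " design cells)")
    fit <- limma::lmFit(exprValues(x), design)
    structure(list(fit = fit, design = design, cells = cells,
                   group = st$group, block = block,
                   s2 = fit$sigma^2, df = fit$df.residual),
              class = "BlockedFit")
}

#' Contrast matrix of each treatment versus contemporary controls
#'
#' For every treatment group, the contrast averages (treatment cell minus
#' control cell) over the year blocks in which both are observed.
#'
#' @param bfit a `BlockedFit` from [fitBlockedLinearModel()].
#' @param control control group label (default `"PTC"`).
#' @param treatments treatments to contrast; default all non-control
#'   groups present.
#' @return design-cells x contrasts numeric matrix, columns named
#'   `<treatment>_vs_<control>`.
#' @export
treatmentContrasts <- function(bfit, control = "PTC", treatments = NULL) {
    stopifnot(inherits(bfit, "BlockedFit"))
    cellNames <- colnames(bfit$design)
    parts <- strsplit(cellNames, ".", fixed = TRUE)
    cellGroup <- vapply(parts, `[[`, character(1), 1L)
    cellBlock <- vapply(parts, function(p)
        paste(p[-1L], collapse = "."), character(1))
    if (!control %in% cellGroup)
        stop("control group '", control, "' absent from the design")
    if (is.null(treatments))
        treatments <- setdiff(unique(cellGroup), control)
    L <- vapply(treatments, function(tr) {
        if (!tr %in% cellGroup)
            stop("treatment group '", tr, "' absent from the design")
        blocks <- intersect(cellBlock[cellGroup == tr],
                            cellBlock[cellGroup == control])
        if (!length(blocks))
            stop("treatment '", tr,
                 "' shares no year block with the control")
        v <- numeric(length(cellNames))
        for (b in blocks) {
            v[cellGroup == tr & cellBlock == b] <- 1 / length(blocks)
            v[cellGroup == control & cellBlock == b] <-
                v[cellGroup == control & cellBlock == b] - 1 / length(blocks)
        }
        v
    }, numeric(length(cellNames)))
    rownames(L) <- cellNames
    colnames(L) <- paste0(treatments, "_vs_", control)
    L
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Shrinks gene-wise residual variances toward a prior (optionally an
#' expression-dependent trend) estimated from the scaled-F distribution of
#' the observed variances, via limma's `squeezeVar`. The posterior
#' variance is the precision-weighted combination
#' `(d0 s0^2 + d s^2) / (d0 + d)`.
#'
#' @param s2 per-gene residual variances (or a `BlockedFit`).
#' @param df residual degrees of freedom (scalar or per gene).
#' @param covariate optional per-gene mean expression enabling the trended
#'   prior.
#' @param robust winsorize outlier variances during hyperparameter
#'   estimation.
#' @return list of class `ModerationFit`: `s2`, `df`, `d0` (prior df,
#'   possibly `Inf`), `s02` (prior variance, scalar or per gene) and
#'   `s2post`.
#' @export
moderateVariances <- function(s2, df, covariate = NULL, robust = FALSE) {
    if (inherits(s2, "BlockedFit")) {
        covariate <- s2$fit$Amean
        df <- s2$df
        s2 <- s2$s2
    }
    if (all(s2 == 0))
        stop("all residual variances are zero; moderation is degenerate")
    sq <- limma::squeezeVar(s2, df, covariate = covariate, robust = robust)
    structure(list(s2 = s2, df = df, d0 = sq$df.prior,
                   s02 = sq$var.prior, s2post = sq$var.post),
              class = "ModerationFit")
}

#' Posterior variance under empirical-Bayes moderation
#'
#' @param s2 observed per-gene variance.
#' @param df residual df.
#' @param d0 prior df (may be `Inf`).
#' @param s02 prior variance.
#' @return the shrunken variance `(d0 s02 + df s2) / (d0 + df)`.
#' @export
posteriorVar <- function(s2, df, d0, s02) {
    n <- length(s2)
    d0 <- rep_len(d0, n)
    s02 <- rep_len(s02, n)
    df <- rep_len(df, n)
    out <- (d0 * s02 + df * s2) / (d0 + df)
    out[is.infinite(d0)] <- s02[is.infinite(d0)]
    out
}

#' Moderated t-tests for treatment contrasts
#'
#' Applies the contrasts to the blocked fit, moderates variances
#' (expression trend on, robust hyperparameter estimation on, matching
#' standard practice for TPM-scale data) and computes two-sided moderated
#' t P values with `d0 + d` degrees of freedom. BH FDR is computed on the
#' aggregate collection of P values from all contrasts (default) or per
#' contrast.
#'
#' @param bfit a `BlockedFit`.
#' @param contrasts contrast matrix from [treatmentContrasts()] (or any
#'   matrix of in-span contrast vectors over design cells).
#' @param trend,robust passed to limma's `eBayes`.
#' @param fdrScope `"aggregate"` (default) or `"per_contrast"`.
#' @return data.frame of class `ContrastResult`: `gene`, `contrast`,
#'   `log2fc`, `aveExpr`, `t`, `df`, `pvalue`, `fdr`.
#' @export
contrastTest <- function(bfit, contrasts, trend = TRUE, robust = TRUE,
                         fdrScope = c("aggregate", "per_contrast")) {
    stopifnot(inherits(bfit, "BlockedFit"))
    fdrScope <- match.arg(fdrScope)
    contrasts <- as.matrix(contrasts)
    if (nrow(contrasts) != ncol(bfit$design))
        stop("contrast rows must match design cells")
    if (is.null(colnames(contrasts)))
        colnames(contrasts) <- paste0("contrast", seq_len(ncol(contrasts)))
    zero <- colSums(contrasts != 0) == 0L
    eb <- NULL
    if (any(!zero)) {
        cfit <- limma::contrasts.fit(bfit$fit,
                                     contrasts[, !zero, drop = FALSE])
        eb <- limma::eBayes(cfit, trend = trend, robust = robust)
    }
    res <- do.call(rbind, lapply(colnames(contrasts), function(cn) {
        if (zero[cn]) {
            ## a null contrast tests nothing: t = 0, P = 1 per gene
            return(data.frame(gene = rownames(bfit$fit$coefficients),
                              contrast = cn, log2fc = 0,
                              aveExpr = bfit$fit$Amean, t = 0,
                              df = bfit$df,
                              pvalue = 1, stringsAsFactors = FALSE))
        }
        data.frame(gene = rownames(eb$coefficients),
                   contrast = cn,
                   log2fc = eb$coefficients[, cn],
                   aveExpr = eb$Amean,
                   t = eb$t[, cn],
                   df = eb$df.total,
                   pvalue = eb$p.value[, cn],
                   stringsAsFactors = FALSE)
    }))
    rownames(res) <- NULL
    if (fdrScope == "aggregate") {
        res$fdr <- bhAdjust(res$pvalue)
    } else {
        res$fdr <- stats::ave(res$pvalue, res$contrast, FUN = bhAdjust)
    }
    class(res) <- c("ContrastResult", "data.frame")
    res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues numeric vector in (0, 1].
#' @return adjusted values (monotone, never below the raw P).
#' @export
bhAdjust <- function(pvalues) {
    if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
        stop("P values must lie in (0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' Registered DEG threshold rules
#'
#' Named rules mirroring the analyses: `gsea` (raw P <= 0.05 and |log2FC|
#' >= log2(1.25), boundary inclusive) feeding enrichment; `rmm_lung`
#' (FDR <= 0.05, |log2FC| >= 1) and `rmm_amniotic_fluid` (FDR <= 0.05,
#' |log2FC| >= log2(1.5)) selecting maturity-model genes;
#' `hippocampus_down_picks` (log2FC < -0.4, raw P < 0.05, strict,
#' down only) and `lung_up_picks` (fold > 1.5, raw P < 0.05, strict,
#' up only) for individual gene display.
#'
#' @return named list of rule definitions.
#' @export
degRules <- function() {
    list(
        gsea = list(pType = "raw", pMax = 0.05, lfcMin = log2(1.25),
                    direction = "both", inclusive = TRUE),
        rmm_lung = list(pType = "fdr", pMax = 0.05, lfcMin = 1,
                        direction = "both", inclusive = TRUE),
        rmm_amniotic_fluid = list(pType = "fdr", pMax = 0.05,
                                  lfcMin = log2(1.5),
                                  direction = "both", inclusive = TRUE),
        hippocampus_down_picks = list(pType = "raw", pMax = 0.05,
                                      lfcMin = 0.4, direction = "down",
                                      inclusive = FALSE),
        lung_up_picks = list(pType = "raw", pMax = 0.05,
                             lfcMin = log2(1.5), direction = "up",
                             inclusive = FALSE))
}

#' Select differentially expressed genes by a threshold rule
#'
#' Deterministically partitions a contrast result into up- and
#' down-regulated lists by a named rule (see [degRules()]) or an explicit
#' rule list with fields `pType` (`"raw"`/`"fdr"`), `pMax`, `lfcMin`
#' (absolute log2FC floor), `direction` and `inclusive` (`>=`/`<=` versus
#' strict comparison).
#'
#' @param results a `ContrastResult` data.frame (one contrast).
#' @param rule rule name or definition list.
#' @return list of class `DegSelection` with `up`, `down` gene vectors,
#'   `counts` and the rule used. Convert non-empty lists to a
#'   [GeneSetCollection-class] with [degGeneSets()].
#' @export
selectDegs <- function(results, rule = "gsea") {
    if (is.character(rule)) {
        reg <- degRules()
        if (!rule %in% names(reg))
            stop("unknown rule '", rule, "'; registered rules: ",
                 paste(names(reg), collapse = ", "))
        rule <- reg[[rule]]
    }
    p <- if (identical(rule$pType, "fdr")) results$fdr else results$pvalue
    cmpP <- if (isTRUE(rule$inclusive)) `<=` else `<`
    cmpL <- if (isTRUE(rule$inclusive)) `>=` else `>`
    pass <- cmpP(p, rule$pMax) & cmpL(abs(results$log2fc), rule$lfcMin)
    up <- results$gene[pass & results$log2fc > 0]
    down <- results$gene[pass & results$log2fc < 0]
    if (identical(rule$direction, "up")) down <- character()
    if (identical(rule$direction, "down")) up <- character()
    structure(list(up = up, down = down,
                   counts = c(up = length(up), down = length(down)),
                   rule = rule),
              class = "DegSelection")
}

#' @rdname selectDegs
#' @param sel a `DegSelection`.
#' @param prefix set-name prefix (e.g. the contrast name).
#' @export
degGeneSets <- function(sel, prefix = "deg") {
    stopifnot(inherits(sel, "DegSelection"))
    sets <- list()
    if (length(sel$up)) sets[[paste0(prefix, "_up")]] <- sel$up
    if (length(sel$down)) sets[[paste0(prefix, "_down")]] <- sel$down
    GeneSetCollection(sets)
}
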