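## Preprocessing: log2(1+TPM) transform, mean-expression filtering, purge of
## genes with reproducible sex-linked profiles (two-year consistency rule),
## and removal of systematic batch noise from the residual space while
## preserving the treatment factor exactly.

#' Log2(1 + TPM) transform
#'
#' @param x a TPM-scale [ExpressionMatrix-class]. Applying the transform to
#'   an already log-scale matrix is an error (no double transforms).
#' @return the matrix on `LOG2P1` scale.
#' @export
log2p1Transform <- function(x) {
    stopifnot(is(x, "ExpressionMatrix"))
    if (exprScale(x) != "TPM")
        stop("matrix is already on the log2(1+TPM) scale")
    out <- x
    assay(out, "expr") <- log2(1 + exprValues(x))
    out@exprScale <- "LOG2P1"
    validObject(out)
    out
}

.log2p1Values <- function(x) {
    if (exprScale(x) == "TPM") log2(1 + exprValues(x)) else exprValues(x)
}

#' Filter genes by mean log-scale expression
#'
#' Retains genes whose mean `log2(1 + TPM)` across samples is at or above
#' the threshold (boundary inclusive). The filter is idempotent and
#' preserves gene order.
#'
#' @param x an [ExpressionMatrix-class] (either scale; the mean is always
#'   computed on the log scale).
#' @param threshold minimum mean log2(1+TPM), default 1.0.
#' @return the filtered matrix on its original scale.
#' @export
filterLowExpression <- function(x, threshold = 1.0) {
    stopifnot(is(x, "ExpressionMatrix"))
    keep <- rowMeans(.log2p1Values(x)) >= threshold
    if (!any(keep))
        stop("threshold ", threshold, " removes every gene")
    x[keep, ]
}

#' Identify genes with reproducible sex-linked expression
#'
#' For each tissue, lowly expressed genes (mean log2(1+TPM) at or below
#' `prefilterMean`) are set aside, preterm controls are excluded (their
#' male/female representation is inadequate by design), and the remaining
#' samples are split by collection year. Within each tissue-year stratum a
#' moderated linear model `expression ~ treatment group + sex` (limma)
#' estimates the female-minus-male coefficient. A gene is a candidate in a
#' tissue when the sex coefficient keeps its sign with raw P <=
#' `pMax` in both years, and is kept for removal when both yearly
#' coefficients are >= `lfcUp` or both <= `lfcDown` (the asymmetric
#' refinement thresholds). The final removal list is the union over
#' tissues (or the genes recurring in >= 2 tissues with
#' `combine = "atLeast2"`).
#'
#' @param exprsByTissue named list of per-tissue [ExpressionMatrix-class]
#'   objects (TPM or LOG2P1).
#' @param samples sample metadata data.frame.
#' @param pMax per-year raw P ceiling (default 0.05).
#' @param lfcUp,lfcDown asymmetric log2FC refinement thresholds on the
#'   female-minus-male axis (defaults +0.25 and -0.15).
#' @param prefilterMean mean log2(1+TPM) at or below which genes are not
#'   considered (default 0.1).
#' @param excludeGroups treatment groups dropped before fitting
#'   (default `"PTC"`).
#' @param minPerSex minimum samples per sex for a tissue-year stratum to be
#'   usable (default 2; unusable strata are skipped with a warning).
#' @param combine `"union"` (default) or `"atLeast2"` across tissues.
#' @param denyList optional genes never removed (externally curated).
#' @return list of class `SexPurgeResult`: `removed` (final gene list),
#'   `candidates` (per tissue/gene yearly coefficients and P values) and
#'   `rationale` (per removed gene, supporting tissues and direction).
#' @export
identifySexLinkedGenes <- function(exprsByTissue, samples, pMax = 0.05,
                                   lfcUp = 0.25, lfcDown = -0.15,
                                   prefilterMean = 0.1,
                                   excludeGroups = "PTC",
                                   minPerSex = 2L,
                                   combine = c("union", "atLeast2"),
                                   denyList = NULL) {
    combine <- match.arg(combine)
    samples <- validateSampleTable(samples)
    candAll <- list()
    for (tis in names(exprsByTissue)) {
        x <- exprsByTissue[[tis]]
        stopifnot(is(x, "ExpressionMatrix"))
        logv <- .log2p1Values(x)
        logv <- logv[rowMeans(logv) > prefilterMean, , drop = FALSE]
        st <- samples[match(colnames(logv), samples$sample_id), , drop = FALSE]
        keep <- !is.na(st$sample_id) & !(st$group %in% excludeGroups)
        logv <- logv[, keep, drop = FALSE]
        st <- st[keep, , drop = FALSE]
        years <- sort(unique(st$year))
        fits <- list()
        for (yr in years) {
            sel <- st$year == yr
            sexTab <- table(st$sex[sel])
            if (length(sexTab) < 2L || any(sexTab < minPerSex)) {
                warning(sprintf("tissue %s year %s: fewer than %d samples per sex; stratum skipped",
                                tis, yr, minPerSex))
                next
            }
            grpF <- droplevels(factor(st$group[sel]))
            sexF <- factor(st$sex[sel], levels = c("M", "F"))
            design <- if (nlevels(grpF) > 1L)
                stats::model.matrix(~ grpF + sexF)
            else stats::model.matrix(~ sexF)
            fit <- limma::eBayes(limma::lmFit(logv[, sel, drop = FALSE],
                                              design))
            fits[[as.character(yr)]] <-
                data.frame(gene = rownames(logv),
                           coef = fit$coefficients[, "sexFF"],
                           p = fit$p.value[, "sexFF"],
                           stringsAsFactors = FALSE)
        }
        if (length(fits) < 2L) {
            warning(sprintf("tissue %s: fewer than 2 usable years; excluded from candidacy", tis))
            next
        }
        yrs <- names(fits)[1:2]
        a <- fits[[yrs[1]]]; b <- fits[[yrs[2]]]
        tab <- data.frame(tissue = tis, gene = a$gene,
                          coef1 = a$coef, p1 = a$p,
                          coef2 = b$coef[match(a$gene, b$gene)],
                          p2 = b$p[match(a$gene, b$gene)],
                          stringsAsFactors = FALSE)
        tab$candidate <- sign(tab$coef1) == sign(tab$coef2) &
            tab$p1 <= pMax & tab$p2 <= pMax
        tab$kept <- tab$candidate &
            ((tab$coef1 >= lfcUp & tab$coef2 >= lfcUp) |
             (tab$coef1 <= lfcDown & tab$coef2 <= lfcDown))
        candAll[[tis]] <- tab
    }
    cand <- do.call(rbind, candAll)
    if (is.null(cand))
        stop("no tissue had two usable years of both-sex samples")
    rownames(cand) <- NULL
    keptTab <- cand[cand$kept, , drop = FALSE]
    counts <- table(keptTab$gene)
    removed <- if (combine == "union") names(counts)
               else names(counts)[counts >= 2L]
    removed <- setdiff(removed, denyList)
    rationale <- do.call(rbind, lapply(removed, function(g) {
        rows <- keptTab[keptTab$gene == g, , drop = FALSE]
        data.frame(gene = g,
                   tissues = paste(rows$tissue, collapse = ";"),
                   direction = if (all(rows$coef1 > 0)) "female_up"
                               else if (all(rows$coef1 < 0)) "female_down"
                               else "mixed",
                   stringsAsFactors = FALSE)
    }))
    structure(list(removed = sort(removed),
                   candidates = cand,
                   rationale = rationale,
                   params = list(pMax = pMax, lfcUp = lfcUp,
                                 lfcDown = lfcDown,
                                 prefilterMean = prefilterMean,
                                 combine = combine)),
              class = "SexPurgeResult")
}

#' Drop genes from an expression matrix
#'
#' Removes the listed genes (list members absent from the matrix are
#' ignored with a warning) and records the removed count and the fraction
#' of the gene universe in the result's metadata.
#'
#' @param x an [ExpressionMatrix-class].
#' @param genes character vector of gene ids to drop.
#' @return the reduced matrix; `metadata(x)$geneDrop` holds `nDropped`,
#'   `nUniverse`, `fraction` and `pctLabel` (percentage to 2 decimals).
#' @export
dropGenes <- function(x, genes) {
    stopifnot(is(x, "ExpressionMatrix"))
    genes <- unique(as.character(genes))
    absent <- setdiff(genes, geneIds(x))
    if (length(absent))
        warning("gene(s) not in matrix, ignored: ",
                paste(absent, collapse = ", "))
    hit <- intersect(genes, geneIds(x))
    if (length(hit) == nrow(x))
        stop("removal would empty the expression matrix")
    nUniverse <- nrow(x)
    out <- x[!geneIds(x) %in% hit, ]
    metadata(out)$geneDrop <- list(
        nDropped = length(hit), nUniverse = nUniverse,
        fraction = length(hit) / nUniverse,
        pctLabel = sprintf("%.2f", 100 * length(hit) / nUniverse))
    out
}

#' ASCA-style batch correction preserving the treatment factor
#'
#' Decomposes the log-scale matrix as X = G + E, where G carries the
#' per-treatment-group gene means, runs PCA (SVD) on the residual matrix E
#' and removes the leading residual components whose variance exceeds
#' `gamma` times the average residual-component variance — systematic
#' structure (collection-year batches, handling effects) that survives in
#' the residual space after the design factor is accounted for. The
#' corrected residual is re-centered within treatment groups so group
#' centroids are preserved exactly, and total residual variance never
#' increases.
#'
#' @param x a `LOG2P1` [ExpressionMatrix-class].
#' @param samples sample metadata data.frame, or a vector of group labels
#'   parallel to the matrix columns.
#' @param gamma variance multiplier gating component removal (default 2;
#'   must be > 1).
#' @param maxComponents cap on removed components (default 5).
#' @return the corrected matrix; `metadata(x)$asca` records the number of
#'   removed components and the residual variance fraction removed.
#' @export
ascaBatchCorrect <- function(x, samples, gamma = 2, maxComponents = 5L) {
    stopifnot(is(x, "ExpressionMatrix"))
    if (exprScale(x) != "LOG2P1")
        stop("batch correction expects log2(1+TPM) values")
    if (gamma <= 1)
        stop("gamma must be > 1")
    if (is.data.frame(samples)) {
        samples <- validateSampleTable(samples)
        grp <- samples$group[match(sampleIds(x), samples$sample_id)]
        if (anyNA(grp))
            stop("sample(s) missing from metadata: ",
                 paste(sampleIds(x)[is.na(grp)], collapse = ", "))
    } else {
        grp <- as.character(samples)
        if (length(grp) != ncol(x))
            stop("group labels must parallel matrix columns")
    }
    X <- exprValues(x)
    f <- factor(grp)
    sizes <- table(f)
    if (any(sizes < 2L))
        warning("group(s) with a single sample contribute no residual df: ",
                paste(names(sizes)[sizes < 2L], collapse = ", "))
    centroid <- function(M) {
        gm <- vapply(levels(f), function(l)
            rowMeans(M[, f == l, drop = FALSE]), numeric(nrow(M)))
        gm[, as.integer(f), drop = FALSE]
    }
    G <- centroid(X)
    E <- X - G
    q <- min(nrow(E), ncol(E) - nlevels(f))
    if (q < 1L)
        stop("no residual degrees of freedom for batch estimation")
    sv <- svd(E)
    vars <- sv$d^2
    avg <- mean(vars[seq_len(q)])
    nRemove <- 0L
    while (nRemove < min(maxComponents, q) &&
           vars[nRemove + 1L] > gamma * avg)
        nRemove <- nRemove + 1L
    Etil <- E
    if (nRemove > 0L) {
        rm1 <- sv$u[, seq_len(nRemove), drop = FALSE] %*%
            (sv$d[seq_len(nRemove)] * t(sv$v[, seq_len(nRemove), drop = FALSE]))
        Etil <- E - rm1
        Etil <- Etil - centroid(Etil)  # conserve treatment centroids exactly
    }
    corrected <- G + Etil
    dimnames(corrected) <- dimnames(X)
    out <- x
    assay(out, "expr") <- corrected
    metadata(out)$asca <- list(
        nRemoved = nRemove,
        residualVarianceRemoved =
            if (sum(vars) > 0) 1 - sum(Etil^2) / sum(vars) else 0,
        gamma = gamma)
    out
}
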