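## Enrichment statistics: Fisher exact overrepresentation with a
## normal-approximation Z score (the Z > 2 plus FDR-corrected P < 0.05
## display criterion), and preranked GSEA (weighted Kolmogorov-Smirnov
## running-sum enrichment score with a gene-permutation null and
## normalized enrichment scores), applied to DEG and correlation-derived
## gene lists.

#' Fisher exact + Z-score overrepresentation test
#'
#' For each gene set (intersected with the universe; sets with fewer than
#' `minSetSize` universe genes are skipped), computes the overlap `r`
#' with the query list of size `n`, set size `R`, universe size `N`, the
#' two-sided Fisher exact P, the hypergeometric Z score
#' `(r - nR/N) / sqrt(nR/N (1 - R/N)(1 - (n-1)/(N-1)))` and BH FDR across
#' tested sets. The fully saturated table (query = set = universe) is
#' degenerate: Z is undefined and P = 1.
#'
#' @param query character vector of query genes (subset of universe).
#' @param sets a [GeneSetCollection-class] or named list.
#' @param universe character vector of all assayed genes.
#' @param minSetSize minimum in-universe set size (default 3).
#' @return data.frame: set, overlap `r`, `n`, `R`, `N`, `pvalue`, `z`,
#'   `fdr`, `genes` (comma-separated overlap).
#' @export
fisherZEnrich <- function(query, sets, universe, minSetSize = 3L) {
    sets <- if (is(sets, "GeneSetCollection")) geneSets(sets) else sets
    universe <- unique(universe)
    query <- unique(query)
    if (!length(universe) || !length(query))
        stop("query and universe must be non-empty")
    bad <- setdiff(query, universe)
    if (length(bad))
        stop("query gene(s) outside the universe: ",
             paste(utils::head(bad, 5L), collapse = ", "))
    N <- length(universe)
    n <- length(query)
    rows <- lapply(names(sets), function(nm) {
        set <- intersect(sets[[nm]], universe)
        R <- length(set)
        if (R < minSetSize) return(NULL)
        ov <- intersect(query, set)
        r <- length(ov)
        denom <- n * (R / N) * (1 - R / N) * (1 - (n - 1) / (N - 1))
        z <- if (denom > 0) (r - n * R / N) / sqrt(denom) else NA_real_
        p <- if (R == N || n == N) 1
             else stats::fisher.test(matrix(c(r, n - r, R - r,
                                              N - n - R + r), 2L))$p.value
        data.frame(set = nm, r = r, n = n, R = R, N = N,
                   pvalue = p, z = z,
                   genes = paste(ov, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows))
        stop("no gene set passes the minimum size after universe intersection")
    rows$fdr <- stats::p.adjust(rows$pvalue, method = "BH")
    rows[order(rows$pvalue), ]
}

#' Build a preranked gene vector from a contrast result
#'
#' Mode `"t"` sorts by the moderated t statistic in decreasing order;
#' mode `"signed_p"` by `sign(log2FC) * (-log10 P)`. Ties are broken by
#' gene id (lexicographic) so the ranking is deterministic.
#'
#' @param results a `ContrastResult` data.frame (one contrast).
#' @param mode `"t"` (default) or `"signed_p"`.
#' @return named numeric vector, decreasing.
#' @export
buildRanking <- function(results, mode = c("t", "signed_p")) {
    mode <- match.arg(mode)
    stat <- switch(mode,
        t = results$t,
        signed_p = sign(results$log2fc) * (-log10(results$pvalue)))
    if (any(!is.finite(stat)))
        stop("non-finite ranking statistic for gene(s): ",
             paste(utils::head(results$gene[!is.finite(stat)], 5L),
                   collapse = ", "))
    if (anyDuplicated(results$gene))
        stop("duplicate genes in the contrast result")
    ord <- order(-stat, results$gene)
    stats::setNames(stat[ord], results$gene[ord])
}

#' Top up/down signature sets from a contrast
#'
#' Truncates a contrast to its `topN` most up- and downregulated genes
#' (by moderated t) for use as GSEA query signatures when comparing
#' conditions.
#'
#' @param results a `ContrastResult` data.frame (one contrast).
#' @param topN genes per direction (default 500).
#' @param prefix set-name prefix.
#' @return a [GeneSetCollection-class] with `<prefix>_up` and
#'   `<prefix>_down` sets.
#' @export
topContrastSignature <- function(results, topN = 500L, prefix = "sig") {
    rk <- buildRanking(results, "t")
    up <- names(rk)[rk > 0]
    down <- rev(names(rk)[rk < 0])
    sets <- list()
    if (length(up)) sets[[paste0(prefix, "_up")]] <- utils::head(up, topN)
    if (length(down))
        sets[[paste0(prefix, "_down")]] <- utils::head(down, topN)
    GeneSetCollection(sets)
}

#' Preranked GSEA with a gene-permutation null
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score (weight
#' `|stat|^gseaParam`, default exponent 1) with a seeded gene-permutation
#' null, normalized enrichment score (ES divided by the mean |ES| of
#' same-sign permutations) and smoothed permutation P values, via fgsea's
#' fixed-permutation mode. Sets are intersected with the ranking; those
#' below `minSize` are skipped.
#'
#' @param ranking named decreasing statistic vector from
#'   [buildRanking()] (no duplicated genes).
#' @param sets a [GeneSetCollection-class] or named list.
#' @param nperm permutations (default 10000; < 100 is an error).
#' @param seed RNG seed.
#' @param minSize minimum intersected set size (default 3; use 15 for the
#'   classic convention).
#' @param gseaParam enrichment weight exponent (default 1).
#' @param fdrThreshold significance flag threshold on the BH-adjusted
#'   permutation P (default 0.1).
#' @return data.frame: set, size, `es`, `nes`, `pvalue`, `fdr`,
#'   `significant`, `leadingEdge` (comma-separated).
#' @export
gseaPreranked <- function(ranking, sets, nperm = 10000L, seed = 1L,
                          minSize = 3L, gseaParam = 1,
                          fdrThreshold = 0.1) {
    if (nperm < 100L)
        stop("nperm must be >= 100")
    if (anyDuplicated(names(ranking)))
        stop("ranking contains duplicated genes")
    sets <- if (is(sets, "GeneSetCollection")) geneSets(sets) else sets
    disjoint <- names(sets)[vapply(sets, function(s)
        !any(s %in% names(ranking)), logical(1))]
    if (length(disjoint))
        warning("set(s) disjoint from the ranking skipped: ",
                paste(disjoint, collapse = ", "))
    set.seed(seed)
    res <- suppressWarnings(fgsea::fgseaSimple(
        pathways = sets, stats = ranking, nperm = nperm,
        minSize = minSize, maxSize = length(ranking) - 1L,
        gseaParam = gseaParam, nproc = 0))
    out <- data.frame(set = res$pathway, size = res$size,
                      es = res$ES, nes = res$NES, pvalue = res$pval,
                      stringsAsFactors = FALSE)
    out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
    out$significant <- out$fdr < fdrThreshold
    out$leadingEdge <- vapply(res$leadingEdge, paste, character(1),
                              collapse = ",")
    out[order(out$pvalue), ]
}

#' Running-sum enrichment score for one gene set
#'
#' The deterministic core of preranked GSEA: with genes ordered by
#' decreasing statistic, hits advance the running sum by
#' `|stat|^gseaParam` (normalized over the set) and misses retreat by
#' `1/(N - |S|)`; the ES is the extremum of largest magnitude.
#'
#' @param ranking named decreasing statistic vector.
#' @param set character vector of member genes.
#' @param gseaParam weight exponent (default 1).
#' @return the enrichment score in `[-1, 1]`.
#' @export
enrichmentScore <- function(ranking, set, gseaParam = 1) {
    hits <- names(ranking) %in% set
    if (!any(hits))
        stop("set is disjoint from the ranking")
    fgsea::calcGseaStat(ranking, selectedStats = which(hits),
                        gseaParam = gseaParam)
}
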