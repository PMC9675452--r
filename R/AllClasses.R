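#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays colData rowData
NULL

.EXPR_SCALES <- c("TPM", "LOG2P1")
.TISSUES <- c("lung", "hippocampus", "amniotic_fluid")
.GROUPS <- c("PTC", "B060", "B125", "C1x", "C2x", "POB", "POD", "Term")

#' ExpressionMatrix: genes-by-samples expression with a scale tag
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single dense `expr` assay (rows = genes, columns = samples) plus a scale
#' tag recording whether values are raw TPM or `log2(1 + TPM)`. All
#' downstream stages (filtering, batch correction, differential expression,
#' maturity scoring, deconvolution) consume this class, and the scale tag
#' prevents accidental double log transforms.
#'
#' @slot exprScale character scalar, one of `"TPM"` or `"LOG2P1"`.
#' @export
setClass("ExpressionMatrix",
    contains = "SummarizedExperiment",
    slots = c(exprScale = "character"))

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    if (length(object@exprScale) != 1L || !object@exprScale %in% .EXPR_SCALES)
        msg <- c(msg, sprintf("exprScale must be one of %s",
                              paste(.EXPR_SCALES, collapse = ", ")))
    if (!"expr" %in% names(assays(object)))
        msg <- c(msg, "an assay named 'expr' is required")
    else {
        m <- assay(object, "expr")
        if (!is.numeric(m))
            msg <- c(msg, "expr assay must be numeric")
        if ((nrow(m) > 0L && is.null(rownames(m))) ||
            (ncol(m) > 0L && is.null(colnames(m))))
            msg <- c(msg, "expr assay must carry gene (row) and sample (column) names")
        else {
            if (anyDuplicated(rownames(m)))
                msg <- c(msg, sprintf("duplicated gene ids: %s",
                    paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
            if (anyDuplicated(colnames(m)))
                msg <- c(msg, sprintf("duplicated sample ids: %s",
                    paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
        }
        if (is.numeric(m) && !all(is.finite(m)))
            msg <- c(msg, "all expression values must be finite")
        if (is.numeric(m) && identical(object@exprScale, "TPM") &&
            any(m < 0, na.rm = TRUE))
            msg <- c(msg, "TPM-scale values must be nonnegative")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param scale `"TPM"` for raw transcripts-per-million or `"LOG2P1"` for
#'   `log2(1 + TPM)` values.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample metadata
#'   (one row per column of `values`), stored as `colData`.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'     dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- ExpressionMatrix(m, "TPM")
#' exprScale(em)
#' @export
ExpressionMatrix <- function(values, scale = c("TPM", "LOG2P1"),
                             sampleData = NULL) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(sampleData)) {
        se <- SummarizedExperiment(assays = list(expr = values))
    } else {
        se <- SummarizedExperiment(assays = list(expr = values),
                                   colData = DataFrame(sampleData))
    }
    new("ExpressionMatrix", se, exprScale = scale)
}

#' GeneSetCollection: named sets of gene identifiers
#'
#' Container for GMT-style gene set collections (GO/KEGG pathways, marker
#' gene sets, DEG lists). Member lists are stored deduplicated; set names
#' are unique.
#'
#' @slot sets named list of character vectors of gene ids.
#' @slot descriptions character vector parallel to `sets`.
#' @export
setClass("GeneSetCollection",
    slots = c(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || any(names(object@sets) == ""))
            msg <- c(msg, "every gene set must be named")
        else if (anyDuplicated(names(object@sets)))
            msg <- c(msg, sprintf("duplicated set names: %s",
                paste(unique(names(object@sets)[duplicated(names(object@sets))]),
                      collapse = ", ")))
        if (!all(vapply(object@sets, is.character, logical(1))))
            msg <- c(msg, "sets must be character vectors")
        if (any(lengths(object@sets) == 0L))
            msg <- c(msg, "empty gene sets are not allowed")
        if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0L))
            msg <- c(msg, "gene sets must be deduplicated")
    }
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "descriptions must parallel sets")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors; members are deduplicated.
#' @param descriptions optional character vector of per-set descriptions.
#' @return a [GeneSetCollection-class] object.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(x) unique(as.character(x)))
    if (is.null(descriptions))
        descriptions <- rep("", length(sets))
    new("GeneSetCollection", sets = sets,
        descriptions = as.character(descriptions))
}

#' MaturityModel: an oriented PC1 projection of organ maturation
#'
#' Fitted on preterm-control and term-control training samples restricted to
#' term-vs-preterm differential genes: per-gene training center and scale,
#' unit-norm first-principal-component loadings oriented so term training
#' scores exceed preterm ones, and the fraction of training variance the
#' component explains. The model is portable across tissues: any expression
#' matrix sharing most of the gene list can be scored.
#'
#' @slot sourceTissue character, tissue the model was trained on.
#' @slot genes character vector of retained model genes.
#' @slot center,scale numeric named vectors of per-gene training mean and SD.
#' @slot loadings numeric named vector, oriented unit-norm PC1 loadings.
#' @slot varExplained numeric, proportion of training variance on PC1.
#' @slot training list with training sample ids, group labels and scores.
#' @export
setClass("MaturityModel",
    slots = c(sourceTissue = "character", genes = "character",
              center = "numeric", scale = "numeric", loadings = "numeric",
              varExplained = "numeric", training = "list"))

setValidity("MaturityModel", function(object) {
    msg <- character()
    n <- length(object@genes)
    if (length(object@center) != n || length(object@scale) != n ||
        length(object@loadings) != n)
        msg <- c(msg, "center, scale and loadings must parallel genes")
    if (any(object@scale <= 0))
        msg <- c(msg, "per-gene training SD must be > 0")
    if (n > 0 && abs(sqrt(sum(object@loadings^2)) - 1) > 1e-6)
        msg <- c(msg, "loadings must be unit norm")
    if (length(msg)) msg else TRUE
})

#' SignatureMatrix: population marker weights for deconvolution
#'
#' @slot weights numeric matrix, genes x populations.
#' @slot markers named list of per-population marker gene vectors; each
#'   marker gene belongs to exactly one population.
#' @slot mode `"correlation"` (marker-indicator correlations, zero outside
#'   the owning population) or `"centroid"` (dense expression centroids).
#' @slot valueScale scale of centroid entries (`"TPM"`) or `"correlation"`.
#' @export
setClass("SignatureMatrix",
    slots = c(weights = "matrix", markers = "list", mode = "character",
              valueScale = "character"))

setValidity("SignatureMatrix", function(object) {
    msg <- character()
    w <- object@weights
    if (is.null(rownames(w)) || is.null(colnames(w)))
        msg <- c(msg, "weights must carry gene and population names")
    if (!identical(sort(names(object@markers)), sort(colnames(w))))
        msg <- c(msg, "marker list must be named by population")
    allm <- unlist(object@markers, use.names = FALSE)
    if (anyDuplicated(allm))
        msg <- c(msg, "each marker gene must belong to exactly one population")
    if (!length(object@mode) == 1L ||
        !object@mode %in% c("correlation", "centroid"))
        msg <- c(msg, "mode must be 'correlation' or 'centroid'")
    if (any(w < 0))
        msg <- c(msg, "signature weights must be nonnegative")
    if (identical(object@mode, "correlation")) {
        for (p in colnames(w)) {
            nz <- rownames(w)[w[, p] != 0]
            if (!all(nz %in% object@markers[[p]])) {
                msg <- c(msg, "correlation mode: nonzero entries only at owning population cells")
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' DeconvResult: per-sample population proportions
#'
#' @slot proportions numeric matrix, samples x populations; rows on the
#'   probability simplex (nonnegative, summing to one within 1e-8).
#' @slot residuals numeric vector of per-sample residual norms.
#' @export
setClass("DeconvResult",
    slots = c(proportions = "matrix", residuals = "numeric"))

setValidity("DeconvResult", function(object) {
    msg <- character()
    p <- object@proportions
    if (any(p < -1e-10))
        msg <- c(msg, "proportions must be nonnegative")
    if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-8))
        msg <- c(msg, "proportion rows must sum to 1 within 1e-8")
    if (length(object@residuals) != nrow(p))
        msg <- c(msg, "one residual norm per sample required")
    if (length(msg)) msg else TRUE
})

#' MarkerZScores: reference-standardized marker-set scores
#'
#' Per (sample, marker set) mean of gene-level Z scores where each gene is
#' centered and scaled by its mean and SD in a reference treatment group
#' (typically the preterm controls).
#'
#' @slot scores numeric matrix, samples x marker sets.
#' @slot referenceGroup character, the standardizing group label.
#' @slot refMeans,refSds numeric named vectors of reference statistics.
#' @slot dropped character vector of genes dropped for zero reference SD.
#' @export
setClass("MarkerZScores",
    slots = c(scores = "matrix", referenceGroup = "character",
              refMeans = "numeric", refSds = "numeric", dropped = "character"))

## ---- show methods -----------------------------------------------------

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]\n",
                nrow(object), ncol(object), object@exprScale))
    if (ncol(colData(object)))
        cat("  colData:", paste(colnames(colData(object)), collapse = ", "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection with %d sets", length(object@sets)))
    if (length(object@sets)) {
        sz <- lengths(object@sets)
        cat(sprintf(" (sizes %d-%d)", min(sz), max(sz)))
    }
    cat("\n")
})

setMethod("show", "MaturityModel", function(object) {
    cat(sprintf("MaturityModel (%s): %d genes, PC1 explains %.1f%% of training variance\n",
                object@sourceTissue, length(object@genes),
                100 * object@varExplained))
})

setMethod("show", "SignatureMatrix", function(object) {
    cat(sprintf("SignatureMatrix [%s]: %d genes x %d populations\n",
                object@mode, nrow(object@weights), ncol(object@weights)))
})

setMethod("show", "DeconvResult", function(object) {
    cat(sprintf("DeconvResult: %d samples x %d populations (median residual %.3g)\n",
                nrow(object@proportions), ncol(object@proportions),
                stats::median(object@residuals)))
})

setMethod("show", "MarkerZScores", function(object) {
    cat(sprintf("MarkerZScores: %d samples x %d sets (reference %s)\n",
                nrow(object@scores), ncol(object@scores),
                object@referenceGroup))
})
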