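#' Accessors for amnioseq S4 classes
#'
#' `exprValues()` returns the dense genes-by-samples matrix, `exprScale()`
#' the scale tag, `geneIds()`/`sampleIds()` the identifier vectors,
#' `geneSets()` the member lists of a collection, `mixProportions()` the
#' simplex rows of a deconvolution result and `modelGenes()`/`modelLoadings()`
#' the gene list and oriented loadings of a maturity model.
#'
#' @param x an amnioseq object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x, "expr"))

#' @rdname accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname accessors
#' @export
setMethod("exprScale", "ExpressionMatrix", function(x) x@exprScale)

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname accessors
#' @export
setMethod("setDescriptions", "GeneSetCollection",
    function(x) stats::setNames(x@descriptions, names(x@sets)))

#' @rdname accessors
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname accessors
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @rdname accessors
#' @export
setGeneric("mixProportions", function(x) standardGeneric("mixProportions"))

#' @rdname accessors
#' @export
setMethod("mixProportions", "DeconvResult", function(x) x@proportions)

#' @rdname accessors
#' @export
setGeneric("residualNorms", function(x) standardGeneric("residualNorms"))

#' @rdname accessors
#' @export
setMethod("residualNorms", "DeconvResult", function(x) x@residuals)

#' @rdname accessors
#' @export
setGeneric("modelGenes", function(x) standardGeneric("modelGenes"))

#' @rdname accessors
#' @export
setMethod("modelGenes", "MaturityModel", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("modelLoadings", function(x) standardGeneric("modelLoadings"))

#' @rdname accessors
#' @export
setMethod("modelLoadings", "MaturityModel",
    function(x) stats::setNames(x@loadings, x@genes))

#' @rdname accessors
#' @export
setGeneric("signatureWeights", function(x) standardGeneric("signatureWeights"))

#' @rdname accessors
#' @export
setMethod("signatureWeights", "SignatureMatrix", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("signatureMarkers", function(x) standardGeneric("signatureMarkers"))

#' @rdname accessors
#' @export
setMethod("signatureMarkers", "SignatureMatrix", function(x) x@markers)

#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))

#' @rdname accessors
#' @export
setMethod("zScores", "MarkerZScores", function(x) x@scores)
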