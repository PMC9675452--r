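## Readers and writers for the plain-text formats shared by every stage:
## TSV expression matrices, CSV sample tables, GMT gene sets and JSON model
## serializations. The TSV dialect is UTF-8, tab-delimited, unquoted and
## dense (no missing-value markers inside expression matrices).

.SAMPLE_COLS <- c("sample_id", "animal_id", "tissue", "group", "year",
                  "sex", "pv40")

#' Read a genes-by-samples expression TSV
#'
#' Expects a header row of sample ids with the first column holding gene
#' ids. Cells must be dense numeric; duplicated identifiers, non-numeric
#' cells and negative TPM values raise errors naming the offender.
#'
#' @param path file path.
#' @param scale `"TPM"` or `"LOG2P1"`, recorded on the returned object.
#' @return an [ExpressionMatrix-class]; row/column order is preserved.
#' @export
readExpressionTsv <- function(path, scale = c("TPM", "LOG2P1")) {
    scale <- match.arg(scale)
    if (!file.exists(path))
        stop("file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             quote = "")
    if (ncol(tab) < 2L)
        stop("expression TSV needs a gene-id column plus >= 1 sample column: ",
             path)
    genes <- tab[[1L]]
    if (anyDuplicated(genes))
        stop("duplicated gene id(s) in ", path, ": ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    samples <- colnames(tab)[-1L]
    if (anyDuplicated(samples))
        stop("duplicated sample id(s) in ", path, ": ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    vals <- vapply(seq_along(samples), function(j) {
        col <- tab[[j + 1L]]
        v <- suppressWarnings(as.numeric(col))
        if (anyNA(v)) {
            bad <- which(is.na(v))[1L]
            stop("non-numeric cell at gene '", genes[bad], "', sample '",
                 samples[j], "' in ", path)
        }
        v
    }, numeric(nrow(tab)))
    vals <- matrix(vals, nrow = nrow(tab),
                   dimnames = list(genes, samples))
    if (scale == "TPM" && any(vals < 0)) {
        bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
        stop("negative TPM at gene '", genes[bad[1L]], "', sample '",
             samples[bad[2L]], "' in ", path)
    }
    ExpressionMatrix(vals, scale)
}

#' Write an expression matrix to TSV
#'
#' Values are serialized with 12 significant digits so a write/read
#' round trip is lossless well below 1e-9.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionTsv <- function(x, path) {
    stopifnot(is(x, "ExpressionMatrix"))
    if (ncol(x) == 0L)
        stop("refusing to write an expression matrix with no samples")
    m <- exprValues(x)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
    body <- apply(format(m, digits = 12, scientific = TRUE, trim = TRUE),
                  1L, paste, collapse = "\t")
    writeLines(paste(rownames(m), body, sep = "\t"), con)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' Members are deduplicated; duplicate set names or short lines error.
#'
#' @param path file path.
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3L)
    if (length(short))
        stop("GMT line(s) with fewer than 3 fields in ", path, ": line ",
             paste(short, collapse = ", "))
    nm <- vapply(parts, `[[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop("duplicated gene set name(s) in ", path, ": ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    desc <- vapply(parts, `[[`, character(1), 2L)
    sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
    names(sets) <- nm
    GeneSetCollection(sets, desc)
}

#' Write a GeneSetCollection to GMT
#'
#' @param gsc a [GeneSetCollection-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(gsc, path) {
    stopifnot(is(gsc, "GeneSetCollection"))
    desc <- gsc@descriptions
    desc[!nzchar(desc)] <- "na"
    lines <- vapply(seq_along(gsc@sets), function(i)
        paste(c(names(gsc@sets)[i], desc[i], gsc@sets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read and validate a sample metadata CSV
#'
#' Fixed column names: `sample_id, animal_id, tissue, group, year, sex,
#' pv40` (pv40 may be empty for samples without a lung-compliance
#' measurement). Tissue, group and sex levels are checked against the
#' study design vocabulary.
#'
#' @param path CSV file path.
#' @return a validated `data.frame`.
#' @export
readSampleTable <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    validateSampleTable(tab)
}

#' @rdname readSampleTable
#' @param tab a data.frame to validate in place of a file.
#' @export
validateSampleTable <- function(tab) {
    miss <- setdiff(setdiff(.SAMPLE_COLS, "pv40"), colnames(tab))
    if (length(miss))
        stop("sample table missing column(s): ", paste(miss, collapse = ", "))
    if (!"pv40" %in% colnames(tab))
        tab$pv40 <- NA_real_
    if (anyDuplicated(tab$sample_id))
        stop("duplicated sample_id(s): ",
             paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
                   collapse = ", "))
    badT <- setdiff(unique(tab$tissue), .TISSUES)
    if (length(badT))
        stop("unknown tissue level(s): ", paste(badT, collapse = ", "))
    badG <- setdiff(unique(tab$group), .GROUPS)
    if (length(badG))
        stop("unknown treatment group(s): ", paste(badG, collapse = ", "))
    badS <- setdiff(unique(tab$sex), c("M", "F"))
    if (length(badS))
        stop("unknown sex level(s): ", paste(badS, collapse = ", "))
    tab$year <- as.integer(tab$year)
    tab$pv40 <- as.numeric(tab$pv40)
    if (any(!is.na(tab$pv40) & tab$pv40 < 0))
        stop("pv40 must be nonnegative (mL)")
    tab
}

#' Write a sample table CSV
#'
#' @param tab sample metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSampleTable <- function(tab, path) {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Cross-check an expression matrix against its sample table
#'
#' Reports samples missing metadata, metadata rows without expression
#' columns, treatment groups below a sample-size floor, and the tissues
#' present. Validation is pure: inputs are not modified.
#'
#' @param x an [ExpressionMatrix-class].
#' @param samples sample metadata data.frame.
#' @param minGroupN flag groups with fewer samples than this (default 5,
#'   the smallest per-group size in the study design).
#' @return list with `missing_metadata`, `unmatched_metadata`,
#'   `small_groups` (named integer vector), `tissues`, `group_census`
#'   and a logical `ok`.
#' @export
validateCohort <- function(x, samples, minGroupN = 5L) {
    stopifnot(is(x, "ExpressionMatrix"))
    samples <- validateSampleTable(samples)
    common <- intersect(sampleIds(x), samples$sample_id)
    if (!length(common))
        stop("expression matrix and sample table share no sample ids")
    missingMeta <- setdiff(sampleIds(x), samples$sample_id)
    unmatched <- setdiff(samples$sample_id, sampleIds(x))
    sub <- samples[samples$sample_id %in% common, , drop = FALSE]
    census <- table(factor(sub$group, levels = .GROUPS))
    present <- census[census > 0L]
    small <- present[present < minGroupN]
    list(missing_metadata = missingMeta,
         unmatched_metadata = unmatched,
         group_census = as.integer(present) |> stats::setNames(names(present)),
         small_groups = as.integer(small) |> stats::setNames(names(small)),
         tissues = sort(unique(sub$tissue)),
         ok = length(missingMeta) == 0L && length(small) == 0L)
}

## ---- JSON model serialization -----------------------------------------

.SCHEMA_VERSION <- "1.0"

#' Serialize a MaturityModel to JSON
#'
#' Documented schema with a `schema_version` field so fitted models can be
#' exchanged across languages and sessions.
#'
#' @param model a [MaturityModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaturityModel <- function(model, path) {
    stopifnot(is(model, "MaturityModel"))
    obj <- list(schema_version = .SCHEMA_VERSION,
                type = "MaturityModel",
                source_tissue = model@sourceTissue,
                genes = model@genes,
                center = model@center,
                scale = model@scale,
                loadings = model@loadings,
                var_explained = model@varExplained,
                training = model@training)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeMaturityModel
#' @export
readMaturityModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$type, "MaturityModel"))
        stop("not a MaturityModel JSON file: ", path)
    new("MaturityModel", sourceTissue = obj$source_tissue,
        genes = obj$genes,
        center = as.numeric(obj$center), scale = as.numeric(obj$scale),
        loadings = as.numeric(obj$loadings),
        varExplained = obj$var_explained,
        training = as.list(obj$training))
}

#' Serialize a SignatureMatrix to JSON
#'
#' @param sig a [SignatureMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSignatureMatrix <- function(sig, path) {
    stopifnot(is(sig, "SignatureMatrix"))
    obj <- list(schema_version = .SCHEMA_VERSION,
                type = "SignatureMatrix",
                mode = sig@mode,
                value_scale = sig@valueScale,
                genes = rownames(sig@weights),
                populations = colnames(sig@weights),
                ## flat column-major vector avoids JSON array-shape
                ## ambiguity on read-back
                weights = as.numeric(sig@weights),
                markers = sig@markers)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeSignatureMatrix
#' @export
readSignatureMatrix <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$type, "SignatureMatrix"))
        stop("not a SignatureMatrix JSON file: ", path)
    w <- matrix(as.numeric(obj$weights), length(obj$genes),
                length(obj$populations),
                dimnames = list(obj$genes, obj$populations))
    new("SignatureMatrix", weights = w,
        markers = lapply(obj$markers, as.character),
        mode = obj$mode, valueScale = obj$value_scale)
}
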