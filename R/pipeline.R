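## End-to-end orchestration: simulate (or load) a cohort, preprocess,
## differential expression, maturity modeling with cross-tissue transfer,
## PV40 association, deconvolution of amniotic fluid against tissue
## centroids, and enrichment — one seeded, auditable run directory.

#' Assemble a pipeline run configuration
#'
#' A single global seed is expanded into per-stage seeds by a fixed
#' counter scheme (`seed * 100 + stage index`) so stage-level results are
#' reproducible independently of stage order. Pass a YAML file path to
#' merge file values over these defaults.
#'
#' @param config optional YAML file path or list of overrides.
#' @param seed global integer seed.
#' @return a validated config list of class `RunConfig`.
#' @export
runConfig <- function(config = NULL, seed = 1L) {
    base <- list(
        seed = as.integer(seed),
        tissues = .TISSUES,
        cohort = list(),
        sexPurge = list(pMax = 0.05, lfcUp = 0.25, lfcDown = -0.15),
        asca = list(gamma = 2, maxComponents = 5L),
        meanLog2Min = 1.0,
        degRuleByTissue = list(lung = "rmm_lung",
                               amniotic_fluid = "rmm_amniotic_fluid",
                               hippocampus = "gsea"),
        rmm = list(minOverlap = 0.9),
        deconv = list(nMarkers = 200L, rMin = 0.5, maxPerTissue = 30L,
                      topMarkerN = 20L),
        gsea = list(nperm = 2000L, topN = 500L, minSize = 3L),
        dunnett = list(nMC = 2e5))
    if (is.character(config))
        config <- yaml::read_yaml(config)
    if (!is.null(config)) {
        for (nm in names(config)) {
            if (is.list(base[[nm]]) && is.list(config[[nm]]))
                base[[nm]][names(config[[nm]])] <- config[[nm]]
            else base[[nm]] <- config[[nm]]
        }
    }
    if (!is.null(config$seed)) base$seed <- as.integer(config$seed)
    bad <- setdiff(base$tissues, .TISSUES)
    if (length(bad))
        stop("unknown tissue(s) in config: ", paste(bad, collapse = ", "))
    need <- base$tissues[vapply(base$tissues, function(t)
        is.null(base$degRuleByTissue[[t]]), logical(1))]
    if (length(need))
        stop("missing degRuleByTissue block for: ",
             paste(need, collapse = ", "))
    class(base) <- "RunConfig"
    base
}

.stageSeed <- function(cfg, stage) cfg$seed * 100L + stage

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> differential expression -> maturity
#' model -> PV40 association -> deconvolution -> enrichment into a
#' write-once run directory, recording a manifest with per-stage seeds,
#' parameters and output checksums. Re-running the same config
#' reproduces identical checksums.
#'
#' @param config a [runConfig()] list (or YAML path / override list).
#' @param outdir run directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param overwrite allow writing into an existing run directory.
#' @return (invisibly) list with the manifest and in-memory stage results.
#' @export
runPipeline <- function(config = runConfig(), outdir = tempfile("amnioseq_run_"),
                        overwrite = FALSE) {
    if (!inherits(config, "RunConfig"))
        config <- runConfig(config)
    cfg <- config
    if (dir.exists(outdir) &&
        file.exists(file.path(outdir, "manifest.json")) && !overwrite)
        stop("run directory already holds a manifest; use overwrite = TRUE")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(package = "amnioseq",
                     version = as.character(utils::packageVersion("amnioseq")),
                     seed = cfg$seed, stages = list())
    results <- list()
    stageNo <- 0L

    runStage <- function(name, fun) {
        stageNo <<- stageNo + 1L
        sdir <- file.path(outdir, sprintf("%02d_%s", stageNo, name))
        dir.create(sdir, showWarnings = FALSE)
        out <- tryCatch(fun(sdir, .stageSeed(cfg, stageNo)),
                        error = function(e)
                            stop("stage '", name, "' failed: ",
                                 conditionMessage(e), call. = FALSE))
        files <- list.files(sdir, full.names = TRUE, recursive = TRUE)
        manifest$stages[[name]] <<- list(
            index = stageNo, seed = .stageSeed(cfg, stageNo),
            checksums = as.list(tools::md5sum(files)) |>
                stats::setNames(basename(files)))
        out
    }

    ## 1. simulate
    results$cohort <- runStage("simulate", function(sdir, sd) {
        cohort <- simulateCohort(do.call(cohortConfig,
            c(cfg$cohort, list(seed = sd))))
        for (tis in cfg$tissues)
            writeExpressionTsv(cohort$expression[[tis]],
                               file.path(sdir, paste0(tis, "_tpm.tsv")))
        writeSampleTable(cohort$samples, file.path(sdir, "samples.csv"))
        jsonlite::write_json(
            list(maturity = cohort$truth$maturity,
                 sexGenes = cohort$truth$sexGenes,
                 pv40 = cohort$truth$pv40),
            file.path(sdir, "truth_manifest.json"),
            auto_unbox = TRUE, digits = NA)
        cohort
    })
    samples <- results$cohort$samples

    ## 2. preprocess: sex purge, batch correction, expression filter
    results$preprocess <- runStage("preprocess", function(sdir, sd) {
        tpms <- results$cohort$expression[cfg$tissues]
        purge <- identifySexLinkedGenes(tpms, samples,
                                        pMax = cfg$sexPurge$pMax,
                                        lfcUp = cfg$sexPurge$lfcUp,
                                        lfcDown = cfg$sexPurge$lfcDown)
        jsonlite::write_json(list(removed = purge$removed,
                                  params = purge$params),
                             file.path(sdir, "sex_purge.json"),
                             auto_unbox = TRUE, digits = NA)
        corrected <- lapply(cfg$tissues, function(tis) {
            x <- dropGenes(tpms[[tis]], purge$removed)
            x <- log2p1Transform(x)
            x <- ascaBatchCorrect(x, samples, gamma = cfg$asca$gamma,
                                  maxComponents = cfg$asca$maxComponents)
            writeExpressionTsv(x, file.path(sdir,
                paste0(tis, "_corrected_log2p1.tsv")))
            x
        })
        names(corrected) <- cfg$tissues
        filtered <- lapply(corrected, filterLowExpression,
                           threshold = cfg$meanLog2Min)
        list(purge = purge, corrected = corrected, filtered = filtered)
    })

    ## 3. differential expression
    results$de <- runStage("de", function(sdir, sd) {
        out <- lapply(cfg$tissues, function(tis) {
            bfit <- fitBlockedLinearModel(results$preprocess$filtered[[tis]],
                                          samples)
            L <- treatmentContrasts(bfit, control = "PTC")
            res <- contrastTest(bfit, L)
            utils::write.table(res, file.path(sdir,
                paste0(tis, "_contrasts.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
            list(fit = bfit, contrasts = L, results = res)
        })
        names(out) <- cfg$tissues
        out
    })

    ## 4. maturity model (per tissue + lung model transferred to fluid)
    results$rmm <- runStage("rmm", function(sdir, sd) {
        models <- list()
        scores <- list()
        for (tis in intersect(c("lung", "amniotic_fluid"), cfg$tissues)) {
            deRes <- results$de[[tis]]$results
            termRes <- deRes[deRes$contrast == "Term_vs_PTC", , drop = FALSE]
            sel <- selectDegs(termRes, cfg$degRuleByTissue[[tis]])
            models[[tis]] <- fitRmm(results$preprocess$filtered[[tis]],
                                    samples, c(sel$up, sel$down),
                                    sourceTissue = tis)
            writeMaturityModel(models[[tis]],
                               file.path(sdir, paste0(tis, "_rmm.json")))
            scores[[tis]] <- scoreRmm(models[[tis]],
                                      results$preprocess$filtered[[tis]])
        }
        if (all(c("lung", "amniotic_fluid") %in% names(models)))
            scores$amniotic_fluid_by_lung_model <- scoreRmm(
                models$lung, results$preprocess$corrected$amniotic_fluid,
                minOverlap = cfg$rmm$minOverlap)
        scoreTab <- do.call(rbind, lapply(names(scores), function(nm)
            data.frame(model = nm, sample_id = names(scores[[nm]]),
                       score = unname(scores[[nm]]))))
        utils::write.table(scoreTab, file.path(sdir, "maturity_scores.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        list(models = models, scores = scores)
    })

    ## 5. PV40 association
    results$assoc <- runStage("assoc", function(sdir, sd) {
        lungSamples <- samples[samples$tissue == "lung", , drop = FALSE]
        sc <- results$rmm$scores$lung[lungSamples$sample_id]
        year <- as.integer(dichotomizeYear(lungSamples$year) == "y2018")
        ps <- partialSpearman(sc, lungSamples$pv40, year)
        dn <- anovaDunnett(sc, lungSamples$group, control = "PTC",
                           nMC = cfg$dunnett$nMC, seed = sd)
        lv <- leveneVarianceTest(lungSamples$pv40, lungSamples$group)
        rep <- list(partial_spearman = list(rho = ps$estimate,
                                            p = ps$p.value, n = ps$n),
                    anova_f = dn$fStatistic, anova_p = dn$fPvalue,
                    dunnett = dn$comparisons,
                    levene_p = lv$p.value)
        jsonlite::write_json(rep, file.path(sdir, "pv40_association.json"),
                             auto_unbox = TRUE, digits = NA)
        rep
    })

    ## 6. deconvolution of amniotic fluid against tissue centroids
    results$deconv <- runStage("deconv", function(sdir, sd) {
        refTissues <- setdiff(cfg$tissues, "amniotic_fluid")
        tissueRef <- do.call(cbind, lapply(refTissues,
            function(tis) exprValues(results$cohort$expression[[tis]])))
        labels <- unlist(lapply(refTissues, function(tis)
            rep(tis, ncol(results$cohort$expression[[tis]]))))
        colnames(tissueRef) <- make.unique(colnames(tissueRef))
        sig <- centroidSignature(tissueRef, labels,
                                 nMarkers = cfg$deconv$nMarkers,
                                 rMin = cfg$deconv$rMin,
                                 maxPerTissue = cfg$deconv$maxPerTissue,
                                 seed = sd)
        dec <- deconvolveConstrained(sig,
            results$cohort$expression$amniotic_fluid)
        utils::write.table(data.frame(sample_id = rownames(mixProportions(dec)),
                                      mixProportions(dec)),
                           file.path(sdir, "af_proportions.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        afSamples <- samples[samples$tissue == "amniotic_fluid", ,
                             drop = FALSE]
        mz <- markerZscore(log2p1Transform(
            results$cohort$expression$amniotic_fluid), samples,
            topMarkers(sig, cfg$deconv$topMarkerN))
        list(signature = sig, deconv = dec, zscores = mz)
    })

    ## 7. enrichment: steroid contrasts against the term signature
    results$enrich <- runStage("enrich", function(sdir, sd) {
        tis <- if ("lung" %in% cfg$tissues) "lung" else cfg$tissues[1]
        deRes <- results$de[[tis]]$results
        termRes <- deRes[deRes$contrast == "Term_vs_PTC", , drop = FALSE]
        termSig <- topContrastSignature(termRes, topN = cfg$gsea$topN,
                                        prefix = "term")
        gres <- lapply(setdiff(unique(deRes$contrast), "Term_vs_PTC"),
            function(cn) {
                rk <- buildRanking(deRes[deRes$contrast == cn, ,
                                         drop = FALSE])
                g <- gseaPreranked(rk, termSig, nperm = cfg$gsea$nperm,
                                   seed = sd, minSize = cfg$gsea$minSize)
                g$contrast <- cn
                g
            })
        gtab <- do.call(rbind, gres)
        utils::write.table(gtab, file.path(sdir, "gsea_term_signature.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        gtab
    })

    manifest$config <- unclass(cfg)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(list(manifest = manifest, results = results,
                   outdir = outdir))
}
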