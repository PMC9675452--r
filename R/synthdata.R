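## Synthetic cohort generator. Emulates the staged-gestation corticosteroid
## design: three sample types from the same animals, eight treatment groups,
## two collection years, both sexes, a latent maturity axis with term
## controls at the top and preterm controls at the bottom, and a
## lung-compliance endpoint (PV40) linearly tied to latent maturity.
## Every draw is governed by the config seed; the ground truth is returned
## alongside the data for parameter-recovery tests.

#' Configuration for a synthetic cohort
#'
#' Defaults encode the study design the analysis assumes: 2,000 genes, the
#' eight treatment groups at n = 6 each across two mating-season years,
#' latent maturity means ordered Term > injected steroids > oral steroids >
#' PTC, sex-linked genes mixing strong (|log2FC| 0.5-1) and
#' threshold-straddling (0.15-0.3) effects, a 150-gene maturity program per
#' tissue with cross-tissue overlap 0.5, additive Gaussian log2-scale noise
#' (SD 0.15, the within-group residual spread typical of well-expressed
#' genes in controlled bulk TPM cohorts), a rank-1 year batch shift, and
#' PV40 = 30 + 25 m + N(0, 3) mL.
#'
#' @param nGenes number of genes per tissue.
#' @param groupSizes named integer vector of per-group sample counts.
#' @param maturityMeans named numeric vector of latent maturity group means
#'   on an arbitrary 0 (preterm) to 1 (term) scale.
#' @param maturitySd within-group SD of latent maturity.
#' @param years the two collection years.
#' @param batchMagnitude log2-scale SD multiplier of the rank-1 year shift
#'   (0 disables the batch effect).
#' @param nSexStrong,nSexWeak counts of sex-linked genes with strong
#'   (uniform 0.5-1) and threshold-straddling (uniform 0.15-0.3) absolute
#'   log2 effects (female minus male; signs mixed).
#' @param nMaturityGenes genes per tissue-level maturity program.
#' @param loadingRange absolute per-gene maturity loading range (log2 units
#'   per unit latent maturity); signs mixed.
#' @param crossTissueOverlap fraction of the amniotic-fluid and hippocampus
#'   programs shared (same genes, same loadings) with the lung program.
#' @param noiseSd iid Gaussian log2-scale noise SD.
#' @param baselineRange log2 baseline abundance range per gene.
#' @param pv40 list with intercept `a` (mL), slope `b` (mL per unit
#'   maturity) and noise `sd` (mL).
#' @param librarySize column sum each TPM profile is rescaled to.
#' @param seed integer seed fixing all randomness.
#' @return a validated config list of class `CohortConfig`.
#' @export
cohortConfig <- function(nGenes = 2000L,
                         groupSizes = c(PTC = 6L, B060 = 6L, B125 = 6L,
                                        C1x = 6L, C2x = 6L, POB = 6L,
                                        POD = 6L, Term = 6L),
                         maturityMeans = c(PTC = 0, B060 = 0.35, B125 = 0.55,
                                           C1x = 0.6, C2x = 0.5, POB = 0.25,
                                           POD = 0.2, Term = 1),
                         maturitySd = 0.08,
                         years = c(2017L, 2018L),
                         batchMagnitude = 0.6,
                         nSexStrong = 20L, nSexWeak = 6L,
                         nMaturityGenes = 150L,
                         loadingRange = c(0.75, 1.5),
                         crossTissueOverlap = 0.5,
                         noiseSd = 0.15,
                         baselineRange = c(2, 9),
                         pv40 = list(a = 30, b = 25, sd = 3),
                         librarySize = 1e6,
                         seed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes), groupSizes = groupSizes,
                maturityMeans = maturityMeans, maturitySd = maturitySd,
                years = as.integer(years), batchMagnitude = batchMagnitude,
                nSexStrong = as.integer(nSexStrong),
                nSexWeak = as.integer(nSexWeak),
                nMaturityGenes = as.integer(nMaturityGenes),
                loadingRange = loadingRange,
                crossTissueOverlap = crossTissueOverlap,
                noiseSd = noiseSd, baselineRange = baselineRange,
                pv40 = pv40, librarySize = librarySize,
                seed = as.integer(seed))
    if (any(cfg$groupSizes <= 0L))
        stop("group sizes must be positive")
    if (is.null(names(cfg$groupSizes)) ||
        !all(names(cfg$groupSizes) %in% .GROUPS))
        stop("groupSizes must be named by treatment group")
    if (!setequal(names(cfg$maturityMeans), names(cfg$groupSizes)))
        stop("maturityMeans must cover the same groups as groupSizes")
    if (length(cfg$years) != 2L)
        stop("exactly two collection years are required")
    if (cfg$crossTissueOverlap < 0 || cfg$crossTissueOverlap > 1)
        stop("crossTissueOverlap must be in [0, 1]")
    nSpecial <- cfg$nSexStrong + cfg$nSexWeak +
        cfg$nMaturityGenes * (1 + 2 * (1 - cfg$crossTissueOverlap))
    if (cfg$nGenes < ceiling(nSpecial) + 10L)
        stop("nGenes too small for the designated sex and maturity gene counts")
    class(cfg) <- "CohortConfig"
    cfg
}

#' Simulate a three-tissue cohort with ground truth
#'
#' Log2-scale expression is built as per-gene baseline + maturity loading x
#' latent maturity + sex effect + rank-1 year batch shift + iid Gaussian
#' noise, exponentiated to TPM and column-rescaled to a fixed library-size
#' constant. The same animals contribute lung, hippocampus and amniotic
#' fluid profiles; PV40 is a linear function of latent maturity plus noise.
#'
#' @param config a [cohortConfig()] list.
#' @return list with `expression` (named list of TPM
#'   [ExpressionMatrix-class] per tissue), `samples` (metadata data.frame)
#'   and `truth` (manifest: per-animal latent maturity, planted sex genes
#'   with signed effects, per-tissue maturity genes with loadings, batch
#'   directions and the PV40 parameters).
#' @export
simulateCohort <- function(config = cohortConfig()) {
    if (!inherits(config, "CohortConfig"))
        config <- do.call(cohortConfig, config)
    cfg <- config
    set.seed(cfg$seed)
    grp <- rep(names(cfg$groupSizes), cfg$groupSizes)
    nAnim <- length(grp)
    animals <- sprintf("A%02d", seq_len(nAnim))
    sex <- unlist(lapply(cfg$groupSizes, function(n)
        rep_len(c("M", "F"), n)), use.names = FALSE)
    year <- unlist(lapply(cfg$groupSizes, function(n)
        rep(cfg$years, length.out = n, each = ceiling(n / 2))[seq_len(n)]),
        use.names = FALSE)
    m <- cfg$maturityMeans[grp] + stats::rnorm(nAnim, 0, cfg$maturitySd)
    names(m) <- animals

    genes <- sprintf("g%04d", seq_len(cfg$nGenes))
    pool <- genes

    draw <- function(n) {
        if (n > length(pool))
            stop("gene pool exhausted; increase nGenes")
        picked <- sample(pool, n)
        pool <<- setdiff(pool, picked)
        picked
    }
    sexGenes <- draw(cfg$nSexStrong + cfg$nSexWeak)
    sexEffect <- as.numeric(c(
        if (cfg$nSexStrong) sample(c(-1, 1), cfg$nSexStrong, TRUE) *
            stats::runif(cfg$nSexStrong, 0.5, 1.0),
        if (cfg$nSexWeak) sample(c(-1, 1), cfg$nSexWeak, TRUE) *
            stats::runif(cfg$nSexWeak, 0.15, 0.3)))
    names(sexEffect) <- sexGenes
    sexClass <- rep(c("strong", "weak"),
                    c(cfg$nSexStrong, cfg$nSexWeak))

    nShared <- round(cfg$crossTissueOverlap * cfg$nMaturityGenes)
    lungGenes <- draw(cfg$nMaturityGenes)
    sharedAf <- if (nShared) sample(lungGenes, nShared) else character()
    sharedHip <- if (nShared) sample(lungGenes, nShared) else character()
    afOwn <- draw(cfg$nMaturityGenes - nShared)
    hipOwn <- draw(cfg$nMaturityGenes - nShared)

    rloading <- function(k) sample(c(-1, 1), k, TRUE) *
        stats::runif(k, cfg$loadingRange[1], cfg$loadingRange[2])
    lungLoad <- stats::setNames(rloading(cfg$nMaturityGenes), lungGenes)
    afLoad <- c(lungLoad[sharedAf],
                stats::setNames(rloading(length(afOwn)), afOwn))
    hipLoad <- c(lungLoad[sharedHip],
                 stats::setNames(rloading(length(hipOwn)), hipOwn))
    programs <- list(lung = lungLoad, amniotic_fluid = afLoad,
                     hippocampus = hipLoad)

    yearSign <- ifelse(year == cfg$years[2], 1, -1)
    sexInd <- as.numeric(sex == "F")

    exprs <- list()
    batchDirs <- list()
    for (tis in .TISSUES) {
        base <- stats::runif(cfg$nGenes, cfg$baselineRange[1],
                             cfg$baselineRange[2])
        load <- stats::setNames(numeric(cfg$nGenes), genes)
        load[names(programs[[tis]])] <- programs[[tis]]
        sexv <- stats::setNames(numeric(cfg$nGenes), genes)
        sexv[sexGenes] <- sexEffect
        v <- stats::rnorm(cfg$nGenes)
        if (sum(load^2) > 0)  # batch direction orthogonal to the program
            v <- v - load * sum(v * load) / sum(load^2)
        batchDirs[[tis]] <- stats::setNames(cfg$batchMagnitude * v, genes)
        L <- outer(base, rep(1, nAnim)) +
            outer(load, m) +
            outer(sexv, sexInd) +
            outer(batchDirs[[tis]], yearSign) +
            matrix(stats::rnorm(cfg$nGenes * nAnim, 0, cfg$noiseSd),
                   cfg$nGenes, nAnim)
        tpm <- 2^L
        tpm <- sweep(tpm, 2L, colSums(tpm) / cfg$librarySize, "/")
        dimnames(tpm) <- list(genes, paste(animals, tis, sep = "_"))
        exprs[[tis]] <- tpm
    }

    pv <- cfg$pv40$a + cfg$pv40$b * m + stats::rnorm(nAnim, 0, cfg$pv40$sd)
    pv <- pmax(pv, 0)

    samples <- do.call(rbind, lapply(.TISSUES, function(tis)
        data.frame(sample_id = paste(animals, tis, sep = "_"),
                   animal_id = animals, tissue = tis, group = grp,
                   year = year, sex = sex, pv40 = pv,
                   stringsAsFactors = FALSE)))
    rownames(samples) <- NULL

    ems <- lapply(.TISSUES, function(tis) {
        st <- samples[samples$tissue == tis, , drop = FALSE]
        rownames(st) <- st$sample_id
        ExpressionMatrix(exprs[[tis]], "TPM", sampleData = st)
    })
    names(ems) <- .TISSUES

    truth <- list(
        maturity = m,
        sexGenes = data.frame(gene = sexGenes, effect = unname(sexEffect),
                              class = sexClass, stringsAsFactors = FALSE),
        maturityGenes = lapply(programs, function(p)
            data.frame(gene = names(p), loading = unname(p),
                       stringsAsFactors = FALSE)),
        batchDirections = batchDirs,
        pv40 = cfg$pv40,
        config = cfg)
    list(expression = ems, samples = samples, truth = truth)
}

#' Simulate bulk mixtures of signature profiles
#'
#' Each sample is the signature-weighted combination of population profiles
#' with multiplicative lognormal noise of a stated coefficient of
#' variation (mean-one noise, so expectations match the noiseless mixture).
#'
#' @param signature a [SignatureMatrix-class] or genes x populations
#'   numeric matrix of nonnegative expression profiles.
#' @param proportions samples x populations matrix; rows must be
#'   nonnegative and sum to 1.
#' @param noiseCv coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed RNG seed.
#' @return a TPM-scale [ExpressionMatrix-class] of mixed profiles.
#' @export
simulateMixtures <- function(signature, proportions, noiseCv = 0,
                             seed = 1L) {
    W <- if (is(signature, "SignatureMatrix")) signatureWeights(signature)
         else as.matrix(signature)
    P <- as.matrix(proportions)
    if (ncol(W) != ncol(P))
        stop("signature populations (", ncol(W),
             ") and proportion columns (", ncol(P), ") disagree")
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
        stop("proportion rows must be nonnegative and sum to 1")
    set.seed(seed)
    X <- W %*% t(P)
    if (noiseCv > 0) {
        sdlog <- sqrt(log(1 + noiseCv^2))
        X <- X * matrix(stats::rlnorm(length(X), -sdlog^2 / 2, sdlog),
                        nrow(X), ncol(X))
    }
    if (is.null(rownames(P)))
        rownames(P) <- sprintf("mix%03d", seq_len(nrow(P)))
    dimnames(X) <- list(rownames(W), rownames(P))
    ExpressionMatrix(X, "TPM")
}
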