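---
title: "Models and methods behind amnioseq"
author: "amnioseq maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amnioseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amnioseq)
```

amnioseq analyzes staged-gestation bulk transcriptomes — matched amniotic
fluid, fetal lung and fetal hippocampus from the same animals, collected
at preterm or near-term gestation with or without antenatal
corticosteroid treatment — and asks whether cell-free RNA in the fluid
reports on organ maturation. This vignette explains each model, its
assumptions and the numerical choices, in the order the pipeline applies
them. The package works throughout on `log2(1 + TPM)` values, the scale
on which bulk expression residuals are closest to Gaussian and on which
all linear modeling below is justified.

## The synthetic cohort and what it does (and does not) emulate

Every recovery test in the package runs against cohorts from
`simulateCohort()`, whose defaults are the study design: eight treatment
groups (`PTC`, six steroid regimens, `Term`) with six animals each, two
mating-season years, both sexes, and the same animals contributing all
three sample types. Expression is built additively on the log2 scale,

```
L[g, s] = baseline[g] + loading[g] * m[s] + sexEffect[g] * 1{female}
          + batch[g] * yearSign[s] + N(0, noiseSd)
```

then exponentiated and column-rescaled to a fixed library size. The
latent maturity `m` runs from 0 (preterm controls) through intermediate
steroid values to 1 (term controls); a 150-gene program per tissue loads
on it with absolute log2 loadings in 0.75–1.5 (term-vs-preterm fold
changes of roughly 1.7–2.8, the range from which 1.5- and 2-fold DEG
rules actually select), and half of the amniotic-fluid program is shared
with the lung program so that cross-tissue scoring has a defined ground
truth. Sex effects mix strong (|log2FC| 0.5–1) and threshold-straddling
(0.15–0.3) genes, so the purge's asymmetric cutoffs are exercised on
both sides. The year batch is a rank-1 gene-direction shift
orthogonalized against the maturity loadings, which makes its removal by
residual PCA a well-posed recovery problem. The lung-compliance endpoint
is linear in maturity, `PV40 = 30 + 25 m + N(0, 3)` mL, spanning roughly
30 mL (preterm) to 55 mL (term).

The residual noise SD defaults to 0.15 log2 units. That represents the
within-group spread of well-expressed genes in a controlled primate
cohort — the stratum that survives the mean-expression prefilters on
which the purge, DEG selection and maturity model all operate; it is the
regime in which a 0.25-fold-change refinement threshold is meaningfully
stricter than the `P <= 0.05` consistency filter. What the generator
does *not* emulate: count-level sampling noise (values are lognormal, not
negative binomial), gene–gene correlation beyond the planted programs,
library-composition artifacts, or partial cell-type mixing within a
tissue. Passing recovery tests therefore demonstrate that the estimators
are correct and calibrated under their own assumptions, not that real
cohorts satisfy those assumptions.

## Sex-linked gene purge

Treatment groups are not balanced on fetal sex, so genes with inherent
male/female differences would confound treatment contrasts. The purge
(`identifySexLinkedGenes()`) fits, per tissue and collection year, a
moderated linear model `expression ~ group + sex` (limma) on samples
excluding the preterm controls (whose sex representation is inadequate
by design) after setting aside genes with mean `log2(1+TPM)` at or below
0.1 — a floor below which sex coefficients are unreliable. A gene is a
candidate when its female-minus-male coefficient keeps the same sign
with raw `P <= 0.05` in both years of a tissue, and is removed when both
yearly coefficients are at least +0.25 or at most −0.15. The asymmetry
reflects that female-up effects (X-linked escape) are typically larger
than female-down (Y-linked) ones on the female-minus-male axis; both
magnitudes are arguments, since the anchoring of the published
thresholds to a reference level is a genuinely open reading. Tissue
results are combined by union (a stricter two-tissue mode is provided).
The low-expression prefilter is evaluated on `log2(1+TPM)` rather than
`log2(TPM)`, which is undefined at zero; at the 0.1 boundary the two
scales are within 0.07 of each other.

## Batch correction preserving the treatment factor

`ascaBatchCorrect()` follows the ANOVA-simultaneous-component idea:
decompose `X = G + E`, where `G` holds per-treatment-group gene means,
and remove from the residual `E` the leading principal components whose
variance exceeds `gamma` (default 2) times the mean residual-component
variance, up to `maxComponents` (default 5). The rule formalizes
"systematic structure that the design does not explain": collection-year
batches concentrate in one or a few residual components with variance
far above the average, whereas iid noise spreads variance evenly, so a
doubling threshold separates the two without naming the batch factors.
Two numerical guarantees matter downstream. First, after component
removal the residual is re-centered within treatment groups: individual
residual components are not themselves group-centered, so without this
step removal would shift group means; with it, treatment centroids are
preserved to machine precision and all subsequent contrasts are
untouched by the correction. Second, removal plus re-centering can only
shrink the residual sum of squares, so the correction never manufactures
variance. The average component variance is computed over the first
`n - g` components (the residual degrees of freedom with `g` groups);
groups of one sample contribute no residual information and are flagged.
Correction is applied per tissue.

## Blocked differential expression with moderated t statistics

`fitBlockedLinearModel()` fits a cell-means design with one cell per
(treatment group, year block), the year dichotomized to 2018 versus
other. `treatmentContrasts()` then compares each treatment with the
preterm controls *within* the year blocks where both were collected,
averaging across shared blocks — treatments are judged against
contemporary controls, and any residual year effect cancels.
Variance moderation is limma's empirical Bayes machinery (`eBayes` with
`trend = TRUE`, `robust = TRUE`): gene variances are shrunk toward a
prior that follows mean expression, with outlier variances winsorized
during hyperparameter estimation, and moderated t statistics gain
`d0` prior degrees of freedom. `moderateVariances()` exposes the
hyperparameter step directly and `posteriorVar()` the shrinkage formula
`(d0 s0^2 + d s^2) / (d0 + d)`, whose limits (ordinary t at `d0 = 0`,
pooled z at `d0 = Inf`) anchor the unit tests. BH correction defaults to
the aggregate collection of P values from all contrasts within a tissue
(a per-contrast mode exists); the aggregate scope is also the default
feeding the maturity-model DEG rules, a choice the source methods leave
open. DEG rules are registered by name (`degRules()`) with their exact
boundary semantics: the enrichment lists use inclusive `P <= 0.05`,
`|log2FC| >= log2(1.25)`; the lung and amniotic-fluid maturity rules use
FDR `<= 0.05` with 2-fold and 1.5-fold floors; the display picks use
strict inequalities.

## The RNA maturity model

`fitRmm()` restricts to preterm- and term-control samples and to the
term-vs-preterm DEGs for that tissue, standardizes each gene by its
*training* mean and SD, and takes the first principal component of the
standardized training matrix. The component's sign is mathematically
arbitrary; it is fixed so the mean term training score exceeds the mean
preterm score, making "more mature" always positive. `scoreRmm()`
standardizes any target matrix with the stored training center and scale
and projects onto the loadings — this is deliberately a frozen linear
predictor, not a re-fit, so steroid-treated samples are measured on the
axis defined by normal gestation, and a lung-trained model can score
amniotic fluid (scored on batch-corrected but unfiltered values, since
the target tissue's expression filter would discard model genes).
Training-derived standardization is the default; an all-sample mode
would re-center on the scored cohort and is intentionally not the
projection semantics used here. Model genes missing from a target are
imputed as 0 after standardization — the training-mean value, so absent
genes pull scores toward indifference rather than in a direction — with
a hard error below 90% overlap (configurable). Genes with zero training
SD are dropped before standardization. The fit requires at least 3 genes
by default (`minGenes`, floor 2: one component needs two dimensions).

Validation ties scores to physiology: `partialSpearman()` implements the
first-order partial rank correlation with the collection year as the
control variable, with `t = r sqrt((n-3)/(1-r^2))` on `n - 3` degrees of
freedom; ties take average ranks. PV40 outliers are excluded only by an
explicit sample list, never automatically.

## Dunnett many-to-one comparisons

`anovaDunnett()` runs the overall F test and compares each treatment to
the control with pooled-error t statistics. The family-wise adjusted P
is `Pr(max_j |T_j| >= |t_i|)` under the equicorrelated multivariate-t
null with `lambda_i = sqrt(n_i / (n_i + n_0))`, evaluated by seeded
Monte Carlo (`dunnettMaxNull()`, default 2e5 draws; the representation
`T_j = (lambda_j Z_0 + sqrt(1 - lambda_j^2) Z_j) / S` with a shared
chi-square denominator reproduces the correlation structure exactly).
Monte Carlo was chosen over quadrature because it is dimension-free,
trivially seeded, and testable against both the single-contrast
reduction (where the adjusted P must equal the ordinary two-sided t
probability) and an established multivariate-t implementation; the tail
fraction is reported unsmoothed so that reduction is unbiased. Null
draws can be precomputed and reused across calls with the same design —
that is how the family-wise calibration test covers 10,000 null
datasets. The two-way form adds a categorical covariate (sex) to the
linear model; the equicorrelation approximation then still uses the raw
group sizes. Variance homogeneity diagnostics use the Brown–Forsythe
variant (deviations from group medians) via `car::leveneTest`.

## Deconvolution

Two signature modes mirror two reference types. `markerFinderSignature()`
(single-cell style) correlates every gene with each population's 0/1
indicator profile, assigns the gene to its best-correlated population
(ties broken by first label order, with a warning), keeps the top 100
per population, and stores the correlations themselves as weights — zero
outside the owning population. `centroidSignature()` (bulk-compendium
style) first drops tissues with fewer than 5 samples and subsamples the
rest to at most 30 with a seeded RNG, takes the top 200
indicator-correlated genes per tissue with Pearson r > 0.5, and stores
per-tissue centroids: gene-wise mean `log2(1+TPM)` back-transformed to
TPM.

`deconvolveConstrained()` estimates per-sample proportions by the
quadratic program `min ||S w - x||^2` with `w >= 0` and `sum(w) = 1`
enforced exactly — a primal active-set iteration on the bound
constraints with the equality handled in the KKT system, rather than the
shortcut of solving unconstrained nonnegative least squares and
renormalizing. The solver normalizes `S` and `x` jointly before
factorization so the KKT matrix mixes comparable magnitudes (the
solution is invariant to that scaling), and identifiability is checked
on the constraint-augmented matrix `rbind(S, 1)` because per-gene
standardization (default on, mirroring reference-tool scaling) centers
rows and thereby nulls exactly the direction the equality constraint
pins down. With the sum-to-one constraint active, standardization does
not move the noiseless optimum, and the tests run both modes. The
exhaustive enumeration oracle in the test suite certifies the active-set
solution as the global optimum for small population counts.

`markerZscore()` implements the complementary marker-set readout: each
gene standardized by its mean and SD in the preterm-control reference
group, averaged over a set's genes per sample. `groupwiseExtremumTest()`
encodes the gated decision rule used for both proportions and Z scores:
an ANOVA gate at `P < 0.05`, Dunnett with the term controls as
comparator, and an extremum flag only when the comparator mean is the
numerical extremum and every adjusted P is below 0.05.

## Enrichment

`fisherZEnrich()` reports, per gene set intersected with the universe
(sets under 3 in-universe genes skipped), the two-sided Fisher exact P
and the hypergeometric Z score
`(r - nR/N) / sqrt(nR/N (1 - R/N)(1 - (n-1)/(N-1)))`, BH-corrected
across sets; the conventional display criterion is Z > 2 with corrected
P < 0.05. The fully saturated table is reported as degenerate (P = 1, Z
undefined) rather than an error. `gseaPreranked()` performs preranked
GSEA through fgsea's fixed-permutation mode: weighted running-sum
enrichment score with exponent 1 (configurable; the weight convention of
the reference implementation), gene-permutation null, NES defined as ES
divided by the mean |ES| of same-sign permutations, smoothed permutation
P, and a significance flag at BH-corrected P < 0.1. Gene permutation
(not phenotype permutation) matches preranked semantics; the adaptive
multilevel estimator is deliberately not used, so P values are bounded
below by `1/(nperm+1)` and their Monte Carlo precision is explicit.
Rankings come from `buildRanking()` — descending moderated t, or
signed `-log10 P` — with lexicographic tie-breaks for determinism, and
`topContrastSignature()` truncates a contrast to its top 500 genes per
direction for cross-condition comparisons.

## The pipeline and reproducibility

`runPipeline()` chains simulate → preprocess → differential expression →
maturity model (with the lung model transferred to amniotic fluid) →
PV40 association → deconvolution of amniotic fluid against lung and
hippocampus centroids → enrichment of each steroid contrast against the
term signature. The run directory is write-once; a manifest records the
package version, per-stage seeds (derived from the global seed by
`seed * 100 + stage`), the full configuration and MD5 checksums of every
output, and re-running a configuration reproduces identical checksums.
Configuration is an R list or YAML file merged over documented defaults.

## Problem sizes and known limitations

The default test conditions are 2,000 genes and 8 × 6 samples per
tissue; calibration checks use 2,000-gene null fits, 10,000-replicate
Dunnett null studies against a 1e6-draw critical value, and
200-gene/5-population deconvolution probes. These sizes make every
distributional claim testable in seconds while leaving the estimators'
asymptotics visible. Known limitations: the purge requires both
collection years to contain both sexes outside the controls; the batch
model removes only structure expressible as a few residual components;
maturity scoring is a single linear component and will not represent
nonmonotone maturation programs; deconvolution assumes the signature
spans the mixture (no "unknown" compartment); and the Dunnett
equicorrelation is exact only for the one-way layout, an approximation
under covariate adjustment.
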