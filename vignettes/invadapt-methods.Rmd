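---
title: "Models and methods behind invadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind invadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

invadapt chains four analyses that together address one question: when an
invasive population establishes outside its source range, does it keep the
source's environmental niche (conservatism), and is there nonetheless
measurable adaptation — genomic or morphometric — along the new range's
environmental gradients?  This vignette records the models, their
assumptions, the tunable parameters, and the design choices made where the
underlying methods literature leaves options open.

## Niche overlap in ordination space

Occurrences from all ranges are pooled, their environmental values centred
and scaled, and decomposed by PCA; background cells are projected with the
same centring and scaling so that both ranges and their availability live
in one two-axis space.  Occupancy on that space is estimated on an R×R grid
(default R = 100) by Gaussian kernel smoothing with the normal-reference
bandwidth per axis; the occupancy surface is divided by the smoothed
background prevalence (z = o/e where e > 0, zero elsewhere) and normalized.
Correcting by prevalence is the standard choice in gridded-niche analysis
and is the default here; the uncorrected variant (`correction = "none"`)
remains available because published descriptions do not always state which
was used.  Overlap is Schoener's D = 1 − ½Σ|z₁ − z₂|.

Two permutation tests accompany D, both with the add-one estimator
p = (1 + k)/(nPerm + 1).  The *equivalency* test pools the occurrences and
permutes range labels, preserving sample sizes; small p means the niches
are less overlapping than exchangeable samples would be.  The *similarity*
test keeps the reference niche fixed and translates the shifted niche's
occurrence cloud to a uniformly random centroid within its own background,
restricted so that the entire cloud stays inside the background bounding
box — a shift that would push density outside the background is never
drawn.  Each niche is smoothed with its own bandwidth; the shifted niche's
bandwidth rule is translation-invariant, which keeps the null exchangeable
with the observed placement (a pooled bandwidth would couple smoothing to
the observed distance between niches and bias the test, which we verified
by calibration simulation).  Centroid displacement between two occurrence
sets is reported descriptively, without a test: no accepted test statistic
exists for it in this framework.

## Ensemble distribution modelling

Occurrences are thinned to one per raster cell, and pseudo-absences are
drawn uniformly from cells outside the presences' surface range envelope
(the per-variable [0.025, 0.975] quantile box; five sets of 5000 at study
scale).  Five learner families are fitted behind a common fit/predict
contract: binomial GLM with linear terms; mgcv GAM with small smooth bases
(k = 4); gradient-boosted trees (100 rounds, depth 3, learning rate 0.1);
an adaptive-spline learner built from per-variable natural-spline bases
(df = 4) with lasso term selection via cross-validated glmnet; and a
500-tree-default random forest (here 200 trees).  Each (learner ×
pseudo-absence set × repeat) member is calibrated on a class-stratified
random 70 % and scored on the held-out 30 % by ROC-AUC and by TSS at its
TSS-maximizing threshold; stratification avoids single-class evaluation
folds.  Members with TSS ≥ 0.4 enter the ensemble with weight proportional
to TSS, and the continuous ensemble map is binarized at the ensemble's own
TSS-maximizing threshold on the calibration data — weighting rule,
inclusion cutoff and binarization are common conventions, stated here
because they materially affect the map-agreement metrics.  Variable
importance is 1 minus the mean correlation between predictions before and
after permuting one variable.  Niche change between an invaded-range model
A and a source-range model B, inside an analysis mask, is
stability = |A∩B|/|A|, expansion = |A∖B|/|A| (the two share a denominator
and sum to one exactly), unfilling = |B∖A|/|B|.

## Dual genotype–environment scans

SNPs are filtered to ≤ 30 % missing calls and minor allele count ≥ 40 (the
count rule is a floor), then mean-imputed per SNP.

The latent-factor scan regresses each SNP on one standardized environmental
variable plus K latent factors (default K = 3, matching the number of
ancestral groups).  The factors are estimated from the environment-
residualized genotype matrix by alternating ridge least squares from a
random initialization; the scan is repeated (default five times) and
repeat-to-repeat variation comes from those initializations.  This
deterministic solver replaces the original method's MCMC sampler: with
matched K and repeats it reproduces the sampler's statistical behaviour
(calibration and power, both verified against planted truth in the test
suite) while remaining fast and exactly reproducible.  Per-SNP z-scores are
combined across repeats by the median — the robust convention recommended
for multi-run scans — and calibrated by the genomic inflation factor
λ = median(z²)/0.456, where 0.456 is the median of a 1-df chi-square;
adjusted p-values are z²/λ against χ²₁.  Note that the median across
*independent* repeats would shrink the statistic (the median of five
independent standard normals has variance ≈ 0.29); in practice repeats are
strongly correlated because they share the data, and the GIF absorbs the
residual scale either way.

The multivariate scan is a partial redundancy analysis (vegan) of the
imputed, centred (not scaled) genotype matrix on all environmental
variables, conditioned on the ancestry coefficients with one of the K
columns dropped to avoid the sum-to-one singularity.  Each SNP's loading
vector on the leading constrained axes (as many as K) is turned into a
robust Mahalanobis distance — axes standardized by median and MAD, so that
a handful of true outliers cannot inflate the scatter — calibrated by the
same GIF construction against χ² with that many degrees of freedom.
Storey q-values (smoother-estimated π₀ over a λ grid, monotone step-down
transform) are attached to both scans, and SNPs with q < 0.05 in *both*
are the outliers; intersecting two methods with different confounding
behaviour is what keeps the empirical FDR of the pipeline low, which the
acceptance suite measures directly (planted clines of logit-slope 3 across
90 populations × 6 individuals, 20 causal among 2000 SNPs, sensitivity
≥ 0.8 and FDR ≤ 0.1 averaged over 20 seeds).

## Allelic turnover by generalized dissimilarity modelling

For each RAD locus, pairwise Weir–Cockerham θ between populations is
computed per SNP from the variance components a, b, c and combined across
a locus's SNPs by ratio of sums; populations with fewer than five
individuals genotyped at the locus are excluded from that locus's roster
(sample-size-driven rosters of 50–70 of 90 populations are typical under
study-scale missingness).  Negative estimates are floored at zero and the
pairwise matrix min–max rescaled to [0, 1] per locus; per-locus rescaling
(rather than a global one) keeps each locus's model on the same response
scale as its own null comparison.

The dissimilarity model is d = 1 − exp(−η) with η an intercept plus
non-negative coefficients on order-2 I-spline transforms (three splines,
knots at the 0/50/100th percentiles — the originating package's default)
of each predictor's per-site values, entered as |I(xᵢ) − I(xⱼ)|; geographic
distance enters as the I-spline of the pairwise distance itself.  Fitting
is iteratively reweighted non-negative least squares on the link scale
with step-halving to keep the binomial-type deviance monotone (the NNLS
active set can otherwise cycle between near-identical solutions); a fit
that still fails to stabilize raises an error rather than returning a
doubtful model.  Explained deviance is reported as a percentage of the
intercept-only model's deviance.  The fitted dissimilarities lie in [0, 1)
by construction, and a predictor's *partial turnover* — the height of its
fitted monotone function over the observed gradient — is simply the sum of
its coefficients, since each basis function spans 0 to 1.

The null level comes from a reference group: 200 random SNPs treated as a
single multi-SNP locus and fitted identically.  Candidates among tested
loci must (C1) exceed the reference's explained-deviance percentage; (C2)
have their largest environmental turnover exceed both the reference's
turnover for that predictor and the locus's own geographic turnover, loci
dominated by geography being flagged false positives; and (C3) retain at
least 40 % of the full model's explained-deviance percentage when refitted
with the winning predictor alone.  The single-predictor-refit reading of
"explains ≥ 40 % of the deviance" is a documented choice — per-predictor
deviance shares are not uniquely defined in this model family — and it is
conservative: shared deviance counts toward the winner only if the winner
can carry it alone.

## Wing morphometrics

Landmark configurations (20 two-dimensional landmarks) are read from TPS
files, centred, scaled to unit centroid size and iteratively rotated to
their consensus until it stabilizes (tolerance 1e−10).  Rotations are
constrained to determinant +1: all wings come from the same body side, so
reflections would be artefacts.  Shape PCA operates on the flattened
aligned coordinates.  Group tests use type II sums of squares (car):
univariate ANOVA on log centroid size, with pairwise comparisons restricted
to groups of at least five individuals, and MANOVA with Pillai's trace on
the leading principal components capturing 95 % of shape variance —
aligned coordinates have only 2k − 4 free dimensions and small groups make
the full-dimensional within-group covariance singular, so the reduced
dimension is always reported alongside the statistic.  Environmental
correlations use partial RDA of shape (or log size) on per-population
environmental values conditioned on population-averaged ancestry
coefficients, with residual permutation under the reduced model (999
permutations by default); individuals carry their population's values
because trait and genotype data are matched at population level.

## The synthetic-data generator

The generator produces every input the chain consumes, with planted truth.
Environmental layers are white noise smoothed by a Gaussian kernel (width
`spatialRange` cells, FFT convolution) and mixed through the Cholesky
factor of a target correlation matrix; six layers named after winter
precipitation, precipitation seasonality, minimum winter temperature,
isothermality, productivity and human footprint form the default predictor
roster.  Occurrences are drawn proportional to a logistic suitability
surface.  Genotypes follow a hierarchical Balding–Nichols model: ancestral
frequencies uniform on [0.05, 0.95]; three spatially banded ancestries
diverging at `baselineFst` (default 0.1, a realistic continental-scale
divergence); population frequencies as the admixture-weighted mixture plus
small within-ancestry drift (0.02); causal SNPs shifted on the logit scale
by `clineStrength` per standardized unit of one predictor, clamped to
[0.01, 0.99]; genotypes Binomial(2, p); missingness applied per
locus × individual block (whole-tag dropout, as in reduced-representation
data) at 18.5 % by default.  Monomorphic SNPs are redrawn up to a retry
cap.  Study-scale defaults are 90 populations × 6 individuals and several
thousand SNPs grouped into 1–3-SNP loci.  Landmark sets are mean shape +
group displacement + isotropic noise, scaled log-normally and placed at
random orientation and position.

What the generator does *not* emulate — linkage disequilibrium, coalescent
genealogies, selection dynamics through time, informative missingness,
spatially continuous admixture clines — bounds what green tests prove:
they validate the estimators and their calibration under the stated model,
not robustness to every pathology of real reduced-representation data.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: constant variables in the ordination,
single-class labels in TSS, all-missing SNPs, rank-deficient predictor
matrices, degenerate landmark configurations.  Kernel-density backgrounds
are treated as absent below 1e−10 of their maximum; GDM fitted values are
clamped away from 1; the IRLS tolerance is 1e−6 on coefficients with a
deviance-stall fallback.  The test suite runs the full chain at reduced
but structurally faithful sizes — 50×50 rasters, 90 × 6 genotype matrices
with 2000 SNPs, 200-replicate calibration studies, 20-seed power studies —
chosen so the whole suite completes in minutes while keeping Monte-Carlo
error well inside the asserted margins; the acceptance script states each
quantity's problem size next to its value.
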