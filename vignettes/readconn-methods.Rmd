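---
title: "Methods: gene-brain-behavior analysis of specific comprehension difficulty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-brain-behavior analysis of specific comprehension difficulty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`readconn` implements a three-arm analysis of *specific* (unexpected) reading
comprehension difficulty: a behavioral phenotype built from regression
residuals, an association arm linking that phenotype to functional groups of
READ1 — a polymorphic tandem repeat regulating *DCDC2* — and a resting-state
fMRI arm relating READ1 carrier status to network connectivity. Because the
cohorts such analyses run on are shared only under collaborative agreements,
the package ships a first-class synthetic-data module that reproduces the
statistical structure the pipeline assumes, with planted effects whose
recovery the test suite verifies end to end.

## The comprehension phenotype

Reading comprehension is regressed by OLS on age, performance IQ, two
decoding measures, and three word-recognition measures. The residual — how
much better or worse a child comprehends than their word-level skills
predict — is the phenotype. Standardized by the in-sample residual SD,
subjects are banded: `z <= -1` unexpected poor (UPC), `z >= +1` unexpected
good (UGC), `|z| <= 0.5` expected average (EAC); the gaps are unclassified.
Boundary values are inclusive toward the labeled bands — the convention is
arbitrary but must be deterministic, and pulling exact boundaries into the
extreme groups matches how the bands are described (at one SD *or beyond*).
Two alternative bandings support the reclassification sensitivity analysis:
`contiguous` widens EAC to `|z| < 1`, and `split` divides the 0.5–1 gap at
0.75 between EAC and the adjacent extreme group. Contiguous is the default
reading of "reconfigured to include participants between 0.5 and 1.0 SD"
because it is the most common one.

## READ1 functional groups

Alleles are grouped by repeat-unit copy structure: RU1-1 (one copy of repeat
unit 1: alleles 2, 3, 8, 12, 25, 27), RU2Long (>= 8 copies of repeat unit 2:
5, 6, 13, 14, 19, 20, 22, 23), and RU2Short (<= 6 copies: 4, 10, 15, 16, 17,
21, 24, 26, 30, 37, 39). Where published prose and table disagree on RU1-1
membership (allele 8 vs 9), the table's allele list is used, since the lists
are the operational definition behind the carrier counts. A copy-count rule
engine covers alleles outside the lists and flags its output as
extrapolation. A subject *carries* a group if at least one allele belongs to
it after deletion substitution: one copy of the READ1 microdeletion makes
the subject effectively homozygous for the other allele; dual deletions are
excluded from analysis.

## Association arm

The carrier-by-group table is tested with a Pearson chi-square (no
continuity correction, df = 2). Group membership is then modeled by
multinomial logistic regression (UPC reference, so both coefficient sets
contrast against the poor comprehenders) with age, sex, vocabulary, SES,
Spanish-home and bilingual flags, maternal education, carrier status, and
ancestry principal components; odds ratios carry symmetric-on-log Wald 95%
intervals and the fit reports Nagelkerke's pseudo R². Missing covariate
cells are handled by chained-equation multiple imputation — predictive mean
matching (5 donors, Bayesian parameter draws) for continuous columns,
Bayesian logistic draws for binary ones, 10 burn-in passes, m = 15
independent chains — pooled by Rubin's rules. The fraction of missing
information uses the large-sample form `gamma = (1 + 1/m) B / T`, and the
relative efficiency `(1 + gamma/m)^-1` is reported per coefficient. No
chained-equation imputation engine is available among the package's
dependencies, so the sampler is implemented here; with zero missingness it
reduces exactly to the complete-data fit, which the tests assert.

Population structure is controlled EIGENSTRAT-style: SNPs failing
missingness (> 5%), Hardy-Weinberg equilibrium (1-df chi-square p < 1e-4),
autosomal-location, or minor-allele-frequency (< 0.05) rules are dropped;
samples are dropped for > 3% missingness or an X-heterozygosity sex call
(< 0.05 male, > 0.15 female; the cutoffs are conventional, the method only
being named in the source analyses) contradicting the reported sex. Missing
dosages are mean-imputed, each SNP centered at 2p and scaled by
`sqrt(p(1-p))`, and the top singular vectors serve as ancestry covariates.
The genomic inflation factor is the median association chi-square over
0.4549. The trend-scan helper converts (partial) correlations to squared
t statistics at their residual degrees of freedom; without that correction,
lambda is biased upward by roughly n/(n-k) when k covariate dimensions are
projected out.

## Imaging arm

**Motion QC.** Per-volume movement is the Euclidean norm of the
point-to-point change across the six rigid-body parameters. The first six
volumes of each run are discarded; a volume is censored if movement strictly
exceeds 0.3 mm or if more than 10% of in-mask voxels are outliers (detrended
deviation beyond 3.5 scaled MADs from the voxel's run median — a MAD rule is
used because only the "10% outlier voxels" criterion, not its exact
statistic, is specified by the upstream tooling). Strict inequalities
implement "exceeded the thresholds". Subjects retaining fewer than 60% of
volumes across runs are excluded.

**Nuisance regression.** Per voxel, OLS removes the six motion parameters,
their first derivatives, a discrete-cosine drift basis below 0.01 Hz, the
first three ventricle-mask principal components, and the mean white-matter
signal, fit on retained volumes only. Collinear columns are dropped with a
warning rather than failing, since degenerate designs arise legitimately on
censored short runs.

**ICD maps.** For every gray-matter voxel, the survival function
`S(tau)` = fraction of other in-mask voxels whose correlation exceeds `tau`
(positive tail, grid `0, 0.01, ..., 0.99`) is fit with a stretched
exponential `S(tau) = exp(-(alpha * tau)^beta)`, `alpha, beta` in (0, 100],
initialized from the log-log linearization. This parameterization makes
smaller `alpha` (and, via the tail shape, larger `beta`) correspond to a
larger degree metric — more extensive connectivity. The exact formula is a
design choice (the originating analyses never print one); the group analyses
here use the `alpha` map, whose monotone relationship to planted
connectivity is the cleanest, and the choice of dependent parameter is a
function argument. Whole-brain fitting uses a vectorized damped Gauss-Newton
that solves each voxel's 2x2 normal equations in closed form; it matches the
reference `nlsLM` fit to ~1e-3 on noisy curves and to 1e-6 on noiseless
ones, and recovers generating parameters with median absolute error well
under 0.05 at observation noise sigma = 0.01.

**Voxelwise inference and cluster correction.** Smoothed (6 mm FWHM,
mask-renormalized) ICD maps enter a per-voxel OLS on the comprehension
residual with sex, maternal education, SES, and three ancestry PCs as
covariates. Familywise control follows the Monte-Carlo cluster-extent
approach: per-axis Gaussian smoothness is estimated from the model's
residual maps via lag-1 autocorrelations of in-mask first differences; null
Gaussian fields at that smoothness are simulated, thresholded at the
two-sided voxel p (default 0.001), and the (1 - 0.05) quantile of the null
maximum cluster size (6-connectivity) gives the extent threshold. Two
lattice corrections matter at desk scale and are applied: the smoothing
kernel's width is solved numerically so the *realized lattice* ACF matches
the requested FWHM (the continuum rule `s_kernel = s_field / sqrt(2)`
under-smooths coarse grids by ~8%), and each simulated field is standardized
by its exact per-voxel kernel variance, since the observed statistic is
studentized per voxel while raw smoothed noise has depressed variance at
grid edges — without this the null over-clusters in the high-variance
interior and the threshold is anticonservative. Calibration tests hold the
familywise error inside 0.05 +/- 0.02 over 200 null datasets at 1000
iterations each. Influence diagnostics for the focal regression report
Cook's distance (> 4/n) and standardized DFBETA (> 2/sqrt(n)) flags — the
conventional cutoffs, as the source analyses state only that thresholds were
applied — plus refits excluding flagged subjects and restricting the
phenotype to +/- 20.

**Seed network and genotype regressions.** The seed is the top
cluster-corrected ICD cluster; when nothing survives correction at desk
scale the largest uncorrected supra-threshold cluster is used and flagged
exploratory, so the network stage remains exercisable (a seed *definition*
need not itself be confirmatory). Per subject, the seed's mean time course
is correlated with every voxel and Fisher-z transformed (correlations at
|r| = 1 are clipped to 1 - 1e-7 and flagged); a one-sample t across subjects
thresholded at a configurable p (default 1e-6; the real-scale 1e-20
threshold presumes far larger samples than desk-scale runs) and restricted
to positive means defines the network. Peaks (local maxima, greedy 30 mm
minimum separation, value-ordered with predictor-order tie-break) get 6 mm
spheres — 33 voxel centers on a 3 mm grid; the continuous volume ratio is
33.5 — whose mean z per subject feeds node models: OLS of connectivity on
the carrier indicator (forced in) plus covariates retained by p-value
backward selection (refit after each single removal, drop the largest p
above 0.05).

## The synthetic-data generator

The generator defines the study conditions. Cohorts draw group labels first
(sampling fractions 216/530/223 over the three groups), then carrier status
at the group frequencies 0.47 / 0.37 / 0.32, then genotypes conditional on
carrier status from an invented allele-frequency table in which alleles 4/10
and 5/6 dominate their groups; call failures occur at 1.3%. Covariates get
the published group-dependent means and SDs (age, vocabulary, maternal
education, SES, sex); Spanish-home (0.30) and bilingual (0.35) rates are
unpublished and set to plausible constants. Comprehension is built from a
generating linear model whose residual z is drawn truncated to the group's
band, so classification on the true scale recovers the labels exactly and
classification on refitted residuals recovers them up to boundary noise.
Missingness is MCAR at 1.5% over the designated covariates, matching the
only fact stated about it. SNP panels follow the Balding-Nichols
two-population model, with optional X SNPs (hemizygous males) for the sex
check.

BOLD runs place five spherical nodes (bilateral anterior, bilateral
posterior, one midline) on a small centered grid, 3 mm voxels, TR 1.55 s,
two 240-volume runs by default. Latent node signals are Gaussian series
band-limited to 0.01-0.1 Hz — the standard resting-state band; keeping the
planted signal out of the drift band means the pipeline's own drift
regressors cannot eat it, which a low-pass-only design violates — and are
empirically whitened then Cholesky-mixed so the *realized* correlation
matrix equals the target exactly (the `mvrnorm(empirical = TRUE)`
convention). A planted-effect generator should realize its planted
parameters: recovery tests then measure pipeline error, not generator
sampling noise. Carriers get +0.2 on one designated (anterior-posterior)
pair; optionally one node's correlations tilt with the comprehension
residual, which is what gives the ICD arm its detectable cluster. Voxels
take their node's signal plus unit white noise (hard-sphere kernel — the
simplest spatial structure satisfying the analysis assumptions); white
matter and ventricles carry shared sub-0.01 Hz drifts; motion traces are
slow random walks with spikes above the censoring threshold at rate 0.03,
mirrored by intensity spikes in 15% of voxels.

What the generator does *not* emulate: hemodynamics, scanner artifacts,
anatomy, spatial autocorrelation of the noise floor, linkage disequilibrium,
or non-MCAR missingness. Passing tests therefore demonstrate that the
pipeline's operations are correct and calibrated under their stated
assumptions — not that the pipeline is robust to the full complexity of
real acquisitions.

## Problem sizes and reproducibility

Desk-scale defaults keep the full pipeline around half a minute: 600
subjects behavioral, 2,000-SNP panels, 20 imaging subjects on a
14 x 16 x 14 grid with two 120-volume runs, 200-iteration cluster
simulations (10,000 remains the real-scale default). Law-of-large-numbers
checks run at n = 10,000; calibration suites use 200-400 replicates. All
randomness flows from one root seed through per-stage streams
(`derive_seed`), and identical configurations reproduce byte-identical
outputs, which the manifest hash records.

## Known limitations

The Gaussian-field null of the cluster simulation approximates the
studentized statistic map; at very small degrees of freedom or lax voxel
thresholds it is mildly conservative. Survival-curve fitting weights all
thresholds equally rather than by bin occupancy. Backward selection's
properties are those of p-value stepwise procedures generally; it is
provided because it is part of the analysis design, not as a recommendation.
The copy-count rule engine extrapolates beyond the published allele lists
and says so. Real-data idiosyncrasies — site effects, scanner drift
families, admixture beyond two populations — are out of scope.
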