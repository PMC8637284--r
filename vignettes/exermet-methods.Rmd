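---
title: "Methods: paired exercise metabolomics and oximetry in LEAD"
author: "exermet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired exercise metabolomics and oximetry in LEAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exermet)
```

# Scope

`exermet` analyses paired blood metabolomes — one sample at rest, one a few
minutes after a treadmill test — in patients with lower-extremity artery
disease (LEAD), jointly with exercise transcutaneous oximetry (TcPO2). The
pipeline is: quantitation-range QC of a 188-analyte targeted panel, a paired
(multilevel) PCA outlier screen, paired PLS-DA validated by an
exhaustive-combination resampling ensemble, VIP/loading-based discriminant
selection, and Pearson correlation of exercise-induced metabolite changes
with clinical severity indices (ABI, summed-DROP severity index, maximum
walking time, WELCH score). Because no patient-level cohort is available, a
ground-truthed synthetic generator reproduces the statistical structure the
analysis assumes, and every stage is tested against it.

# The panel and quantitation-range QC

The AbsoluteIDQ p180 panel quantifies 188 endogenous metabolites: free
carnitine, 39 acylcarnitines, the hexose sum, 21 amino acids, 21 biogenic
amines and 105 lipids (14 lysoPC, 38 diacyl-PC, 38 acyl-alkyl-PC, 15 SM).
Lipid species names encode the summed chain length and double-bond count
(`PC aa C42:6`), which `parseLipidName()` recovers. The shipped
quantitation limits are order-of-magnitude per-class placeholders — real
analyses must supply kit calibration limits via `buildP180Panel(lloq=,
uloq=)`.

A concentration is reliable only inside its calibration range
(LLOQ–ULOQ). `quantitationFilter()` removes metabolites with more than 20%
of values out of range (strict `> 0.20`). In the 20–40% band a 2x2
chi-squared test (plain Pearson, no continuity correction; configurable)
of in/out-of-range status against the rest/post condition is recorded
before removal, because condition-dependent missingness is itself a signal
— a warning is raised when its p < 0.05, and `retainIfDependent = TRUE`
keeps such metabolites. Out-of-range values in retained metabolites are
clamped to the violated limit (alternative: LLOQ/2). Clamped values lie
inside the range, so the filter is idempotent.

The three ratio indicators are kynurenine/tryptophan, SDMA/arginine and
MUFA(PC)/SFA(PC). Saturation for the last is resolved at species level on
the summed-chain annotation: SFA(PC) sums all PC (aa + ae) species with 0
double bonds and MUFA(PC) those with exactly 1. Chain-level saturation
cannot be recovered from summed-chain names, so the species-level
convention is the only one the naming supports; it is documented rather
than configurable.

# Exercise oximetry

Eight heated probes record TcPO2 (mmHg): two chest references and
buttock/thigh/calf probes on each side, over 2 min standing rest, a
treadmill phase (speed ramping 1 to 3.2 km/h over the first minute, 10%
slope, at most 15 min) and 10 min standing recovery. The DROP index is the
limb change from its rest mean minus the chest reference change from its
rest mean; the reference is the left chest probe, falling back to the
right one on probe failure. Per limb probe the minimal DROP is taken over
a window from exercise start to the end of recovery (configurable to
exercise only: the minimum often occurs shortly after exercise stops, so
the wider window is the default). Ischemia is a minimal DROP strictly
below -15 mmHg; systemic hypoxemia a chest decrease strictly above 5
mmHg; the severity index is the summed magnitude of the six limb minimal
DROPs, with positive minima clipped to zero so the index is non-negative
and monotone in ischemia depth.

Numerical choices: the rest baseline is the arithmetic mean of the rest
phase; series are smoothed with a centred 30-s moving average (window
shrinking at the edges) before extrema are taken, matching the slow
(tens of seconds) response of heated transcutaneous electrodes — without
smoothing, the minimum of a noisy trace is biased downward by the noise
floor rather than the physiology. Irregular sampling is handled by the
shared time base of the recording.

# Multilevel (paired) decomposition and PLS-DA

Each subject contributes a rest and a post row. The multilevel split
writes each row as subject mean plus within-subject deviation; for a pair
with difference `d = post - rest` the within rows are `-d/2` and `+d/2`,
and `within + between + grand` reconstructs the input exactly. Paired PCA
and paired PLS-DA operate on the within part, which removes
between-subject concentration differences and isolates the exercise
response. The within split is subject-local, so computing it once on the
full dataset leaks nothing across resampling splits.

Autoscaling (centre, unit variance, denominator n-1) is refit inside
every training split and applied frozen to validation and test samples.
The split-then-scale order is a choice the source design leaves open; it
is the leakage-safe one.

PLS-DA is NIPALS PLS1 on the class vector coded 0 = rest, 1 = post and
centred: per component the weight vector is the normalised covariance
X'y, scores t = Xw, X-loadings p = X't/t't, Y-loading q = y't/t't, then
deflation of X and y. Components are sign-fixed so q > 0, making a
positive variable loading mean "higher after exercise". Two latent
variables are the default. Variable importance is the standard VIP with
unit-norm weights and per-component Y-variance weights; mean squared VIP
is 1, so VIP >= 1 flags above-average contribution.

The PC1 outlier screen replaces a visual call with an explicit rule: a
sample whose PC1 score deviates from the median by more than 5 MAD-based
robust SDs flags its subject, and both the subject's samples are removed.

# The combination ensemble

Subjects — never individual samples — are allocated, so both members of a
pair travel together (sample-level splitting would let a subject's rest
sample train and its post sample validate, which is leakage under the
mirror structure). Nine test subjects are drawn once with a required
seed; the remaining pool of 30 is split 20 training / 10 validation by
walking the lexicographic enumeration of 20-subsets: C(30,20) =
30,045,015 combinations, thinned every 1,287 columns to 23,345 models.
Neighbouring columns differ by one subject, which is the rationale for a
large stride; columns are reconstructed on demand by combinatorial-number-
system unranking, so the combination matrix is never materialised.

Each model is evaluated on its validation subjects by AUROC
(Mann-Whitney formulation, mid-ranks for ties) of the predicted class
score, plus a two-sided Mann-Whitney p-value (exact when n0*n1 <= 400 and
tie-free, tie-corrected normal approximation otherwise; the source design
names only "the p-value associated with the AUROC", so the test choice is
ours and recorded here). Aggregation uses medians throughout. The global
gate requires median validation AUROC >= 0.8 and median p <= 0.05; if it
fails, discriminant selection is suppressed. Best models (validation
AUROC >= 0.95 by default; empty selections fall back to the top decile
with a warning) are applied to the held-out test subjects, and
per-metabolite VIPs and component-1 loadings, per-sample latent scores
and test AUROC/p are aggregated across best models by the median. The
volcano table flags median VIP >= 1 and takes direction from the median
loading sign (negative = decreased after exercise).

A caveat worth stating: validation predictions of a paired model are
exactly antisymmetric within each subject pair, so a sample-level
Mann-Whitney p-value on 2k validation samples behaves like one on k
independent units and is anti-conservative under the null (empirically
~15% of null models reach p < 0.05 at nominal 5%). Model selection
therefore leans on the AUROC medians and the gate; the p-values are
reported as the study design prescribes but should not be read as
calibrated per-model error rates.

# The synthetic cohort generator

Concentrations are log-normal: `log C = mu_j + b_i + s/2 * delta_j + eps`
with class-typical baselines `mu_j`, a subject random effect `b_i`
(SD 0.5 log units), residual noise (SD 0.25) and `s = -1/+1` for
rest/post. Positivity and right skew are generic features of targeted
metabolomics concentrations; the model is a generator assumption, not an
empirical claim. The study-scale scenario (`paperLikeConfig()`) has 39
subjects; 38 metabolites censored below the LLOQ at a 35% rate (placing
each LLOQ at the 35% quantile of that metabolite's marginal), so the QC
filter retains 150; and 71 discriminant metabolites at log-effect 0.6
(about 1.8-fold, a typical magnitude for a strong acute-exercise response)
— 4 decreased (spermine, putrescine, serine, methionine sulfoxide) and 67
increased (C2, C12, C16, alanine, glutamine, acetylornithine,
alpha-aminoadipate, 9 SM, 7 lysoPC, 44 PC species).

TcPO2 traces are piecewise: rest plateau, linear decline to a 60-s trough
plateau placed so the DROP reaches the target minimum, exponential
recovery (time constant 120 s), chest probes declining by the configured
hypoxemia amount, additive Gaussian noise of SD 1 mmHg. Severity scores
are drawn at study-typical locations (ABI 0.67 +/- 0.17, MWT 420 +/- 150 s,
WELCH 25 +/- 10); the DROPs score is the severity index computed from the
simulated recordings through the oximetry module itself. Configured
metabolite-score couplings are injected through a bivariate-normal copula
on the standardized log-ratio exercise change, which is exactly Gaussian
under the model — coupling on the raw-scale delta would let lognormal
leverage points inflate the realised Pearson correlation past its target.

What the generator does not emulate: instrument drift, batch and plate
effects, correlated metabolite blocks beyond the shared subject effect,
missingness other than range censoring, and probe artefacts other than
white noise. Passing tests therefore demonstrate that the pipeline
recovers structure it assumes, not that the assumptions hold in real
cohorts.

# Problem sizes and determinism

The test suite and the acceptance script run scaled-down ensembles chosen
to exercise the full code path at interactive cost: the study-scale
cohort uses ~500 of the 30,045,015 combinations (stride ~60,000); the
full 23,345-model run at stride 1,287 is a documented option of the
command-line tool (`--stride 1287`, minutes on one CPU). Null calibration
is judged over replicate null cohorts (pool 12 / train 8 / 495 models
each): within one cohort the models recycle the same 12 subjects and with
4 validation subjects the AUROC lives on a 1/16 grid, so a single
cohort's median is coarse and noisy; the mean over cohorts of the
per-cohort median is continuous and centred on 0.5 under the null, and is
the statistic checked.

Every stochastic component takes an explicit seed; a master seed fans out
to per-stage seeds through a seeded integer draw, and identical
configuration plus seed reproduces byte-identical outputs (checksummed in
the run manifest).

# Limitations

- Quantitation limits ship as placeholders; QC decisions on real exports
  require the kit's calibration limits.
- The per-model p-value is anti-conservative under pairing (above); the
  gate and AUROC medians carry the inferential weight.
- Severity correlations are unadjusted for multiplicity by design,
  mirroring the source analysis; the report labels them as such.
- The generator's independence assumptions make discriminant recovery
  easier than in real plasma, where lipid species are strongly
  co-regulated; recovery rates on synthetic data are upper bounds.
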