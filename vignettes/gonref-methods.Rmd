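---
title: "Methods: an objective GON reference standard and its evaluation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an objective GON reference standard and its evaluation machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonref)
```

## The classification model

The package's core is a deterministic rule that labels an SDOCT–SAP exam
pair *glaucoma*, *normal* or *suspect*. Its central assumption is that
glaucomatous damage is only unambiguous when structure and function agree
spatially: because the retinal nerve fibre bundles arch above and below the
fovea, a superior RNFL defect projects to the **inferior** visual hemifield
and vice versa. The three glaucoma criteria in `classify_gon()` encode
exactly this — global structural loss with any field abnormality, or a
localized superior (inferior) sector defect with a depressed inferior
(superior) hemifield MD. The normality criterion is deliberately demanding
(all seven flags within limits, GHT within limits, PSD not significant), so
the suspect class absorbs every ambiguous configuration, including
borderline flags. Suspects are excluded from accuracy evaluation: mixing
uncertain diagnoses into either class would bias sensitivity and specificity
in unknown directions.

Two readings of the rule were genuinely open and are fixed as follows.
"PSD p < 5%" means any significant p-category (`lt5` through `lt0.5`), and
"not significant" is the literal device category. Hemifield abnormality uses
strict `<` against the cutoff, mirroring "p < 5%". Whether "all sectors" in
the normality criterion includes the temporal and nasal sectors is
ambiguous on the original wording; the package requires all six, which makes
normality stricter and never changes a glaucoma call (the T and N flags
provably never enter the glaucoma criteria — the test suite verifies this by
perturbation over the full category lattice). Severity staging uses the
paired SAP's MD with the standard Hodapp–Parrish–Anderson boundaries, early
above −6 dB, moderate on the closed interval [−12, −6] dB, severe below
−12 dB; the boundary placement at exactly −6 and −12 follows the published
classification, with the ties assigned to moderate.

## Hemifield MD and normative cutoffs

`hemifield_md()` averages the 26 total-deviation values of each hemifield of
the fixed 52-point 24-2 grid (54 points minus the two blind-spot points).
Coordinates are stored in mapped right-eye orientation for both eyes; a
strict left-eye mirroring is impossible on this grid (the blind-spot column
and the 30° nasal column make it x-asymmetric), and unnecessary — every rule
consumes only the sign of y.

`derive_hemifield_cutoffs()` takes the empirical percentile (default 5th,
linear interpolation between order statistics, `quantile` type 7) of the
per-eye hemifield MDs of a healthy reference sample, by default 462 eyes of
231 subjects. The two eyes of a subject are treated as independent for the
percentile point estimate; a clustered quantile estimator would change the
point estimate negligibly relative to its sampling noise and has no
standard form. Below 40 reference eyes the function warns and proceeds.

## Diagnostic accuracy

`auc()` is the Mann–Whitney concordance (midranks, ties credit 0.5).
Age differs systematically between glaucoma and normal groups in clinical
registries, and any score correlated with age inherits spurious
discrimination. `age_adjusted_auc()` removes this by the placement-value
construction: a linear location model of control scores on age is fitted,
each case's residual is ranked against the empirical control residuals, and
the adjusted AUC is the mean of those (mid-)CDF values. The mid-CDF carries
the same tie credit as the pooled estimator, so with a constant covariate
the two coincide **exactly**; under independence they agree up to sampling
noise; under pure age confounding the adjusted value drops to the binormal
form Φ(δ/σ√2) of the residual model. The location model is linear and
homoscedastic by design — with a heteroscedastic age effect the adjustment
would be approximate; this is a documented limitation, not a detected one.

Sensitivity at fixed specificity uses the conservative step-function ROC:
the smallest observed threshold whose control specificity reaches the
target. The adjusted variant is the fraction of case placement values at or
below 1 − specificity.

Because eyes contribute many photos, confidence intervals resample **eyes**,
not photos: `cluster_bootstrap_ci()` draws clusters with replacement,
carries all records of a drawn cluster, and takes percentile intervals
(default 2000 replicates). Replicates on which the statistic fails (e.g. a
resample losing one class) are dropped with a warning; more than 10%
failures aborts, since the percentile interval would no longer be
trustworthy. Severity strata are each contrasted against **all** controls —
the controls are a single reference population, and stratifying them would
change the question being asked.

## Interval likelihood ratios

`interval_lr_table()` bins scores on the percent scale (default edges 0,
0.1, 1, 10, 50, 90, 99, 99.9, 100; left-closed, last bin closed, so a score
of exactly 99% falls in the 99–99.9 bin) and forms
LR(bin) = [n₁(bin)/N₁] / [n₀(bin)/N₀]. Zero-control bins give +∞ (flagged),
empty bins NaN; an optional Haldane +0.5 correction exists but is off by
default because the reference analysis uses raw counts. Reported values are
rounded to 2 decimals below 10 and 3 significant figures above, with raw
values retained. Effect bands: large above 10 or below 0.1, moderate (5,10]
or [0.1,0.2), small (2,5] or [0.2,0.5), else insignificant.
`posttest_probability()` is Bayes on the odds scale, with 0 and 1 as fixed
points. Two identities anchor the tests: per-group bin probabilities sum to
one, and averaging post-test probability over bins with the marginal bin
frequencies returns the prevalence exactly.

## Agreement

`adjudicate()` implements two-grader consensus with third-grader
resolution. `weighted_kappa()` supports linear and quadratic weights over
the ordered categories normal < suspect < glaucoma; the reference analysis
says only "weighted kappa", so both are exposed and linear is the default
(reported alongside the weighting used). On 2×2 tables both weightings
collapse to unweighted Cohen's kappa, which the tests exploit as an
independent cross-check.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a clinical
registry; it exists so every stage of the machinery can be exercised and
calibrated against known truth. Defaults are matched to the registry's
printed cohort: glaucoma subjects older than normals (62.8 ± 15.8 vs
52.9 ± 15.7 years, truncated to [21, 95]) so that age adjustment has real
work to do; healthy global RNFL ≈ 98.3 µm with SD ≈ 11.5 µm declining
2 µm/decade; glaucomatous global RNFL ≈ 67 µm. Per eye, a latent severity
s ≥ 0 (gamma, mean 29.5 µm, shape 2, truncated at 85 µm; exactly 0 for
normal eyes) drives everything:

- **Structure**: sector thickness = healthy mean − age decline − loss +
  shared eye factor + sector noise. Diffuse defects spread s uniformly;
  localized defects keep 30% diffuse and concentrate 70% in the two
  affected sectors (scaled by arc weight so the weighted loss stays s),
  floored at 25 µm. The global average is its own measurement channel,
  healthy mean ≈ 98.25 µm (the arc-weighted sector mean) minus s.
- **Function**: hemifield depression = 0.3 dB/µm × s, doubled in the
  hemifield opposite a localized defect and damped to 0.2× in the other —
  this is the structure–function correspondence the classifier relies on.
  Point noise SD 1.5 dB, eye-level shift SD 1 dB, values clamped to
  [−35, 10] dB. MD is the unweighted mean and PSD the SD of the 52 points;
  exact perimeter weightings are unpublished detail the rules never use.
- **Device categories**: flags are percentile thresholds (1st/5th) on the
  age-conditional healthy normal model — so a healthy-only cohort shows
  ≈1% outside flags per sector by construction. The GHT surrogate flags
  the absolute hemifield-mean difference beyond thresholds calibrated in
  closed form to 1% (outside) and 5% (borderline) false-positive rates,
  or joint depression below −3 dB; the proprietary algorithm is not
  replicated because only the category reaches the classifier. PSD
  p-categories come from the closed-form healthy sampling distribution
  σ√(χ²₅₁/51).
- **Score**: `plogis(0.35 s − 6 + ε)`, ε ~ N(0, 1.8) per photo. The link is
  monotone in severity, so interval LRs rise over bins, and the implied
  population AUC has a closed form (`implied_score_auc()`): binormal
  Φ(a·s̄/σ√2) for degenerate severity, numerically integrated over the
  gamma otherwise. Second eyes of glaucoma subjects are glaucomatous with
  probability 0.6, and repeated visits share eye-level factors, making the
  eye-level bootstrap consequential.

One seeded stream draws per-table sub-seeds, then each table has its own
stream — same seed, byte-identical tables. The generator does **not**
simulate image artifacts, media opacity, longitudinal progression,
floor-effect perimetry nonlinearity, or real GHT/PSD algorithms; passing
tests therefore demonstrate correctness of the machinery under a plausible
data-generating model, not performance on real registry data. In
particular, the synthetic score separation is tuned for exercising the LR
and ROC stages, and end-to-end AUCs near 0.95–0.99 on synthetic cohorts say
nothing about any real classifier.

## Numerical choices and degenerate inputs

Pairing ties (equidistant tests) break to the earlier date, and inputs are
sorted before matching, so results are invariant to row order. "Within six
months" is ≤ 180 days everywhere, inclusive. QC boundaries follow the
wording exactly: fixation losses of exactly 33% and false positives of 15%
are kept, quality 15 is kept. Empty strata yield NA rows; a zero-width
pairing window yields empty downstream tables and a clean exit; constant
suspect scores make quartiles undefined and raise an error rather than an
arbitrary split. Quartile membership is right-closed against type-7
quantiles. Rank-sum p-values in the suspect contrast treat photos as
records; within-eye correlation is ignored there, and the output documents
that caveat.

## Problem sizes

The shipped tests run the classifier lattice exhaustively (218,700
combinations), the AUC oracle on 1000 random instances, cutoff recovery on
20,000 eyes, bootstrap coverage on 500 simulation replicates at 500
resamples each, and end-to-end synthetic runs of 250–1000 subjects — sizes
chosen so Monte-Carlo error is well inside each assertion's tolerance while
the suite stays comfortably interactive.
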