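# gonref

An objective structural–functional reference standard for glaucomatous optic
neuropathy (GON), and the full evaluation machinery for continuous diagnostic
scores graded against it.

## The problem

Glaucoma has no agreed-upon reference standard. Human gradings of optic-disc
photos are poorly reproducible, which undermines any diagnostic algorithm
trained or evaluated against them. `gonref` implements a rule-based
alternative: an eye is labelled *glaucoma* only when structural damage on
spectral-domain OCT (peripapillary retinal nerve fibre layer, RNFL) is
accompanied by **corresponding** functional damage on standard automated
perimetry (SAP, 24-2), in the spatially consistent hemifield. The package is
aimed at researchers evaluating screening scores (e.g. the output of an image
classifier) against such a standard.

## The reference standard

For an SDOCT–SAP pair acquired within 180 days of each other, the label is
**glaucoma** if any of:

1. *Global loss* — global RNFL flag outside normal limits **and** abnormal
   SAP (Glaucoma Hemifield Test outside normal limits **or** PSD p < 5%);
2. *Localized superior loss* — temporal-superior or nasal-superior RNFL flag
   outside normal limits **and** inferior hemifield MD < 5th percentile of a
   healthy reference sample;
3. *Localized inferior loss* — temporal-inferior or nasal-inferior RNFL flag
   outside normal limits **and** superior hemifield MD below its cutoff.

The label is **normal** only when the global and all six sector flags are
within normal limits, GHT is within normal limits, and PSD is not
significant. Everything else — including isolated structural or functional
findings and borderline results — is a **suspect**, excluded from accuracy
evaluation but analysed separately.

Hemifield MD is the mean of the 26 total-deviation values in each hemifield
of the 24-2 grid; its normative cutoffs are empirical percentiles of a
healthy sample (by default 462 eyes of 231 subjects).

Around the rule, the package provides:

- **QC and pairing** — reliability exclusions (fixation losses > 33%, false
  positives > 15%, OCT quality < 15), nearest-date SDOCT–SAP pairing, photo
  matching, subject-level 80/20 splits.
- **Accuracy evaluation** — empirical ROC/AUC (Mann–Whitney concordance),
  age-adjusted AUC via placement values (each case's score ranked against
  the age-conditional control distribution), sensitivity at fixed
  specificity, eye-level clustered bootstrap CIs, Hodapp–Parrish–Anderson
  severity strata (early > −6 dB, moderate −6 to −12 dB, severe < −12 dB).
- **Interval likelihood ratios** — `LR(bin) = P(bin | D) / P(bin | ¬D)` over
  score bins (0–0.1, 0.1–1, …, 99.9–100 %), Bayesian post-test updating
  (`post-odds = LR × pre-odds`), and effect bands (LR > 10 or < 0.1: large).
- **Agreement** — three-grader adjudication and linear/quadratic weighted
  kappa over the ordered categories normal < suspect < glaucoma.
- **Synthetic cohorts** — a seeded generator emulating a clinical registry
  (age-confounded groups, structure–function correspondence, device flags,
  tunable score separation) used throughout the tests.

## Worked example

```r
library(gonref)

# Interval likelihood ratios from a published-style contingency table
tab <- lr_table_from_counts(c(38, 32, 57, 70, 78, 141, 146, 499),
                            c(604, 141, 116, 86, 47, 36, 14, 13))
tab[c("bin_label", "n_diseased", "n_nondiseased", "lr_printed", "effect")]
#>   bin_label n_diseased n_nondiseased lr_printed        effect
#> 1     0-0.1         38           604       0.06         large
#> 2     0.1-1         32           141       0.23         small
#> 3      1-10         57           116       0.49         small
#> 4     10-50         70            86       0.81 insignificant
#> 5     50-90         78            47       1.65 insignificant
#> 6     90-99        141            36       3.90         small
#> 7   99-99.9        146            14      10.40         large
#> 8  99.9-100        499            13      38.20         large

# A screening case: 5% pre-test probability, top-bin result
100 * posttest_probability(0.05, 38.2)
#> [1] 66.8
```

A score of 99.9%+ carries LR 38.2: in a screening population with 5%
prevalence it lifts the probability of GON to ~67%, grounds for referral.
A score below 0.1% (LR 0.06) drops a 50% pre-test probability to 5.7%.

The full pipeline on a synthetic cohort:

```r
b <- run_pipeline(run_config(simulate = list(n_subjects = 300L),
                             n_boot = 500L, seed = 1L))
#> [gonref] simulated cohort: 300 subjects, 1200 scans, 1200 fields, 2400 photos (seed 1)
#> [gonref] QC: 1132/1200 fields reliable, 1146/1200 scans adequate quality
#> [gonref] pairing: 1116 pairs, 30 scans unpaired
#> [gonref] classification: 328 glaucoma, 485 normal, 303 suspect
#> [gonref] photo matching: 2318 labeled photos, 82 unmatched
#> [gonref] split: 1842 train photos, 476 test photos (365 eval, 111 suspect)

b$cutoffs
#> Hemifield MD cutoffs (5th percentile of 462 reference eyes):
#>   superior: -1.58 dB
#>   inferior: -1.74 dB
round(b$auc[c("auc", "ci_lower", "ci_upper", "sensitivity_at_95_spec")], 3)
#>     auc ci_lower ci_upper sensitivity_at_95_spec
#> 1 0.990    0.980    0.997                  0.944
#> 2 0.989    0.974    0.998                  0.965
```

Row 1 is the pooled estimate, row 2 the age-adjusted one; CIs come from the
eye-level clustered bootstrap. `b$severity` holds the per-stage table (AUC
rises from 0.93 in early to 1.00 in severe disease in this run), `b$lr_table`
the interval LRs of the synthetic score, and `b$suspect_quartiles` the
contrast of top- versus bottom-quartile suspects.

A thin CLI wrapping the same functions lives at
`inst/scripts/gonref-cli.R` (`simulate`, `run-all`, `posttest` subcommands,
YAML config via `read_run_config()`).

## Input schemas

All inputs are UTF-8 CSV with `.` decimal and ISO 8601 dates, read by
`read_sdoct_table()`, `read_sap_table()`, `read_photo_table()`,
`read_subject_table()`. Rows failing validation are returned in a report
with reason codes, never silently dropped.

| file | columns |
|---|---|
| `sdoct.csv` | `subject_id, eye (OD/OS), scan_date, quality_score, rnfl_global, rnfl_T, rnfl_TS, rnfl_NS, rnfl_N, rnfl_NI, rnfl_TI, flag_global, flag_T, ... flag_TI` (flags: `within/borderline/outside`) |
| `sap.csv` | `subject_id, eye, test_date, md, psd, psd_p (not_significant/lt5/lt2/lt1/lt0.5), ght, fixation_loss_frac, false_positive_frac`, plus 52 `td_*` columns named by 24-2 grid coordinate (e.g. `td_n27p03` = x −27°, y +3°) |
| `photos.csv` | `subject_id, eye, photo_date, score` (in [0,1]), `camera_id` |
| `subjects.csv` | `subject_id, age, sex, race` |

Total-deviation columns are in mapped right-eye orientation for both eyes
(the blind-spot points at (+15°, ±3°) are excluded); all classification
logic uses only the superior/inferior axis, so laterality never affects the
rules.

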