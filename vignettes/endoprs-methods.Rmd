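---
title: "Methods: liability-threshold simulation and PRS-comorbidity interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: liability-threshold simulation and PRS-comorbidity interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoprs)
library(dplyr)
```

## The scientific problem

Endometriosis co-occurs with a wide range of other diagnoses, and its
heritable component can be summarized in a polygenic risk score (PRS). Two
questions follow naturally in a biobank setting:

1. **Which diagnosis codes are comorbid with endometriosis?** — a
   phenome-wide scan of ICD-10 codes against case status.
2. **How do polygenic risk and diagnosed comorbidities combine?** — is the
   extra endometriosis risk conferred by a comorbidity constant across the
   PRS distribution (no additive interaction), and does the product term of
   a logistic model vanish (no multiplicative interaction)?

A subtler, third question concerns what conditioning on disease status does
to these relationships. Under a liability-threshold model, disease occurs
when a latent liability — the sum of many small genetic and environmental
contributions — exceeds a threshold. Among people *over* the threshold
(cases), a high genetic contribution implies, on average, a smaller
environmental contribution: selecting on case status induces a negative
correlation between causes that are independent, or even positively
correlated, in the population. This index-event (collider) effect predicts
that the PRS-comorbidity-burden correlation is positive in controls but
negative in cases, and hence that the PRS × status interaction on burden is
negative. `endoprs` implements the full pipeline and a generative model in
which that signature can be produced, measured and tested, with no access
to restricted individual-level biobank data.

## The generative model

Every simulated individual *i* receives three independent standard-normal
draws: a genetic score $g_i$, a latent shared factor $C_i$ (non-genetic
risk common to endometriosis and its comorbidities — e.g. inflammation,
healthcare-relevant physiology), and noise $e_i$. The endometriosis
liability is

$$L_i = \sqrt{r^2}\, g_i + b\, C_i + \sqrt{1 - r^2 - b^2}\; e_i,$$

so $\mathrm{Var}(L) = 1$ by construction, and individual *i* is a case iff
$L_i > \Phi^{-1}(1 - K)$ with $K$ the prevalence. Each comorbidity $j$ has
its own unit-variance liability re-using $g$ and $C$,

$$L_{ij} = \alpha_j\, g_i + \beta_j\, C_i +
  \sqrt{1 - \alpha_j^2 - \beta_j^2}\; \varepsilon_{ij},$$

thresholded at its own prevalence; a diagnosis appends the comorbidity's
4-character ICD-10-style code to the participant's stream. Cases carry the
code `N809`. On top sits a Poisson number of *background* diagnoses drawn
uniformly from per-chapter code pools, independent of status by default; an
optional log-linear, mean-preserving coupling of the individual background
rate to $C$ is available to emulate healthcare-exposure confounding, so
tests can isolate the collider mechanism from utilization effects.

### Default parameters and why

| Parameter | Default | Rationale |
|---|---|---|
| `n_individuals` | 200,000 | of the order of a large biobank case-control extract; big enough that the qualitative signatures are stable across seeds |
| `endo_prevalence` | 0.0556 | the case fraction of a 1:17 matched case-control cohort (5,432/97,776) |
| `prs_r2` | 0.26 | all-common-SNP heritability scale for endometriosis; the package treats it as the liability variance explained by the score |
| `shared_factor_loading` ($b$) | 0.45 | a substantial but sub-dominant shared-environment path; $r^2 + b^2 < 1$ leaves half the variance idiosyncratic |
| comorbidities | 20 codes, $\alpha = 0.1$, $\beta = 0.5$ | six index comorbidities (asthma, diverticular disease, irritable bowel syndrome, uterine fibroids, dysmenorrhea, heavy menstrual bleeding) at field-typical prevalences (0.05–0.12) plus fourteen conditions at 0.07; mild pleiotropy, strong shared factor |
| `background_rate` | 5 | yields a control mean total 3-character burden of about 5, matching the magnitude seen in biobank hospital records |
| `age_range` | 40–69 | a typical adult-biobank recruitment window |
| `control_case_ratio` | 17 | ≈ 92,344/5,432 |

`prs_r2` deserves a caveat: a realized PRS built from genome-wide summary
statistics explains far less liability variance than the full SNP
heritability, which is why biobank AUCs sit near 0.60 while this
simulation's true-score AUC at $r^2 = 0.26$ is about 0.80. The package
deliberately simulates the *true* standardized genetic score by default —
PRS accuracy is an emergent property to check (AUC 0.5 at $r^2 = 0$,
strictly increasing in $r^2$), not an input to calibrate. The genotype mode
(`simulate_genotypes()` + `score_genotypes()`) exists to exercise
file-based scoring: the standardized weighted dosage sum is used as $g$, so
phenotypes and genotype files stay mutually consistent.

Ages are drawn independently of every liability. Real cohorts are
age-matched precisely to remove age effects, so simulating them would only
add nuisance structure that the pipeline is designed to cancel;
`age_match_controls()` is still provided (greedy nearest-age matching
without replacement, tolerance exposed as a parameter because matching
algorithms are rarely reported in enough detail to copy).

## Code handling and burden metrics

Codes are stored dot-less and uppercase (`N80.1` → `N801`), so "3-character"
and "4-character" refer to string length without the dot. 5-character codes
are simplified to 4 characters before any analysis. A native 3-character
code is a legitimate member of a 4-character analysis set: resolutions are
maxima, not exact lengths. Chapter assignment follows the WHO ICD-10 ranges
(A00–B99 → 1, …, U00–U99 → 22); stems falling in classification gaps (e.g.
`D49`) raise an error rather than being guessed, so dialect mismatches in
loaded data fail loudly.

Burden counting applies, in order: normalization, exclusion (chapters 19–21
— injuries, external causes, health-service contact — plus the
endometriosis subcodes `N801`–`N809`), truncation, and per-person
deduplication. `N800` (adenomyosis) is retained by default since the
excluded range is stated as N80.1–N80.9; a `drop_all_n80` flag removes the
whole stem. Deduplication happens after 5→4 simplification. Comorbid
membership is decided at 4-character resolution against a scanned code set
and then reduced, mirroring a scan that is itself run at 4 characters.
Chapter-wise counts and leave-one-chapter-out counts (full count minus the
chapter's count — an exact identity, tested as such) use the 3-character
stems.

### The cross-cohort contract

Counting a cohort's burden against a comorbid set discovered *in the same
cohort* inflates the case-control burden difference by construction. The
pipeline therefore scans cohort A, counts in cohort B with A's set, and
vice versa. Code-set objects carry the label of the cohort they were
derived from, and `count_burden()` refuses a same-label combination unless
`allow_same_cohort = TRUE` is passed explicitly.

## The statistical toolkit

* **Per-code association** (`test_code_association()`): Pearson chi-squared
  without continuity correction, switching to Fisher's exact test
  (two-sided, point-probability method) when any expected cell is below 5 —
  the most common epidemiological convention; the switch lives in one
  function so a sensitivity analysis can replace it. Odds ratios are plain
  cross-products with `Inf`/`0` sentinels on zero cells; the
  Haldane–Anscombe +0.5 correction is opt-in because direction filtering
  only needs the side of 1.
* **Multiplicity** (`bh_fdr()`): Benjamini–Hochberg at $q = 0.05$, applied
  over *all* tested codes before any exclusion, because the biobank
  workflow filters the significant set afterwards. "Significant decreased
  risk" for the direction filter means FDR-significant with OR < 1 (the
  same FDR set, not a separate nominal test).
* **PRS scoring** (`score_genotypes()`): plink-style average-per-allele
  scores, $\sum_m w_m d_{im} / (2 M_i)$, with missing dosages imputed to
  twice the effect-allele frequency when available, else dropped with the
  divisor adjusted. The convention is irrelevant after z-scoring but fixed
  for reproducibility. Standardization is over the combined case-control
  cohort with the $n-1$ standard deviation.
* **Stratification** (`assign_quantiles()`): rank-based bins of maximally
  even size; ties broken by stable id order (with a warning when all scores
  tie). Per-bin odds ratios are unconditional 2×2 tables against the middle
  bin with Woolf (log-normal) confidence intervals — chosen over per-bin
  logistic models as the simplest estimator consistent with reporting a
  reference-bin OR of exactly 1.
* **AUC** (`roc_auc()`): the Mann–Whitney U statistic over case-control
  pairs, ties counted one half; verified against brute-force pair counting
  and against pROC.
* **Interaction models**: `burden_prs_interaction()` fits
  `burden ~ prs + status + prs:status` by OLS with classical
  (homoskedastic) standard errors — robust (HC1) errors are behind a flag,
  not the default, because the reference analyses report plain linear
  regressions on counts. `multiplicative_interaction()` fits
  `status ~ prs + comorbidity + prs:comorbidity` by IRLS logistic
  regression; separation is detected and reported as non-convergence with
  coefficients withheld. `additive_interaction()` tabulates per-PRS-decile
  endometriosis prevalence with and without the comorbidity and summarizes
  the top-to-bottom-decile ratio of the absolute differences, reported to
  one decimal place by convention. No age covariates enter the default
  models: the cohorts are age-matched (or age-independent) by construction.
  No formal test is attached to the decile-difference ratio; it is a
  descriptive statistic, and the trend assertion in the test suite is a
  Spearman correlation across deciles.

### Additive vs multiplicative scales

The two scales can disagree, and the package's test suite asserts that they
*do* disagree under the default parameterization: the absolute prevalence
increase upon comorbidity diagnosis grows steeply across PRS deciles (an
additive-scale synergy) while the logistic product term is zero or negative.
This is not a contradiction: the multiplicative statistic is anchored to
baseline (without-comorbidity) risk, which itself rises steeply with PRS,
so a constant-or-shrinking odds multiplier can coexist with a growing
absolute risk difference. Interpreting a negative product term as a
protective interaction would be an artifact of scale.

## What the simulation does and does not show

The generator reproduces the *mechanistic* features the analyses rely on:
unit-variance liabilities, threshold case definition, pleiotropic and
shared-factor paths from PRS and a latent factor into comorbidity
liabilities, status-independent background coding, and deterministic
seeding. Passing tests therefore demonstrate that the pipeline recovers
known signatures from data generated under its own assumed model —
internal validity.

They do not demonstrate external validity. Real diagnosis streams have
longitudinal structure, source heterogeneity (self-report vs hospital vs
primary care; the simulator has a single stream), age- and
utilization-dependent coding intensity, code frequency distributions far
more skewed than uniform chapter pools, and PRS measurement error. In
particular, the simulated case-control PRS separation (AUC ≈ 0.80 at the
default $r^2$) is deliberately the *upper bound* implied by the heritability
parameter, not the accuracy of any realizable score.

## Numerical choices and degenerate inputs

* Thresholds are standard-normal quantiles of stated prevalences; no
  empirical recalibration is performed.
* All randomness flows from explicit integer seeds; pipeline stages derive
  per-stage seeds from one root via `derive_seed()` (kept below $2^{31}$),
  so adding a stage never perturbs earlier stages' draws.
* A cohort realizing zero cases or zero controls aborts with an error
  naming the empty arm; a reference quantile bin without both classes,
  constant scores at standardization, rank-deficient designs (collinear
  columns are named), and empty case/control margins in a 2×2 all raise
  typed errors rather than returning numbers.
* p-values from the underlying tests are clamped to $[0,1]$ to absorb
  floating-point excursions.
* Empty decile arms in the additive table are flagged, excluded from the
  summary ratio, and warned about; an empty comorbid code set degrades the
  downstream stages to zero counts with warnings rather than failure.

## Problem sizes used by the test and acceptance runs

The packaged checks simulate cohorts of 200,000 for the index-event
signature (10 replicate seeds) and the AUC limit behaviour, 100 replicates
of 5,000 for the FDR and confidence-interval calibration studies, and
cohorts of 1,500–4,000 for pipeline round-trip and determinism checks.
These sizes were chosen so that every asserted signature is comfortably
powered (the collider interaction at the defaults is roughly $-0.3 \pm
0.03$ at $n = 200{,}000$) while a full run of the suite stays in the
low minutes on a single core.

## Known limitations

* Controls are simply non-cases; no exclusion of related gynecological
  conditions from the control pool is modelled, as the corresponding
  real-world criterion is not documented precisely enough to copy.
* The phenome scan fits no per-code covariate models (no age, no sex-
  specific denominators) — by design, since the cohorts are matched.
* ICD-9, ICD-10-CM and phecode dialects are out of scope; the code
  machinery is strict WHO ICD-10.
* GWAS summary-statistic production, Bayesian reweighting of SNP effects
  and conditioning on a second trait's genetics are upstream of this
  package: it consumes a finished weight table.
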