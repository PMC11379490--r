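---
title: "Methods: integrating a polygenic score with clinical 10-year CVD risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating a polygenic score with clinical 10-year CVD risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdprs)
```

## The question and the design

Clinical 10-year cardiovascular risk equations (QRISK2 in the UK, the
ASCVD pooled cohort equations in the US, SCORE2 in Europe) drive statin
and lifestyle decisions through fixed actionable thresholds, but they
flag only a fraction of the people who go on to have an event. A
cardiovascular polygenic risk score (CVD-PRS) measures a complementary,
largely age-independent component of risk. The question this package
operationalises is the clinically pointed one: if the PRS is folded into
the clinical score as an *integrated risk tool* (IRT) that reports on the
same percentage scale and threshold, how many additional future cases
would have been flagged as high risk at their health check?

The design it supports is a nested case-control study inside a screened
cohort: subjects who later had a major CVD event (cases, labelled by a
fixed hierarchy: CVD death, then MI/ACS, then PCI/CABG, then stroke) are
compared with event-free controls matched approximately 2:1 on a
propensity score built from age, sex, ethnicity, smoking status, BMI and
the clinical risk score. Because controls are selected to resemble cases,
population discrimination and calibration metrics (C-statistics, full
net reclassification) are deliberately out of scope; the headline
statistics are paired sensitivity comparisons within cases, a case-only
NRI, and the case-vs-control odds of up-classification.

## The integration model

Let $p$ be the clinical 10-year risk (as a fraction) and $z$ the
standardised PRS. The IRT risk is

$$\mathrm{irt}(p, z) \;=\; \operatorname{logit}^{-1}\!\big(
\operatorname{logit}(p) + \beta z - \tfrac{\beta^2}{2}\big),$$

with $\beta$ the log-odds per SD of PRS. The $-\beta^2/2$ offset is the
mean-preserving calibration: when $z \sim N(0,1)$ independently of $p$,
$E[e^{\beta z - \beta^2/2}] = 1$, so the mean event *odds* equal the
clinical odds and the IRT inherits the clinical score's threshold without
re-calibration. The offset is configurable (set it to 0 to mimic an
uncalibrated combination), and a single global offset is used — no
age/sex-specific recalibration is attempted, since nothing in the design
requires it and the data to fit one are not modelled.

$\beta$ defaults to $\log(1.6)$ per SD. This is a documented assumption:
an odds ratio near 1.6 per SD is typical of genome-wide CVD scores, and
the upstream publications that derived the deployed score do not restate
the exact value. Every function takes $\beta$ as a parameter, and the
synthetic generator uses the *same* value, which is what makes
parameter-recovery tests meaningful.

The generator is the exact inverse of this model: events are drawn with
$\operatorname{logit} P(\text{event}) = \operatorname{logit}(p) +
\beta z - \beta^2/2$. Both directions therefore share one set of
assumptions, and a pipeline run on synthetic data must recover a positive
sensitivity uplift whenever $\beta > 0$ — which the test suite checks
over 200 seeded replicates.

## Clinical scores

QRISK2 is licensed and is **not** re-implemented: in the design the score
arrives as data from GP records, and `qrisk2_passthrough()` treats it
exactly that way. For self-contained synthetic cohorts a clearly
labelled logistic **surrogate** maps the generated covariates to a score
with the location and spread of GP-recorded QRISK2 in a 40–74 screening
population (calibrated once, at design time, to mean ≈ 12% and SD ≈ 7–8%
to match the reported baseline tables; its coefficients are fixed
constants and it is labelled `surrogate` wherever it appears). It is not
QRISK2 and is never used where stored scores exist.

The ASCVD pooled cohort equations and SCORE2 are implemented from their
published coefficient tables, shipped as commented CSVs under
`inst/extdata/` so they can be inspected and independently re-evaluated
(the test suite does exactly that, term by term). Units are mmol/L and
mmHg at the interface; PCE converts cholesterol internally to mg/dL.
SCORE2's region recalibration defaults to the `low` risk region (a UK
cohort) and its age-banded high-risk thresholds default to the guideline
convention: 2.5% under 50, 5% at 50–69, 7.5% at 70+, all configurable.
Individuals of ancestries outside the PCE's two coefficient groups are
scored with the white coefficients, as its source guideline recommends.
Threshold categories are left-closed on the high side everywhere
(score ≥ threshold is high).

## PRS scoring and ancestry standardisation

Weights use the PGS-Catalog tab-delimited convention. Alignment matches
by variant id (falling back to chromosome:position), classifies matches
as direct or allele-flipped (effective dosage $2-d$), and excludes
strand-ambiguous A/T and C/G variants, because no strand information is
modelled. Missing dosages are mean-imputed ($2 \times$ effect-allele
frequency) by default; a skip-and-rescale policy is available. A subject
missing every aligned variant gets `NA`, never a silent zero.

Standardisation regresses raw reference-panel scores on $K$ principal
components of the reference genotypes and scales by the residual SD:
$z = (\mathrm{raw} - \hat\mu(\mathrm{PC}))/\hat\sigma$. A single
homoscedastic $\hat\sigma$ is used; the mean-only model is the default
because the published description of the deployed score promises only
"approximately zero mean and unit variance", and a PC-dependent variance
model adds parameters the synthetic data cannot constrain. With $K=0$
this degenerates to plain z-scoring. A residual SD below tolerance
(reference scores deterministic in the PCs) is an error, not a warning.

## Matching

Greedy 1-to-$k$ nearest-neighbour matching without replacement on the
logit propensity, processing cases in a randomised order under the run
seed, in passes (every case receives its first control before any case
receives its second). The caliper defaults to 0.2 SD of the logit
propensity — the standard choice; the source design reports no caliper —
and cases with no in-caliper control are retained and flagged, which is
what makes the achieved ratio "approximately" 2:1. Balance is summarised
as standardised mean differences; for categorical covariates each level
is scored as a binary indicator and the per-level SMDs aggregated as
their maximum, so a covariate only counts as balanced when every level
is.

## Headline statistics

* Single sensitivities use Clopper–Pearson exact intervals by default
  (Wilson and Wald available).
* The uplift of the union rule (high by clinical **or** IRT) over the
  clinical score alone is a paired comparison on the same cases:
  difference $(b-c)/n$ with Wald variance
  $(b + c - (b-c)^2/n)/n^2$ from the discordant counts. Against the
  union rule $c \equiv 0$, so the uplift is $b/n \geq 0$ by
  construction.
* The case-NRI, $100(b-c)/n$, uses the IRT's own down-classifications.
* The up-classification odds ratio between low-risk cases and low-risk
  controls uses the 2×2 cross-product with a conditional exact (Fisher)
  interval.
* Percentile enrichment reports, for each upper-tail cut $q$, the
  fraction of cases at or above the reference $(1-q)$-quantile divided
  by $q$; cuts default to 20/10/5/3/1%.
* Baseline tables use Student's t (equal variances) for continuous rows
  and Pearson $\chi^2$ for categorical rows, with continuity correction
  for 2×2 tables only — the convention that reproduces published
  three-category p-values exactly.
* The preventable-events model is deliberately a transparent linear
  product: newly-high fraction × uptake × relative risk reduction ×
  annual event rate × $10^5$ patient-years. Its inputs are parameters,
  not estimates smuggled in.

## What the synthetic generator does and does not emulate

It reproduces: covariate marginals of a UK Health Check population
(ages 40–74, mean ≈ 57.5, ≈ 62% male, ≈ 76.5% white, ≈ 31% current
smokers, ≈ 10.5% on statins); hard-call genotypes in exact
Hardy–Weinberg proportions with configurable allele frequencies;
Gaussian PRS weights; the case-mix hierarchy proportions
(5.6/57.9/12.8/23.5%); and an event process that is the exact inverse of
the IRT. Covariates are drawn independently — only marginals are
specified upstream, and a correlation hook exists but none is imposed.

It does **not** emulate: linkage disequilibrium, imputation error,
genuine population structure (reference and study subjects share one
ancestry, so PCs capture noise), covariate correlations, longitudinal
follow-up beyond a single 10-year indicator, or the licensed QRISK2
algorithm itself. Passing tests therefore certify the *machinery* —
scoring, QC, matching, inference — under the stated generative model,
not the field performance of any particular weight set.

## Numerical and replicate-size choices

* The Hardy–Weinberg exact test computes the conditional distribution of
  the heterozygote count by the stable mid-out recurrence and sums
  probabilities ≤ that of the observed table (with a $1+10^{-7}$
  slack for ties); it is validated against direct log-factorial
  enumeration for every table with $n \le 50$.
* QC filters apply in the fixed order call rate → MAF → HWE; a variant
  is attributed to the first filter it fails. MAF comes from non-missing
  dosages; HWE from dosages rounded to called genotypes, over all
  subjects (testing in controls only is a known alternative; all-subject
  testing is the documented choice here). `min_maf = 0` disables the
  MAF filter.
* When a target event rate is requested, the generator shifts all
  clinical log-odds by a constant solved with `uniroot` to $10^{-10}$
  tolerance.
* Matching-balance replicates use cohorts of 5,000 with an 8% event
  fraction: large enough case groups (≈ 400) that the SMD estimator's
  own sampling noise ($\mathrm{SE} \approx \sqrt{1/n_1 + 1/n_2}$) sits
  well below the 0.1 balance convention, while keeping the control pool
  an order of magnitude larger than the 2:1 draw — the regime a nested
  case-control design assumes. Sign-recovery replicates use 2,500
  subjects × 200 replicates; the Monte-Carlo calibration check uses
  $10^6$ draws.
* Degenerate inputs fail loudly: clinical risks of exactly 0 or 100%
  (logit undefined), empty control pools, zero-variance references,
  separation in the propensity model, all-zero genotype tables.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(n_subjects = 8000, n_variants = 60,
                   prs_beta = log(1.6), baseline_event_rate = 0.08,
                   seed = 1),
  seed = 1)
res <- run_pipeline(cfg)
print(res$report)
```

The `analysis/` directory replays the same stages as a narrated,
numbered workflow (simulate → QC → score → integrate → match →
evaluate → prevention scenarios) writing its tables under `results/`.

## Known limitations

The surrogate clinical score is a calibration device, not QRISK2; the
up-classification odds ratio in any single synthetic replicate is noisy
(matched low-risk subgroups are small, exactly as in the motivating
study, whose interval spanned 1.03–5.64); and because covariates are
independent by default, propensity overlap is better than real cohorts
typically enjoy — matching diagnostics on real data should expect larger
pre-match SMDs. Quantities that depend on unavailable individual-level
inputs (the real score's case/control means, the deployed prevention
model's supplementary inputs) are covered by properties and
parameterised models rather than numeric reproduction.
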