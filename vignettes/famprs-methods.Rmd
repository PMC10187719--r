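---
title: "Models and methods behind famprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind famprs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

famprs estimates how much a genome-wide polygenic risk score (PRS) tells a
family about disease risk in a late-onset, polygenic disease modelled on
familial Alzheimer's disease. It covers four linked questions: how penetrant
the top of the PRS distribution is; whether, within a discordant sibling pair,
the affected sibling tends to carry the higher score; how cumulative
penetrance grows with age in high- versus low-score groups; and what
recurrence risk an affected, high-PRS proband confers on a sibling. This
vignette explains the models, the simulator that stands in for the
access-controlled family cohorts, the tunable parameters, and the numerical
and design choices, in that order.

## The liability-threshold model and sibling recurrence

Disease status is modelled by a latent, unit-variance liability $L$; an
individual is affected when $L$ exceeds the threshold
$T = \Phi^{-1}(1 - K)$ fixed by the population prevalence $K$. A standardized
polygenic score explains a fraction $r^2$ of liability variance, and the score
components of full siblings correlate with $\rho = 1/2$ under additive
inheritance.

The sibling recurrence risk given a proband whose score lies above the
population percentile $q$ is

$$
R(K, r^2, q, \rho) \;=\;
\mathbb{E}_{x}\!\left[
  \Phi\!\left(\frac{\rho x - T}{\sqrt{1 - \rho^2 r^2}}\right)
\right],
\qquad
x \sim \mathcal{N}(0, r^2)\ \text{truncated to}\ x > \Phi^{-1}(q)\sqrt{r^2}.
$$

The expectation is taken over the truncated proband score distribution, not
evaluated at its mean; the distinction is below two-decimal precision at the
parameter values used here, but it is the exact definition and matters for
more extreme parameters. `liability_recurrence()` evaluates the integral by
adaptive quadrature (relative tolerance $10^{-10}$); `recurrence_table()`
tabulates it over grids of prevalences (e.g. age bands), score $r^2$ values
(with and without the APOE locus) and percentile thresholds. The $r^2$ is
consumed as supplied, on the liability scale, with no observed-to-liability
conversion; what to feed it (e.g. a logistic pseudo-$R^2$) is the caller's
modelling decision, deliberately decoupled from the regression machinery.

Two limiting identities pin the implementation down: $r^2 = 0$ or $\rho = 0$
returns exactly $K$ (an uninformative score), and the risk is strictly
increasing in each of $K$, $r^2$, $q$ and $\rho$. Both are asserted in the
test suite, alongside agreement with a Monte-Carlo oracle that simulates the
truncated proband score and the conditional sibling liability directly.

```{r recurrence}
library(famprs)
liability_recurrence(K = 0.13, r2 = 0.068, q = 0.80)       # top-quintile proband
recurrence_table(c(`65-74` = 0.03, `75-84` = 0.17, `85+` = 0.32),
                 c(PRS = 0.068, PRS.AD = 0.12))
```

## The synthetic cohort generator

Real multiplex family data of this kind are access-controlled, so every
cohort-dependent stage runs against `simulate_cohort()`, which generates the
statistical structure the analysis assumes:

* **Families.** Two-parent nuclear families; sibship sizes 2–6 drawn from a
  configurable distribution whose default (0.40, 0.25, 0.20, 0.10, 0.05) gives
  a mean sibship of ~3, i.e. about five members per family including parents —
  chosen once as a realistic multiplex-study figure (observed family sizes in
  such studies average around four genotyped members) and not revisited.
  Unrelated singletons emulate clinic-referred sporadic cases.
* **Genotypes.** Panel SNPs live in LD blocks (default 10 SNPs per block) with
  exchangeable within-block haplotype correlation generated by a Gaussian
  copula, and zero LD across blocks. Children receive whole-block haplotypes
  from each parent (no within-block recombination, free recombination between
  blocks), so per-SNP and aggregate-score sibling correlations are 0.5 in
  expectation by construction. Two APOE-tag SNPs (ids `rs429358`, `rs7412`)
  are appended on chromosome 19 inside the canonical 2 MB exclusion window;
  their dosages are the individual's e4 and e2 allele counts at a separately
  simulated, Mendelian three-allele major locus.
* **Liability.** $L = g_{\text{prs}} + g_{\text{apoe}} + g_{\text{poly}} + e$
  with configured variances (defaults 0.068, 0.052, 0.35, remainder to 1).
  $g_{\text{prs}}$ is a weighted sum of a random 20% of panel SNPs;
  $g_{\text{apoe}}$ weights the e4 count against half-magnitude protective e2;
  $g_{\text{poly}}$ is a shared polygenic residual transmitted as
  midparent-plus-segregation noise (sibling correlation 0.5) representing
  genetic liability the SNP panel does not tag. The 0.35 default keeps total
  heritability in the range reported for late-onset Alzheimer's disease while
  leaving the score's share at its configured value. Component weights are
  rescaled so the *realized* sample variance of each component equals its
  configured value exactly — a deliberate simulation-design choice that makes
  variance-decomposition checks sharp without changing any correlation
  structure.
* **Onset and censoring.** Everyone draws an examination age, uniform on
  [65, 95] (the stand-in choice for an unstated real-world censoring
  distribution; it is a config field). Affection is decided by an
  age-declining threshold: affected at exam age $a$ iff
  $L > \Phi^{-1}(1 - K(\text{band}(a)))$, with the default band prevalences
  3% (65–74), 17% (75–84) and 32% (85+). Onset age is drawn uniformly inside
  the first band whose threshold the liability exceeds, never after the exam
  age; unaffected individuals are right-censored at the exam age. This makes
  the population cumulative incidence available in closed form as a test
  oracle. One caveat is documented and tested rather than hidden: because
  affection is evaluated at the *band* of the exam age, an individual examined
  early in a band already carries the band's full prevalence, so under
  mid-band censoring the product-limit curve reaches a band's prevalence early
  within that band. Calibration tests therefore pin the analytic values
  {0.03, 0.17, 0.32} in a design where everyone is examined at the closing
  age of 95 (where the estimator is exactly calibrated) and assert the band
  envelope under uniform censoring.
* **Summary statistics.** An external base GWAS is emulated per SNP as
  $\hat\beta = \beta + \varepsilon$, $\varepsilon \sim
  \mathcal{N}(0, se^2)$ with $se = 1/\sqrt{2\,\text{MAF}(1-\text{MAF})\,
  n_{\text{gwas}}}$ and a normal-reference p-value. A fraction of SNPs is
  emitted on the opposite allele (with the matching sign flip) so the scorer's
  allele normalization is always exercised.
* **Ascertainment.** `ascertain_families()` keeps families with at least two
  affected siblings, one with onset after 60, and retains affected singletons
  flagged as unrelated cases.

A single master seed drives everything; identical configurations produce
byte-identical cohorts and files.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: realistic genome-wide LD maps, imputation error,
population admixture (principal components are simulated as pure noise
covariates), secular trends in diagnosis, competing mortality, or the precise
ascertainment pressure of any real study. Tests against the generator verify
that the estimators recover the structure they assume; they do not validate
that structure against any real cohort.

## PRS scoring

`clump_snps()` implements greedy clumping+thresholding: SNPs failing the MAF
(default $\ge 0.01$) or p-value filter (default $\le 0.1$) are dropped;
survivors are visited in ascending p-value order (ties broken by SNP id), each
retained index SNP removing neighbours within 250 kb whose dosage $r^2$
(computed from the genotype panel itself, a self-contained choice) is at least
0.2. `compute_prs()` sums `beta * dosage` over retained SNPs outside the 2 MB
APOE window (GRCh38 chr19:42,905,791–46,909,393), orienting each weight to the
panel's counted allele and mean-imputing missing dosages. Scores are
residualized on the first three principal components, standardized to unit SD
(so odds ratios are per SD — a reproducible scale), and augmented into PRS.AD
by adding the two APOE-tag SNP effects. Quantile bins are computed over the
pooled analysis cohort (cases and controls together); this is the only reading
under which a top quintile can be majority-affected, and it is switchable by
binning any reference subset with `bin_quantiles()`, whose ties break by
stable id order so degenerate inputs are deterministic.

## Sibling pairs and pair statistics

Two pairing strategies mirror standard practice in family studies: one random
sibling pair per family, or a maximum random matching using each sibling once
(`floor(s/2)` pairs, a random leftover when `s` is odd). Statistics are
reported as mean (sample SD) over 100 replicate pairings with derived seeds.
Eligibility requires both siblings to have non-missing affection and PRS;
age ties in older/younger orientation break by individual id.

The discordant-pair statistic is the fraction of affection-discordant pairs in
which the affected sibling has the strictly higher PRS; exact score ties are
dropped from both numerator and denominator. For stratified rows (e.g. "pairs
in the highest quintile") a pair qualifies when its higher-PRS member lies in
the stated bin, and APOE-stratified rows require both siblings to share the
carrier status — the only reading under which lowest-quintile rows can fall
well below 0.5, recorded here as an interpretive choice. Percentile
concordance uses each sibling of a pair once as index: among index siblings in
the top $p$ of the cohort distribution, the fraction of co-siblings also in
the top $p$; under sibling score correlation 0.5 the bivariate-normal value at
$p = 0.2$ is 0.44 by quadrature, and the statistic reduces to $p$ under
independence.

## Association and age-at-onset models

`fit_ad_association()` is a logistic regression of affection on the
standardized score plus age, sex and principal components, optionally within
an APOE-e4 stratum. Variance explained is reported as the Nagelkerke
pseudo-$R^2$ of the score model against the covariate-only model; which
pseudo-$R^2$ a study means by "$R^2$" is often unstated, so the recurrence
model deliberately accepts whatever $r^2$ the caller supplies rather than
binding to this choice. Complete separation is flagged and refit with a small
ridge penalty (point estimate only). Covariate handling is complete-case.
`fit_aao_model()` regresses onset age on the standardized score plus
principal components among affected individuals only and refuses to fit with
fewer than 10 cases.

## Age-specific cumulative penetrance

The published description of the risk estimator is verbal (nonparametric,
genotype-specific, covariate-allowing); famprs implements it as a
product-limit (Kaplan–Meier-type) cumulative incidence $1 - \hat S(\text{age})$
within each carrier group, with covariate adjustment by stabilized
inverse-probability weights from a logistic model of group membership on sex
and principal components. This is a substitution consistent with the verbal
description, not a reproduction of an unpublished estimator. Confidence bands
are a nonparametric bootstrap over whole families (default 200 resamples),
respecting within-family dependence; curves are evaluated on integer ages
60–95.

Group differences are tested by permutation: each individual's
`(affected, age)` record is kept intact and labels are permuted jointly across
the pooled two-group sample (preserving the pooled age distribution under the
null — whether diagnosis alone or diagnosis-plus-age should be permuted is
ambiguous in the source description; the joint choice is implemented), with
two-sided p-values from the absolute risk difference and the add-one
correction $p = (1 + \#\{|\text{null}| \ge |\text{obs}|\})/(1 + n_{perm})$,
so $p \in (0, 1]$ and 1000 permutations resolve p-values to $10^{-3}$. The
scheme requires disjoint groups; overlapping contrasts (e.g. top PRS quintile
versus all e4 carriers) are reported as curves but not permutation-tested.

## Parameters that matter

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `r2_prs` | 0.068 | liability variance fraction | score share of liability |
| `r2_apoe` | 0.052 | liability variance fraction | APOE-locus share (0.12 total with the score) |
| `r2_polygenic` | 0.35 | liability variance fraction | untagged familial liability, sibling correlation 0.5 |
| `prevalence_schedule` | 3/17/32% at 65/75/85 | cumulative prevalence per age band | census-based age-specific prevalence |
| `K` (recurrence) | 0.13 | prevalence | population prevalence over 65 |
| `p_threshold`, `r2_max`, `window_bp`, `maf_min` | 0.1, 0.2, 250 kb, 0.01 | clumping | standard C+T settings |
| `rho` | 0.5 | score correlation | full siblings, additive model |
| percentiles | 0.99/0.95/0.90/0.80 | proband threshold | top 1/5/10/20% of the score distribution |
| `n_rep` | 100 | replicates | pairing replicate convention |
| `n_perm` | 1000 | permutations | p-value resolution $10^{-3}$ |

## Numerical choices and degenerate inputs

Quadrature uses `stats::integrate` with relative tolerance $10^{-10}$ over the
truncated support, with the analytic shortcut $R = K$ when $r^2 = 0$ or
$\rho = 0$ (the integrand is then constant and the truncation irrelevant).
Quantile binning resolves ties by id order; clumping resolves p-value ties by
SNP id; monomorphic SNPs yield undefined correlations and are treated as
unlinked. IPW probabilities are clipped to $[10^{-6}, 1 - 10^{-6}]$. Empty
strata report `NA` with `n = 0` rather than erroring; replicate statistics
undefined on a replicate are recorded as missing and counted. All replicate
and permutation seeds derive deterministically from the master seed.

## Problem sizes used in the checks

The test suite exercises cohorts of roughly 250–5000 families (up to ~20,000
individuals) with panels of 200–1000 SNPs, 100–300 pairing replicates, 500
null simulations for permutation-test calibration, and $10^5$–$10^6$ draws for
Monte-Carlo oracles — sizes chosen so each check's Monte-Carlo error is small
against its 3-standard-error tolerance while the whole suite stays
interactive. The analysis scripts under `analysis/` default to 3000 base
families (~16,000 individuals, 1000 panel SNPs), which multiplex ascertainment
reduces to a family cohort of several hundred families, comparable to the
motivating studies.

## Known limitations

* The recurrence reconstruction is validated against published numerical
  tables, not against a published formula; the source for the original
  calculation prints none.
* The liability $r^2$ of a fitted logistic model is not the liability-scale
  variance the recurrence model treats it as; famprs keeps the two decoupled
  and leaves the conversion to the user.
* The IPW product-limit estimator is a stand-in for an unpublished
  covariate-adjusted estimator; bands come from a family bootstrap, not a
  closed-form variance.
* Cumulative-incidence estimation ignores competing mortality and left
  truncation; with late-onset disease in elderly cohorts both matter in real
  data.
* The simulator's LD, admixture and ascertainment are stylized (see above);
  empirical concordance and penetrance values from synthetic runs are
  qualitative analogues of the published cohort values, not reproductions.
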