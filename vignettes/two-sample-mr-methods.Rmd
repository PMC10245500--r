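---
title: "Methods: two-sample Mendelian randomization with mediation and meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with mediation and meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
options(mrpipe.verbose = FALSE)
```

## The causal model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure. A SNP $j$ is a valid instrument when
(1) it is robustly associated with the exposure, (2) it is independent of
exposure–outcome confounders, and (3) it affects the outcome only through
the exposure. In the two-sample design the SNP–exposure associations
$(\hat\beta_{X_j}, \sigma_{X_j})$ and SNP–outcome associations
$(\hat\beta_{Y_j}, \sigma_{Y_j})$ come from different GWAS cohorts, and
the per-SNP Wald ratio $\hat\theta_j = \hat\beta_{Y_j}/\hat\beta_{X_j}$
estimates the causal effect $\theta$ of one exposure unit (typically an
SD) on the outcome (log-odds for a binary outcome).

`mrpipe` implements the workflow around this model end to end:

1. **Instrument selection** — `select_by_pvalue()` at a strict
   genome-wide threshold ($p < 5\times10^{-8}$ by default;
   $5\times10^{-6}$ is the conventional relaxation for weakly
   instrumented behavioural exposures and can be set per exposure),
   `clump()` for LD independence, and `f_statistic()` /
   `instrument_set()` for instrument strength.
2. **Harmonization** — `harmonize()` aligns both tables to a shared
   effect allele.
3. **Estimation** — `mr_ivw()` (primary), `mr_egger()`,
   `mr_weighted_median()`, `mr_presso()`, with `cochran_q()` and
   `leave_one_out()` diagnostics.
4. **Meta-analysis** — `fixed_effect_meta()` pools per-cohort estimates.
5. **Mediation** — `two_step_mediation()` / `mediation_pipeline()`
   decompose a total effect through a mediator.

## Estimators

**IVW with multiplicative random effects.** With first-order weights
$w_j = \hat\beta_{X_j}^2/\sigma_{Y_j}^2$ (the delta-method inverse
variance of the Wald ratio, exposure-side error ignored), the estimate is
$\hat\theta = \sum w_j \hat\theta_j / \sum w_j$, identical to weighted
least squares of $\hat\beta_Y$ on $\hat\beta_X$ through the origin.
Cochran's $Q = \sum w_j(\hat\theta_j - \hat\theta)^2$ on $n-1$ df
measures heterogeneity; the fixed-effect SE $1/\sqrt{\sum w_j}$ is
multiplied by $\max(1, \sqrt{Q/(n-1)})$. The multiplicative (rather than
additive) form is the standard reading of "IVW with random effects" in
two-sample MR and guarantees the random-effects CI never undercuts the
fixed-effect one. First-order weights are used because they are the
default in the field's standard packages; second-order corrections change
little for strong instruments.

**MR-Egger.** Weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$
*with* an intercept, after orienting each SNP so $\hat\beta_X \ge 0$.
Under the InSIDE assumption (instrument strength independent of direct
effects) the slope is a pleiotropy-corrected causal estimate and the
intercept estimates the average directional pleiotropy; the intercept's
p-value is the pleiotropy test. Residual overdispersion inflates the
parameter variances by $\max(1, \mathrm{RSS}/(n-2))$. Inference uses the
t distribution on $n-2$ df; published analyses are ambiguous between t
and normal quantiles here, so `p_method = "normal"` is available and the
choice is recorded in the estimate. Egger's leverage comes entirely from
*variation* in instrument strength, and measurement error in
$\hat\beta_X$ attenuates the slope (the NOME consideration); the
package's validation therefore assesses Egger recovery on instruments
with dispersed, precisely estimated effects, the regime in which the
estimator is consistent.

**Weighted median.** Ratios are ordered and the estimate interpolates the
weighted empirical CDF (midpoint convention, $s_j = (\sum_{i\le j} p_i) -
p_j/2$) at 0.5. It is consistent while valid instruments carry more than
half the weight. The SE is a parametric bootstrap (default 1000
replicates) redrawing both betas from their sampling distributions; a
seed is required, making every report reproducible.

**MR-PRESSO.** The global test compares the observed residual sum of
squares around leave-one-out IVW fits with parametric simulations; the
per-SNP outlier test compares each SNP's residual contribution with its
simulated distribution, Bonferroni-corrected across the instruments
actually tested; the corrected estimate is IVW on unflagged SNPs; the
distortion test compares the pre/post-correction change with the change
from removing random pseudo-outlier sets of the same size (two-sided).
Simulation p-values use the add-one correction $(r+1)/(n_\mathrm{sim}+1)$,
so with the default $n_\mathrm{sim} = 1000$ the smallest attainable
p-value is $\approx 10^{-3}$ — when the Bonferroni threshold
$\alpha/n$ falls below $1/(n_\mathrm{sim}+1)$, no outlier can be flagged
and `n_sim` must be raised. The distortion p-value is `NA` exactly when
no SNP is flagged.

**Scaling.** `rescale_estimate()` multiplies the log-scale estimate by a
positive factor (for example $\ln 1.5$ to express a per-log-unit effect
per 50% increase in the exposure); the z-score and p-value are invariant.

## Meta-analysis and mediation

Per-cohort log-odds estimates are pooled with fixed-effect
inverse-variance weights; $I^2 = \max(0, (Q-(k-1))/Q)\cdot 100$ is banded
low / medium / high / extreme at the 25/50/75 cutpoints. `from_ci()`
reconstructs $(\beta, \mathrm{SE})$ from printed ORs and 95% CIs using
the 1.96 convention of published tables (internal CIs use the exact
normal quantile); pooling is done on the log-OR scale.

Two-step MR mediation estimates step A (exposure on mediator, using the
exposure's instruments) and step B (mediator on outcome, using the
*mediator's own* genome-wide-significant instruments — each step is a
univariable MR) by IVW. The indirect effect is the product of
coefficients $\beta_A\beta_B$, the mediated proportion is
indirect/total, and the indirect-effect SE is the first-order delta
method $\sqrt{\beta_A^2\sigma_B^2 + \beta_B^2\sigma_A^2}$ without a
covariance term, appropriate because the two steps come from
non-overlapping instrument-outcome regressions. The proportion is
reported even when it falls outside $[0,1]$ or the signs of total and
indirect effects disagree, carrying an `inconsistent_mediation` flag,
and is undefined (flagged `NA`) for a zero total effect. For tables the
proportion is conventionally rounded to an integer percentage; full
precision is kept on the object.

## Harmonization rules

Alleles are upper-cased on read and matched per SNP: same order
(`as_is`), swapped order (outcome beta sign-flipped, frequency
complemented), complementary strand (recoded, then swap logic), or
irreconcilable (dropped with a reason code). Palindromic SNPs (A/T, C/G)
make strand and swap indistinguishable; the default policy infers
orientation from allele frequencies on both sides, dropping SNPs whose
frequency falls inside the ambiguity band (0.42, 0.58) — the prevailing
practice, retaining more instruments than the stricter `drop_all` policy
also provided. Palindromic SNPs with a missing frequency on either side
are always dropped, since inference is impossible; if frequencies are
absent from a whole table the `eaf_infer` policy errors rather than
silently degrading. Indels are never palindromic and match by exact or
swapped labels only. Instruments missing from the outcome are dropped and
counted — no proxy substitution. Harmonizing a table against itself is
the identity, and harmonization is idempotent; both properties are
tested.

## LD clumping

Greedy selection by ascending p-value: a SNP is kept iff no already-kept
SNP on the same chromosome within the window (default 10,000 kb, read as
$|\Delta\mathrm{pos}| \le 10^7$ bp) has $r^2$ at or above the cutoff
(default 0.01). Ties in p are broken by (chrom, pos, snp_id) so results
are platform-deterministic, and the output is sorted by genomic position,
making it invariant to input row order. SNP pairs absent from the LD
matrix are treated as independent with a warning — reference panels
(e.g. 1000 Genomes Europeans) rarely cover every variant and the package
does not ship one. Equivalence with an index-based (PLINK-style) oracle
is tested on correlated 20-SNP blocks.

Instrument strength uses the summary-data approximation
$R^2_j = 2\,\mathrm{eaf}_j(1-\mathrm{eaf}_j)\beta_j^2$ on a standardized
phenotype (no formula is universal in published reports; this is the
conventional choice), summed over instruments and entered into
$F = R^2(N-k-1)/(k(1-R^2))$ with the configured study $N$ — published
sample sizes are often "up to" values, so the study-level $N$ is an
explicit input rather than inferred per SNP.

## The synthetic-data generator

`simulate_two_sample()` draws summary statistics directly — no
individual-level genotypes — because the pipeline consumes only summary
data and direct simulation makes the causal truth exact: MAF uniform on
`maf_range`; instrument effects $\gamma_j \sim N(\mu_\gamma,
\sigma_\gamma^2)$; direct (pleiotropic) outcome effects $\alpha_j$ that
are zero, balanced, directional, or correlated with $\gamma_j$ through a
Gaussian copula (the minimal parameterization of an InSIDE violation);
sampling SEs $1/\sqrt{2p(1-p)N}$; observed betas normal around the true
values, with binary-outcome effects treated as log-odds with normal
error, matching how biobank log-ORs are consumed downstream. Allele
dressing (palindromic pairs, strand flips in the outcome table, missing
outcome rows) exercises harmonization, and a block-diagonal LD matrix
($r^2 = \rho^{|i-j|}$ within blocks) exercises clumping; LD is generated
independently of effect sizes since clumping is tested structurally.

Defaults were chosen once to emulate a typical anthropometric-exposure /
biobank-outcome analysis and are not tuned per test: 25 instruments
(matching a waist-to-hip-ratio instrument count), exposure GWAS
$N = 224{,}459$ and outcome GWAS $N = 107{,}814$ (typical consortium and
biobank sizes), mediator GWAS $N = 210{,}088$, $\gamma_j \sim
N(0.03, 0.005^2)$ giving per-SNP F statistics of order $10^2$ as seen for
published hits, MAF in (0.05, 0.5), 20% palindromic SNPs, 10% of outcome
rows strand-flipped, and 5% of instruments absent from the outcome.
`simulate_mediation_triple()` adds a mediator table and a second,
mediator-specific instrument set $\delta_j$ (outcome effects
$\beta_{MO}\delta_j$, null exposure effects): with shared instruments
only, regressing the outcome on the mediator would recover
total$/\beta_{EM}$ rather than $\beta_{MO}$, so a mediator needs its own
instruments for step B to be identified — the same requirement real
two-step MR faces.

What the generator does *not* emulate: realistic allele-frequency
spectra, population stratification, sample overlap between the two GWAS,
winner's-curse selection of instruments, and LD between causal effect
sizes. Passing tests therefore validate the estimators and plumbing
under their stated assumptions, not robustness to those additional
real-data complications.

## Validation design and problem sizes

The test suite validates each estimator against an independent oracle
(weighted `lm()` fits for IVW and Egger, an `approx()`-based cumulative
CDF for the weighted median, elementwise arithmetic for the
meta-analysis, an index-based greedy clumper) to $10^{-10}$–$10^{-12}$
on small fixtures, and statistically at the generator's default
operating conditions: IVW type-I error across 2000 seeded null
replicates (accepted within 3.5–6.5% at nominal 5%); recovery of the
causal effect, the Egger intercept, and the mediated proportion within 3
Monte-Carlo SEs across 200 replicates each; MR-PRESSO flagging of a
10-residual-SD planted outlier in at least 95% of 50 replicates with
near-uniform global p under the null (Kolmogorov–Smirnov at
$\alpha = 0.01$, 200 replicates at $n_\mathrm{sim} = 1000$). These sizes
keep the full suite around a minute on one CPU while leaving
Monte-Carlo error well below the tested tolerances. Published mediation
and meta-analysis arithmetic (the worked examples in the README) is
reproduced exactly at printed precision from the printed inputs.

## Numerical and degenerate-input conventions

* Internal 95% CIs use `qnorm(0.975)`; `from_ci()` uses 1.96 when
  consuming printed tables.
* P-values from simulated betas are floored at $10^{-300}$ to stay in
  (0, 1].
* `mr_ivw()` requires 2 instruments (`wald_ratio()` covers the
  single-SNP case), `mr_egger()` and the weighted median 3,
  `mr_presso()` 4; each failure names the shortfall.
* Zero-$\hat\beta_X$ SNPs are excluded from ratio-based estimators with
  a warning.
* In MR-PRESSO, flagging *all* instruments is an error (the corrected
  estimate would be degenerate), and the corrected estimate is absent
  (not a silent copy of IVW) when nothing is flagged.
* Leave-one-out flags use the fixed-effect SE as the influence
  yardstick: a gross outlier inflates the random-effects SE and would
  otherwise mask its own influence.
* Multiple-testing across exposures is deliberately not adjusted;
  `run_plan()` records a note in its manifest instead, and borderline
  p-values should be read as suggestive.

## Known limitations

No multivariable MR (and hence no multivariable direct-effect
mediation), no mode-based or contamination-mixture estimators, no proxy
SNP lookup, no liftover between genome builds, no VCF-encoded summary
statistics, and no live LD reference queries. The weighted median's
bootstrap SE and all simulation-based p-values inherit Monte-Carlo
resolution from their replicate counts; both are configurable and
seeded.
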