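---
title: "Measuring frailty in trial baseline data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring frailty in trial baseline data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtytrials)
```

## The cumulative-deficit frailty index

`frailtytrials` implements a retrospective frailty analysis for clinical-trial
individual participant data, built on the cumulative-deficit frailty index
(FI). The FI treats frailty as the proportion of age-related health deficits
an individual has accumulated out of those assessed:

$$\mathrm{FI}_i = \frac{\sum_{j \in A_i} s_{ij}}{|A_i|},$$

where $s_{ij} \in [0,1]$ is participant $i$'s score on deficit $j$ and $A_i$
is the set of deficits with non-missing data for that participant. A deficit
can be any health-related item — a diagnosed condition, an abnormal
laboratory value, a functional limitation — provided it increases in
prevalence with age, does not saturate too early, and the full set covers
several physiological systems with at least 30 items. There is deliberately
no canonical deficit list; the catalog is user-supplied configuration
(`load_catalog()`), which is what makes the method applicable to whatever a
given trial happened to measure at baseline.

Scoring conventions (`score_deficit()`):

* **binary** deficits score 0 (absent) or 1 (present);
* **ordinal** deficits at 0-indexed level $k$ of $n$ levels score $k/(n-1)$
  (so a 5-level item scores 0, 0.25, 0.5, 0.75, 1);
* **threshold** deficits score 1 when a continuous measurement lies beyond a
  single cut-point in the stated direction.

Missing deficits are removed from both numerator and denominator.
Participants missing strictly more than 20% of a variant's deficits are
excluded; exactly 20% missing is retained, reading the exclusion rule "more
than 20%" literally. The excluded count is always reported rather than
assumed to be zero.

Two index variants are computed: a *physical* FI, and a *physical +
cognitive* FI that adds a small set (five, by default) of cognitive deficits
covering orientation, memory, language, executive function and
constructional praxis. Comparing the two quantifies how much of measured
frailty is carried by cognitive items — important in dementia populations,
where a physical-only index can understate frailty.

Because trial medical histories are often redacted, condition deficits can
be inferred from concomitant medications: a declarative map from
medication-class codes to condition deficits (`map_medications()`, set
semantics, unknown codes counted but never fatal) plus a polypharmacy
deficit (five or more distinct medications). This inference is deliberately
coarse — conditions treated without drugs are invisible to it — and that
limitation is inherited by any catalog relying on it.

### Frailty categories

For comparability with primary-care electronic frailty index practice, FI
values are categorised as robust (FI ≤ 0.12), mild (0.12 < FI ≤ 0.24),
moderate (0.24 < FI ≤ 0.36) and severe (FI > 0.36). Published category
tables often print overlapping labels ("0.12–0.24", "0.24–0.36") without
resolving the boundaries; we fix the half-open-on-the-right convention so
that "frailty prevalence, FI > 0.24" is *exactly* the moderate plus severe
prevalence, making category tables and threshold prevalences mutually
consistent (`prevalence_over_threshold()` enforces this identity and
refuses non-boundary thresholds on category input).

## Parametric distribution summaries

Secure data repositories typically forbid exporting individual-level FI
values, so the distribution must leave the enclave as a parametric summary.
`fit_fi_distribution()` fits lognormal, gamma, Weibull and generalised
gamma families by maximum likelihood; `select_best_fit()` compares them by
the Kolmogorov–Smirnov statistic
$D = \sup_x |\hat F_n(x) - F(x)|$ (computed with both one-sided ECDF limits;
no p-value is attached because parameters are estimated from the same
sample — the Lilliefors problem). Ties within $10^{-3}$ go to the family
with fewer parameters.

The generalised gamma uses the Stacy parameterisation

$$f(x) = \frac{p}{a^{d}}\, x^{d-1} e^{-(x/a)^{p}} / \Gamma(d/p),
\qquad a, d, p > 0,$$

which nests the gamma ($p = 1$), the Weibull ($d = p$) and, as a limit, the
lognormal. Density, CDF and quantile come from `flexsurv`'s `*gengamma.orig`
functions, which implement exactly this form. The MLE is a multi-start BFGS
on $(\log a, \log d, \log p)$; the start set includes moment-matched points
*and* the fitted gamma and Weibull solutions mapped into the parameter
space, and a start point is never discarded in favour of a worse optimum, so
the nesting inequality $\ell(\text{gengamma}) \ge \ell(\text{gamma}),
\ell(\text{weibull})$ holds by construction (tests assert it to $10^{-4}$).
Convergence uses a relative log-likelihood tolerance of $10^{-12}$ per
start.

Exact zeros — attainable in low-frailty samples — are shifted to
$1/(2\,n_\text{deficits})$, half the smallest attainable positive FI, before
positive-support fitting; the shift is configurable. `model_summary()`
exports category prevalences as CDF differences and an upper centile from
the inverse CDF, verifying the round trip $F(F^{-1}(q)) = q$ to $10^{-8}$.
The 99th centile is reported both empirically (linear-interpolation
quantile, R type 7) and model-based, since published tables rarely say which
estimator was used; any model mass above the FI upper bound of 1 is exposed
as a model-adequacy diagnostic rather than silently renormalised.

## Outcome models

Two per-trial associations are estimated, both with the FI rescaled by 10 so
coefficients are per 0.1-unit FI — a conventional, clinically interpretable
increment:

* **Serious adverse events.** Participants are censored at their first SAE
  or end of follow-up; the first-event indicator is modelled by a log-link
  Poisson GLM with offset $\log t_i$ (observation time), adjusted for age
  (linear, years) and sex (female = 1). Under this censoring rule the
  outcome count is 0/1 and the Poisson likelihood coincides with the
  exponential (constant-hazard) first-event likelihood, so the exponentiated
  coefficient is an incidence rate ratio (IRR). Because the censoring rule
  makes counts above 1 impossible, total-SAE-count models are out of scope.
  Time units cancel from the IRR (tested).
* **Attrition.** Withdrawal before the stipulated endpoint, any reason, via
  a logit-link binomial GLM with the same adjustment; effect reported as an
  odds ratio (OR).

Standard errors are model-based with Wald 95% intervals
($\exp(\hat\beta \pm 1.96\,\mathrm{se})$); profile-likelihood or sandwich
intervals were considered and not adopted, as the Wald form is what is
conventionally pooled downstream. Separation and IRLS non-convergence are
detected and raised as errors rather than returned as absurd estimates. A
sex × FI interaction (post hoc in the motivating analyses) and an optional
quadratic FI term (off by default) are exposed as flags.

## Random-effects pooling

Per-trial log-coefficients are pooled by DerSimonian–Laird random-effects
meta-analysis (`pool_random_effects()`, computed via
`metafor::rma.uni(method = "DL")`): fixed-effect weights $w_i = 1/se_i^2$,
heterogeneity $Q = \sum w_i (b_i - b_{FE})^2$,
$\tau^2 = \max\!\big(0, (Q - (k-1))/(\sum w - \sum w^2/\sum w)\big)$,
re-weighting by $w^*_i = 1/(se_i^2 + \tau^2)$. DL is the default and the
tested path because the estimator is fully determined by printed trial
statistics; REML is available behind a flag. Normal-quantile CIs are used
without the Knapp–Hartung adjustment — with $k = 3$ trials the adjustment's
assumptions buy little and the unadjusted form matches common practice.
`forest_table()` emits per-study and pooled rows with weights summing to
100%.

## The synthetic-trial generator

The real individual participant data this kind of analysis targets is
access-restricted, so the package ships a generator
(`trial_sim_config()` / `generate_trial()`) whose role is to produce data
with the statistical structure the analysis assumes, making every stage
executable and testable end to end.

It is a one-factor latent-trait model: participant $i$ draws liability
$z_i \sim N(0,1)$; deficit $j$ has linear predictor
$\eta_{ij} = \alpha_j + \lambda_j z_i + \gamma_j (age_i - 70)/10$ with
$\lambda_j, \gamma_j \ge 0$, giving positive inter-deficit correlation and
prevalence rising with age — the two structural facts that make FI
distributions right-skewed with a long upper tail. Binary deficits are
Bernoulli in $\mathrm{invlogit}(\eta)$; ordinal deficits use cumulative
logits with symmetric equally spaced offsets (default gap 1.5 logits), so a
common shift moves all deficit types coherently; threshold deficits place a
raw measurement on the deficit side of the cut-point when present.
Medication lists are generated backwards from the simulated conditions plus
a Poisson number of decoy over-the-counter codes (mean 2), exercising both
the medication map's unknown-code path and polypharmacy. Missingness is
MCAR per column-sourced entry. Event times are exponential — deliberately,
because the downstream Poisson-with-offset model is then exactly correctly
specified, making parameter-recovery and CI-coverage checks a clean
validation surface. All randomness fans out from a single seed through
fixed per-stage substreams, so generation is reproducible table-for-table.

Outcomes are generated from the *complete-data physical* FI (before
missingness is applied): the analysis then sees a slightly noisy version of
the generating FI, as it would in reality.

### Presets and calibration

Two presets encode the emulated study conditions:

| preset | n | follow-up | age | % female | target FI | true IRR/0.1 FI | true attrition OR |
|---|---|---|---|---|---|---|---|
| `mci` | 1000 | 365 d | 70 (7) | 55 | 0.14 (0.06) | 1.6 | 1.05 |
| `dementia` | 408 | 730 d | 83 (6) | 81 | 0.24 (0.08) | 1.6 | 1.66 |

Per-deficit base prevalences follow a fixed log-odds grid from 2% to 40%
across the 40 physical deficits (many rare deficits, a few common — the
shape that produces realistic right skew). A scalar shift `delta`, a common
liability loading `lambda` and the cognitive-deficit centre were calibrated
once, by simulation at large n, so the complete-data physical FI hits the
target mean and SD above and the combined-index means (0.145 for MCI, 0.29
for dementia, implying mild cognitive impairment scores ~0.15 and severe
dementia cognitive scores ~0.7). The calibrated constants are frozen in the
package; they are study conditions, not tuning knobs. The age slope is
fixed at 0.25 logits per decade for all deficits, a moderate, realistic
gradient. Baseline event rates were set to plausible trial incidences
(~15%/year SAE risk in MCI at average covariates, ~45% over 24 months in
severe dementia; attrition ~20% and ~30%).

What the generator does *not* emulate: informative (non-MCAR) missingness,
treatment-arm effects (ignored in the motivating analyses), site or country
structure, non-exponential hazards, and measurement error within deficit
instruments. Passing tests therefore demonstrate that the pipeline's
estimators are correct under their own assumptions and calibrated
conditions — not that those assumptions hold in any particular real trial.

## Numerical choices and degenerate inputs

* Ordinal scaling assumes an equally spaced grid over declared levels.
* Distribution fits require n ≥ 30 and a non-constant sample; constant
  samples, all-excluded samples, empty variant sets, zero-event Poisson
  data, single-sex interaction requests and separated logistic fits all
  raise typed errors rather than returning numbers.
* Rendered percentages round half-up to one decimal to match how such
  tables are conventionally printed; raw values are retained in the
  machine-readable outputs, and every rendered number is traceable to a
  field there (no report-side arithmetic beyond rounding).
* Sex enters models as a female indicator; other codings pass through
  `encode_sex` and unrecognised codes are errors, not silent NAs.

## Problem sizes used in validation

The shipped validation suite runs the coverage study at 200 replicates of
n = 4000 (the scale at which CI coverage of the generating log-IRR and
log-OR is assessed against the nominal 95% ± 4%), parameter-recovery fits at
n = 10,000, calibration checks at n = 5000, and the end-to-end three-trial
pipeline at the emulated per-trial sizes (987 / 1064 / 408). These sizes
were chosen so each check has enough resolution to detect a real defect
while the full suite remains quick to run on a laptop.

## Worked example

```{r example, eval = FALSE}
catalog <- load_catalog(system.file("extdata", "deficit_catalog.yaml",
                                    package = "frailtytrials"))
trials <- list(
  generate_trial(sim_preset("mci", seed = 11, trial_name = "MCI-1", catalog = catalog)),
  generate_trial(sim_preset("mci", seed = 12, trial_name = "MCI-2", catalog = catalog)),
  generate_trial(sim_preset("dementia", seed = 13, trial_name = "AD", catalog = catalog)))
res <- run_pipeline(trials, catalog = catalog)
print(res)
```

## Known limitations

* The catalog shipped in `inst/extdata` is a synthetic, plausible deficit
  list; real analyses must encode the deficits their trial actually
  measured.
* Medication-inferred comorbidity undercounts conditions managed without
  drugs and collapses related conditions into broad groups.
* No imputation beyond denominator removal; no recurrent-event or survival
  (Cox) models; no meta-regression or publication-bias diagnostics (with
  k = 3 these are uninformative).
* KS comparison is relative, not an absolute goodness-of-fit test.
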