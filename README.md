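# frailtytrials

Frailty is rarely measured or reported in randomised controlled trials, even
for conditions — like dementia and mild cognitive impairment (MCI) — where it
shapes both who enrols and what happens to them. `frailtytrials` is an R
package for quantifying frailty retrospectively from trial baseline
individual participant data (IPD) and relating it to trial outcomes. It is
aimed at biostatisticians and epidemiologists running secondary analyses of
trial IPD, typically inside secure data enclaves that only permit aggregate
exports.

## What it computes

**Frailty index (FI).** The cumulative-deficit model: for participant *i*
with non-missing deficit set *Aᵢ*,

```
FI_i = ( Σ_{j ∈ A_i} s_ij ) / |A_i| ,   s_ij ∈ [0, 1]
```

built from a user-supplied deficit catalog (binary, ordinal and
threshold-scored items; conditions inferrable from concomitant medications;
polypharmacy = 5+ distinct drugs). Participants missing > 20% of deficits are
excluded. Two variants: physical, and physical + cognitive. Categories use
the electronic-frailty-index cut-points (robust ≤ 0.12 < mild ≤ 0.24 <
moderate ≤ 0.36 < severe), so "frailty prevalence (FI > 0.24)" is exactly
moderate + severe.

**Distribution summaries.** Maximum-likelihood fits of lognormal, gamma,
Weibull and Stacy generalised-gamma families, compared by
Kolmogorov–Smirnov statistic, with CDF-based category prevalences and
centiles — the exportable, individual-data-free description of an FI sample.

**Outcome associations.** Per trial: Poisson regression of first serious
adverse event (SAE) with a log person-time offset (IRR per 0.1-unit FI), and
logistic regression of attrition (OR per 0.1 FI), both age/sex-adjusted,
with optional sex × FI interaction.

**Pooling.** DerSimonian–Laird random-effects meta-analysis of the per-trial
log-coefficients, with forest-table output.

**Synthetic trials.** A latent-trait generator (`sim_preset("mci")`,
`sim_preset("dementia")`) calibrated so the physical FI has mean 0.14
(SD 0.06) and 0.24 (SD 0.08) respectively, right-skewed, with a true SAE IRR
of 1.6 per 0.1 FI — so the whole pipeline runs and is validated without any
restricted data.

## Worked example

```r
library(frailtytrials)
catalog <- load_catalog(system.file("extdata", "deficit_catalog.yaml",
                                    package = "frailtytrials"))
trials <- list(
  generate_trial(sim_preset("mci",      seed = 11, trial_name = "MCI-1", catalog = catalog)),
  generate_trial(sim_preset("mci",      seed = 12, trial_name = "MCI-2", catalog = catalog)),
  generate_trial(sim_preset("dementia", seed = 13, trial_name = "AD",    catalog = catalog)))
res <- run_pipeline(trials, catalog = catalog)
print(res)
```

```
Frailty pipeline results

Descriptive summaries:
 trial            variant    n n_excluded mean   sd  q99 robust mild moderate severe
 MCI-1           physical 1000          0 0.14 0.06 0.30   43.2 51.2      5.6    0.0
 MCI-1 physical_cognitive 1000          0 0.15 0.06 0.31   33.6 58.6      7.5    0.3
 MCI-2           physical 1000          0 0.14 0.06 0.33   40.6 52.6      6.7    0.1
 MCI-2 physical_cognitive 1000          0 0.15 0.06 0.33   31.7 59.2      8.7    0.4
    AD           physical  408          0 0.24 0.09 0.44    8.6 43.6     38.0    9.8
    AD physical_cognitive  408          0 0.29 0.08 0.48    0.7 28.7     52.2   18.4

Pooled associations (per 0.1 FI):
  sae       physical           IRR = 1.60 [1.30, 1.95]  tau2 = 0.018
  sae       physical_cognitive IRR = 1.61 [1.27, 2.02]  tau2 = 0.027
  attrition physical           OR = 1.34 [0.94, 1.90]  tau2 = 0.076
  attrition physical_cognitive OR = 1.37 [0.93, 2.02]  tau2 = 0.099
```

Reading this: the two MCI-like trials have mean physical FI 0.14 with
essentially no severe frailty and a 99th centile near 0.30 — frailty present
but its upper range truncated relative to general-population samples (~0.65).
The dementia-like trial is frailer (mean 0.24, 99th centile 0.44), and adding
the five cognitive deficits raises its mean to 0.29 while barely moving the
MCI trials — the physical-only index understates frailty specifically in
dementia. The pooled IRR of 1.60 per 0.1 FI recovers the generator's true
value of 1.6; the pooled attrition OR straddles 1 even though the
dementia-trial attrition effect is real (true OR 1.66), because the two
larger MCI trials were generated with a near-null OR of 1.05.

Individual stages are available as plain functions —
`build_fi_table()`, `summarize_fi()`, `select_best_fit()`,
`fit_sae_poisson()`, `fit_attrition_logistic()`, `pool_random_effects()` —
and a thin CLI lives in `inst/scripts/frailty_pipeline.R`
(`simulate` and `run` subcommands).

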