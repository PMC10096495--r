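---
title: "Small-area estimation of crisis-attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of crisis-attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisismort)
```

## The estimation problem

In protracted humanitarian crises, no vital registration exists, and the
question "how many people died because of this crisis?" has to be answered
from fragments: retrospective household mortality surveys done for
nutrition programming, discrepant census estimates, displacement tracking,
and routinely collected indicators such as armed-conflict event counts,
admissions of children with severe acute malnutrition (SAM) into
therapeutic feeding, and facility-reported epidemic cases. `crisismort`
implements a small-area estimation workflow over such inputs, stratified by
district and calendar month:

1. **Survey re-analysis.** Each eligible survey is reduced to household
   rows (deaths, person-days at risk) and fitted with an intercept-only
   Poisson model with a log person-time offset, giving the crude death rate
   (CDR) and under-5 death rate (U5DR) per 10,000 person-days with
   cluster-robust uncertainty.
2. **Population denominators.** Each census-source anchor is projected
   forward and backward month by month with a natural growth factor
   `g = (1 + r)^(1/12)` and net displacement flows, then the sources are
   averaged with quality-score weights.
3. **Predictor panel.** Raw predictor series are screened for completeness,
   imputed spatially, optionally spline-smoothed, converted to per-100,000
   person-month rates, lagged, and cut into ordered categories.
4. **Predictive model.** Household death counts across all surveys are
   regressed on recall-averaged predictor categories in a quasi-Poisson
   model offset by log person-time. Candidate predictors are screened, all
   subsets brute-force searched, and models ranked by cross-validated mean
   Dawid–Sebastiani score (DSS), with an 80/20 survey-level holdout as
   secondary confirmation.
5. **Excess mortality.** The fitted model predicts district-month death
   tolls under actual conditions and under counterfactual no-crisis
   scenarios; 10,000 bootstrap coefficient draws propagate model
   uncertainty, and excess is the within-replicate difference, summarised
   by histogram mode and 95% percentile interval.
6. **Sensitivity.** A multiplicative bias grid on population/displacement
   inputs, and a child-death under-reporting analysis that reattributes
   "unseen" deaths across households and re-runs the downstream stages.

Every stage is a package function; the numbered scripts under `analysis/`
are thin drivers that chain them and write tables under `results/`.

## The statistical model

For household $i$ in survey cluster $c$, deaths $y_i$ follow a
quasi-Poisson model

$$ E[y_i] = \exp\!\big(x_i^\top \beta\big)\, t_i, \qquad
   \operatorname{Var}[y_i] = \phi\, E[y_i], $$

where $t_i$ is household person-days at risk (entered as offset
$\log t_i$), $x_i$ holds the predictor terms averaged over the survey's
recall window, $\phi$ is the Pearson dispersion, and the coefficient
covariance $\Sigma$ is the CR0 sandwich clustered on $c$. Coefficients are
log rate ratios; quasi-Poisson point estimates coincide with the Poisson
MLE, so dispersion affects only uncertainty.

Predicted district-month tolls multiply the rate per person-day by
population person-time (population × days in month). Excess for a stratum
is
$$ \text{excess} = \sum_{d,t} \big( \hat\mu_{dt}^{\text{actual}} -
   \hat\mu_{dt}^{\text{counterfactual}} \big), $$
with both arms evaluated under the *same* coefficient draw
$\beta^{(b)} \sim N(\hat\beta, \Sigma)$ in every bootstrap replicate — an
identity counterfactual therefore yields exactly zero excess in every
replicate, a property the tests assert.

**Model-error interpretation.** The bootstrap samples coefficient
uncertainty only; Poisson realization noise is deliberately excluded
because the target is the *expected* excess toll, not a predictive draw of
one realized history. This is the single most consequential interpretation
in the package and is recorded in each run's manifest.

### Scoring and selection

The DSS for a held-out household is
$(y-\mu)^2/\sigma^2 + \log \sigma^2$ with $\sigma^2 = \phi \mu$ (the
quasi-Poisson-consistent predictive variance, with $\phi$ taken from that
fold's training fit); lower is better. Folds partition *surveys*, not
households, so a survey's clusters never straddle train and test — the
leakage-free choice given survey-level covariates. All subsets of the
screened candidates are scored on identical folds; the top 20%
(`ceiling(0.2 n)`) form the shortlist. In real-data applications of this
workflow the final model is chosen manually within such a shortlist; here a deterministic default
rule stands in — lowest holdout DSS, then fewest parameters — and the
manifest records that the rule fired. A parsimonious selected model can
legitimately omit weaker crisis channels (e.g. measles), which drags the
point excess somewhat below the generative truth; the acceptance script
therefore also reports recovery under the full generative specification.

### Counterfactual scenarios

The scenario rules are defined as follows: the
most likely scenario replaces SAM, measles and malaria with their
month-specific 2014–2016 medians within each district (falling back to the
region when a district lacks reference values) and conflict with its plain
2014–2016 median, and removes drought-attributed displacement from
January 2017 onward; the "worst case" keeps conflict and measles as
observed, raises SAM to the month-specific 75th percentile and scales
malaria to 25% of actuality; the "best case" lowers SAM to the 25th
percentile, zeroes measles, keeps malaria and scales conflict to 25%,
removing all new internal displacement. Refugee flows stay as observed in
every scenario, and counterfactual rules apply from January 2017 onward
(pre-crisis months are never altered).

One caveat worth stating plainly: taken literally, several "worst-case"
rules *raise* the counterfactual (p75 SAM, as-observed conflict), and
several "best-case" rules lower it, so on synthetic data the scenario
labels need not order the resulting excess the way their names suggest.
The rules are implemented as written; no direction is imposed.

## Key parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `growth_rate_yr` | 0.021 | natural yearly population growth |
| `under5_fraction` | 0.250 | proportion of the population under 5 |
| `w_in`, `w_out` | 1.0, 0.3 | spatial imputation weights (same region / other) |
| `smoothness` | 0.3 | `smooth.spline` spar for price series |
| completeness | 0.70 / 0.70 | cell and coverage thresholds for retention |
| `max_lag` | 6 | months of predictor lag explored |
| `cv_folds` | 10 | survey-level cross-validation folds |
| `train_frac` | 0.8 | holdout training share |
| `shortlist_frac` | 0.2 | share of ranked models shortlisted |
| `B` | 10,000 | bootstrap coefficient sets |
| `alpha` | 0.05 | percentile-interval tail mass |

Category cut-points: conflict events per 100,000 person-months at 0.25 and
0.50; malaria at 1 and 50; measles any-vs-none; SAM admissions at 100 and
200 per 100,000 person-months. The SAM cut-points are configuration
defaults — no canonical SAM cut-points exist for this kind of analysis, so
round per-100,000 values were fixed here and are flagged as a package
choice. All categorization is
half-open and lower-inclusive: 0.25 falls in the middle conflict band,
0.50 in the top one.

## What the synthetic generator emulates — and what it does not

`generate_world()` builds the full input stack with known ground truth:
district-month log death rates are exactly
`log(baseline) + sum(coefficient × term)` using the same category
cut-points and lags the models use, with baseline CDR 0.43 and U5DR 0.66
per 10,000 person-days and, as default truth, a rate-ratio set
representative of re-analyses of the 2017–18 Somalia drought crisis
(conflict ≥0.50: 1.60; SAM 1.36/1.48; malaria 0.78/0.71; measles >0:
1.27; south-central 0.97). A 2017–18 crisis window raises conflict, SAM
admissions and measles and suppresses malaria; displacement flows carry
reason tags whose 2016–18 aggregate lands near the reported
drought/insecurity/flooding/other split (≈54/30/13/3); four census anchors
carry independent multiplicative biases drawn uniformly within ±15%;
household sizes are shifted-Poisson with mean 5.6 and under-5 membership
binomial at 25%.

Surveys draw a district and a 3–4-month recall window; household death
counts are Poisson with expectation `rate × person-time`, where the
survey-level rate applies the true coefficients to *recall-averaged, then
categorized* predictor values — the same encoding the fitting stage uses,
so the model's estimand is well defined. Under-5 deaths are drawn first
and over-5 deaths added, keeping the under-5 count weakly below the
all-age count while both outcome expectations are exact. Cluster designs
support a lognormal multiplicative frailty on the cluster rate (mean 1,
variance configurable, default 0) to induce intra-cluster correlation; the
frailty variance is a free parameter, not an estimate: survey design
effects are not reliably known for these data.

Deliberate simplifications, hence what green tests do *not* show about
real data: members are listed for the whole recall window (no explicit
birth/join/leave event streams by default, so individual-mode person-time
has no truncation at death); aggregate-mode totals report the dead as
departed, which the mid-period convention undercounts by half a recall per
death (a <1% person-time effect at realistic death rates); predictors are
generated independently across months apart from the crisis factor, so
real serial confounding structures are not represented; census-source
biases are a single multiplicative factor per source, not spatially
structured error; and survey non-response, age heaping and frame exclusion
biases are absent entirely.

## Numerical choices

* **Intercept-only rates** use the closed form
  `log(Σ deaths / Σ person-days)` for the point estimate (the analytic
  MLE), with the sandwich variance from the IRLS fit, so the GLM identity
  holds to machine precision.
* **Zero-death surveys** report rate 0 with a one-sided exact Poisson
  upper bound (`qgamma(conf, 1) / person-time`).
* **Sandwich variant** is CR0 (no small-sample correction), clustered on
  the survey cluster; under a systematic design each household is its own
  cluster, where CR0 coincides with HC0 — asserted in the tests.
* **DSS floor**: predicted means are floored at 1e-12 so the log stays
  finite for degenerate predictions; comparisons are unaffected at
  realistic scales.
* **Aggregate person-time** uses the mid-period convention
  `recall × (N_end + ½(deaths + leaves − births − joins))`; no single
  standard formula exists for aggregate questionnaires, so this is a
  stated convention. Births count as under-5 entries; joins/leaves are
  treated as all-age only.
* **Confidence intervals** use normal quantiles on the log scale.
* **Percentiles** are type-7 (linear interpolation) everywhere, so
  intervals are bit-reproducible; the **mode** is the midpoint of the
  modal Freedman–Diaconis histogram bin, a bit-reproducible convention.
* **Unused factor levels**: when a rare category never occurs in a
  training subset, predictions for such district-months fall back to the
  reference level rather than failing.
* **Projection floor**: populations are floored at 1 person; floored cells
  are counted and surfaced as data-quality warnings. Backward projection
  uses the exact algebraic inverse of the forward step, so round trips are
  lossless, and net flows are applied after growth within a month (the
  ordering is a package decision).
* **Report rounding** is half-away-from-zero to the nearest 100;
  `unseen_deaths()` uses banker's rounding (documented, the source is
  silent).
* **Seeds**: one master seed fans out to per-stage seeds by hashing the
  stage name (`stage_seed()`), all below 2^31, so any stage can be re-run
  standalone and reproduce the orchestrated run bit for bit.

## Design choices on genuinely open points

* The completeness rule's two thresholds are read as: coverage share of
  district-months for ordinary predictors, with the cell threshold
  reserved for composite predictors assembled from sub-series.
* Recall-window averaging happens on the continuous scale *before*
  categorization, matching the continuous-then-cut order of the model
  terms.
* The under-reporting sensitivity *refits* the mortality model in every
  replicate — the expensive reading of re-running all downstream stages —
  with the replicate count configurable down to desk scale; the
  reattribution weights households by under-5 person-time (uniform
  weighting is the other defensible reading; the choice is logged).
  Because model covariates vary at survey level, reallocating deaths
  *within* a survey leaves the refitted coefficients, and hence the
  plug-in excess, unchanged: the replicate distribution of the point
  excess is degenerate by construction, and reattribution matters for
  cluster-robust uncertainty rather than the point estimate.
* Counterfactual displacement rules apply from January 2017 onward; the
  screening margin for "poor fit" defaults to 0 (any CV-DSS improvement
  over intercept-only retains a predictor).
* Random effects and interactions are represented as explored-and-rejected
  options: they are outside the default search space.

## Problem sizes used in tests and the acceptance script

The default synthetic study is 20 districts × 60 months with 60 surveys of
500 households each; the acceptance script runs it with B = 4,000
bootstrap sets (a few seconds end to end). Parameter recovery is checked
over 200 replications of 50 surveys; excess recovery over 100 scaled-down
runs (12 districts, 24 surveys, B = 500); coverage for survey intervals
over 300 replicate surveys. These sizes were chosen so each property is
measured with useful precision while a full check of the package remains a
coffee-break affair.

## Known limitations

* The excess interval propagates coefficient uncertainty only — not
  dispersion, denominator or survey-sampling uncertainty — so it is a
  lower bound on honest uncertainty; the bias grid quantifies denominator
  sensitivity separately.
* Model selection optimises predictive fit, not counterfactual
  sensitivity; a selected submodel can underestimate excess when it omits
  a crisis channel the scenarios act on. The shortlist plus selection rule
  make this explicit rather than hiding it.
* Categorical encodings discard within-band variation; a district sitting
  just under a cut-point for two years contributes no contrast.
* The quality score is a simplified checklist for reporting only; it is
  not the full SMART plausibility score and never weights anything.
* Livelihood-zone vs district frame mismatch, the dominant real-world
  exclusion reason, is represented only as metadata, not as geometry.

## A worked micro-example

```{r example, eval = FALSE}
world <- generate_world(world_config(seed = 1))
surveys <- generate_surveys(world, 40, seed = 2)
md <- survey_model_data(surveys, world$predictors, world$districts)
fit <- fit_quasipoisson(md, model_spec("CDR", c("admin_level", "conflict",
                                                "sam", "malaria", "measles")))
coef_table(fit)

cfg <- analysis_config(B = 2000, seed = 1)
boot <- excess_for_inputs(fit, world$predictors, world$districts,
                          world$anchors, world$flows,
                          scenario_spec("most_likely"), cfg, seed = 3)
summarize_excess(boot, "overall")
true_excess(world)$excess   # generator ground truth for comparison
```
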