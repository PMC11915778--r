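---
title: "Methods: deriving cardiac-extended SOFA scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving cardiac-extended SOFA scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cesofa)
```

## The problem

The SOFA score sums six organ sub-scores (0–4 each, 0–24 total). Its
cardiovascular component grades mean arterial pressure (MAP) and vasopressor
dose, which in a cohort where *every* patient receives vasopressors carries
little prognostic contrast and no information about the myocardium itself.
`cesofa` implements the machinery for extending SOFA with ordinal points for
cardiac biomarkers (hs-cTnT for myocardial injury, NT-proBNP for myocardial
dysfunction) and atrial fibrillation (arrhythmia), and for testing whether
the extension buys real discrimination for 30-day mortality.

This vignette documents the statistical procedure, the synthetic cohort the
package uses as its test bed, the numerical choices, and the limits of what
the passing test suite demonstrates.

## The derivation procedure

**Stage 1 — spline screening.** Each candidate variable $x$ (hs-cTnT,
NT-proBNP, HR, SBP, DBP, and the derived MAP $= \mathrm{DBP} +
(\mathrm{SBP}-\mathrm{DBP})/3$, PP $= \mathrm{SBP}-\mathrm{DBP}$, RPP
$= \mathrm{HR}\times\mathrm{SBP}$, PPP $= \mathrm{PP}/\mathrm{SBP}$) is
modelled by logistic regression of the 30-day outcome on a natural cubic
spline basis of $x$. The right-skewed biomarkers enter on the log scale.
Basis construction (`ncs_basis`): boundary knots at the data extremes,
interior knots at the equally spaced quantiles implied by the degrees of
freedom ($df-1$ knots at probabilities $1/df,\dots,(df-1)/df$), linear tails
outside the boundary. The df is selected over candidates $\{1,\dots,5\}$ by
minimising $\mathrm{AIC} = 2k - 2\ell$, ties toward the smaller df; df
candidates are an argument, and the default range was fixed once as the
smallest set that covers "linear" through "visibly flexible" at cohort sizes
in the hundreds. Discrimination is summarised by the AUC of the fitted risk.

**Stage 2 — ordinalization.** A retained variable is cut into five bins
worth 0–4 points (heart rate into three bins worth 0–2, reflecting its
weaker, narrower dose-response). "Balanced effect size across categories" is
operationalised as: choose thresholds so the mean spline-fitted log-odds of
the bins increases by equal increments bin to bin. The estimator
(`ordinalize`) initialises thresholds at equal quantiles and runs coordinate
descent over a quantile grid (0.5% steps) minimising the variance of
adjacent-bin increments, with every bin forced to keep at least 5% of the
observations; exact ties are broken toward the larger first-to-last span,
which also makes the two-bin case seek maximal separation. Objective, grid
resolution and mass constraint are all arguments. Two properties justify the
operationalisation: on data generated with risk linear in $\log x$ the
recovered cut-offs agree with a closed-form truncated-normal oracle for the
same objective, and the achieved increments evaluated under the generative
truth are equal to within a few percent. Note that the equal-increment
optimum is *not* equally spaced in $\log x$ — it concentrates cut-offs where
the latent density is high — so no geometric-spacing behaviour should be
expected or enforced.

Binning is **left-closed**: a value equal to a threshold enters the upper
bin. The convention is arbitrary but fixed and documented; thresholds are
stored in original variable units.

**Stage 3 — substitution models and extension.** The independent prognostic
value of each point group is tested in a multivariable logistic model of
mortality on the five non-cardiovascular SOFA sub-scores plus either the
conventional cardiovascular sub-score or the point group
(`substitution_fit`). A binary AF scheme enters as a presence indicator, so
its odds ratio reads "per presence of AF", not per point — with 0/2 coding a
per-point odds ratio would be the square root of the presence effect, which
is how such a table is conventionally read. Point groups with a positive,
significant association (Wald $p < .05$, OR $> 1$) are retained. Every
weighted combination of retained schemes — per scheme: absent, or weight 1–3
(1–2 for binary AF) — is enumerated (`enumerate_extensions`), each candidate
scored on the training cohort, ranked by AUC with ties broken toward fewer
added points, and the top four compared against base SOFA with the paired
DeLong test and the NRI (`select_best`).

**Stage 4 — validation.** The selected model is evaluated once on the test
cohort (`evaluate_extension`): AUC of the composite score against AUC of
base SOFA, paired DeLong test, category-free NRI, and a
quintile-of-predicted-probability calibration table with the
Hosmer-Lemeshow statistic. Predicted probabilities come from a univariate
logistic recalibration of the integer score on the evaluation cohort; this
is order-preserving, so NRI up/down movement reflects score movement.

## The inferential machinery

All of it is implemented in the package rather than delegated, so that every
reported number has a single auditable definition; the test suite
cross-checks against independent oracles (explicit pair counting for the
AUC, a bootstrap for the DeLong variance, `pROC` for the paired test,
closed-form 2×2 odds ratios for the logistic MLE).

* `fit_logistic` — IRLS with step-halving (deviance provably
  non-increasing), convergence on score norm $< 10^{-8}$, cap 100
  iterations; Wald standard errors from the inverse observed information;
  separation flagged (runaway coefficients or exploding SEs) with the
  affected CI bounds reported unbounded.
* `auc_ci` — Mann-Whitney estimator with midrank tie handling; variance from
  the DeLong structural components $V_{10}, V_{01}$.
* `delong_test` — paired comparison through the empirical covariance of the
  structural components; two-sided normal $p$; identical placements give a
  degenerate comparison reported as $z = 0, p = 1$ rather than 0/0.
* `nri` — category-free (any strict change in predicted probability counts),
  with the standard asymptotic variance; a categorical variant with
  user-supplied risk thresholds is available. The category-free variant is
  the default because no risk categories are pre-specified in this setting.
* `hosmer_lemeshow` — quintile groups by default (matching
  calibration-by-quintile reporting, not the conventional deciles), $\chi^2$
  on $g-2$ df; quantile boundary ties collapse into the lower group,
  deterministic; emptied groups are merged with a warning.
* `sample_size_auc` — smallest $n$ for a two-sided test of the empirical AUC
  against a null value, analytic (Hanley-McNeil variance under null and
  alternative) or Monte-Carlo (binormal simulation with bisection on $n$);
  the two agree within 10% on the design point used in the tests (null 0.70
  vs alternative 0.74, α .05, power .80, 31% events).

Two-sided tests and Wald intervals are used throughout.

## The synthetic cohort generator

The generator is the package's study-condition bed, not a tuning knob. Its
defaults emulate a vasopressor-dependent sepsis cohort:

| quantity | default | basis |
|---|---|---|
| hs-cTnT | log-normal, median 50 ng/L, log-sd 1.22 | pooled cohort median; spread back-computed from a survivor IQR under log-normality (log IQR width / 1.349) |
| NT-proBNP | log-normal, median 5300 ng/L, log-sd 1.39 | same construction |
| AF prevalence | 0.48 combined (57.5% of it pre-existing) | pre-existing + new-onset counts |
| HR / SBP / DBP | 95±18 / 110±18 / 60±10 | not reported for this setting; chosen once as clinically realistic for septic patients on vasopressors |
| SOFA sub-scores | iid per component over {0..4}, P = (.40,.30,.17,.09,.04) | gives a total (with the computed cardiovascular component) around 9 ± 3 |
| vasoactive doses | norepinephrine log-normal median 0.2 µg/kg/min; dopamine in 5%; other agent in 8% | peak-norepinephrine reporting; keeps the cardiovascular sub-score concentrated at 3–4 as in a pressor-dependent cohort |
| 30-day mortality | 0.31 | target for intercept calibration |

The outcome is drawn from
$\operatorname{logit} P(\text{death}) = \beta_0 + \sum_v \beta_v x_v$, where
the $x_v$ are the five SOFA sub-scores, the computed cardiovascular
sub-score, the biomarker point groups cut at the 20/40/60/80th percentiles
of their marginal distributions, AF presence and the HR point group. Default
effects use published substitution-model odds ratios as generative truth
(hs-cTnT 1.88/point, NT-proBNP 1.68/point, AF 4.15 per presence, non-CV SOFA
sub-scores 1.27–1.43/point); the cardiovascular sub-score and HR effects are
zero, mirroring their non-significance in that structure. $\beta_0$ is found
by bisection on a fixed-seed calibration sample of 20 000 covariate draws so
the marginal mortality hits the target to $10^{-4}$ (`calibrate_intercept`);
the expectation is monotone in $\beta_0$, so bisection cannot stall.

Because the outcome sees the biomarkers only through their point groups, the
generative cut-offs are a well-defined truth for ordinalization recovery,
and the generative odds ratios are a well-defined truth for
parameter-recovery tests (each generative log-odds falls inside its 95% Wald
CI in ≥90/100 replicates at n = 5000).

**What the generator does not emulate.** Covariates are drawn independently
by default (real biomarkers, hemodynamics and organ failure are correlated;
a `latent_correlation` hook accepts a user matrix for sensitivity analyses);
biomarker values are single admission samples with no kinetics; there is no
missingness; the outcome model is exactly logistic in the point groups, so
model misspecification — the main hazard in real derivation work — is absent
by construction. Passing tests therefore demonstrate correctness of the
machinery under the stated data-generating process, not clinical validity of
any derived cut-off.

## Data contracts and degenerate inputs

* Cohorts are plain CSV/data.frames with a fixed schema; validation reports
  offending rows by number. Biomarker values below assay detection are
  stored at floors (hs-cTnT 3 ng/L, NT-proBNP 5 ng/L) so log transforms stay
  finite.
* MAP is always computed from SBP/DBP, never read, so derived hemodynamics
  cannot contradict the recorded pressures.
* Pre-existing and new-onset AF are distinct input levels, collapsed into a
  single presence variable everywhere downstream.
* The train/test split is seeded simple random sampling; the seed is part of
  every provenance record. Degenerate requests (empty train or test side)
  are errors.
* Single-class cohorts make AUC, NRI and the DeLong test undefined and raise
  errors rather than returning NaN; constant predictors make `ordinalize`
  fail with a "distinct values" error.

## Problem sizes in the shipped tests

The suite runs the type-I-error study of the paired DeLong test at 2000
replicates of n = 250 (prevalence 0.3), parameter recovery at 100
replicates of n = 5000, Hosmer-Lemeshow null calibration at 500 replicates
of n = 2000, ordinalization recovery at n = 10 000, and the end-to-end
pipeline property (selected extension's training AUC at least that of base
SOFA) over 50 seeds at the 503/250/253 design. These sizes were chosen so
that Monte-Carlo error is small relative to each assertion's tolerance.

## Known limitations

* The equal-increment ordinalization objective is one reading of "balanced
  effect size"; alternatives (equal observed-risk increments, ordinal
  regression with equality constraints) would give different cut-offs. The
  objective function is isolated and swappable.
* Wald inference throughout; near-separation (e.g. an AF scheme in a tiny
  cohort) is flagged but not profiled.
* The heart-rate point range (0–2 by default) and the AF weight ceiling
  (double) are conventions of the shipped defaults, both configurable.
* No default CE-SOFA cut-offs ship with the package: published thresholds
  must be transcribed by the user, or re-derived — the package deliberately
  does not pretend to know numbers it cannot compute.
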