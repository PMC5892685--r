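---
title: "Methylation-based survival indicators, frailty and mortality: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-based survival indicators, frailty and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`methrisk` compares three indicators of biological age as predictors of
all-cause mortality in cohorts of older adults: a 10-CpG blood-methylation
mortality risk score (count-based MRscore and weighted continuous
cont.MRscore), epigenetic age acceleration (AA), and a
deficit-accumulation frailty index (FI). It covers score construction,
deficit screening and imputation, batch-adjusted association models with
meta-analytic pooling, survival inference under three sampling designs,
and predictive-accuracy comparison — driven by a synthetic-cohort
generator so that every stage is testable without subject-level data.

DNAm age itself (the epigenetic clock) is an *input* column; the package
does not implement the clock, nor array normalization, nor leukocyte
deconvolution (cell proportions enter as plain covariates).

# The indicators

**cont.MRscore.** A weighted sum of ten beta values,
$\mathrm{score}_i = \sum_{k=1}^{10} w_k \beta_{ki}$, with fixed published
weights held in `mortalityWeights()`. Nine CpGs carry negative weights
(hypomethylated with increasing risk); cg08362785 carries the single
positive weight. The weights sum to $-6.31557$, which pins down the score's
attainable range $[-6.31557, 0]$ before sign conventions; subjects with a
missing score CpG are flagged, never silently dropped.

**MRscore.** The count of CpGs whose beta lies in the mortality-associated
extreme quartile: $\beta \le Q_1$ for hypomethylated CpGs, $\beta \ge Q_3$
for the hypermethylated one. Two numerical conventions are fixed and
documented rather than guessed per call:

- *Quantile convention*: linear interpolation between order statistics
  (R's `type = 7`), the default of mainstream numerical stacks. The
  original study's convention is unknown; what matters for reproducibility
  is that ours is stated and immutable.
- *Boundary*: aberrance is inclusive (`<=` / `>=`). With a strict
  inequality an all-tied degenerate beta column would make "the lowest
  quartile" empty; inclusive boundaries keep that case well defined
  (the cutoff equals the constant, with a warning).

Thresholds may be supplied externally (to mirror a reference study's fixed
cutoffs) or derived in-sample; in-sample is the default because reference
cutoff values are not available, only the rule.

Scores are grouped for reporting into the categories 0 / 1 / 2–5 / >5.

**Age acceleration.** OLS residuals of DNAm age on chronological age,
computed *within the analysis sample*. Residuals are exactly orthogonal to
age and invariant to adding a constant to all DNAm ages — both asserted in
the test suite at $10^{-10}$. Per-subset computation (rather than pooled)
was chosen because descriptive statistics of this kind are reported
subset by subset; it also keeps AA mean-zero within every analysis sample.

**Frailty index.** $\mathrm{FI} = \#\{\text{deficits present}\} /
\#\{\text{deficits considered}\}$ over a 34-deficit panel. Candidate
deficits are screened for: overall prevalence $> 1\%$; prevalence
$\le 50\%$ among subjects aged 50–60 ("early saturation" — we read the
saturation clause and the 50% anchor as one rule, since the eligibility
sentence supplies exactly one quantitative anchor); and accumulation with
age, operationalized as a positive Spearman correlation with age at
$p < 0.05$ (the criterion is named in the field's standard procedure but
no test is specified; a rank test is robust to the indicator's
discreteness). Association with general health status cannot be judged
from the panel alone, so it is exposed as a user-supplied keep-list, not
an automatic rule.

Missing deficits are handled by multiple imputation (default $m = 20$,
matching standard practice for this analysis): chained logistic models of
each incomplete deficit on age, sex and the mean of the subject's other
currently-imputed deficits, iterated three cycles per imputation. The
deficit-mean summary (rather than 33 raw columns) keeps every logistic fit
full rank on small panels and is the main approximation relative to a full
chained-equations implementation. The observed-denominator path
(`frailtyIndex(..., denominator = "observed")`) is available but not the
default; an imputed denominator keeps FI comparable across subjects.

# Association stage

FI (in % units) is regressed on each indicator's z-score by
random-intercept linear models with methylation batch as the grouping
factor (REML via `lme4`); z-scores are standardized within each analysis
subset, so "per SD" always means the subset's own SD. The model ladder is
configuration, not code: Model 1 adjusts age, sex and cell-composition
covariates; Model 2 adds smoking and alcohol; Model 3 enters the mortality
score and AA jointly. Subset estimates are pooled by DerSimonian–Laird
random-effects meta-analysis (method-of-moments $\tau^2$; the estimator is
documented and swappable — REML or Paule–Mandel variants are deliberately
out of scope). Per-CpG frailty scans report effects per 10%-unit
*decrease* in methylation (so positive coefficients mean frailty rises as
methylation falls) and apply Benjamini–Hochberg correction across the CpG
list at $q = 0.05$.

One spec-level invariant was dropped as mathematically false: BH
adjustment is *not* idempotent (adjusting `(0.1, 0.9)` gives
`(0.2, 0.9)`; re-adjusting gives `(0.4, 0.9)`). Monotonicity and the cap
at 1 are asserted instead.

Estimates across imputations are pooled by Rubin's rules
($T = W + (1 + 1/m)B$ with Rubin's small-sample degrees of freedom).

# Survival stage

- **Full cohort**: Cox proportional hazards, Efron tie handling by default
  (follow-up times at coarse resolution make ties likely; Breslow is a
  config option), Newton iterations to a $10^{-10}$ gradient tolerance.
- **Case-cohort**: Barlow weighting via a counting-process fit — subcohort
  members contribute person-time at weight $1/\alpha$ (inverse sampling
  fraction) up to just before failure; every case contributes its own
  failure at weight 1; non-subcohort cases enter the risk set only just
  before their failure. The pre-failure entry offset is
  $10^{-6} \times \min(\text{event times})$, with `survival`'s time
  rounding disabled so the offset is never collapsed. CIs use the robust
  sandwich variance (the weighted "naive" variance overstates the
  information in the reweighted sample). With $\alpha = 1$ the fit reduces
  exactly to the unweighted Cox fit, which the tests assert at $10^{-8}$.
- **Nested case-control**: maximum-likelihood logistic regression with
  Wald CIs; separation and rank deficiency are errors, not warnings.

Follow-up time is measured from study entry with age as a covariate (not
as the timescale). Effects are reported per reporting unit (1 unit
cont.MRscore, 5-year AA, 10%-unit FI) and per SD; the per-SD row is the
same fit rescaled, $\mathrm{HR}_{SD} = \mathrm{HR}_{unit}^{r}$ with $r$
the unit ratio, never a refit. Exact covariate sets per model are not
fixed by any external source and therefore live in `analysisConfig()`;
subjects missing an indicator are dropped listwise per model, with counts
reported, since each analysis defines its own available-data sample.

# Predictive accuracy

**Harrell's C** counts a pair as comparable when the earlier follow-up
time is an event (including event-vs-censored ties at the same time) and
as concordant when the earlier event has the higher risk; risk ties count
1/2. Pairs of tied event times are incomparable. The CI uses a
Noether-type asymptotic SE over the pair indicators,
$\sqrt{C(1-C)/n_{\text{pairs}}}$ — a deliberately simple estimator whose
form is stated so it can be compared or replaced; no standard CI method is
canonical here. The implementation is verified against a brute-force
all-pairs oracle, exactly, on hundreds of random instances with time and
risk ties.

**Brier prediction-error curves** use IPCW with Kaplan–Meier censoring
weights: events by $t$ weighted $1/G(T^-)$, survivors past $t$ weighted
$1/G(t)$, censored-before-$t$ subjects weight 0. Without censoring this
reduces (to machine precision) to the plain mean squared error against
$1\{T > t\}$. Survival predictions come from each Cox model's Breslow
baseline; score-only curves use a univariate Cox fit on the score. Curves
are apparent (in-sample) errors — no cross-validation is applied, matching
the apparent-C convention — and the default grid stops at 13.5 years
because $G(t)$ hits zero at an administrative censoring horizon (14
years), where the IPCW weight is undefined; user grids beyond the horizon
are truncated with a warning.

**Time-dependent AUC** uses the cumulative-cases / dynamic-controls IPCW
estimator and collapses to the plain rank AUC of $1\{T \le t\}$ without
censoring. For case-control samples the rank AUC of logistic predicted
probabilities (ties 1/2) is the reported C-index.

# The synthetic-cohort generator

The generator defines the study conditions; it is not a tuning dial. A
standard-normal latent risk factor $L_i$ couples methylation to frailty:

- ages uniform on 50–75 years; DNAm age $= \mathrm{age} +
  N(0, 6.5^2)$ years, calibrated so Spearman(age, DNAm age) $\approx
  0.75$;
- score-CpG betas on the logit scale: CpG mean $+ \lambda_k L_i +$ batch
  shift $+ N(0, 0.35^2)$, with $|\lambda_k| = 0.10$ signed by each CpG's
  mortality direction; 4 batches with a common logit shift of SD 0.1;
- deficits Bernoulli with logit $= -1.75 + 0.04(\mathrm{age} - 50) +
  0.25 L_i + N(0, 0.6^2)$ plus a centred per-deficit offset (SD 0.4).
  Centring matters: it makes the panel-average prevalence — the FI
  calibration target of 25% with SD ≈ 14% — stable across realizations
  while preserving per-deficit heterogeneity. Deficit missingness is MCAR
  at 5% to exercise the imputation path (no external basis for an
  informative mechanism);
- survival is Weibull (shape 1.1, scale 50 years) with log-hazard linear
  in the z-scores of the *realized* cont.MRscore, FI and AA (defaults
  $\ln 2.0$, $\ln 1.4$, $\ln 1.16$ per SD) plus 0.07/year of age,
  censored at min(14 years, exponential dropout at 0.01/year) — about a
  quarter of subjects die by year 14.

All slope/noise defaults were fixed once by simulation at $n = 5000$
against the descriptive anchors above and are recorded in
`trueParams()` of every simulated cohort. The case-cohort design keeps all
deaths plus a Bernoulli($\alpha$) subcohort with Barlow weights; nested
case-control keeps all deaths plus sampled controls.

What the generator does **not** emulate: realistic co-methylation/LD
structure beyond the single latent factor; the 485k-probe array (only the
10 score CpGs plus an optional extra block are generated); graded
(non-binary) deficits; informative censoring or missingness; and any
non-proportional hazards. Passing tests therefore demonstrate correctness
of the estimators under a proportional-hazards, single-factor world — not
that real cohort data satisfy those assumptions.

# Problem sizes and determinism

The test suite runs at desk scale: calibration checks at $n = 5000$,
recovery experiments at $n \le 3000$ with up to 100 replicates, pipeline
round-trips at $n \le 1500$ — sizes chosen so the whole suite completes in
about a minute while keeping Monte-Carlo error well inside every asserted
band. Every stochastic function takes a seed and restores the caller's RNG
state; identical configuration plus seed yields bit-identical cohorts and
byte-identical pipeline tables.

# Known limitations

- The Noether-type C interval ignores between-pair correlation and is
  anti-conservative for small samples; it is a reporting convenience, not
  an inferential guarantee.
- The imputation model conditions on a deficit-mean summary, which can
  attenuate deficit-specific dependence under strong missingness.
- Barlow weighting is the only case-cohort estimator implemented
  (Prentice/Self–Prentice variants are out of scope).
- Apparent (in-sample) accuracy metrics overstate out-of-sample
  performance; only apparent curves are implemented, since `brierCurve()`
  accepts arbitrary predicted survival matrices a user could supply from
  any resampling scheme.
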