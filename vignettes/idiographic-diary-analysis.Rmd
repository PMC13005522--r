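---
title: "Person-specific analysis of intensive longitudinal diary data"
author: "idiodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-specific analysis of intensive longitudinal diary data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idiodyn)
```

# Why person-specific?

Group-level (nomothetic) statistics describe individuals only under
strong homogeneity and stationarity assumptions. Daily-diary studies
with 75--100 assessments per person permit the opposite strategy: treat
each person as their own study, with days as the unit of observation,
and generalize to that person's future days rather than across people.
`idiodyn` implements three idiographic analysis stages for bounded
daily self-report data (femininity/masculinity composites on 1--5,
depressive-symptom composites on 0--2, sensation seeking on 1--4, a
0--5 verbal-recall count) together with a binary day-level
hormone-milieu indicator (1 = low milieu: menstrual bleeding or
inactive pill; 0 = high milieu):

1. **Intraindividual descriptives** -- each person's own mean (iM) and
   sample standard deviation (iSD) per variable, a variability
   classification, and day-level dominance counts.
2. **Phase-moderated residualized regression** -- daily recall,
   residualized on its own one-day lag, regressed on femininity, the
   hormone-milieu phase, and their interaction, with a simple-slopes
   decomposition.
3. **Person-specific hybrid uSEM networks** -- a unified structural
   equation model over the lag-embedded day pairs, combining directed
   same-day paths, directed next-day paths and residual covariances,
   grown by a Lagrange-multiplier forward search.

Because participant-level diary data of this kind are typically not
shareable, the package ships a synthetic generator
(`simulateStudy()`) whose ground truth is recorded next to every
dataset, so each stage can be validated by parameter recovery rather
than by reproducing any particular participant's numbers.

# Data model

A `PersonSeries` stores one person's day-by-variable matrix on the
full calendar grid `1..T` with a parallel logical observation mask; a
skipped day is a fully masked row, so day 4 after day 2 is *not*
treated as day 3's successor. This matters for anything lagged: diary
items ask about "today"/"the past 24 h", so a (t-1, t) pair is only
meaningful for truly consecutive calendar days. `lagEmbed()` therefore
pairs consecutive calendar days on which all requested variables were
observed, and drops the rest (listwise deletion; full-information
alternatives are out of scope). A guard refuses analyses with fewer
than 10 complete pairs (`minPairs`, configurable).

Composites (e.g. the three-item femininity score) are averaged per
day; by default a composite is missing whenever any constituent item
is missing that day -- the conservative choice, since no partial-item
rule is standard -- with `rule = "available"` as the alternative.
Compliance filtering retains persons with a response rate of at least
0.80 on every analysis variable (boundary inclusive), the emerging
field standard for this design.

All standardization uses the sample (n - 1) denominator, matching the
convention under which standardized coefficients are reported; iSD
likewise uses n - 1 by default with a population-denominator switch
for sensitivity checks.

# Intraindividual descriptives

`intraMean()` and `intraSD()` use observed days only. The variability
classification (`classifyVariability()`) defaults to iSD < 0.21 =
low, iSD > 0.50 = high. These two numbers were originally
sample-selection devices for illustrating low- versus high-variability
women, not universal cutoffs; they are exposed as arguments and the
boundaries themselves fall in the `mid` class (strict inequalities on
both sides).

# Phase-moderated residualized regression

For one person, with daily recall $y_t$, femininity $f_t$ and phase
$m_t \in \{0, 1\}$:

1. **Residualize**: fit $y_t = a + \phi\, y_{t-1}$ by OLS over
   complete consecutive-day pairs, keep $r_t = y_t - \hat a -
   \hat\phi\, y_{t-1}$. This removes the autoregressive carry-over --
   yesterday's score predicting today's -- before asking the
   substantive question.
2. **Moderate**: fit $r_t = b_0 + b_f f_t + b_m m_t + b_{fm} f_t m_t +
   \varepsilon_t$ by OLS with classical SEs and t tests on $n - 4$
   degrees of freedom.
3. **Decompose**: the femininity--recall slope is $b_f$ in the high
   milieu ($m = 0$) and $b_f + b_{fm}$ in the low milieu, with
   $\mathrm{SE} = \sqrt{V_{ff} + V_{ii} + 2 V_{fi}}$ from the
   coefficient covariance. The identity
   $\text{slope}_{\text{low}} - \text{slope}_{\text{high}} = b_{fm}$
   holds exactly, and recoding the phase swaps the two slopes exactly.

Design choices, all configurable and all recorded in the per-person
report:

* Only the **outcome** is residualized on its own lag ("the previous
  day variable predicting itself"); predictors enter raw. A
  `residualizePredictor` switch exists because the alternative reading
  is defensible.
* Femininity is **not centered** before forming the interaction, so
  main effects keep their reference-level reading. `centerPredictor`
  switches this.
* **Classical OLS SEs**: the AR(1) pre-whitening is the stated remedy
  for serial dependence; an autocorrelation-robust option would be a
  natural extension but is off by default.
* **Phase coding** defaults to 1 = bleeding/inactive pill (low
  milieu). Published coefficient tables for this design differ in
  which level they call the reference group, so the report always
  prints the reference level rather than assuming one convention.

Under the generator with $s_0 = 0.2$, $s_1 = -0.6$, AR 0.3, noise SD
0.5 and $T = 75$ (the diary length of the moderated-regression
study), the interaction estimate is recovered with mean bias well
inside $\pm 0.05$ and 95% CI coverage near nominal (0.90--0.98 band);
the simple-slope identity holds to machine precision in every
replicate. The validation draws femininity as standardized white
noise, which keeps slope recovery separable from the
AR-residualization step (whose own recovery is tested separately);
with autocorrelated predictors the residualization can transmit a
small finite-sample bias, a known property of residualized designs.

# The hybrid uSEM network

## Model

For $p$ variables, let $\eta_t$ be the current day and
$\eta_{t-1}$ the previous day (the "lagged block"). The structural
model is

$$\eta_t = A\,\eta_t + \Phi\,\eta_{t-1} + \zeta_t,\qquad
\zeta_t \sim N(0, \Psi),$$

where $A$ (zero diagonal) holds directed contemporaneous same-day
paths, $\Phi$ holds directed next-day paths -- its diagonal, the
autoregressions, is always estimated for model performance -- and
off-diagonal entries of $\Psi$ are residual covariances, the "hybrid"
ingredient, interpretable as the footprint of an unmodeled common
cause (e.g. masculinity and femininity both driven by latent gender
expression). The covariance of the lagged block is saturated. With
$B = (I - A)^{-1}$ the implied covariance of the stacked
$(\eta_{t-1}, \eta_t)$ vector is

$$\Sigma = \begin{pmatrix}
\Sigma_{xx} & \Sigma_{xx}\Phi' B' \\
B \Phi \Sigma_{xx} & B(\Phi \Sigma_{xx} \Phi' + \Psi)B'
\end{pmatrix}.$$

## Estimation

`fitUSEM()` minimizes the ML discrepancy
$F = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - 2p$ over the
free structural parameters, on the sample covariance $S$ of the
z-scored lag-embedded data. Because the exogenous block is saturated,
the likelihood factorizes and $\hat\Sigma_{xx} = S_{xx}$ exactly; the
optimizer works on the concentrated conditional discrepancy, which
also makes the expected information block-diagonal between
$\Sigma_{xx}$ and the structural parameters, so score tests and SEs
need only the structural block. Numerics: quasi-Newton (`nlminb`)
with analytic gradients, followed by Fisher-scoring polish until the
gradient norm falls below 1e-8 (convergence is declared below 1e-6).
The polish step is what makes exact identities hold at test
tolerance: a saturated (df = 0) pattern reaches `chi2 <= 1e-8`, and
recursive diagonal-$\Psi$ patterns reproduce per-equation OLS
coefficients to 1e-5 (the per-equation factorization is the
independent oracle for this estimator). Residual variances are
bounded below at 1e-6; a fit ending on the bound is flagged as a
Heywood case. `chi2 = (N - 1) F` -- the (N - 1) multiplier is the
classical convention and is recorded in every export.

Fit indices follow the standard definitions (`computeFitIndices()`):
RMSEA $= \sqrt{\max(\chi^2 - df, 0)/(df\,(N-1))}$ (0 at df = 0), SRMR
as the root mean squared standardized residual moment over the unique
$i \le j$ entries, CFI and NNFI against the independence baseline
(all covariances zero, variances free; NNFI reported as 1 at df = 0
by convention). "Excellent" thresholds are RMSEA $\le .05$, SRMR
$\le .05$, CFI $\ge .95$, NNFI $\ge .95$.

## Forward search

`forwardSearch()` starts from the null structural model
(autoregressions + residual variances only) and repeats:

1. Stop if at least 2 of the 4 indices are excellent (the
   conventional "fits well" rule; count and thresholds configurable).
2. Score every admissible fixed-at-zero candidate with a univariate
   Lagrange-multiplier statistic
   $\mathrm{MI} = (N-1)\, g^2 / (2h)$, where $g$ is the gradient of
   $F$ in the candidate and $h$ its expected-information diagonal
   Schur-adjusted for all free parameters -- the estimated
   $\Delta\chi^2$ from freeing the candidate without refitting
   (verified against brute-force refits, Spearman agreement
   $\approx 1$).
3. Free the top-scoring candidate if it passes the significance test
   (below), refit warm-started, and record the step; a refit that
   fails to converge or drives $I - A$ near singularity (condition
   $> 10^{10}$) is reverted and the candidate blocked.

Admissibility: no contemporaneous self-loops; the reverse of an
already-freed contemporaneous path is excluded (reciprocal same-day
pairs are weakly identified and make models fragile); lagged
off-diagonals and unordered residual pairs are always candidates.
Ties are broken deterministically (score, then contemporaneous >
lagged > residual covariance, then row/column order). `maxSteps`
defaults to $2p^2$.

**Candidate significance is tested family-wise.** Each search step
scans roughly $2p(p-1) + p(p-1)/2$ candidates (30 at $p = 4$). Testing
each at $\alpha = .05$ on $\chi^2(1)$ lets the *maximum* null MI
exceed the bar in a large fraction of searches, so a search on data
with no structural paths would add spurious edges 20--30% of the
time. The default therefore applies a Bonferroni correction over the
candidate set scanned at each step (`correction = "bonferroni"`,
family-wise $\alpha = .05$); measured on null-truth data at $T = 100$
this keeps 95--98% of searches free of spurious edges while true
standardized 0.4 paths are still recovered (see below).
`correction = "none"` restores the literal per-candidate test.

After stopping, non-significant freed structural parameters are
pruned one at a time (largest p first, refitting in between) --
autoregressions and residual variances are exempt. Pruning is a
convention of this estimation framework rather than part of the
substantive model, so every export flags whether it was applied.

## What recovery can and cannot promise

At the study scale ($p = 4$, $T = 100$, standardized 0.4 paths),
validation gives a differentiated picture:

* **Dependence detection** -- that a relation exists between the
  right pair of variables -- succeeds in ~95% of replicates.
* **Lagged (next-day) paths** are recovered with the correct
  direction in >90% of replicates: the lagged moment
  $\mathrm{cov}(\eta_{j,t-1}, \eta_{i,t})$ points at the direction
  directly.
* **Contemporaneous direction** is the hard part. The three
  equal-parameter representations of a same-day dependence
  ($i \to j$, $j \to i$, residual covariance) differ in population
  discrepancy by only $\Delta\chi^2 \approx 4$--$7$ at $N = 99$, so
  sampling noise misassigns the representation in roughly 15--20% of
  detected cases; exact-direction sensitivity for contemporaneous
  paths lands near 0.70--0.80. This is an information limit of the
  design, not of the optimizer: direction is identified by
  autoregressive asymmetry between the two variables, and vanishes
  entirely when their inertias are equal. Substantively,
  contemporaneous edge directions in person-specific networks at this
  length should be read with caution.

# The synthetic generator

`simulateStudy()` composes, per person: a phase sequence from a
regimen; a latent structural-VAR series; optionally a phase-moderated
recall series; optional Likert discretization; and whole-day MCAR
missingness. Identical configurations reproduce byte-identical CSVs.

* **Phase regimens** (`simulatePhaseSequence()`): natural cycle
  (default 28-day cycle, 5 bleeding days at onset; also used for
  pre-menopause), OC packs (default 21 active + 7 inactive; phase = 1
  on inactive days), post-menopause (no low-milieu days), and
  perimenopause (cycle lengths drawn uniformly from a configurable
  21--60 day range -- menstrual irregularity is the defining feature
  of that stage).
* **Dynamics** (`simulateUSEM()`):
  $\eta_t = B(\mu + \Phi\,\eta_{t-1} + \zeta_t)$ with a 50-step
  burn-in so day 1 is already (approximately) stationary; a
  non-stationary truth (spectral radius of $B\Phi \ge 1$) is refused
  before simulation. `standardizedUSEMTruth()` calibrates diagonal
  residual variances so every stationary variance equals 1, which
  makes the truth's coefficients directly readable as standardized
  path weights -- the scale on which network edges are reported.
* **Recovery-study truth.** Where magnitudes are not pinned down
  externally, the package's validation truth uses standardized paths
  of 0.4 (a medium-large effect, the conventional 0.3--0.5 band for
  such simulations) and *heterogeneous* autoregressions
  `diag(0.5, 0.25, 0.45, 0.2)`. Heterogeneity is both more realistic
  -- daily variables differ markedly in inertia (mood-like composites
  carry over more than behavior counts) -- and the feature that makes
  contemporaneous direction identifiable at all (see above).
* **Moderated recall** (`simulateModeratedOutcome()`):
  $y_t = c + \mathrm{ar}\, y_{t-1} + (s_0 + s_1 m_t) f_t +
  \varepsilon_t$, started at the stationary mean.
* **Discretization** (`discretizeToScale()`) maps the in-sample
  1st--99th percentile range affinely onto the scale, clips, and
  rounds for integer scales; the percentile anchor stops outliers
  from compressing the bulk of the distribution onto a few
  categories. Constant input maps to the scale midpoint. Estimator
  validation runs on the *continuous* outputs: discretization is a
  robustness surface, and correctness must be measurable without the
  coarsening.
* **Missingness** (`applyMissingness()`): each day is dropped
  whole-sale (all variables and the phase report) with probability
  $\le 0.2$, MCAR -- the mechanics of a skipped diary day under the
  80% compliance standard. The generator does not model MNAR
  compliance, item-level responses, or the pharmacokinetics of
  exogenous hormones; passing tests therefore speak to estimator
  correctness under the stated mechanism, not to robustness against
  informative missingness or coarse scales.

# Validation scale

The test suite and the acceptance script exercise the package at the
designs' own sizes: $T = 75$ for the moderated regression (500 and
200 replicates respectively), $T = 100$ with $p = 4$ for network
recovery (100 and 40 replicates), $T = 200$ for score-test/refit
agreement (20 and 5 seeds), $T = 2000$ for AR recovery, and
$T = 5000$ for moment checks of the generator. Consecutive small
integers seed the replicates.

# Known limitations

* The 0--5 recall count is modeled linearly, as in the original
  analysis; an ordinal or binomial likelihood is a noted extension.
* Only lag 1 is supported in the network stage (next-day relations).
* Listwise deletion of incomplete day pairs; no full-information
  missing-data handling.
* Contemporaneous edge direction at $T \approx 100$ is weakly
  identified (see above); lagged edges and edge existence are the
  robust readings.
* The grouping/subgroup machinery of multi-person network frameworks
  is intentionally out of scope: every analysis here is strictly
  person-specific.
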