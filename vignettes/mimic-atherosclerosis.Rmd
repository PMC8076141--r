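---
title: "Latent-factor modeling of radiation effects on atherosclerosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-factor modeling of radiation effects on atherosclerosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Atherosclerosis is not one pathology but (at least) three interdependent
ones — arterial stiffness, vascular calcification, and plaque — and no
single clinical measurement captures any of them completely.  A
cross-sectional survey of an irradiated cohort therefore measures a battery
of indicators: left and right brachial-ankle pulse wave velocity (baPWV),
augmentation index (AI) and central systolic blood pressure (cSBP) for
stiffness; thoracic (grade 0–3) and abdominal (score 0–24) aortic
calcification read from X-ray films; left and right common-carotid and
internal-carotid intima-media thickness (IMT), ankle-brachial index (ABI)
and pulse upstroke time (UT) for plaque.  Analyzing each indicator
separately ignores their correlations, multiplies tests, and produces
inconsistent left/right estimates.

`mimicsem` implements the alternative: a multiple-indicators,
multiple-causes (MIMIC) structural equation model in which observed
covariates (radiation dose in weighted Gy, age, sex, city, proximal/distal
location at exposure, their interaction, and smoking) predict three latent
factors, and the factors generate the 14 indicators.

## Model

For participant $i$ with covariate vector $x_i$ (length $q$), latent
factor vector $\eta_i$ (length 3) and indicator vector $y_i$ (length 14):

$$\eta_i = \Gamma x_i + \zeta_i, \qquad \zeta_i \sim N(0, \Psi),$$
$$y_i = \nu + \Lambda \eta_i + K x_i + \epsilon_i, \qquad
  \epsilon_i \sim N(0, \Theta),$$

so that, conditional on covariates,

$$\mu_i = \nu + (\Lambda\Gamma + K)\,x_i, \qquad
  \Sigma = \Lambda \Psi \Lambda^\top + \Theta .$$

Structure of the final model (`atherosclerosis_spec()`): each indicator
loads on exactly one factor (4 stiffness, 2 calcification, 8 plaque
loadings); $\Psi$ has a fixed unit diagonal and three free off-diagonal
factor residual correlations; $\Theta$ is diagonal plus four free residual
covariances (AI–cSBP and the left/right pairs of CCA IMT, ABI, UT, which
share hardware or anatomy); one direct covariate–indicator path
(sex $\to$ AI, a well-documented sex difference in augmentation index).
Covariate sets differ by factor: stiffness is adjusted for dose, age, city,
distal and city $\times$ distal; calcification additionally for age$^2$,
sex and smoking (current/past dummies, never as reference); plaque
additionally for smoking.

**Identification.** The factor *residual* variances are fixed at 1.0
($\Psi_{ff} = 1$), the convention under which all loadings are free and the
factor scale is set by the covariate model.  Consequently
$\operatorname{Var}(f) = \gamma_f^\top S_x \gamma_f + 1 \ge 1$ and the
factor's $R^2$ is $1 - 1/\operatorname{Var}(f)$.  Each factor's sign is
normalized so its first loading is positive.

**Standardization.** Reported standardized estimates rescale by the
model-implied total SDs of factors and indicators but *not* of covariates:
loadings as $\lambda\,\mathrm{SD}(f)/\mathrm{SD}(y)$, structural
coefficients as $\gamma/\mathrm{SD}(f)$ (so a dose coefficient is "factor
SDs per Gy"), direct effects as $\kappa/\mathrm{SD}(y)$, and residual
covariances as residual correlations
$\theta_{jk}/\sqrt{\theta_{jj}\theta_{kk}}$.  $S_x$ is the maximum
likelihood covariance of the observed covariates.  Factor "correlations"
are the off-diagonals of $\Psi$, which is already a correlation matrix
given the fixed unit diagonal.

## Estimation

All models are fit by full-information maximum likelihood (FIML): each
record contributes the Gaussian log-density of its *observed* indicator
subvector under the corresponding subvector/submatrix of $(\mu_i, \Sigma)$.
This is the standard likelihood under missingness at random and uses every
record with at least one observed indicator; covariates must be complete
(records with unknown dose or smoking are excluded upstream, mirroring the
design).  The likelihood is conditional on covariates, which is what makes
the MIMIC regression formulation coherent with missing-covariate exclusion.

Numerical design:

* Records are grouped by missingness pattern and reduced to per-pattern
  sufficient statistics ($S_{xx}, S_{xy}, S_{yy}$ over the observed
  subset), so one likelihood evaluation costs O(#patterns), independent of
  $n$.  The kernel, its analytic score, and the observed-information
  Hessian (central differences of the score) are compiled C++
  (RcppArmadillo).  The analytic score is verified against central finite
  differences in the test suite.
* Free parameters are optimized unconstrained: log residual variances,
  Fisher-z factor correlations; residual covariances and all regression
  parameters are untransformed.  Indicators are standardized internally for
  conditioning and results are mapped back exactly.
* Inadmissible proposals (non-positive-definite $\Psi$, $\Theta$, or a
  singular observed submatrix) receive a graded penalty proportional to the
  negative part of the spectrum, so line searches retain a direction back
  to the admissible region, rather than a flat cliff.
* Optimizer: BFGS with up to 8 restarts (a restart resets the Hessian
  approximation).  If a restart stalls with a large gradient, all
  correlation-type parameters are deterministically shrunk halfway to zero
  and optimization resumes; as a final fallback a second deterministic
  start is tried.  Starting values: loadings from each factor's sum-score
  proxy (covariance of the indicator with the row mean of its factor
  block), residual variances at the complementary share, intercepts at
  sample means, all regressions and correlations at zero.  A plain
  "loading = sample SD" start is the fallback; it proved prone to boundary
  stalls on full-size cohorts, which is why the sum-score start is the
  default.
* Convergence is declared only when the score norm at the solution is
  small (scaled with $n$); the convergence code records a failure
  otherwise.  Fits are deterministic: same data, same result.

**Reference models.**  The saturated model (unrestricted regression of all
indicators on all covariates with unrestricted covariance) maximizes the
same FIML likelihood via an EM algorithm operating entirely on the
per-pattern sufficient statistics (closed-form M-step; with complete data
it reproduces closed-form multivariate regression, which the tests check).
The baseline model (intercepts only, diagonal covariance) factorizes into
per-indicator univariate MLEs.  Fit indices:
$\chi^2 = 2(\ell_{sat}-\ell_{model})$ with $df$ the parameter-count
difference, $CFI = 1 - \max(\chi^2-df,0)/\max(\chi^2_b-df_b,0)$,
$RMSEA = \sqrt{\max(\chi^2-df,0)/(df\,n)}$ (with $n$, not $n-1$), and
$AIC = -2\ell + 2k$.  This baseline is one reasonable convention; other
software may define its null model differently, so CFI values are
comparable within this package, not across packages.

**Uncertainty.** Confidence intervals are percentile bootstrap (not BCa),
resampling participants, with non-converged replicates dropped and counted
(warning above 10%); the full analysis uses $B = 2000$.  Asymptotic Wald
standard errors from the observed information are available
(`fit_mimic(se = TRUE)`) and are used by the direct-effect scan, where
bootstrapping 14 refits would be disproportionate.

**Model modification.** `lr_scan()` frees one fixed parameter at a time and
reports the exact likelihood-ratio improvement on 1 df.  This replaces
score-test modification indices: asymptotically equivalent, numerically
different, so index values should not be expected to match score-test
output from other software.

## Derived analyses

* **Indirect (total) effects.**  With no direct dose paths, the per-Gy
  effect on indicator $j$ is $\lambda_{j f}\,\gamma_{f,\text{dose}}$ in
  unstandardized units, equal to $\partial \mu_{ij}/\partial\,\text{dose}$
  (the tests verify this against a finite difference of the implied means).
  Effects are mapped back to natural units by undoing the fitting-scale
  rescaling (ABI $\times 10$; baPWV is fitted in m/s, numerically the
  cm/s-recorded measurements divided by 100).
* **Ordinary-regression comparator.**  The same indicators with a diagonal
  covariance and no latent structure, each adjusted for its factor's
  covariate set (plus sex for AI).  Because covariates are complete, this
  FIML model factorizes exactly into per-indicator least squares
  (`stats::lm`), which the tests confirm against the FIML kernel.  Its
  joint AIC/CFI/RMSEA are directly comparable to the MIMIC fit.
* **Direct-effect scan.**  One indicator at a time, a free dose $\to$
  indicator path is added, refit warm-started, and Wald-tested; the
  family-wise level 0.05 is Bonferroni-divided across the 14 indicators
  and reported at the conventional truncated threshold 0.003.
* **Sensitivity analyses.**  Dose restricted to $\le 2$ or $\le 1$ Gy;
  natural-log transforms of baPWV, IMT and UT; a quadratic dose term added
  to all three factors; exclusion of the younger expansion sub-cohort.
* **E-values.**  For a standardized dose coefficient $b$ with factor
  $R^2$, the approximate risk ratio is
  $RR = \exp(0.91\, b/\sqrt{1-R^2})$ and
  $E = RR + \sqrt{RR(RR-1)}$ (reciprocal first if $RR<1$; applied likewise
  to the CI limit closer to the null, with $E = 1$ if the interval crosses
  it).  The residual SD $\sqrt{1-R^2}$ — not the total SD — is the
  convention under which interval-limit E-values reproduce from reported
  standardized inputs, and matches the linear-model E-value function this
  mirrors.  The contrast is 1 Gy.

## The synthetic cohort generator

No participant-level data are distributable, so the package ships a
generator (`simulate_cohort()`, `assemble_raw_population()`) calibrated to
the published cohort composition; it is first-class, tested code and
defines the conditions of every simulation study here.

What it emulates:

* **Dose strata.**  Five strata with exact sizes (1163, 1529, 251, 229,
  102; $n = 3274$), a point mass of 381 exact zeros in the lowest stratum,
  within-stratum uniform laws rescaled to the published stratum means
  (0.001, 0.116, 0.72, 1.36, 3.09 Gy), truncation at 4.84 Gy.  The grand
  mean dose is then 0.30 Gy by construction.  The weighted dose is split
  into gamma and neutron parts consistent with the gamma $+ 10\times$
  neutron convention.
* **Age–dose confounding** via the published two-sub-cohort mixture: a
  1703-member expansion sub-cohort (mean age 70.8, mean dose 0.096 Gy) and
  a 1571-member primary sub-cohort (78.3, 0.52 Gy), allocated across
  strata by a frozen table; within-sub-cohort age SD 4.94 years makes the
  pooled SD 6.2.  No continuous age-dose copula is attempted — the mixture
  is the simplest mechanism matching the published facts.
* **Covariates** drawn per stratum from the published proportions (sex,
  city, smoking); distal participants occur only in the lowest stratum.
* **Outcomes** from the MIMIC model itself at the published standardized
  estimates (`default_generating_parameters()`), converted internally to
  unstandardized generating matrices against the realized covariate
  covariance, then affine-mapped to each indicator's published mean/SD.
* **Calcification discretization** by fixed thresholds (round and clamp).
  Thoracic constants were solved once so grades 0–3 reproduce the
  published grade moments (1.12/0.81) exactly.  For the abdominal score
  the published moments (4.71/5.04, mode 0) are *not jointly attainable*
  with a covariance-faithful linear measurement model: any continuous
  normal matching that SD puts a double-digit share of mass below zero,
  and the clamp measurably biases the recovered standardized
  dose–calcification coefficient upward.  The frozen compromise keeps the
  published mean and shrinks the continuous SD to 3.3 (about 6% of mass
  clamped).  This is a deliberate trade of marginal realism (the generated
  score is less zero-heavy and less dispersed than the real one) for
  faithfulness of the covariance structure the estimator consumes.
* **Missingness** at the exact published per-indicator counts (33–370 per
  indicator), selected by weighted sampling without replacement with
  weights logistic in age (slope 0.08 per year) — a missing-at-random
  mechanism through an always-observed model covariate that hits the
  configured counts exactly.  The published counts pool "not measured" and
  "invalid"; the split is unknown, so the generator exposes separate knobs
  for the invalid-measurement artifacts below and treats the remainder as
  not-measured.
* **Artifacts and masking.**  Configured numbers of out-of-range ABI
  values (4 left/6 right above 1.4; 39/31 below 0.9), surgery flags
  (5 carotid, 16 peripheral, 21 aorta), and the pre-analysis exclusion
  categories (247 refusers, 321 in-utero, 273 missing dose, 8 missing
  smoking out of 4123 invited).  Hemodialysis is treated as a
  pre-invitation filter (count 0 by default, knob provided), reading the
  recruitment description as excluding such participants before
  invitation.

What it does **not** emulate: X-ray or ultrasound image formation (scores
and IMT are numbers, not images), dosimetry physics or dose-uncertainty
adjustment (doses are consumed as given), longitudinal smoking histories
(only the three-category outcome), real-data skewness of IMT beyond a
small positivity floor, and any departure of the true indicator
distribution from the fitted Gaussian beyond the calcification
discretization.  Passing recovery tests therefore demonstrates that the
estimator is correct under the model plus realistic missingness and
discreteness — not that the model is correct for the real cohort.

## Problem sizes used in the checks

The test suite and acceptance script size their simulations as follows:
parameter recovery uses 12 (tests) and 30 (acceptance script) cohorts of
$n = 3274$ with full missingness; the comparator study uses 50 cohorts of
$n = 1000$; the null direct-effect scan uses 100 complete-data cohorts of
$n = 600$ (14 refits each); bootstrap coverage uses 60 toy replicates with
$B = 80$.  These sizes give Monte-Carlo standard errors comfortably inside
the 3-MC-SE tolerances used by the recovery checks while keeping the whole
suite quick to run.

## Known limitations

* Ordinal/probit treatment of the calcification grades is out of scope;
  like the original analysis, grades enter as continuous variables.
* No robust (sandwich) or rescaled test statistics; inference rests on the
  bootstrap and on observed-information Wald tests.
* The CFI baseline convention and the likelihood-ratio modification scan
  are package conventions, asymptotically but not numerically equivalent
  to other software.
* Recovered standardized dose–calcification coefficients retain a small
  upward residue (about +0.005 at the default calibration) attributable to
  the score discretization; it is well inside the recovery tolerances and
  documented above.
* The generator reproduces published margins and the fitted covariance
  structure, not unpublished joint features of the real data (e.g.
  stratum-specific indicator moments beyond what the model implies).
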