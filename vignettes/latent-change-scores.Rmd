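---
title: "Latent change score models for volume coupling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent change score models for volume coupling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical machinery:
the models, the synthetic cohorts they are verified against, the
numerical choices, and the places where the design was genuinely open and
a decision had to be made.

## 1. The latent change score model

A two-scan design observes each region at baseline (T1) and follow-up
(T2).  The LCS parameterization introduces a latent change Δ per region
with unit-fixed loadings; under the package's **atrophy-positive
convention**,

$$V(T2) = V(T1) - \Delta,$$

so positive Δ means volume loss.  The two changes are regressed on both
baselines:

$$
\begin{aligned}
\Delta_{Hipp} &= \alpha_H + \beta_H V_{Hipp}(T1) + \gamma_{T\to dH}\, V_{Thal}(T1) + \varepsilon_H,\\
\Delta_{Thal} &= \alpha_T + \beta_T V_{Thal}(T1) + \gamma_{H\to dT}\, V_{Hipp}(T1) + \varepsilon_T,
\end{aligned}
$$

with free baseline moments ($\mu_T, \mu_H, \phi_T, \phi_H, \phi_{HT}$)
and change-residual covariance matrix ($\psi_T, \psi_H, \rho_{HT}$).
β is *self-feedback* (regression of a structure's atrophy on its own
baseline), γ the *cross-coupling* of interest.  All volumes are in mL;
couplings are mL of atrophy per mL of baseline volume.

Internally every model is housed in three structural matrices over
observed + latent variables: directed paths $A$ (fixed unit loadings plus
free regressions), symmetric covariances $S$, and means/intercepts $M$.
Implied moments come from $\mu = G(I-A)^{-1}M$ and
$\Sigma = G(I-A)^{-1}S(I-A)^{-\top}G^\top$ with $G$ the selector of
observed rows.  One code path therefore serves the bivariate model, the
age-augmented model (baseline age as an exogenous predictor of both
changes, the between-scan interval as an exogenous variable with free
covariances to the change residuals, and a saturated exogenous block) and
the sex-stratified multigroup model.

### Estimation

Complete-data fits minimize the normal-theory discrepancy

$$F(\theta) = \ln|\Sigma(\theta)| + \mathrm{tr}\,(S\,\Sigma(\theta)^{-1})
+ (\bar x - \mu(\theta))^\top \Sigma(\theta)^{-1} (\bar x - \mu(\theta))
- \ln|S| - p,$$

with the sample covariance on the $n-1$ denominator and
$\chi^2 = (n-1)\,F_{\min}$ (the package documents this convention because
the choice of denominator is not canonical).  The optimizer is BFGS on an
unconstrained reparameterization (variances on the log scale), started at
the **closed-form difference-score solution**: regress the observed
changes (baseline − follow-up) on each change's parents, take the OLS
residual covariance for the ψ/ρ block, the residual–interval
cross-moments for the interval covariances, and the sample moments for
the exogenous block.  For every just-identified member of the family —
the bivariate model (14 parameters = 14 moments), the all-free multigroup
model, and the age-augmented model — this start *is* the exact ML
solution, which the test suite exploits as an oracle; the optimizer then
only has to confirm it (the fit keeps whichever of start and optimizer
output has the lower discrepancy, so the likelihood can never degrade).
Convergence is declared from the optimizer status, with the numerical
gradient norm recorded on the fit.

Incomplete data are handled by **FIML**: rows are grouped by missingness
pattern, and each pattern contributes
$n_k(p_k\ln 2\pi + \ln|\Sigma_k| + \mathrm{tr}(S_k\Sigma_k^{-1}) +
(\bar x_k-\mu_k)^\top\Sigma_k^{-1}(\bar x_k-\mu_k))/2$ over its observed
subset.  The FIML objective is scaled per row so the stopping rule is
sample-size invariant; it reduces exactly to the complete-data fit when
nothing is missing (tested to 1e-8 in relative log-likelihood).  No
saturated-model comparison is computed for FIML fits, so their
`chi_square` is `NA`.

Multigroup fits minimize $\sum_g (n_g-1) F_g$; by default every parameter
is free per group (labels suffixed `|group`), and equality constraints
are expressed by sharing labels across groups.

Standard errors invert the numerically differentiated observed
information of the casewise log-likelihood at the optimum; a singular
information matrix leaves SEs flagged `NA` with the fit retained.
P-values are two-sided Wald z tests — the classical choice, documented
because nothing in the design forces it.

## 2. The synthetic cohorts

Real data for this design are access-controlled, so the generator *is*
the study condition: every verification experiment generates cohorts at
the published parameter values and asks whether the estimators recover
them.

**Longitudinal generator.**  Baseline pairs are drawn from the bivariate
normal with thalamus 14.95 (SD 1.34) mL, hippocampus 7.52 (SD 0.85) mL
and covariance 0.76 mL²; changes follow the LCS regressions above with
correlated Gaussian residuals; follow-up = baseline − change exactly (no
measurement residual on the follow-up indicator, the classical two-wave
LCS identification).  The cross-couplings default to −0.048 and 0.043
(sex-stratified: −0.057/0.049 for women, −0.040/0.008 for men; the
age-adjusted variant uses −0.042/0.048 with an age→hippocampal-atrophy
coupling of 0.013 mL/yr and no age effect on thalamic atrophy).  Baseline
age is normal (67.9, SD 4.8) truncated at 60 — the cohort's inclusion
floor — with age–volume covariances −1.63 and −1.10 mL·yr *on the
realized (truncated) scale*, so the generated covariances match the
stated values exactly; the analytic truncated-normal moments feed both
the generator and the implied-moment oracle.  The between-scan interval
is normal with mean 2.26 y and SD chosen so the IQR is 0.33 y, clipped
below at 1.5 y, independent of everything else.

**Three calibration decisions deserve emphasis.**

1. *The residual covariance vs. the change-score SDs.*  A change-residual
   covariance of ρ_HT = 0.03 mL² is arithmetically incompatible with
   change-score SDs of 0.136 and 0.132 mL: those dispersions cap the
   covariance near 0.017 (the implied residual correlation would exceed
   1).  The generator resolves this by preserving what the verification
   experiments actually check — the hippocampal change-score mean
   (0.155 mL) and SD (0.136 mL, solved exactly via the hippocampal
   residual variance) and ρ_HT = 0.03 as a covariance — and letting the
   thalamic residual variance absorb the excess (residual correlation
   fixed at 0.85, giving a thalamic change SD near 0.29 mL).  The
   asymmetry is deliberate and documented; no analysis in the package
   depends on the thalamic change dispersion.
2. *Self-feedback.*  β_T = β_H = 0.05 (larger structures atrophy slightly
   faster, the regression-to-the-mean direction).  The package's recovery
   experiments estimate the βs but do not test them against an external
   value.
3. *Change intercepts* are always re-solved from the other parameters so
   the change-score means stay at 0.213/0.155 mL under every preset,
   including per group in the sex-stratified preset.

**Cross-sectional generator.**  Eleven volume columns are built from an
age slope, a male offset, and a shared size factor; the
thalamus/hippocampus age slopes reproduce the −1.63/−1.10 mL·yr
covariances and their factor loadings are solved so their covariance is
0.76 mL².  Demographic covariates are independent of each other (age
67.9 ± 4.8 y, 45.4% men, education 17.2 ± 2.3 y, 46.3% ever-smokers,
alcohol-frequency score as a rounded clipped normal on the 1–6 scale with
mean 2.73, sleep 7.2 ± 1.0 h).  Total white matter is generated in mL
(540 ± 60): the published coefficient table only makes dimensional sense
with a per-mL slope.  The cognitive composite is the fifteen-term linear
predictor (slopes as published, intercept 0.817) plus Gaussian noise
whose SD is solved analytically — from the implied predictor covariance
matrix, exposed as `cs_predictor_moments()` — so the population R² is
0.09.  The numeric-memory score is calibrated the same way to R² = 0.027
and clipped to the 2–12 digit range.

**Cognitive indicators.**  DSST and TMT-A/B scores are derived from the
standardized composite through a one-factor measurement model.  The
loadings are *calibrated to the target score–indicator correlations*
(0.66, −0.78, −0.93): for regression-method (Thomson) scores the
score–indicator correlation is λ_j/ρ with validity
ρ² = s/(1+s), s = Σ λ²/(1−λ²), so setting λ = ρ·c and solving the scalar
fixed point yields ρ ≈ 0.880 and loadings (0.581, −0.687, −0.819).  A
pleasant consistency check falls out: the implied variance explained by
the factor is 49.3%, close to the published 49.9% even though the raw
indicator intercorrelations were never published.  TMT times are
exponentiated (log-normal) so they stay positive; the analysis pipeline
therefore log-transforms them before standardizing, which keeps the
measurement model exact on the analyzed scale.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: non-Gaussian tails and floor effects in
volumes and test scores, real covariate intercorrelations (education,
smoking and sleep are independent here), informative (MNAR) attrition,
site/scanner effects, and the spatial error structure of segmentation
pipelines (pipeline disagreement is additive bias + white noise only).
Parameter recovery shows the estimators are correct under the model, not
that the model is true of any cohort.

**Missingness machinery** masks cells MCAR or MAR (logistic in named
predictors with the intercept solved for the target rate), cell-wise or
jointly per row (a missed follow-up visit removes both follow-up
volumes); attrition to roughly 15% follow-up is the default sensitivity
condition, mirroring the cross-sectional → longitudinal sample drop.

## 3. The composite, regression and sensitivity modules

*Factor module.*  With exactly three indicators the one-factor model is
just-identified and the Spearman closed form
$\lambda_1 = \sqrt{r_{12}r_{13}/r_{23}}$ (cyclically) is the ML solution,
so no iteration is needed; `stats::factanal` serves as an independent
cross-check in the tests.  Extraction and scoring methods are otherwise
under-determined: the package uses regression (Thomson) scores and
records an orientation flag, flipping the solution so the anchor
indicator (the correct-matches count) loads positively — higher composite
= better performance.  Inadmissible triads (negative radicand) are
rejected rather than truncated.

*Regression suite.*  `fit_ols()` wraps `stats::lm` with classical SEs and
two-sided t p-values on n−k df; `vif()` is the textbook 1/(1−R²_j) screen
with the threshold at 5; `bh_fdr()` is Benjamini–Hochberg step-up.  The
session test fits `volume ~ session + interval + (1 | participant)` by
REML via `lme4`, with the between-scan interval entered as a
participant-level covariate (one value per participant, as "time between
scans" is measured): because the interval is constant within participant,
the session effect is estimated purely within participants and equals the
mean within-participant volume difference exactly in the balanced
two-scan case — the equivalence the test suite asserts.  Its p-value uses
a t reference with (pairs − 2) df.  The eTIV sensitivity refit swaps
total white matter for GM + WM + ventricular-CSF totals.

*Missing-data module.*  Propensity scores come from `stats::glm`
(logistic IRLS) with an explicit complete-separation rejection.  Matching
is greedy 1:1 nearest-neighbour without replacement, walking the smaller
group in descending propensity order (seed-controlled tie-breaks) with
the caliper applied on the probability scale — the order is not dictated
by anything external, so the deterministic standard greedy behaviour was
chosen and documented.  PMM imputation draws regression parameters from
the normal–inverse-gamma posterior, predicts observed rows with the
posterior mean and missing rows with the draw (type-1 matching), and
fills each missing cell from the k = 5 nearest observed donors by
predicted value; `k_donors = 1` with draws disabled degenerates to
deterministic nearest-prediction imputation, which the tests pin down.
Rubin pooling uses $T = \bar W + (1+1/m)B$ with Barnard–Rubin degrees of
freedom (reducing to $(m-1)/\lambda^2$ at infinite complete-data df).

*Agreement module.*  Bland–Altman differences are pipeline 2 − pipeline 1
against pairwise means, with 95% limits of agreement at bias ± 1.96 SD;
identical inputs give degenerate limits and a within-fraction of 1 by
convention.

## 4. Numerical choices and degenerate inputs

- Covariance inputs are validated for symmetry and (semi)definiteness;
  the generator's sampler uses an eigenvalue square root so legitimately
  singular configurations (e.g. zero residual noise in the degenerate
  test cases) still draw correctly.
- During optimization an indefinite implied covariance returns a large
  finite penalty rather than an error; at evaluation time a singular
  implied covariance is rejected with its condition number.
- Variances are optimized on the log scale; free covariances are
  unconstrained (the penalty handles excursions past definiteness).
- `n = 0` cohorts return empty tables with the full schema; zero-variance
  columns, unknown column names, under-identified specs, empty groups,
  unpaired session rows and all-missing variables are explicit errors or
  warnings, not silent behaviour.
- Every stochastic function takes an explicit seed (or inherits the
  ambient RNG state when the seed is `NULL`); the pipeline derives one
  sub-seed per stage from the run seed and logs it.

## 5. Verification experiment sizes

The recovery experiments use the design's own sample sizes — 653
longitudinal and 4348 cross-sectional participants — with 200 replicate
cohorts for the bivariate, multigroup, age-augmented and cross-sectional
studies, 100 replicates for FIML under 85% follow-up missingness, 500
single-cohort draws for the change-score calibration check, and 500
replicate fits for the SE-calibration check (mean reported SE within 15%
of the Monte-Carlo SD).  Monte-Carlo means are compared with generating
values within two Monte-Carlo standard errors; with bands that tight an
individual stochastic check retains roughly a 5% false-alarm rate by
construction, which is the price of not loosening them.

## 6. Known limitations

- The engine covers the three LCS variants and saturated models, not
  general SEM: no latent growth beyond two waves, no fit indices beyond
  χ²/df/log-likelihood, no Bayesian estimation.
- FIML assumes missing-at-random and multivariate normality; no
  saturated-model χ² is reported for incomplete data.
- The multigroup optimizer treats equality constraints by label sharing;
  there is no general constraint language (inequalities, ratios).
- The imputation module is single-level PMM only; clustered or
  multilevel imputation is out of scope.
- Propensity matching is greedy, not optimal; with heavy caliper
  violations the matched subsample can be small, which is reported via
  the match rate rather than corrected.
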