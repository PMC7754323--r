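---
title: "Pseudo IPD for baseline–follow-up meta-analysis: models, construction, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo IPD for baseline–follow-up meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoIPD)
```

## The model family

Let $Y_{Bij}$ and $Y_{Fij}$ be the baseline and follow-up values of subject
$j$ in study $i = 1,\dots,N$, and $X_{ij}\in\{0,1\}$ the treatment
indicator. The stratified-study ANCOVA mixed model is

$$Y_{Fij} = \beta_{0i} + (\beta_1 + b_{1i})X_{ij}
  + \beta_{2i}\,(Y_{Bij} - \bar Y_{Bi}) + \varepsilon_{ij},
  \qquad b_{1i}\sim N(0,\tau_1^2),$$

with a fixed intercept $\beta_{0i}$ and baseline slope $\beta_{2i}$ per
study and the baseline centered on each study's observed mean
$\bar Y_{Bi}$ (both arms pooled). $\beta_1$ is the summary treatment
effect. The random-study variant replaces $\beta_{0i}$ and $\beta_{2i}$ by
$\beta_0 + b_{0i}$ and $\beta_2 + b_{2i}$; its random effects default to
independence (an unstructured covariance is available). The interaction
extension adds $(\beta_3 + b_{3i})(Y_{Bij}-\bar Y_{Bi})X_{ij}$ — the
within-trial treatment-by-baseline interaction — and a single across-trial
term $\beta_4\,\bar Y_{Bi}X_{ij}$. Separating the two is what protects
$\beta_3$ from ecological bias; dropping the across-trial column (the
`across_trial = FALSE` toggle) deliberately collapses the estimand into a
mixture of the two, which is visible on baseline-imbalanced data.

Residuals are normal with one of four variance structures
$\sigma^2_{ik}$: free per (study, arm), per study, per arm, or pooled —
`model_spec(residual_structure = ...)`. Estimation is always REML.
`model_spec()` defaults to the stratified-study model with study-specific
residual variances, the specification adopted as the final model for the
worked dataset (free residuals win the AIC comparison there, but by little,
and the simpler structure is the natural reporting model).

For the stratified interaction model the two random effects
$(b_{1i}, b_{3i})$ get an unstructured $2\times 2$ covariance by default;
for random-study models the treatment indicator is centered at $0.5$
inside the random-effect columns only (`center_groups`), which decouples
the intercept and treatment variance components; the fixed-effect part is
untouched, so the estimands do not change.

## Why pseudo data reproduce the true-IPD fit

Within one (study, arm) cell the model says
$(Y_B, Y_F)$ is bivariate normal with constant residual variance, so the
cell's contribution to any marginal likelihood in this family depends on
the data only through $n$, $\sum Y_B$, $\sum Y_F$, $\sum Y_B^2$,
$\sum Y_F^2$, $\sum Y_BY_F$ — equivalently the two sample means, two
sample SDs, and the sample correlation. `generate_arm()` constructs records
matching those six numbers exactly (not in expectation): two base draws are
standardized to sample mean 0 / SD 1, the second is replaced by the exact
regression residual construction
$Y_3^* = r\,Y_1^* + \hat\varepsilon\sqrt{(1-r^2)/(1-r^{*2})}$, and the pair
is rescaled to the target moments. The formula for $Y_3^*$ is the unique
scaling for which the sample variance is 1 and the sample correlation with
$Y_1^*$ is exactly $r$ — this is also how the construction resolves the
one genuinely ambiguous step of the algorithm, by the variance algebra
rather than by any distributional argument. Two consequences the test
suite exploits:

* the seed and even the base distribution (`base = "uniform"`, or any
  user function) are irrelevant to every fitted quantity, because only the
  matched moments enter the likelihood;
* a fit to pseudo data equals the fit to the true data the aggregates came
  from, which the suite checks across 24 simulated scenarios crossed with
  all four residual structures and both study levels at a scaled tolerance
  of $10^{-6}$.

Sample moments use the $n-1$ denominator throughout (generation,
summarization, verification) — the convention under which published SDs
are computed; any single consistent convention would do, mixing two would
break exactness. Correlations within $10^{-9}$ of $\pm 1$ are rejected
rather than clipped (`corr_from_change_sd` likewise rejects impossible SD
triples): clipping would silently analyze a different dataset, and the
generator requires $|r| < 1$. The measure-zero event of a numerically
collinear base draw is retried up to 10 times, then errors. Per-arm random
substreams are derived by hashing (seed, study id, arm label), so adding
or removing a study leaves every other arm's records bit-identical.

## Correlation recovery

Trials rarely report $r$ directly. Two recovery routes are implemented,
per arm from the change-score SD,
$r = (sd_B^2 + sd_F^2 - sd_{ch}^2)/(2\,sd_Bsd_F)$, and per study from the
standard error of the between-group difference in mean change, which
assumes the two arms share one correlation and therefore assigns the same
value to both. When both routes are available they can disagree; neither
is auto-selected — `recover_correlations(prefer = ...)` makes the choice
explicit. Imputation of missing follow-up SDs is out of scope by design:
absence is a hard error, and `sensitivity_correlations()` exists for the
case where no route applies and a correlation must be assumed (the sweep
refits the chosen models under each candidate value).

## Fitting engine and numerical choices

Models are fitted by `nlme::lme` (or `nlme::gls` when no random effect is
requested), with the residual structures expressed as `varIdent` weights
and the random-effects covariance as `pdSymm`/`pdDiag` blocks. On top of
the engine the package maintains its own evaluation of the restricted
log-likelihood from per-cell cross-products (`reml_objective`) — constant
included, so the value matches the engine's to $10^{-8}$, which a
dense-matrix oracle test verifies independently. This objective serves
four purposes:

1. **Polish.** Generic stopping rules leave $O(10^{-2})$ slack in
   $\tau_1^2$ where the restricted likelihood is flat (few studies). After
   `lme` converges, the variance parameters are refined by `nlminb` with
   accurate numeric gradients plus a few damped Newton steps, and all
   reported quantities (fixed effects by GLS, SEs, variance components,
   $-2\ell_R$, AIC) come from the polished point. Evaluations exploit the
   exact invariance of $\ell_R$ under outcome translation to keep the
   cross-products well conditioned.
2. **Boundary handling.** A variance component whose removal costs less
   than $10^{-7}$ log-likelihood is statistically indistinguishable from
   zero; it is pinned and reported as an exact 0 with `boundary = TRUE`.
   Without this rule the reported value would be wherever on the flat
   boundary approach the optimizer happened to stop.
3. **Satterthwaite df.** The numeric Hessian of $\ell_R$ at the optimum
   estimates the covariance of the variance parameters; the delta method
   propagates it to $\widehat{se}^2$ of the chosen fixed effect and
   $df = 2\,\widehat{se}^4 / \mathrm{Var}(\widehat{se}^2)$. The result is
   invariant to the smooth reparametrization used internally
   (log-Cholesky / log-SDs).
4. **Diagnostics.** The GLS-consistency invariant — refitting the fixed
   effects explicitly at the returned variance parameters changes nothing
   beyond $10^{-10}$ — is tested directly.

Between-within degrees of freedom assign $N-1$ (studies minus one) to any
fixed effect carrying a study-level random effect (treatment, within-trial
interaction), residual df $n - \mathrm{rank}(X)$ to purely within-study
effects, and $N-2$ to the across-trial coefficient, which is a
between-study regression slope. This is the rule that reproduces the
published $t_{0.975,9}$-based intervals for the ten-trial dataset; how a
between-within rule should interact with the residual-variance structure
is not specified anywhere authoritative, so the package applies it
uniformly across structures.

The AIC is $-2\ell_R + 2q$ with $q$ counting variance–covariance
parameters only — the REML convention under which only models sharing a
fixed-effects structure are comparable, which is exactly the
residual-structure ladder use case. Absolute $-2\ell_R$ levels are
software-convention-sensitive (the $\log|X'V^{-1}X|$ constant depends on
the fixed-effects basis, and overparametrized CLASS-style designs differ
from full-rank ones); differences between structures are not, and those
are what the ladder compares.

## Two-stage analysis and AD comparators

`two_stage()` fits each study's OLS ANCOVA with the same study-mean
centering as the one-stage models (so interaction coefficients are
comparable across stages) and pools with `metafor::rma.uni`. The default
between-study variance estimator is REML; this is the choice under which
the two-stage treatment effect matches the one-stage stratified fit to two
decimals on the worked dataset and under which the change-score
comparator's $\tau^2$ matches its published value, whereas the
DerSimonian–Laird moment estimator shrinks $\tau^2$ noticeably on these
ten studies (3.1 vs 6.6) and moves the pooled change-score effect by a
quarter of a standard error. DL and fixed-effect pooling remain available
(`method = "DL"`, `"FE"`), as do t and Knapp–Hartung intervals.

`change_score_ma()` pools the between-group difference in mean change with
variance $sd^2_{ch,T}/n_T + sd^2_{ch,C}/n_C$, deriving change-score SDs
from the correlations where needed; it is exactly invariant under
treated-arm mean shifts, which is the precise sense in which it cannot
adjust for baseline imbalance. `meta_regression()` takes explicit
per-study effects and a study-level covariate; regressing final-value
differences on the treated arm's mean baseline is the across-trial
analogue of $\beta_4$, and its sign flip on the artificially imbalanced
dataset is the package's ecological-bias illustration.

## The simulation module

`sim_scenario()`/`simulate_ipd()` generate true IPD from the same
generative family the one-stage models assume: normal baselines per study,
follow-ups from the stratified interaction equation, study-level random
effects, residuals per structure. Defaults emulate a modest
blood-pressure-like meta-analysis (baseline means 150–190, SD 15,
treatment effect $-10$, $\tau_1^2 = 7$, residual SD 18). Generative
centering uses the true study mean $\mu_i$ while fitting centers on
observed means — deliberately, since that is all an analyst can do.

What the simulations do *not* emulate: non-normal residuals, missing data,
more than two timepoints, more than two arms, or reporting artifacts
(rounded aggregates, missing SDs). Passing equivalence tests therefore
demonstrate the sufficiency mechanism and the estimators' internal
consistency, not robustness to real-data messiness — although the
equivalence property itself holds for any dataset whose moments are
matched, messy or not, because it is an algebraic property of the
likelihood.

Problem sizes used by the test suite were chosen to make the checked
properties sharp rather than to stress hardware: the equivalence oracle
runs 24 scenarios of 4 studies × 60 subjects/arm with heterogeneity in
every random term (so REML optima are interior and well identified);
parameter-recovery runs 200 replicates of 3 × 40; the published-results
checks use the full 28,580-subject table.

## Known limitations

* Exactly two timepoints and two arms per study; repeated-measures,
  network and cross-over extensions are out of scope.
* No imputation of missing SDs or correlations — recovery is algebraic or
  explicit sensitivity analysis.
* The random-study model's estimates are mildly sensitive to how the
  treatment indicator enters the random-effect columns (centered vs not);
  both codings are exposed and documented, but published results fitted in
  other software may not pin down which was used.
* Satterthwaite df rely on a numeric Hessian; at variance boundaries the
  information matrix can be singular, in which case the df are reported as
  `NA` and intervals fall back to normal quantiles.
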