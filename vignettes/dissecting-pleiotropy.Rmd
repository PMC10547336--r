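---
title: "Dissecting causal and pleiotropic pathways in two-sample MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting causal and pleiotropic pathways in two-sample MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdissect)
```

## The model

`mrdissect` works entirely on GWAS summary statistics in the two-sample
paradigm: per-variant associations $(\hat\gamma_j, \sigma_{\gamma j})$
with an exposure from one study and $(\hat\Gamma_j, \sigma_{\Gamma j})$
with an outcome from a second, non-overlapping study, for $J$
approximately independent instrument variants. Under the instrumental
assumptions, each variant's Wald ratio $\hat\Gamma_j/\hat\gamma_j$
estimates the same causal effect $\theta$, and the IVW estimator pools
them as a weighted zero-intercept regression with weights
$w_j = 1/\sigma_{\Gamma j}^2$. For binary traits on both sides, $\theta$
is a log-odds of outcome per unit log-odds liability of exposure, and
results are reported on the odds-ratio scale.

Cochran's $Q = \sum_j w_j(\hat\Gamma_j - \hat\theta\hat\gamma_j)^2$
measures how far the instruments are from telling one story. The primary
model is IVW with *multiplicative random effects*: standard errors are
inflated by $\sqrt{\phi}$, $\phi = \max(1, Q/(J-1))$. The floor at 1 is a
deliberate choice — published implementations differ here — because an
unfloored $\phi$ would let sampling noise *shrink* the standard error
below the fixed-effect one; the unfloored variant remains available via
`floor_phi = FALSE` (and is what the test-suite oracles based on
`stats::lm` reproduce exactly).

Two sensitivity estimators probe horizontal pleiotropy. MR-Egger refits
with an intercept after orienting every variant to a positive exposure
effect; the intercept estimates directional pleiotropy and the fit is
invariant to variant-level joint sign flips. The weighted median sorts
Wald ratios and interpolates the inverse-variance-weighted cumulative
weight at one half; its standard error comes from a parametric bootstrap
(default 1000 draws, seed 1) because no closed form is in common use —
the draw count and seed are declared defaults, not estimates.

## Radial reformulation and outliers

Rescaling to the radial (Galbraith) frame — regressing
$\hat\beta_j\sqrt{w_j}$ on $\sqrt{w_j}$ with $\hat\beta_j$ the Wald ratio
— leaves the IVW slope unchanged with first-order weights (an algebraic
identity the tests check to 1e-10) but decomposes $Q$ into per-variant
contributions $Q_j \sim \chi^2(1)$. The default weighting is the modified
second-order form
$w_j = \left(\sigma_{\Gamma j}^2/\hat\gamma_j^2 + \hat\theta^2
\sigma_{\gamma j}^2/\hat\gamma_j^2\right)^{-1}$, iterated to a slope
tolerance of 1e-8 (cap 100 iterations; non-convergence returns the last
iterate with a warning and a flag). When $\sigma_{\gamma j}=0$ the
modified weights collapse to first-order ones, which the code treats as a
legitimate degenerate input.

Outlier flagging compares each $Q_j$ p-value with a Bonferroni-corrected
level $\alpha/J$ ($\alpha = 0.05$) by default; a `fixed` policy is
available. Bonferroni is the conservative convention for this purpose:
with ~180 instruments a nominal 5% level would flag ~9 clean variants per
run, while the corrected policy keeps the expected false-positive count
at $\alpha$ per analysis. A caveat worth knowing: when several strong
outliers share a sign, the fitted slope itself is dragged, and clean
variants can be swamped into significance — the package reports what the
statistic says and leaves masking/swamping diagnostics to the analyst.

## Explaining outliers through candidate traits

The dissection stage replaces a live phenome-wide database scan with a
local trait-association table (`trait_id`, `trait_label`, `rsid`,
`beta`, `se`, `pval`), which makes an inherently service-bound step
reproducible and testable. The stages, in order:

1. **Scan** — a trait is a candidate if any outlier variant associates
   with it at $p < 5\times10^{-8}$.
2. **Trait-level MR + FDR** — each candidate's effect on the outcome is
   estimated by IVW over the trait's own genome-wide-significant
   instruments, with the original outlier variants excluded (they are
   the contested ones). Benjamini–Hochberg FDR at 0.05 is applied across
   all candidates jointly; applying it within outlier strata would be
   defensible too, but the joint choice is simpler and uses the larger
   denominator.
3. **Curation as configuration** — manual removal of exposure- or
   outcome-related traits becomes a declarative blocklist of regular
   expressions, and near-duplicate phenotypes (instrument-effect vectors
   correlating above 0.9 over shared variants) collapse to the
   best-instrumented representative, ties broken lexicographically.
   A bidirectional trait-exposure diagnostic is attached but only
   excludes traits when explicitly enabled, since no fixed exclusion
   rule is standard.
4. **LASSO pruning** — redundant candidates are pruned by a weighted
   LASSO of the outcome associations on the trait-effect matrix
   (standardized internally, weights $1/\sigma_{\Gamma j}^2$, variants
   instrumenting the candidates with outliers excluded). The default
   penalty is the cross-validated `lambda.min` (10 folds, fold
   assignment seeded), which targets predictive loss. For *support
   recovery* — deciding which traits are active at all — the
   one-standard-error rule `cv_1se` is the appropriate, sparser choice,
   and it is what the selection-consistency test uses: `lambda.min`
   deliberately tolerates small spurious coefficients in exchange for
   prediction, so it is the right default for effect estimation but the
   wrong yardstick for a zero/nonzero pattern. Survivors are refit
   unpenalized. If everything is shrunk to zero, the single best-q trait
   is kept with a warning. Exact limits `lambda = 0` (no penalty) and
   `lambda = Inf` (empty selection) are honoured literally.
5. **Adjustment and re-estimation** — for each outlier $j$,
   $\Gamma_{j,\text{adj}} = \hat\Gamma_j - \sum_p \hat\beta_p
   \hat\delta_{jp}$ over selected traits with a usable association;
   non-outliers are untouched, so with no outliers the whole stage is
   the identity. By default the outcome standard errors are left
   unchanged — the re-estimated model treats adjusted betas as data, the
   same convention as re-running MR on corrected associations; a
   `propagate` policy adds $\sum_p \hat\delta_{jp}^2
   \mathrm{se}(\hat\beta_p)^2$ in quadrature for users who prefer
   conservative intervals. The re-estimate reports the adjusted IVW, the
   leave-one-out IVW with outliers removed, and heterogeneity reduction
   against **both** the IVW $Q$ and the radial $Q_R$ baselines, because
   the appropriate baseline is genuinely ambiguous and the two can
   differ noticeably.

## Multivariable MR and mediation

`mvmr_fit()` regresses the outcome associations on the variant-effect
matrix of several exposures without intercept, weights
$1/\sigma_{\Gamma j}^2$, overdispersion $\phi = \max(1, Q_{mv}/(J-K))$.
The instrument frame stays the primary exposure's: mediator effects are
looked up (and allele-aligned) for those variants rather than re-clumping
a union of instrument sets — the union variant would change the estimand
of the *total* effect, and the primary-frame choice keeps total and
direct effects comparable. With one exposure the fit reduces to IVW by
construction (same arithmetic, not merely the same formula).

Because odds ratios are noncollapsible, subtracting direct from total
log-odds does not estimate an indirect effect; no proportion mediated is
computed. `mediation_compare()` instead issues a qualitative verdict at
$\alpha = 0.05$: `full` (total significant, direct not), `partial` (both
significant, direct smaller in magnitude), otherwise `none`.

## What the generator emulates — and what it does not

`sim_config()`/`simulate_gwas()` produce summary-level data directly:

* true exposure effects $\gamma_j = s_j\,U(0.03, 0.15)$ with random
  signs — the magnitude range of log-odds effects typical for a large
  case-control GWAS of a common complex disease;
* standard errors $\sigma_{\gamma} \sim U(0.004, 0.009)$,
  $\sigma_{\Gamma} \sim U(0.02, 0.04)$ — chosen so a total effect of
  $\log 1.08$ over 182 instruments yields IVW p-values of order
  $10^{-3}$, the regime of a well-powered but not overwhelming study,
  and so the null model gives $Q/\text{df} \approx 1$;
* a mediator channel $m_j = \kappa\gamma_j + \eta_j$ with variant-level
  pathway heterogeneity $\eta_j \sim N(0, 0.03^2)$ (SD units). The
  heterogeneity term is essential, not decorative: if mediator effects
  were exactly proportional to exposure effects, the multivariable
  design matrix would be singular in truth and no amount of data could
  separate direct from mediated channels. Real pleiotropy is
  variant-specific, which is exactly what makes MVMR identifiable;
* outcome effects $\Gamma_j = \theta_{\text{direct}}\gamma_j + \mu m_j +
  e_j + \sum_p \alpha_p \delta_{jp}$, observed with noise at
  $\sigma_{\Gamma j}$. The diffuse channel $e_j$ is `balanced`
  ($N(0, 0.01^2)$, the default), `directional` (a constant offset per
  copy of the exposure-increasing allele — the orientation matters,
  since an offset attached to arbitrary allele coding would cancel under
  Egger's orientation and model nothing), or `none`;
* four planted outliers whose pleiotropy acts entirely through a small
  set of candidate traits ($\delta_{jp}$ magnitudes 1.0–1.5 SD,
  trait-on-outcome effects $\alpha_p = 0.3$, so planted offsets are
  roughly ten outcome standard errors), plus a roster of decoy traits
  (associated only with non-outlier variants), a weak trait
  (sub-threshold outlier association), a null candidate (outlier
  association but no outcome effect) and a near-duplicate of a real
  trait — one of each kind that the funnel stages must reject;
* per-trait instrument sets (25 variants each) so trait-level MR has
  something to chew on, with sample sizes and allele frequencies
  recorded in the standard table layout.

Everything is a pure function of the configuration seed; identical
configurations give byte-identical datasets.

Deliberately *not* modelled: linkage disequilibrium among instruments
(the pipeline consumes post-clumping variants; the clumping routine is
exercised on explicit LD tables), sample overlap between the two studies,
case-control ascertainment, allele-frequency-dependent power, winner's
curse from instrument discovery, and population stratification. Passing
tests therefore certify the statistical machinery under the stated
generative model — they do not certify robustness to the survey-design
pathologies of real GWAS consortia data.

## Numerical and interface choices

* Confidence intervals use the conventional 1.96 multiplier and normal
  (not t) p-values, the standard convention at large $J$; documented so
  tests can be exact.
* Computed p-values are floored at the smallest positive double so
  extreme z-scores never produce an invalid exact zero.
* Instrument selection is strict (`p <` threshold), greedy in ascending
  p-value with lexicographic rsid tie-breaks, and provably independent
  of input row order; LD pairs absent from the table count as $r^2 = 0$.
* Palindromic (A/T, C/G) variants default to `drop_ambiguous` with a
  0.08 frequency window around 0.5: orientable palindromes are aligned
  by EAF concordance, ambiguous or EAF-less ones are dropped, and
  `drop_all` is available for strict analyses. The window and policy are
  declared defaults — strand inference from frequencies is heuristic by
  nature.
* Harmonization never fails on a single bad variant: irreconcilable
  allele pairs are dropped and logged; only an empty result is fatal.
* All randomness (median bootstrap, cross-validation folds, simulation)
  flows from explicit seeds; the pipeline re-run with the same
  configuration is bit-for-bit reproducible, and input tables are
  content-hashed into the report.

## Problem sizes in the test suite

The suite validates calibration by simulation at sizes chosen to hold
Monte-Carlo error well below the tested margins while staying desk-scale:
oracle equivalence on 50 random instances per estimator ($J \le 100$,
$K \le 4$, agreement to 1e-10); recovery and interval coverage over 500
replicates at $J = 182$; type-I error of the IVW test and the Egger
intercept over 1000 null replicates; planted-outlier detection over 200
replicates (plus 1000 null replicates for the false-positive budget);
trait-adjustment recovery over 200 replicates; mediation patterns over
500 replicates. The Egger-intercept *power* property is evaluated on a
precise-outcome design ($\sigma_\Gamma \approx 0.01$) because a 0.005
per-variant offset is genuinely undetectable at the default outcome noise
— power claims are always relative to a design.

## Known limitations

* Trait-level MR inside the funnel assumes the trait table and outcome
  share an effect-allele frame (the table carries no allele columns);
  build the table accordingly.
* The adjustment treats selected trait effects as fixed when subtracting
  pleiotropic components; the `propagate` policy bounds, but does not
  fully model, the induced correlation between adjusted outcome betas.
* No Steiger filtering, mode-based estimators, PRESSO-style distortion
  tests, conditional F-statistics, or radial-Egger variants; the scope
  is the IVW/Egger/median + radial + TRYX + MVMR recipe.
* Mediation verdicts are threshold-based by design; near-threshold
  p-values flip verdicts, which is a property of the convention, not of
  the implementation.
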