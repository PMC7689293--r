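---
title: "Mediation-aware Mendelian randomization: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediation-aware Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Observational studies associate tobacco smoking with type 2 diabetes (T2D)
and coronary artery disease (CAD), but smoking also tracks adiposity, and
body mass index (BMI) is itself a strong causal risk factor for T2D. The
question this package is built around is a mediation question: *when
genetically proxied smoking raises disease risk, how much of that effect
passes through BMI?* Mendelian randomization (MR) addresses it with genetic
variants as instruments: alleles are randomized at meiosis, so a variant
robustly associated with smoking behaviour can proxy the exposure free of
classical confounding, provided it affects the outcome only through that
exposure.

`mrmediate` implements the full workflow: instrument construction from GWAS
summary statistics, two-sample estimators with pleiotropy diagnostics,
multivariable MR (MVMR) for mediator-conditional direct effects, the
MR-Steiger directionality test, a simplified bivariate LD score regression,
and an individual-level two-stage predictor substitution (2SPS) analysis —
validated end to end against a synthetic cohort generator with known causal
structure.

# Models and estimators

## Harmonization

Two-sample MR needs exposure and outcome effects expressed for the same
allele. `harmonize()` intersects tables on SNP id, flips swapped alleles
(negating the outcome beta and complementing the allele frequency), resolves
strand differences through allele complements, and treats palindromic (A/T,
C/G) variants by allele frequency: both frequencies must fall outside
`0.5 ± w` (default `w = 0.08`, so frequencies in 0.42–0.58 drop the SNP)
and must indicate the same allele side; otherwise the SNP is dropped. Every
row carries an action code (`kept`, `flipped`, `dropped_palindromic`,
`dropped_mismatch`) so attrition is auditable. The default window follows
common two-sample MR practice; it is a parameter because no universal value
exists.

## Instruments

`clump()` performs greedy LD clumping: sort genome-wide-significant SNPs
(default `p < 5e-8`) by ascending p, retain the best remaining SNP, discard
all candidates within a 250 kb *radius* having `r² ≥ 0.01` against it.
Ties in p break by chromosome and position, making the output deterministic
and invariant to row order. Window-as-radius matches the behaviour of the
standard clumping tools; span semantics would halve the effective window.
Instrument strength is summarized by the per-SNP variance explained

$$ r^2_j = \frac{\beta_j^2\,2p_j(1-p_j)}{\beta_j^2\,2p_j(1-p_j) +
se_j^2\,2p_j(1-p_j)\,n} $$

summed over the instrument, and the F-statistic
$F = \frac{n-k-1}{k}\cdot\frac{R^2}{1-R^2}$; $F > 10$ is the conventional
weak-instrument guard and gates the individual-level stage-2 fits.

## Two-sample estimators

With harmonized effects $(\hat\beta_{x,j}, \hat\beta_{y,j})$ and weights
$w_j = 1/se_{y,j}^2$:

* **IVW**: zero-intercept weighted regression,
  $\hat\theta = \sum w b_x b_y / \sum w b_x^2$. The default is the
  *multiplicative random-effects* model: the fixed-effects SE is inflated
  by $\max(1, \sqrt{Q/(k-1)})$, which leaves the point estimate unchanged
  and never rewards underdispersion. Additive random effects are not
  implemented.
* **Weighted median**: per-SNP Wald ratios ordered, weighted by inverse
  ratio variance; the estimate interpolates the ratio at cumulative weight
  0.5 using the midpoint convention (cumulative weight up to SNP $i$ minus
  $w_i/2$). Consistent when at least half the weight is valid. Its SE comes
  from a seeded parametric bootstrap (default 5,000 draws) resampling both
  $b_x$ and $b_y$; the scheme is reproducible by construction.
* **MR-Egger**: the same regression with a free intercept, after orienting
  all exposure betas non-negative (the estimator is not invariant to allele
  coding). A nonzero intercept estimates directional pleiotropy; inference
  uses the t distribution with $k-2$ df and the same residual inflation
  floor.
* **Cochran's Q** with first-order Wald weights $b_x^2/se_y^2$ quantifies
  heterogeneity; its p-value comes from $\chi^2_{k-1}$.

Effect scales follow the doubling convention for binary exposures: the
reported odds ratio is $\exp(\ln 2\cdot\hat\theta)$, the outcome odds
change per 2-fold increase in exposure odds; continuous exposures use
$\exp(\hat\theta)$ per SD. For a continuous outcome, the absolute change
per 2-fold exposure odds is $\ln 2 \cdot \hat\theta$ (used for BMI in
kg/m²).

## MVMR and mediation

`mvmrFit()` regresses outcome betas on the matrix of exposure betas
(no intercept, weights $1/se_y^2$), giving each exposure's *direct* effect
conditional on the others. The combined instrument is the union of the
per-exposure clumped instruments, re-clumped jointly at `r² < 0.01` so no
signal is double-counted. A Sanderson-style conditional F diagnostic is
reported but nothing is gated on it. `mediate()` pairs the univariable
(total) and multivariable (direct) estimates and expresses both as percent
change per 2-fold exposure odds, $100(e^{\ln 2\,\beta}-1)$, transforming CI
endpoints through the same monotone map rather than using the delta method
(the map is exact; the delta method is not). **No indirect effect is
reported for binary outcomes**: odds ratios are noncollapsible, so
total-minus-direct does not identify a mediated path; the result object
carries an explicit reason flag instead of a number.

## MR-Steiger

Causal direction is inferred by comparing instrument variance explained in
each trait: continuous traits via the formula above, binary traits via the
observed-scale approximation $r^2 \approx z^2/(z^2+n)$ (liability-scale
conversion is deliberately not attempted). The z statistic applies the
Fisher transform to $\sqrt{R^2}$ of each trait with its own sample size.
The sensitivity ratio perturbs both traits over a grid of measurement
reliability multipliers $\{0.5, 0.6, \ldots, 1.0\}^2$ (36 points; observed
$R^2$ divided by the reliability) and reports supporting over opposing grid
volume; it is $+\infty$ when no grid point opposes the call. This is an
analog of the published sensitivity concept, not a replication — the
original's grid and bounds are not recoverable, so ours is documented and
configurable.

## Simplified LD score regression

`h2Regression()` regresses squared z-scores on LD scores
($\ell_j = 1 + \sum_{i\neq j} r^2_{ij}$ from an explicit LD reference);
the slope times $M/n$ estimates heritability. Weights
$1/(2(1+n h^2 \ell/M)^2)$ are initialized at $h^2=0$ and updated by one
re-weighting iteration — a documented simplification of full IRWLS that is
adequate at synthetic scale. `rgRegression()` applies the same machinery to
z-score products, normalizes by the two heritabilities, clips to
$[-1, 1]$, and attaches a delete-one block jackknife SE (default 200
contiguous blocks, at least 20). Samples are assumed non-overlapping, so
the cross-product intercept is reported, not modelled.

**Known limitation**: the estimator is identified when causal signal
density scales with LD score. Under the synthetic generator's *sparse*
architecture (60 causal loci, one per LD block, nearly constant LD scores)
that link is broken and per-trait slopes can go negative; the result object
then flags rg as undefined rather than fabricating a value. Validation and
the acceptance report therefore use the infinitesimal generating model
(`simulateZscores()`), which is the regime the method claims.

## Individual-level 2SPS

`twoStage()` implements two-stage predictor substitution: stage 1 is a
logistic regression of smoking status on the polygenic score plus age, sex
and five principal components, carrying *fitted probabilities* forward
(the standard 2SPS choice; linear predictors would only rescale the
second stage). Stage 2 regresses the outcome on predicted smoking plus
covariates — the total effect — and, when a mediator weight table is
supplied, also on predicted BMI built from the *same SNPs* reweighted by a
BMI GWAS ("BMI-by-smoking-SNPs"), giving the direct effect. Stage-2 SEs
are model-based, a documented limitation versus bootstrap/sandwich SEs.
Degenerate mediator scores that collapse into the covariate span are
aliased out of the fit (the adjusted model then equals the total-effect
model, and the mediator coefficient is NA). PRS variance explained in
smoking is reported as Nagelkerke's
$R^2 = [1-e^{(2/n)(\ell_0-\ell_1)}]/[1-e^{(2/n)\ell_0}]$.

**Identifiability caveat.** The BMI-by-smoking-SNPs decomposition requires
the exposure's SNPs to carry mediator information *beyond* the exposure.
Under pure mediation — the synthetic generator's default, where smoking
SNPs affect BMI only through smoking — predicted BMI is a noisier proxy of
the same genetic index as predicted smoking ($E[\mathrm{BMI}\mid G] =
c\,E[\mathrm{smoking}\mid G]$), stage 2 loads the whole mediated effect on
the better proxy (the fitted smoking probability), and the adjusted
smoking coefficient stays at the total effect. The adjustment separates
direct from mediated effects only when per-SNP mediator effects deviate
from proportionality (as they do in real data through pleiotropy). The
package's identifiable mediation demonstration is therefore the
two-sample MVMR, which draws on the mediator's own instruments; the 2SPS
stage is validated on its total effect, its weak-instrument gate and its
algebraic invariants.

# The synthetic cohort generator

`simulationTruth()` fixes the generating model; `simulateCohort()`,
`gwasScan()` and `makeTwoSample()` produce data from it. The structural
model is

* smoking liability $= G\gamma_{smk} + \varepsilon$, standardized;
  smoking status thresholds the liability at prevalence 0.45 (a liability
  model keeps PRS-on-liability scenarios meaningful);
* BMI $= \theta_{SB}\,\mathrm{smoking} + G\gamma_{bmi} + \varepsilon$,
  reported standardized and on a kg/m² scale (mean 28, SD 4.7);
* T2D and CAD are Bernoulli with logistic linear predictors
  $\alpha + \theta_{B\cdot}\mathrm{BMI}_{std} + \theta_{S\cdot}\mathrm{smoking}
  + \mathrm{pleiotropy} + \mathrm{nuisance}$, the intercept solved
  numerically to hit the target prevalence (0.20 / 0.15). The logistic
  scale makes GWAS log odds ratios the natural estimand for the
  estimators.

Default path coefficients were set once from the motivating study's
reported magnitudes and then left alone: $\theta_{SB}=0.8$ SD per
smoking-status unit (implying ≈0.14 SD of BMI per 2-fold smoking odds at
the GWAS level), $\theta_{BT}=\ln 2.5$ (the established BMI→T2D odds ratio
per SD), $\theta_{ST}=0$ (full mediation of the T2D effect),
$\theta_{BC}=0.35$ and $\theta_{SC}=0.66$ (a direct smoking→CAD odds ratio
near 1.12 per doubling). Sixty causal SNPs per trait, disjoint LD blocks,
normally distributed effects summing to $h^2 \approx 0.24$.

Genotypes use a Gaussian copula: one latent AR(1) Gaussian per 10-SNP
block, thresholded to Hardy-Weinberg dosages at minor allele frequencies
drawn U(0.05, 0.5). The latent correlation is calibrated by bivariate
normal quadrature so the *dosage-scale* adjacent $r^2$ hits its target
(default 0.3); larger lags decay approximately geometrically and the
emitted LD reference reports the calibrated dosage-scale values. Because
calibration is at the mean maf, pairs of dissimilar frequencies sit
slightly below the nominal value — the reference then slightly overstates
LD, which is conservative for clumping.

`gwasScan()` adjusts for age, sex and five PCs. Continuous traits use the
exact projection algebra of OLS; binary traits use a one-step score/Wald
approximation from the covariate-only null logistic model (the approach of
fast biobank-scale scan engines), vectorized across SNPs. On a small
fixture it matches per-SNP `glm()` coefficients and SEs to within ~3%,
and exactly matches `lm()` for continuous traits.

Directional pleiotropy scenarios attach direct outcome effects to the
*exposure-increasing allele* — the coding under which the MR-Egger
intercept estimates the pleiotropy mean; attaching them to arbitrary
allele codings would cancel under Egger orientation. The documented default
magnitude is $\alpha \sim N(0.025, 0.01)$, at which the intercept test has
>80% power at $k=100$ instruments while retaining nominal type-I error
under the null.

What the generator does *not* emulate: realistic human LD maps (blocks are
uniform and independent), population stratification beyond nuisance PCs,
imputation uncertainty, assortative mating, or sample overlap (except as a
deliberate warning scenario). Passing tests therefore demonstrate correct
behaviour of the estimators under their stated assumptions, not robustness
to every failure mode of real GWAS data.

# Problem sizes used in validation

Unit tests run on cohorts of 500–10,000 individuals and 60–500 SNPs.
The parameter-recovery experiments mirror the study design at
n = 20,000 per cohort, M = 2,000 SNPs (the 120 causal loci plus null
background; additional null SNPs do not change instrument power), 50
replicates, asserting: total smoking→T2D effect detected in ≥90% of
replicates, BMI-conditional direct T2D effect compatible with zero in
≥85%, direct CAD effect retained in ≥85%. Steiger direction calls use 100
summary-level replicates; Egger calibration uses 1,000 null and 500
pleiotropic replicates; genetic-correlation recovery uses M = 5,000 and 20
replicates. These sizes were chosen so the whole suite runs comfortably on
a single CPU.

# Numerical and design notes

* Clumping tie-break: lower (chromosome, position) wins — determinism over
  arbitrariness.
* Weighted-median knots: the midpoint convention is pinned by worked
  examples; duplicating every SNP moves knots by half a weight, so exact
  duplication-invariance is not a property of this estimator (tests assert
  stability at the knot-spacing scale).
* `.solveIntercept()` brackets the logistic intercept in [-30, 30];
  prevalences unreachable in that range raise an error rather than silently
  saturating.
* Negative fitted heritabilities are clipped to zero with a warning;
  genetic correlations are clipped to [-1, 1] after normalization.
* Indels and multi-allelic records are rejected at read time; positions are
  1-based; chromosome labels are normalized without the "chr" prefix.
* All randomness flows through explicit integer seeds (`withSeed()`
  restores the caller's RNG state), so identical configs give
  byte-identical outputs.
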