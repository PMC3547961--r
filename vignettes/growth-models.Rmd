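---
title: "Modelling childhood BMI trajectories and their genetic determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling childhood BMI trajectories and their genetic determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmigrowth)
```

## The problem

Childhood BMI does not grow monotonically: it falls from infancy to the
*adiposity rebound* around age 5–6 and then rises through adolescence, with
between-subject variability that itself grows with age. Detecting modest
genetic effects on the *level* and *shape* of this trajectory requires
longitudinal models that capture the non-linear mean curve, the growing
between-subject spread, and the serial correlation of repeated measures on
irregular visit schedules. `bmigrowth` implements four such model families
under a common maximum-likelihood estimation contract, a genetic association
layer, a cluster-bootstrap comparison suite, and a synthetic cohort generator
so that every stage is testable without access to any real cohort.

## The four model families

**Polynomial linear mixed model (LMM).** On the log scale,
$\ln \mathrm{BMI}_{jt} = \sum_{i=0}^{3}\beta_i a_{jt}^{\,i}
 + \sum_{k=0}^{2} u_{kj} a_{jt}^{\,k} + \varepsilon_{jt}$,
with $a = \mathrm{age} - 8$ (centred at the design's mean age so estimates are
comparable across strata), multivariate-normal subject effects
$u_j \sim N(0, G)$ and residuals with continuous-time AR(1) correlation
$\mathrm{corr}(\varepsilon_s, \varepsilon_t) = \phi^{|t-s|}$ — the right
serial structure for irregularly spaced visits. Estimation profiles the
fixed effects and $\sigma^2$ out by generalized least squares, so the
optimizer (`nlminb`) searches only the log-Cholesky factor of $G/\sigma^2$
and logit $\phi$; per-subject likelihood pieces are accumulated in compiled
code. The starting value is moment-based (per-subject OLS random-effect
estimates), which keeps the search away from distant local optima when
variance ratios are large. Every converged fit's log-likelihood is checked in
the test suite against a dense per-subject multivariate-normal oracle and
against an independent implementation (`nlme`).

**Semi-parametric spline LMM (SPLMM).** The same machinery with the fixed
time trend replaced by a cubic *truncated power basis*
$\{1, t, t^2, t^3, (t-\kappa_k)^3_+\}$ with knots at 2, 8 and 12 years on the
raw age scale, random effects $1 + a + 0.5a^2$ (the 0.5 scaling is pure
reparameterization of $G$, verified by a unit test), and independent
residuals. The cubic truncated terms make the curve and its first two
derivatives continuous at each knot. Knots are selected by AIC over a
candidate grid; ties break toward fewer parameters. A degree-1 truncated
basis is available behind a flag.

**Skew-t LMM (STLMM).** BMI is left untransformed; the asymmetry and heavy
tail of its distribution are instead absorbed by the model: random effects
follow a multivariate skew-normal law with skewness vector $\lambda$ (one
entry per random effect: intercept and linear age) and the errors a
multivariate $t$ with $\nu$ degrees of freedom, coupled through a single
Gamma$(\nu/2,\nu/2)$ mixing variable per subject so the marginal response is
multivariate skew-t. The random-effect location is shifted so its marginal
mean is zero; otherwise the fixed intercept and the skewness would be
confounded and fixed effects would not be comparable across model families.
Estimation is EM: the E-step uses exact closed-form conditional moments of
the truncated skew representation (each reduces to Student-t CDF ratios via
two Gamma-integral identities; all four moment formulas are verified against
2-D numerical quadrature in the tests), and $\nu$ is updated by a direct 1-D
profile search on the log scale (an ECME step), every 10 iterations by
default, bounded in $(2, 200]$. The observed-data log-likelihood is
asserted non-decreasing at every iteration; a decrease beyond tolerance is
treated as an internal bug, never silently accepted. With $\lambda = 0$ and
$\nu \to \infty$ the marginal log-likelihood collapses to the Gaussian LMM's,
which is tested numerically. Convergence tolerance is $10^{-6}$ relative
log-likelihood.

**SITAR nonlinear mixed model (NLMM).** A single population curve $h$ — a
natural cubic spline of $\ln$ age with 3–8 df, boundary knots at the
2.5th/97.5th percentiles of $\ln$ age — shared by all subjects, each of whom
shifts and stretches it through three random effects:
$y_{it} = \alpha_i + h\!\left((x_{it} - \beta_i)\,e^{\gamma_i}\right)$
with $y = \ln \mathrm{BMI}$, $x = \ln \mathrm{age}$. $\alpha$ is *size*
(vertical shift), $\beta$ *tempo* (timing; because age is log-transformed a
tempo shift is multiplicative in age), $\gamma$ *velocity* (age-scale
stretch). Fixed effects are the spline coefficients including its intercept;
a fixed tempo shift is not identifiable because it is absorbed by $h$.
Estimation follows the Lindstrom–Bates alternating scheme: an inner
penalized Gauss–Newton loop updates the spline coefficients and the
random-effect predictions at fixed variance parameters (linearize, GLS,
BLUP, repeat to the fixed point), then the variance parameters are
re-estimated by ML on the current linearization; the converged linearized
log-likelihood is the Laplace-type approximation used for AIC/deviance
comparison across df (checked against a per-subject-mode Laplace evaluation
of the exact nonlinear model on a 30-subject toy). The df is chosen by AIC
with deviance and residual SD reported alongside.

## Genetic association layer

Risk-allele dosages (0/1/2) enter additively. The unweighted allele score
sums dosages over the 17-locus panel; subjects missing any locus are
excluded from score analyses (complete case), while single-SNP analyses drop
only subjects missing that SNP. For the three linear-family engines the
fixed design gains $g,\; g a,\; g a^2,\; g a^3$ (centred polynomial age even
when the base trend is a spline, so per-term estimates are comparable across
engines; interacting $g$ with spline columns is deliberately not done) and
the engine's null and full fits feed a global likelihood-ratio test with
df = number of added columns (4 by default). For SITAR, subject-level size,
tempo and velocity are each regressed on dosage — three tests per SNP. The
per-age effect curve evaluates
$\hat g + \hat g_1 a + \hat g_2 a^2 + \hat g_3 a^3$ with a delta-method CI;
at the centring age it equals the main-effect coefficient exactly. No
multiple-testing adjustment is applied by default (the panel consists of
previously validated loci); a Bonferroni helper exists but is off.
Principal components can be appended as extra fixed covariates by the user;
their computation is out of scope.

## The synthetic cohort generator

The generator emulates an eight-wave pregnancy cohort: 773 males and 733
females; wave mean ages 1.16, 2.18, 3.11, 5.92, 8.10, 10.60, 14.07, 17.05
years; per-wave attendance probabilities 0.91, 0.27, 0.66, 0.88, 0.88, 0.85,
0.85, 0.68 (the observed wave sample fractions), which reproduce a median of
6 visits per subject with IQR 5–7; per-wave age-jitter SDs 0.10–0.35 years;
everyone attends at least one wave. The default mean curves are calibration
constants: least-squares projections of smoothed monotone-rebound targets
through the per-sex wave BMI means onto the truncated-power basis with knots
2/8/12, placing the rebound at 5.1 (female) and 5.4 (male) years, with the
early-wave wobble in the raw wave means (a visit-subsample artifact)
smoothed out so the population curve falls monotonically from age 2 to the
rebound. Random-effect SDs default to 0.10 (intercept, ln units), 0.010
(slope/yr) and 0.0015 (quadratic), intercept–slope correlation 0.5, residual
SD 0.05 ln units — together these reproduce the increasing between-subject
BMI spread with age; a well-specified subject-level fit attains $R^2$
around 0.97 on these clean synthetic data (real cohorts sit lower because
of measurement noise and model misfit the generator does not emulate). CAR(1) noise is drawn exactly from the joint covariance
$\sigma^2\phi^{|\Delta t|}$ by per-subject Cholesky factorization (ages are
irregular, so no AR recursion). Skew-t generation uses the
skew-normal/$\sqrt{\text{Gamma}}$ stochastic representation with the same
mixing variable for effects and errors, i.e. exactly the generative model
the STLMM estimates — so the density code can be validated against draws.

Genotypes are independent Binomial(2, p) loci in Hardy–Weinberg equilibrium,
where p is each locus's *risk-allele* frequency. The panel's MAFs and the
major/minor orientation of the risk alleles are literature-typical
calibration constants (FTO 0.41, MC4R 0.23, NEGR1 0.38, one BDNF variant
0.21 fixed by the emulated design); with roughly half the risk alleles being
major alleles the 17-locus score has mean ≈ 16.7 and quartiles near
15/17/18. Linkage disequilibrium between loci is not simulated; the
association layer treats SNPs marginally. The bundled scenarios are `null`
(all genetic effects exactly zero), `single_snp` (an FTO-only effect:
0.010 ln-units level, 0.0012/yr slope per allele) and `allele_score`
(per-allele level/slope effects 0.0049/0.0012 ln-units in females,
0.0071/0.0008 in males).

What the generator does *not* emulate: measurement outliers and data-entry
errors, informative missingness (attendance is independent of BMI), secular
cohort effects, family structure or population stratification, and
mechanistic puberty timing. Passing tests therefore demonstrate estimator
correctness under the assumed generative structure, not robustness to those
real-data features.

## Validation design choices

**Likelihood oracles.** Every Gaussian fit is checked against a dense
per-subject MVN evaluation; the skew-t E-step against numerical quadrature;
the SITAR objective against a mode-centred Laplace evaluation of the exact
nonlinear model.

**Null calibration.** The 4-df global LRT's size is estimated from 1,000
null simulations of 500 subjects on a reduced four-wave schedule (the
reduced schedule keeps the study at desk scale without changing the test's
null distribution); the acceptance band is 3.5–6.5% around the nominal 5%.

**Score-effect recovery.** The spline engine's score-level and score-slope
estimates are averaged over 50 simulated cohorts of 1,500 subjects and
required to bracket the injected truth within two Monte-Carlo standard
errors of the seed-mean.

**Skew-t recovery.** Skewness (4.58, 2.23) and $\nu = 8$ are injected at
n = 1,500; the tolerance scale for recovery is the reported sampling SE of
this estimator on a comparable cohort (1.10, 0.63 at n ≈ 730), rescaled by
$\sqrt{733/1500}$.

**SITAR recovery and identifiability.** Subject-parameter recovery is
validated on a *monotone* growth curve (anchored at the design's wave mean
heights and level-shifted into the BMI range) with tempo SD 0.1 ln-age and
residual SD 0.002 — roughly the technical error of stature measurement. This
choice is deliberate: on a BMI-shaped curve, which is flat around the
rebound, the per-subject Fisher information bound caps the achievable
tempo correlation well below 0.9 at any realistic noise level (the tempo and
velocity gradient columns $-h'(x)$ and $x\,h'(x)$ correlate at about −0.95
over this age range, and the error floor for tempo is ≈ 0.07 ln-age even at
residual SD 0.005). Weak tempo identifiability on rebound-shaped curves is a
property of the data design, not of the estimator, so the estimator is
validated where the parameters are identifiable; the BMI-shaped curve
remains the generator default for all other studies.

**Bootstrap conventions.** All resampling is by subject (cluster bootstrap),
keeping each subject's visits together; the model specification is frozen
across replicates (knots/df are not reselected); non-convergent replicates
are counted and a report with more than 20% failures is flagged unusable.
Two power modes are provided because they answer different questions:
`simulate` draws fresh responses from the known truth (true Monte-Carlo
power; equals the test size at zero effect), while `resample` is the
post-hoc non-parametric bootstrap, whose replicated LRT statistic is
approximately noncentral $\chi^2$ at the *observed* statistic and therefore
tracks the realized sample association — the known optimism of post-hoc
power estimates, worth keeping in mind when reading bootstrap power figures.

**Problem sizes.** Unit tests run at 60–400 subjects; acceptance-level
studies use 1,000–1,500 subjects, 50 recovery seeds, 1,000 null replicates
and B = 200 bootstrap resamples; the analysis scripts default to B = 100–200
with the full B = 1,000 available by changing one constant.

## Known limitations

The SPLMM treats spline terms as unpenalized fixed effects with AIC-chosen
knots; no smoothing-parameter selection is attempted. The STLMM's errors are
symmetric-t (skewness enters only through the random effects) and no CAR(1)
structure is offered under the skew-t family. SITAR is fitted with
independent residuals; a serial-correlation variant is left as a
configuration stub. Wald CIs for the STLMM fixed effects come from a
numerically differenced observed information and inherit its finite-difference
error. The scale of raw-BMI STLMM coefficients is not comparable to the
ln-scale engines and no rescaling is attempted. Correlated loci (e.g. the
two BDNF variants, r² ≈ 0.1 in real panels) are simulated independently.
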