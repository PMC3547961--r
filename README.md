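# bmigrowth

Longitudinal BMI growth-curve models for genetic association studies.

Childhood BMI falls from infancy to the adiposity rebound around age 5–6 and
then rises through adolescence; detecting modest genetic effects on the
level and shape of that trajectory requires longitudinal models that handle
the non-linear mean curve, growing between-subject variance and serial
correlation of irregularly timed repeated measures. `bmigrowth` implements,
under one maximum-likelihood contract, the four model families used for this
problem, a sex-stratified genetic association layer, a cluster-bootstrap
comparison suite, and a synthetic-cohort generator emulating an eight-wave
pregnancy cohort (1,506 children, median 6 visits each), so the entire
pipeline is testable end to end. It is aimed at biostatisticians comparing
trajectory-modelling strategies for candidate-gene and allele-score analyses
of childhood growth.

The four engines:

| engine | response | fixed trend | random effects | residuals |
|---|---|---|---|---|
| LMM | ln BMI | cubic in centred age | `1 + a + a²` | CAR(1), `φ^{Δt}` |
| STLMM | raw BMI | cubic in centred age | `1 + a`, skew-normal | multivariate-t (shared Gamma mixing → marginal skew-t), EM estimation |
| SPLMM | ln BMI | cubic truncated-power spline, knots 2/8/12 y | `1 + a + 0.5a²` | independent |
| NLMM (SITAR) | ln BMI | shared natural cubic spline `h` of ln age | size / tempo / velocity: `y = α_i + h((x−β_i)e^{γ_i})` | independent |

Genetics: risk-allele dosages and the unweighted 17-locus obesity risk-allele
score enter the fixed design as `g, g·a, g·a², g·a³` and are tested jointly
by a 4-df global likelihood-ratio test (for SITAR: regressions of subject
size/tempo/velocity on dosage, three tests per SNP), with per-age effect
curves `ĝ + ĝ₁a + ĝ₂a² + ĝ₃a³` and delta-method CIs.

## Worked example

Simulate a cohort with injected allele-score effects (per-allele ln-BMI
level +0.0049 and slope +0.0012/yr in females), fit the spline model, and
test the score:

```r
library(bmigrowth)

sc <- make_scenario("allele_score", sim_config(seed = 42))
st <- stratify_by_sex(sc$cohort, sc$genotypes)
score <- compute_allele_score(sc$genotypes)

fit <- fit_lmm(st$female$cohort, preset_spec("splmm"))
fit
#> <growth_fit: ln response, truncated_power fixed basis, independent correlation>
#>   733 subjects, 4350 visits; logLik 4764.940, AIC -9501.880
#> (Intercept)         age        age2        age3   (age-2)+3   (age-8)+3
#>     2.79200    -0.02056     0.00401    -0.00012     0.00032    -0.00116
#>  (age-12)+3
#>     0.00116

res <- global_lrt_assoc(st$female$cohort, preset_spec("splmm"),
                        score[names(score) %in% st$female$cohort$subject_id])
res
#> <assoc_result: engine lmm, global LRT chi2 = 76.460 (df 4), p = 9.783e-16>
#>         term   estimate        se   ci_lower  ci_upper   p_value
#> 1      Score  3.183e-03 1.550e-03  1.443e-04 6.222e-03 4.006e-02
#> 2  Score*Age  1.360e-03 2.046e-04  9.588e-04 1.761e-03 3.030e-11
#> 3 Score*Age2  1.868e-05 1.848e-05 -1.754e-05 5.490e-05 3.120e-01
#> 4 Score*Age3 -3.061e-06 3.190e-06 -9.312e-06 3.191e-06 3.372e-01
```

At this single seed the score-level estimate (0.0032, SE 0.0016) and slope
estimate (0.00136, SE 0.0002) bracket the injected truth (0.0049, 0.0012)
within sampling error, and the 4-df global LRT is decisive. The per-age
effect curve shows the per-allele effect growing with age, the timing
signature of these variants:

```r
per_age_effect(res, c(1, 8, 17))
#>   age   effect      se  ci_lower ci_upper
#> 1   1 -0.00437 0.00154 -0.007384 -0.00136
#> 2   8  0.00318 0.00155  0.000144  0.00622
#> 3  17  0.01470 0.00257  0.009670  0.01974
```

`fit_stlmm()` fits the skew-t model on untransformed BMI, and `fit_sitar()`
/ `sitar_param_assoc()` run the size–tempo–velocity route.

The `analysis/` directory holds the numbered drivers of the full study —
`01_simulate_cohort.R` (writes the synthetic visit/genotype tables),
`02_fit_growth_models.R` (four engines per sex, AIC knot/df selection,
model-comparison table), `03_genetic_association.R` (score and single-SNP
association tables, per-age effect curves), `04_model_comparison_bootstrap.R`
(bootstrap R² distributions) and `05_power.R` (Monte-Carlo and post-hoc
bootstrap power) — each writing its tables under `results/`.

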