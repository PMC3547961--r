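# Light spec used throughout: cubic fixed trend, random intercept + slope,
# independent errors -- fast enough for repeated fitting.
light_spec <- function() {
  model_spec("ln",
             fixed = basis_spec("polynomial", degree = 3),
             random = basis_spec("polynomial", degree = 1),
             correlation = "independent")
}

test_that("allele score is the complete-case sum of risk dosages", {
  g <- data.frame(subject_id = c("a", "b", "c"),
                  s1 = c(0L, 2L, 1L), s2 = c(0L, 2L, NA))
  sc <- compute_allele_score(g)
  expect_equal(unname(sc[c("a", "b")]), c(0L, 4L))
  expect_false("c" %in% names(sc))          # missing locus excludes subject
  expect_error(compute_allele_score(g, c("s1", "nope")), "absent")
  # upper bound: seventeen homozygous-risk loci
  g17 <- cbind(data.frame(subject_id = "z"),
               as.data.frame(as.list(setNames(rep(2L, 17),
                                              obesity_snp_panel()$snp_id))))
  expect_equal(as.integer(compute_allele_score(g17)), 34L)
  # locus order is irrelevant
  perm <- sample(obesity_snp_panel()$snp_id)
  expect_equal(compute_allele_score(g17, perm), compute_allele_score(g17))
})

test_that("genetic terms augment the fixed design as specified", {
  sc <- small_female_stratum()
  g <- compute_allele_score(sc$genotypes)
  sp0 <- add_genetic_terms(light_spec(), interaction_degree = 0)
  f0 <- fit_lmm(sc$cohort, sp0, g = g)
  expect_true("score" %in% names(f0$fit$beta))
  expect_equal(ncol(f0$X), 4 + 1)
  sp3 <- add_genetic_terms(light_spec(), interaction_degree = 3)
  f3 <- fit_lmm(sc$cohort, sp3, g = g)
  expect_equal(ncol(f3$X), 4 + 4)
  # constant g is rejected as collinear
  gconst <- setNames(rep(1, length(g)), names(g))
  expect_error(fit_lmm(sc$cohort, sp3, g = gconst), "constant")
})

test_that("global LRT bookkeeping is internally consistent", {
  sc <- small_female_stratum()
  g <- compute_allele_score(sc$genotypes)
  res <- global_lrt_assoc(sc$cohort, light_spec(), g)
  expect_s3_class(res, "assoc_result")
  expect_equal(res$lrt$df, 4)
  expect_equal(nrow(res$terms), 4)
  expect_true(all(res$terms$p_value >= 0 & res$terms$p_value <= 1))
  # statistic equals twice the loglik difference of the stored fits
  expect_equal(res$lrt$statistic,
               2 * (res$fit_full$fit$loglik - res$fit_null$fit$loglik),
               tolerance = 1e-8)
})

test_that("permuted scores give null p-values and injected effects power", {
  sc <- make_scenario("allele_score",
                      sim_config(n_male = 0, n_female = 400, seed = 77))
  g <- compute_allele_score(sc$genotypes)
  res <- global_lrt_assoc(sc$cohort, light_spec(), g)
  # with both level and slope injected at n=400 the LRT should be extreme
  expect_lt(res$lrt$p_value, 0.01)
  # permuting the score breaks the association by construction
  set.seed(1)
  gp <- setNames(sample(unname(g)), names(g))
  resp <- global_lrt_assoc(sc$cohort, light_spec(), gp)
  expect_gt(resp$lrt$p_value, 0.001)
})

test_that("per-age effect curve follows the fitted polynomial exactly", {
  sc <- make_scenario("allele_score",
                      sim_config(n_male = 0, n_female = 300, seed = 78))
  g <- compute_allele_score(sc$genotypes)
  res <- global_lrt_assoc(sc$cohort, light_spec(), g)
  eff <- per_age_effect(res, c(1, 8, 14))
  # at the centring age the effect is the main coefficient exactly
  expect_equal(eff$effect[eff$age == 8],
               unname(res$fit_full$fit$beta["score"]))
  expect_true(all(eff$ci_lower < eff$effect & eff$effect < eff$ci_upper))
  # zeroed genetic coefficients give a zero curve with symmetric CI
  res0 <- res
  gcols <- c("score", "score_x_age", "score_x_age2", "score_x_age3")
  res0$fit_full$fit$beta[gcols] <- 0
  eff0 <- per_age_effect(res0, c(2, 8, 15))
  expect_equal(eff0$effect, rep(0, 3))
  expect_equal(eff0$ci_upper, -eff0$ci_lower)
  # slope-only truth produces an increasing effect curve
  skel <- simulate_schedule(sim_config(n_male = 0, n_female = 400,
                                       seed = 79))
  geno <- simulate_genotypes(unique(skel$subject_id), seed = 80)
  tp <- true_params("female",
                    score_effects = c(level = 0, slope = 0.002))
  co <- simulate_bmi(skel, tp, geno, seed = 81)
  res_slope <- global_lrt_assoc(co, light_spec(),
                                compute_allele_score(geno))
  eff_slope <- per_age_effect(res_slope, c(2, 5, 8, 11, 14, 17))
  expect_true(all(diff(eff_slope$effect) > 0))
})

test_that("SITAR parameter regressions detect an injected tempo effect", {
  set.seed(5)
  n <- 400
  ids <- sprintf("P%03d", 1:n)
  g <- setNames(rbinom(n, 2, 0.4) + rbinom(n, 12, 0.5), ids)  # score-like
  pars <- data.frame(subject_id = ids,
                     size = rnorm(n, 0, 0.05),
                     tempo = -0.009 * unname(g) + rnorm(n, 0, 0.05),
                     velocity = rnorm(n, 0, 0.05))
  res <- sitar_param_assoc(pars, g)
  expect_equal(res$parameter, c("size", "tempo", "velocity"))
  expect_lt(res$slope[res$parameter == "tempo"], 0)
  expect_lt(res$p_value[res$parameter == "tempo"], 0.01)
  expect_equal(res$slope[res$parameter == "tempo"], -0.009,
               tolerance = 0.5)
  # null parameters: slopes near zero
  expect_gt(res$p_value[res$parameter == "size"], 0.01)
  # duplicating every subject halves nothing but the SE
  pars2 <- rbind(pars, transform(pars, subject_id = paste0(subject_id, "b")))
  g2 <- c(g, setNames(unname(g), paste0(ids, "b")))
  res2 <- sitar_param_assoc(pars2, g2)
  expect_equal(res2$slope, res$slope, tolerance = 1e-10)
  expect_true(all(res2$se < res$se))
  expect_error(sitar_param_assoc(pars[1:2, ], g), "fewer than 3")
})
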