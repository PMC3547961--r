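test_that("noise-free data recover the fixed effects almost exactly", {
  set.seed(10)
  sub <- rep(sprintf("s%02d", 1:25), each = 5)
  ages <- rep(c(1, 3, 6, 10, 16), 25) + runif(125, -0.2, 0.2)
  a <- ages - 8
  X <- cbind(1, a, a^2)
  beta <- c(2.8, 0.02, 0.003)
  y <- drop(X %*% beta) + rnorm(125, 0, 1e-7)
  fit <- fit_lmm_xz(y, X, cbind(1, a), sub, ages)
  expect_equal(unname(fit$beta), beta, tolerance = 1e-6)
})

test_that("fitted log-likelihood matches the dense MVN oracle", {
  for (seed in 1:6) {
    inst <- random_lmm_instance(seed, car1 = seed %% 2 == 0)
    corr <- if (inst$truth$phi > 0) "car1" else "independent"
    fit <- fit_lmm_xz(inst$y, inst$X, inst$Z, inst$subject, inst$ages,
                      correlation = corr)
    oracle <- dense_loglik_oracle(inst$y, inst$X, inst$Z, inst$subject,
                                  inst$ages, fit$beta, fit$G, fit$sigma2,
                                  if (corr == "car1") fit$phi else 0)
    expect_equal(fit$loglik, oracle, tolerance = 1e-6)
  }
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  inst <- random_lmm_instance(99, car1 = TRUE)
  fit <- fit_lmm_xz(inst$y, inst$X, inst$Z, inst$subject, inst$ages,
                    correlation = "car1")
  d <- data.frame(y = inst$y, a = inst$X[, 2], ages = inst$ages,
                  sub = inst$subject)
  m <- nlme::lme(y ~ a + I(a^2), random = ~ a | sub, data = d,
                 correlation = nlme::corCAR1(form = ~ ages | sub),
                 method = "ML",
                 control = nlme::lmeControl(opt = "optim"))
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(nlme::fixef(m)), tolerance = 1e-4)
})

test_that("estimates are invariant to subject relabelling", {
  inst <- random_lmm_instance(5)
  fit1 <- fit_lmm_xz(inst$y, inst$X, inst$Z, inst$subject, inst$ages)
  relabel <- setNames(sprintf("z%02d", seq_along(unique(inst$subject))),
                      unique(inst$subject))
  fit2 <- fit_lmm_xz(inst$y, inst$X, inst$Z,
                     unname(relabel[inst$subject]), inst$ages)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-6)
})

test_that("singular designs fail with the collinear column named", {
  inst <- random_lmm_instance(6)
  Xbad <- cbind(inst$X, dup = inst$X[, 2])
  expect_error(fit_lmm_xz(inst$y, Xbad, inst$Z, inst$subject, inst$ages),
               "collinear")
})

test_that("likelihood-ratio machinery follows the chi-square calculus", {
  sc <- small_female_stratum()
  spec2 <- model_spec("ln",
                      fixed = basis_spec("polynomial", degree = 2),
                      random = basis_spec("polynomial", degree = 1),
                      correlation = "independent")
  spec3 <- model_spec("ln",
                      fixed = basis_spec("polynomial", degree = 3),
                      random = basis_spec("polynomial", degree = 1),
                      correlation = "independent")
  f2 <- fit_lmm(sc$cohort, spec2)
  f3 <- fit_lmm(sc$cohort, spec3)
  # identical models: statistic 0, p = 1 (df comes out 0 -> guard)
  expect_error(lrt_nested(f2, f2), "not nested")
  res <- lrt_nested(f3, f2)
  expect_gte(res$statistic, 0)
  expect_equal(res$statistic, 2 * (f3$fit$loglik - f2$fit$loglik))
  expect_equal(res$df, 1)
  # chi-square tail probability against a numerical-integration oracle
  dens4 <- function(x) x * exp(-x / 2) / 4      # chi2 density, df = 4
  p_oracle <- integrate(dens4, 9.49, Inf, rel.tol = 1e-10)$value
  expect_equal(pchisq(9.49, 4, lower.tail = FALSE), p_oracle,
               tolerance = 1e-8)
  expect_equal(p_oracle, 0.0499, tolerance = 2e-3)
  # adding a column never lowers the ML likelihood
  expect_gte(f3$fit$loglik, f2$fit$loglik - 1e-6)
})

test_that("spline fixed basis with no knots reproduces the cubic LMM", {
  sc <- small_female_stratum()
  spec_poly <- model_spec("ln",
                          fixed = basis_spec("polynomial", degree = 3,
                                             center = 0),
                          random = basis_spec("polynomial", degree = 1),
                          correlation = "independent")
  spec_tp <- model_spec("ln",
                        fixed = basis_spec("truncated_power", degree = 3,
                                           knots = numeric(0)),
                        random = basis_spec("polynomial", degree = 1),
                        correlation = "independent")
  f1 <- fit_lmm(sc$cohort, spec_poly)
  f2 <- fit_lmm(sc$cohort, spec_tp)
  expect_equal(unname(f1$fit$beta), unname(f2$fit$beta), tolerance = 1e-4)
  expect_equal(f1$fit$loglik, f2$fit$loglik, tolerance = 1e-4)
})

test_that("the 0.5-scaled quadratic random design only reparameterizes G", {
  sc <- small_female_stratum()
  sp1 <- preset_spec("splmm")                     # random 1 + a + 0.5 a^2
  sp2 <- preset_spec("splmm")
  sp2$random$scale_quadratic <- FALSE             # random 1 + a + a^2
  f1 <- fit_lmm(sc$cohort, sp1)
  f2 <- fit_lmm(sc$cohort, sp2)
  expect_equal(f1$fit$loglik, f2$fit$loglik, tolerance = 1e-4)
  # G maps by the scaling matrix diag(1, 1, 2)
  S <- diag(c(1, 1, 2))
  expect_equal(S %*% f1$fit$G %*% S, unname(f2$fit$G), tolerance = 1e-2)
})

test_that("prediction levels, scales and BLUP shrinkage behave as derived", {
  sc <- small_female_stratum()
  fit <- fit_lmm(sc$cohort, preset_spec("splmm"))
  ages <- c(2, 8, 15)
  pop <- predict(fit, ages)
  # a subject whose random effects are zeroed predicts the population curve
  fit0 <- fit
  sid <- rownames(fit$fit$ranef)[1]
  fit0$fit$ranef[sid, ] <- 0
  expect_equal(predict(fit0, ages, "subject", subject_id = sid), pop)
  # exp/ln consistency
  expect_equal(predict(fit, ages, scale = "bmi"), exp(pop))
  # extrapolation guard warns
  expect_warning(predict(fit, 25), "guard")

  # closed-form BLUP for a single-visit subject: prediction lies strictly
  # between the observation and the population curve
  one <- data.frame(subject_id = "only", sex = "female",
                    age_years = 8, bmi = 19)
  co1 <- validate_cohort(rbind(as.data.frame(sc$cohort), one))
  f1 <- fit_lmm(co1, preset_spec("splmm"))
  yobs <- log(19)
  ypop <- predict(f1, 8)
  ysub <- predict(f1, 8, "subject", subject_id = "only")
  expect_true((ysub - ypop) * (yobs - ypop) > 0)       # same side
  expect_lt(abs(ysub - ypop), abs(yobs - ypop))        # shrunk
  # matches the scalar BLUP formula z G z' / (z G z' + sigma2) * resid
  z <- build_basis(f1$spec$random, 8)
  lever <- drop(z %*% f1$fit$G %*% t(z)) /
    (drop(z %*% f1$fit$G %*% t(z)) + f1$fit$sigma2)
  expect_equal(ysub - ypop, lever * (yobs - ypop), tolerance = 1e-6)
})

test_that("AIC-based knot selection returns the best-supported grid point", {
  sc <- small_female_stratum()
  sel1 <- select_spline_model(sc$cohort, list(c(2, 8, 12)))
  expect_equal(sel1$best_knots, c(2, 8, 12))
  expect_equal(nrow(sel1$table), 1)
  sel <- select_spline_model(sc$cohort,
                             list(c(2, 8, 12), c(3, 9), c(5)))
  tab <- sel$table
  # AIC identity holds row by row
  expect_equal(tab$aic, -2 * tab$loglik + 2 * tab$n_par)
  expect_equal(min(tab$aic, na.rm = TRUE),
               tab$aic[tab$knots == paste(sel$best_knots, collapse = ",")])
})

test_that("residual diagnostics produce plot-ready, sane tables", {
  sc <- small_female_stratum()
  fit <- fit_lmm(sc$cohort, preset_spec("splmm"))
  d <- residual_diagnostics(fit)
  expect_named(d, c("qq", "fitted_observed", "fitted_residual"))
  expect_equal(nrow(d$qq), fit$fit$n_obs)
  expect_false(is.unsorted(d$qq$sample))
  # Gaussian simulation: standardized residuals have roughly unit spread
  expect_lt(abs(sd(fit$fit$residuals_standardized) - 1), 0.1)
  expect_equal(d$fitted_observed$observed, fit$y)
})
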