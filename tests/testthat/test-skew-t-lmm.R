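# Small raw-scale strata for the skew-t model tests.
make_raw_stratum <- function(n = 150, family = "skew_t", seed = 21,
                             lambda = c(3, 1.5), nu = 8, sigma = 1) {
  cfg <- sim_config(n_male = 0, n_female = n, seed = seed)
  skel <- simulate_schedule(cfg)
  tp <- true_params("female", response = "raw",
                    fixed_basis = basis_spec("polynomial", degree = 3,
                                             center = 8),
                    random_basis = basis_spec("polynomial", degree = 1,
                                              center = 8),
                    beta = c(17, 0.5, 0.05, 0.002),
                    G = matrix(c(2.5, 0.15, 0.15, 0.04), 2),
                    sigma = sigma, error_family = family,
                    nu = nu, lambda = if (family == "skew_t") lambda)
  simulate_bmi(skel, tp, seed = seed + 1)
}

test_that("E-step moment formulas agree with 2-D numerical quadrature", {
  beta <- 2; sigma2 <- 0.5; D <- matrix(1.2); lambda <- 2; nu <- 6
  pr <- bmigrowth:::.stlmm_prep(list(D = D, lambda = lambda, nu = nu))
  for (yval in c(3.1, 0.4, -1.5)) {
    sj <- list(y = yval, X = matrix(1), Z = matrix(1), ii = 1)
    e <- bmigrowth:::.stlmm_esubject(sj, beta, sigma2, pr$Delta, pr$Gamma,
                                     nu, pr$cnu)
    f_ytu <- function(t, u) {
      m <- beta + pr$Delta * (t - pr$cnu)
      v <- (pr$Gamma[1, 1] + sigma2) / u
      2 * dnorm(yval, m, sqrt(v)) * dnorm(t, 0, 1 / sqrt(u)) *
        dgamma(u, nu / 2, nu / 2)
    }
    num <- function(fun) {
      integrate(Vectorize(function(u) {
        integrate(function(t) fun(t, u) * f_ytu(t, u), 0, Inf,
                  rel.tol = 1e-10)$value
      }), 0, Inf, rel.tol = 1e-9)$value
    }
    f0 <- num(function(t, u) 1)
    expect_equal(e$logf, log(f0), tolerance = 1e-6)
    expect_equal(e$EU, num(function(t, u) u) / f0, tolerance = 1e-6)
    expect_equal(e$EUt + pr$cnu * e$EU,
                 num(function(t, u) u * t) / f0, tolerance = 1e-6)
    expect_equal(e$EUt2 + 2 * pr$cnu * e$EUt + pr$cnu^2 * e$EU,
                 num(function(t, u) u * t^2) / f0, tolerance = 1e-6)
  }
})

test_that("compiled E-step agrees with the reference R implementation", {
  co <- make_raw_stratum(n = 40, seed = 81)
  spec <- preset_spec("stlmm")
  asm <- bmigrowth:::.assemble(co, spec)
  params <- list(beta = c(17, 0.5, 0.05, 0.002), sigma2 = 1.1,
                 D = matrix(c(2.3, 0.1, 0.1, 0.05), 2),
                 lambda = c(2.5, 1), nu = 7)
  pr <- bmigrowth:::.stlmm_prep(params)
  es <- bmigrowth:::stlmm_estep_cpp(asm$y, asm$X, asm$Z, asm$sub_start,
                                    asm$sub_len, params$beta, params$sigma2,
                                    pr$Delta, pr$Gamma, params$nu, pr$cnu,
                                    FALSE)
  idx <- split(seq_along(asm$y), rep(seq_along(asm$sub_len), asm$sub_len))
  for (j in c(1, 7, 23)) {
    ii <- idx[[j]]
    sj <- list(y = asm$y[ii], X = asm$X[ii, , drop = FALSE],
               Z = asm$Z[ii, , drop = FALSE])
    ref <- bmigrowth:::.stlmm_esubject(sj, params$beta, params$sigma2,
                                       pr$Delta, pr$Gamma, params$nu,
                                       pr$cnu)
    expect_equal(es$logf[j], ref$logf, tolerance = 1e-10)
    expect_equal(es$EU[j], ref$EU, tolerance = 1e-10)
    expect_equal(drop(es$EUb[j, ]), unname(ref$EUb), tolerance = 1e-9)
    expect_equal(matrix(es$EUbb[j, ], 2), unname(ref$EUbb),
                 tolerance = 1e-9)
    expect_equal(drop(es$Eb[j, ]), unname(ref$Eb), tolerance = 1e-9)
  }
})

test_that("the univariate marginal density integrates to one", {
  # one subject, one visit: marginal law is univariate skew-t
  spec <- preset_spec("stlmm")
  params <- list(beta = c(17, 0.5, 0.05, 0.002), sigma2 = 1,
                 D = matrix(c(2.5, 0.15, 0.15, 0.04), 2),
                 lambda = c(3, 1.5), nu = 6)
  one <- validate_cohort(data.frame(subject_id = "s1", sex = "F",
                                    age_years = 10, bmi = 18))
  grid <- seq(2, 60, length.out = 4000)
  dens <- vapply(grid, function(b) {
    one$bmi <- b
    exp(skew_t_marginal_loglik(one, spec, params))
  }, numeric(1))
  expect_equal(sum(dens) * diff(grid)[1], 1, tolerance = 1e-4)
})

test_that("zero skewness and huge df collapse to the Gaussian LMM", {
  co <- make_raw_stratum(n = 120, family = "gaussian", seed = 31)
  glmm <- fit_lmm(co, preset_spec("stlmm"))
  ll_st <- skew_t_marginal_loglik(
    co, preset_spec("stlmm"),
    list(beta = glmm$fit$beta, sigma2 = glmm$fit$sigma2,
         D = glmm$fit$G, lambda = c(0, 0), nu = 1e6))
  expect_equal(ll_st, glmm$fit$loglik, tolerance = 1e-3)
})

test_that("EM increases the log-likelihood monotonically and converges", {
  co <- make_raw_stratum(n = 120, seed = 41)
  fit <- fit_stlmm(co, max_iter = 150, se = FALSE)
  expect_true(fit$fit$monotone)
  expect_true(all(diff(fit$fit$trace) > -1e-6 * abs(fit$fit$trace[-1])))
  expect_true(fit$fit$converged)
  # reported loglik is reproducible from the stored parameters
  ll <- skew_t_marginal_loglik(
    co, preset_spec("stlmm"),
    list(beta = fit$fit$beta, sigma2 = fit$fit$sigma2,
         D = fit$fit$D, lambda = fit$fit$lambda, nu = fit$fit$nu))
  expect_equal(ll, fit$fit$loglik, tolerance = 1e-8)
})

test_that("EM is deterministic given data and initialization", {
  co <- make_raw_stratum(n = 60, seed = 51)
  f1 <- fit_stlmm(co, max_iter = 40, se = FALSE)
  f2 <- fit_stlmm(co, max_iter = 40, se = FALSE)
  expect_identical(f1$fit$trace, f2$fit$trace)
  expect_identical(f1$fit$lambda, f2$fit$lambda)
})

test_that("Gaussian data drive the skewness estimate towards zero", {
  co <- make_raw_stratum(n = 150, family = "gaussian", seed = 61)
  fit <- fit_stlmm(co, max_iter = 250, se = FALSE)
  glmm <- fit_lmm(co, preset_spec("stlmm"))
  # fitted loglik within a couple of units of the Gaussian fit
  expect_lt(abs(fit$fit$loglik - glmm$fit$loglik), 2.5)
  # no spurious strong skewness
  expect_lt(max(abs(fit$fit$lambda)), 2)
})

test_that("skew-t quantile and residual constructions are coherent", {
  # lambda = 0 and large nu reproduce the Gaussian QQ construction
  p <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  expect_equal(qskewt(p, alpha = 0, nu = 1e5), qnorm(p), tolerance = 1e-2)
  # density integrates to 1 and matches the quantile inversion
  expect_equal(integrate(dskewt, -Inf, Inf, alpha = 2, nu = 8)$value, 1,
               tolerance = 1e-6)
  med <- qskewt(0.5, alpha = 2, nu = 8)
  expect_equal(integrate(dskewt, -Inf, med, alpha = 2, nu = 8)$value, 0.5,
               tolerance = 1e-3)

  co <- make_raw_stratum(n = 80, seed = 71)
  fit <- fit_stlmm(co, max_iter = 60, se = FALSE)
  qq <- stlmm_standardized_residuals(fit)
  expect_equal(nrow(qq), fit$fit$n_obs)
  expect_false(is.unsorted(qq$sample))
  expect_false(is.unsorted(qq$theoretical))
  # median of the theoretical quantiles is the fitted law's median
  Zd <- drop(fit$Z %*% fit$fit$Delta)
  psi <- pmax(rowSums((fit$Z %*% fit$fit$D) * fit$Z) + fit$fit$sigma2 -
                Zd^2, 1e-10)
  alpha_bar <- mean(Zd / sqrt(psi))
  expect_equal(median(qq$theoretical),
               qskewt(0.5, alpha_bar, fit$fit$nu), tolerance = 1e-2)
})
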