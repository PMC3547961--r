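test_that("full attendance with no jitter gives every wave at its mean age", {
  cfg <- sim_config(n_male = 3, n_female = 2,
                    attendance = rep(1, 8),
                    age_jitter_sd = rep(0, 8), seed = 1)
  s <- simulate_schedule(cfg)
  expect_equal(nrow(s), 5 * 8)
  expect_equal(sort(unique(s$age_years)), sort(cfg$wave_ages))
  expect_error(sim_config(attendance = rep(0, 8)), "all-zero")
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_male = 30, n_female = 30, seed = 11)
  expect_identical(simulate_schedule(cfg), simulate_schedule(cfg))
  ids <- sprintf("s%02d", 1:40)
  expect_identical(simulate_genotypes(ids, seed = 3),
                   simulate_genotypes(ids, seed = 3))
  sc1 <- make_scenario("allele_score", sim_config(n_male = 20, n_female = 20,
                                                  seed = 5))
  sc2 <- make_scenario("allele_score", sim_config(n_male = 20, n_female = 20,
                                                  seed = 5))
  expect_identical(sc1$cohort$bmi, sc2$cohort$bmi)
})

test_that("genotype dosages follow Hardy-Weinberg at the panel frequencies", {
  n <- 10000
  g <- simulate_genotypes(sprintf("s%05d", 1:n), seed = 17)
  # FTO risk-allele frequency 0.41 (risk allele is the minor allele):
  # expected genotype frequencies 0.348 / 0.484 / 0.168
  tab <- tabulate(g$FTO + 1L, 3) / n
  expect_equal(tab, c(0.3481, 0.4838, 0.1681), tolerance = 0.035)
  # mean dosage at frequency ~0.5 is ~1 within 3 Monte-Carlo SDs
  half <- snp_info("HALF", "A", 0.5)
  gh <- simulate_genotypes(sprintf("s%05d", 1:n), half, seed = 2)
  mc_sd <- sqrt(2 * 0.5 * 0.5 / n)
  expect_lt(abs(mean(gh$HALF) - 1), 3 * mc_sd)
  # a vanishing frequency gives (almost surely) all-zero dosages
  rare <- snp_info("RARE", "A", 1e-8)
  gr <- simulate_genotypes(sprintf("s%04d", 1:1000), rare, seed = 2)
  expect_true(all(gr$RARE == 0))
})

test_that("noise-free simulation reproduces the deterministic curve", {
  cfg <- sim_config(n_male = 0, n_female = 10, attendance = rep(1, 8),
                    age_jitter_sd = rep(0, 8), seed = 3)
  skel <- simulate_schedule(cfg)
  tp <- true_params("female", sigma = 1e-9,
                    G = matrix(0, 3, 3))
  co <- simulate_bmi(skel, tp, seed = 4)
  expected <- exp(drop(build_basis(tp$fixed_basis, co$age_years) %*% tp$beta))
  expect_equal(co$bmi, expected, tolerance = 1e-6)
})

test_that("default sex curves show the adiposity rebound analytically", {
  for (sx in c("female", "male")) {
    tp <- true_params(sx)
    b <- tp$beta
    dcurve <- function(t) {
      b[2] + 2 * b[3] * t + 3 * b[4] * t^2 + 3 * b[5] * pmax(t - 2, 0)^2 +
        3 * b[6] * pmax(t - 8, 0)^2 + 3 * b[7] * pmax(t - 12, 0)^2
    }
    expect_true(all(dcurve(seq(2, 4.2, by = 0.05)) < 0))   # falling
    expect_true(all(dcurve(seq(6.6, 17, by = 0.05)) > 0))  # rising
    g <- seq(2, 10, by = 0.01)
    min_age <- g[which.min(cumsum(dcurve(g)))]
    expect_gt(min_age, 4)
    expect_lt(min_age, 7)
  }
})

test_that("skew-t error family produces positively skewed residuals", {
  cfg <- sim_config(n_male = 0, n_female = 5000,
                    wave_ages = 8, attendance = 1, age_jitter_sd = 0,
                    seed = 9)
  skel <- simulate_schedule(cfg)
  tp <- true_params("female", response = "raw",
                    fixed_basis = basis_spec("polynomial", degree = 0),
                    random_basis = basis_spec("polynomial", degree = 0),
                    beta = 17, G = matrix(0.25), sigma = 0.5,
                    error_family = "skew_t", nu = 8, lambda = 4)
  co <- simulate_bmi(skel, tp, seed = 10)
  r <- co$bmi - mean(co$bmi)
  skew <- mean(r^3) / sd(r)^3
  expect_gt(skew, 0.3)
  # random effects are centred: mean response close to the fixed curve
  expect_lt(abs(mean(co$bmi) - 17), 0.05)
})

test_that("simulated random effects reproduce G increasingly well with n", {
  frob <- function(n) {
    cfg <- sim_config(n_male = 0, n_female = n, attendance = rep(1, 8),
                      age_jitter_sd = rep(0, 8), seed = 31)
    skel <- simulate_schedule(cfg)
    tp <- true_params("female", sigma = 1e-6)
    co <- simulate_bmi(skel, tp, seed = 32)
    # recover each subject's random effects by per-subject OLS (noise-free)
    Xf <- build_basis(tp$fixed_basis, co$age_years)
    Z <- build_basis(tp$random_basis, co$age_years)
    resid <- log(co$bmi) - drop(Xf %*% tp$beta)
    bs <- t(vapply(split(seq_len(nrow(co)), co$subject_id), function(ii) {
      qr.solve(Z[ii, , drop = FALSE], resid[ii])
    }, numeric(3)))
    sqrt(sum((cov(bs) - tp$G)^2)) / sqrt(sum(tp$G^2))
  }
  err_small <- frob(300)
  err_big <- frob(4000)
  expect_lt(err_big, err_small)
  expect_lt(err_big, 0.15)
})

test_that("bundled scenarios carry the advertised genetic truths", {
  nul <- make_scenario("null", sim_config(n_male = 10, n_female = 10,
                                          seed = 2))
  expect_true(all(nul$truth$female$score_effects == 0))
  expect_null(nul$truth$female$snp_effects)

  sc <- make_scenario("allele_score", sim_config(n_male = 10, n_female = 10,
                                                 seed = 2))
  expect_equal(unname(sc$truth$female$score_effects["level"]), 0.0049)
  expect_equal(unname(sc$truth$female$score_effects["slope"]), 0.0012)
  expect_equal(unname(sc$truth$male$score_effects["level"]), 0.0071)

  ss <- make_scenario("single_snp", sim_config(n_male = 10, n_female = 10,
                                               seed = 2))
  expect_equal(nrow(ss$truth$female$snp_effects), 1)
  expect_equal(ss$truth$female$snp_effects$snp_id, "FTO")
  expect_error(make_scenario("unknown"))
})

test_that("allele score distribution matches the published quartiles", {
  g <- simulate_genotypes(sprintf("s%05d", 1:20000), seed = 3)
  sc <- compute_allele_score(g)
  q <- unname(quantile(sc, c(0.25, 0.5, 0.75)))
  expect_equal(q, c(15, 17, 18), tolerance = 0.5)
})
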