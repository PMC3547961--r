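#' Synthetic cohort generator
#'
#' Generates cohorts with the statistical structure the growth-curve analyses
#' assume: eight visit waves with realistic attendance and age jitter,
#' sex-specific mean BMI curves with an adiposity rebound near age 5--6,
#' subject-level random effects, optionally heavy-tailed or skewed errors with
#' CAR(1) serial correlation, Hardy-Weinberg genotypes at a 17-SNP obesity
#' panel, and injected SNP/allele-score effects on trajectory level and slope.
#' Every generator is deterministic given its seed.
#'
#' @name synthetic-cohort
NULL

#' The 17-SNP obesity risk panel
#'
#' SNP labels, arbitrary risk-allele letters, minor-allele frequencies and
#' risk-allele orientation for the 16-gene / 17-variant adult-obesity panel
#' (BDNF contributes two variants). MAFs for FTO (0.41), MC4R (0.23), NEGR1
#' (0.38) and BDNF_1 (0.21) follow the emulated cohort; the remainder, and
#' the major/minor orientation of each risk allele, are literature-typical
#' calibration constants for this panel, not claims about any particular
#' sample. With this orientation the unweighted 17-locus risk-allele score
#' has mean about 16.7 and quartiles near 15 / 17 / 18.
#'
#' @return A [snp_info()] data frame with 17 rows.
#' @export
obesity_snp_panel <- function() {
  snp_info(
    snp_id = c("FTO", "MC4R", "TMEM18", "GNPDA2", "KCTD15", "NEGR1",
               "BDNF_1", "BDNF_2", "ETV5", "SEC16B", "LYPLAL1", "TFAP2B",
               "MTCH2", "BCDIN3D", "NRXN3", "SH2B1", "MRSA"),
    risk_allele = c("A", "C", "C", "G", "A", "A", "T", "T", "C", "C", "G",
                    "G", "G", "A", "G", "A", "C"),
    maf = c(0.41, 0.23, 0.17, 0.43, 0.33, 0.38,
            0.21, 0.28, 0.21, 0.19, 0.30, 0.18,
            0.34, 0.38, 0.21, 0.40, 0.28),
    risk_is_minor = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE,
                      FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                      TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' Simulation configuration
#'
#' Defaults emulate an eight-wave pregnancy cohort: 773 male and 733 female
#' subjects, wave mean ages 1.16, 2.18, 3.11, 5.92, 8.10, 10.60, 14.07 and
#' 17.05 years, per-wave attendance probabilities equal to the observed wave
#' sample fractions (giving a median of 6 visits per subject, IQR 5--7), and
#' per-wave age-jitter standard deviations of 0.10--0.35 years.
#'
#' @param n_male,n_female Subjects per sex.
#' @param wave_ages Mean age (years) of each visit wave.
#' @param attendance Per-wave attendance probability in `[0, 1]`.
#' @param age_jitter_sd Per-wave SD (years) of the Gaussian age jitter.
#' @param seed Integer seed recorded in the output metadata.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_male = 773, n_female = 733,
                       wave_ages = c(1.16, 2.18, 3.11, 5.92, 8.10, 10.60,
                                     14.07, 17.05),
                       attendance = c(1375, 402, 994, 1324, 1320, 1274,
                                      1276, 1021) / 1506,
                       age_jitter_sd = c(0.10, 0.14, 0.12, 0.18, 0.35, 0.18,
                                         0.20, 0.25),
                       seed = 1L) {
  stopifnot(length(wave_ages) >= 1,
            length(attendance) == length(wave_ages),
            length(age_jitter_sd) == length(wave_ages))
  if (any(attendance < 0 | attendance > 1)) {
    stop("attendance probabilities must lie in [0, 1]")
  }
  if (all(attendance == 0)) stop("all-zero attendance: no visits possible")
  structure(list(n_male = n_male, n_female = n_female, wave_ages = wave_ages,
                 attendance = attendance, age_jitter_sd = age_jitter_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' True generative parameters for one sex stratum
#'
#' Houses the fixed-effect curve, random-effect covariance, residual
#' structure and genetic effect sizes that [simulate_bmi()] realizes. The
#' default mean-curve coefficients are calibration constants fitted once to
#' the emulated cohort's per-sex wave BMI means on the cubic truncated-power
#' basis with knots at 2, 8 and 12 years; they place the adiposity rebound at
#' 5.1 years (female) and 5.4 years (male).
#'
#' @param sex `"female"` or `"male"` (selects the default mean curve).
#' @param response `"ln"` or `"raw"` scale for the linear predictor.
#' @param fixed_basis,random_basis [basis_spec()]s naming the design bases.
#' @param beta Fixed-effect coefficients on `fixed_basis` (defaults to the
#'   calibrated sex curve).
#' @param G Random-effect covariance matrix (PSD) on `random_basis` columns.
#' @param sigma Residual SD on the response scale.
#' @param phi CAR(1) correlation at a one-year gap, in `[0, 1)`.
#' @param error_family `"gaussian"`, `"t"` or `"skew_t"`.
#' @param nu Degrees of freedom (> 2) for the t families.
#' @param lambda Skewness vector (one entry per random-effect column) for
#'   `"skew_t"`.
#' @param score_effects Per-allele effects of the allele score:
#'   `c(level =, slope =)` on the response scale (slope per centred-age year).
#' @param snp_effects Optional data frame `snp_id`, `level`, `slope` of
#'   per-allele effects for individual SNPs.
#' @param center Centring constant used for genetic age interactions.
#' @return List of class `true_params`.
#' @export
true_params <- function(sex = c("female", "male"), response = "ln",
                        fixed_basis = basis_spec("truncated_power",
                                                 degree = 3,
                                                 knots = c(2, 8, 12)),
                        random_basis = basis_spec("polynomial", degree = 2,
                                                  center = 8,
                                                  scale_quadratic = TRUE),
                        beta = NULL, G = NULL, sigma = 0.05, phi = 0,
                        error_family = c("gaussian", "t", "skew_t"),
                        nu = 8, lambda = NULL,
                        score_effects = c(level = 0, slope = 0),
                        snp_effects = NULL, center = 8) {
  sex <- match.arg(sex)
  error_family <- match.arg(error_family)
  if (is.null(beta)) {
    beta <- if (sex == "female") {
      c(2.83743764, 0.00279821, -0.01736825, 0.00342761,
        -0.00321669, -0.00116517, 0.00115964)
    } else {
      c(2.89330947, -0.02671004, -0.00779817, 0.00199882,
        -0.00184972, -0.00109143, 0.00128122)
    }
  }
  if (is.null(G)) {
    sds <- c(0.10, 0.010, 0.0015)
    R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
    G <- diag(sds) %*% R %*% diag(sds)
  }
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("G must be positive semi-definite")
  if (sigma <= 0) stop("sigma must be positive")
  if (error_family != "gaussian" && nu <= 2) stop("nu must exceed 2")
  if (error_family == "skew_t") {
    if (is.null(lambda)) lambda <- rep(0, nrow(G))
    if (length(lambda) != nrow(G)) {
      stop("lambda must have one entry per random-effect column")
    }
  }
  structure(list(sex = sex, response = response, fixed_basis = fixed_basis,
                 random_basis = random_basis, beta = beta, G = G,
                 sigma = sigma, phi = phi, error_family = error_family,
                 nu = nu, lambda = lambda, score_effects = score_effects,
                 snp_effects = snp_effects, center = center),
            class = "true_params")
}

#' Simulate the visit schedule (no BMI yet)
#'
#' Each subject attends each wave independently with the configured
#' probability; a subject drawing zero waves is redrawn so everyone has at
#' least one visit. Attended visit ages are the wave means plus Gaussian
#' jitter, truncated below at 0.25 years.
#'
#' @param config A [sim_config()].
#' @return Data frame `subject_id`, `sex`, `age_years` sorted by subject and
#'   age, with the config stored in `attr(, "config")`.
#' @export
simulate_schedule <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_male + config$n_female
  sexes <- rep(c("male", "female"), c(config$n_male, config$n_female))
  ids <- sprintf("S%04d", seq_len(n))
  W <- length(config$wave_ages)
  att <- matrix(stats::runif(n * W), n, W) <
    matrix(config$attendance, n, W, byrow = TRUE)
  empty <- which(rowSums(att) == 0)
  while (length(empty)) {  # everyone attends at least one wave
    att[empty, ] <- matrix(stats::runif(length(empty) * W),
                           length(empty), W) <
      matrix(config$attendance, length(empty), W, byrow = TRUE)
    empty <- empty[rowSums(att[empty, , drop = FALSE]) == 0]
  }
  jit <- matrix(stats::rnorm(n * W), n, W) *
    matrix(config$age_jitter_sd, n, W, byrow = TRUE)
  ages_mat <- matrix(config$wave_ages, n, W, byrow = TRUE) + jit
  keep <- which(t(att))  # row-major order: subject blocks contiguous
  subj_row <- rep(seq_len(n), each = W)[keep]
  out <- data.frame(subject_id = ids[subj_row], sex = sexes[subj_row],
                    age_years = pmax(t(ages_mat)[keep], 0.25),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$age_years), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  out
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Independent biallelic loci; each risk-allele dosage is Binomial(2, p) for
#' risk-allele frequency `p` (`maf` or `1 - maf` per the panel's
#' orientation), i.e. genotype frequencies `(1-p)^2, 2p(1-p), p^2`.
#'
#' @param subject_ids Character vector of subjects.
#' @param snps A [snp_info()] table.
#' @param seed Integer seed.
#' @return Genotype table: `subject_id` plus one 0/1/2 column per SNP.
#' @export
simulate_genotypes <- function(subject_ids, snps = obesity_snp_panel(),
                               seed = 1L) {
  set.seed(seed)
  out <- data.frame(subject_id = as.character(subject_ids),
                    stringsAsFactors = FALSE)
  p <- if ("risk_freq" %in% names(snps)) snps$risk_freq else snps$maf
  for (i in seq_len(nrow(snps))) {
    out[[snps$snp_id[i]]] <- stats::rbinom(length(subject_ids), 2L, p[i])
  }
  out
}

# mean of a half-t variate |N(0,1)|/sqrt(U), U ~ Gamma(nu/2, nu/2); used to
# centre skew random effects so their marginal mean is zero (needs nu > 1)
.half_t_mean <- function(nu) {
  sqrt(nu / pi) * exp(lgamma((nu - 1) / 2) - lgamma(nu / 2))
}

.mat_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate BMI values onto a visit schedule
#'
#' Realizes `y = X beta + Z b + e` on the declared response scale, adds
#' genetic effects (allele score and/or per-SNP) to the linear predictor, and
#' exponentiates when the scale is `ln`. Under `error_family = "skew_t"` the
#' random effects follow the skew-normal/Gamma stochastic representation
#' (scale matrix `G`, skewness `lambda`) and the errors are multivariate-t
#' with the same subject-level mixing variable, so the marginal response is
#' skew-t; random effects are location-shifted to have marginal mean zero.
#' CAR(1) serial correlation is generated exactly from the joint covariance
#' `sigma^2 phi^|age gap|` by per-subject Cholesky factorization (visit ages
#' are irregular, so no AR recursion is used).
#'
#' @param skeleton Schedule from [simulate_schedule()] (one sex or both; the
#'   per-sex `params` is applied by matching `sex`).
#' @param params A [true_params()] or a named list
#'   `list(male =, female =)`.
#' @param genotypes Optional genotype table; required when `params` carries
#'   nonzero genetic effects.
#' @param seed Integer seed.
#' @return A validated `cohort` with the truth recorded in
#'   `attr(, "truth")`.
#' @export
simulate_bmi <- function(skeleton, params, genotypes = NULL, seed = 1L) {
  if (inherits(params, "true_params")) {
    pl <- list(male = params, female = params)
  } else {
    pl <- params
  }
  set.seed(seed)
  skeleton <- skeleton[order(skeleton$subject_id, skeleton$age_years), ,
                       drop = FALSE]
  bmi <- numeric(nrow(skeleton))
  score <- NULL
  for (sx in intersect(c("male", "female"), unique(skeleton$sex))) {
    p <- pl[[sx]]
    idx <- which(skeleton$sex == sx)
    ages <- skeleton$age_years[idx]
    sub <- skeleton$subject_id[idx]
    X <- build_basis(p$fixed_basis, ages)
    Z <- build_basis(p$random_basis, ages)
    eta <- drop(X %*% p$beta)
    a <- center_age(ages, p$center)
    if (any(p$score_effects != 0) || !is.null(p$snp_effects)) {
      if (is.null(genotypes)) stop("genetic effects requested without genotypes")
      gm <- genotypes[match(sub, genotypes$subject_id), , drop = FALSE]
      if (any(p$score_effects != 0)) {
        sc <- rowSums(gm[, setdiff(names(gm), "subject_id"), drop = FALSE])
        eta <- eta + sc * (p$score_effects[["level"]] +
                             p$score_effects[["slope"]] * a)
      }
      if (!is.null(p$snp_effects)) {
        for (r in seq_len(nrow(p$snp_effects))) {
          d <- gm[[p$snp_effects$snp_id[r]]]
          eta <- eta + d * (p$snp_effects$level[r] +
                              p$snp_effects$slope[r] * a)
        }
      }
    }
    q <- ncol(Z)
    usub <- unique(sub)
    nsub <- length(usub)
    # subject-level random effects
    if (p$error_family == "gaussian") {
      b <- matrix(stats::rnorm(nsub * q), nsub) %*% .mat_sqrt(p$G)
      u_mix <- rep(1, nsub)
    } else if (p$error_family == "t") {
      u_mix <- stats::rgamma(nsub, p$nu / 2, p$nu / 2)
      b <- (matrix(stats::rnorm(nsub * q), nsub) %*%
              .mat_sqrt(p$G)) / sqrt(u_mix)
    } else {
      delta <- p$lambda / sqrt(1 + sum(p$lambda^2))
      Dhalf <- .mat_sqrt(p$G)
      Delta <- drop(Dhalf %*% delta)
      Gamma <- p$G - tcrossprod(Delta)
      u_mix <- stats::rgamma(nsub, p$nu / 2, p$nu / 2)
      tvar <- abs(stats::rnorm(nsub)) / sqrt(u_mix)
      b <- outer(tvar - .half_t_mean(p$nu), Delta) +
        (matrix(stats::rnorm(nsub * q), nsub) %*%
           .mat_sqrt(Gamma)) / sqrt(u_mix)
    }
    rownames(b) <- usub
    # residuals: exact joint CAR(1) covariance per subject (independent
    # errors take the vectorized path)
    row_of <- match(sub, usub)
    if (p$phi == 0) {
      e <- stats::rnorm(length(idx), 0, p$sigma)
      if (p$error_family != "gaussian") e <- e / sqrt(u_mix[row_of])
    } else {
      e <- numeric(length(idx))
      pos <- split(seq_along(idx), factor(sub, levels = usub))
      for (j in seq_len(nsub)) {
        ii <- pos[[j]]
        C <- car1_correlation(ages[ii], p$phi)
        ej <- drop(stats::rnorm(length(ii)) %*% chol(p$sigma^2 * C))
        if (p$error_family != "gaussian") ej <- ej / sqrt(u_mix[j])
        e[ii] <- ej
      }
    }
    eta <- eta + rowSums(Z * b[sub, , drop = FALSE]) + e
    bmi[idx] <- if (p$response == "ln") exp(eta) else eta
  }
  out <- data.frame(subject_id = skeleton$subject_id, sex = skeleton$sex,
                    age_years = skeleton$age_years, bmi = bmi,
                    stringsAsFactors = FALSE)
  out <- validate_cohort(out)
  attr(out, "truth") <- pl
  attr(out, "seed") <- seed
  out
}

#' Bundled simulation scenarios
#'
#' `"null"` has all genetic effects exactly zero; `"allele_score"` injects
#' per-allele effects on trajectory level and linear slope of the magnitude
#' the association analyses are powered for (ln-scale level 0.0049 and slope
#' 0.0012 per allele in females, 0.0071 and 0.0008 in males);
#' `"single_snp"` gives FTO alone a level effect of 0.010 ln-units and slope
#' 0.0012 per risk allele.
#'
#' @param name Scenario name.
#' @param config A [sim_config()] (its seed drives all randomness).
#' @param error_family,phi Passed to [true_params()] for both sexes.
#' @param overrides Named list of [true_params()] arguments applied to both
#'   sexes after the scenario defaults.
#' @return List with `cohort`, `genotypes`, `truth` (per-sex
#'   [true_params()]), `config`.
#' @export
make_scenario <- function(name = c("null", "single_snp", "allele_score"),
                          config = sim_config(),
                          error_family = "gaussian", phi = 0,
                          overrides = list()) {
  name <- match.arg(name)
  skel <- simulate_schedule(config)
  genotypes <- simulate_genotypes(unique(skel$subject_id),
                                  seed = config$seed + 1000L)
  mk <- function(sx) {
    args <- list(sex = sx, error_family = error_family, phi = phi)
    if (name == "allele_score") {
      args$score_effects <- if (sx == "female") {
        c(level = 0.0049, slope = 0.0012)
      } else {
        c(level = 0.0071, slope = 0.0008)
      }
    } else if (name == "single_snp") {
      args$snp_effects <- data.frame(snp_id = "FTO", level = 0.010,
                                     slope = 0.0012)
    }
    do.call(true_params, utils::modifyList(args, overrides))
  }
  truth <- list(male = mk("male"), female = mk("female"))
  cohort <- simulate_bmi(skel, truth, genotypes, seed = config$seed + 2000L)
  list(cohort = cohort, genotypes = genotypes, truth = truth,
       config = config)
}
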