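#' Genetic trajectory association
#'
#' Obesity-risk-allele-score construction and sex-stratified association of
#' SNP dosages or the score with BMI trajectory: the genetic main effect plus
#' centred-age interaction terms (up to cubic) are added to a growth model's
#' fixed design and tested jointly against the genetics-free nested model by
#' a global likelihood-ratio test. For the SITAR model, per-subject
#' size/tempo/velocity estimates are regressed on dosage instead (three tests
#' per SNP). No multiple-testing adjustment is applied by default.
#'
#' @name gene-assoc
NULL

#' Unweighted obesity-risk-allele score
#'
#' Sum of risk-allele dosages over the panel loci; subjects missing any locus
#' are excluded (complete case), so the score is always an integer in
#' `[0, 2L]` for `L` loci.
#'
#' @param genotypes Genotype table (`subject_id` + dosage columns).
#' @param loci Character vector of locus columns to sum (default: all).
#' @return Named integer vector (subject id -> score) with attribute
#'   `n_loci`.
#' @export
compute_allele_score <- function(genotypes, loci = NULL) {
  if (is.null(loci)) loci <- setdiff(names(genotypes), "subject_id")
  miss <- setdiff(loci, names(genotypes))
  if (length(miss)) {
    stop("locus absent from genotype table: ", paste(miss, collapse = ", "))
  }
  M <- as.matrix(genotypes[, loci, drop = FALSE])
  complete <- stats::complete.cases(M)
  score <- as.integer(rowSums(M[complete, , drop = FALSE]))
  names(score) <- genotypes$subject_id[complete]
  attr(score, "n_loci") <- length(loci)
  score
}

#' Add genetic fixed-effect terms to a model specification
#'
#' Augments the fixed design with `g, g*a, g*a^2, ..., g*a^degree` where `a`
#' is centred age, regardless of whether the base time trend is polynomial or
#' spline (interactions always use the centred polynomial scale, so the
#' per-term estimates are comparable across engines).
#'
#' @param spec A [model_spec()].
#' @param interaction_degree Highest age power interacting with the genetic
#'   covariate (0--3; default 3 gives 4 added columns).
#' @param label Column-name stem for the added terms.
#' @param center Centring constant for the interaction age scale.
#' @return The augmented `model_spec`.
#' @export
add_genetic_terms <- function(spec, interaction_degree = 3L,
                              label = "score", center = 8) {
  stopifnot(inherits(spec, "model_spec"))
  if (!interaction_degree %in% 0:3) {
    stop("interaction_degree must be in 0..3")
  }
  spec$genetic <- list(interaction_degree = as.integer(interaction_degree),
                       label = label, center = center)
  spec
}

#' Global likelihood-ratio association test
#'
#' Fits the genetics-free null model and the model augmented with the genetic
#' main effect and age interactions on the same complete-case rows, and
#' reports per-term Wald summaries plus the global LRT (df = number of added
#' genetic columns).
#'
#' @param data A `cohort` stratum.
#' @param spec Base [model_spec()] without genetic terms.
#' @param g Named per-subject numeric vector (dosage or allele score).
#' @param engine `"lmm"` for the Gaussian engine (covers both the polynomial
#'   and spline models via `spec`) or `"stlmm"` for the skew-t engine.
#' @param interaction_degree Passed to [add_genetic_terms()].
#' @param label Term label for the output.
#' @param ... Passed to the underlying fitter.
#' @return An object of class `assoc_result`: data frame `terms` (estimate,
#'   SE, 95% Wald CI, p), `lrt` list (statistic, df, p_value), the two fits.
#' @export
global_lrt_assoc <- function(data, spec, g, engine = c("lmm", "stlmm"),
                             interaction_degree = 3L, label = "score", ...) {
  engine <- match.arg(engine)
  g <- g[!is.na(g)]
  keep <- data$subject_id %in% names(g)
  dat <- data[keep, , drop = FALSE]
  class(dat) <- class(data)
  spec_full <- add_genetic_terms(spec, interaction_degree, label,
                                 center = if (spec$fixed$kind == "polynomial")
                                   spec$fixed$center else 8)
  fitter <- if (engine == "lmm") fit_lmm else fit_stlmm
  fit_null <- fitter(dat, spec, ...)
  fit_full <- if (engine == "lmm") {
    # the null fit's variance parameters are an excellent start for the full
    # model (identical random structure)
    fitter(dat, spec_full, g = g, start = fit_null$fit$theta, ...)
  } else {
    fitter(dat, spec_full, g = g, ...)
  }
  conv <- isTRUE(fit_null$fit$converged) && isTRUE(fit_full$fit$converged)
  gcols <- paste0(label, c("", "_x_age", "_x_age2",
                           "_x_age3"))[1:(interaction_degree + 1)]
  est <- fit_full$fit$beta[gcols]
  se <- sqrt(diag(fit_full$fit$vcov_beta)[gcols])
  terms <- data.frame(
    term = c("Score", "Score*Age", "Score*Age2",
             "Score*Age3")[1:(interaction_degree + 1)],
    estimate = unname(est), se = unname(se),
    ci_lower = unname(est - 1.96 * se), ci_upper = unname(est + 1.96 * se),
    p_value = unname(2 * stats::pnorm(-abs(est / se))))
  lrt <- if (conv) lrt_nested(fit_full, fit_null) else
    list(statistic = NA_real_, df = interaction_degree + 1L,
         p_value = NA_real_)
  structure(list(terms = terms, lrt = lrt, engine = engine,
                 converged = conv, fit_full = fit_full,
                 fit_null = fit_null, label = label),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result: engine %s, global LRT chi2 = %.3f (df %d), p = %.4g%s>\n",
              x$engine, x$lrt$statistic, x$lrt$df, x$lrt$p_value,
              if (x$converged) "" else "; NOT CONVERGED"))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Regress SITAR subject parameters on a genetic covariate
#'
#' Three ordinary least-squares regressions (size, tempo and velocity on
#' dosage), the per-test counterpart of the trajectory LRT for the nonlinear
#' model.
#'
#' @param subject_params Data frame from [extract_subject_params()].
#' @param g Named per-subject numeric vector.
#' @return Data frame with one row per parameter: slope, SE, p.
#' @export
sitar_param_assoc <- function(subject_params, g) {
  g <- g[!is.na(g)]
  m <- merge(subject_params,
             data.frame(subject_id = names(g), g = unname(g)),
             by = "subject_id")
  if (nrow(m) < 3) stop("fewer than 3 subjects with both parameters and g")
  one <- function(par) {
    fit <- stats::lm(m[[par]] ~ m$g)
    cf <- summary(fit)$coefficients
    data.frame(parameter = par, slope = cf[2, 1], se = cf[2, 2],
               p_value = cf[2, 4])
  }
  out <- do.call(rbind, lapply(c("size", "tempo", "velocity"), one))
  rownames(out) <- NULL
  out
}

#' Per-age genetic effect curve
#'
#' Effect of one additional risk allele on the mean response at each age:
#' `effect(a) = g + g1*a + g2*a^2 + g3*a^3` at centred age `a`, with a
#' delta-method 95% CI from the coefficient covariance. At the centring age
#' the effect equals the main-effect coefficient exactly.
#'
#' @param assoc An `assoc_result` (or a `growth_fit` with genetic terms).
#' @param ages Ages (years) at which to evaluate.
#' @return Data frame `age`, `effect`, `se`, `ci_lower`, `ci_upper`.
#' @export
per_age_effect <- function(assoc, ages) {
  fit <- if (inherits(assoc, "assoc_result")) assoc$fit_full else assoc
  gen <- fit$spec$genetic
  if (is.null(gen)) stop("fit has no genetic terms")
  gcols <- paste0(gen$label, c("", "_x_age", "_x_age2",
                               "_x_age3"))[1:(gen$interaction_degree + 1)]
  beta <- fit$fit$beta[gcols]
  V <- fit$fit$vcov_beta[gcols, gcols, drop = FALSE]
  rng <- range(fit$data$age_years)
  if (any(ages < rng[1] - 0.5 | ages > rng[2] + 0.5)) {
    warning("effect ages outside observed range +/- 0.5 yr")
  }
  a <- center_age(ages, gen$center)
  A <- outer(a, 0:gen$interaction_degree, `^`)
  eff <- drop(A %*% beta)
  se <- sqrt(rowSums((A %*% V) * A))
  data.frame(age = ages, effect = eff, se = se,
             ci_lower = eff - 1.96 * se, ci_upper = eff + 1.96 * se)
}

#' Bonferroni adjustment helper for association p-values
#'
#' Off by default everywhere: the package mirrors an analysis of previously
#' validated loci where no multiplicity adjustment is applied.
#'
#' @param p Vector of p-values.
#' @return Adjusted p-values via [stats::p.adjust()] (method "bonferroni").
#' @export
bonferroni <- function(p) stats::p.adjust(p, method = "bonferroni")
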