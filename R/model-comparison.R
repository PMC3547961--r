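#' Cross-method model comparison
#'
#' The comparison suite used to rank the four growth-curve engines:
#' subject-level R-squared, its distribution over non-parametric cluster
#' (subject-level) bootstrap resamples, squared observed-minus-fitted
#' summaries, detection tallies across a SNP panel, and bootstrap power for a
#' genetic effect. Bootstrap resampling is always by subject, keeping each
#' subject's visits together, as required for longitudinal data.
#'
#' @name model-comparison
NULL

#' Coefficient of determination
#'
#' `1 - SSE/SST` with SST about the observed mean. Fitted values should be
#' subject-level (fixed effects plus predicted random effects), the
#' resolution at which longitudinal fit quality is compared.
#'
#' @param observed,fitted Equal-length numeric vectors on the model's
#'   response scale.
#' @return Scalar R-squared.
#' @export
r_squared <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values have zero variance; R^2 undefined")
  1 - sum((observed - fitted)^2) / sst
}

#' Median and IQR of squared residuals
#'
#' @param observed,fitted As in [r_squared()].
#' @return List `median`, `iqr` (named lower/upper quartiles).
#' @export
squared_error_summary <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted))
  sq <- (observed - fitted)^2
  qs <- stats::quantile(sq, c(0.25, 0.75), names = FALSE)
  list(median = stats::median(sq), iqr = c(lower = qs[1], upper = qs[2]))
}

# Resample subjects with replacement; duplicated subjects get fresh ids so
# the grouping structure stays valid.
.resample_subjects <- function(data) {
  ids <- unique(data$subject_id)
  pick <- sample(ids, length(ids), replace = TRUE)
  pieces <- lapply(seq_along(pick), function(k) {
    d <- data[data$subject_id == pick[k], , drop = FALSE]
    d$subject_id <- sprintf("B%05d", k)
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  attr(out, "source_ids") <- pick
  out
}

#' Bootstrap distribution of R-squared
#'
#' Refits a frozen model specification on `B` subject-level bootstrap
#' resamples and summarizes the per-replicate subject-level R-squared.
#' Non-convergent replicates are excluded and their rate reported; above 20%
#' failures the report is flagged unusable.
#'
#' @param data A `cohort` stratum.
#' @param spec A [model_spec()] (frozen across replicates; knots/df are not
#'   reselected).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param engine `"lmm"` or `"stlmm"`.
#' @param g Optional named genetic covariate if `spec` carries genetic terms.
#' @return List `median`, `iqr`, `replicates` (vector of R-squared values),
#'   `failure_rate`, `usable`.
#' @export
bootstrap_r_squared <- function(data, spec, B = 200, seed = 1L,
                                engine = c("lmm", "stlmm"), g = NULL) {
  engine <- match.arg(engine)
  stopifnot(B >= 1)
  set.seed(seed)
  fitter <- if (engine == "lmm") fit_lmm else fit_stlmm
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    d <- .resample_subjects(data)
    gb <- g
    if (!is.null(g)) {
      src <- attr(d, "source_ids")
      gb <- stats::setNames(unname(g[src]), sprintf("B%05d", seq_along(src)))
    }
    fit <- tryCatch(fitter(d, spec, g = gb), error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit$fit$converged)) {
      reps[b] <- r_squared(fit$y, fit$fit$fitted_subject)
    }
  }
  ok <- !is.na(reps)
  fr <- mean(!ok)
  qs <- stats::quantile(reps[ok], c(0.25, 0.75), names = FALSE)
  list(median = stats::median(reps[ok]),
       iqr = c(lower = qs[1], upper = qs[2]),
       replicates = reps, failure_rate = fr, usable = fr <= 0.2, B = B)
}

#' Tally significant association results
#'
#' Counts results with p below `alpha`. For the LRT engines pass one global
#' p-value per SNP; for the nonlinear model pass all three per-parameter
#' p-values per SNP (so the denominator is `3 * L`).
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha Significance level.
#' @return List `detected`, `tested`.
#' @export
count_significant <- function(p_values, alpha = 0.05) {
  list(detected = sum(p_values < alpha, na.rm = TRUE),
       tested = sum(!is.na(p_values)))
}

#' Bootstrap or Monte-Carlo power for a genetic trajectory effect
#'
#' Fraction of `B` replicate datasets whose global LRT p-value falls below
#' `alpha`, with a binomial 95% CI. Two replicate-generation modes:
#'
#' * `"resample"` -- non-parametric subject-level bootstrap of the supplied
#'   stratum (the post-hoc power construction). Note that the resampled LRT
#'   statistic is approximately noncentral chi-square at the *observed*
#'   statistic, so with zero true effect this estimate tracks the realized
#'   sample association rather than the nominal test size.
#' * `"simulate"` -- Monte-Carlo power from the known generative truth: each
#'   replicate regenerates the responses on the same visit skeleton via
#'   [simulate_bmi()]. Requires `truth` (and `genotypes` when the truth
#'   carries genetic effects). With zero injected effect this estimate
#'   coincides with the test size.
#'
#' @param data A `cohort` stratum.
#' @param spec Base [model_spec()] without genetic terms.
#' @param g Named per-subject genetic covariate.
#' @param B Number of replicates.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param engine `"lmm"` or `"stlmm"`.
#' @param interaction_degree Passed to [add_genetic_terms()].
#' @param mode `"resample"` or `"simulate"`.
#' @param truth A [true_params()] for `mode = "simulate"` (defaults to the
#'   `truth` attribute stored by [simulate_bmi()], matched by stratum sex).
#' @param genotypes Genotype table for `mode = "simulate"`.
#' @return List `power`, `ci`, `n_effective`, `failure_rate`, `mode`.
#' @export
power_bootstrap <- function(data, spec, g, B = 200, alpha = 0.05, seed = 1L,
                            engine = c("lmm", "stlmm"),
                            interaction_degree = 3L,
                            mode = c("resample", "simulate"),
                            truth = NULL, genotypes = NULL) {
  engine <- match.arg(engine)
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "simulate" && is.null(truth)) {
    tr <- attr(data, "truth")
    if (is.null(tr)) stop("mode = 'simulate' requires the generative truth")
    truth <- if (inherits(tr, "true_params")) tr else tr[[data$sex[1]]]
  }
  skel <- data[, c("subject_id", "sex", "age_years")]
  hit <- rep(NA, B)
  for (b in seq_len(B)) {
    if (mode == "resample") {
      d <- .resample_subjects(data)
      src <- attr(d, "source_ids")
      gb <- stats::setNames(unname(g[src]), sprintf("B%05d", seq_along(src)))
      gb <- gb[!is.na(gb)]
    } else {
      d <- simulate_bmi(skel, truth, genotypes,
                        seed = seed * 1000L + b)
      gb <- g
    }
    res <- tryCatch(
      global_lrt_assoc(d, spec, gb, engine = engine,
                       interaction_degree = interaction_degree),
      error = function(e) NULL)
    if (!is.null(res) && res$converged) hit[b] <- res$lrt$p_value < alpha
  }
  ok <- !is.na(hit)
  k <- sum(hit[ok]); m <- sum(ok)
  ci <- stats::binom.test(k, m)$conf.int
  list(power = k / m, ci = c(lower = ci[1], upper = ci[2]),
       n_effective = m, failure_rate = mean(!ok), mode = mode)
}

#' One-line fit summary for the comparison table
#'
#' @param fit A `growth_fit`, `stlmm_fit` or `sitar_fit`.
#' @param method Label for the row.
#' @return Data frame row: R-squared, squared-error median and IQR, logLik,
#'   AIC.
#' @export
comparison_row <- function(fit, method = class(fit)[1]) {
  obs <- fit$y
  pred <- fit$fit$fitted_subject
  se <- squared_error_summary(obs, pred)
  scale <- if (inherits(fit, "sitar_fit")) "ln" else fit$spec$response
  data.frame(method = method, response_scale = scale,
             r_squared = r_squared(obs, pred),
             sq_err_median = se$median,
             sq_err_q1 = unname(se$iqr["lower"]),
             sq_err_q3 = unname(se$iqr["upper"]),
             loglik = fit$fit$loglik, aic = fit$fit$aic)
}
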