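#' Gaussian linear mixed growth models
#'
#' Maximum-likelihood estimation of linear mixed models for longitudinal BMI,
#' covering both the polynomial growth-curve model (with optional CAR(1)
#' within-subject correlation) and the semi-parametric truncated-power spline
#' model as two basis configurations of the same engine. Fixed effects and the
#' residual variance are profiled out by generalized least squares; the
#' optimizer searches only the scaled random-effect covariance (log-Cholesky
#' parameterization) and, when present, the CAR(1) parameter on a logit scale,
#' so the problem is smooth and unconstrained.
#'
#' @name gaussian-lmm
NULL

#' Model specification for the linear mixed growth models
#'
#' @param response `"ln"` (model `ln(BMI)`) or `"raw"` (model BMI).
#' @param fixed A [basis_spec()] for the fixed-effect time trend.
#' @param random A [basis_spec()] for the random-effect design (columns are
#'   functions of age only).
#' @param correlation `"independent"` or `"car1"` within-subject residual
#'   correlation; CAR(1) distance is measured in raw years of age.
#' @param genetic Optional genetic-term descriptor from
#'   [add_genetic_terms()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response = c("ln", "raw"),
                       fixed = basis_spec("polynomial", degree = 3),
                       random = basis_spec("polynomial", degree = 2),
                       correlation = c("independent", "car1"),
                       genetic = NULL) {
  response <- match.arg(response)
  correlation <- match.arg(correlation)
  stopifnot(inherits(fixed, "basis_spec"), inherits(random, "basis_spec"))
  structure(list(response = response, fixed = fixed, random = random,
                 correlation = correlation, genetic = genetic),
            class = "model_spec")
}

#' Shipped model presets
#'
#' The selected specifications for the polynomial mixed model (`"lmm"`:
#' ln(BMI), cubic fixed and quadratic random polynomials of centred age,
#' CAR(1) correlation) and the semi-parametric spline model (`"splmm"`:
#' ln(BMI), cubic truncated-power fixed spline with knots at 2, 8 and 12
#' years, random `1 + age + 0.5*age^2`, independent residuals). The same
#' specification applies to both sexes.
#'
#' @param method `"lmm"`, `"splmm"` or `"stlmm"` (the skew-t model: raw-scale
#'   BMI, cubic polynomial fixed trend, random intercept + linear age,
#'   independent residuals).
#' @param center Age-centring constant in years for polynomial terms.
#' @return A [model_spec()].
#' @export
preset_spec <- function(method = c("lmm", "splmm", "stlmm"), center = 8) {
  method <- match.arg(method)
  if (method == "lmm") {
    model_spec("ln",
               fixed = basis_spec("polynomial", degree = 3, center = center),
               random = basis_spec("polynomial", degree = 2, center = center),
               correlation = "car1")
  } else if (method == "stlmm") {
    model_spec("raw",
               fixed = basis_spec("polynomial", degree = 3, center = center),
               random = basis_spec("polynomial", degree = 1, center = center),
               correlation = "independent")
  } else {
    model_spec("ln",
               fixed = basis_spec("truncated_power", degree = 3,
                                  knots = c(2, 8, 12)),
               random = basis_spec("polynomial", degree = 2, center = center,
                                   scale_quadratic = TRUE),
               correlation = "independent")
  }
}

# Assemble response/design matrices for a cohort under a model_spec.
# g: optional named per-subject numeric vector (dosage or allele score);
# subjects without a value are dropped (complete case).
.assemble <- function(data, spec, g = NULL) {
  stopifnot(inherits(data, "cohort") || is.data.frame(data))
  df <- data[order(data$subject_id, data$age_years), , drop = FALSE]
  if (!is.null(g)) {
    keep <- df$subject_id %in% names(g)[!is.na(g)]
    df <- df[keep, , drop = FALSE]
  }
  y <- if (spec$response == "ln") log(df$bmi) else df$bmi
  if (spec$fixed$kind == "truncated_power" && length(spec$fixed$knots) &&
      (min(spec$fixed$knots) < min(df$age_years) ||
         max(spec$fixed$knots) >= max(df$age_years))) {
    warning("spline knot outside the observed age range; ",
            "its column may be all zero")
  }
  X <- build_basis(spec$fixed, df$age_years)
  if (!is.null(spec$genetic)) {
    if (is.null(g)) stop("spec has genetic terms but no g supplied")
    gv <- unname(g[df$subject_id])
    if (stats::var(gv) == 0) {
      stop("genetic covariate is constant; columns would be collinear")
    }
    a <- center_age(df$age_years, spec$genetic$center)
    deg <- spec$genetic$interaction_degree
    Gm <- outer(a, 0:deg, `^`) * gv
    colnames(Gm) <- paste0(spec$genetic$label,
                           c("", "_x_age", "_x_age2", "_x_age3")[1:(deg + 1)])
    X <- cbind(X, Gm)
  }
  Z <- build_basis(spec$random, df$age_years)
  sub <- factor(df$subject_id, levels = unique(df$subject_id))
  len <- as.integer(table(sub))
  start <- cumsum(c(0L, len[-length(len)]))
  list(df = df, y = y, X = X, Z = Z,
       subjects = levels(sub), sub_start = start, sub_len = len,
       ages = df$age_years)
}

# Negative profiled log-likelihood at unconstrained parameters theta.
# theta = log-Cholesky of Gstar (diagonal on log scale) [+ logit phi].
.theta_to_cov <- function(theta, q, car1) {
  nG <- q * (q + 1) / 2
  L <- matrix(0, q, q)
  L[lower.tri(L, diag = TRUE)] <- theta[seq_len(nG)]
  diag(L) <- exp(diag(L))
  phi <- if (car1) stats::plogis(theta[nG + 1]) else 0
  list(Gstar = L %*% t(L), phi = phi)
}

.profiled_nll <- function(theta, asm, car1) {
  q <- ncol(asm$Z)
  cv <- .theta_to_cov(theta, q, car1)
  pieces <- lmm_profile_cpp(asm$y, asm$X, asm$Z, asm$sub_start, asm$sub_len,
                            asm$ages, cv$Gstar, cv$phi, car1)
  if (!pieces$ok) return(1e10)
  N <- length(asm$y)
  beta <- tryCatch(solve(pieces$XtX, pieces$Xty), error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  rss <- pieces$yty - sum(beta * pieces$Xty)
  if (rss <= 0) return(1e10)
  sigma2 <- rss / N
  0.5 * (N * log(2 * pi) + N * log(sigma2) + pieces$ldet + N)
}

#' Fit a Gaussian linear mixed model from raw design matrices
#'
#' Low-level entry point used by [fit_lmm()], by the SITAR linearization and
#' by tests. Rows must be grouped by subject.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix.
#' @param Z Random-effect design matrix.
#' @param subject Subject id per row (grouping factor).
#' @param ages Raw ages per row (used for the CAR(1) distance).
#' @param correlation `"independent"` or `"car1"`.
#' @param start Optional start for the unconstrained covariance parameters.
#' @param n_restarts Jittered restarts attempted when the first optimization
#'   does not converge.
#' @return An object of class `lmm_fit`.
#' @export
fit_lmm_xz <- function(y, X, Z, subject, ages,
                       correlation = c("independent", "car1"),
                       start = NULL, n_restarts = 3) {
  correlation <- match.arg(correlation)
  car1 <- correlation == "car1"
  sub <- factor(subject, levels = unique(subject))
  len <- as.integer(table(sub))
  start_idx <- cumsum(c(0L, len[-length(len)]))
  asm <- list(y = y, X = as.matrix(X), Z = as.matrix(Z),
              sub_start = start_idx, sub_len = len, ages = ages,
              subjects = levels(sub))
  qr_X <- qr(asm$X)
  if (qr_X$rank < ncol(asm$X)) {
    bad <- colnames(asm$X)[qr_X$pivot[(qr_X$rank + 1):ncol(asm$X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  q <- ncol(asm$Z)
  nG <- q * (q + 1) / 2
  npar_theta <- nG + as.integer(car1)
  if (is.null(start)) {
    # moment-based start: per-subject OLS random-effect estimates give a
    # crude Gstar; keeps the optimizer out of far-away local optima when
    # variance ratios are large
    start <- rep(0, npar_theta)
    beta0 <- qr.coef(qr_X, y)
    r0 <- y - drop(asm$X %*% beta0)
    bs <- list(); rss0 <- 0; m0 <- 0
    for (j in seq_along(len)) {
      ii <- (start_idx[j] + 1):(start_idx[j] + len[j])
      if (len[j] >= q + 1) {
        Zj <- asm$Z[ii, , drop = FALSE]
        qz <- qr(Zj)
        if (qz$rank == q) {
          bj <- qr.coef(qz, r0[ii])
          bs[[length(bs) + 1]] <- bj
          rss0 <- rss0 + sum((r0[ii] - drop(Zj %*% bj))^2)
          m0 <- m0 + len[j] - q
        }
      }
    }
    Gstar0 <- NULL
    if (length(bs) >= max(10, 2 * q) && m0 > 0 && rss0 > 0) {
      s2 <- rss0 / m0
      Bm <- do.call(rbind, bs)
      G0 <- stats::cov(Bm) / s2
      G0 <- G0 + diag(0.05 * pmax(diag(G0), 0.01), q)
      ch <- tryCatch(t(chol(G0)), error = function(e) NULL)
      if (!is.null(ch)) {
        th0 <- ch[lower.tri(ch, diag = TRUE)]
        L0 <- matrix(0L, q, q)
        L0[lower.tri(L0, diag = TRUE)] <- seq_len(nG)
        th0[diag(L0)] <- log(diag(ch))
        start[seq_len(nG)] <- th0
        Gstar0 <- G0
      }
    }
    if (is.null(Gstar0)) {
      L0 <- matrix(0L, q, q)
      L0[lower.tri(L0, diag = TRUE)] <- seq_len(nG)
      start[diag(L0)] <- log(c(1, rep(0.1, max(q - 1, 0))))[seq_len(q)]
    }
  }
  if (length(start) != npar_theta) stop("start has wrong length")
  # nlminb frequently reports "false convergence" at a genuine optimum when
  # a variance component sits near its boundary; accept such fits when the
  # numerical gradient is negligible, otherwise restart from jittered points
  is_stationary <- function(opt) {
    h <- 1e-5
    g <- vapply(seq_along(opt$par), function(k) {
      ep <- em <- opt$par
      ep[k] <- ep[k] + h; em[k] <- em[k] - h
      (.profiled_nll(ep, asm, car1) - .profiled_nll(em, asm, car1)) / (2 * h)
    }, numeric(1))
    max(abs(g)) < 0.05
  }
  best <- NULL
  for (r in 0:n_restarts) {
    th0 <- if (r == 0) start else start + stats::rnorm(npar_theta, 0, 0.5)
    opt <- tryCatch(
      stats::nlminb(th0, .profiled_nll, asm = asm, car1 = car1,
                    control = list(rel.tol = 1e-10, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence != 0 && is_stationary(opt)) opt$convergence <- 0L
    if (is.null(best) || opt$objective < best$objective - 1e-8) best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) stop("LMM optimization failed from all starts")
  theta <- best$par
  cv <- .theta_to_cov(theta, q, car1)
  pieces <- lmm_profile_cpp(asm$y, asm$X, asm$Z, asm$sub_start, asm$sub_len,
                            asm$ages, cv$Gstar, cv$phi, car1)
  N <- length(y)
  beta <- solve(pieces$XtX, pieces$Xty)
  rss <- pieces$yty - sum(beta * pieces$Xty)
  sigma2 <- rss / N
  loglik <- -best$objective
  G <- sigma2 * cv$Gstar
  vcov_beta <- sigma2 * solve(pieces$XtX)
  re <- lmm_ranef_cpp(asm$y, asm$X, asm$Z, asm$sub_start, asm$sub_len,
                      asm$ages, cv$Gstar, cv$phi, car1, beta)
  ranef <- re$ranef
  rownames(ranef) <- asm$subjects
  colnames(ranef) <- colnames(asm$Z)
  fitted_pop <- drop(asm$X %*% beta)
  # marginal variance per visit for standardized residuals
  vdiag <- sigma2 * (rowSums((asm$Z %*% cv$Gstar) * asm$Z) + 1)
  npar <- ncol(asm$X) + nG + 1L + as.integer(car1)
  beta <- drop(beta)
  names(beta) <- colnames(asm$X)
  dimnames(vcov_beta) <- list(colnames(asm$X), colnames(asm$X))
  structure(list(
    beta = beta, vcov_beta = vcov_beta, G = G, sigma2 = sigma2,
    phi = if (car1) cv$phi else NULL, correlation = correlation,
    loglik = loglik, npar = npar, aic = -2 * loglik + 2 * npar,
    theta = theta, n_obs = N, n_subjects = length(asm$subjects),
    subjects = asm$subjects,
    fitted_population = fitted_pop,
    fitted_subject = drop(re$fitted_subject),
    residuals_marginal = y - fitted_pop,
    residuals_standardized = (y - fitted_pop) / sqrt(vdiag),
    residuals_conditional = y - drop(re$fitted_subject),
    ranef = ranef,
    converged = best$convergence == 0,
    optim_message = best$message),
    class = "lmm_fit")
}

#' Fit a linear mixed growth model to a cohort stratum
#'
#' @param data A `cohort` data frame (typically one sex stratum).
#' @param spec A [model_spec()].
#' @param g Optional named per-subject numeric vector (SNP dosage or allele
#'   score) required when `spec` carries genetic terms; subjects without a
#'   value are excluded (complete case).
#' @param ... Passed to [fit_lmm_xz()].
#' @return An object of class `growth_fit` (contains the `lmm_fit` plus the
#'   spec and the analysis frame).
#' @export
fit_lmm <- function(data, spec = preset_spec("lmm"), g = NULL, ...) {
  asm <- .assemble(data, spec, g)
  fit <- fit_lmm_xz(asm$y, asm$X, asm$Z, asm$df$subject_id, asm$ages,
                    correlation = spec$correlation, ...)
  structure(list(fit = fit, spec = spec, data = asm$df, y = asm$y,
                 X = asm$X, Z = asm$Z, g = g),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf("<growth_fit: %s response, %s fixed basis, %s correlation>\n",
              x$spec$response, x$spec$fixed$kind, x$spec$correlation))
  cat(sprintf("  %d subjects, %d visits; logLik %.3f, AIC %.3f%s\n",
              f$n_subjects, f$n_obs, f$loglik, f$aic,
              if (f$converged) "" else "  [NOT CONVERGED]"))
  print(round(f$beta, 5))
  invisible(x)
}

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$fit$loglik, df = object$fit$npar, class = "logLik")
}

#' Predict from a fitted growth model
#'
#' @param object A `growth_fit`.
#' @param ages Ages (years) at which to predict.
#' @param level `"population"` (fixed effects only) or `"subject"`.
#' @param subject_id Subject whose random effects to use when
#'   `level = "subject"`.
#' @param scale `"model"` (the response scale the model was fitted on) or
#'   `"bmi"` (exponentiated when the model is on the ln scale).
#' @param g Value of the genetic covariate for the predicted profile (needed
#'   when the spec carries genetic terms); default 0.
#' @param extrapolation_guard Years beyond the observed age range allowed
#'   before a warning is raised.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.growth_fit <- function(object, ages,
                               level = c("population", "subject"),
                               subject_id = NULL,
                               scale = c("model", "bmi"), g = 0,
                               extrapolation_guard = 0.5, ...) {
  level <- match.arg(level)
  scale <- match.arg(scale)
  rng <- range(object$data$age_years)
  if (any(ages < rng[1] - extrapolation_guard |
          ages > rng[2] + extrapolation_guard)) {
    warning("prediction ages outside observed range +/- guard")
  }
  X <- build_basis(object$spec$fixed, ages)
  if (!is.null(object$spec$genetic)) {
    a <- center_age(ages, object$spec$genetic$center)
    deg <- object$spec$genetic$interaction_degree
    X <- cbind(X, outer(a, 0:deg, `^`) * g)
  }
  pred <- drop(X %*% object$fit$beta)
  if (level == "subject") {
    if (is.null(subject_id)) stop("subject_id required for subject level")
    b <- object$fit$ranef[as.character(subject_id), ]
    Z <- build_basis(object$spec$random, ages)
    pred <- pred + drop(Z %*% b)
  }
  if (scale == "bmi" && object$spec$response == "ln") pred <- exp(pred)
  pred
}

#' Likelihood-ratio test of nested ML fits
#'
#' @param fit_full,fit_null `growth_fit` (or `lmm_fit`) objects fitted by ML
#'   on identical data, the null's fixed-effect set nested in the full's.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt_nested <- function(fit_full, fit_null) {
  unwrap <- function(x) {
    if (inherits(x, c("growth_fit", "stlmm_fit", "sitar_fit"))) x$fit else x
  }
  ff <- unwrap(fit_full)
  fn <- unwrap(fit_null)
  if (ff$n_obs != fn$n_obs) {
    stop("fits are not on identical data (different observation counts)")
  }
  df <- ff$npar - fn$npar
  if (df <= 0) stop("models are not nested (full has no extra parameters)")
  stat <- 2 * (ff$loglik - fn$loglik)
  if (stat < -1e-4) {
    stop("negative LRT statistic beyond tolerance; refit the full model")
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' AIC-based knot selection for the semi-parametric spline model
#'
#' Fits every candidate knot vector (holding the rest of the specification
#' fixed) and returns the AIC-minimizing one; ties break toward fewer
#' parameters. Candidates that fail to converge are recorded and skipped.
#'
#' @param data A `cohort` stratum.
#' @param knot_grid List of numeric knot vectors.
#' @param base_spec Template [model_spec()]; its fixed-basis knots are
#'   replaced per candidate.
#' @return List with `best_spec`, `best_knots` and the full `table`
#'   (knots, n_par, loglik, AIC, converged).
#' @export
select_spline_model <- function(data, knot_grid,
                                base_spec = preset_spec("splmm")) {
  stopifnot(length(knot_grid) >= 1)
  rows <- lapply(knot_grid, function(kn) {
    sp <- base_spec
    sp$fixed$knots <- as.numeric(kn)
    fit <- tryCatch(fit_lmm(data, sp), error = function(e) NULL)
    if (is.null(fit) || !fit$fit$converged) {
      data.frame(knots = paste(kn, collapse = ","),
                 n_par = NA_integer_, loglik = NA_real_, aic = NA_real_,
                 converged = FALSE)
    } else {
      data.frame(knots = paste(kn, collapse = ","),
                 n_par = fit$fit$npar, loglik = fit$fit$loglik,
                 aic = fit$fit$aic, converged = TRUE)
    }
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$converged)
  if (!length(ok)) stop("no candidate converged")
  ord <- ok[order(tab$aic[ok], tab$n_par[ok])]
  best <- ord[1]
  sp <- base_spec
  sp$fixed$knots <- knot_grid[[best]]
  list(best_spec = sp, best_knots = knot_grid[[best]], table = tab)
}

#' Residual diagnostics tables for a fitted growth model
#'
#' Plot-ready data frames (no rendering dependency): standardized marginal
#' residual QQ coordinates, fitted-vs-observed and fitted-vs-residual pairs at
#' the subject level.
#'
#' @param fit A `growth_fit`.
#' @return List of data frames `qq`, `fitted_observed`, `fitted_residual`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  r <- fit$fit$residuals_standardized
  n <- length(r)
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
                   sample = sort(r))
  list(qq = qq,
       fitted_observed = data.frame(fitted = fit$fit$fitted_subject,
                                    observed = fit$y),
       fitted_residual = data.frame(fitted = fit$fit$fitted_subject,
                                    residual = fit$y - fit$fit$fitted_subject))
}
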