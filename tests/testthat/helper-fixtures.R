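# Shared fixtures and independent oracles for the test suite.

# A tiny hand-written valid visit table.
tiny_cohort_df <- function() {
  data.frame(
    subject_id = c("a", "a", "a", "b", "b", "c"),
    sex = c("F", "F", "F", "M", "M", "F"),
    age_years = c(1, 6, 14, 2, 10, 8),
    bmi = c(17.0, 15.8, 21.5, 16.2, 18.4, 16.9),
    stringsAsFactors = FALSE
  )
}

# Independent dense multivariate-normal log-likelihood oracle: builds each
# subject's full covariance V_j = Z_j G Z_j' + sigma2 * C_j(phi) explicitly
# and sums dense Gaussian log-densities. Kept free of the package's
# likelihood code path.
dense_loglik_oracle <- function(y, X, Z, subject, ages, beta, G, sigma2,
                                phi = 0) {
  ll <- 0
  for (id in unique(subject)) {
    ii <- which(subject == id)
    Zj <- Z[ii, , drop = FALSE]
    C <- if (phi > 0) phi^abs(outer(ages[ii], ages[ii], `-`)) else
      diag(length(ii))
    V <- Zj %*% G %*% t(Zj) + sigma2 * C
    r <- y[ii] - drop(X[ii, , drop = FALSE] %*% beta)
    ll <- ll - 0.5 * (length(ii) * log(2 * pi) +
                        as.numeric(determinant(V)$modulus) +
                        drop(t(r) %*% solve(V, r)))
  }
  ll
}

# Simulate a small random LMM instance (subjects, designs, parameters and
# data drawn under the given seed) for likelihood-oracle checks.
random_lmm_instance <- function(seed, car1 = FALSE) {
  set.seed(seed)
  nsub <- sample(10:30, 1)
  sub <- character(0); ages <- numeric(0)
  for (j in seq_len(nsub)) {
    nv <- sample(2:8, 1)
    sub <- c(sub, rep(sprintf("s%02d", j), nv))
    ages <- c(ages, sort(runif(nv, 1, 17)))
  }
  a <- ages - 8
  X <- cbind(1, a, a^2)
  Z <- cbind(1, a)
  Lg <- matrix(c(0.2, 0, runif(1, -0.01, 0.01), 0.03), 2)
  G <- tcrossprod(Lg)
  sigma2 <- runif(1, 0.005, 0.05)
  phi <- if (car1) runif(1, 0.2, 0.8) else 0
  beta <- c(2.8, 0.02, 0.003)
  y <- numeric(length(ages))
  for (id in unique(sub)) {
    ii <- which(sub == id)
    C <- if (car1) phi^abs(outer(ages[ii], ages[ii], `-`)) else
      diag(length(ii))
    V <- Z[ii, , drop = FALSE] %*% G %*% t(Z[ii, , drop = FALSE]) +
      sigma2 * C
    y[ii] <- drop(X[ii, , drop = FALSE] %*% beta) +
      drop(rnorm(length(ii)) %*% chol(V))
  }
  list(y = y, X = X, Z = Z, subject = sub, ages = ages,
       truth = list(beta = beta, G = G, sigma2 = sigma2, phi = phi))
}

# Small Gaussian-simulation stratum for fitting tests (cached per session).
.fixture_env <- new.env(parent = emptyenv())

small_female_stratum <- function() {
  if (is.null(.fixture_env$small_female)) {
    sc <- make_scenario("null", sim_config(n_male = 0, n_female = 200,
                                           seed = 42))
    .fixture_env$small_female <- sc
  }
  .fixture_env$small_female
}
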