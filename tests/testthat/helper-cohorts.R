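# Small fixture builders used across test files. Everything is generated in
# code; no data files.

# Minimal hand-built cohort: two complete pairs plus one singleton.
tiny_cohort <- function() {
  twin_cohort(data.frame(
    pair_id = c("a", "a", "b", "b", "c"),
    twin_index = c(1L, 2L, 1L, 2L, 1L),
    zygosity = c("MZ", "MZ", "DZ", "DZ", "MZ"),
    sex = c("F", "F", "M", "M", "F"),
    age = c(60, 60, 65, 65, 58),
    lon = c(1.2, 0.8, -0.3, 0.1, 2.0),
    swls = c(0.5, 0.7, -1.0, 0.2, NA),
    stringsAsFactors = FALSE))
}

# Random valid cohort with missingness and singletons, for round-trip
# property tests.
random_cohort <- function(seed, n_pairs = 20) {
  set.seed(seed)
  zyg <- sample(c("MZ", "DZ"), n_pairs, replace = TRUE)
  sex <- sample(c("F", "M"), n_pairs, replace = TRUE)
  age <- round(rnorm(n_pairs, 63, 4.5), 1)
  rows <- lapply(seq_len(n_pairs), function(i) {
    k <- if (runif(1) < 0.15) sample(1:2, 1) else 1:2
    data.frame(pair_id = sprintf("p%03d", i), twin_index = k,
               zygosity = zyg[i], sex = sex[i], age = age[i],
               x = ifelse(runif(length(k)) < 0.1, NA, round(rnorm(length(k)), 6)),
               y = round(rnorm(length(k)), 6),
               stringsAsFactors = FALSE)
  })
  twin_cohort(do.call(rbind, rows), traits = c("x", "y"))
}

# Direct (non-pattern-grouped) -2 log-likelihood oracle: per-pair evaluation
# of the multivariate-normal density over observed entries using solve() and
# det(), independent of the package's chol/sufficient-statistic path.
m2ll_oracle <- function(params, wide, traits) {
  cols <- c(paste0(traits, "_1"), paste0(traits, "_2"))
  Y <- as.matrix(wide[cols])
  total <- 0
  for (i in seq_len(nrow(Y))) {
    obs <- which(!is.na(Y[i, ]))
    if (length(obs) == 0L) next
    Sigma <- expected_pair_covariance(params, wide$zygosity[i])
    S <- Sigma[obs, obs, drop = FALSE]
    x <- Y[i, obs]
    total <- total + length(obs) * log(2 * pi) + log(det(S)) +
      drop(t(x) %*% solve(S, x))
  }
  total
}

# Dense-matrix ML mixed-model oracle: per-cluster covariance built
# explicitly, GLS via solve(), 1-D search over the variance ratio.
lmm_ml_oracle <- function(y, X, pair) {
  clusters <- split(seq_along(y), pair)
  dev <- function(lambda) {
    A <- matrix(0, ncol(X), ncol(X)); b <- rep(0, ncol(X))
    yVy <- 0; logdetV <- 0
    for (idx in clusters) {
      V <- diag(length(idx)) + lambda * matrix(1, length(idx), length(idx))
      Vi <- solve(V)
      A <- A + t(X[idx, , drop = FALSE]) %*% Vi %*% X[idx, , drop = FALSE]
      b <- b + t(X[idx, , drop = FALSE]) %*% Vi %*% y[idx]
      yVy <- yVy + t(y[idx]) %*% Vi %*% y[idx]
      logdetV <- logdetV + log(det(V))
    }
    beta <- solve(A, b)
    rss <- drop(yVy - t(b) %*% beta)
    n <- length(y)
    list(dev = n * log(2 * pi * rss / n) + logdetV + n, beta = drop(beta),
         sigma2 = rss / n)
  }
  opt <- optimize(function(l) dev(l)$dev, interval = c(0, 50), tol = 1e-10)
  sol <- dev(opt$minimum)
  list(beta = sol$beta, sigma2 = sol$sigma2,
       tau2 = opt$minimum * sol$sigma2, dev = sol$dev)
}
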