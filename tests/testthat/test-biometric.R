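# Single-trait parameter shorthand used throughout
p1 <- function(a2, c2, e2) {
  chol_params(L_a = matrix(sqrt(a2)), L_c = matrix(sqrt(c2)),
              L_e = matrix(sqrt(e2)))
}

test_that("expected pair covariance: analytic single-trait cases", {
  p <- p1(0.4, 0, 0.6)
  mz <- expected_pair_covariance(p, "MZ")
  dz <- expected_pair_covariance(p, "DZ")
  expect_equal(mz, matrix(c(1, 0.4, 0.4, 1), 2))
  expect_equal(dz, matrix(c(1, 0.2, 0.2, 1), 2))
  # no genetic paths -> zygosity is irrelevant
  p0 <- chol_params(L_e = diag(2) * 0.5,
                    L_c = matrix(c(0.3, 0.1, 0, 0.2), 2))
  expect_equal(expected_pair_covariance(p0, "MZ"),
               expected_pair_covariance(p0, "DZ"))
})

test_that("expected pair covariance matches a Monte-Carlo simulation oracle", {
  set.seed(31)
  m <- 2
  L_a <- matrix(c(0.6, 0.3, 0, 0.5), 2)
  L_c <- matrix(c(0.3, 0.1, 0, 0.2), 2)
  L_e <- matrix(c(0.7, 0.2, 0, 0.6), 2)
  p <- chol_params(L_a = L_a, L_c = L_c, L_e = L_e)
  n <- 2e5  # scaled from the 1e6 of a full MC check to keep the suite fast
  for (zyg in c("MZ", "DZ")) {
    g_c <- matrix(rnorm(n * m), n, m)
    if (zyg == "MZ") { g1 <- g_c; g2 <- g_c } else {
      g1 <- sqrt(0.5) * g_c + sqrt(0.5) * matrix(rnorm(n * m), n, m)
      g2 <- sqrt(0.5) * g_c + sqrt(0.5) * matrix(rnorm(n * m), n, m)
    }
    cc <- matrix(rnorm(n * m), n, m)
    y1 <- g1 %*% t(L_a) + cc %*% t(L_c) + matrix(rnorm(n * m), n, m) %*% t(L_e)
    y2 <- g2 %*% t(L_a) + cc %*% t(L_c) + matrix(rnorm(n * m), n, m) %*% t(L_e)
    emp <- cov(cbind(y1, y2))
    expect_lt(max(abs(emp - expected_pair_covariance(p, zyg))), 0.02)
  }
})

test_that("FIML equals direct density evaluation; marginalization; additivity", {
  sim <- simulate_cohort(simulation_config(60, 60, traits = c("u", "v"),
                                           h2 = c(0.4, 0.3),
                                           incomplete_fraction = 0.1,
                                           seed = 5))
  spec <- cholesky_spec(c("u", "v"), c("A", "E"))
  wide <- to_wide(sim$cohort, c("u", "v"))
  p <- chol_params(L_a = matrix(c(0.6, 0.2, 0, 0.5), 2),
                   L_e = matrix(c(0.75, 0.1, 0, 0.8), 2))
  expect_equal(minus2_log_likelihood(p, wide, spec),
               m2ll_oracle(p, wide, c("u", "v")), tolerance = 1e-10)

  # a pair with twin 2 fully missing contributes the m-dim marginal term
  lone <- wide[1, , drop = FALSE]
  lone$u_2 <- NA; lone$v_2 <- NA
  Sigma <- expected_pair_covariance(p, lone$zygosity)[1:2, 1:2]
  x <- c(lone$u_1, lone$v_1)
  expect_equal(minus2_log_likelihood(p, lone, spec),
               2 * log(2 * pi) + log(det(Sigma)) + drop(x %*% solve(Sigma, x)),
               tolerance = 1e-10)

  # duplicating every pair doubles the deviance
  dup <- rbind(wide, transform(wide, pair_id = paste0(pair_id, "_d")))
  class(dup) <- class(wide)
  expect_equal(minus2_log_likelihood(p, dup, spec),
               2 * minus2_log_likelihood(p, wide, spec), tolerance = 1e-10)

  # non-PD parameter points return a large finite penalty, not an error
  bad <- chol_params(L_a = matrix(0, 2, 2),
                     L_e = matrix(c(1e-12, 0, 0, 1e-12), 2))
  expect_true(is.finite(minus2_log_likelihood(bad, wide, spec)))
})

test_that("single-trait AE fit recovers generating heritability", {
  sim <- simulate_cohort(simulation_config(5000, 5000, traits = "t",
                                           h2 = 0.42, seed = 21))
  fit <- fit_cholesky(sim$cohort, cholesky_spec("t", c("A", "E")), seed = 1,
                      restarts = 3)
  expect_lt(abs(fit$h2[["t"]] - 0.42), 0.03)
  expect_equal(unname(fit$h2 + fit$c2 + fit$e2), 1, tolerance = 1e-6)
  expect_equal(fit$AIC, fit$minus2lnL + 2 * fit$k)
})

test_that("null heritability is recovered as near zero", {
  sim <- simulate_cohort(simulation_config(5000, 5000, traits = "t",
                                           h2 = 0, c2 = 0.3, seed = 22))
  fit <- fit_cholesky(sim$cohort, cholesky_spec("t", c("A", "C", "E")),
                      seed = 1, restarts = 3)
  expect_lt(fit$h2[["t"]], 0.02)
})

test_that("standardization identities: rg structure and share normalization", {
  # diagonal genetic paths -> no genetic covariance -> rg = identity
  p <- chol_params(L_a = diag(c(0.5, 0.6)), L_e = diag(c(0.7, 0.8)))
  std <- standardize_components(p, c("a", "b"))
  expect_equal(std$rg, diag(2), ignore_attr = TRUE)
  expect_equal(unname(std$h2 + std$c2 + std$e2), c(1, 1), tolerance = 1e-12)
  # rank-1 genetic structure (single shared factor) -> |rg| = 1 everywhere
  L1 <- matrix(0, 2, 2); L1[, 1] <- c(0.5, -0.4)
  std1 <- standardize_components(chol_params(L_a = L1, L_e = diag(2) * 0.7),
                                 c("a", "b"))
  expect_equal(abs(std1$rg), matrix(1, 2, 2), ignore_attr = TRUE)
  # zero genetic variance -> undefined (NA) rg row/column, not zero
  L0 <- diag(c(0.5, 0))
  std0 <- standardize_components(chol_params(L_a = L0, L_e = diag(2) * 0.7),
                                 c("a", "b"))
  expect_true(all(is.na(std0$rg[2, ])))
  expect_false(is.na(std0$rg[1, 1]))
})

test_that("model comparison respects AIC definition and nesting monotonicity", {
  sim <- simulate_cohort(simulation_config(400, 400, traits = "t",
                                           h2 = 0.4, seed = 23))
  cmp <- compare_models(sim$cohort, "t", seed = 2, restarts = 2)
  tab <- cmp$table
  expect_equal(tab$AIC, tab$minus2lnL + 2 * tab$k)
  m2 <- sapply(cmp$fits, `[[`, "minus2lnL")
  expect_lte(m2[["ACE"]], m2[["AE"]] + 1e-6)
  expect_lte(m2[["AE"]], m2[["E"]] + 1e-6)
  expect_equal(sum(tab$best), 1L)
})

test_that("twin correlations: identity, null, and Falconer patterns", {
  df <- data.frame(pair_id = rep(sprintf("p%02d", 1:20), each = 2),
                   twin_index = rep(1:2, 20),
                   zygosity = rep(c("MZ", "DZ"), each = 20),
                   sex = "F", age = 60,
                   t = rep(rnorm(20), each = 2))
  ds <- twin_cohort(df)
  tc <- twin_correlations(ds, "t")
  expect_equal(tc$r_MZ, 1, tolerance = 1e-12)
  expect_equal(tc$r_DZ, 1, tolerance = 1e-12)

  set.seed(44)
  df$t <- rnorm(nrow(df))  # independent twins
  big <- do.call(rbind, lapply(1:500, function(i)
    transform(df, pair_id = paste0(pair_id, "_", i), t = rnorm(nrow(df)))))
  tc0 <- twin_correlations(twin_cohort(big), "t")
  expect_lt(abs(tc0$r_MZ), 0.05)
  expect_error(twin_correlations(ds[1:4, ], "t"), "fewer than")
})

test_that("Falconer consistency: h2 ~ 2(r_MZ - r_DZ) under AE at large n", {
  sim <- simulate_cohort(simulation_config(5000, 5000, traits = "t",
                                           h2 = 0.3, seed = 24,
                                           incomplete_fraction = 0))
  tc <- twin_correlations(sim$cohort, "t")
  fit <- fit_cholesky(sim$cohort, cholesky_spec("t", c("A", "E")), seed = 1,
                      restarts = 2)
  expect_lt(abs(fit$h2[["t"]] - 2 * (tc$r_MZ - tc$r_DZ)), 0.05)
  expect_lt(abs(tc$r_MZ - 0.30), 0.03)
  expect_lt(abs(tc$r_DZ - 0.15), 0.03)
})

test_that("fitted deviance is never above the generating-parameter deviance", {
  for (seed in 1:3) {
    sim <- simulate_cohort(simulation_config(300, 300, traits = "t",
                                             h2 = 0.35, seed = seed,
                                             incomplete_fraction = 0))
    truth <- chol_params(L_a = matrix(sqrt(0.35)), L_e = matrix(sqrt(0.65)))
    spec <- cholesky_spec("t", c("A", "E"))
    fit <- fit_cholesky(sim$cohort, spec, seed = seed, restarts = 2,
                        residualize_age_sex = FALSE, standardize = FALSE)
    wide <- to_wide(sim$cohort, "t")
    expect_lte(fit$minus2lnL,
               minus2_log_likelihood(truth, wide, spec) + 1e-6)
  }
})

test_that("twin-swap invariance of the deviance", {
  sim <- simulate_cohort(simulation_config(200, 200, traits = c("u", "v"),
                                           h2 = 0.4, seed = 25,
                                           incomplete_fraction = 0.1))
  ds <- sim$cohort
  swapped <- as.data.frame(ds)
  swapped$twin_index <- 3L - swapped$twin_index
  dss <- twin_cohort(swapped, traits = traits(ds))
  p <- chol_params(L_a = matrix(c(0.6, 0.2, 0, 0.5), 2),
                   L_e = matrix(c(0.75, 0.1, 0, 0.8), 2))
  spec <- cholesky_spec(c("u", "v"), c("A", "E"))
  expect_equal(minus2_log_likelihood(p, to_wide(ds, c("u", "v")), spec),
               minus2_log_likelihood(p, to_wide(dss, c("u", "v")), spec),
               tolerance = 1e-10)
})

test_that("minimum pair-count guard fires", {
  sim <- simulate_cohort(simulation_config(10, 40, traits = "t", seed = 26))
  expect_error(fit_cholesky(sim$cohort, cholesky_spec("t", c("A", "E"))),
               "fewer than 30 pairs")
})
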