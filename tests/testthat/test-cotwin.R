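test_that("within/between decomposition identities", {
  d <- decompose_pair(c(3, 5), c("a", "a"))
  expect_equal(d$within, c(-1, 1))
  expect_equal(d$between, c(4, 4))
  expect_equal(decompose_pair(c(4, 4), c("a", "a"))$within, c(0, 0))
  set.seed(8)
  x <- rnorm(50)
  pair <- rep(1:25, each = 2)
  d <- decompose_pair(x, pair)
  expect_equal(as.numeric(tapply(d$within, pair, sum)), rep(0, 25),
               tolerance = 1e-12)
  expect_equal(sum(d$within), 0, tolerance = 1e-10)
  # exact orthogonality of the two components after pairwise centering
  expect_lt(abs(sum(d$within * d$between)), 1e-10)
})

mk_mz_cohort <- function(n_pairs, seed, beta = 0.5, confound_sd = 0) {
  set.seed(seed)
  x <- rnorm(2 * n_pairs)
  u <- rep(rnorm(n_pairs, sd = confound_sd), each = 2)
  y <- beta * x + u + rnorm(2 * n_pairs, sd = 0.8)
  twin_cohort(data.frame(
    pair_id = rep(sprintf("p%04d", 1:n_pairs), each = 2),
    twin_index = rep(1:2, n_pairs),
    zygosity = "MZ", sex = rep(sample(c("F", "M"), n_pairs, TRUE), each = 2),
    age = rep(rnorm(n_pairs, 63, 4), each = 2),
    x = x, y = y, stringsAsFactors = FALSE))
}

test_that("perfect-fit limit: y = x gives unit within/between slopes", {
  ds <- mk_mz_cohort(100, 1)
  df <- as.data.frame(ds); df$y <- df$x
  ds2 <- twin_cohort(df)
  fit <- fit_mixed(ds2, cotwin_spec("x", "y", sample = "mz"))
  expect_equal(fit$beta_w, 1, tolerance = 1e-6)
  expect_equal(fit$beta_b, 1, tolerance = 1e-6)
  expect_lt(fit$sigma2, 1e-10)
})

test_that("MZ within-pair slope equals the paired-difference regression", {
  ds <- mk_mz_cohort(200, 2, confound_sd = 0.5)
  fit <- fit_mixed(ds, cotwin_spec("x", "y", sample = "mz"))
  w <- to_wide(ds, c("x", "y"))
  # reproduce the fit's standardization before differencing
  zx <- (c(w$x_1, w$x_2) - mean(c(w$x_1, w$x_2))) / sd(c(w$x_1, w$x_2))
  zy <- (c(w$y_1, w$y_2) - mean(c(w$y_1, w$y_2))) / sd(c(w$y_1, w$y_2))
  n <- nrow(w)
  dx <- zx[1:n] - zx[(n + 1):(2 * n)]
  dy <- zy[1:n] - zy[(n + 1):(2 * n)]
  slope <- sum(dx * dy) / sum(dx^2)
  expect_equal(fit$beta_w, slope, tolerance = 1e-6)
})

test_that("ML estimates match a dense brute-force likelihood maximization", {
  ds <- mk_mz_cohort(30, 3, confound_sd = 0.6)
  spec <- cotwin_spec("x", "y", sample = "mz", standardize = FALSE)
  fit <- fit_mixed(ds, spec, method = "ML")
  df <- as.data.frame(ds)
  wb <- decompose_pair(df$x, df$pair_id)
  X <- cbind(1, wb$within, wb$between, as.numeric(df$sex == "M"), df$age)
  oracle <- lmm_ml_oracle(df$y, X, df$pair_id)
  expect_equal(unname(fit$coefficients$estimate), unname(oracle$beta),
               tolerance = 1e-4)
  expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-4)
  expect_equal(fit$tau2, oracle$tau2, tolerance = 1e-4)
})

test_that("REML fit agrees with lme4 on fixed and random effects", {
  skip_if_not_installed("lme4")
  sim <- simulate_cohort(scenario("mixed", 400, 400, seed = 6))
  ds <- sim$cohort
  spec <- cotwin_spec("soc", "swls", sample = "full")
  fit <- fit_mixed(ds, spec)
  df <- as.data.frame(ds)
  df <- df[complete.cases(df[c("swls", "soc", "age")]), ]
  df$y <- as.numeric(scale(df$swls))
  df$x <- as.numeric(scale(df$soc))
  df$sexn <- as.numeric(df$sex == "M")
  lf <- lme4::lmer(y ~ x + sexn + age + (1 | pair_id), data = df, REML = TRUE)
  expect_equal(unname(fit$coefficients$estimate),
               unname(lme4::fixef(lf)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$tau2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(fit$coefficients$se),
               unname(coef(summary(lf))[, "Std. Error"]), tolerance = 1e-4)
})

test_that("standardization invariance: rescaling the exposure changes nothing", {
  ds <- mk_mz_cohort(150, 4, confound_sd = 0.4)
  fit1 <- fit_mixed(ds, cotwin_spec("x", "y", sample = "mz"))
  df <- as.data.frame(ds); df$x <- df$x * 37.5
  fit2 <- fit_mixed(twin_cohort(df), cotwin_spec("x", "y", sample = "mz"))
  expect_equal(fit1$beta_w, fit2$beta_w, tolerance = 1e-10)
  expect_equal(fit1$beta_b, fit2$beta_b, tolerance = 1e-10)
})

test_that("degenerate design: exposure-concordant pairs are an error", {
  ds <- mk_mz_cohort(50, 5)
  df <- as.data.frame(ds)
  df$x <- rep(rnorm(50), each = 2)  # identical within every pair
  expect_error(fit_mixed(twin_cohort(df), cotwin_spec("x", "y", sample = "mz")),
               "beta_w")
})

test_that("effect-size classification bands", {
  expect_equal(classify_effect(0.20), "medium")
  expect_equal(classify_effect(-0.53), "large")
  expect_equal(classify_effect(0.0), "negligible")
  expect_equal(classify_effect(0.05), "very_small")
  expect_equal(classify_effect(-0.10), "small")
  expect_equal(classify_effect(0.30), "large")
  expect_equal(classify_effect(0.2999), "medium")
})

test_that("attenuation summary: ratios and verdicts", {
  out <- attenuation_summary(-0.41, -0.20, within_ci = c(-0.26, -0.13))
  expect_equal(out$ratio, 0.4878, tolerance = 1e-3)
  expect_equal(out$verdict, "partial_confounding")
  same <- attenuation_summary(0.3, 0.3, within_ci = c(0.2, 0.4))
  expect_equal(same$ratio, 1)
  expect_equal(same$verdict, "no_confounding_indicated")
  gone <- attenuation_summary(0.3, 0.05, within_ci = c(-0.02, 0.12))
  expect_equal(gone$verdict, "fully_attenuated")
  undef <- attenuation_summary(0, 0.1, within_ci = c(0.05, 0.15))
  expect_true(is.na(undef$ratio))
  expect_error(attenuation_summary(0.3, 0.1), "within_ci required")
})

test_that("panel has the contracted shape and is deterministic", {
  sim <- simulate_cohort(study_config(250, 250, seed = 9))
  ds <- sim$cohort
  exposures <- c("rs", "lon")
  p1 <- run_panel(ds, exposures)
  expect_equal(nrow(p1), length(exposures) * 2 * 2)
  expect_setequal(unique(p1$sample), c("full", "mz"))
  expect_setequal(unique(p1$outcome), c("concurrent", "lagged"))
  expect_true(all(is.na(p1$beta) | (p1$ci_lo <= p1$beta & p1$beta <= p1$ci_hi)))
  p2 <- run_panel(ds, exposures)
  expect_identical(p1, p2)
})

test_that("incomplete pairs are kept in full-sample but dropped in MZ fits", {
  sim <- simulate_cohort(scenario("causal", 300, 300, seed = 10,
                                  incomplete_fraction = 0.2))
  ds <- sim$cohort
  full <- fit_mixed(ds, cotwin_spec("soc", "swls", sample = "full"))
  mz <- fit_mixed(ds, cotwin_spec("soc", "swls", sample = "mz"))
  expect_gt(full$n_individuals, 2 * mz$n_pairs)
  expect_equal(mz$n_individuals, 2 * mz$n_pairs)
  expect_gt(mz$n_excluded_singletons, 0)
})
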