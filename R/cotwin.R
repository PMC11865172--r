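#' Within-pair / between-pair decomposition of an exposure
#'
#' Splits each individual's exposure into the pair mean (between component,
#' constant within pair) and the deviation from the pair mean (within
#' component, summing to zero within every pair). In MZ pairs the within
#' component is free of all genetic and shared-environmental variation, so
#' its regression coefficient estimates the exposure-outcome association
#' net of familial confounding.
#'
#' @param x numeric exposure values.
#' @param pair pair identifiers aligned with `x`.
#' @return data.frame with columns `within` and `between` aligned with `x`.
#' @export
decompose_pair <- function(x, pair) {
  stopifnot(length(x) == length(pair))
  means <- stats::ave(x, pair, FUN = function(v) mean(v))
  data.frame(within = x - means, between = means)
}

#' Specify a co-twin control model
#'
#' @param exposure exposure trait name.
#' @param outcome outcome trait name (must differ from `exposure`).
#' @param covariates fixed covariates (default `c("sex", "age")`).
#' @param sample `"full"` (all twins, pooled exposure effect) or `"mz"`
#'   (MZ complete pairs, within/between decomposition).
#' @param standardize z-score the outcome and the raw exposure over the
#'   analysis sample before (for `"mz"`) decomposing into within/between.
#'   Binary 0/1 exposures such as disruption indicators are conventionally
#'   left unstandardized.
#' @return object of class `cotwin_spec`.
#' @export
cotwin_spec <- function(exposure, outcome, covariates = c("sex", "age"),
                        sample = c("full", "mz"), standardize = TRUE) {
  sample <- match.arg(sample)
  if (identical(exposure, outcome))
    stop("exposure and outcome must differ", call. = FALSE)
  structure(list(exposure = exposure, outcome = outcome,
                 covariates = covariates, sample = sample,
                 standardize = standardize),
            class = "cotwin_spec")
}

# ---- random-intercept LMM for pair-clustered data --------------------------
#
# y_ij = X_ij beta + u_i + e_ij, u_i ~ N(0, tau2), e_ij ~ N(0, sigma2),
# clusters of size 1 or 2. With lambda = tau2/sigma2 the per-cluster
# covariance is sigma2 (I + lambda J); its inverse and determinant are
# closed-form, so the profiled REML/ML criterion is a one-dimensional
# function of lambda: optimize it, then GLS gives the fixed effects. For
# cluster sizes <= 2 this is exact and fast.

lmm_profile <- function(lambda, parts, reml) {
  c2 <- lambda / (1 + 2 * lambda)
  A <- parts$XtX2 - c2 * parts$TtT2
  b <- parts$Xty2 - c2 * parts$Tty2
  yVy <- parts$yty2 - c2 * parts$tyty2
  logdetV <- parts$n2 * log(1 + 2 * lambda)
  if (parts$n1 > 0L) {
    w1 <- 1 / (1 + lambda)
    A <- A + w1 * parts$XtX1
    b <- b + w1 * parts$Xty1
    yVy <- yVy + w1 * parts$yty1
    logdetV <- logdetV + parts$n1 * log(1 + lambda)
  }
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(list(dev = Inf))
  beta <- backsolve(R, backsolve(R, b, transpose = TRUE))
  rss <- max(yVy - sum(b * beta), 1e-300)
  n <- parts$n
  p <- length(beta)
  if (reml) {
    s2 <- rss / (n - p)
    dev <- (n - p) * log(2 * pi * s2) + logdetV +
      2 * sum(log(diag(R))) + (n - p)
  } else {
    s2 <- rss / n
    dev <- n * log(2 * pi * s2) + logdetV + n
  }
  list(dev = dev, beta = beta, sigma2 = s2, R = R)
}

lmm_parts <- function(y, X, pair) {
  tab <- table(pair)
  size <- as.integer(tab[as.character(pair)])
  i2 <- size == 2L
  X2 <- X[i2, , drop = FALSE]; y2 <- y[i2]; p2 <- pair[i2]
  X1 <- X[!i2, , drop = FALSE]; y1 <- y[!i2]
  T2 <- rowsum(X2, p2)                     # per-pair column sums
  ty2 <- rowsum(y2, p2)
  list(n = length(y), n1 = sum(!i2), n2 = sum(i2) / 2L,
       XtX2 = crossprod(X2), Xty2 = crossprod(X2, y2), yty2 = sum(y2^2),
       TtT2 = crossprod(T2), Tty2 = crossprod(T2, ty2)[, 1L],
       tyty2 = sum(ty2^2),
       XtX1 = crossprod(X1), Xty1 = crossprod(X1, y1), yty1 = sum(y1^2))
}

fit_lmm_pairs <- function(y, X, pair, method = c("REML", "ML")) {
  method <- match.arg(method)
  reml <- method == "REML"
  parts <- lmm_parts(y, X, pair)
  f <- function(theta) lmm_profile(exp(theta), parts, reml)$dev
  opt <- stats::optimize(f, interval = c(-14, 14), tol = 1e-10)
  # check the tau2 = 0 boundary explicitly; truncate negative estimates there
  at0 <- lmm_profile(0, parts, reml)
  boundary <- FALSE
  if (at0$dev <= opt$objective) {
    lambda <- 0
    sol <- at0
    boundary <- TRUE
  } else {
    lambda <- exp(opt$minimum)
    sol <- lmm_profile(lambda, parts, reml)
    if (lambda < 1e-6) boundary <- TRUE
  }
  vcov <- sol$sigma2 * chol2inv(sol$R)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(beta = stats::setNames(sol$beta[, 1L], colnames(X)),
       vcov = vcov, sigma2 = sol$sigma2, tau2 = lambda * sol$sigma2,
       lambda = lambda, boundary = boundary, deviance = sol$dev,
       method = method, n = parts$n,
       n_pairs = parts$n2 + parts$n1)
}

#' Fit a co-twin control mixed model
#'
#' Random-intercept Gaussian mixed model for twin-pair-clustered data,
#' estimated by profiling the variance ratio lambda = tau2/sigma2 (REML by
#' default, ML optional) followed by closed-form GLS for the fixed effects.
#'
#' Two designs, per `spec$sample`:
#' * `"full"`: all twins pooled (incomplete pairs included), fixed effects
#'   exposure + covariates; the exposure coefficient is the conventional
#'   population association.
#' * `"mz"`: MZ complete pairs only; the exposure is decomposed with
#'   [decompose_pair()] and the model carries separate within-pair
#'   (`beta_w`) and between-pair (`beta_b`) fixed effects plus covariates.
#'
#' Complete-case analysis on all model variables; for `"mz"`, pairs must be
#' complete after listwise deletion (excluded singletons are counted in
#' `n_excluded_singletons`). When `spec$standardize` is TRUE the outcome and
#' the raw exposure are z-scored over the analysis sample before
#' decomposition. Confidence intervals are Wald, normal approximation.
#' Negative variance-ratio estimates are truncated at zero with
#' `boundary = TRUE`.
#'
#' @param ds a [twin_cohort()].
#' @param spec a [cotwin_spec()].
#' @param method `"REML"` (default) or `"ML"`.
#' @param level confidence level (default 0.95).
#' @return object of class `cotwin_fit`: coefficient table (`coefficients`
#'   with est/se/ci), `beta_w`/`beta_b` or `beta_full`, `tau2`, `sigma2`,
#'   `n_individuals`, `n_pairs`, `effect_label` (from [classify_effect()] on
#'   the exposure/within coefficient), `boundary`, `spec`.
#' @export
fit_mixed <- function(ds, spec, method = c("REML", "ML"), level = 0.95) {
  stopifnot(inherits(ds, "twin_cohort"), inherits(spec, "cotwin_spec"))
  method <- match.arg(method)
  vars <- c(spec$outcome, spec$exposure, spec$covariates)
  miss <- setdiff(setdiff(vars, c("sex", "age")), names(ds))
  if (length(miss) > 0L)
    stop("variable(s) not in cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(ds)
  df$sex_num <- as.numeric(df$sex == "M")
  use_vars <- c(spec$outcome, spec$exposure,
                ifelse(spec$covariates == "sex", "sex_num", spec$covariates))
  cc <- stats::complete.cases(df[use_vars])
  df <- df[cc, , drop = FALSE]
  n_excluded_singletons <- 0L
  if (spec$sample == "mz") {
    df <- df[df$zygosity == "MZ", , drop = FALSE]
    sz <- table(df$pair_id)
    singletons <- names(sz)[sz == 1L]
    n_excluded_singletons <- length(singletons)
    df <- df[!df$pair_id %in% singletons, , drop = FALSE]
  }
  if (nrow(df) < 4L) stop("too few usable rows after filtering", call. = FALSE)

  y <- df[[spec$outcome]]
  x <- df[[spec$exposure]]
  if (spec$standardize) {
    y <- as.numeric(scale(y))
    x <- as.numeric(scale(x))
  }
  covs <- ifelse(spec$covariates == "sex", "sex_num", spec$covariates)
  Z <- as.matrix(df[covs])
  colnames(Z) <- spec$covariates
  if (spec$sample == "mz") {
    wb <- decompose_pair(x, df$pair_id)
    if (stats::sd(wb$within) < 1e-12)
      stop("degenerate design: no within-pair variance in exposure ",
           "(beta_w unidentified; all pairs concordant)", call. = FALSE)
    X <- cbind(`(Intercept)` = 1, within = wb$within, between = wb$between, Z)
  } else {
    X <- cbind(`(Intercept)` = 1, exposure = x, Z)
  }
  fit <- fit_lmm_pairs(y, X, df$pair_id, method = method)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit$vcov))
  coefs <- data.frame(term = names(fit$beta), estimate = unname(fit$beta),
                      se = unname(se),
                      ci_lo = unname(fit$beta - z * se),
                      ci_hi = unname(fit$beta + z * se),
                      row.names = NULL, stringsAsFactors = FALSE)
  key <- if (spec$sample == "mz") "within" else "exposure"
  bkey <- coefs[coefs$term == key, , drop = FALSE]
  out <- list(spec = spec, method = method, coefficients = coefs,
              tau2 = fit$tau2, sigma2 = fit$sigma2,
              boundary = fit$boundary, deviance = fit$deviance,
              n_individuals = fit$n, n_pairs = fit$n_pairs,
              n_excluded_singletons = n_excluded_singletons,
              effect_label = classify_effect(bkey$estimate),
              level = level)
  if (spec$sample == "mz") {
    out$beta_w <- bkey$estimate
    out$beta_w_ci <- c(bkey$ci_lo, bkey$ci_hi)
    bb <- coefs[coefs$term == "between", , drop = FALSE]
    out$beta_b <- bb$estimate
    out$beta_b_ci <- c(bb$ci_lo, bb$ci_hi)
  } else {
    out$beta_full <- bkey$estimate
    out$beta_full_ci <- c(bkey$ci_lo, bkey$ci_hi)
  }
  class(out) <- "cotwin_fit"
  out
}

#' @export
print.cotwin_fit <- function(x, ...) {
  cat("Co-twin control fit (", x$spec$sample, " sample, ", x$method, "): ",
      x$spec$exposure, " -> ", x$spec$outcome, "\n", sep = "")
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4), ci_lo = round(ci_lo, 4),
                  ci_hi = round(ci_hi, 4)))
  cat(sprintf("tau2 = %.4f, sigma2 = %.4f, n = %d (%d pairs)\n",
              x$tau2, x$sigma2, x$n_individuals, x$n_pairs))
  invisible(x)
}

#' Attenuation of an association within MZ pairs
#'
#' Compares the full-sample exposure coefficient with the MZ within-pair
#' coefficient. Attenuation of the within-pair estimate relative to the
#' pooled association indicates partial confounding by familial (genetic or
#' shared environmental) factors; a within CI covering zero indicates the
#' association is fully attributable to them.
#'
#' Verdict rules (bands configurable): ratio = beta_w / beta_full;
#' * within CI covers 0 -> `"fully_attenuated"`;
#' * ratio >= `no_confounding_min` (default 0.8) -> `"no_confounding_indicated"`;
#' * otherwise -> `"partial_confounding"`.
#'
#' @param full a full-sample `cotwin_fit`, or the numeric pooled coefficient.
#' @param mz an MZ `cotwin_fit`, or the numeric within-pair coefficient (in
#'   which case `within_ci` must be supplied).
#' @param within_ci length-2 CI for the within coefficient when `mz` is
#'   numeric.
#' @param no_confounding_min ratio band (default 0.8).
#' @return list with `beta_full`, `beta_w`, `ratio` (NA when
#'   |beta_full| < 1e-8, reported as undefined), `verdict`.
#' @export
attenuation_summary <- function(full, mz, within_ci = NULL,
                                no_confounding_min = 0.8) {
  if (inherits(full, "cotwin_fit")) {
    if (inherits(mz, "cotwin_fit") &&
        !identical(full$spec$exposure, mz$spec$exposure))
      stop("fits must share the exposure", call. = FALSE)
    beta_full <- full$beta_full
  } else beta_full <- full
  if (inherits(mz, "cotwin_fit")) {
    beta_w <- mz$beta_w
    within_ci <- mz$beta_w_ci
  } else {
    beta_w <- mz
    if (is.null(within_ci))
      stop("within_ci required when mz is numeric", call. = FALSE)
  }
  ratio <- if (abs(beta_full) < 1e-8) NA_real_ else beta_w / beta_full
  covers0 <- within_ci[1] <= 0 && within_ci[2] >= 0
  verdict <- if (covers0) "fully_attenuated"
  else if (!is.na(ratio) && ratio >= no_confounding_min)
    "no_confounding_indicated"
  else "partial_confounding"
  list(beta_full = beta_full, beta_w = beta_w, ratio = ratio,
       verdict = verdict)
}

#' Classify a standardized effect size
#'
#' Bands for individual-difference research: |r| >= 0.30 large, >= 0.20
#' medium, >= 0.10 small, >= 0.05 very small; below 0.05 is labelled
#' negligible.
#'
#' @param r standardized coefficient (sign is ignored).
#' @return one of `"negligible"`, `"very_small"`, `"small"`, `"medium"`,
#'   `"large"`.
#' @export
classify_effect <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1L)
  a <- abs(r)
  if (a >= 0.30) "large"
  else if (a >= 0.20) "medium"
  else if (a >= 0.10) "small"
  else if (a >= 0.05) "very_small"
  else "negligible"
}

#' Run a panel of co-twin control analyses
#'
#' For each exposure x outcome combination, fits the full-sample and MZ
#' within-pair models and summarizes attenuation. Cell failures are recorded
#' (`note` column) rather than aborting the panel.
#'
#' @param ds a [twin_cohort()].
#' @param exposures character vector of exposure trait names.
#' @param outcomes named character vector mapping outcome labels to trait
#'   names, e.g. `c(concurrent = "swls", lagged = "swls_w2")`.
#' @param unstandardized exposures left on their raw (e.g. 0/1) scale.
#' @param method passed to [fit_mixed()].
#' @return data.frame with columns exposure, outcome, sample, beta, se,
#'   ci_lo, ci_hi, n_individuals, n_pairs, label, verdict, note (two rows
#'   per combination: full and mz).
#' @export
run_panel <- function(ds, exposures,
                      outcomes = c(concurrent = "swls", lagged = "swls_w2"),
                      unstandardized = character(), method = "REML") {
  rows <- list()
  for (oname in names(outcomes)) {
    for (ex in exposures) {
      std <- !ex %in% unstandardized
      cell <- list(full = NULL, mz = NULL)
      notes <- c(full = "", mz = "")
      for (s in c("full", "mz")) {
        cell[[s]] <- tryCatch(
          fit_mixed(ds, cotwin_spec(ex, outcomes[[oname]], sample = s,
                                    standardize = std), method = method),
          error = function(e) { notes[s] <<- conditionMessage(e); NULL })
      }
      verdict <- if (!is.null(cell$full) && !is.null(cell$mz))
        attenuation_summary(cell$full, cell$mz)$verdict else NA_character_
      for (s in c("full", "mz")) {
        f <- cell[[s]]
        rows[[length(rows) + 1L]] <- data.frame(
          exposure = ex, outcome = oname, sample = s,
          beta = if (is.null(f)) NA_real_ else
            if (s == "full") f$beta_full else f$beta_w,
          se = if (is.null(f)) NA_real_ else {
            key <- if (s == "full") "exposure" else "within"
            f$coefficients$se[f$coefficients$term == key]
          },
          ci_lo = if (is.null(f)) NA_real_ else
            if (s == "full") f$beta_full_ci[1] else f$beta_w_ci[1],
          ci_hi = if (is.null(f)) NA_real_ else
            if (s == "full") f$beta_full_ci[2] else f$beta_w_ci[2],
          n_individuals = if (is.null(f)) NA_integer_ else f$n_individuals,
          n_pairs = if (is.null(f)) NA_integer_ else f$n_pairs,
          label = if (is.null(f)) NA_character_ else f$effect_label,
          verdict = if (s == "mz") verdict else NA_character_,
          note = notes[[s]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
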