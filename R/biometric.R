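#' Specify a Cholesky twin model
#'
#' A classical twin design decomposes trait (co)variance into additive
#' genetic (A), shared environmental (C) and non-shared environmental (E)
#' contributions. The multivariate Cholesky parameterization writes each
#' component's m x m covariance contribution as L %*% t(L) with L lower
#' triangular, which guarantees positive semidefiniteness without
#' constraints on the free parameters. E is always included: it carries the
#' residual variance needed for a proper likelihood.
#'
#' @param traits ordered character vector of trait names (m >= 1).
#' @param components subset of `c("A", "C", "E")`; `"E"` is added if absent.
#' @return object of class `cholesky_spec`.
#' @export
cholesky_spec <- function(traits, components = c("A", "C", "E")) {
  stopifnot(length(traits) >= 1L)
  components <- unique(toupper(components))
  if (!all(components %in% c("A", "C", "E")))
    stop("components must be drawn from A, C, E", call. = FALSE)
  components <- intersect(c("A", "C", "E"), union(components, "E"))
  structure(list(traits = as.character(traits), components = components),
            class = "cholesky_spec")
}

#' Cholesky path matrices
#'
#' Container for the lower-triangular path matrices of the included
#' components. Upper-triangular entries must be zero; the diagonal of `L_e`
#' must be strictly positive.
#'
#' @param L_a,L_c,L_e m x m lower-triangular matrices (NULL if the component
#'   is excluded; `L_e` is mandatory).
#' @return object of class `chol_params`.
#' @export
chol_params <- function(L_a = NULL, L_c = NULL, L_e) {
  chk <- function(L, nm, pos_diag = FALSE) {
    if (is.null(L)) return(NULL)
    L <- as.matrix(L)
    if (nrow(L) != ncol(L)) stop(nm, " must be square", call. = FALSE)
    if (any(abs(L[upper.tri(L)]) > 0))
      stop(nm, " must be lower triangular", call. = FALSE)
    if (pos_diag && any(diag(L) <= 0))
      stop("diag(", nm, ") must be strictly positive", call. = FALSE)
    L
  }
  L_e <- chk(L_e, "L_e", pos_diag = TRUE)
  L_a <- chk(L_a, "L_a")
  L_c <- chk(L_c, "L_c")
  m <- nrow(L_e)
  for (L in list(L_a, L_c))
    if (!is.null(L) && nrow(L) != m)
      stop("path matrices must share dimension", call. = FALSE)
  structure(list(L_a = L_a, L_c = L_c, L_e = L_e, m = m),
            class = "chol_params")
}

component_cov <- function(params) {
  m <- params$m
  zero <- matrix(0, m, m)
  list(A = if (is.null(params$L_a)) zero else tcrossprod(params$L_a),
       C = if (is.null(params$L_c)) zero else tcrossprod(params$L_c),
       E = tcrossprod(params$L_e))
}

#' Expected covariance of a twin pair
#'
#' The 2m x 2m model-implied covariance of the stacked trait vectors
#' (twin 1, twin 2): within-twin blocks A + C + E; cross-twin blocks
#' r A + C with the genetic correlation r = 1 for MZ pairs and r = 0.5 for
#' DZ pairs (shared environment correlates 1 in both zygosities, non-shared
#' environment 0). Symmetric PSD by construction.
#'
#' @param params a [chol_params()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return 2m x 2m covariance matrix.
#' @export
expected_pair_covariance <- function(params, zygosity) {
  stopifnot(inherits(params, "chol_params"))
  zygosity <- match.arg(zygosity, c("MZ", "DZ"))
  r <- if (zygosity == "MZ") 1 else 0.5
  cc <- component_cov(params)
  within <- cc$A + cc$C + cc$E
  cross <- r * cc$A + cc$C
  rbind(cbind(within, cross), cbind(cross, within))
}

# ---- parameter packing ------------------------------------------------------

lt_index <- function(m) which(lower.tri(matrix(0, m, m), diag = TRUE))

pack_params <- function(params, components) {
  m <- params$m
  idx <- lt_index(m)
  unlist(lapply(components, function(cp) {
    L <- params[[paste0("L_", tolower(cp))]]
    if (is.null(L)) L <- matrix(0, m, m)
    L[idx]
  }))
}

unpack_params <- function(theta, m, components) {
  idx <- lt_index(m)
  nlt <- length(idx)
  out <- list(L_a = NULL, L_c = NULL, L_e = NULL, m = m)
  for (i in seq_along(components)) {
    L <- matrix(0, m, m)
    L[idx] <- theta[((i - 1L) * nlt + 1L):(i * nlt)]
    out[[paste0("L_", tolower(components[i]))]] <- L
  }
  class(out) <- "chol_params"
  out
}

# ---- FIML over missingness patterns ----------------------------------------
#
# Pairs are grouped by (zygosity, observed-entry pattern); each group
# contributes n_g * (log det S_sub + d log 2pi) + tr(S_sub^-1 %*% SS_g)
# where SS_g is the group's raw cross-product matrix over observed entries.
# This makes a likelihood evaluation O(#patterns * m^3) instead of
# O(#pairs * m^3), which is what keeps repeated fitting cheap.

fiml_groups <- function(Y, zyg) {
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0L
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  zyg <- zyg[keep]
  key <- paste(zyg, apply(obs, 1L, function(b) paste(as.integer(b),
                                                     collapse = "")))
  groups <- lapply(split(seq_len(nrow(Y)), key), function(rows) {
    cols <- which(obs[rows[1L], ])
    Ysub <- Y[rows, cols, drop = FALSE]
    list(n = length(rows), cols = cols, d = length(cols),
         r = if (zyg[rows[1L]] == "MZ") 1 else 0.5,
         S = crossprod(Ysub), s = colSums(Ysub))
  })
  attr(groups, "n_pairs") <- nrow(Y)
  groups
}

LOG2PI <- log(2 * pi)

fiml_m2ll <- function(params, groups, mu = NULL) {
  cc <- component_cov(params)
  within <- cc$A + cc$C + cc$E
  m <- params$m
  total <- 0
  for (g in groups) {
    cross <- g$r * cc$A + cc$C
    Sigma <- rbind(cbind(within, cross), cbind(cross, within))
    Ssub <- Sigma[g$cols, g$cols, drop = FALSE]
    R <- tryCatch(chol(Ssub), error = function(e) NULL)
    if (is.null(R)) return(1e10 + sum(unlist(cc)^2))
    logdet <- 2 * sum(log(diag(R)))
    SS <- g$S
    if (!is.null(mu)) {
      mu_sub <- rep(mu, 2L)[g$cols]
      SS <- SS - outer(g$s, mu_sub) - outer(mu_sub, g$s) +
        g$n * outer(mu_sub, mu_sub)
    }
    total <- total + g$n * (logdet + g$d * LOG2PI) +
      sum(chol2inv(R) * SS)
  }
  total
}

pairs_to_matrix <- function(wide, traits) {
  cols <- c(paste0(traits, "_1"), paste0(traits, "_2"))
  miss <- setdiff(cols, names(wide))
  if (length(miss) > 0L)
    stop("paired data lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  list(Y = as.matrix(wide[cols]), zyg = wide$zygosity)
}

#' FIML -2 log-likelihood of paired twin data
#'
#' Sum over pairs of -2 log multivariate-normal density of the observed
#' sub-vector of the stacked (twin 1, twin 2) trait values, under the
#' zygosity-appropriate [expected_pair_covariance()]. Missing entries are
#' marginalized by sub-matrix selection, so incomplete pairs and incomplete
#' trait vectors contribute their exact marginal terms (full-information
#' treatment). The mean is zero unless `mu` is supplied (data are expected
#' to be residualized/centered upstream; see [fit_cholesky()]).
#'
#' A non-positive-definite observed sub-covariance returns a large finite
#' penalty (1e10 plus a ridge on the implied covariances) rather than an
#' error, so numerical optimizers can recover.
#'
#' @param params a [chol_params()].
#' @param pairs a `twin_pairs` data.frame from [to_wide()].
#' @param spec a [cholesky_spec()] naming the traits (order defines the
#'   stacking).
#' @param mu optional per-trait mean vector (length m).
#' @return scalar -2 log likelihood.
#' @export
minus2_log_likelihood <- function(params, pairs, spec, mu = NULL) {
  stopifnot(inherits(spec, "cholesky_spec"))
  pm <- pairs_to_matrix(pairs, spec$traits)
  fiml_m2ll(params, fiml_groups(pm$Y, pm$zyg), mu = mu)
}

# Phenotypic-covariance start values: pool both twins' residualized trait
# vectors, take a PD-clipped covariance, and split its Cholesky factor
# evenly across the included components.
start_values <- function(Y, m, components, free_means) {
  stacked <- rbind(Y[, 1:m, drop = FALSE], Y[, (m + 1):(2 * m), drop = FALSE])
  P <- stats::cov(stacked, use = "pairwise.complete.obs")
  P[is.na(P)] <- 0
  eg <- eigen(P, symmetric = TRUE)
  P <- eg$vectors %*% diag(pmax(eg$values, 1e-3), m) %*% t(eg$vectors)
  Lp <- t(chol(P))
  w <- sqrt(1 / length(components))
  theta <- unlist(lapply(components, function(cp) (w * Lp)[lt_index(m)]))
  if (free_means) theta <- c(theta, colMeans(stacked, na.rm = TRUE))
  theta
}

#' Fit a multivariate Cholesky twin model
#'
#' Maximum-likelihood estimation of the Cholesky path matrices by numerical
#' minimization of the FIML -2 log-likelihood over the free lower-triangular
#' entries (unconstrained; positive semidefiniteness is automatic from the
#' L %*% t(L) parameterization). By default each trait is residualized on
#' age and sex and standardized to unit variance before fitting, and the
#' likelihood then uses a zero-mean model; set `free_means = TRUE` to
#' estimate per-trait means for unresidualized input instead.
#'
#' Optimization uses `stats::nlminb` with `restarts` perturbed restarts from
#' phenotypic-Cholesky start values (perturbation scale `perturb`); the best
#' optimum is kept. Results are invariant to trait ordering and to swapping
#' twins within pairs (up to numerical tolerance).
#'
#' @param ds a [twin_cohort()].
#' @param spec a [cholesky_spec()], or a character string like `"AE"` when
#'   `traits` is given.
#' @param traits trait names, defaulting to `spec$traits`.
#' @param residualize_age_sex residualize each trait on age + sex first
#'   (default TRUE).
#' @param standardize rescale each trait to unit variance (default TRUE).
#' @param free_means estimate per-trait means (default FALSE: zero-mean
#'   model for pre-centered data).
#' @param restarts number of perturbed restarts (default 5).
#' @param perturb perturbation scale for restarts (default 0.2).
#' @param min_pairs guard: minimum pairs per zygosity (default 30).
#' @param seed optional seed for the restart perturbations.
#' @param extra_starts optional list of [chol_params()] used as additional
#'   start points (used internally by [compare_models()] to seed richer
#'   models with nested optima).
#' @return object of class `biometric_fit` with elements `spec`, `params`,
#'   `minus2lnL`, `k`, `AIC`, `h2`, `c2`, `e2` (summing to 1 per trait),
#'   `rg`, `re`, `A`, `C`, `E`, `n_pairs`, `convergence`.
#' @export
fit_cholesky <- function(ds, spec, traits = NULL,
                         residualize_age_sex = TRUE, standardize = TRUE,
                         free_means = FALSE, restarts = 5, perturb = 0.2,
                         min_pairs = 30, seed = NULL, extra_starts = NULL) {
  if (is.character(spec)) spec <- cholesky_spec(traits, strsplit(spec, "")[[1]])
  stopifnot(inherits(spec, "cholesky_spec"), inherits(ds, "twin_cohort"))
  traits <- spec$traits
  m <- length(traits)

  work <- as.data.frame(ds)
  for (tr in traits) {
    v <- work[[tr]]
    if (residualize_age_sex) v <- residualize(v, work$age, work$sex)
    if (standardize) {
      s <- stats::sd(v, na.rm = TRUE)
      if (!is.na(s) && s > 0) v <- v / s
    }
    work[[tr]] <- v
  }
  wds <- twin_cohort(work, traits = traits, items = character())
  wide <- to_wide(wds, traits)
  pm <- pairs_to_matrix(wide, traits)
  nz <- table(factor(pm$zyg, levels = c("MZ", "DZ")))
  if (any(nz < min_pairs))
    stop("fewer than ", min_pairs, " pairs in a zygosity group (MZ=",
         nz[["MZ"]], ", DZ=", nz[["DZ"]], ")", call. = FALSE)
  groups <- fiml_groups(pm$Y, pm$zyg)

  comps <- spec$components
  nlt <- m * (m + 1) / 2
  npar <- nlt * length(comps) + if (free_means) m else 0L
  objective <- function(theta) {
    p <- unpack_params(theta[seq_len(nlt * length(comps))], m, comps)
    mu <- if (free_means) theta[(nlt * length(comps) + 1L):npar] else NULL
    fiml_m2ll(p, groups, mu = mu)
  }

  base_start <- start_values(pm$Y, m, comps, free_means)
  starts <- list(base_start)
  for (ex in extra_starts) {
    th <- pack_params(ex, comps)
    if (free_means) th <- c(th, rep(0, m))
    starts[[length(starts) + 1L]] <- th
  }
  if (!is.null(seed)) set.seed(seed)
  while (length(starts) < restarts)
    starts[[length(starts) + 1L]] <- base_start +
      perturb * stats::rnorm(npar) * pmax(abs(base_start), 0.1)

  best <- NULL
  objs <- numeric(0)
  for (th0 in starts) {
    opt <- stats::nlminb(th0, objective,
                         control = list(iter.max = 2000, eval.max = 4000,
                                        rel.tol = 1e-12))
    objs <- c(objs, opt$objective)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best) || !is.finite(best$objective) || best$objective >= 1e10)
    stop("Cholesky fit failed to converge; objectives: ",
         paste(signif(objs, 6), collapse = ", "), call. = FALSE)

  params <- unpack_params(best$par[seq_len(nlt * length(comps))], m, comps)
  mu_hat <- if (free_means) best$par[(nlt * length(comps) + 1L):npar] else NULL
  std <- standardize_components(params, traits)
  fit <- structure(list(
    spec = spec, traits = traits, params = params, mu = mu_hat,
    minus2lnL = best$objective, k = npar,
    AIC = best$objective + 2 * npar,
    A = std$A, C = std$C, E = std$E,
    h2 = std$h2, c2 = std$c2, e2 = std$e2, rg = std$rg, re = std$re,
    n_pairs = c(MZ = unname(nz[["MZ"]]), DZ = unname(nz[["DZ"]])),
    convergence = list(code = best$convergence, message = best$message,
                       objectives = objs)),
    class = "biometric_fit")
  fit
}

#' Standardized variance components and component correlations
#'
#' From the implied component covariances A, C, E: per-trait standardized
#' shares h2 = A_ii / v_i, c2 = C_ii / v_i, e2 = E_ii / v_i with
#' v_i = A_ii + C_ii + E_ii (so h2 + c2 + e2 = 1), the genetic correlation
#' matrix rg_ij = A_ij / sqrt(A_ii A_jj) and the non-shared environmental
#' correlation re analogously from E. Traits with (numerically) zero genetic
#' variance get an undefined (NA) rg row/column rather than zero.
#'
#' @param x a `biometric_fit` or [chol_params()].
#' @param traits optional trait names for dimnames.
#' @return list with `A`, `C`, `E`, `h2`, `c2`, `e2`, `rg`, `re`.
#' @export
standardize_components <- function(x, traits = NULL) {
  params <- if (inherits(x, "biometric_fit")) x$params else x
  stopifnot(inherits(params, "chol_params"))
  if (is.null(traits) && inherits(x, "biometric_fit")) traits <- x$traits
  cc <- component_cov(params)
  v <- diag(cc$A) + diag(cc$C) + diag(cc$E)
  cor_of <- function(M, tol = 1e-10) {
    d <- diag(M)
    out <- matrix(NA_real_, nrow(M), ncol(M))
    ok <- d > tol
    out[ok, ok] <- M[ok, ok] / sqrt(outer(d[ok], d[ok]))
    out
  }
  nm <- function(M) { dimnames(M) <- list(traits, traits); M }
  vec <- function(z) stats::setNames(z, traits)
  list(A = nm(cc$A), C = nm(cc$C), E = nm(cc$E),
       h2 = vec(diag(cc$A) / v), c2 = vec(diag(cc$C) / v),
       e2 = vec(diag(cc$E) / v),
       rg = nm(cor_of(cc$A)), re = nm(cor_of(cc$E)))
}

#' @export
print.biometric_fit <- function(x, ...) {
  cat("Cholesky", paste(x$spec$components, collapse = ""),
      "model:", length(x$traits), "trait(s),",
      x$n_pairs[["MZ"]], "MZ /", x$n_pairs[["DZ"]], "DZ pairs\n")
  cat(sprintf("-2lnL = %.4f, k = %d, AIC = %.4f\n", x$minus2lnL, x$k, x$AIC))
  tab <- data.frame(h2 = round(x$h2, 3), c2 = round(x$c2, 3),
                    e2 = round(x$e2, 3))
  print(tab)
  invisible(x)
}

#' Compare Cholesky model variants by AIC
#'
#' Fits each requested component set on the same traits and the same
#' retained pairs and ranks by AIC (lower is better). Models are fitted in
#' order of increasing complexity and each richer model also starts from the
#' embedded optimum of the previous one (with the new component at zero), so
#' the fitted -2lnL respects nesting monotonicity.
#'
#' @param ds a [twin_cohort()].
#' @param traits trait names.
#' @param models character vector of component sets (default
#'   `c("ACE", "AE", "E")`).
#' @param ... passed to [fit_cholesky()].
#' @return list with `table` (model, minus2lnL, k, AIC, dAIC, best) sorted
#'   by AIC, and `fits` (named list of `biometric_fit`s).
#' @export
compare_models <- function(ds, traits, models = c("ACE", "AE", "E"), ...) {
  comps <- lapply(models, function(s) strsplit(toupper(s), "")[[1]])
  ord <- order(lengths(comps))
  fits <- list()
  prev <- NULL
  for (i in ord) {
    spec <- cholesky_spec(traits, comps[[i]])
    extra <- if (!is.null(prev)) list(prev$params) else NULL
    fits[[models[i]]] <- fit_cholesky(ds, spec, extra_starts = extra, ...)
    prev <- fits[[models[i]]]
  }
  fits <- fits[models]
  tab <- data.frame(
    model = models,
    minus2lnL = vapply(fits, `[[`, numeric(1), "minus2lnL"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    row.names = NULL, stringsAsFactors = FALSE)
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$best <- tab$dAIC == 0
  tab <- tab[order(tab$AIC), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Twin intraclass correlations by zygosity
#'
#' Double-entry intraclass correlation of a trait in complete pairs: each
#' pair contributes both twin orderings, per zygosity. r_MZ exceeding r_DZ
#' indicates genetic influence; under a pure AE model the Falconer
#' approximation gives h2 ~ 2 (r_MZ - r_DZ).
#'
#' @param ds a [twin_cohort()].
#' @param trait trait name.
#' @param min_pairs minimum complete pairs per zygosity (default 3).
#' @return list with `r_MZ`, `r_DZ`, `n_MZ`, `n_DZ` (complete pairs used).
#' @export
twin_correlations <- function(ds, trait, min_pairs = 3) {
  wide <- to_wide(ds, trait)
  x1 <- wide[[paste0(trait, "_1")]]
  x2 <- wide[[paste0(trait, "_2")]]
  ok <- !is.na(x1) & !is.na(x2)
  out <- list()
  for (z in c("MZ", "DZ")) {
    sel <- ok & wide$zygosity == z
    n <- sum(sel)
    if (n < min_pairs)
      stop("fewer than ", min_pairs, " complete ", z, " pairs", call. = FALSE)
    out[[paste0("r_", z)]] <- stats::cor(c(x1[sel], x2[sel]),
                                         c(x2[sel], x1[sel]))
    out[[paste0("n_", z)]] <- n
  }
  out
}

#' Bootstrap confidence intervals for heritability and genetic correlations
#'
#' Nonparametric bootstrap over pairs (resampled with replacement within
#' zygosity strata). Each resample is refitted starting from the full-sample
#' optimum with a single restart, which is cheap and stable.
#'
#' @param ds a [twin_cohort()].
#' @param spec a [cholesky_spec()].
#' @param B number of resamples (default 200).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @param ... passed to [fit_cholesky()].
#' @return list with `h2` (per-trait lower/upper) and `rg` (per-pair-of-
#'   traits lower/upper), plus the bootstrap draws.
#' @export
bootstrap_biometric <- function(ds, spec, B = 200, seed = NULL, level = 0.95,
                                ...) {
  full <- fit_cholesky(ds, spec, ...)
  if (!is.null(seed)) set.seed(seed)
  first <- match(unique(ds$pair_id), ds$pair_id)
  pid <- unique(ds$pair_id)
  zyg <- ds$zygosity[first]
  m <- length(spec$traits)
  h2_draws <- matrix(NA_real_, B, m)
  rg_draws <- array(NA_real_, c(B, m, m))
  for (b in seq_len(B)) {
    res_pid <- unlist(lapply(c("MZ", "DZ"), function(z) {
      zp <- pid[zyg == z]
      sample(zp, length(zp), replace = TRUE)
    }))
    idx <- unlist(lapply(seq_along(res_pid), function(i) {
      rows <- which(ds$pair_id == res_pid[i])
      rows
    }))
    reps <- rep(seq_along(res_pid),
                vapply(res_pid, function(p) sum(ds$pair_id == p), integer(1)))
    boot_df <- as.data.frame(ds)[idx, , drop = FALSE]
    boot_df$pair_id <- paste0("b", reps)
    bds <- twin_cohort(boot_df, traits = traits(ds), items = character())
    fit <- tryCatch(
      fit_cholesky(bds, spec, restarts = 1,
                   extra_starts = list(full$params), ...),
      error = function(e) NULL)
    if (is.null(fit)) next
    h2_draws[b, ] <- fit$h2
    rg_draws[b, , ] <- fit$rg
  }
  a <- (1 - level) / 2
  qs <- function(x) stats::quantile(x, c(a, 1 - a), na.rm = TRUE,
                                    names = FALSE)
  h2_ci <- t(apply(h2_draws, 2L, qs))
  dimnames(h2_ci) <- list(spec$traits, c("lower", "upper"))
  rg_lo <- apply(rg_draws, c(2L, 3L), function(x) qs(x)[1])
  rg_hi <- apply(rg_draws, c(2L, 3L), function(x) qs(x)[2])
  dimnames(rg_lo) <- dimnames(rg_hi) <- list(spec$traits, spec$traits)
  list(fit = full, h2 = h2_ci, rg = list(lower = rg_lo, upper = rg_hi),
       draws = list(h2 = h2_draws, rg = rg_draws))
}
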