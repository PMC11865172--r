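#' Configure a synthetic twin cohort
#'
#' Defines the generative truth for a simulated cohort of MZ and DZ twin
#' pairs. Traits follow the standard biometric factor model: each twin's
#' trait vector is S = L_a g + L_c c + L_e e with standard-normal factor
#' vectors, where the genetic factors are identical for MZ co-twins and
#' split as g = sqrt(0.5) g_common + sqrt(0.5) g_unique for DZ co-twins
#' (cross-twin genetic correlation exactly 0.5 by construction); c is shared
#' within a pair and e is unique. A wellbeing outcome is generated as
#' y = sum_j gamma_j S_j + delta' g + resid_sd * eps, mixing direct causal
#' paths (gamma) with genetic confounding (delta loads on the same genetic
#' factors that drive the traits). Wave-2 wellbeing reuses the structural
#' part with a residual correlated `stability` with the wave-1 residual,
#' and is subject to logistic attrition on wave-1 wellbeing.
#'
#' Instead of explicit path matrices you may give the shorthand `h2`, `c2`
#' (per-trait variance shares) and correlation matrices `rg` / `re`; these
#' are converted internally via A = D_a rg D_a etc. and must yield positive
#' semidefinite components. If `resid_sd` is NULL it is solved so that the
#' wellbeing variance is exactly 1, which keeps standardized regression
#' coefficients on the generating scale.
#'
#' @param n_mz_pairs,n_dz_pairs pair counts.
#' @param traits trait names (length m).
#' @param L_a,L_c,L_e explicit m x m lower-triangular paths, or NULL to use
#'   the shorthand.
#' @param h2,c2 per-trait variance shares (shorthand; recycled to length m).
#' @param rg,re genetic / non-shared correlation matrices (shorthand;
#'   default identity).
#' @param gamma named causal coefficients of wellbeing on traits.
#' @param delta confound loadings of wellbeing on the genetic factors.
#' @param resid_sd wellbeing residual sd (NULL: solved for unit variance).
#' @param stability wave-1/wave-2 residual correlation of wellbeing.
#' @param items optional named list per trait:
#'   `list(n_items=, loading=, min=, max=)` for Likert item generation.
#' @param attrition list with `intercept` and `slope` of the logistic
#'   retention model on standardized wave-1 wellbeing. Defaults emulate
#'   roughly 60% retention selectively favouring the satisfied
#'   (`plogis(0.45 + 0.33 y)`).
#' @param incomplete_fraction fraction of pairs reduced to a singleton.
#' @param binary_traits named numeric of prevalences; those traits are
#'   dichotomized at the matching liability threshold (0/1 scale).
#' @param seed RNG seed for [simulate_cohort()].
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_mz_pairs, n_dz_pairs, traits = "soc",
                              L_a = NULL, L_c = NULL, L_e = NULL,
                              h2 = 0.4, c2 = 0, rg = NULL, re = NULL,
                              gamma = NULL, delta = NULL, resid_sd = NULL,
                              stability = 0.6, items = NULL,
                              attrition = list(intercept = 0.45, slope = 0.33),
                              incomplete_fraction = 0.05,
                              binary_traits = NULL, seed = NULL) {
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0, length(traits) >= 1L)
  m <- length(traits)
  lower_chol <- function(M, nm) {
    eg <- eigen(M, symmetric = TRUE)
    if (min(eg$values) < -1e-8)
      stop("config error: ", nm, " implies a non-PSD component", call. = FALSE)
    ev <- pmax(eg$values, 0)
    # ridge-free lower Cholesky via pivot-safe reconstruction
    t(chol(eg$vectors %*% diag(ev, m) %*% t(eg$vectors) + diag(1e-12, m)))
  }
  if (is.null(L_e)) {
    h2 <- rep_len(h2, m); c2 <- rep_len(c2, m)
    if (any(h2 < 0 | h2 > 1) || any(c2 < 0) || any(h2 + c2 > 1))
      stop("config error: h2/c2 shares must lie in [0, 1]", call. = FALSE)
    e2 <- 1 - h2 - c2
    if (is.null(rg)) rg <- diag(m)
    if (is.null(re)) re <- diag(m)
    chk_corr <- function(R, nm) {
      R <- as.matrix(R)
      if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-8))
        stop("config error: ", nm,
             " must be symmetric with unit diagonal", call. = FALSE)
      R
    }
    rg <- chk_corr(rg, "rg"); re <- chk_corr(re, "re")
    A <- diag(sqrt(h2), m) %*% rg %*% diag(sqrt(h2), m)
    C <- diag(c2, m)
    E <- diag(sqrt(e2), m) %*% re %*% diag(sqrt(e2), m)
    L_a <- lower_chol(A, "rg/h2")
    L_c <- lower_chol(C, "c2")
    L_e <- lower_chol(E, "re/e2")
  } else {
    as_lower <- function(L, nm) {
      if (is.null(L)) return(matrix(0, m, m))
      L <- as.matrix(L)
      if (any(abs(L[upper.tri(L)]) > 0))
        stop("config error: ", nm, " must be lower triangular", call. = FALSE)
      L
    }
    L_a <- as_lower(L_a, "L_a"); L_c <- as_lower(L_c, "L_c")
    L_e <- as_lower(L_e, "L_e")
  }
  if (is.null(gamma)) gamma <- stats::setNames(rep(0, m), traits)
  if (is.null(names(gamma))) names(gamma) <- traits[seq_along(gamma)]
  gamma <- gamma[traits]; gamma[is.na(gamma)] <- 0
  gamma <- stats::setNames(as.numeric(gamma), traits)
  if (is.null(delta)) delta <- rep(0, m)
  delta <- rep_len(as.numeric(delta), m)
  if (is.null(resid_sd)) {
    Sigma_S <- tcrossprod(L_a) + tcrossprod(L_c) + tcrossprod(L_e)
    vy <- drop(t(gamma) %*% Sigma_S %*% gamma) + sum(delta^2) +
      2 * drop(t(gamma) %*% L_a %*% delta)
    if (vy >= 1)
      stop("config error: structural wellbeing variance >= 1; ",
           "supply resid_sd explicitly", call. = FALSE)
    resid_sd <- sqrt(1 - vy)
  }
  stopifnot(is.finite(attrition$slope), stability >= -1, stability <= 1)
  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    traits = traits, L_a = L_a, L_c = L_c, L_e = L_e,
    gamma = gamma, delta = delta, resid_sd = resid_sd,
    stability = stability, items = items, attrition = attrition,
    incomplete_fraction = incomplete_fraction,
    binary_traits = binary_traits, seed = seed),
    class = "simulation_config")
}

#' Simulate a twin cohort with known ground truth
#'
#' Draws a cohort under a [simulation_config()]. One pseudo-random stream
#' keyed by the config seed; pair order (MZ block then DZ block) and the
#' order of draws are fixed, so identical configs yield byte-identical
#' cohorts. Sex (same within pair, ~58% female pairs) and age (normal around
#' 63, sd 4.5, shared within pair) emulate an older adult registry sample
#' and are generated independently of the traits, so age/sex
#' residualization is a null operation in expectation.
#'
#' Columns: `swls` is wave-1 wellbeing, `swls_w2` wave-2 wellbeing (NA for
#' individuals lost to follow-up under the logistic retention model); trait
#' columns as named in the config; optional Likert items `<trait>_i<k>`
#' (discretized by rounding then clipping — this attenuates reliability and
#' is intentional, see the package vignette).
#'
#' @param cfg a [simulation_config()].
#' @return list with `cohort` (a [twin_cohort()]) and `truth` (the full
#'   generating parameter record; JSON-serializable).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- length(cfg$traits)
  n_pairs <- cfg$n_mz_pairs + cfg$n_dz_pairs
  if (n_pairs == 0L) stop("no pairs to simulate", call. = FALSE)
  zyg <- rep(c("MZ", "DZ"), c(cfg$n_mz_pairs, cfg$n_dz_pairs))

  g_common <- matrix(stats::rnorm(n_pairs * m), n_pairs, m)
  g_u1 <- matrix(stats::rnorm(n_pairs * m), n_pairs, m)
  g_u2 <- matrix(stats::rnorm(n_pairs * m), n_pairs, m)
  c_pair <- matrix(stats::rnorm(n_pairs * m), n_pairs, m)
  e1 <- matrix(stats::rnorm(n_pairs * m), n_pairs, m)
  e2 <- matrix(stats::rnorm(n_pairs * m), n_pairs, m)

  dz <- zyg == "DZ"
  g1 <- g_common; g2 <- g_common
  g1[dz, ] <- sqrt(0.5) * g_common[dz, ] + sqrt(0.5) * g_u1[dz, ]
  g2[dz, ] <- sqrt(0.5) * g_common[dz, ] + sqrt(0.5) * g_u2[dz, ]

  S1 <- g1 %*% t(cfg$L_a) + c_pair %*% t(cfg$L_c) + e1 %*% t(cfg$L_e)
  S2 <- g2 %*% t(cfg$L_a) + c_pair %*% t(cfg$L_c) + e2 %*% t(cfg$L_e)

  eps1_1 <- stats::rnorm(n_pairs); eps1_2 <- stats::rnorm(n_pairs)
  eps2_1 <- stats::rnorm(n_pairs); eps2_2 <- stats::rnorm(n_pairs)
  struct1 <- drop(S1 %*% cfg$gamma + g1 %*% cfg$delta)
  struct2 <- drop(S2 %*% cfg$gamma + g2 %*% cfg$delta)
  y1_w1 <- struct1 + cfg$resid_sd * eps1_1
  y2_w1 <- struct2 + cfg$resid_sd * eps1_2
  rho <- cfg$stability
  y1_w2 <- struct1 + cfg$resid_sd * (rho * eps1_1 + sqrt(1 - rho^2) * eps2_1)
  y2_w2 <- struct2 + cfg$resid_sd * (rho * eps1_2 + sqrt(1 - rho^2) * eps2_2)

  sex <- ifelse(stats::runif(n_pairs) < 0.58, "F", "M")
  age <- stats::rnorm(n_pairs, 63, 4.5)

  mk <- function(S, tw, y_w1, y_w2) {
    df <- data.frame(
      pair_id = sprintf("p%05d", seq_len(n_pairs)), twin_index = tw,
      zygosity = zyg, sex = sex, age = age, stringsAsFactors = FALSE)
    for (j in seq_len(m)) df[[cfg$traits[j]]] <- S[, j]
    df$swls <- y_w1
    df$swls_w2 <- y_w2
    df
  }
  df <- rbind(mk(S1, 1L, y1_w1, y1_w2), mk(S2, 2L, y2_w1, y2_w2))

  # dichotomize designated traits at the liability threshold
  if (!is.null(cfg$binary_traits)) {
    sd_tr <- sqrt(diag(tcrossprod(cfg$L_a) + tcrossprod(cfg$L_c) +
                         tcrossprod(cfg$L_e)))
    names(sd_tr) <- cfg$traits
    for (tr in names(cfg$binary_traits)) {
      thr <- stats::qnorm(1 - cfg$binary_traits[[tr]]) * sd_tr[[tr]]
      df[[tr]] <- as.numeric(df[[tr]] > thr)
    }
  }

  # Likert items from standardized true scores plus item noise
  if (!is.null(cfg$items)) {
    sd_tr <- sqrt(diag(tcrossprod(cfg$L_a) + tcrossprod(cfg$L_c) +
                         tcrossprod(cfg$L_e)))
    names(sd_tr) <- cfg$traits
    for (tr in names(cfg$items)) {
      it <- cfg$items[[tr]]
      z <- df[[tr]] / sd_tr[[tr]]
      mid <- (it$min + it$max) / 2
      span <- (it$max - it$min) / 4
      for (k in seq_len(it$n_items)) {
        latent <- it$loading * z +
          sqrt(1 - it$loading^2) * stats::rnorm(length(z))
        df[[paste0(tr, "_i", k)]] <-
          pmin(it$max, pmax(it$min, round(mid + span * latent)))
      }
    }
  }

  # wave-2 attrition: retention depends on wave-1 wellbeing
  p_keep <- stats::plogis(cfg$attrition$intercept +
                            cfg$attrition$slope * as.numeric(scale(df$swls)))
  lost <- stats::runif(nrow(df)) > p_keep
  df$swls_w2[lost] <- NA_real_

  # incomplete pairs: drop twin 2 of a random subset of pairs
  if (cfg$incomplete_fraction > 0) {
    drop_pairs <- stats::runif(n_pairs) < cfg$incomplete_fraction
    drop_ids <- sprintf("p%05d", which(drop_pairs))
    df <- df[!(df$pair_id %in% drop_ids & df$twin_index == 2L), ,
             drop = FALSE]
  }

  cohort <- twin_cohort(df, traits = c(cfg$traits, "swls", "swls_w2"))
  truth <- unclass(cfg)
  list(cohort = cohort, truth = truth)
}

#' Canned simulation scenarios for co-twin control validation
#'
#' Four single-exposure worlds that exercise the inferential logic of the
#' co-twin design (exposure `"soc"`, h2 = 0.4, c2 = 0; wellbeing variance
#' 1 by construction):
#' * `"causal"`: direct effect gamma = 0.3, no confounding — within-pair and
#'   full-sample estimates agree;
#' * `"confounded"`: gamma = 0, genetic confound delta = 0.5 — the pooled
#'   association is spurious and the MZ within-pair effect is null;
#' * `"mixed"`: gamma = 0.3 and delta = 0.3 — attenuation without
#'   elimination, the signature of partial familial confounding;
#' * `"null"`: both zero.
#'
#' @param name scenario name.
#' @param n_mz_pairs,n_dz_pairs pair counts (default 2000 each).
#' @param seed RNG seed.
#' @param ... further arguments to [simulation_config()].
#' @return a [simulation_config()].
#' @export
scenario <- function(name, n_mz_pairs = 2000, n_dz_pairs = 2000,
                     seed = NULL, ...) {
  known <- c("causal", "confounded", "mixed", "null")
  if (!name %in% known)
    stop("unknown scenario '", name, "'; options: ",
         paste(known, collapse = ", "), call. = FALSE)
  par <- switch(name,
    causal     = list(gamma = 0.3, delta = 0),
    confounded = list(gamma = 0,   delta = 0.5),
    mixed      = list(gamma = 0.3, delta = 0.3),
    null       = list(gamma = 0,   delta = 0))
  simulation_config(n_mz_pairs, n_dz_pairs, traits = "soc",
                    h2 = 0.4, c2 = 0,
                    gamma = stats::setNames(par$gamma, "soc"),
                    delta = par$delta, seed = seed, ...)
}

#' Default multi-trait study configuration
#'
#' A six-trait world mirroring a social-factor battery: relationship
#' satisfaction (rs), attachment anxiety (aanx), attachment avoidance
#' (aavo), loneliness (lon), disruptions (disr) and trust, with
#' heritabilities spanning 0.24-0.42, no shared environment (AE truth),
#' genetic correlations of 0.6 and non-shared environmental correlations of
#' 0.2 between all traits, and a wellbeing outcome receiving both direct
#' and genetically confounded input.
#'
#' @param n_mz_pairs,n_dz_pairs pair counts.
#' @param seed RNG seed.
#' @param ... overrides passed to [simulation_config()].
#' @return a [simulation_config()].
#' @export
study_config <- function(n_mz_pairs = 1000, n_dz_pairs = 1000, seed = NULL,
                         ...) {
  traits <- c("rs", "aanx", "aavo", "lon", "disr", "trust")
  h2 <- c(rs = 0.42, aanx = 0.33, aavo = 0.38, lon = 0.35, disr = 0.24,
          trust = 0.30)
  off <- function(v, m) { R <- matrix(v, m, m); diag(R) <- 1; R }
  gamma <- c(rs = 0.15, aanx = -0.08, aavo = -0.08, lon = -0.15,
             disr = -0.10, trust = 0.05)
  simulation_config(n_mz_pairs, n_dz_pairs, traits = traits,
                    h2 = unname(h2[traits]), c2 = 0,
                    rg = off(0.6, 6), re = off(0.2, 6),
                    gamma = gamma, delta = c(0.15, 0, 0, -0.1, 0, 0),
                    seed = seed, ...)
}
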