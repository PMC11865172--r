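#' Define a psychometric scale
#'
#' @param name scale name.
#' @param items character vector of item column names.
#' @param response_min,response_max integer bounds of the response format.
#' @param reverse subset of `items` that are reverse-keyed; their responses
#'   are mapped `x -> response_min + response_max - x` before scoring.
#' @param scoring `"sum"` (default) or `"mean"`.
#' @return an object of class `scale_definition`.
#' @export
scale_definition <- function(name, items, response_min, response_max,
                             reverse = character(), scoring = c("sum", "mean")) {
  scoring <- match.arg(scoring)
  stopifnot(length(items) >= 1L, response_min < response_max)
  if (!all(reverse %in% items))
    stop("reverse items must be a subset of items", call. = FALSE)
  structure(list(name = name, items = as.character(items),
                 response_min = as.integer(response_min),
                 response_max = as.integer(response_max),
                 reverse = as.character(reverse), scoring = scoring),
            class = "scale_definition")
}

#' Bundled scale definitions
#'
#' Definitions for the instruments used in the cohort: SWLS (life
#' satisfaction, 5 items, 1-7), RSS (relationship satisfaction, 5 items,
#' 1-6), ECR-N12 attachment anxiety and avoidance subscales (6 items each,
#' 1-7), UCLA-3 loneliness (3 items, 1-5) and generalized trust (3 items,
#' 0-10). Negatively keyed items (RSS "problems in the relationship", trust
#' "take advantage") default to reverse scoring; this is configuration, not
#' something the instruments' score range forces, and can be overridden by
#' editing the JSON shipped in `inst/extdata/scales.json`.
#'
#' @param path optional path to a JSON file of definitions; defaults to the
#'   bundled file.
#' @return named list of [scale_definition()] objects.
#' @export
load_scale_definitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "scales.json", package = "twinsocial")
  defs <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(defs, function(d)
    scale_definition(d$name, d$items, d$response_min, d$response_max,
                     reverse = if (is.null(d$reverse)) character() else d$reverse,
                     scoring = d$scoring))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Score a scale from item responses
#'
#' Reverse-keyed items are reflected about the response midpoint, then items
#' are summed (or averaged). Scoring is strict complete-case: any missing
#' item yields a missing score. Out-of-range responses are a validation
#' error, not silently clipped.
#'
#' @param items a data.frame or matrix of item responses (persons x items),
#'   with columns named as in `def$items`.
#' @param def a [scale_definition()].
#' @return numeric vector of scores (NA where any item is missing).
#' @export
score_scale <- function(items, def) {
  stopifnot(inherits(def, "scale_definition"))
  items <- as.data.frame(items)
  miss <- setdiff(def$items, names(items))
  if (length(miss) > 0L)
    stop("missing item column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(items[def$items])
  rng <- !is.na(m) & (m < def$response_min | m > def$response_max)
  if (any(rng))
    stop("out-of-range response in item(s): ",
         paste(unique(colnames(m)[col(m)[rng]]), collapse = ", "),
         call. = FALSE)
  rev_cols <- match(def$reverse, def$items)
  if (length(rev_cols) > 0L)
    m[, rev_cols] <- def$response_min + def$response_max - m[, rev_cols]
  score <- switch(def$scoring, sum = rowSums(m), mean = rowMeans(m))
  score[rowSums(is.na(m)) > 0L] <- NA_real_
  unname(score)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability, alpha = k/(k-1) * (1 - sum_i var(item_i)
#' / var(total)), computed on complete-case rows with unbiased (n-1)
#' variances.
#'
#' @param items persons x items matrix or data.frame (>= 2 items; >= 3
#'   complete rows required).
#' @return alpha in (-Inf, 1].
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2L) stop("alpha undefined for fewer than 2 items",
                         call. = FALSE)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("alpha requires at least 3 complete rows",
                         call. = FALSE)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) stop("alpha undefined: zero total-score variance",
                           call. = FALSE)
  item_var <- sum(apply(m, 2L, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Composite indicator of relationship disruptions
#'
#' Collapses three stressful interpersonal events (divorce/separation,
#' partner conflict, other conflict), each with a timing of `"past_year"`,
#' `"previously"` or `"none"`, into binary indicators: `overall` (any event,
#' any timing), `past_year` (any event in the last year) and `previous` (any
#' event before that). The two timing windows are kept separate because they
#' are analysed as distinct exposures.
#'
#' @param rec a data.frame with columns `divorce`, `partner_conflict`,
#'   `other_conflict`, each in `c("past_year", "previously", "none")`. One
#'   row per person.
#' @return data.frame with integer 0/1 columns `overall`, `past_year`,
#'   `previous`.
#' @export
disruption_composite <- function(rec) {
  rec <- as.data.frame(rec)
  events <- c("divorce", "partner_conflict", "other_conflict")
  miss <- setdiff(events, names(rec))
  if (length(miss) > 0L)
    stop("missing event column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(rec[events])
  ok <- m %in% c("past_year", "previously", "none")
  if (!all(ok))
    stop("invalid timing value(s): ",
         paste(unique(m[!ok]), collapse = ", "), call. = FALSE)
  data.frame(
    overall  = as.integer(rowSums(m != "none") > 0L),
    past_year = as.integer(rowSums(m == "past_year") > 0L),
    previous = as.integer(rowSums(m == "previously") > 0L))
}

#' Residualize scores on age and sex
#'
#' Ordinary least-squares residuals of `y` on intercept + age + sex
#' indicator (F = 0, M = 1; the coding does not affect the residuals).
#' Rows with missing `y` propagate NA; `age` and `sex` must be complete for
#' retained rows. Residuals have mean zero and are orthogonal to both
#' regressors. Residualization is idempotent.
#'
#' @param y numeric scores (may contain NA).
#' @param age numeric, years.
#' @param sex character `"F"`/`"M"` (or a numeric indicator).
#' @return numeric vector of residuals, NA where `y` was NA.
#' @export
residualize <- function(y, age, sex) {
  stopifnot(length(y) == length(age), length(y) == length(sex))
  sx <- if (is.numeric(sex)) sex else as.numeric(sex == "M")
  keep <- !is.na(y)
  if (any(is.na(age[keep])) || any(is.na(sx[keep])))
    stop("age/sex must be complete for rows with observed y", call. = FALSE)
  out <- rep(NA_real_, length(y))
  if (sum(keep) == 0L) return(out)
  X <- cbind(1, age[keep], sx[keep])
  fit <- stats::lm.fit(X, y[keep])
  out[keep] <- unname(fit$residuals)
  out
}

#' Compare retained and lost groups at follow-up
#'
#' Welch two-sample t test (unequal variances) of the group means, used to
#' check whether loss to follow-up is selective on a score.
#'
#' @param scores_retained,scores_lost numeric vectors (NA dropped); each
#'   group needs >= 2 observations.
#' @return list with `mean_retained`, `mean_lost`, `diff`, `t`, `df`, `p`.
#' @export
attrition_compare <- function(scores_retained, scores_lost) {
  x <- scores_retained[!is.na(scores_retained)]
  y <- scores_lost[!is.na(scores_lost)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(mean_retained = mean(x), mean_lost = mean(y),
       diff = mean(x) - mean(y),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
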