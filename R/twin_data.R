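#' Construct a validated twin cohort
#'
#' A twin cohort is a long-format table with one row per individual. Each row
#' identifies the twin pair (`pair_id`), the member within the pair
#' (`twin_index`, 1 or 2), zygosity (`"MZ"` or `"DZ"`), `sex` (`"F"` or
#' `"M"`), `age` in years, and any number of trait or item columns. Pairs may
#' be incomplete (a single row), which downstream full-information analyses
#' handle by marginalization.
#'
#' Structural invariants enforced here:
#' * at most two members per `pair_id`, with distinct `twin_index` values;
#' * both members of a pair share zygosity, sex and age (same-sex pairs only);
#' * `zygosity` and `sex` are drawn from their enumerations.
#'
#' @param data a data.frame containing at least the columns `pair_id`,
#'   `twin_index`, `zygosity`, `sex`, `age`.
#' @param traits character vector naming the trait-score columns. Defaults to
#'   every numeric column that is not part of the required schema and does not
#'   look like an item column (no `_i<k>` suffix).
#' @param items character vector naming item-level response columns.
#' @param strict if `TRUE` (default) any invariant violation is an error; if
#'   `FALSE`, offending pairs are dropped with a warning carrying a per-pair
#'   report (available via `attr(x, "rejected")`).
#' @return an object of class `twin_cohort` (a data.frame).
#' @examples
#' df <- data.frame(pair_id = c(1, 1, 2, 2), twin_index = c(1, 2, 1, 2),
#'                  zygosity = c("MZ", "MZ", "DZ", "DZ"),
#'                  sex = "F", age = 63, lon = c(1.2, 0.8, -0.3, 0.1))
#' ds <- twin_cohort(df)
#' n_pairs(ds)
#' @export
twin_cohort <- function(data, traits = NULL, items = NULL, strict = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("pair_id", "twin_index", "zygosity", "sex", "age")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$pair_id <- as.character(data$pair_id)
  data$twin_index <- as.integer(data$twin_index)
  data$zygosity <- as.character(data$zygosity)
  data$sex <- as.character(data$sex)
  data$age <- as.numeric(data$age)

  if (is.null(items)) items <- grep("_i[0-9]+$", names(data), value = TRUE)
  if (is.null(traits)) {
    cand <- setdiff(names(data), c(required, "wave", items))
    traits <- cand[vapply(data[cand], is.numeric, logical(1))]
  }
  unknown <- setdiff(c(traits, items), names(data))
  if (length(unknown) > 0L) {
    stop("unknown trait/item column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  problems <- validate_twin_rows(data)
  if (nrow(problems) > 0L) {
    report <- paste0("  pair ", problems$pair_id, ": ", problems$problem,
                     collapse = "\n")
    if (strict) {
      stop("integrity error in twin cohort:\n", report, call. = FALSE)
    }
    bad <- unique(problems$pair_id)
    warning("dropping ", length(bad), " pair(s) violating invariants:\n",
            report, call. = FALSE)
    rejected <- data[data$pair_id %in% bad, , drop = FALSE]
    data <- data[!data$pair_id %in% bad, , drop = FALSE]
    attr(data, "rejected") <- rejected
  }

  # canonical row order: pair, then twin_index
  data <- data[order(data$pair_id, data$twin_index), , drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            traits = traits, items = items,
            class = c("twin_cohort", "data.frame"))
}

# Per-pair invariant checks; returns a data.frame(pair_id, problem).
validate_twin_rows <- function(data) {
  probs <- list()
  note <- function(pair, msg) probs[[length(probs) + 1L]] <<-
    data.frame(pair_id = pair, problem = msg, stringsAsFactors = FALSE)

  bad_zyg <- !data$zygosity %in% c("MZ", "DZ")
  for (p in unique(data$pair_id[bad_zyg]))
    note(p, "zygosity not in {MZ, DZ}")
  bad_sex <- !data$sex %in% c("F", "M")
  for (p in unique(data$pair_id[bad_sex]))
    note(p, "sex not in {F, M}")
  bad_idx <- !data$twin_index %in% c(1L, 2L) | is.na(data$twin_index)
  for (p in unique(data$pair_id[bad_idx]))
    note(p, "twin_index not in {1, 2}")

  sp <- split(seq_len(nrow(data)), data$pair_id)
  for (p in names(sp)) {
    idx <- sp[[p]]
    if (length(idx) > 2L) note(p, "more than two members")
    ti <- data$twin_index[idx]
    if (anyDuplicated(ti)) note(p, "duplicate twin_index within pair")
    if (length(unique(data$zygosity[idx])) > 1L)
      note(p, "discordant zygosity within pair")
    if (length(unique(data$sex[idx])) > 1L)
      note(p, "discordant sex within pair")
    if (length(unique(data$age[idx])) > 1L)
      note(p, "discordant age within pair")
  }
  if (length(probs) == 0L)
    return(data.frame(pair_id = character(), problem = character()))
  unique(do.call(rbind, probs))
}

#' @rdname twin_cohort
#' @param x a `twin_cohort`
#' @export
traits <- function(x) attr(x, "traits")

#' @rdname twin_cohort
#' @export
n_pairs <- function(x) length(unique(x$pair_id))

#' Read a twin cohort from a long-format CSV file
#'
#' The canonical on-disk format is long CSV, UTF-8, header row mandatory,
#' missing values as empty cells. A schema may rename columns: either a named
#' character vector (`c(pair_id = "fam", ...)`, names are canonical, values
#' are file columns) or the path to a JSON file holding such a map, optionally
#' with `traits` / `items` entries.
#'
#' @param path CSV file path.
#' @param schema optional column map (named character vector or JSON path).
#' @param traits,items,strict passed to [twin_cohort()].
#' @return a validated [twin_cohort()].
#' @export
read_cohort <- function(path, schema = NULL, traits = NULL, items = NULL,
                        strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1L && file.exists(schema) &&
      is.null(names(schema))) {
    sc <- jsonlite::read_json(schema, simplifyVector = TRUE)
    if (!is.null(sc$traits) && is.null(traits)) traits <- sc$traits
    if (!is.null(sc$items) && is.null(items)) items <- sc$items
    schema <- unlist(sc$columns)
  }
  # read everything as character first: "F" in a sex column must not be
  # parsed as logical FALSE
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = c("", "NA"), check.names = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(unname(schema), names(df))
    if (length(miss) > 0L)
      stop("schema error: file lacks mapped column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    names(df)[match(schema, names(df))] <- names(schema)
  }
  keep_char <- c("pair_id", "zygosity", "sex")
  for (cl in setdiff(names(df), keep_char))
    df[[cl]] <- utils::type.convert(df[[cl]], as.is = TRUE)
  twin_cohort(df, traits = traits, items = items, strict = strict)
}

#' Write a twin cohort to CSV
#'
#' Inverse of [read_cohort()]: long format, empty cells for missing values.
#'
#' @param ds a `twin_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Reshape a cohort to one row per pair
#'
#' Produces the per-pair unit over which the biometric likelihood is
#' evaluated: columns `<trait>_1` / `<trait>_2` aligned by `twin_index`
#' (never by file order, so likelihood evaluation is order-stable). Singleton
#' pairs get all-missing entries for the absent twin; which member indices
#' were actually present is kept in the `members` attribute so that
#' [to_long()] is lossless.
#'
#' @param ds a `twin_cohort`.
#' @param traits character vector of trait names to carry (must be non-empty).
#' @return a data.frame of class `twin_pairs` with pair-level columns
#'   `pair_id`, `zygosity`, `sex`, `age` and the paired trait columns.
#' @export
to_wide <- function(ds, traits) {
  stopifnot(inherits(ds, "twin_cohort"))
  if (length(traits) == 0L) stop("empty trait list", call. = FALSE)
  unknown <- setdiff(traits, names(ds))
  if (length(unknown) > 0L)
    stop("unknown trait(s): ", paste(unknown, collapse = ", "), call. = FALSE)

  pid <- unique(ds$pair_id)
  first <- match(pid, ds$pair_id)
  out <- data.frame(pair_id = pid,
                    zygosity = ds$zygosity[first],
                    sex = ds$sex[first],
                    age = ds$age[first],
                    stringsAsFactors = FALSE)
  members <- matrix(FALSE, nrow = length(pid), ncol = 2L,
                    dimnames = list(pid, c("1", "2")))
  row1 <- match(paste(pid, 1L), paste(ds$pair_id, ds$twin_index))
  row2 <- match(paste(pid, 2L), paste(ds$pair_id, ds$twin_index))
  members[, 1L] <- !is.na(row1)
  members[, 2L] <- !is.na(row2)
  for (tr in traits) {
    out[[paste0(tr, "_1")]] <- ifelse(is.na(row1), NA_real_, ds[[tr]][row1])
    out[[paste0(tr, "_2")]] <- ifelse(is.na(row2), NA_real_, ds[[tr]][row2])
  }
  structure(out, traits = traits, members = members,
            class = c("twin_pairs", "data.frame"))
}

#' Reshape paired data back to long format
#'
#' Inverse of [to_wide()]; `to_long(to_wide(ds, tr))` equals `ds` restricted
#' to `tr` (plus the pair-level columns) for any valid cohort.
#'
#' @param wide a `twin_pairs` object.
#' @return a `twin_cohort`.
#' @export
to_long <- function(wide) {
  stopifnot(inherits(wide, "twin_pairs"))
  trs <- attr(wide, "traits")
  members <- attr(wide, "members")
  rows <- list()
  for (k in 1:2) {
    keep <- members[, k]
    if (!any(keep)) next
    blk <- data.frame(pair_id = wide$pair_id[keep],
                      twin_index = k,
                      zygosity = wide$zygosity[keep],
                      sex = wide$sex[keep],
                      age = wide$age[keep],
                      stringsAsFactors = FALSE)
    for (tr in trs) blk[[tr]] <- wide[[paste0(tr, "_", k)]][keep]
    rows[[k]] <- blk
  }
  twin_cohort(do.call(rbind, rows), traits = trs, items = character())
}

#' Summarize a twin cohort
#'
#' @param ds a `twin_cohort`.
#' @return a list with `n_individuals`, `n_pairs`, a `pairs` table of pair
#'   counts by zygosity and sex (complete and singleton), and per-trait
#'   summary statistics. Pair counts sum to `n_pairs`.
#' @export
describe_cohort <- function(ds) {
  stopifnot(inherits(ds, "twin_cohort"))
  first <- match(unique(ds$pair_id), ds$pair_id)
  size <- as.integer(table(ds$pair_id)[ds$pair_id[first]])
  pairs <- as.data.frame(table(zygosity = ds$zygosity[first],
                               sex = ds$sex[first],
                               complete = size == 2L),
                         stringsAsFactors = FALSE)
  names(pairs)[names(pairs) == "Freq"] <- "n_pairs"
  trs <- traits(ds)
  trait_summary <- data.frame(
    trait = trs,
    n = vapply(trs, function(t) sum(!is.na(ds[[t]])), integer(1)),
    mean = vapply(trs, function(t) mean(ds[[t]], na.rm = TRUE), numeric(1)),
    sd = vapply(trs, function(t) stats::sd(ds[[t]], na.rm = TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(n_individuals = nrow(ds),
       n_pairs = length(first),
       pairs = pairs[pairs$n_pairs > 0L, , drop = FALSE],
       traits = trait_summary)
}

#' @export
print.twin_cohort <- function(x, ...) {
  d <- describe_cohort(x)
  cat("Twin cohort:", d$n_individuals, "individuals in", d$n_pairs,
      "pairs\n")
  cat("Traits:", paste(traits(x), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}
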