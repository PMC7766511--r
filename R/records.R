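#' Cow life-history records
#'
#' A life-history table has one row per cow with columns:
#' \describe{
#'   \item{cow_id}{identifier}
#'   \item{herd_id}{identifier (may be missing before QC)}
#'   \item{birth_date}{`Date`}
#'   \item{first_calving_age}{age at first calving, months}
#'   \item{calving_ages}{list-column of calving ages in months, strictly
#'     increasing, first element equal to `first_calving_age`}
#'   \item{culling_age}{age at culling, fractional years}
#'   \item{culling_reason}{raw reason code (see [default_culling_map()])}
#'   \item{embryo_transfer}{logical}
#' }
#' Optionally `sire_id` (for daughter-sire linkage) and `birth_year_season`
#' (derived if absent: birth year crossed with a two-level season,
#' Jan–Jun / Jul–Dec).
#'
#' @name life_history
NULL

#' Derive the year-season-of-birth label
#'
#' @param birth_date `Date` vector.
#' @return Character labels like `"1995_S1"` (Jan–Jun) / `"1995_S2"`.
#' @export
birth_year_season <- function(birth_date) {
  y <- as.integer(format(birth_date, "%Y"))
  s <- ifelse(as.integer(format(birth_date, "%m")) <= 6, "S1", "S2")
  ifelse(is.na(birth_date), NA_character_, paste0(y, "_", s))
}

#' Quality control of life-history records
#'
#' Applies the standard edits in a fixed order so removal counts are
#' reproducible:
#' \enumerate{
#'   \item missing birth date, herd, culling reason or culling age;
#'   \item duplicated cow ids (more than one culling record);
#'   \item born before `min_birth_year` (default 1990);
#'   \item first calving outside \[19, 30\] months;
#'   \item culling age above 20 years.
#' }
#'
#' @param records life-history tibble (see [life_history]).
#' @param min_birth_year earliest admissible birth year.
#' @param first_calving_window admissible first-calving age, months.
#' @param max_culling_age maximum culling age, years.
#' @return List with `records` (retained rows, with `birth_year_season`
#'   filled in) and `report`, a tibble of per-rule removal counts plus the
#'   retained count; counts add up to the input count.
#' @export
apply_quality_control <- function(records,
                                  min_birth_year = 1990,
                                  first_calving_window = c(19, 30),
                                  max_culling_age = 20) {
  records <- tibble::as_tibble(records)
  n_in <- nrow(records)
  counts <- c(missing_fields = 0L, duplicated_cow = 0L,
              birth_year = 0L, first_calving_age = 0L, culling_age_cap = 0L)

  if (n_in) {
    keep <- !(is.na(records$birth_date) | is.na(records$herd_id) |
                is.na(records$culling_reason) | is.na(records$culling_age))
    counts["missing_fields"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]

    dup <- records$cow_id %in% records$cow_id[duplicated(records$cow_id)]
    counts["duplicated_cow"] <- sum(dup)
    records <- records[!dup, , drop = FALSE]

    by <- as.integer(format(records$birth_date, "%Y"))
    keep <- by >= min_birth_year
    counts["birth_year"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]

    fca <- records$first_calving_age
    keep <- !is.na(fca) & fca >= first_calving_window[1] &
      fca <= first_calving_window[2]
    counts["first_calving_age"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]

    keep <- records$culling_age <= max_culling_age
    counts["culling_age_cap"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }

  if (!"birth_year_season" %in% names(records) ||
      anyNA(records$birth_year_season)) {
    records$birth_year_season <- birth_year_season(records$birth_date)
  }
  report <- tibble::tibble(
    rule = c(names(counts), "retained"),
    n = c(unname(counts), nrow(records))
  )
  stopifnot(sum(report$n) == n_in)
  list(records = records, report = report)
}

#' Default raw-code to culling-group mapping
#'
#' Raw culling-reason codes map to six specific groups; `all_reasons` is
#' their union. Cows culled above 15 years are reassigned to natural death
#' regardless of the recorded code ("culled due to age"), and cows with an
#' unknown reason under 15 years fall to miscellaneous.
#'
#' @return Tibble with columns `code` and `group`.
#' @export
default_culling_map <- function() {
  tibble::tribble(
    ~code,                       ~group,
    "died_unknown",              "natural_death",
    "culled_age",                "natural_death",
    "eye_problem",               "structural_problems",
    "body_structure",            "structural_problems",
    "teat_udder_conformation",   "structural_problems",
    "rectal_prolapse",           "structural_problems",
    "vaginal_prolapse",          "structural_problems",
    "feet_conformation",         "structural_problems",
    "illness_disease",           "disease",
    "fertility",                 "fertility",
    "missed_calving",            "fertility",
    "productivity",              "performance",
    "temperament",               "performance",
    "miscellaneous",             "miscellaneous",
    "sold_commercial",           "miscellaneous",
    "unknown_reason",            "miscellaneous"
  )
}

#' Culling-group levels
#' @param specific_only drop the `all_reasons` union level.
#' @return Character vector of group names.
#' @export
culling_groups <- function(specific_only = FALSE) {
  g <- c("natural_death", "structural_problems", "disease", "fertility",
         "performance", "miscellaneous")
  if (specific_only) g else c(g, "all_reasons")
}

#' Assign a culling group
#'
#' @param raw_code raw reason code(s).
#' @param culling_age culling age(s), years.
#' @param map code-to-group mapping, default [default_culling_map()].
#' @return Character vector of group labels.
#' @export
#' @examples
#' assign_culling_group("unknown_reason", 16)  # natural_death
#' assign_culling_group("unknown_reason", 10)  # miscellaneous
assign_culling_group <- function(raw_code, culling_age,
                                 map = default_culling_map()) {
  raw_code <- as.character(raw_code)
  unknown <- setdiff(unique(raw_code), map$code)
  if (length(unknown)) {
    stop("unmapped culling-reason code(s): ", paste(unknown, collapse = ", "))
  }
  grp <- map$group[match(raw_code, map$code)]
  grp[culling_age > 15] <- "natural_death"
  grp
}

#' Build a binary longevity panel
#'
#' Codes one record per cow and age (2–15 years, 14 slots) under one of
#' the three longevity definitions:
#' \describe{
#'   \item{TL}{traditional longevity: 1 while the cow is alive (her
#'     completed-years culling age is at least the slot age), 0 after
#'     culling;}
#'   \item{FLa}{functional longevity, no missing codes: 1 if a calving is
#'     assigned to the slot, 0 otherwise (culled or simply not calving);}
#'   \item{FLb}{functional longevity with missing codes: 1 if calved at the
#'     slot, 0 for slots after culling, `NA` while alive without a calving
#'     record.}
#' }
#' Ages at events use completed years,
#' `floor(days / 365.25)`; a calving at `m` months is assigned to slot
#' `clamp(round(m / 12), 2, 15)`.
#'
#' @param records QC-passed life-history tibble.
#' @param definition one of `"TL"`, `"FLa"`, `"FLb"`.
#' @param map culling-group mapping for the per-cow group label.
#' @return A `longevity_panel` object: list with `definition`, `cow_ids`,
#'   `codes` (cow x 14 integer matrix, `NA` allowed only for FLb) and
#'   `culling_group`. Use [tidy()] for a long tibble.
#' @export
build_longevity_panel <- function(records, definition = c("TL", "FLa", "FLb"),
                                  map = default_culling_map()) {
  definition <- match.arg(definition)
  records <- tibble::as_tibble(records)
  if (anyNA(records$culling_age)) {
    stop("cow(s) lacking culling age: ",
         paste(utils::head(records$cow_id[is.na(records$culling_age)], 5),
               collapse = ", "))
  }
  ages <- age_grid()
  cull_yr <- floor(records$culling_age)
  calved <- matrix(FALSE, nrow(records), length(ages))
  for (i in seq_len(nrow(records))) {
    ca <- records$calving_ages[[i]]
    if (!length(ca)) next
    # half-up rounding of months to a yearly slot, clamped to the grid
    slots <- pmin(pmax(floor(ca / 12 + 0.5), min(ages)), max(ages))
    calved[i, match(unique(slots), ages)] <- TRUE
  }
  alive <- outer(cull_yr, ages, `>=`)
  codes <- switch(definition,
    TL  = ifelse(alive, 1L, 0L),
    FLa = ifelse(calved, 1L, 0L),
    FLb = ifelse(calved, 1L, ifelse(alive, NA_integer_, 0L))
  )
  dimnames(codes) <- list(records$cow_id, ages)
  structure(
    list(definition = definition,
         cow_ids = records$cow_id,
         codes = codes,
         culling_group = assign_culling_group(records$culling_reason,
                                              records$culling_age, map)),
    class = "longevity_panel"
  )
}

#' @export
print.longevity_panel <- function(x, ...) {
  cat("<longevity_panel> definition:", x$definition, "-", nrow(x$codes),
      "cows x", ncol(x$codes), "ages;", sum(is.na(x$codes)),
      "missing codes\n")
  invisible(x)
}

#' @rdname build_longevity_panel
#' @param x a `longevity_panel`.
#' @param ... unused.
#' @method tidy longevity_panel
#' @export
tidy.longevity_panel <- function(x, ...) {
  tibble::tibble(
    cow_id = rep(x$cow_ids, times = ncol(x$codes)),
    age = rep(as.integer(colnames(x$codes)), each = nrow(x$codes)),
    code = as.integer(x$codes),
    culling_group = rep(x$culling_group, times = ncol(x$codes)),
    definition = x$definition
  ) |>
    dplyr::arrange(.data$cow_id, .data$age)
}

#' Descriptive summary of life histories
#'
#' Per culling group (and overall): number of cows, mean and sample SD of
#' culling age, and the mean number of calvings.
#'
#' @param records QC-passed life-history tibble.
#' @param map culling-group mapping.
#' @return Tibble with one row per group plus an `all_reasons` row.
#' @export
summarize_life_histories <- function(records, map = default_culling_map()) {
  records <- tibble::as_tibble(records)
  records$culling_group <- assign_culling_group(records$culling_reason,
                                                records$culling_age, map)
  records$n_calvings <- vapply(records$calving_ages, length, integer(1))
  one <- function(df, label) {
    tibble::tibble(
      culling_group = label,
      n = nrow(df),
      mean_culling_age = mean(df$culling_age),
      sd_culling_age = stats::sd(df$culling_age),
      mean_calvings = mean(df$n_calvings)
    )
  }
  records |>
    dplyr::group_by(.data$culling_group) |>
    dplyr::group_map(~ one(.x, .y$culling_group)) |>
    dplyr::bind_rows(one(records, "all_reasons"))
}

#' Cumulative cow counts by culling age
#'
#' @param records QC-passed life-history tibble.
#' @return Tibble of completed-years culling age, count, and cumulative
#'   count.
#' @export
culling_age_distribution <- function(records) {
  tibble::tibble(culling_age = floor(records$culling_age)) |>
    dplyr::count(.data$culling_age) |>
    dplyr::arrange(.data$culling_age) |>
    dplyr::mutate(cumulative = cumsum(.data$n))
}

#' Write a longevity panel as long-format delimited text
#'
#' @param panel a `longevity_panel`.
#' @param path output file; codes written with `NA` for missing.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(tidy(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
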