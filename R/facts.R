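# The materialised retrieval (fact) table and ROLAP aggregation.
#
# Grain: one row per clinical entry, in the paper-style wide column layout;
# the concept columns that do not apply to a row's entry kind stay null, and
# a consultation with no clinical entry keeps exactly one all-null-codes row.
# A literal star join of diagnoses x drugs x labs would cartesian-multiply
# the entries of a visit; the long grain preserves the finest granularity
# without inflating counts.

FACT_COLUMNS <- c(
  "regional_health_name", "health_district_name",
  "health_care_facility_name", "health_care_service_name",
  "num_examination", "code_icd10_or_icpc2", "code_atc", "code_loinc",
  "examination_date", "patient_sex", "patient_age", "patient_nationality",
  "patient_habitation",
  "local_concept_diagnosis", "standard_concept_diagnosis",
  "local_concept_medicine", "standard_concept_medicine",
  "local_concept_biology", "standard_concept_biology"
)

GEO_DIMENSIONS <- FACT_COLUMNS[1:4]

#' Build the fact (retrieval) table
#'
#' Materialises one wide row per clinical entry of every consultation, with
#' the geography columns resolved from the pyramid and the code column of
#' the entry's family populated (`code_icd10_or_icpc2` for diagnoses,
#' `code_atc` for drugs, `code_loinc` for laboratory tests). Consultations
#' without any entry contribute one all-null-codes row so no visit
#' disappears from the warehouse. Rows are ordered deterministically by
#' `num_examination`, entry kind, then code.
#'
#' @param reg a `register_set`, normally after [attach_mappings()].
#' @param pyramid the `health_pyramid` used at parse time.
#' @return a `fact_table` (data frame with the exact `FACT_COLUMNS` layout).
#' @export
build_fact_table <- function(reg, pyramid) {
  stopifnot(inherits(reg, "register_set"))
  records <- reg$records
  entries <- reg$entries
  if (!"code" %in% names(entries)) {
    entries$code <- NA_character_
    entries$system <- NA_character_
    entries$standard_term <- NA_character_
    entries$score <- NA_real_
    entries$accepted <- FALSE
  }

  geo <- geography_table(pyramid)
  gi <- match(records$service_id, geo$service_id)
  if (anyNA(gi)) {
    hf_validation_error(sprintf(
      "unresolvable service id(s): %s",
      paste(unique(records$service_id[is.na(gi)]), collapse = ", ")))
  }

  base <- data.frame(
    regional_health_name = geo$regional_health_name[gi],
    health_district_name = geo$health_district_name[gi],
    health_care_facility_name = geo$health_care_facility_name[gi],
    health_care_service_name = geo$health_care_service_name[gi],
    num_examination = records$num_examination,
    examination_date = records$examination_date,
    patient_sex = records$patient_sex,
    patient_age = records$patient_age,
    patient_nationality = records$patient_nationality,
    patient_habitation = records$patient_residence,
    stringsAsFactors = FALSE
  )
  for (col in names(base)) {
    if (is.character(base[[col]])) base[[col]][base[[col]] == ""] <- NA_character_
  }

  n_entries <- integer(nrow(records))
  tab <- table(entries$num_examination)
  n_entries <- as.integer(tab[records$num_examination])
  n_entries[is.na(n_entries)] <- 0L

  # entry rows
  ei <- match(entries$num_examination, records$num_examination)
  facts_e <- base[ei, , drop = FALSE]
  if (nrow(entries) == 0) {
    for (col in setdiff(FACT_COLUMNS, names(facts_e))) facts_e[[col]] <- character(0)
    facts_e$.kind <- character(0)
    facts_e$.code <- character(0)
  } else {
  facts_e$code_icd10_or_icpc2 <- ifelse(entries$kind == "diagnosis", entries$code, NA_character_)
  facts_e$code_atc <- ifelse(entries$kind == "drug", entries$code, NA_character_)
  facts_e$code_loinc <- ifelse(entries$kind == "laboratory", entries$code, NA_character_)
  facts_e$local_concept_diagnosis <- ifelse(entries$kind == "diagnosis", entries$local_term, NA_character_)
  facts_e$standard_concept_diagnosis <- ifelse(entries$kind == "diagnosis", entries$standard_term, NA_character_)
  facts_e$local_concept_medicine <- ifelse(entries$kind == "drug", entries$local_term, NA_character_)
  facts_e$standard_concept_medicine <- ifelse(entries$kind == "drug", entries$standard_term, NA_character_)
  facts_e$local_concept_biology <- ifelse(entries$kind == "laboratory", entries$local_term, NA_character_)
  facts_e$standard_concept_biology <- ifelse(entries$kind == "laboratory", entries$standard_term, NA_character_)
  facts_e$.kind <- entries$kind
  facts_e$.code <- entries$code
  }

  # one all-null row per entry-less consultation
  empty <- base[n_entries == 0L, , drop = FALSE]
  if (nrow(empty) > 0) {
    for (col in setdiff(FACT_COLUMNS, names(empty))) empty[[col]] <- NA_character_
    empty$.kind <- NA_character_
    empty$.code <- NA_character_
  }

  facts <- rbind(facts_e[, c(FACT_COLUMNS, ".kind", ".code")],
                 if (nrow(empty) > 0) empty[, c(FACT_COLUMNS, ".kind", ".code")])
  ord <- order(facts$num_examination,
               match(facts$.kind, ENTRY_KINDS),
               facts$.code,
               method = "radix", na.last = TRUE)
  facts <- facts[ord, FACT_COLUMNS, drop = FALSE]
  rownames(facts) <- NULL
  class(facts) <- c("fact_table", "data.frame")
  facts
}

#' @export
print.fact_table <- function(x, ...) {
  cat("<fact_table> ", nrow(x), " rows, ",
      length(unique(x$num_examination)), " distinct consultations\n", sep = "")
  invisible(x)
}

fact_dimensions <- function() {
  c(GEO_DIMENSIONS, "examination_date", "patient_sex", "age_band",
    "patient_nationality",
    "code_icd10_or_icpc2", "code_atc", "code_loinc",
    "local_concept_diagnosis", "standard_concept_diagnosis",
    "local_concept_medicine", "standard_concept_medicine",
    "local_concept_biology", "standard_concept_biology")
}

#' Default age bands
#'
#' Lower bounds of the default reporting age bands 0-4, 5-14, 15-49, 50+.
#' @export
default_age_breaks <- function() c(0, 5, 15, 50)

age_band_labels <- function(breaks) {
  upper <- c(breaks[-1] - 1, NA)
  ifelse(is.na(upper), sprintf("%d+", breaks), sprintf("%d-%d", breaks, upper))
}

time_grain_label <- function(dates, grain) {
  switch(grain,
    day = format(dates, "%Y-%m-%d"),
    week = format(dates, "%G-W%V"),   # ISO-8601 week
    month = format(dates, "%Y-%m"),
    year = format(dates, "%Y"),
    hf_validation_error(sprintf("unknown time grain: %s", grain))
  )
}

#' ROLAP aggregation over the fact table
#'
#' Groups the fact table by any combination of documented dimensions
#' (geography names, `examination_date` at a day/week/month/year grain,
#' `patient_sex`, `age_band`, `patient_nationality`, or a code/concept
#' column) and computes per group: `consultation_count` (distinct
#' `num_examination`), `entry_count` (rows carrying a clinical entry) and
#' `share` (group consultation count over the total distinct consultations
#' within the filter scope).
#'
#' @param facts a `fact_table`.
#' @param group_by character vector of dimension names.
#' @param filters named list: fact column -> vector of values to keep.
#' @param time_grain one of `"day"`, `"week"`, `"month"`, `"year"`; required
#'   when `examination_date` is grouped on.
#' @param age_breaks lower bounds of the age bands (default 0, 5, 15, 50).
#' @return a `fact_cube`: data frame of group keys plus the three measures,
#'   with the grouping recorded in attributes for [drill_down()].
#' @export
aggregate_facts <- function(facts, group_by, filters = NULL, time_grain = NULL,
                            age_breaks = default_age_breaks()) {
  stopifnot(is.data.frame(facts))
  bad <- setdiff(group_by, fact_dimensions())
  if (length(bad) > 0) {
    hf_validation_error(sprintf("unknown dimension(s): %s", paste(bad, collapse = ", ")))
  }
  if ("examination_date" %in% group_by && is.null(time_grain)) {
    hf_validation_error("grouping by examination_date requires a time_grain")
  }
  if (!is.null(time_grain) && !time_grain %in% c("day", "week", "month", "year")) {
    hf_validation_error(sprintf("unknown time grain: %s", time_grain))
  }

  f <- as.data.frame(facts)
  if (!is.null(filters)) {
    for (col in names(filters)) {
      if (!col %in% names(f)) hf_validation_error(sprintf("unknown filter column: %s", col))
      f <- f[!is.na(f[[col]]) & f[[col]] %in% filters[[col]], , drop = FALSE]
    }
  }
  total <- length(unique(f$num_examination))

  if (nrow(f) == 0 || total == 0) {
    out <- stats::setNames(
      as.data.frame(matrix(character(0), 0, length(group_by))), group_by)
    out$consultation_count <- integer(0)
    out$entry_count <- integer(0)
    out$share <- numeric(0)
    class(out) <- c("fact_cube", "data.frame")
    attr(out, "group_by") <- group_by
    attr(out, "filters") <- filters
    attr(out, "time_grain") <- time_grain
    attr(out, "age_breaks") <- age_breaks
    attr(out, "scope_total") <- 0L
    return(out)
  }

  keys <- lapply(group_by, function(dim) {
    if (dim == "examination_date") {
      time_grain_label(f$examination_date, time_grain)
    } else if (dim == "age_band") {
      labs <- age_band_labels(age_breaks)
      idx <- findInterval(f$patient_age, age_breaks)
      ifelse(is.na(f$patient_age) | idx == 0, NA_character_, labs[idx])
    } else {
      f[[dim]]
    }
  })
  names(keys) <- group_by
  key_str <- do.call(paste, c(lapply(keys, function(k) ifelse(is.na(k), "\r<NA>", k)),
                              sep = "\r"))

  has_entry <- !is.na(f$code_icd10_or_icpc2) | !is.na(f$code_atc) |
    !is.na(f$code_loinc) |
    !is.na(f$local_concept_diagnosis) | !is.na(f$local_concept_medicine) |
    !is.na(f$local_concept_biology)

  groups <- sort(unique(key_str))
  gidx <- match(key_str, groups)
  consultation_count <- vapply(seq_along(groups), function(g) {
    length(unique(f$num_examination[gidx == g]))
  }, integer(1))
  entry_count <- vapply(seq_along(groups), function(g) {
    sum(has_entry[gidx == g])
  }, integer(1))

  first <- match(groups, key_str)
  out <- as.data.frame(lapply(keys, function(k) k[first]), stringsAsFactors = FALSE,
                       optional = TRUE)
  names(out) <- group_by
  out$consultation_count <- consultation_count
  out$entry_count <- entry_count
  out$share <- consultation_count / total
  rownames(out) <- NULL
  class(out) <- c("fact_cube", "data.frame")
  attr(out, "group_by") <- group_by
  attr(out, "filters") <- filters
  attr(out, "time_grain") <- time_grain
  attr(out, "age_breaks") <- age_breaks
  attr(out, "scope_total") <- total
  out
}

geo_level_of_column <- function(col) {
  c(regional_health_name = "region", health_district_name = "district",
    health_care_facility_name = "facility", health_care_service_name = "service")[[col]]
}

geo_column_of_level <- function(level) {
  c(region = "regional_health_name", district = "health_district_name",
    facility = "health_care_facility_name", service = "health_care_service_name")[[level]]
}

#' Drill a cube down to a finer geographic level
#'
#' Re-aggregates the same measures at a geographic level strictly below the
#' cube's current one, keeping all ancestor name columns in the grouping so
#' that facilities or services with colliding names in different branches
#' stay separate. The children's measure sums reproduce the parent values
#' exactly (roll-up conservation).
#'
#' @param cube a `fact_cube` whose grouping includes a geographic dimension.
#' @param facts the `fact_table` the cube was computed from.
#' @param child_level target level, strictly below the cube's geographic
#'   level (e.g. from district down to `"facility"`).
#' @return a `fact_cube` at the finer level.
#' @export
drill_down <- function(cube, facts, child_level) {
  group_by <- attr(cube, "group_by")
  geo_cols <- intersect(GEO_DIMENSIONS, group_by)
  if (length(geo_cols) == 0) {
    hf_validation_error("cube has no geographic dimension to drill from")
  }
  cur_level <- geo_level_of_column(geo_cols[length(geo_cols)])
  if (!child_level %in% c("region", "district", "facility", "service")) {
    hf_validation_error(sprintf("unknown geographic level: %s", child_level))
  }
  if (level_rank(child_level) <= level_rank(cur_level)) {
    hf_validation_error(sprintf(
      "child level '%s' is not below the cube's level '%s'", child_level, cur_level))
  }
  path_cols <- vapply(pyramid_levels()[2:level_rank(child_level)],
                      geo_column_of_level, character(1))
  new_group <- unique(c(setdiff(group_by, GEO_DIMENSIONS), path_cols))
  # keep geography first for readability
  new_group <- c(path_cols, setdiff(new_group, path_cols))
  aggregate_facts(facts, new_group,
                  filters = attr(cube, "filters"),
                  time_grain = attr(cube, "time_grain"),
                  age_breaks = attr(cube, "age_breaks"))
}

#' Export the fact table to CSV
#'
#' Writes the exact `FACT_COLUMNS` order; [load_facts()] restores a
#' byte-equivalent table (lossless round trip).
#'
#' @param facts a `fact_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_facts <- function(facts, path) {
  stopifnot(is.data.frame(facts))
  write_hf_csv(as.data.frame(facts)[, FACT_COLUMNS], path)
}

#' Load a fact table from CSV
#'
#' @param path path written by [export_facts()].
#' @return a `fact_table`.
#' @export
load_facts <- function(path) {
  df <- read_hf_csv(path)
  if (!identical(names(df), FACT_COLUMNS)) {
    hf_validation_error(sprintf(
      "fact file %s does not have the expected column layout (missing/extra: %s)",
      path,
      paste(c(setdiff(FACT_COLUMNS, names(df)), setdiff(names(df), FACT_COLUMNS)),
            collapse = ", ")))
  }
  for (col in names(df)) df[[col]][df[[col]] == ""] <- NA_character_
  df$examination_date <- parse_iso_date(df$examination_date)
  df$patient_age <- suppressWarnings(as.integer(df$patient_age))
  class(df) <- c("fact_table", "data.frame")
  df
}
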