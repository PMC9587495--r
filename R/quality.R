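# Data-quality audit: the three dimensions routinely assessed on health
# information systems — completeness (all data recorded), timeliness
# (available by the 5th of the following month), accuracy (conforming to the
# source register) — plus scoring of paired user-evaluation questionnaires
# and an exact binomial McNemar comparison.

#' Field completeness of consultation records
#'
#' Percentage of filled cells among the required fields:
#' `100 * filled / (records * fields)`. A cell is filled when it is neither
#' `NA` nor an empty string.
#'
#' @param records data frame of consultation records (e.g. the `records`
#'   element of a `register_set`).
#' @param required_fields column names audited for completeness.
#' @return percentage in \[0, 100\].
#' @export
field_completeness <- function(records, required_fields) {
  if (nrow(records) == 0) hf_validation_error("no records to audit")
  missing <- setdiff(required_fields, names(records))
  if (length(missing) > 0 || length(required_fields) == 0) {
    hf_validation_error(sprintf("required_fields must be a non-empty subset of record fields (unknown: %s)",
                                paste(missing, collapse = ", ")))
  }
  filled <- vapply(required_fields, function(col) {
    v <- records[[col]]
    sum(!is.na(v) & (!is.character(v) | nzchar(v)))
  }, numeric(1))
  100 * sum(filled) / (nrow(records) * length(required_fields))
}

report_key <- function(df) paste(df$facility, df$month, sep = "\r")

#' Reporting completeness over a facility-month grid
#'
#' Percentage of expected monthly reports actually received:
#' `100 * |expected intersect received| / |expected|`. A missing report also
#' counts as late in [timeliness()]; absence must be visible to both
#' dimensions.
#'
#' @param expected,received data frames with columns `facility` and `month`
#'   (`"YYYY-MM"`).
#' @return percentage in \[0, 100\].
#' @export
reporting_completeness <- function(expected, received) {
  if (nrow(expected) == 0) hf_validation_error("expected report set is empty")
  100 * sum(report_key(expected) %in% report_key(received)) / nrow(expected)
}

month_end <- function(month) {
  first <- as.Date(paste0(month, "-01"), format = "%Y-%m-%d")
  if (anyNA(first)) {
    hf_validation_error(sprintf("malformed month key(s): %s",
                                paste(unique(month[is.na(first)]), collapse = ", ")))
  }
  seq_month <- seq_len(length(first))
  nxt <- as.Date(vapply(seq_month, function(i) {
    format(seq(first[i], by = "1 month", length.out = 2)[2], "%Y-%m-%d")
  }, character(1)))
  nxt - 1
}

#' Timeliness of monthly report submission
#'
#' A report for month M is on time iff it was submitted on or before day
#' `deadline_day` (default the 5th) of month M+1. The delay of a submitted
#' report is the number of days after the end of month M until submission,
#' floored at 0. A missing submission date counts as late but contributes no
#' delay value, so the mean delay stays finite.
#'
#' @param report_dates data frame with columns `facility`, `month`
#'   (`"YYYY-MM"`) and `submission_date` (ISO date string or `NA` when the
#'   report never arrived).
#' @param deadline_day day of the following month that closes the window.
#' @return list with `on_time_pct`, `mean_delay_days` and a `per_report`
#'   data frame (`facility`, `month`, `on_time`, `delay_days`).
#' @export
timeliness <- function(report_dates, deadline_day = 5) {
  stopifnot(all(c("facility", "month", "submission_date") %in% names(report_dates)))
  if (nrow(report_dates) == 0) hf_validation_error("no reports to audit")
  end <- month_end(report_dates$month)
  deadline <- end + deadline_day
  sub <- report_dates$submission_date
  if (!inherits(sub, "Date")) {
    sub_chr <- as.character(sub)
    sub <- parse_iso_date(ifelse(is.na(sub_chr) | sub_chr == "", NA_character_, sub_chr))
  }
  on_time <- !is.na(sub) & sub <= deadline
  delay <- as.numeric(pmax(0, sub - end))
  per_report <- data.frame(
    facility = report_dates$facility, month = report_dates$month,
    on_time = on_time, delay_days = delay, stringsAsFactors = FALSE
  )
  list(
    on_time_pct = 100 * mean(on_time),
    mean_delay_days = if (all(is.na(delay))) NA_real_ else mean(delay, na.rm = TRUE),
    per_report = per_report
  )
}

#' Accuracy as conformity between warehouse facts and source registers
#'
#' Percentage of register consultations whose fact-derived field values
#' (examination date, sex, age, nationality, residence) all equal the source
#' register values. Consultations absent from the fact table count as
#' nonconforming.
#'
#' @param facts a `fact_table`.
#' @param source_records data frame of source consultation records keyed by
#'   `num_examination` (unique).
#' @return percentage in \[0, 100\].
#' @export
accuracy_conformity <- function(facts, source_records) {
  if (anyDuplicated(source_records$num_examination)) {
    hf_validation_error("key collision: duplicate num_examination in source records")
  }
  if (nrow(source_records) == 0) hf_validation_error("no source records to audit")
  f <- as.data.frame(facts)
  first <- f[!duplicated(f$num_examination), , drop = FALSE]
  i <- match(source_records$num_examination, first$num_examination)

  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == ""] <- "\r<NA>"
    x
  }
  pairs <- rbind(
    c("examination_date", "examination_date"),
    c("patient_sex", "patient_sex"),
    c("patient_age", "patient_age"),
    c("patient_nationality", "patient_nationality"),
    c("patient_residence", "patient_habitation")
  )
  ok <- !is.na(i)
  for (r in seq_len(nrow(pairs))) {
    src <- norm(source_records[[pairs[r, 1]]])
    fct <- norm(first[[pairs[r, 2]]][i])
    ok <- ok & !is.na(fct) & src == fct
  }
  100 * sum(ok) / nrow(source_records)
}

check_evaluation_matrix <- function(matrix) {
  need <- c("user_id", "criterion_id", "dimension", "system", "response")
  missing <- setdiff(need, names(matrix))
  if (length(missing) > 0) {
    hf_validation_error(sprintf("evaluation matrix is missing column(s): %s",
                                paste(missing, collapse = ", ")))
  }
  if (nrow(matrix) == 0) hf_validation_error("evaluation matrix is empty")
  # a criterion must live in exactly one dimension
  cd <- unique(matrix[, c("criterion_id", "dimension")])
  if (anyDuplicated(cd$criterion_id)) {
    hf_validation_error("a criterion is assigned to more than one dimension")
  }
  users <- unique(matrix$user_id)
  criteria <- unique(matrix$criterion_id)
  systems <- unique(matrix$system)
  expect <- length(users) * length(criteria) * length(systems)
  key <- paste(matrix$user_id, matrix$criterion_id, matrix$system, sep = "\r")
  if (anyDuplicated(key) || length(key) != expect) {
    hf_validation_error("evaluation matrix is not a complete users x criteria x systems grid")
  }
  if (!all(matrix$response %in% c(0, 1))) {
    hf_validation_error("responses must be binary 0/1")
  }
  invisible(matrix)
}

#' Score a paired system-evaluation matrix
#'
#' Computes, per system: the per-criterion yes percentage
#' (`100 * yes / users`), the per-dimension aggregate as the pooled yes
#' fraction over users x criteria of the dimension, and the overall pooled
#' percentage. Display values are rounded half-away-from-zero; raw
#' fractions are kept.
#'
#' @param matrix long data frame with columns `user_id`, `criterion_id`,
#'   `dimension`, `system`, `response` (0/1); a complete grid.
#' @return list of class `evaluation_scores` with data frames `criteria`,
#'   `dimensions` and `overall`.
#' @export
score_evaluation <- function(matrix) {
  check_evaluation_matrix(matrix)
  n_users <- length(unique(matrix$user_id))

  agg <- function(split_cols) {
    key <- interaction(matrix[split_cols], drop = TRUE, sep = "\r", lex.order = TRUE)
    yes <- tapply(matrix$response, key, sum)
    tot <- tapply(matrix$response, key, length)
    parts <- do.call(rbind, strsplit(names(yes), "\r", fixed = TRUE))
    out <- stats::setNames(as.data.frame(parts, stringsAsFactors = FALSE), split_cols)
    out$yes <- as.integer(yes)
    out$total <- as.integer(tot)
    out$pct_raw <- 100 * out$yes / out$total
    out$pct <- round_half_up(out$pct_raw)
    rownames(out) <- NULL
    out
  }

  criteria <- agg(c("system", "dimension", "criterion_id"))
  criteria$n_users <- n_users
  dimensions <- agg(c("system", "dimension"))
  overall <- agg("system")

  structure(list(criteria = criteria, dimensions = dimensions, overall = overall),
            class = "evaluation_scores")
}

#' @export
print.evaluation_scores <- function(x, ...) {
  cat("<evaluation_scores>\n")
  for (i in seq_len(nrow(x$dimensions))) {
    d <- x$dimensions[i, ]
    cat(sprintf("  %-12s %-13s %3d%% (%d/%d)\n",
                d$system, d$dimension, d$pct, d$yes, d$total))
  }
  invisible(x)
}

#' Completeness bands declared by users
#'
#' Tallies users' achievable-completeness estimates into the reporting bands
#' `<30`, `30-50`, `50-80`, `>=80` percent.
#'
#' @param estimates character vector of band labels, or a data frame with a
#'   `band` column (optionally split by a `system` column).
#' @return data frame with `band`, `count`, `pct_raw`, `pct` (and `system`
#'   when present in the input).
#' @export
completeness_categories <- function(estimates) {
  bands <- c("<30", "30-50", "50-80", ">=80")
  if (is.data.frame(estimates)) {
    if (!"band" %in% names(estimates)) hf_validation_error("estimates need a 'band' column")
    if ("system" %in% names(estimates)) {
      out <- do.call(rbind, lapply(split(estimates, estimates$system), function(s) {
        r <- completeness_categories(s$band)
        cbind(system = s$system[1], r, stringsAsFactors = FALSE)
      }))
      rownames(out) <- NULL
      return(out)
    }
    estimates <- estimates$band
  }
  bad <- setdiff(unique(estimates), bands)
  if (length(bad) > 0) {
    hf_validation_error(sprintf("unknown band label(s): %s (expected %s)",
                                paste(bad, collapse = ", "), paste(bands, collapse = ", ")))
  }
  counts <- as.integer(table(factor(estimates, levels = bands)))
  data.frame(
    band = bands,
    count = counts,
    pct_raw = 100 * counts / length(estimates),
    pct = round_half_up(100 * counts / length(estimates)),
    stringsAsFactors = FALSE
  )
}

#' Exact binomial McNemar test
#'
#' Two-sided exact test on the discordant pairs of a paired binary
#' comparison: with `b` pairs positive only under the first condition and
#' `c` only under the second,
#' `p = min(1, 2 * P(Bin(b + c, 1/2) >= max(b, c)))`.
#' Chosen over the chi-square approximation because evaluation panels are
#' small (here 14 respondents) and the exact form is deterministic.
#'
#' @param b,c non-negative discordant-pair counts with `b + c >= 1`.
#' @return p-value in (0, 1\].
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0 || b + c < 1) {
    hf_validation_error("b and c must be non-negative with b + c >= 1")
  }
  n <- b + c
  k <- max(b, c)
  p <- 2 * stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, p)
}

#' Worst-case McNemar p-value from marginal yes-counts
#'
#' Published evaluations often print only marginal yes-counts per system,
#' not the individual pairings. This enumerates every paired 2x2 table
#' consistent with the marginals — discordant cells `(b, c)` with
#' `b - c = yes_new - yes_old` and all four cells non-negative — and returns
#' the maximum exact McNemar p-value over them: an upper bound on the
#' p-value whatever the true pairing was.
#'
#' @param yes_new,yes_old yes-counts for the two systems.
#' @param n number of paired responses (users x criteria).
#' @return list of class `mcnemar_bound` with `p_value` (the maximum),
#'   and `tables` (one row per feasible `(b, c)` with its p-value).
#' @export
mcnemar_bound_from_marginals <- function(yes_new, yes_old, n) {
  if (yes_new < 0 || yes_old < 0 || yes_new > n || yes_old > n) {
    hf_validation_error("marginals must satisfy 0 <= yes <= n")
  }
  d <- yes_new - yes_old
  c_vals <- 0:min(yes_old, n - yes_new)
  b_vals <- c_vals + d
  keep <- b_vals >= 0 & b_vals <= yes_new & (n - yes_new - c_vals) >= 0
  b_vals <- b_vals[keep]; c_vals <- c_vals[keep]
  if (length(b_vals) == 0 || all(b_vals + c_vals == 0)) {
    if (length(b_vals) > 0 && d == 0) {
      # the only feasible table may be fully concordant: no evidence either way
      return(structure(list(p_value = 1,
                            tables = data.frame(b = b_vals, c = c_vals, p = 1)),
                       class = "mcnemar_bound"))
    }
    hf_validation_error("no paired table is consistent with these marginals")
  }
  p <- vapply(seq_along(b_vals), function(i) {
    if (b_vals[i] + c_vals[i] == 0) 1 else mcnemar_exact(b_vals[i], c_vals[i])
  }, numeric(1))
  structure(
    list(p_value = max(p),
         tables = data.frame(b = b_vals, c = c_vals, p = p)),
    class = "mcnemar_bound"
  )
}

#' @export
print.mcnemar_bound <- function(x, ...) {
  cat("<mcnemar_bound> max exact p =", format(x$p_value, digits = 4),
      "over", nrow(x$tables), "feasible pairing(s)\n")
  invisible(x)
}

#' Full data-quality report
#'
#' Convenience wrapper computing every quality dimension in one pass, with
#' per-facility breakdowns.
#'
#' @param reg a `register_set` (the audited warehouse input).
#' @param facts the `fact_table` built from it.
#' @param pyramid the `health_pyramid`.
#' @param submissions data frame `facility`, `month`, `submission_date`
#'   (the monthly report calendar), or `NULL` to skip timeliness.
#' @param expected_reports data frame `facility`, `month` of expected
#'   reports; defaults to the rows of `submissions`.
#' @param required_fields fields audited by [field_completeness()].
#' @param source_records register records to check conformity against;
#'   defaults to `reg$records` (a self-check that must give 100).
#' @param deadline_day see [timeliness()].
#' @return list of class `quality_report`.
#' @export
quality_report <- function(reg, facts, pyramid, submissions = NULL,
                           expected_reports = NULL,
                           required_fields = c("patient_sex", "patient_age",
                                               "patient_nationality", "patient_residence",
                                               "insurance_status", "occupation"),
                           source_records = NULL, deadline_day = 5) {
  source_records <- source_records %||% reg$records
  out <- list(
    field_completeness_pct = field_completeness(reg$records, required_fields),
    accuracy_pct = accuracy_conformity(facts, source_records)
  )
  f <- as.data.frame(facts)
  fac_of <- f$health_care_facility_name[!duplicated(f$num_examination)]
  out$per_facility <- data.frame(
    facility = sort(unique(fac_of)),
    consultations = as.integer(table(fac_of)[sort(unique(fac_of))]),
    stringsAsFactors = FALSE
  )
  if (!is.null(submissions)) {
    expected_reports <- expected_reports %||% submissions[, c("facility", "month")]
    received <- submissions[!is.na(submissions$submission_date) &
                              nzchar(as.character(submissions$submission_date)),
                            c("facility", "month")]
    tl <- timeliness(submissions, deadline_day = deadline_day)
    out$reporting_completeness_pct <- reporting_completeness(expected_reports, received)
    out$timeliness_pct <- tl$on_time_pct
    out$mean_delay_days <- tl$mean_delay_days
    out$per_report <- tl$per_report
  }
  class(out) <- "quality_report"
  out
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  field completeness: %5.1f%%\n", x$field_completeness_pct))
  if (!is.null(x$reporting_completeness_pct)) {
    cat(sprintf("  reporting completeness: %5.1f%%\n", x$reporting_completeness_pct))
    cat(sprintf("  timeliness: %5.1f%% on time, mean delay %.1f days\n",
                x$timeliness_pct, x$mean_delay_days))
  }
  cat(sprintf("  accuracy (register conformity): %5.1f%%\n", x$accuracy_pct))
  invisible(x)
}
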