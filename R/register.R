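# Ingest of identity-free register replicas. One CSV row = one consultation;
# the clinical entries of a visit (several diagnoses, prescriptions, lab
# requests are common) are packed into three pipe-separated columns.

REGISTER_COLUMNS <- c(
  "num_examination", "examination_date", "recorded_at", "service_id",
  "patient_sex", "patient_age", "patient_nationality", "patient_residence",
  "insurance_status", "government_coverage", "occupation", "copayment_rate",
  "diagnoses", "drugs", "labs"
)

ENTRY_KINDS <- c("diagnosis", "drug", "laboratory")

# clinical entry kind -> terminology systems allowed for its mappings
KIND_SYSTEMS <- list(
  diagnosis  = c("ICD10", "ICPC2"),
  drug       = "ATC",
  laboratory = "LOINC"
)

#' Default identity-column blocklist
#'
#' Register replicas must be identity-free. If a register file contains any
#' of these columns the whole file is refused, never partially ingested.
#'
#' @export
identity_blocklist <- function() {
  c("name", "surname", "phone", "national_id")
}

parse_iso_date <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d", optional = TRUE)
  # reject partial matches such as "2018-1-5" vs round-trip
  d[!is.na(d) & format(d, "%Y-%m-%d") != x] <- NA
  d
}

split_packed <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  parts <- trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

#' Parse a consultation-register file
#'
#' Reads a register CSV (see `REGISTER_COLUMNS` for the documented header),
#' validates every row against the loaded pyramid, and splits valid rows
#' into typed consultation records plus a long table of clinical entries.
#' Invalid rows are rejected with machine-readable reasons, never silently
#' dropped. The presence of any identity column (default blocklist: name,
#' surname, phone, national_id) aborts the whole file.
#'
#' @param path path to the register CSV.
#' @param pyramid a `health_pyramid`; `service_id` values must resolve to
#'   service-level nodes.
#' @param blocklist identity column names that force a hard abort.
#' @return a `register_set`: list with `records` (typed data frame, one row
#'   per accepted consultation), `entries` (long data frame:
#'   `num_examination`, `kind`, `local_term`), and `rejections`
#'   (`row_number`, `reason_code`, `detail`).
#' @export
parse_register <- function(path, pyramid, blocklist = identity_blocklist()) {
  df <- read_hf_csv(path)
  hit <- intersect(tolower(names(df)), blocklist)
  if (length(hit) > 0) {
    hf_validation_error(
      sprintf("register file %s contains identity column(s): %s; file refused",
              path, paste(hit, collapse = ", ")),
      identity_columns = hit
    )
  }
  missing <- setdiff(REGISTER_COLUMNS, names(df))
  if (length(missing) > 0) {
    hf_validation_error(sprintf("register file %s is missing column(s): %s",
                                path, paste(missing, collapse = ", ")))
  }
  df <- df[, REGISTER_COLUMNS]
  as_register_set(df, pyramid)
}

#' Build a register set from an in-memory register table
#'
#' Same validation as [parse_register()] but starting from a data frame in
#' the register-CSV layout.
#'
#' @param df data frame with the register columns (all character).
#' @param pyramid a `health_pyramid`.
#' @return a `register_set`.
#' @export
as_register_set <- function(df, pyramid) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
  n <- nrow(df)

  services <- pyramid$node_id[pyramid$level == "service"]
  exam_date <- parse_iso_date(df$examination_date)
  rec_date <- parse_iso_date(df$recorded_at)
  age <- suppressWarnings(as.integer(df$patient_age))
  copay <- suppressWarnings(as.numeric(df$copayment_rate))

  reason <- character(n)
  detail <- character(n)
  flag <- function(bad, code, det) {
    new <- bad & !nzchar(reason)
    reason[new] <<- code
    detail[new] <<- det[new]
  }

  flag(!df$service_id %in% services, "unknown_service",
       sprintf("service_id '%s' not a service node of the pyramid", df$service_id))
  flag(is.na(exam_date), "bad_date",
       sprintf("examination_date '%s' is not an ISO 8601 date", df$examination_date))
  flag(is.na(rec_date), "bad_date",
       sprintf("recorded_at '%s' is not an ISO 8601 date", df$recorded_at))
  flag(!is.na(exam_date) & !is.na(rec_date) & rec_date < exam_date,
       "recorded_before_exam",
       sprintf("recorded_at %s precedes examination_date %s", df$recorded_at, df$examination_date))
  flag(nzchar(df$patient_age) & (is.na(age) | age < 0), "bad_age",
       sprintf("patient_age '%s' is not a non-negative integer", df$patient_age))
  flag(nzchar(df$patient_sex) & !df$patient_sex %in% c("F", "M", "unknown"), "bad_sex",
       sprintf("patient_sex '%s' not one of F, M, unknown", df$patient_sex))
  flag(nzchar(df$copayment_rate) & (is.na(copay) | copay < 0 | copay > 1), "bad_copayment",
       sprintf("copayment_rate '%s' not in [0, 1]", df$copayment_rate))
  flag(!nzchar(df$num_examination), "missing_num_examination",
       rep("num_examination is empty", n))
  flag(duplicated(df$num_examination) & nzchar(df$num_examination), "duplicate_num_examination",
       sprintf("num_examination '%s' already seen", df$num_examination))

  keep <- !nzchar(reason)
  rejections <- data.frame(
    row_number = which(!keep),
    reason_code = reason[!keep],
    detail = detail[!keep],
    stringsAsFactors = FALSE
  )

  records <- df[keep, , drop = FALSE]
  entries <- register_entries(records)

  records$examination_date <- exam_date[keep]
  records$recorded_at <- rec_date[keep]
  records$patient_age <- age[keep]
  records$copayment_rate <- copay[keep]
  records$government_coverage <- ifelse(
    records$government_coverage %in% c("true", "TRUE", "1", "yes"), TRUE,
    ifelse(records$government_coverage %in% c("false", "FALSE", "0", "no"), FALSE, NA)
  )
  rownames(records) <- NULL

  structure(
    list(records = records, entries = entries, rejections = rejections),
    class = "register_set"
  )
}

# unpack the three packed entry columns into one long table
register_entries <- function(records) {
  cols <- c(diagnosis = "diagnoses", drug = "drugs", laboratory = "labs")
  out <- list()
  for (kind in names(cols)) {
    terms <- lapply(records[[cols[[kind]]]], split_packed)
    counts <- lengths(terms)
    if (sum(counts) == 0) next
    out[[kind]] <- data.frame(
      num_examination = rep(records$num_examination, counts),
      kind = kind,
      local_term = unlist(terms, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(num_examination = character(0), kind = character(0),
                      local_term = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$num_examination, records$num_examination),
                   match(res$kind, ENTRY_KINDS)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Serialize accepted records back to the register-CSV layout
#'
#' Inverse of [parse_register()] on the accepted rows: writing then
#' re-parsing reproduces the same records and entries.
#'
#' @param reg a `register_set`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_register <- function(reg, path) {
  stopifnot(inherits(reg, "register_set"))
  df <- reg$records[, REGISTER_COLUMNS]
  df$copayment_rate <- ifelse(is.na(df$copayment_rate), "",
                              sprintf("%.4g", df$copayment_rate))
  write_hf_csv(df, path)
}

#' Attach terminology mappings to the clinical entries of a register set
#'
#' Maps every distinct local term against the dictionary of its entry kind
#' (diagnoses against ICD-10/ICPC-2, drugs against ATC, laboratory tests
#' against LOINC) and attaches the best accepted candidate. Entries with no
#' candidate at or above the threshold keep a null code and are flagged
#' unmapped — they are never dropped, so completeness accounting downstream
#' keeps its denominator.
#'
#' @param reg a `register_set`.
#' @param dictionaries list of `term_dictionary` objects, together covering
#'   the systems needed by the entry kinds present in the data.
#' @param threshold acceptance threshold passed to [map_term()].
#' @return the `register_set` with mapping columns (`code`, `system`,
#'   `standard_term`, `score`, `accepted`) added to `entries`.
#' @export
attach_mappings <- function(reg, dictionaries, threshold = 0.6) {
  stopifnot(inherits(reg, "register_set"))
  if (inherits(dictionaries, "term_dictionary")) dictionaries <- list(dictionaries)
  combined <- do.call(rbind, lapply(dictionaries, function(d) {
    as.data.frame(as_dictionary(d))
  }))

  entries <- reg$entries
  entries$code <- rep(NA_character_, nrow(entries))
  entries$system <- rep(NA_character_, nrow(entries))
  entries$standard_term <- rep(NA_character_, nrow(entries))
  entries$score <- rep(NA_real_, nrow(entries))
  entries$accepted <- rep(FALSE, nrow(entries))

  for (kind in unique(entries$kind)) {
    systems <- KIND_SYSTEMS[[kind]]
    sub <- combined[combined$system %in% systems, , drop = FALSE]
    if (is.null(sub) || nrow(sub) == 0) {
      hf_validation_error(sprintf(
        "no dictionary loaded for entry kind '%s' (needs system %s)",
        kind, paste(systems, collapse = " or ")))
    }
    dict <- as_dictionary(sub)
    sel <- entries$kind == kind
    for (term in unique(entries$local_term[sel])) {
      hits <- map_term(term, dict, threshold = threshold, top_k = 1L)
      rows <- sel & entries$local_term == term
      if (nrow(hits) > 0 && hits$accepted[1]) {
        entries$code[rows] <- hits$code[1]
        entries$system[rows] <- hits$system[1]
        entries$standard_term[rows] <- hits$standard_term[1]
        entries$score[rows] <- hits$score[1]
        entries$accepted[rows] <- TRUE
      }
    }
  }
  reg$entries <- entries
  reg$threshold <- threshold
  reg
}

#' @export
print.register_set <- function(x, ...) {
  cat("<register_set> ", nrow(x$records), " consultations, ",
      nrow(x$entries), " clinical entries, ",
      nrow(x$rejections), " rejected rows\n", sep = "")
  if ("accepted" %in% names(x$entries) && nrow(x$entries) > 0) {
    cat("  mapped entries: ", sum(x$entries$accepted), "/", nrow(x$entries),
        " accepted at threshold ", x$threshold %||% NA, "\n", sep = "")
  }
  invisible(x)
}
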