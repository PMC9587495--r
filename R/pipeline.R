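# Config-driven pipeline: ingest -> map -> facts -> aggregate -> quality,
# with role-profile enforcement and a structured log. The command-line front
# end at inst/cli/healthfacts.R is a thin dispatcher over these functions.

#' Read a flat key=value pipeline configuration
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#'
#' @param path path to the config file.
#' @return named list of character values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) hf_io_error(sprintf("config file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad) > 0) {
    hf_validation_error(sprintf("malformed config line(s): %s", paste(bad, collapse = "; ")))
  }
  out <- lapply(kv, function(m) trimws(m[3]))
  names(out) <- vapply(kv, function(m) trimws(m[2]), character(1))
  out
}

# capability needed to run each pipeline command. Entering register rows and
# matching concepts are data-production actions reserved to the service
# profile; reading existing registers for analysis is `analyze`.
COMMAND_CAPABILITY <- c(
  simulate = "create_record",
  ingest = "create_record",
  "map-terms" = "match_concepts",
  "build-facts" = "analyze",
  aggregate = "analyze",
  quality = "analyze",
  evaluate = "analyze",
  full = "analyze",
  "check-access" = "visualize"
)

pipeline_log <- function(con, level, stage, ...) {
  kv <- c(...)
  line <- paste0(level, " stage=", stage,
                 if (length(kv) > 0) paste0(" ", paste(names(kv), kv, sep = "=", collapse = " ")))
  cat(line, "\n", sep = "", file = con, append = TRUE)
  line
}

#' Run the warehouse pipeline from a configuration file
#'
#' Chains register ingest, terminology mapping, fact materialisation,
#' aggregation and the quality report, writing each stage's output under
#' `out_dir` together with a structured log (`log.txt`, lines
#' `LEVEL stage=<name> key=value ...`). The configured profile is checked
#' against the capability matrix: a command the profile is not allowed to
#' run raises a permission error (nonzero exit in the CLI); optional
#' side outputs the profile may not export are logged and skipped.
#'
#' Config keys: `register`, `pyramid`, `dict_icd10`, `dict_atc`,
#' `dict_loinc` (input paths), `profile`, `threshold`, `out_dir`,
#' `aggregate_by` (comma-separated dimensions, default
#' `standard_concept_diagnosis`), `group_level` (optional geographic level
#' prefixed to the grouping, e.g. `district`), `submissions` (optional
#' report calendar), `seed` and `n_consultations` (simulate command only).
#'
#' @param config path to a config file or a named list.
#' @param command pipeline command; `"full"` runs ingest through quality.
#' @param overrides named list overriding config keys (CLI flags).
#' @return invisibly, a list with the stage outputs (`register_set`,
#'   `facts`, `cube`, `quality`, paths and the log lines).
#' @export
run_pipeline <- function(config, command = "full", overrides = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (k in names(overrides)) config[[k]] <- overrides[[k]]

  if (!command %in% names(COMMAND_CAPABILITY)) {
    hf_validation_error(sprintf("unknown command: %s", command))
  }
  profile <- config$profile %||% "service"
  needed <- COMMAND_CAPABILITY[[command]]
  if (!check_permission(profile, needed)) {
    hf_permission_error(sprintf(
      "profile '%s' lacks capability '%s' required by command '%s'",
      profile, needed, command))
  }

  out_dir <- config$out_dir %||% tempfile("hfout")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  if (file.exists(log_path)) file.remove(log_path)
  logf <- function(level, stage, ...) pipeline_log(log_path, level, stage, ...)
  result <- list(out_dir = out_dir, log = log_path)

  if (command == "check-access") {
    path <- file.path(out_dir, "capability_matrix.csv")
    serialize_capability_matrix(path)
    logf("INFO", "check-access", profile = profile)
    result$capability_matrix <- path
    return(invisible(result))
  }

  if (command == "simulate") {
    cfg <- generator_config(
      seed = as.integer(config$seed %||% 1L),
      n_consultations = as.integer(config$n_consultations %||% 2000L)
    )
    ds <- generate_dataset(cfg, dir = out_dir)
    logf("INFO", "simulate", seed = cfg$seed, n = cfg$n_consultations)
    result$dataset <- ds
    return(invisible(result))
  }

  if (command == "evaluate") {
    fix <- evaluation_fixture()
    scores <- score_evaluation(fix$matrix)
    write_hf_csv(scores$dimensions, file.path(out_dir, "evaluation_dimensions.csv"))
    write_hf_csv(scores$criteria, file.path(out_dir, "evaluation_criteria.csv"))
    logf("INFO", "evaluate", users = length(unique(fix$matrix$user_id)))
    result$scores <- scores
    return(invisible(result))
  }

  for (key in c("register", "pyramid")) {
    if (is.null(config[[key]])) {
      hf_validation_error(sprintf("config key '%s' is required by command '%s'", key, command))
    }
  }

  pyramid <- load_pyramid(config$pyramid)
  reg <- parse_register(config$register, pyramid)
  write_hf_csv(reg$rejections, file.path(out_dir, "rejections.csv"))
  logf("INFO", "ingest", rows = nrow(reg$records) + nrow(reg$rejections),
       accepted = nrow(reg$records), rejected = nrow(reg$rejections))
  result$register_set <- reg
  if (command == "ingest") return(invisible(result))

  dicts <- list()
  for (key in c("dict_icd10", "dict_atc", "dict_loinc")) {
    if (!is.null(config[[key]])) dicts[[key]] <- load_dictionary(config[[key]])
  }
  threshold <- as.numeric(config$threshold %||% 0.6)
  reg <- attach_mappings(reg, dicts, threshold = threshold)
  write_hf_csv(
    reg$entries[, c("local_term", "code", "system", "standard_term", "score", "accepted")],
    file.path(out_dir, "mapping_report.csv"))
  logf("INFO", "map-terms", entries = nrow(reg$entries),
       accepted = sum(reg$entries$accepted), threshold = threshold)
  result$register_set <- reg
  if (command == "map-terms") return(invisible(result))

  facts <- build_fact_table(reg, pyramid)
  can_export <- check_permission(profile, "export")
  if (can_export) {
    export_facts(facts, file.path(out_dir, "facts.csv"))
  } else {
    logf("WARN", "build-facts", skipped = "export", reason = "permission")
  }
  logf("INFO", "build-facts", rows = nrow(facts),
       consultations = length(unique(facts$num_examination)))
  result$facts <- facts
  if (command == "build-facts") return(invisible(result))

  group_by <- strsplit(config$aggregate_by %||% "standard_concept_diagnosis", ",")[[1]]
  group_by <- trimws(group_by)
  if (!is.null(config$group_level)) {
    group_by <- c(geo_column_of_level(config$group_level), group_by)
  }
  cube <- aggregate_facts(facts, group_by)
  if (can_export) {
    write_hf_csv(as.data.frame(cube), file.path(out_dir, "aggregate.csv"))
  }
  logf("INFO", "aggregate", groups = nrow(cube),
       dims = paste(group_by, collapse = "+"))
  result$cube <- cube
  if (command == "aggregate") return(invisible(result))

  submissions <- NULL
  if (!is.null(config$submissions)) {
    submissions <- read_hf_csv(config$submissions,
                               required_cols = c("facility", "month", "submission_date"))
    submissions$submission_date[submissions$submission_date == ""] <- NA
  }
  qr <- quality_report(reg, facts, pyramid, submissions = submissions)
  qlines <- utils::capture.output(print(qr))
  writeLines(qlines, file.path(out_dir, "quality.txt"))
  logf("INFO", "quality",
       field_completeness = sprintf("%.2f", qr$field_completeness_pct),
       accuracy = sprintf("%.2f", qr$accuracy_pct))
  result$quality <- qr
  invisible(result)
}
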