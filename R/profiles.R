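# Role profiles: one connection profile per decision level. Only the
# service profile — the producer of the data — can create records, record
# clinical data and match concepts; every profile can update, analyze,
# visualize and export.

PROFILE_NAMES <- c("service", "facility", "district", "region", "country")
CAPABILITY_NAMES <- c("create_record", "record_clinical_data", "match_concepts",
                      "update_data", "analyze", "visualize", "export")

#' Capability matrix of the access profiles
#'
#' The service profile holds all seven capabilities; the facility, district,
#' region and country profiles hold exactly `update_data`, `analyze`,
#' `visualize` and `export`. At aggregation levels, `update_data` means
#' re-running mapping and aggregation — never editing service-level register
#' rows, which only the producing service may do.
#'
#' @return data frame, one row per profile, one logical column per
#'   capability.
#' @export
capability_matrix <- function() {
  upper <- c("update_data", "analyze", "visualize", "export")
  m <- data.frame(profile = PROFILE_NAMES, stringsAsFactors = FALSE)
  for (cap in CAPABILITY_NAMES) {
    m[[cap]] <- ifelse(m$profile == "service", TRUE, cap %in% upper)
  }
  m
}

#' Check whether a profile may perform an action
#'
#' @param profile one of `service`, `facility`, `district`, `region`,
#'   `country`.
#' @param action one of the seven capabilities (see [capability_matrix()]).
#' @return `TRUE` or `FALSE`.
#' @export
check_permission <- function(profile, action) {
  if (!profile %in% PROFILE_NAMES) {
    hf_validation_error(sprintf("unknown profile: %s", profile))
  }
  if (!action %in% CAPABILITY_NAMES) {
    hf_validation_error(sprintf("unknown action: %s", action))
  }
  m <- capability_matrix()
  m[[action]][m$profile == profile]
}

#' Serialize the capability matrix
#'
#' Writes the matrix as CSV (profiles x capabilities, `true`/`false`
#' cells); the committed copy under `inst/extdata/` is the golden
#' reference the code is tested against.
#'
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
serialize_capability_matrix <- function(path) {
  write_hf_csv(capability_matrix(), path)
}
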