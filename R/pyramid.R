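# Five-level health pyramid: country > region > district > facility > service.
# A node has exactly one parent at the immediately superior level; the service
# level is where consultations happen and data are produced.

#' Pyramid levels, from top to bottom
#'
#' The administrative hierarchy of the health system: a country is composed
#' of health regions, a region of health districts, a district of health
#' facilities, and a facility of health care services. Every consultation is
#' recorded at exactly one service.
#'
#' @export
pyramid_levels <- function() {
  c("country", "region", "district", "facility", "service")
}

level_rank <- function(level) {
  match(level, pyramid_levels())
}

#' Load and validate a health-pyramid definition
#'
#' Reads a delimited pyramid file (columns `node_id`, `name`, `level`,
#' `parent_id`, optionally `admin_category`) and validates the hierarchy:
#' unique ids, exactly one country node, every non-country node with one
#' parent at the immediately superior level, no cycles.
#'
#' @param path path to the pyramid definition CSV.
#' @return a `health_pyramid` object (a validated data frame).
#' @seealso [geography_of()], [descendants_at()]
#' @export
load_pyramid <- function(path) {
  df <- read_hf_csv(path, required_cols = c("node_id", "name", "level", "parent_id"))
  if (!"admin_category" %in% names(df)) df$admin_category <- ""
  as_pyramid(df)
}

#' Build a health pyramid from a data frame
#'
#' @param df data frame with columns `node_id`, `name`, `level`, `parent_id`
#'   and optionally `admin_category`.
#' @return a `health_pyramid` object.
#' @export
as_pyramid <- function(df) {
  df <- as.data.frame(df)
  if (!"admin_category" %in% names(df)) df$admin_category <- ""
  df <- df[, c("node_id", "name", "level", "parent_id", "admin_category")]
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
  df$parent_id[is.na(df$parent_id)] <- ""
  errs <- validate_pyramid(df)
  if (nrow(errs) > 0) {
    hf_validation_error(
      paste0("invalid pyramid definition:\n",
             paste(format_validation_report(errs), collapse = "\n")),
      report = errs
    )
  }
  rownames(df) <- NULL
  class(df) <- c("health_pyramid", "data.frame")
  df
}

#' Validate a pyramid definition without stopping
#'
#' Each violated invariant yields one report row with an error code
#' (`duplicate_id`, `unknown_level`, `multiple_country`, `no_country`,
#' `country_has_parent`, `orphan`, `level_skip`, `cycle`) and the offending
#' node id.
#'
#' @param df pyramid definition data frame.
#' @return data frame with columns `code`, `node_id`, `message` (zero rows
#'   when valid).
#' @export
validate_pyramid <- function(df) {
  errs <- list()
  add <- function(code, node_id, message) {
    errs[[length(errs) + 1]] <<- data.frame(
      code = code, node_id = node_id, message = message,
      stringsAsFactors = FALSE
    )
  }

  dup <- unique(df$node_id[duplicated(df$node_id)])
  for (id in dup) add("duplicate_id", id, "node_id appears more than once")

  bad_level <- df$node_id[!df$level %in% pyramid_levels()]
  for (id in bad_level) add("unknown_level", id, "level is not one of the five pyramid levels")

  country <- df$node_id[df$level == "country"]
  if (length(country) == 0) {
    add("no_country", "", "pyramid has no country node")
  } else if (length(country) > 1) {
    for (id in country[-1]) add("multiple_country", id, "more than one country node")
  }
  for (id in df$node_id[df$level == "country" & df$parent_id != ""]) {
    add("country_has_parent", id, "country node must not have a parent")
  }

  idx <- match(df$parent_id, df$node_id)
  for (i in seq_len(nrow(df))) {
    if (df$level[i] == "country" || !df$level[i] %in% pyramid_levels()) next
    if (df$parent_id[i] == "" || is.na(idx[i])) {
      add("orphan", df$node_id[i], "parent_id missing or not a known node")
    } else {
      want <- pyramid_levels()[level_rank(df$level[i]) - 1L]
      got <- df$level[idx[i]]
      if (!identical(got, want)) {
        add("level_skip", df$node_id[i],
            sprintf("parent has level '%s' but the immediate superior level is '%s'", got, want))
      }
    }
  }

  # cycle detection by parent walking with a step bound
  if (length(dup) == 0) {
    for (i in seq_len(nrow(df))) {
      seen <- character(0)
      cur <- df$node_id[i]
      repeat {
        if (cur %in% seen) {
          add("cycle", df$node_id[i], "parent chain contains a cycle")
          break
        }
        seen <- c(seen, cur)
        p <- df$parent_id[match(cur, df$node_id)]
        if (is.na(p) || p == "" || !p %in% df$node_id) break
        cur <- p
      }
    }
  }

  if (length(errs) == 0) {
    return(data.frame(code = character(0), node_id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, errs))
}

#' Format a pyramid validation report as plain text lines
#'
#' @param report data frame from [validate_pyramid()].
#' @return character vector of lines `"ERROR <code> <node_id> <message>"`.
#' @export
format_validation_report <- function(report) {
  if (nrow(report) == 0) return(character(0))
  sprintf("ERROR %s %s %s", report$code, report$node_id, report$message)
}

node_level <- function(pyramid, node_id) {
  i <- match(node_id, pyramid$node_id)
  if (is.na(i)) hf_validation_error(sprintf("unknown node id: %s", node_id))
  pyramid$level[i]
}

#' Resolve the geography of a health care service
#'
#' Walks the parent chain of a service node and returns the names of its
#' region, district, facility and the service itself — the four geographic
#' columns of the fact table.
#'
#' @param service_id node id at the service level.
#' @param pyramid a `health_pyramid`.
#' @return named character vector with elements `region`, `district`,
#'   `facility`, `service`.
#' @export
geography_of <- function(service_id, pyramid) {
  lev <- node_level(pyramid, service_id)
  if (!identical(lev, "service")) {
    hf_validation_error(sprintf("node %s has level '%s', not 'service'", service_id, lev))
  }
  out <- character(0)
  cur <- service_id
  while (!is.na(cur) && cur != "") {
    i <- match(cur, pyramid$node_id)
    out[pyramid$level[i]] <- pyramid$name[i]
    cur <- pyramid$parent_id[i]
  }
  c(region = out[["region"]], district = out[["district"]],
    facility = out[["facility"]], service = out[["service"]])
}

#' All descendants of a node at a given level
#'
#' Supports drill-down: enumerate, for example, every service under a
#' district. The target level must be strictly below the node's own level.
#'
#' @param node_id node id of the ancestor.
#' @param level target level, one of [pyramid_levels()].
#' @param pyramid a `health_pyramid`.
#' @return character vector of node ids at `level` in the subtree.
#' @export
descendants_at <- function(node_id, level, pyramid) {
  own <- node_level(pyramid, node_id)
  if (!level %in% pyramid_levels()) {
    hf_validation_error(sprintf("unknown level: %s", level))
  }
  if (level_rank(level) <= level_rank(own)) {
    hf_validation_error(sprintf(
      "level '%s' is not below the level '%s' of node %s", level, own, node_id))
  }
  frontier <- node_id
  repeat {
    kids <- pyramid$node_id[pyramid$parent_id %in% frontier]
    if (length(kids) == 0) return(character(0))
    if (identical(pyramid$level[match(kids[1], pyramid$node_id)], level)) {
      return(sort(kids))
    }
    frontier <- kids
  }
}

#' @export
print.health_pyramid <- function(x, ...) {
  counts <- table(factor(x$level, levels = pyramid_levels()))
  cat("<health_pyramid> ", nrow(x), " nodes (",
      paste(sprintf("%s: %d", names(counts), as.integer(counts)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# Fast lookup table service_id -> the four geography names, used when
# materialising facts for thousands of consultations.
geography_table <- function(pyramid) {
  services <- pyramid$node_id[pyramid$level == "service"]
  rows <- lapply(services, function(s) {
    g <- geography_of(s, pyramid)
    data.frame(service_id = s,
               regional_health_name = g[["region"]],
               health_district_name = g[["district"]],
               health_care_facility_name = g[["facility"]],
               health_care_service_name = g[["service"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
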