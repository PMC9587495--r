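# Shared helpers: classed conditions, strict CSV I/O, display rounding.

hf_stop <- function(message, class, ...) {
  stop(structure(
    class = c(class, "hf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

hf_validation_error <- function(message, ...) {
  hf_stop(message, "hf_validation_error", ...)
}

hf_io_error <- function(message, ...) {
  hf_stop(message, "hf_io_error", ...)
}

hf_permission_error <- function(message, ...) {
  hf_stop(message, "hf_permission_error", ...)
}

# All on-disk tables are plain comma-separated UTF-8 with a header row.
# Reading keeps every column as character; typing is done by the caller so
# that blank cells stay distinguishable from zeros.
read_hf_csv <- function(path, required_cols = NULL) {
  if (!file.exists(path)) {
    hf_io_error(sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8", na.strings = NULL)
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing) > 0) {
      hf_validation_error(sprintf(
        "file %s is missing required column(s): %s",
        path, paste(missing, collapse = ", ")
      ))
    }
  }
  df
}

write_hf_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (inherits(col, "Date")) {
      col <- format(col, "%Y-%m-%d")
    } else if (is.logical(col)) {
      col <- ifelse(is.na(col), NA_character_, ifelse(col, "true", "false"))
    } else if (is.numeric(col)) {
      col <- ifelse(is.na(col), NA_character_,
                    format(col, trim = TRUE, scientific = FALSE))
    }
    df[[j]] <- as.character(col)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Round half away from zero
#'
#' Display rounding used for reported percentages: halves move away from
#' zero (92.857 -> 93, 17.5 -> 18), unlike [round()]'s round-half-even.
#' Raw fractions are always kept alongside rounded values in machine output.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return numeric vector rounded half-away-from-zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
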