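# Terminology matching: map free-text local clinical terms (French-oriented
# register vocabulary) onto standard dictionary entries (ICD-10/ICPC-2 for
# diagnoses, ATC for drugs, LOINC for laboratory tests) with a [0,1] score.

TERM_SYSTEMS <- c("ICD10", "ICPC2", "ATC", "LOINC")

# accent folding map; deliberately a fixed table (no iconv) so behaviour is
# identical across platforms and locales
ACCENT_FROM <- "àáâãäåçèéêëìíîïñòóôõöùúûüýÿ"
ACCENT_TO   <- "aaaaaaceeeeiiiinooooouuuuyy"

#' Normalize a clinical term to comparable tokens
#'
#' Lowercases, folds French accents to ASCII, expands oe/ae ligatures,
#' strips punctuation and splits on whitespace. Total function: any string
#' (including `""`) is accepted; the empty string yields zero tokens.
#' No stemming is applied.
#'
#' @param text a single character string.
#' @return character vector of tokens (possibly empty).
#' @examples
#' normalize_term("Paludisme grave")
#' normalize_term("Anémie, sévère!")
#' @export
normalize_term <- function(text) {
  if (length(text) != 1) hf_validation_error("normalize_term() takes a single string")
  if (is.na(text)) text <- ""
  x <- tolower(text)
  x <- chartr(ACCENT_FROM, ACCENT_TO, x)
  x <- gsub("œ", "oe", x, fixed = TRUE)
  x <- gsub("æ", "ae", x, fixed = TRUE)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), " +")[[1]]
  toks[nzchar(toks)]
}

#' Dice similarity between two clinical terms
#'
#' Score in \[0, 1\] between the normalized token sets of two terms:
#' `2 |A intersect B| / (|A| + |B|)`. Two empty terms score 1; exactly one
#' empty term scores 0. Symmetric, and 1 for identical non-empty terms.
#'
#' @param local_term,standard_term character strings.
#' @return numeric score in \[0, 1\].
#' @examples
#' match_score("paludisme grave", "paludisme") # 2/3
#' @export
match_score <- function(local_term, standard_term) {
  a <- unique(normalize_term(local_term))
  b <- unique(normalize_term(standard_term))
  if (length(a) == 0 && length(b) == 0) return(1)
  if (length(a) == 0 || length(b) == 0) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Load a terminology dictionary
#'
#' Reads a delimited dictionary (columns `code`, `system`, `preferred_term`,
#' `synonyms`; synonyms pipe-separated) and validates it: known system
#' (`ICD10`, `ICPC2`, `ATC`, `LOINC`), non-empty codes, unique
#' (code, system) pairs.
#'
#' @param path path to the dictionary CSV.
#' @return a `term_dictionary` object (a validated data frame).
#' @export
load_dictionary <- function(path) {
  df <- read_hf_csv(path, required_cols = c("code", "system", "preferred_term", "synonyms"))
  as_dictionary(df)
}

#' Build a terminology dictionary from a data frame
#'
#' @param df data frame with columns `code`, `system`, `preferred_term`,
#'   `synonyms` (pipe-separated string, may be empty).
#' @return a `term_dictionary` object.
#' @export
as_dictionary <- function(df) {
  df <- as.data.frame(df)[, c("code", "system", "preferred_term", "synonyms")]
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
  df$synonyms[is.na(df$synonyms)] <- ""
  if (any(!nzchar(df$code))) hf_validation_error("dictionary has an empty code")
  bad <- unique(df$system[!df$system %in% TERM_SYSTEMS])
  if (length(bad) > 0) {
    hf_validation_error(sprintf("unknown terminology system(s): %s",
                                paste(bad, collapse = ", ")))
  }
  key <- paste(df$code, df$system, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE]
    hf_validation_error(sprintf("duplicate (code, system) entries: %s",
                                paste(unique(paste0(d$code, "/", d$system)), collapse = ", ")))
  }
  rownames(df) <- NULL
  class(df) <- c("term_dictionary", "data.frame")
  df
}

# token sets for preferred term + each synonym of every entry
dictionary_token_sets <- function(dictionary) {
  lapply(seq_len(nrow(dictionary)), function(i) {
    terms <- c(dictionary$preferred_term[i],
               strsplit(dictionary$synonyms[i], "|", fixed = TRUE)[[1]])
    terms <- terms[nzchar(trimws(terms))]
    lapply(terms, function(t) unique(normalize_term(t)))
  })
}

dice_sets <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  if (length(a) == 0 || length(b) == 0) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Map a local term to its best dictionary candidates
#'
#' Scores the local term against the preferred term and every synonym of
#' each dictionary entry (the entry's score is the maximum), ranks entries
#' by score descending with ties broken by code ascending, flags candidates
#' at or above the acceptance threshold, and returns at most `top_k`.
#' A term with no accepted candidate is never dropped downstream: it keeps
#' its local wording with a null code (see [attach_mappings()]).
#'
#' @param local_term character string as written in the register.
#' @param dictionary a `term_dictionary`.
#' @param threshold acceptance threshold in \[0, 1\] (default 0.6).
#' @param top_k maximum number of candidates returned.
#' @return data frame with columns `local_term`, `code`, `system`,
#'   `standard_term`, `score`, `accepted`, ordered best-first.
#' @export
map_term <- function(local_term, dictionary, threshold = 0.6, top_k = 5L) {
  if (!inherits(dictionary, "term_dictionary")) dictionary <- as_dictionary(dictionary)
  if (nrow(dictionary) == 0) hf_validation_error("dictionary is empty")
  if (threshold < 0 || threshold > 1) hf_validation_error("threshold must be in [0, 1]")
  if (top_k < 1) hf_validation_error("top_k must be a positive integer")
  a <- unique(normalize_term(local_term))
  sets <- dictionary_token_sets(dictionary)
  score <- vapply(sets, function(entry_sets) {
    if (length(entry_sets) == 0) return(0)
    max(vapply(entry_sets, function(b) dice_sets(a, b), numeric(1)))
  }, numeric(1))
  out <- data.frame(
    local_term = local_term,
    code = dictionary$code,
    system = dictionary$system,
    standard_term = dictionary$preferred_term,
    score = score,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, out$code), , drop = FALSE]
  out$accepted <- out$score >= threshold
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}
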