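# Seeded synthetic-register generator. Every consuming module is testable
# against files whose ground truth (per-code counts, per-facility totals,
# injected missing cells and corruptions) is recorded in a manifest.
#
# One pseudo-random stream per dataset, keyed by the seed; a fixed seed
# yields byte-identical output files.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Generator configuration
#'
#' Bundles and validates the knobs of the synthetic-register generator.
#'
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @param n_consultations number of register rows to generate.
#' @param pyramid_spec named integer vector of branching counts per level:
#'   `regions`, `districts` (per region), `facilities` (per district),
#'   `services` (per facility).
#' @param diagnosis_mix named probability vector, ICD-10 code -> probability
#'   (must sum to 1); codes must exist in the ICD-10 dictionary.
#' @param diagnoses_per_visit,drugs_per_visit,labs_per_visit named
#'   probability vectors over entry counts (names are the counts).
#' @param missingness_rate probability that an audited sociodemographic or
#'   economic cell is left blank.
#' @param delay_distribution list with `lambda` (Poisson mean of the
#'   monthly-report submission delay in days beyond the period end) and
#'   `prob_missing` (probability a monthly report is never submitted).
#' @param corruption_rate probability that a register row is transcribed
#'   with a corrupted patient age (the clean source is kept alongside).
#' @param date_start,date_end ISO dates bounding examination dates.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_consultations = 2000L,
                             pyramid_spec = c(regions = 2L, districts = 2L,
                                              facilities = 2L, services = 2L),
                             diagnosis_mix = c(B54 = 0.35, A09 = 0.15, J11 = 0.12,
                                               I10 = 0.10, N39.0 = 0.08, A01.0 = 0.07,
                                               K29 = 0.05, E11 = 0.04, J15 = 0.02,
                                               M54.5 = 0.01, B05 = 0.01),
                             diagnoses_per_visit = c("1" = 0.85, "2" = 0.15),
                             drugs_per_visit = c("0" = 0.25, "1" = 0.5, "2" = 0.25),
                             labs_per_visit = c("0" = 0.55, "1" = 0.35, "2" = 0.10),
                             missingness_rate = 0,
                             delay_distribution = list(lambda = 3, prob_missing = 0),
                             corruption_rate = 0,
                             date_start = "2018-01-20",
                             date_end = "2018-07-12") {
  check_prob <- function(p, what, tol = 1e-9) {
    if (length(p) == 0 || any(p < 0) || abs(sum(p) - 1) > tol) {
      hf_validation_error(sprintf("%s must be non-negative probabilities summing to 1", what))
    }
  }
  check_prob(diagnosis_mix, "diagnosis_mix")
  check_prob(diagnoses_per_visit, "diagnoses_per_visit")
  check_prob(drugs_per_visit, "drugs_per_visit")
  check_prob(labs_per_visit, "labs_per_visit")
  if (missingness_rate < 0 || missingness_rate > 1) {
    hf_validation_error("missingness_rate must be in [0, 1]")
  }
  if (corruption_rate < 0 || corruption_rate > 1) {
    hf_validation_error("corruption_rate must be in [0, 1]")
  }
  structure(list(
    seed = as.integer(seed), n_consultations = as.integer(n_consultations),
    pyramid_spec = pyramid_spec, diagnosis_mix = diagnosis_mix,
    diagnoses_per_visit = diagnoses_per_visit, drugs_per_visit = drugs_per_visit,
    labs_per_visit = labs_per_visit, missingness_rate = missingness_rate,
    delay_distribution = delay_distribution, corruption_rate = corruption_rate,
    date_start = as.Date(date_start), date_end = as.Date(date_end)
  ), class = "generator_config")
}

SERVICE_NAMES <- c("Médecine Générale", "Pédiatrie", "Maternité", "Urgences")

#' Generate a synthetic pyramid definition
#'
#' Deterministic (no randomness): country, then `regions` regions,
#' `districts` districts per region, `facilities` facilities per district,
#' `services` services per facility. Service names cycle through a short
#' list, so names collide across facilities while node ids stay unique —
#' as in real hierarchies.
#'
#' @param spec named counts, see [generator_config()].
#' @return a `health_pyramid`.
#' @export
generate_pyramid <- function(spec = c(regions = 2L, districts = 2L,
                                      facilities = 2L, services = 2L)) {
  rows <- list(data.frame(node_id = "CT", name = "Country", level = "country",
                          parent_id = "", admin_category = "", stringsAsFactors = FALSE))
  for (r in seq_len(spec[["regions"]])) {
    rid <- sprintf("R%d", r)
    rows[[length(rows) + 1]] <- data.frame(
      node_id = rid, name = sprintf("Region %d", r), level = "region",
      parent_id = "CT", admin_category = "", stringsAsFactors = FALSE)
    for (d in seq_len(spec[["districts"]])) {
      did <- sprintf("%s-D%d", rid, d)
      rows[[length(rows) + 1]] <- data.frame(
        node_id = did, name = sprintf("District %d.%d", r, d), level = "district",
        parent_id = rid, admin_category = "", stringsAsFactors = FALSE)
      for (f in seq_len(spec[["facilities"]])) {
        fid <- sprintf("%s-F%d", did, f)
        rows[[length(rows) + 1]] <- data.frame(
          node_id = fid, name = sprintf("Centre de Santé %d.%d.%d", r, d, f),
          level = "facility", parent_id = did,
          admin_category = c("public", "para-public", "private")[(f - 1) %% 3 + 1],
          stringsAsFactors = FALSE)
        for (s in seq_len(spec[["services"]])) {
          sid <- sprintf("%s-S%d", fid, s)
          rows[[length(rows) + 1]] <- data.frame(
            node_id = sid, name = SERVICE_NAMES[(s - 1) %% length(SERVICE_NAMES) + 1],
            level = "service", parent_id = fid, admin_category = "",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  as_pyramid(do.call(rbind, rows))
}

# pick an emitted register phrasing for a dictionary code: usually the
# preferred term, sometimes a synonym (registers rarely use textbook wording)
term_for_codes <- function(codes, dictionary, synonym_prob = 0.3) {
  i <- match(codes, dictionary$code)
  vapply(seq_along(codes), function(k) {
    syns <- strsplit(dictionary$synonyms[i[k]], "|", fixed = TRUE)[[1]]
    syns <- syns[nzchar(syns)]
    if (length(syns) > 0 && stats::runif(1) < synonym_prob) {
      sample(syns, 1)
    } else {
      dictionary$preferred_term[i[k]]
    }
  }, character(1))
}

sample_counts <- function(n, dist) {
  as.integer(sample(names(dist), n, replace = TRUE, prob = dist))
}

NATIONALITIES <- c("Gabonaise", "Camerounaise", "Congolaise", "Équato-guinéenne")
RESIDENCES <- c("Libreville", "Ntoum", "Owendo", "Akanda", "Kango", "Cocobeach")
INSURANCES <- c("CNAMGS", "assurance privée", "aucune")
OCCUPATIONS <- c("agriculteur", "commerçant", "enseignant", "fonctionnaire",
                 "élève", "sans emploi", "pêcheur")

# build the character register table for n consultations at given services
build_register_rows <- function(n, service_ids, diag_codes_list, drug_counts,
                                lab_counts, dicts, id_prefix = "E") {
  diag_terms <- vapply(diag_codes_list, function(codes) {
    paste(term_for_codes(codes, dicts$icd10), collapse = "|")
  }, character(1))
  drug_terms <- vapply(drug_counts, function(k) {
    if (k == 0) return("")
    codes <- sample(dicts$atc$code, k, replace = FALSE)
    paste(term_for_codes(codes, dicts$atc), collapse = "|")
  }, character(1))
  lab_terms <- vapply(lab_counts, function(k) {
    if (k == 0) return("")
    codes <- sample(dicts$loinc$code, k, replace = FALSE)
    paste(term_for_codes(codes, dicts$loinc), collapse = "|")
  }, character(1))

  data.frame(
    num_examination = sprintf("%s%06d", id_prefix, seq_len(n)),
    examination_date = "",   # filled by caller
    recorded_at = "",
    service_id = service_ids,
    patient_sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45)),
    patient_age = as.character(stats::rpois(n, 24)),
    patient_nationality = sample(NATIONALITIES, n, replace = TRUE,
                                 prob = c(0.85, 0.06, 0.06, 0.03)),
    patient_residence = sample(RESIDENCES, n, replace = TRUE),
    insurance_status = sample(INSURANCES, n, replace = TRUE, prob = c(0.5, 0.1, 0.4)),
    government_coverage = sample(c("true", "false"), n, replace = TRUE),
    occupation = sample(OCCUPATIONS, n, replace = TRUE),
    copayment_rate = sprintf("%.1f", sample(c(0, 0.1, 0.2, 0.5), n, replace = TRUE)),
    diagnoses = diag_terms,
    drugs = drug_terms,
    labs = lab_terms,
    stringsAsFactors = FALSE
  )
}

months_in_window <- function(start, end) {
  first <- as.Date(format(start, "%Y-%m-01"))
  out <- character(0)
  while (first <= end) {
    out <- c(out, format(first, "%Y-%m"))
    first <- seq(first, by = "1 month", length.out = 2)[2]
  }
  out
}

# submission calendar for every facility x month of the window
build_submissions <- function(facilities, start, end, delay_distribution) {
  months <- months_in_window(start, end)
  grid <- expand.grid(facility = facilities, month = months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$facility, grid$month), , drop = FALSE]
  n <- nrow(grid)
  period_end <- month_end(grid$month)
  delay <- 1 + stats::rpois(n, delay_distribution$lambda %||% 3)
  date <- format(period_end + delay, "%Y-%m-%d")
  miss <- stats::runif(n) < (delay_distribution$prob_missing %||% 0)
  grid$submission_date <- ifelse(miss, "", date)
  rownames(grid) <- NULL
  grid
}

write_manifest <- function(manifest, path) {
  lines <- character(0)
  for (key in names(manifest$values)) {
    lines <- c(lines, sprintf("%s: %s", key, manifest$values[[key]]))
  }
  for (tab in names(manifest$tables)) {
    df <- manifest$tables[[tab]]
    lines <- c(lines, sprintf("[%s]", tab),
               vapply(seq_len(nrow(df)), function(i) {
                 paste(as.character(unlist(df[i, ])), collapse = ",")
               }, character(1)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Generate a complete synthetic dataset on disk
#'
#' Emits, under `dir`: `pyramid.csv`, `register.csv`,
#' `dictionary_icd10.csv` / `dictionary_atc.csv` / `dictionary_loinc.csv`,
#' `submissions.csv` (the monthly report calendar) and `manifest.txt`
#' recording the ground truth (true per-code counts, per-facility
#' consultation totals, injected missing cells and corrupted rows). When
#' `corruption_rate > 0`, the clean source register is kept as
#' `register_source.csv` next to the corrupted `register.csv`.
#'
#' With `missingness_rate = 0` and `corruption_rate = 0` every emitted file
#' parses through its consuming module with zero rejections.
#'
#' @param config a `generator_config`.
#' @param dir output directory (created if needed).
#' @return a `synthetic_dataset`: list with `dir`, `files` (named paths) and
#'   `manifest` (ground-truth list with `values` and `tables`).
#' @export
generate_dataset <- function(config, dir = tempfile("hfdata")) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dicts <- builtin_dictionaries()
  bad <- setdiff(names(config$diagnosis_mix), dicts$icd10$code)
  if (length(bad) > 0) {
    hf_validation_error(sprintf("diagnosis_mix codes not in the ICD-10 dictionary: %s",
                                paste(bad, collapse = ", ")))
  }

  with_seed(config$seed, {
    pyramid <- generate_pyramid(config$pyramid_spec)
    services <- pyramid$node_id[pyramid$level == "service"]
    n <- config$n_consultations

    service_ids <- sample(services, n, replace = TRUE)
    n_diag <- sample_counts(n, config$diagnoses_per_visit)
    diag_codes <- lapply(n_diag, function(k) {
      if (k == 0) return(character(0))
      sample(names(config$diagnosis_mix), k, replace = TRUE,
             prob = config$diagnosis_mix)
    })
    drug_counts <- sample_counts(n, config$drugs_per_visit)
    lab_counts <- sample_counts(n, config$labs_per_visit)

    reg <- build_register_rows(n, service_ids, diag_codes, drug_counts,
                               lab_counts, dicts)
    span <- as.integer(config$date_end - config$date_start)
    exam <- config$date_start + sample.int(span + 1L, n, replace = TRUE) - 1L
    reg$examination_date <- format(exam, "%Y-%m-%d")
    reg$recorded_at <- format(exam + stats::rpois(n, 0.5), "%Y-%m-%d")

    # injected missingness on audited sociodemographic/economic cells
    audit_cols <- c("patient_sex", "patient_age", "patient_nationality",
                    "patient_residence", "insurance_status", "occupation")
    n_missing <- 0L
    if (config$missingness_rate > 0) {
      for (col in audit_cols) {
        hit <- stats::runif(n) < config$missingness_rate
        reg[[col]][hit] <- ""
        n_missing <- n_missing + sum(hit)
      }
    }

    # transcription corruption: emitted register differs from clean source
    source_reg <- reg
    corrupted <- character(0)
    if (config$corruption_rate > 0) {
      hit <- which(stats::runif(n) < config$corruption_rate & nzchar(reg$patient_age))
      reg$patient_age[hit] <- as.character(
        suppressWarnings(as.integer(reg$patient_age[hit])) + 10L)
      corrupted <- reg$num_examination[hit]
    }

    facilities <- pyramid$node_id[pyramid$level == "facility"]
    submissions <- build_submissions(facilities, config$date_start,
                                     config$date_end, config$delay_distribution)

    files <- c(
      pyramid = file.path(dir, "pyramid.csv"),
      register = file.path(dir, "register.csv"),
      dictionary_icd10 = file.path(dir, "dictionary_icd10.csv"),
      dictionary_atc = file.path(dir, "dictionary_atc.csv"),
      dictionary_loinc = file.path(dir, "dictionary_loinc.csv"),
      submissions = file.path(dir, "submissions.csv"),
      manifest = file.path(dir, "manifest.txt")
    )
    write_hf_csv(as.data.frame(pyramid), files[["pyramid"]])
    write_hf_csv(reg, files[["register"]])
    write_hf_csv(as.data.frame(dicts$icd10), files[["dictionary_icd10"]])
    write_hf_csv(as.data.frame(dicts$atc), files[["dictionary_atc"]])
    write_hf_csv(as.data.frame(dicts$loinc), files[["dictionary_loinc"]])
    write_hf_csv(submissions, files[["submissions"]])
    if (config$corruption_rate > 0) {
      files[["register_source"]] <- file.path(dir, "register_source.csv")
      write_hf_csv(source_reg, files[["register_source"]])
    }

    code_tab <- table(unlist(diag_codes))
    fac_of_service <- pyramid$parent_id[match(service_ids, pyramid$node_id)]
    fac_tab <- table(fac_of_service)
    manifest <- list(
      values = list(
        seed = config$seed,
        n_consultations = n,
        n_missing_cells = n_missing,
        n_corrupted_rows = length(corrupted),
        date_start = format(config$date_start, "%Y-%m-%d"),
        date_end = format(config$date_end, "%Y-%m-%d")
      ),
      tables = list(
        diagnosis_code_counts = data.frame(code = names(code_tab),
                                           count = as.integer(code_tab),
                                           stringsAsFactors = FALSE),
        facility_consultations = data.frame(facility = names(fac_tab),
                                            count = as.integer(fac_tab),
                                            stringsAsFactors = FALSE),
        corrupted_num_examinations = if (length(corrupted) > 0) {
          data.frame(num_examination = corrupted, stringsAsFactors = FALSE)
        } else {
          data.frame(num_examination = character(0), stringsAsFactors = FALSE)
        }
      )
    )
    write_manifest(manifest, files[["manifest"]])

    structure(list(dir = dir, files = files, manifest = manifest),
              class = "synthetic_dataset")
  })
}

#' District worked-example fixture with exact counts
#'
#' Builds, by exact construction (a shuffled fixed multiset of diagnosis
#' codes, not sampling), a single-district dataset of exactly 6054
#' consultations of which exactly 2966 carry the malaria code (ICD-10 B54):
#' the district-level malaria share is 2966/6054, i.e. 49% of consultations.
#' Each consultation has exactly one diagnosis; the manifest records the
#' per-facility malaria distribution, whose drill-down totals sum back to
#' 2966.
#'
#' @param dir output directory.
#' @param n_facilities number of facilities in the district (one
#'   general-medicine service each).
#' @param seed seed for the shuffle and the sociodemographic fields; the
#'   headline counts are exact regardless of the seed.
#' @return a `synthetic_dataset` (see [generate_dataset()]).
#' @export
komo_mondah_fixture <- function(dir = tempfile("komo"), n_facilities = 12L,
                                seed = 2018L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dicts <- builtin_dictionaries()
  n_total <- 6054L
  n_malaria <- 2966L
  other <- c(A09 = 800L, J11 = 700L, I10 = 500L, N39.0 = 400L,
             A01.0 = 300L, K29 = 388L)
  stopifnot(sum(other) + n_malaria == n_total)

  with_seed(seed, {
    rows <- list(
      data.frame(node_id = "CT", name = "Country", level = "country",
                 parent_id = "", admin_category = "", stringsAsFactors = FALSE),
      data.frame(node_id = "R1", name = "Estuaire", level = "region",
                 parent_id = "CT", admin_category = "", stringsAsFactors = FALSE),
      data.frame(node_id = "R1-D1", name = "Komo-Mondah", level = "district",
                 parent_id = "R1", admin_category = "", stringsAsFactors = FALSE)
    )
    for (f in seq_len(n_facilities)) {
      fid <- sprintf("R1-D1-F%02d", f)
      rows[[length(rows) + 1]] <- data.frame(
        node_id = fid, name = sprintf("Centre de Santé %02d", f),
        level = "facility", parent_id = "R1-D1", admin_category = "public",
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        node_id = sprintf("%s-S1", fid), name = "Médecine Générale",
        level = "service", parent_id = fid, admin_category = "",
        stringsAsFactors = FALSE)
    }
    pyramid <- as_pyramid(do.call(rbind, rows))
    services <- pyramid$node_id[pyramid$level == "service"]

    # exact multiset of codes, shuffled over consultations
    codes <- sample(c(rep("B54", n_malaria),
                      rep(names(other), times = other)))
    service_ids <- sample(services, n_total, replace = TRUE)
    diag_codes <- as.list(codes)
    reg <- build_register_rows(n_total, service_ids, diag_codes,
                               integer(n_total), integer(n_total), dicts,
                               id_prefix = "KM")
    start <- as.Date("2018-01-20"); end <- as.Date("2018-07-12")
    exam <- start + sample.int(as.integer(end - start) + 1L, n_total,
                               replace = TRUE) - 1L
    reg$examination_date <- format(exam, "%Y-%m-%d")
    reg$recorded_at <- reg$examination_date

    files <- c(
      pyramid = file.path(dir, "pyramid.csv"),
      register = file.path(dir, "register.csv"),
      dictionary_icd10 = file.path(dir, "dictionary_icd10.csv"),
      dictionary_atc = file.path(dir, "dictionary_atc.csv"),
      dictionary_loinc = file.path(dir, "dictionary_loinc.csv"),
      manifest = file.path(dir, "manifest.txt")
    )
    write_hf_csv(as.data.frame(pyramid), files[["pyramid"]])
    write_hf_csv(reg, files[["register"]])
    write_hf_csv(as.data.frame(dicts$icd10), files[["dictionary_icd10"]])
    write_hf_csv(as.data.frame(dicts$atc), files[["dictionary_atc"]])
    write_hf_csv(as.data.frame(dicts$loinc), files[["dictionary_loinc"]])

    fac_of_service <- pyramid$parent_id[match(service_ids, pyramid$node_id)]
    fac_names <- pyramid$name[match(fac_of_service, pyramid$node_id)]
    mal_tab <- table(fac_names[codes == "B54"])
    all_tab <- table(fac_names)
    manifest <- list(
      values = list(
        seed = seed,
        n_consultations = n_total,
        n_malaria = n_malaria,
        malaria_code = "B54",
        district = "Komo-Mondah"
      ),
      tables = list(
        facility_malaria_counts = data.frame(facility = names(mal_tab),
                                             count = as.integer(mal_tab),
                                             stringsAsFactors = FALSE),
        facility_consultations = data.frame(facility = names(all_tab),
                                            count = as.integer(all_tab),
                                            stringsAsFactors = FALSE)
      )
    )
    write_manifest(manifest, files[["manifest"]])
    structure(list(dir = dir, files = files, manifest = manifest),
              class = "synthetic_dataset")
  })
}

#' Paired evaluation-matrix fixture
#'
#' A complete 14-user yes/no matrix for the two compared systems over seven
#' criteria grouped as completeness (3), timeliness (2) and accuracy (2),
#' with deterministic per-user assignments whose column sums are: new system
#' 14, 12, 13 | 13, 14 | 14, 14 and traditional system 2, 1, 2 | 1, 4 | 4, 1.
#' Also returns the users' achievable-completeness band declarations
#' (new system: 12 of 14 in the `>=80` band).
#'
#' @return list with `matrix` (long evaluation data frame) and
#'   `completeness_bands` (`system`, `user_id`, `band`).
#' @export
evaluation_fixture <- function() {
  users <- sprintf("U%02d", 1:14)
  criteria <- data.frame(
    criterion_id = c("COMP1", "COMP2", "COMP3", "TIME1", "TIME2", "ACC1", "ACC2"),
    dimension = c("completeness", "completeness", "completeness",
                  "timeliness", "timeliness", "accuracy", "accuracy"),
    stringsAsFactors = FALSE
  )
  yes_new <- c(COMP1 = 14L, COMP2 = 12L, COMP3 = 13L,
               TIME1 = 13L, TIME2 = 14L, ACC1 = 14L, ACC2 = 14L)
  yes_old <- c(COMP1 = 2L, COMP2 = 1L, COMP3 = 2L,
               TIME1 = 1L, TIME2 = 4L, ACC1 = 4L, ACC2 = 1L)

  rows <- list()
  for (i in seq_len(nrow(criteria))) {
    cid <- criteria$criterion_id[i]
    for (sys in c("new", "traditional")) {
      k <- if (sys == "new") yes_new[[cid]] else yes_old[[cid]]
      rows[[length(rows) + 1]] <- data.frame(
        user_id = users, criterion_id = cid, dimension = criteria$dimension[i],
        system = sys, response = as.integer(seq_along(users) <= k),
        stringsAsFactors = FALSE
      )
    }
  }
  matrix <- do.call(rbind, rows)
  rownames(matrix) <- NULL

  bands <- rbind(
    data.frame(system = "new", user_id = users,
               band = c(rep(">=80", 12), rep("50-80", 2)),
               stringsAsFactors = FALSE),
    data.frame(system = "traditional", user_id = users,
               band = c("<30", rep("30-50", 11), "50-80", ">=80"),
               stringsAsFactors = FALSE)
  )
  list(matrix = matrix, completeness_bands = bands)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> in ", x$dir, "\n", sep = "")
  for (k in names(x$manifest$values)) {
    cat("  ", k, ": ", as.character(x$manifest$values[[k]]), "\n", sep = "")
  }
  invisible(x)
}
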