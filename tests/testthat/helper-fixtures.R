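# Shared in-code fixtures for the test suite. Everything is built
# programmatically; no binary data.

# minimal legal tree: one node per level
chain_pyramid_df <- function() {
  data.frame(
    node_id = c("CT", "R1", "D1", "F1", "S1"),
    name = c("Country", "North", "Upper North", "Central Clinic", "Outpatient"),
    level = c("country", "region", "district", "facility", "service"),
    parent_id = c("", "CT", "R1", "D1", "F1"),
    stringsAsFactors = FALSE
  )
}

chain_pyramid <- function() as_pyramid(chain_pyramid_df())

# 31 nodes: 1 + 2 regions x (1 + 2 districts x (1 + 2 facilities x (1 + 2 services)))
full_pyramid <- function() {
  generate_pyramid(c(regions = 2L, districts = 2L, facilities = 2L, services = 2L))
}

tiny_icd10 <- function() {
  as_dictionary(data.frame(
    code = c("A09", "B54", "J11"),
    system = "ICD10",
    preferred_term = c("Diarrhée et gastro-entérite", "Paludisme", "Grippe"),
    synonyms = c("diarrhée aiguë", "paludisme grave|palu", "syndrome grippal"),
    stringsAsFactors = FALSE
  ))
}

# one register row in the CSV column layout
register_row <- function(num = "E1", date = "2018-02-03", recorded = date,
                         service = "S1", sex = "F", age = "30",
                         diagnoses = "paludisme", drugs = "", labs = "") {
  data.frame(
    num_examination = num, examination_date = date, recorded_at = recorded,
    service_id = service, patient_sex = sex, patient_age = age,
    patient_nationality = "Gabonaise", patient_residence = "Ntoum",
    insurance_status = "CNAMGS", government_coverage = "true",
    occupation = "enseignant", copayment_rate = "0.2",
    diagnoses = diagnoses, drugs = drugs, labs = labs,
    stringsAsFactors = FALSE
  )
}

write_register_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  path
}

# independent random-string maker for property tests
random_term <- function(n_tokens, vocab) {
  paste(sample(vocab, n_tokens, replace = TRUE), collapse = " ")
}

# full chain register -> mapped -> facts, used by several suites
komo_facts <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- komo_mondah_fixture(dir = tempfile("komo"))
      pyr <- load_pyramid(ds$files[["pyramid"]])
      reg <- parse_register(ds$files[["register"]], pyr)
      dicts <- list(load_dictionary(ds$files[["dictionary_icd10"]]),
                    load_dictionary(ds$files[["dictionary_atc"]]),
                    load_dictionary(ds$files[["dictionary_loinc"]]))
      reg <- attach_mappings(reg, dicts)
      cache <<- list(ds = ds, pyramid = pyr, reg = reg,
                     facts = build_fact_table(reg, pyr))
    }
    cache
  }
})
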