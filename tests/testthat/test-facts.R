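mapped_chain_reg <- function(rows) {
  reg <- parse_register(write_register_csv(rows), chain_pyramid())
  attach_mappings(reg, builtin_dictionaries(), threshold = 0.6)
}

test_that("fact grain is one row per clinical entry, sharing the consultation id", {
  rows <- register_row("E1", diagnoses = "paludisme|grippe", drugs = "Paracétamol")
  facts <- build_fact_table(mapped_chain_reg(rows), chain_pyramid())
  expect_equal(nrow(facts), 3)
  expect_equal(unique(facts$num_examination), "E1")
  expect_equal(sum(!is.na(facts$code_icd10_or_icpc2)), 2)
  expect_equal(sum(!is.na(facts$code_atc)), 1)
  # per row only the originating family's columns are populated
  diag_rows <- !is.na(facts$code_icd10_or_icpc2)
  expect_true(all(is.na(facts$code_atc[diag_rows])))
  expect_true(all(is.na(facts$local_concept_medicine[diag_rows])))
  # geography resolved from the pyramid
  expect_equal(unique(facts$health_district_name), "Upper North")
  expect_equal(unique(facts$health_care_service_name), "Outpatient")
})

test_that("a consultation without entries keeps one all-null-codes row", {
  rows <- register_row("E9", diagnoses = "", drugs = "", labs = "")
  facts <- build_fact_table(mapped_chain_reg(rows), chain_pyramid())
  expect_equal(nrow(facts), 1)
  expect_true(is.na(facts$code_icd10_or_icpc2))
  expect_true(is.na(facts$code_atc))
  expect_true(is.na(facts$code_loinc))
  expect_true(is.na(facts$local_concept_diagnosis))
})

test_that("fact row count equals the sum over consultations of max(1, entries)", {
  ds <- generate_dataset(generator_config(seed = 11, n_consultations = 300),
                         dir = tempfile())
  pyr <- load_pyramid(ds$files[["pyramid"]])
  reg <- parse_register(ds$files[["register"]], pyr)
  facts <- build_fact_table(reg, pyr)
  per_consult <- table(reg$entries$num_examination)
  expected <- sum(vapply(reg$records$num_examination, function(id) {
    max(1L, if (id %in% names(per_consult)) as.integer(per_consult[[id]]) else 0L)
  }, integer(1)))
  expect_equal(nrow(facts), expected)
})

test_that("aggregation counts distinct consultations and shares sum to one", {
  rows <- rbind(register_row("E1", sex = "F", diagnoses = "paludisme|palu"),
                register_row("E2", sex = "M", diagnoses = "grippe"),
                register_row("E3", sex = "F", diagnoses = "gastrite"))
  facts <- build_fact_table(mapped_chain_reg(rows), chain_pyramid())
  cube <- aggregate_facts(facts, "patient_sex")
  expect_equal(sum(cube$share), 1, tolerance = 1e-9)
  # duplicated entries within a visit never inflate consultation_count
  expect_equal(cube$consultation_count[cube$patient_sex == "F"], 2)
  expect_equal(sum(cube$consultation_count), 3)
})

test_that("time grains label days, ISO weeks, months and years", {
  rows <- rbind(register_row("E1", date = "2018-01-01"),
                register_row("E2", date = "2018-01-04"),
                register_row("E3", date = "2018-02-05"))
  facts <- build_fact_table(mapped_chain_reg(rows), chain_pyramid())
  wk <- aggregate_facts(facts, "examination_date", time_grain = "week")
  # 2018-01-01 (Mon) and 2018-01-04 share ISO week 2018-W01
  expect_equal(wk$examination_date,  c("2018-W01", "2018-W06"))
  expect_equal(wk$consultation_count, c(2L, 1L))
  mo <- aggregate_facts(facts, "examination_date", time_grain = "month")
  expect_equal(mo$examination_date, c("2018-01", "2018-02"))
  yr <- aggregate_facts(facts, "examination_date", time_grain = "year")
  expect_equal(yr$consultation_count, 3L)
})

test_that("age bands follow the configured breaks", {
  rows <- rbind(register_row("E1", age = "4"), register_row("E2", age = "5"),
                register_row("E3", age = "30"), register_row("E4", age = "70"))
  facts <- build_fact_table(mapped_chain_reg(rows), chain_pyramid())
  cube <- aggregate_facts(facts, "age_band")
  expect_setequal(cube$age_band, c("0-4", "5-14", "15-49", "50+"))
  expect_equal(cube$consultation_count[cube$age_band == "15-49"], 1L)
})

test_that("invalid aggregation requests are refused", {
  rows <- register_row("E1")
  facts <- build_fact_table(mapped_chain_reg(rows), chain_pyramid())
  expect_error(aggregate_facts(facts, "favourite_colour"), class = "hf_validation_error")
  expect_error(aggregate_facts(facts, "examination_date"), class = "hf_validation_error")
  cube <- aggregate_facts(facts, "health_care_facility_name")
  expect_error(drill_down(cube, facts, "district"), class = "hf_validation_error")
})

test_that("an empty fact set aggregates to an empty cube", {
  rows <- register_row("E1")
  facts <- build_fact_table(mapped_chain_reg(rows), chain_pyramid())
  cube <- aggregate_facts(facts, "patient_sex",
                          filters = list(patient_sex = "M"))
  expect_equal(nrow(cube), 0)
})

test_that("roll-up conserves measures from district to facility and service", {
  ds <- generate_dataset(generator_config(seed = 5, n_consultations = 400),
                         dir = tempfile())
  pyr <- load_pyramid(ds$files[["pyramid"]])
  reg <- parse_register(ds$files[["register"]], pyr)
  facts <- build_fact_table(reg, pyr)
  parent <- aggregate_facts(facts, "health_district_name")
  child <- drill_down(parent, facts, "facility")
  for (d in parent$health_district_name) {
    expect_equal(sum(child$consultation_count[child$health_district_name == d]),
                 parent$consultation_count[parent$health_district_name == d])
    expect_equal(sum(child$entry_count[child$health_district_name == d]),
                 parent$entry_count[parent$health_district_name == d])
  }
  grandchild <- drill_down(parent, facts, "service")
  expect_equal(sum(grandchild$consultation_count), sum(parent$consultation_count))
  # brute-force recount of one district from the raw records
  d1 <- parent$health_district_name[1]
  svc <- pyr$node_id[pyr$level == "service"]
  svc_d1 <- svc[vapply(svc, function(s) geography_of(s, pyr)[["district"]] == d1, logical(1))]
  expect_equal(parent$consultation_count[1],
               sum(reg$records$service_id %in% svc_d1))
})

test_that("export and load round-trip the fact table losslessly", {
  rows <- rbind(register_row("E1", diagnoses = "paludisme", labs = "glycémie"),
                register_row("E2", diagnoses = ""))
  facts <- build_fact_table(mapped_chain_reg(rows), chain_pyramid())
  path <- tempfile(fileext = ".csv")
  export_facts(facts, path)
  back <- load_facts(path)
  expect_equal(as.data.frame(back), as.data.frame(facts))
  header <- readLines(path, n = 1)
  expect_equal(strsplit(gsub('"', "", header), ",")[[1]],
               names(as.data.frame(facts)))
})

test_that("a fact file with a missing column is refused on load", {
  rows <- register_row("E1")
  facts <- build_fact_table(mapped_chain_reg(rows), chain_pyramid())
  path <- tempfile(fileext = ".csv")
  export_facts(facts, path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  utils::write.csv(df[, -6], path, row.names = FALSE)
  expect_error(load_facts(path), class = "hf_validation_error")
})

test_that("the committed golden fact file parses to its three known rows", {
  facts <- load_facts(test_path("golden_facts.csv"))
  expect_equal(nrow(facts), 3)
  expect_equal(facts$num_examination, c("G1", "G1", "G2"))
  expect_equal(facts$code_icd10_or_icpc2, c("B54", NA, NA))
  expect_equal(facts$code_atc, c(NA, "N02BE01", NA))
  expect_equal(facts$standard_concept_diagnosis[1], "Paludisme")
  expect_equal(facts$examination_date, as.Date(c("2018-03-01", "2018-03-01", "2018-03-02")))
})
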