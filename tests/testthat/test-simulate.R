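test_that("a fixed seed reproduces byte-identical dataset files", {
  cfg <- generator_config(seed = 1, n_consultations = 150)
  d1 <- generate_dataset(cfg, dir = tempfile())
  d2 <- generate_dataset(cfg, dir = tempfile())
  for (k in names(d1$files)) {
    expect_identical(readLines(d1$files[[k]], warn = FALSE),
                     readLines(d2$files[[k]], warn = FALSE),
                     label = k)
  }
})

test_that("a degenerate diagnosis mix codes every consultation identically", {
  cfg <- generator_config(seed = 2, n_consultations = 100,
                          diagnosis_mix = c(B54 = 1),
                          diagnoses_per_visit = c("1" = 1))
  ds <- generate_dataset(cfg, dir = tempfile())
  expect_equal(ds$manifest$tables$diagnosis_code_counts$code, "B54")
  expect_equal(ds$manifest$tables$diagnosis_code_counts$count, 100L)
  # and the emitted terms all map back to that code
  pyr <- load_pyramid(ds$files[["pyramid"]])
  reg <- parse_register(ds$files[["register"]], pyr)
  reg <- attach_mappings(reg, list(load_dictionary(ds$files[["dictionary_icd10"]]),
                                   load_dictionary(ds$files[["dictionary_atc"]]),
                                   load_dictionary(ds$files[["dictionary_loinc"]])))
  diag <- reg$entries[reg$entries$kind == "diagnosis", ]
  expect_true(all(diag$code == "B54"))
})

test_that("an invalid probability vector is rejected", {
  expect_error(generator_config(diagnosis_mix = c(B54 = 0.7, A09 = 0.7)),
               class = "hf_validation_error")
  expect_error(generator_config(missingness_rate = 1.5), class = "hf_validation_error")
})

test_that("a 49% sampling mix lands in the binomial 99% interval around 2966", {
  cfg <- generator_config(seed = 21, n_consultations = 6054,
                          diagnosis_mix = c(B54 = 0.49, A09 = 0.51),
                          diagnoses_per_visit = c("1" = 1),
                          drugs_per_visit = c("0" = 1), labs_per_visit = c("0" = 1))
  ds <- generate_dataset(cfg, dir = tempfile())
  counts <- ds$manifest$tables$diagnosis_code_counts
  malaria <- counts$count[counts$code == "B54"]
  lo <- qbinom(0.005, 6054, 0.49)
  hi <- qbinom(0.995, 6054, 0.49)
  expect_gte(malaria, lo)
  expect_lte(malaria, hi)
})

test_that("clean-rate datasets parse with zero rejections and a truthful manifest", {
  ds <- generate_dataset(generator_config(seed = 4, n_consultations = 250),
                         dir = tempfile())
  pyr <- load_pyramid(ds$files[["pyramid"]])
  reg <- parse_register(ds$files[["register"]], pyr)
  expect_equal(nrow(reg$rejections), 0)
  expect_equal(nrow(reg$records), 250)
  # manifest counts equal brute-force recounts of the emitted CSV
  fac_of <- pyr$parent_id[match(reg$records$service_id, pyr$node_id)]
  recount <- table(fac_of)
  man <- ds$manifest$tables$facility_consultations
  expect_equal(man$count, as.integer(recount[man$facility]))
  dict <- load_dictionary(ds$files[["dictionary_icd10"]])
  expect_s3_class(dict, "term_dictionary")
  subs <- utils::read.csv(ds$files[["submissions"]], colClasses = "character")
  expect_true(all(c("facility", "month", "submission_date") %in% names(subs)))
})

test_that("the district worked-example fixture has exact headline counts", {
  fx <- komo_facts()
  expect_equal(fx$ds$manifest$values$n_consultations, 6054L)
  expect_equal(fx$ds$manifest$values$n_malaria, 2966L)
  man <- fx$ds$manifest$tables$facility_malaria_counts
  expect_equal(sum(man$count), 2966L)
  expect_equal(nrow(fx$reg$records), 6054)
  # one diagnosis per consultation, by construction
  expect_equal(nrow(fx$reg$entries), 6054)
  expect_true(all(fx$reg$entries$kind == "diagnosis"))
})

test_that("the evaluation fixture is a complete grid with the printed column sums", {
  fix <- evaluation_fixture()
  m <- fix$matrix
  expect_equal(nrow(m), 14 * 7 * 2)
  expect_equal(anyDuplicated(m[, c("user_id", "criterion_id", "system")]), 0)
  sums <- tapply(m$response, list(m$system, m$criterion_id), sum)
  expect_equal(sums["new", c("COMP1", "COMP2", "COMP3")],
               c(COMP1 = 14L, COMP2 = 12L, COMP3 = 13L))
  expect_equal(sums["new", c("TIME1", "TIME2")], c(TIME1 = 13L, TIME2 = 14L))
  expect_equal(sums["new", c("ACC1", "ACC2")], c(ACC1 = 14L, ACC2 = 14L))
  expect_equal(sums["traditional", c("COMP1", "COMP2", "COMP3")],
               c(COMP1 = 2L, COMP2 = 1L, COMP3 = 2L))
  expect_equal(sums["traditional", c("TIME1", "TIME2")], c(TIME1 = 1L, TIME2 = 4L))
  expect_equal(sums["traditional", c("ACC1", "ACC2")], c(ACC1 = 4L, ACC2 = 1L))
})
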