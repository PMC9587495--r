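test_that("field completeness counts filled cells over records x fields", {
  full <- data.frame(a = c("x", "y"), b = c("1", "2"), stringsAsFactors = FALSE)
  expect_equal(field_completeness(full, c("a", "b")), 100)
  half <- data.frame(a = c("x", ""), b = c(NA, "2"), stringsAsFactors = FALSE)
  expect_equal(field_completeness(half, c("a", "b")), 50)
  expect_error(field_completeness(full[0, ], "a"), class = "hf_validation_error")
  expect_error(field_completeness(full, "zz"), class = "hf_validation_error")
})

test_that("field completeness recovers the generator's injected missingness", {
  ds <- generate_dataset(generator_config(seed = 3, n_consultations = 500,
                                          missingness_rate = 0.2),
                         dir = tempfile())
  pyr <- load_pyramid(ds$files[["pyramid"]])
  reg <- parse_register(ds$files[["register"]], pyr)
  audit <- c("patient_sex", "patient_age", "patient_nationality",
             "patient_residence", "insurance_status", "occupation")
  pct <- field_completeness(reg$records, audit)
  # brute-force recount straight off the emitted file
  raw <- utils::read.csv(ds$files[["register"]], colClasses = "character")
  filled <- sum(vapply(audit, function(c) sum(nzchar(raw[[c]])), numeric(1)))
  expect_equal(pct, 100 * filled / (nrow(raw) * length(audit)))
  expect_equal(pct, 80, tolerance = 3 / 80)
  # manifest agrees with the recount of blanks
  blanks <- sum(vapply(audit, function(c) sum(!nzchar(raw[[c]])), numeric(1)))
  expect_equal(ds$manifest$values$n_missing_cells, blanks)
})

test_that("reporting completeness is the received fraction of expected reports", {
  expected <- expand.grid(facility = c("F1", "F2"), month = c("2018-01", "2018-02", "2018-03"),
                          stringsAsFactors = FALSE)
  expect_equal(reporting_completeness(expected, expected), 100)
  expect_equal(reporting_completeness(expected, expected[0, ]), 0)
  five <- expected[-4, ]
  expect_equal(round_half_up(reporting_completeness(expected, five)), 83)
  expect_error(reporting_completeness(expected[0, ], expected), class = "hf_validation_error")
})

test_that("the submission deadline is inclusive on day 5 of the next month", {
  reports <- data.frame(facility = "F1", month = "2018-01",
                        submission_date = "2018-02-05", stringsAsFactors = FALSE)
  expect_equal(timeliness(reports)$on_time_pct, 100)
  reports$submission_date <- "2018-02-06"
  expect_equal(timeliness(reports)$on_time_pct, 0)
  # missing submission is late but leaves the mean delay finite
  two <- data.frame(facility = "F1", month = c("2018-01", "2018-02"),
                    submission_date = c("2018-02-03", NA), stringsAsFactors = FALSE)
  tl <- timeliness(two)
  expect_equal(tl$on_time_pct, 50)
  expect_equal(tl$mean_delay_days, 3)
  expect_error(timeliness(data.frame(facility = "F1", month = "2018-13",
                                     submission_date = "2019-01-02")),
               class = "hf_validation_error")
})

test_that("a 12-report calendar reproduces hand-computed timeliness", {
  # months 2018-01..2018-12 submitted 1..12 days after period end
  months <- sprintf("2018-%02d", 1:12)
  ends <- as.Date(c("2018-01-31", "2018-02-28", "2018-03-31", "2018-04-30",
                    "2018-05-31", "2018-06-30", "2018-07-31", "2018-08-31",
                    "2018-09-30", "2018-10-31", "2018-11-30", "2018-12-31"))
  reports <- data.frame(facility = "F1", month = months,
                        submission_date = format(ends + 1:12, "%Y-%m-%d"),
                        stringsAsFactors = FALSE)
  tl <- timeliness(reports)
  # delays 1..12; on time iff delay <= 5 -> 5 of 12
  expect_equal(tl$on_time_pct, 100 * 5 / 12)
  expect_equal(tl$mean_delay_days, mean(1:12))
  expect_equal(tl$per_report$delay_days, as.numeric(1:12))
})

test_that("accuracy conformity is 100 on an untouched pipeline and drops per corruption", {
  rows <- do.call(rbind, lapply(1:10, function(i)
    register_row(sprintf("E%d", i), age = as.character(20 + i))))
  reg <- parse_register(write_register_csv(rows), chain_pyramid())
  facts <- build_fact_table(reg, chain_pyramid())
  expect_equal(accuracy_conformity(facts, reg$records), 100)
  corrupted <- reg$records
  corrupted$patient_age[4] <- 99L
  expect_equal(accuracy_conformity(facts, corrupted), 90)
  dup <- rbind(reg$records, reg$records[1, ])
  expect_error(accuracy_conformity(facts, dup), class = "hf_validation_error")
})

test_that("generator corruption rate is recovered by the conformity audit", {
  ds <- generate_dataset(generator_config(seed = 9, n_consultations = 500,
                                          corruption_rate = 0.1),
                         dir = tempfile())
  pyr <- load_pyramid(ds$files[["pyramid"]])
  emitted <- parse_register(ds$files[["register"]], pyr)
  source <- parse_register(ds$files[["register_source"]], pyr)
  facts <- build_fact_table(emitted, pyr)
  pct <- accuracy_conformity(facts, source$records)
  n_corrupt <- nrow(ds$manifest$tables$corrupted_num_examinations)
  expect_equal(pct, 100 * (1 - n_corrupt / 500))
  expect_equal(pct, 90, tolerance = 4 / 90)
})

test_that("evaluation scoring pools yes-fractions with the equal-weight identity", {
  fix <- evaluation_fixture()
  s <- score_evaluation(fix$matrix)
  # dimension aggregate = user-weighted mean of its criterion fractions
  for (i in seq_len(nrow(s$dimensions))) {
    d <- s$dimensions[i, ]
    crit <- s$criteria[s$criteria$system == d$system & s$criteria$dimension == d$dimension, ]
    expect_equal(d$pct_raw, mean(crit$pct_raw))
    expect_equal(d$yes, sum(crit$yes))
  }
  # all-no matrix scores zero everywhere
  zero <- fix$matrix
  zero$response <- 0L
  s0 <- score_evaluation(zero)
  expect_true(all(s0$overall$pct == 0))
  expect_true(all(s0$dimensions$pct_raw == 0))
})

test_that("incomplete or mislabelled evaluation matrices are refused", {
  fix <- evaluation_fixture()
  expect_error(score_evaluation(fix$matrix[-1, ]), class = "hf_validation_error")
  bad <- fix$matrix
  bad$response[1] <- 2L
  expect_error(score_evaluation(bad), class = "hf_validation_error")
  expect_error(score_evaluation(fix$matrix[0, ]), class = "hf_validation_error")
})

test_that("completeness bands tally users and refuse unknown labels", {
  one <- completeness_categories(rep(">=80", 5))
  expect_equal(one$pct, c(0, 0, 0, 100))
  expect_equal(sum(one$count), 5)
  set.seed(8)
  bands <- sample(c("<30", "30-50", "50-80", ">=80"), 40, replace = TRUE)
  tallied <- completeness_categories(bands)
  expect_equal(tallied$count,
               as.integer(table(factor(bands, levels = tallied$band))))
  expect_equal(sum(tallied$count), 40)
  expect_error(completeness_categories(c(">=80", "80-90")), class = "hf_validation_error")
})

test_that("mcnemar_exact matches hand computations and caps at one", {
  expect_equal(mcnemar_exact(4, 4), 1)
  expect_equal(mcnemar_exact(5, 0), 2 * (1 / 32))
  expect_lt(mcnemar_exact(34, 0), 1e-9)
  expect_error(mcnemar_exact(0, 0), class = "hf_validation_error")
})

test_that("mcnemar_exact agrees with full enumeration of discordance sequences", {
  for (pair in list(c(1, 0), c(2, 1), c(3, 3), c(5, 0), c(6, 2), c(7, 5), c(12, 0))) {
    b <- pair[1]; c <- pair[2]; n <- b + c
    # oracle: all 2^n equally likely yes/no sequences; two-sided doubled tail
    seqs <- expand.grid(rep(list(0:1), n))
    k <- rowSums(seqs)
    p_enum <- min(1, 2 * mean(k >= max(b, c)))
    expect_equal(mcnemar_exact(b, c), p_enum)
  }
})

test_that("the marginal bound enumerates exactly the feasible paired tables", {
  # forced table when one margin is zero
  forced <- mcnemar_bound_from_marginals(10, 0, 10)
  expect_equal(nrow(forced$tables), 1)
  expect_equal(forced$tables$b, 10)
  expect_equal(forced$tables$c, 0)

  bound <- mcnemar_bound_from_marginals(39, 5, 42)
  expect_equal(bound$tables$b, c(34, 35, 36, 37))
  expect_equal(bound$tables$c, c(0, 1, 2, 3))
  expect_equal(bound$p_value, max(bound$tables$p))
  expect_error(mcnemar_bound_from_marginals(50, 0, 42), class = "hf_validation_error")
})

test_that("the quality report self-check always reaches full conformity", {
  ds <- generate_dataset(generator_config(seed = 12, n_consultations = 200),
                         dir = tempfile())
  pyr <- load_pyramid(ds$files[["pyramid"]])
  reg <- parse_register(ds$files[["register"]], pyr)
  facts <- build_fact_table(reg, pyr)
  subs <- utils::read.csv(ds$files[["submissions"]], colClasses = "character")
  subs$submission_date[subs$submission_date == ""] <- NA
  qr <- quality_report(reg, facts, pyr, submissions = subs)
  expect_equal(qr$accuracy_pct, 100)
  expect_equal(qr$reporting_completeness_pct, 100)
  expect_gte(qr$timeliness_pct, 0); expect_lte(qr$timeliness_pct, 100)
  expect_gte(qr$field_completeness_pct, 0); expect_lte(qr$field_completeness_pct, 100)
  expect_true(is.finite(qr$mean_delay_days))
})
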