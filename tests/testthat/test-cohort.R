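test_that("catalog has 20 entities and the documented composites", {
  expect_equal(nrow(catalog20), 20L)
  expect_setequal(unique(catalog20$instrument),
                  c("mini", "addis", "nods", "igds"))
  expect_setequal(composite_members(catalog20, "any_anxiety"),
                  c("panic_disorder", "agoraphobia", "social_anxiety",
                    "ocd", "ptsd", "gad"))
  expect_equal(composite_members(catalog20, "at_least_one"), catalog20$entity)
  expect_error(composite_members(catalog20, "nope"), "unknown composite")
  expect_error(entity_instrument(catalog20, "nope"), "not in catalog")
})

test_that("cohorts round-trip through write/read byte-identically", {
  ch <- hand_counts_cohort()[1:3, ]
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, f)
  back <- read_cohort(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ch))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("a freshly generated cohort re-reads equal to what was written", {
  sim <- generate_cohort(cohort_config(seed = 31))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, f)
  expect_equal(tibble::as_tibble(read_cohort(f)),
               tibble::as_tibble(sim$cohort))
})

test_that("writing an empty cohort yields a header-only file", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(blank_cohort(2)[0, ], f)
  lines <- readLines(f)
  expect_length(lines, 1L)
  expect_equal(strsplit(lines, ",")[[1]], cohort_columns())
})

test_that("missing optional items are written with the NA token", {
  ch <- blank_cohort(1)
  ch$attraction_same <- NA_character_
  ch$attraction_opposite <- NA_character_
  ch$gender_contentment <- NA_character_
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, f)
  expect_match(readLines(f)[2], "NA,NA,NA")
  expect_equal(tibble::as_tibble(read_cohort(f)), tibble::as_tibble(ch))
})

test_that("validation rejects a diagnosis recorded without an interview", {
  ch <- blank_cohort(3)
  ch$dx_depression[2] <- "present"   # int_mini stays FALSE
  expect_error(validate_cohort(ch), "dx_depression.*rows 2")
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, f)
  expect_error(read_cohort(f), "dx_depression.*rows 2")
})

test_that("validation pinpoints bad enum values, duplicates, not_screened misuse", {
  ch <- blank_cohort(4)
  ch$legal_gender[3] <- "FEMALE"
  expect_error(validate_cohort(ch), "invalid legal_gender.*rows 3")
  ch <- blank_cohort(4)
  ch$participant_id[4] <- ch$participant_id[1]
  expect_error(validate_cohort(ch), "duplicated participant_id.*rows 4")
  ch <- blank_cohort(4)                       # sub-cohort 2 throughout
  ch$screen_gambling[1] <- "not_screened"
  expect_error(validate_cohort(ch), "not_screened.*never-screened")
  ch <- blank_cohort(4)
  ch$screen_depression[2] <- "not_screened"
  expect_error(validate_cohort(ch), "only allowed.*gambling/gaming")
})

test_that("reading fails loudly on missing mandatory columns", {
  ch <- blank_cohort(2)
  f <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::as_tibble(ch)
  df$dx_gaming <- NULL
  readr::write_csv(df, f)
  expect_error(read_cohort(f), "missing mandatory column.*dx_gaming")
  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("write/read is the identity on randomly mutated valid cohorts", {
  set.seed(99)
  for (rep in 1:5) {
    ch <- blank_cohort(10)
    rows <- sample(10, 4)
    ch <- set_outcome(ch, rows[1], "suicidality", dx = "present")
    ch <- set_outcome(ch, rows[2], "alcohol_use", dx = "absent")
    ch <- set_outcome(ch, rows[3], "gaming", interviewed = FALSE)
    ch$attraction_same[rows[4]] <- NA_character_
    f <- withr::local_tempfile(fileext = ".csv")
    write_cohort(ch, f)
    expect_equal(tibble::as_tibble(read_cohort(f)), tibble::as_tibble(ch))
  }
})
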