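# Independent oracle: the adjustment formula evaluated directly.
prev_oracle <- function(D, ND, NI, T, PD2 = 0, NS1 = 0) {
  (D + (if (D + ND > 0) D / (D + ND) * NI else 0) + PD2 * NS1) / T
}

test_that("worked arithmetic cases match direct evaluation of the formula", {
  expect_equal(estimate_prevalence(two_phase_counts(0, 10, 5, 100))$P, 0)
  expect_equal(estimate_prevalence(two_phase_counts(4, 6, 0, 50))$P, 0.08)
  expect_equal(estimate_prevalence(two_phase_counts(5, 15, 8, 200))$P,
               0.035, tolerance = 1e-12)
  expect_equal(
    estimate_prevalence(two_phase_counts(2, 8, 5, 400, PD2 = 0.1,
                                         NS1 = 40))$P,
    0.0175, tolerance = 1e-12)
  # degenerate no-signal cell
  expect_equal(estimate_prevalence(two_phase_counts(0, 0, 0, 10))$P, 0)
})

test_that("inestimable and invalid counts raise explicit errors", {
  expect_error(estimate_prevalence(two_phase_counts(0, 0, 3, 10)),
               "inestimable")
  expect_error(estimate_prevalence(two_phase_counts(0, 0, 0, 0)),
               "T must be positive")
  expect_error(two_phase_counts(5, 5, 5, 10), "exceed group size")
  expect_error(two_phase_counts(1, 1, 1, 10, PD2 = 0.5), "together")
  expect_error(two_phase_counts(1, 1, 1, 10, PD2 = 1.5, NS1 = 2),
               "proportion")
  expect_error(two_phase_counts(-1, 1, 1, 10), "non-negative")
})

test_that("the extended formula reduces to the basic one and stays in bounds", {
  set.seed(7)
  for (i in 1:200) {
    T <- sample(5:500, 1)
    D <- sample(0:min(T, 30), 1)
    ND <- sample(0:(T - D), 1)
    NI <- sample(0:(T - D - ND), 1)
    if (NI > 0 && D + ND == 0) NI <- 0
    basic <- estimate_prevalence(two_phase_counts(D, ND, NI, T))$P
    expect_identical(
      estimate_prevalence(two_phase_counts(D, ND, NI, T, PD2 = 0.37,
                                           NS1 = 0))$P, basic)
    expect_identical(
      estimate_prevalence(two_phase_counts(D, ND, NI, T, PD2 = 0,
                                           NS1 = T - D - ND - NI))$P, basic)
    expect_equal(basic, prev_oracle(D, ND, NI, T), tolerance = 1e-12)
    expect_gte(basic, D / T)
    expect_lte(basic, (D + NI) / T)
    if (NI == 0) expect_identical(basic, D / T)
  }
})

test_that("P is monotone in D and, when D > 0, in NI", {
  p <- function(D, ND, NI, T) estimate_prevalence(
    two_phase_counts(D, ND, NI, T))$P
  for (D in 1:5) expect_gt(p(D + 1, 10, 4, 100), p(D, 10, 4, 100))
  for (NI in 0:5) expect_gt(p(3, 10, NI + 1, 100), p(3, 10, NI, 100))
  # with D = 0 the imputed term stays 0
  expect_equal(p(0, 10, 9, 100), p(0, 10, 2, 100))
})

test_that("aggregate_counts reproduces hand-enumerated fixtures", {
  all10 <- aggregate_counts(blank_cohort(10), 1:10, "depression")
  expect_equal(all10[c("D", "ND", "NI", "T")],
               list(D = 0L, ND = 0L, NI = 0L, T = 10L))
  cnt <- aggregate_counts(hand_counts_cohort(), 1:20, "depression")
  expect_equal(cnt[c("D", "ND", "NI", "T")],
               list(D = 2L, ND = 2L, NI = 2L, T = 20L))
  expect_null(cnt$NS1)
  expect_error(aggregate_counts(blank_cohort(3), 1:3, "nope"),
               "not in catalog")
})

test_that("gambling counts carry NS1 and a group-restricted PD2", {
  ch <- gambling_cohort()
  expect_equal(compute_pd2(ch, "gambling"), 0.1)
  cnt <- aggregate_counts(ch, 1:20, "gambling")
  expect_equal(cnt$NS1, 5L)
  expect_equal(cnt$PD2, 0.1)
  expect_equal(cnt[c("D", "ND", "NI", "T")],
               list(D = 1L, ND = 1L, NI = 0L, T = 20L))
  expect_equal(estimate_prevalence(cnt)$P, (1 + 0.1 * 5) / 20)
  # all-negative reference: PD2 = 0; empty reference errors
  ch0 <- blank_cohort(10)
  expect_equal(compute_pd2(ch0, "gambling"), 0)
  ch1 <- blank_cohort(4, sub_cohort = 1L)
  ch1$screen_gambling <- "not_screened"
  ch1$screen_gaming <- "not_screened"
  expect_error(compute_pd2(ch1, "gambling"), "reference sub-cohort empty")
  expect_error(compute_pd2(ch0, "depression"), "only for the gambling")
})

test_that("PD2 reference subset follows the spec'd adjusted-prevalence rule", {
  # subset of 50 with (D=2, ND=3, NI=0) -> 0.04; (D=2, ND=2, NI=4) -> 0.08
  ch <- blank_cohort(50)
  ch <- set_outcome(ch, 1:2, "gambling", dx = "present")
  ch <- set_outcome(ch, 3:5, "gambling", dx = "absent")
  expect_equal(compute_pd2(ch, "gambling"), 0.04)
  ch <- blank_cohort(50)
  ch <- set_outcome(ch, 1:2, "gambling", dx = "present")
  ch <- set_outcome(ch, 3:4, "gambling", dx = "absent")
  ch <- set_outcome(ch, 5:8, "gambling", interviewed = FALSE)
  expect_equal(compute_pd2(ch, "gambling"), (2 + 2) / 50)
})

test_that("a singleton composite equals the per-entity estimate", {
  sim <- generate_cohort(cohort_config(n = 400, seed = 9))
  groups <- build_analysis_groups(sim$cohort)
  members <- groups$cells$female_heterosexual
  for (e in c("depression", "panic_disorder", "alcohol_use")) {
    single <- estimate_composite(sim$cohort, members, e)
    per_entity <- estimate_prevalence(
      aggregate_counts(sim$cohort, members, e))
    expect_equal(single$P, per_entity$P)
    expect_equal(single$counts$D, per_entity$counts$D)
    expect_equal(single$counts$ND, per_entity$counts$ND)
    expect_equal(single$counts$NI, per_entity$counts$NI)
  }
})

test_that("composite D is a person-level union", {
  # disjoint diagnoses, all indicated interviews complete:
  # composite D = sum of member D's
  ch <- blank_cohort(30)
  ch <- set_outcome(ch, 1:2, "panic_disorder", dx = "present")
  ch <- set_outcome(ch, 3, "gad", dx = "present")
  ch <- set_outcome(ch, 4:6, "social_anxiety", dx = "absent")
  anx <- estimate_composite(ch, 1:30, composite_members(catalog20,
                                                        "any_anxiety"))
  expect_equal(anx$counts$D, 3L)
  expect_equal(anx$counts$ND, 3L)
  expect_equal(anx$counts$NI, 0L)
  # one person holding two member diagnoses counts once
  ch2 <- set_outcome(ch, 1, "gad", dx = "present")
  anx2 <- estimate_composite(ch2, 1:30, composite_members(catalog20,
                                                          "any_anxiety"))
  expect_equal(anx2$counts$D, 3L)
  # an indicated-but-missing interview moves a person to NI, not ND
  ch3 <- set_outcome(ch, 7, "ocd", interviewed = FALSE)
  anx3 <- estimate_composite(ch3, 1:30, composite_members(catalog20,
                                                          "any_anxiety"))
  expect_equal(anx3$counts$NI, 1L)
})

test_that("mean diagnosis count is the sum of adjusted prevalences", {
  ch <- blank_cohort(5)
  # per-person diagnosis counts {2, 1, 0, 0, 1} with complete interviews
  ch <- set_outcome(ch, 1, "suicidality", dx = "present")
  ch <- set_outcome(ch, 1, "depression", dx = "present")
  ch <- set_outcome(ch, 2, "mania", dx = "present")
  ch <- set_outcome(ch, 5, "panic_disorder", dx = "present")
  expect_equal(mean_diagnosis_count(ch, 1:5), 0.80, tolerance = 1e-12)
  expect_equal(mean_diagnosis_count(blank_cohort(4), 1:4), 0)
  expect_error(mean_diagnosis_count(blank_cohort(4), integer(0)), "empty")
  # under complete response it equals per-person counting
  sim <- generate_cohort(no_noise_config(n = 600, seed = 17))
  groups <- build_analysis_groups(sim$cohort)
  latent <- as.matrix(sim$truth[, paste0("latent_", catalog20$entity)])
  for (cl in c("female_heterosexual", "male_bisexual")) {
    m <- groups$cells[[cl]]
    expect_equal(mean_diagnosis_count(sim$cohort, m),
                 mean(rowSums(latent[m, , drop = FALSE])),
                 tolerance = 1e-12)
  }
})

test_that("estimate_all agrees with the per-cell operations", {
  sim <- generate_cohort(cohort_config(n = 500, seed = 21))
  groups <- build_analysis_groups(sim$cohort)
  est <- estimate_all(sim$cohort, groups, on_inestimable = "na")
  for (cl in c("female_bisexual", "male_heterosexual", "gd")) {
    m <- groups$cells[[cl]]
    if (length(m) == 0) next
    for (e in c("depression", "gambling")) {
      row <- est[est$group == cl & est$entity == e, ]
      if (row$inestimable) next
      ref <- estimate_prevalence(aggregate_counts(sim$cohort, m, e))
      expect_equal(row$P, ref$P)
    }
    row <- est[est$group == cl & est$entity == "any_anxiety", ]
    ref <- estimate_composite(sim$cohort, m,
                              composite_members(catalog20, "any_anxiety"))
    expect_equal(row$P, ref$P)
  }
})
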