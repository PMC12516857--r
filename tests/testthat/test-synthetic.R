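test_that("generation is deterministic in config + seed", {
  cfg <- cohort_config(n = 500, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  d <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$cohort, d$cohort))
})

test_that("every generated cohort passes validation", {
  configs <- list(
    cohort_config(n = 300, seed = 1),
    cohort_config(n = 300, seed = 2, subcohort1_fraction = 1),
    cohort_config(n = 300, seed = 3, subcohort1_fraction = 0),
    cohort_config(n = 300, seed = 4, comorbidity_sd = 1),
    inject_informative_attrition(cohort_config(n = 300, seed = 5), 0.4),
    no_noise_config(n = 300, seed = 6)
  )
  for (cfg in configs) {
    sim <- generate_cohort(cfg)
    expect_true(validate_cohort(sim$cohort))
    expect_equal(sim$truth$participant_id, sim$cohort$participant_id)
  }
})

test_that("invalid configs are rejected before sampling", {
  expect_error(cohort_config(n = 0), "positive")
  expect_error(cohort_config(female_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(orientation_probs = list(
    female = c(0.3, 0.3, 0.3, 0.3), male = c(0.25, 0.25, 0.25, 0.25))),
    "sum to 1")
  expect_error(cohort_config(sensitivity = c(mini = 0.9)), "scalar or")
  tp <- default_true_prevalence()
  tp[1, 1] <- 2
  expect_error(cohort_config(true_prevalence = tp), "\\[0, 1\\]")
  expect_error(cohort_config(true_prevalence = tp[1:5, ]),
               "entity x stratum")
  expect_error(inject_informative_attrition(cohort_config(), 0), "positive")
})

test_that("the no-noise limit reproduces latent prevalence exactly", {
  sim <- generate_cohort(no_noise_config(n = 800, seed = 13))
  groups <- build_analysis_groups(sim$cohort)
  est <- estimate_all(sim$cohort, groups)
  truth <- latent_cell_proportions(sim, groups)
  for (cl in rownames(truth)) {
    e <- est[est$group == cl & !est$composite, ]
    expect_identical(e$P[match(colnames(truth), e$entity)],
                     unname(truth[cl, ]))
  }
})

test_that("realized group sizes track their expectations (binomial SE)", {
  reps <- 100
  cfg <- cohort_config(seed = 0)
  counts <- matrix(0, reps, 4,
                   dimnames = list(NULL, c("female", "gd", "bisexual",
                                           "selected")))
  set.seed(314)
  seeds <- sample.int(1e6, reps)
  for (r in seq_len(reps)) {
    sim <- generate_cohort(cfg, seed = seeds[r])
    g <- build_analysis_groups(sim$cohort)
    counts[r, "female"] <- sum(sim$cohort$legal_gender == "female")
    counts[r, "gd"] <- g$sizes[["gd"]]
    counts[r, "bisexual"] <- g$sizes[["female_bisexual"]] +
      g$sizes[["male_bisexual"]]
    counts[r, "selected"] <- participation_flow(sim$cohort)$n_selected
  }
  n <- cfg$n
  p_female <- cfg$female_fraction
  p_gd <- (1 - cfg$gd_missing_prob) * cfg$gd_prob
  p_bi <- (1 - cfg$orientation_missing_prob) *
    (p_female * cfg$orientation_probs$female[["bisexual"]] +
       (1 - p_female) * cfg$orientation_probs$male[["bisexual"]])
  check <- function(col, p) {
    se_mean <- sqrt(n * p * (1 - p) / reps)
    expect_lt(abs(mean(counts[, col]) - n * p), 3 * se_mean)
  }
  check("female", p_female)
  check("gd", p_gd)
  check("bisexual", p_bi)
  # aggregate screen selection lands near the design's ~80% (wide net:
  # instrument-level screens, sens .95 / spec .70)
  expect_gt(mean(counts[, "selected"]) / n, 0.75)
  expect_lt(mean(counts[, "selected"]) / n, 0.85)
})

test_that("imperfect screen sensitivity biases prevalence downward", {
  cfg <- cohort_config(n = 1500, sensitivity = 0.8, specificity = 1,
                       interview_response_prob = 1,
                       subcohort1_fraction = 0, seed = 0)
  set.seed(271)
  seeds <- sample.int(1e6, 40)
  bias <- numeric(40)
  for (r in 1:40) {
    sim <- generate_cohort(cfg, seed = seeds[r])
    groups <- build_analysis_groups(sim$cohort)
    m <- groups$cells$female_heterosexual
    est <- estimate_prevalence(aggregate_counts(sim$cohort, m, "depression"))
    bias[r] <- est$P - mean(sim$truth$latent_depression[m])
  }
  expect_lt(mean(bias), 0)
  # approximately -(1 - sens) * prevalence
  expect_equal(mean(bias), -0.2 * 0.199, tolerance = 0.035)
})

test_that("informative attrition composes on the odds scale", {
  cfg <- cohort_config()
  expect_identical(inject_informative_attrition(cfg, 1), cfg)
  cfg2 <- inject_informative_attrition(inject_informative_attrition(cfg, 0.5),
                                       4)
  expect_equal(cfg2$case_response_odds_multiplier, 2)
})

test_that("configs round-trip through YAML with partial overrides", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n: 250",
    "seed: 42",
    "interview_response_prob: 0.5",
    "true_prevalence:",
    "  female_heterosexual:",
    "    depression: 0.25"
  ), f)
  cfg <- cohort_config_from_file(f)
  expect_equal(cfg$n, 250L)
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$interview_response_prob, 0.5)
  expect_equal(cfg$true_prevalence["depression", "female_heterosexual"], 0.25)
  expect_equal(cfg$true_prevalence["mania", "female_heterosexual"],
               default_true_prevalence()["mania", "female_heterosexual"])
})
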