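#' Latent strata of the synthetic generator
#'
#' The generator assigns each participant a latent stratum that determines
#' their true diagnosis probabilities: the orientation x legal-gender cell,
#' overridden by `"gd"` for gender-discontent participants (GD is reported
#' pooled over legal genders).
#'
#' @return Character vector of stratum names.
#' @export
generator_strata <- function() c(orientation_cells(), "gd")

#' Default true-prevalence matrix of the generator
#'
#' [default_prevalence_targets()] rearranged as the entity x stratum matrix
#' of proportions consumed by [cohort_config()]: one column per
#' [generator_strata()] stratum, zero columns for the asexual cells (both
#' genders) and homosexual boys.
#'
#' @return Numeric matrix, 20 entities x 9 strata, values in \[0, 1\].
#' @export
default_true_prevalence <- function() {
  targets <- default_prevalence_targets()
  ents <- targets$entity
  m <- matrix(0, nrow = length(ents), ncol = length(generator_strata()),
              dimnames = list(ents, generator_strata()))
  for (cl in c("female_homosexual", "female_bisexual", "female_heterosexual",
               "male_bisexual", "male_heterosexual", "gd")) {
    m[, cl] <- targets[[cl]] / 100
  }
  # asexual cells (both genders) and male homosexuals: zero prevalence
  m
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study conditions of a two-phase community cohort of
#' Swedish late adolescents: N = 949 with 528/949 female legal gender;
#' orientation distribution per gender proportional to the observed group
#' sizes (female 11/18/101/385 and male 14/10/23/361 for asexual /
#' homosexual / bisexual / heterosexual, of 923 classifiable); 26/949
#' missing an attraction item; gender-discontent rate 16/941 with 8/949 item
#' non-response and a 15:1 doubts : not-at-all-comfortable split; two school
#' sub-cohorts of similar size; per-instrument screen sensitivity 0.95 and
#' specificity 0.70 (high-sensitivity "generous cut-off" screens); and 51.1%
#' interview response among the screen-selected. True lifetime prevalences
#' default to [default_prevalence_targets()] (zero for asexuals and
#' homosexual boys).
#'
#' @param n Cohort size.
#' @param female_fraction Probability of female legal gender.
#' @param orientation_probs List with `female` and `male` probability vectors
#'   over asexual/homosexual/bisexual/heterosexual (each summing to 1).
#' @param orientation_missing_prob Probability both attraction items missing.
#' @param gd_prob Probability of gender discontent among item responders.
#' @param gd_missing_prob Probability the contentment item is missing.
#' @param gd_severe_prob Probability a GD participant answers
#'   `not_at_all_comfortable` rather than `doubts`.
#' @param subcohort1_fraction Fraction in school sub-cohort 1 (the cohort
#'   whose gambling/gaming screens ran only at M.I.N.I./ADDIS interview).
#' @param true_prevalence Numeric matrix entity x stratum of true lifetime
#'   prevalences (see [generator_strata()]).
#' @param sensitivity,specificity Screen operating characteristics: scalar
#'   or named per-instrument vector (`mini`, `addis`, `nods`, `igds`).
#' @param interview_response_prob Interview participation probability among
#'   screen-selected participants (missing at random given screen status).
#' @param case_response_odds_multiplier Odds multiplier on interview response
#'   for participants with at least one latent diagnosis; 1 = MAR (default).
#'   See [inject_informative_attrition()].
#' @param comorbidity_sd Standard deviation of an optional person-level
#'   shared frailty on the logit scale inducing comorbidity between
#'   entities; 0 (default) draws diagnoses independently.
#' @param seed Integer root seed used by [generate_cohort()].
#' @return A validated `cohort_config` object (list).
#' @export
cohort_config <- function(n = 949,
                          female_fraction = 528 / 949,
                          orientation_probs = list(
                            female = c(asexual = 11, homosexual = 18,
                                       bisexual = 101,
                                       heterosexual = 385) / 515,
                            male = c(asexual = 14, homosexual = 10,
                                     bisexual = 23,
                                     heterosexual = 361) / 408),
                          orientation_missing_prob = 26 / 949,
                          gd_prob = 16 / 941,
                          gd_missing_prob = 8 / 949,
                          gd_severe_prob = 1 / 16,
                          subcohort1_fraction = 0.5,
                          true_prevalence = default_true_prevalence(),
                          sensitivity = 0.95,
                          specificity = 0.70,
                          interview_response_prob = 0.511,
                          case_response_odds_multiplier = 1,
                          comorbidity_sd = 0,
                          seed = 1L) {
  config <- list(n = as.integer(n), female_fraction = female_fraction,
                 orientation_probs = orientation_probs,
                 orientation_missing_prob = orientation_missing_prob,
                 gd_prob = gd_prob, gd_missing_prob = gd_missing_prob,
                 gd_severe_prob = gd_severe_prob,
                 subcohort1_fraction = subcohort1_fraction,
                 true_prevalence = true_prevalence,
                 sensitivity = expand_instrument(sensitivity, "sensitivity"),
                 specificity = expand_instrument(specificity, "specificity"),
                 interview_response_prob = interview_response_prob,
                 case_response_odds_multiplier = case_response_odds_multiplier,
                 comorbidity_sd = comorbidity_sd,
                 seed = as.integer(seed))
  class(config) <- "cohort_config"
  validate_config(config)
  config
}

# Internal: scalar or named vector -> named per-instrument vector.
expand_instrument <- function(x, what) {
  codes <- instrument_codes()
  if (length(x) == 1 && is.null(names(x))) {
    return(setNames(rep(as.numeric(x), length(codes)), codes))
  }
  if (!all(codes %in% names(x))) {
    stop(what, " must be a scalar or a vector named ",
         paste(codes, collapse = ", "), call. = FALSE)
  }
  as.numeric(x[codes]) |> setNames(codes)
}

# Internal: reject invalid configs before any sampling.
validate_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  prob1 <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop(nm, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (!is.finite(config$n) || config$n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  prob1(config$female_fraction, "female_fraction")
  for (g in c("female", "male")) {
    op <- config$orientation_probs[[g]]
    if (length(op) != 4) {
      stop("orientation_probs$", g, " must have 4 entries", call. = FALSE)
    }
    prob1(op, paste0("orientation_probs$", g))
    if (abs(sum(op) - 1) > 1e-8) {
      stop("orientation_probs$", g, " must sum to 1", call. = FALSE)
    }
  }
  prob1(config$orientation_missing_prob, "orientation_missing_prob")
  prob1(config$gd_prob, "gd_prob")
  prob1(config$gd_missing_prob, "gd_missing_prob")
  prob1(config$gd_severe_prob, "gd_severe_prob")
  prob1(config$subcohort1_fraction, "subcohort1_fraction")
  prob1(config$sensitivity, "sensitivity")
  prob1(config$specificity, "specificity")
  prob1(config$interview_response_prob, "interview_response_prob")
  if (!is.finite(config$case_response_odds_multiplier) ||
      config$case_response_odds_multiplier <= 0) {
    stop("case_response_odds_multiplier must be positive", call. = FALSE)
  }
  if (!is.finite(config$comorbidity_sd) || config$comorbidity_sd < 0) {
    stop("comorbidity_sd must be non-negative", call. = FALSE)
  }
  tp <- config$true_prevalence
  ents <- diagnosis_catalog()$entity
  if (!is.matrix(tp) || !identical(rownames(tp), ents) ||
      !identical(colnames(tp), generator_strata())) {
    stop("true_prevalence must be an entity x stratum matrix over the full ",
         "catalog and generator_strata()", call. = FALSE)
  }
  prob1(tp, "true_prevalence")
  invisible(TRUE)
}

#' Make interview non-response depend on true diagnosis status
#'
#' Stress test of the estimator's missing-at-random assumption: multiplies
#' the interview-response odds for participants with at least one latent
#' diagnosis. `effect = 1` leaves the configuration unchanged; `effect < 1`
#' makes true cases respond less (downward-biased prevalence estimates),
#' `effect > 1` more.
#'
#' @param config A [cohort_config()].
#' @param effect Positive odds multiplier.
#' @return Modified config.
#' @export
inject_informative_attrition <- function(config, effect) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.finite(effect) || effect <= 0) {
    stop("effect must be a positive odds multiplier", call. = FALSE)
  }
  config$case_response_odds_multiplier <-
    config$case_response_odds_multiplier * effect
  validate_config(config)
  config
}

#' Read a generator configuration from YAML
#'
#' Scalar fields override [cohort_config()] defaults; `true_prevalence`, if
#' given, is a map stratum -> entity -> proportion (unlisted strata/entities
#' keep their defaults).
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
cohort_config_from_file <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  # YAML 1.1 reads a bare `n:` key as boolean; map it back to the n field
  bool_keys <- names(args) %in% c("FALSE", "false")
  if (any(bool_keys) && !"n" %in% names(args)) {
    names(args)[which(bool_keys)[1]] <- "n"
  }
  if (!is.null(raw$true_prevalence)) {
    tp <- default_true_prevalence()
    for (stratum in names(raw$true_prevalence)) {
      for (entity in names(raw$true_prevalence[[stratum]])) {
        tp[entity, stratum] <- raw$true_prevalence[[stratum]][[entity]]
      }
    }
    args$true_prevalence <- tp
  }
  if (!is.null(raw$orientation_probs)) {
    args$orientation_probs <- lapply(raw$orientation_probs, unlist)
  }
  do.call(cohort_config, args)
}

#' Generate a synthetic two-phase cohort
#'
#' Generative mirror of the sampling design. For each participant: draw
#' legal gender, a latent orientation (attraction items are then rendered,
#' with `somewhat`/`strongly` split evenly among the attracted, or set
#' missing for item non-responders), gender-discontent status, school
#' sub-cohort, and an optional shared frailty; then for each entity in
#' catalog order a latent true diagnosis status; then one screen outcome per
#' *instrument* -- positive with probability `sensitivity` when any of the
#' instrument's entities is truly present, `1 - specificity` otherwise --
#' copied to all entities the instrument owns (with the defaults this
#' reproduces an aggregate screen-selection rate near 80%); then a single
#' person-level interview-response draw (one phone session covers all
#' indicated instruments). Participants screen-positive on a M.I.N.I./ADDIS entity are
#' selected, and interviewed if they respond. Gambling/gaming screens run
#' for everyone in sub-cohort 2, but in sub-cohort 1 only during a completed
#' M.I.N.I./ADDIS interview (otherwise `not_screened`); a positive
#' gambling/gaming screen in that session is followed by the NODS/IGDS
#' module within the same session. Diagnoses are revealed (equal to latent
#' truth) exactly for screen-positive entities whose owning instrument was
#' interviewed; everything else is `unknown`.
#'
#' Draws are ordered demographics-first, then per entity in catalog order,
#' then response, so appending entities to the catalog does not perturb
#' earlier draws under the same seed. Identical config and seed give
#' byte-identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param seed Root seed; defaults to `config$seed`.
#' @return List with `cohort` (a validated `twophase_cohort`) and `truth`
#'   (tibble: `participant_id`, true `stratum`, and one logical
#'   `latent_<entity>` column per entity).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  catalog <- diagnosis_catalog()
  n <- config$n
  ents <- catalog$entity
  set.seed(as.integer(seed))

  # 1. demographics
  female <- stats::runif(n) < config$female_fraction
  gender <- ifelse(female, "female", "male")
  orientation <- character(n)
  cats <- c("asexual", "homosexual", "bisexual", "heterosexual")
  u_or <- stats::runif(n)
  for (g in c("female", "male")) {
    idx <- which(gender == g)
    cum <- cumsum(config$orientation_probs[[g]])
    orientation[idx] <- cats[findInterval(u_or[idx], cum) + 1L]
  }
  strength_same <- ifelse(stats::runif(n) < 0.5, "somewhat", "strongly")
  strength_opp <- ifelse(stats::runif(n) < 0.5, "somewhat", "strongly")
  or_missing <- stats::runif(n) < config$orientation_missing_prob
  gd_missing <- stats::runif(n) < config$gd_missing_prob
  gd <- stats::runif(n) < config$gd_prob
  gd_severe <- stats::runif(n) < config$gd_severe_prob
  sub_cohort <- ifelse(stats::runif(n) < config$subcohort1_fraction, 1L, 2L)
  frailty <- stats::rnorm(n)

  attraction_same <- ifelse(orientation %in% c("homosexual", "bisexual"),
                            strength_same, "not_at_all")
  attraction_opp <- ifelse(orientation %in% c("heterosexual", "bisexual"),
                           strength_opp, "not_at_all")
  attraction_same[or_missing] <- NA_character_
  attraction_opp[or_missing] <- NA_character_
  contentment <- ifelse(gd, ifelse(gd_severe, "not_at_all_comfortable",
                                   "doubts"), "happy")
  contentment[gd_missing] <- NA_character_

  stratum <- ifelse(gd, "gd", paste(gender, orientation, sep = "_"))

  # 2. latent statuses per entity in catalog order, then instrument-level
  #    screens (a screen instrument covers all entities it owns)
  latent <- matrix(FALSE, n, length(ents), dimnames = list(NULL, ents))
  screen_pos <- latent
  for (e in ents) {
    p <- config$true_prevalence[e, stratum]
    if (config$comorbidity_sd > 0) {
      inner <- p > 0 & p < 1
      p[inner] <- stats::plogis(stats::qlogis(p[inner]) +
                                  config$comorbidity_sd * frailty[inner])
    }
    latent[, e] <- stats::runif(n) < p
  }
  for (instr in instrument_codes()) {
    ents_i <- ents[catalog$instrument == instr]
    any_latent <- rowSums(latent[, ents_i, drop = FALSE]) > 0
    u <- stats::runif(n)
    pos_i <- ifelse(any_latent, u < config$sensitivity[[instr]],
                    u < 1 - config$specificity[[instr]])
    screen_pos[, ents_i] <- pos_i
  }

  # 3. interview response (one per-person draw; odds shifted for latent
  #    cases when attrition is informative)
  p_resp <- rep(config$interview_response_prob, n)
  mult <- config$case_response_odds_multiplier
  if (mult != 1) {
    any_case <- rowSums(latent) > 0
    odds <- p_resp / (1 - p_resp)
    shifted <- ifelse(is.finite(odds), (odds * mult) / (1 + odds * mult), 1)
    p_resp[any_case] <- shifted[any_case]
  }
  responded <- stats::runif(n) < p_resp

  mini_ents <- ents[catalog$instrument == "mini"]
  addis_ents <- ents[catalog$instrument == "addis"]
  selected_mini <- rowSums(screen_pos[, mini_ents, drop = FALSE]) > 0
  selected_addis <- rowSums(screen_pos[, addis_ents, drop = FALSE]) > 0
  int_mini <- selected_mini & responded
  int_addis <- selected_addis & responded
  in_session <- int_mini | int_addis

  # 4. sub-cohort-1 gambling/gaming rule
  bg_screened <- sub_cohort == 2L | in_session
  int_nods <- ifelse(sub_cohort == 1L,
                     in_session & screen_pos[, "gambling"],
                     screen_pos[, "gambling"] & responded)
  int_igds <- ifelse(sub_cohort == 1L,
                     in_session & screen_pos[, "gaming"],
                     screen_pos[, "gaming"] & responded)

  screen <- ifelse(screen_pos, "positive", "negative")
  screen[!bg_screened, "gambling"] <- "not_screened"
  screen[!bg_screened, "gaming"] <- "not_screened"

  int_by_instr <- cbind(mini = int_mini, addis = int_addis,
                        nods = int_nods, igds = int_igds)
  int_entity <- int_by_instr[, catalog$instrument, drop = FALSE]
  revealed <- screen == "positive" & int_entity
  dx <- ifelse(revealed, ifelse(latent, "present", "absent"), "unknown")

  ids <- sprintf("p%0*d", nchar(as.character(n)), seq_len(n))
  cohort <- tibble::tibble(
    participant_id = ids,
    legal_gender = gender,
    attraction_opposite = attraction_opp,
    attraction_same = attraction_same,
    gender_contentment = contentment,
    sub_cohort = sub_cohort
  )
  for (e in ents) cohort[[paste0("screen_", e)]] <- screen[, e]
  cohort$int_mini <- int_mini
  cohort$int_addis <- int_addis
  cohort$int_nods <- int_nods
  cohort$int_igds <- int_igds
  for (e in ents) cohort[[paste0("dx_", e)]] <- dx[, e]
  cohort <- as_cohort(cohort, catalog, validate = FALSE)

  truth <- tibble::tibble(participant_id = ids, stratum = stratum)
  for (e in ents) truth[[paste0("latent_", e)]] <- latent[, e]

  list(cohort = cohort, truth = truth)
}

#' Write the latent truth table alongside a cohort
#'
#' @param truth Truth tibble from [generate_cohort()].
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  for (nm in grep("^latent_", names(out), value = TRUE)) {
    out[[nm]] <- as.integer(out[[nm]])
  }
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
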