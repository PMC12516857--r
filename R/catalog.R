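#' Catalog of the 20 diagnostic entities and their owning instruments
#'
#' The analysis covers 20 lifetime diagnostic entities assessed by four
#' structured instruments: the M.I.N.I. (general psychiatric modules), ADDIS
#' (substance use disorders), NODS (gambling) and IGDS (gaming). The catalog
#' fixes entity identifiers, display labels, instrument ownership and the two
#' composite outcomes used in reporting:
#'
#' * `any_anxiety` -- any of panic disorder, agoraphobia, social anxiety,
#'   OCD, PTSD or GAD;
#' * `at_least_one` -- at least one of all 20 entities.
#'
#' @return An object of class `diagnosis_catalog`: a [tibble::tibble()] with
#'   columns `entity`, `label`, `instrument`, carrying the composite
#'   definitions in `attr(, "composites")`.
#' @export
#' @examples
#' cat20 <- diagnosis_catalog()
#' nrow(cat20)                      # 20
#' composite_members(cat20, "any_anxiety")
diagnosis_catalog <- function() {
  tab <- tibble::tibble(
    entity = c(
      "suicidality", "depression", "mania", "panic_disorder", "agoraphobia",
      "social_anxiety", "ocd", "ptsd", "gad", "psychotic_syndrome",
      "affective_psychosis", "bulimia", "anorexia", "aspd", "adhd", "add",
      "alcohol_use", "drug_use", "gambling", "gaming"
    ),
    label = c(
      "Suicidality", "Depression", "Mania", "Panic disorder", "Agoraphobia",
      "Social anxiety", "Obsessive compulsive disorder (OCD)",
      "Post traumatic stress disorder (PTSD)",
      "Generalized anxiety disorder (GAD)", "Psychotic syndrome",
      "Affective psychosis", "Bulimia", "Anorexia",
      "Antisocial personality disorder (ASPD)",
      "Attention deficit hyperactivity disorder (ADHD)",
      "Attention deficit disorder (ADD)",
      "Dependence/harmful use of alcohol", "Dependence/harmful use of drugs",
      "Gambling problem or disorder", "Gaming disorder"
    ),
    instrument = c(rep("mini", 16), "addis", "addis", "nods", "igds")
  )
  attr(tab, "composites") <- list(
    any_anxiety = c("panic_disorder", "agoraphobia", "social_anxiety",
                    "ocd", "ptsd", "gad"),
    at_least_one = tab$entity
  )
  class(tab) <- c("diagnosis_catalog", class(tab))
  tab
}

#' Members of a named composite outcome
#'
#' @param catalog A [diagnosis_catalog()].
#' @param name Composite name, `"any_anxiety"` or `"at_least_one"`.
#' @return Character vector of entity identifiers.
#' @export
composite_members <- function(catalog, name) {
  comps <- attr(catalog, "composites")
  if (is.null(comps) || !name %in% names(comps)) {
    stop("unknown composite: ", name, call. = FALSE)
  }
  comps[[name]]
}

#' Owning instrument for each entity
#'
#' @param catalog A [diagnosis_catalog()].
#' @param entities Character vector of entity identifiers.
#' @return Character vector of instrument codes (`mini`, `addis`, `nods`,
#'   `igds`), same length as `entities`.
#' @export
entity_instrument <- function(catalog, entities) {
  idx <- match(entities, catalog$entity)
  if (anyNA(idx)) {
    stop("entity not in catalog: ",
         paste(entities[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  catalog$instrument[idx]
}

#' Default per-group lifetime prevalence targets (percent)
#'
#' The calibration table behind the synthetic-cohort generator's defaults:
#' lifetime prevalence (in percent) for each diagnostic entity in the seven
#' analysis groups reported by the study design this package emulates --
#' homosexual, bisexual and heterosexual girls; bisexual and heterosexual
#' boys; the gender-discontent (GD) group pooled over legal genders; and all
#' others (non-GD). Asexual girls and boys and homosexual boys carry zero
#' prevalence for every entity and are therefore not columns here; the
#' generator assigns them zero vectors.
#'
#' These percentages are used (divided by 100) as the generator's default
#' true prevalences, and as rounded inputs when re-deriving relative risks
#' from displayed percentages with [rr_from_rounded_percent()].
#'
#' @return Tibble with column `entity` plus one numeric percent column per
#'   group: `female_homosexual`, `female_bisexual`, `female_heterosexual`,
#'   `male_bisexual`, `male_heterosexual`, `gd`, `non_gd`.
#' @export
default_prevalence_targets <- function() {
  tibble::tribble(
    ~entity,               ~female_homosexual, ~female_bisexual, ~female_heterosexual, ~male_bisexual, ~male_heterosexual, ~gd,  ~non_gd,
    "suicidality",         13.9,               9.3,              2.7,                  31.6,           4.0,                9.7,  4.5,
    "depression",          13.9,               34.9,             19.9,                 20.2,           5.2,                0,    4.5,
    "mania",               0,                  6.9,              0.4,                  5.9,            2.0,                0,    1.8,
    "panic_disorder",      19.4,               20.5,             8.3,                  22.1,           1.3,                27.1, 6.6,
    "agoraphobia",         0.6,                6.5,              1.1,                  0,              0.3,                9.0,  1.3,
    "social_anxiety",      19.4,               11.8,             3.7,                  0,              1.0,                18.1, 3.4,
    "ocd",                 2.8,                11.8,             3.5,                  23.7,           1.3,                8.3,  4.1,
    "ptsd",                0,                  2.5,              0,                    0,              0,                  0,    0.3,
    "gad",                 0,                  2.6,              2.1,                  0,              0.3,                9.7,  1.3,
    "psychotic_syndrome",  0,                  6.4,              1.7,                  5.5,            2.1,                0,    2.8,
    "affective_psychosis", 0,                  1.3,              0.3,                  0,              0,                  0,    0.3,
    "bulimia",             0,                  1.3,              0.7,                  0,              0,                  0,    0.3,
    "anorexia",            6.9,                0,                0.4,                  0,              0,                  0,    0.4,
    "aspd",                0,                  1.3,              0.4,                  5.9,            0.8,                9.0,  0.7,
    "adhd",                0,                  5.1,              0.7,                  11.9,           0.7,                9.0,  1.3,
    "add",                 6.9,                1.3,              1.5,                  5.9,            0.4,                0,    1.2,
    "alcohol_use",         0,                  22.3,             15.3,                 0,              11.9,               0,    14.3,
    "drug_use",            0,                  4.4,              0.6,                  0,              2.4,                0,    1.8,
    "gambling",            0,                  2.2,              0,                    7.0,            6.2,                0,    2.9,
    "gaming",              0,                  0,                0,                    8.7,            4.0,                0,    1.9
  )
}

# Internal: instrument codes in fixed order.
instrument_codes <- function() c("mini", "addis", "nods", "igds")
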