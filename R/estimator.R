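#' Half-up rounding
#'
#' Rounds halves away from zero (so 0.5 -> 1, 2.5 -> 3), matching the
#' display convention of the reported tables; R's [round()] rounds halves
#' to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Two-phase aggregate counts for one group x entity cell
#'
#' @param D Interviewed participants who met the diagnosis.
#' @param ND Interviewed participants who did not meet the diagnosis.
#' @param NI Screen-positive participants not interviewed.
#' @param T Total group size (phase-1 participants in the group).
#' @param PD2 Optional reference prevalence from sub-cohort 2 (gambling and
#'   gaming only), a proportion in \[0, 1\]. Must be given together with `NS1`.
#' @param NS1 Optional count of sub-cohort-1 group members never screened for
#'   the entity.
#' @return A `two_phase_counts` object.
#' @export
two_phase_counts <- function(D, ND, NI, T, PD2 = NULL, NS1 = NULL) {
  is_count <- function(x) length(x) == 1 && is.finite(x) && x >= 0 &&
    x == as.integer(x)
  if (!is_count(D) || !is_count(ND) || !is_count(NI) || !is_count(T)) {
    stop("D, ND, NI and T must be single non-negative integers",
         call. = FALSE)
  }
  if (is.null(PD2) != is.null(NS1)) {
    stop("PD2 and NS1 must be supplied together", call. = FALSE)
  }
  if (!is.null(PD2)) {
    if (!(length(PD2) == 1 && is.finite(PD2) && PD2 >= 0 && PD2 <= 1)) {
      stop("PD2 must be a proportion in [0, 1]", call. = FALSE)
    }
    if (!is_count(NS1)) stop("NS1 must be a non-negative integer",
                             call. = FALSE)
  }
  if (D + ND + NI + (if (is.null(NS1)) 0 else NS1) > T) {
    stop("counts exceed group size: D + ND + NI + NS1 > T", call. = FALSE)
  }
  structure(list(D = D, ND = ND, NI = NI, T = T, PD2 = PD2, NS1 = NS1),
            class = "two_phase_counts")
}

#' @export
print.two_phase_counts <- function(x, ...) {
  cat(sprintf("two-phase counts: D=%d ND=%d NI=%d T=%d", x$D, x$ND, x$NI,
              x$T))
  if (!is.null(x$NS1)) cat(sprintf(" NS1=%d PD2=%.4f", x$NS1, x$PD2))
  cat("\n")
  invisible(x)
}

#' Attrition-adjusted prevalence from two-phase counts
#'
#' The core estimator. Interview non-response among screen-positives is
#' assumed missing at random given screen status, so the diagnosis rate
#' among the interviewed, `D / (D + ND)`, is imputed to the `NI`
#' not-interviewed screen-positives; screen-negatives are assumed free of
#' the diagnosis:
#'
#' \deqn{P = (D + (D / (D + ND)) \cdot NI) / T}
#'
#' When the entity's screen was never administered to part of the group
#' (`NS1` sub-cohort-1 members, gambling/gaming only), the reference
#' prevalence `PD2` estimated in sub-cohort 2 is imputed to them:
#'
#' \deqn{P = (D + (D / (D + ND)) \cdot NI + PD_2 \cdot NS_1) / T}
#'
#' A cell with screen-positives but no completed interviews (`NI > 0`,
#' `D + ND = 0`) is inestimable and raises an error -- never a silent zero.
#'
#' @param counts A [two_phase_counts()] object.
#' @return A `prevalence_estimate`: list with `P` (proportion),
#'   `percent_1dp` (P x 100, half-up to 1 decimal) and `counts`.
#' @export
#' @examples
#' estimate_prevalence(two_phase_counts(D = 5, ND = 15, NI = 8, T = 200))$P
#' # (5 + 5/20 * 8) / 200 = 0.035
estimate_prevalence <- function(counts) {
  stopifnot(inherits(counts, "two_phase_counts"))
  if (counts$T <= 0) stop("group size T must be positive", call. = FALSE)
  if (counts$NI > 0 && counts$D + counts$ND == 0) {
    stop("inestimable cell: NI > 0 but no completed interviews (D + ND = 0)",
         call. = FALSE)
  }
  adj <- if (counts$D + counts$ND > 0) {
    counts$D / (counts$D + counts$ND) * counts$NI
  } else {
    0
  }
  imput <- if (is.null(counts$NS1)) 0 else counts$PD2 * counts$NS1
  P <- (counts$D + adj + imput) / counts$T
  structure(list(P = P,
                 percent_1dp = round_half_up(100 * P, 1),
                 counts = counts),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("adjusted prevalence: %.4f (%.1f%%)\n", x$P, x$percent_1dp))
  print(x$counts)
  invisible(x)
}

# Internal: logical matrices used by the counting operations.
# Returns n x 20 matrices of screen-positive / never-screened / diagnosis
# status plus the per-entity interviewed flag.
cohort_matrices <- function(cohort, catalog = diagnosis_catalog()) {
  n <- nrow(cohort)
  ents <- catalog$entity
  pick <- function(prefix) {
    m <- vapply(ents, function(e) cohort[[paste0(prefix, e)]],
                character(n))
    if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, ents))
    m
  }
  scr <- pick("screen_")
  dx <- pick("dx_")
  int_by_instr <- vapply(instrument_codes(),
                         function(i) cohort[[paste0("int_", i)]],
                         logical(n))
  if (n == 1) int_by_instr <- matrix(int_by_instr, nrow = 1,
                                     dimnames = list(NULL, instrument_codes()))
  int_entity <- int_by_instr[, catalog$instrument, drop = FALSE]
  colnames(int_entity) <- ents
  list(
    screen_pos = scr == "positive",
    not_screened = scr == "not_screened",
    dx_present = dx == "present",
    dx_absent = dx == "absent",
    interviewed = int_entity,
    sub_cohort = cohort$sub_cohort,
    int_mini_addis = cohort$int_mini | cohort$int_addis
  )
}

#' Aggregate two-phase counts for a group and entity
#'
#' Tallies, over the group members: `D` = diagnosis present, `ND` =
#' interviewed with the owning instrument and diagnosis absent, `NI` =
#' screen-positive but not interviewed, `T` = group size. Screen-negatives
#' contribute only to `T`. For the gambling and gaming entities, sub-cohort-1
#' members never screened are counted in `NS1` and the sub-cohort-2 reference
#' prevalence `PD2` (from [compute_pd2()] on the full cohort) is attached
#' whenever `NS1 > 0`.
#'
#' @param cohort A validated cohort table (the full cohort: the gambling and
#'   gaming reference prevalence is computed outside the group).
#' @param members Integer row indices of the group members.
#' @param entity Entity identifier from the catalog.
#' @param catalog A [diagnosis_catalog()].
#' @return A [two_phase_counts()] object.
#' @export
aggregate_counts <- function(cohort, members, entity,
                             catalog = diagnosis_catalog()) {
  if (!entity %in% catalog$entity) {
    stop("entity not in catalog: ", entity, call. = FALSE)
  }
  mats <- cohort_matrices(cohort, catalog)
  aggregate_counts_mats(mats, cohort, members, entity, catalog)
}

# Internal work-horse shared with estimate_all(): counts from precomputed
# matrices.
aggregate_counts_mats <- function(mats, cohort, members, entity, catalog) {
  e <- entity
  D <- sum(mats$dx_present[members, e])
  ND <- sum(mats$dx_absent[members, e])
  NI <- sum(mats$screen_pos[members, e] & !mats$interviewed[members, e])
  T <- length(members)
  if (e %in% c("gambling", "gaming")) {
    NS1 <- sum(mats$not_screened[members, e])
    if (NS1 > 0) {
      PD2 <- compute_pd2(cohort, e, catalog, members = members, mats = mats)
      return(two_phase_counts(D, ND, NI, T, PD2 = PD2, NS1 = NS1))
    }
  }
  two_phase_counts(D, ND, NI, T)
}

#' Reference prevalence of gambling/gaming in sub-cohort 2
#'
#' In the first school sub-cohort the gambling and gaming screens were only
#' administered to participants contacted for an M.I.N.I./ADDIS interview.
#' The reference prevalence imputed to the never-screened is estimated among
#' sub-cohort-2 participants *not* interviewed with the M.I.N.I. or ADDIS (a
#' fully screened subset comparable to the never-screened), itself
#' attrition-adjusted with [estimate_prevalence()]. When `members` is given,
#' the reference subset is additionally restricted to that analysis group,
#' so the imputed prevalence reflects the group's own rate (prevalences
#' differ strongly between groups; a pooled reference would bias
#' high-prevalence groups downward).
#'
#' @param cohort Full cohort table.
#' @param entity `"gambling"` or `"gaming"`.
#' @param catalog A [diagnosis_catalog()].
#' @param members Optional integer row indices of an analysis group to
#'   restrict the reference subset to; `NULL` uses the whole cohort.
#' @param mats Internal precomputed matrices (optional).
#' @return Proportion in \[0, 1\].
#' @export
compute_pd2 <- function(cohort, entity, catalog = diagnosis_catalog(),
                        members = NULL, mats = NULL) {
  if (!entity %in% c("gambling", "gaming")) {
    stop("PD2 is defined only for the gambling and gaming entities",
         call. = FALSE)
  }
  if (is.null(mats)) mats <- cohort_matrices(cohort, catalog)
  in_group <- if (is.null(members)) TRUE else
    seq_len(nrow(cohort)) %in% members
  ref <- which(mats$sub_cohort == 2L & !mats$int_mini_addis & in_group)
  if (length(ref) == 0) stop("reference sub-cohort empty", call. = FALSE)
  D <- sum(mats$dx_present[ref, entity])
  ND <- sum(mats$dx_absent[ref, entity])
  NI <- sum(mats$screen_pos[ref, entity] & !mats$interviewed[ref, entity])
  estimate_prevalence(two_phase_counts(D, ND, NI, length(ref)))$P
}

# Internal: person-level union counts for a composite outcome.
composite_counts_mats <- function(mats, members, members_set, catalog) {
  sub <- function(m) m[members, members_set, drop = FALSE]
  anyD <- rowSums(sub(mats$dx_present)) > 0
  indicated_missing <- rowSums(sub(mats$screen_pos) &
                                 !sub(mats$interviewed)) > 0
  any_indicated <- rowSums(sub(mats$screen_pos)) > 0
  D <- sum(anyD)
  ND <- sum(!anyD & any_indicated & !indicated_missing)
  NI <- sum(!anyD & indicated_missing)
  two_phase_counts(D, ND, NI, length(members))
}

#' Adjusted prevalence of a composite ("any of") outcome
#'
#' Person-level union over a member set of entities: `D` counts group members
#' with at least one member diagnosis (each person once); `ND` counts persons
#' with no member diagnosis who were screen-positive for at least one member
#' entity and interviewed on every instrument their screens indicated; `NI`
#' counts persons with no recorded member diagnosis and at least one
#' indicated-but-missing interview. Persons screen-negative on all member
#' entities contribute only to `T`. The same adjustment formula is then
#' applied, so a singleton member set reduces exactly to
#' [estimate_prevalence()] for that entity.
#'
#' @param cohort Full cohort table.
#' @param members Integer row indices of the group members.
#' @param member_set Character vector of entity identifiers (subset of the
#'   catalog).
#' @param catalog A [diagnosis_catalog()].
#' @return A `prevalence_estimate`.
#' @export
estimate_composite <- function(cohort, members, member_set,
                               catalog = diagnosis_catalog()) {
  unknown <- setdiff(member_set, catalog$entity)
  if (length(unknown) > 0) {
    stop("entity not in catalog: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mats <- cohort_matrices(cohort, catalog)
  estimate_prevalence(composite_counts_mats(mats, members, member_set,
                                            catalog))
}

#' Mean number of diagnoses per group member
#'
#' Sum over the 20 entities of the group's adjusted prevalence; under the
#' linearity of expectation this is the expected number of lifetime
#' diagnoses per group member, with the attrition adjustment inherited
#' consistently from [estimate_prevalence()]. Under complete response it
#' equals the per-person mean count of diagnoses.
#'
#' @inheritParams estimate_composite
#' @return Non-negative number.
#' @export
mean_diagnosis_count <- function(cohort, members,
                                 catalog = diagnosis_catalog()) {
  if (length(members) == 0) stop("group is empty", call. = FALSE)
  mats <- cohort_matrices(cohort, catalog)
  ps <- vapply(catalog$entity, function(e) {
    estimate_prevalence(aggregate_counts_mats(mats, cohort, members, e,
                                              catalog))$P
  }, numeric(1))
  sum(ps)
}

#' Adjusted prevalences for every analysis cell and entity
#'
#' The pipeline's estimation core: for each analysis cell (orientation x
#' legal-gender strata, GD, non-GD) and each catalog entity plus the two
#' composites, aggregates two-phase counts and applies the adjustment
#' formula. Inestimable cells (screen-positives but no completed interviews)
#' raise an error by default or are returned as `NA` with a flag.
#'
#' @param cohort A validated cohort table.
#' @param groups An [build_analysis_groups()] object (computed if `NULL`).
#' @param catalog A [diagnosis_catalog()].
#' @param on_inestimable `"error"` (default) or `"na"`.
#' @return Tibble with one row per cell x outcome: `group`, `entity`,
#'   `composite`, `D`, `ND`, `NI`, `NS1`, `PD2`, `T`, `P`, `percent_1dp`,
#'   `inestimable`.
#' @export
estimate_all <- function(cohort, groups = NULL,
                         catalog = diagnosis_catalog(),
                         on_inestimable = c("error", "na")) {
  on_inestimable <- match.arg(on_inestimable)
  if (is.null(groups)) groups <- build_analysis_groups(cohort)
  mats <- cohort_matrices(cohort, catalog)
  comps <- attr(catalog, "composites")
  outcomes <- c(catalog$entity, names(comps))
  nr <- length(groups$cells) * length(outcomes)
  col <- function(init) rep(init, nr)
  group <- col(NA_character_); entity <- col(NA_character_)
  composite <- col(NA); D <- col(NA_integer_); ND <- col(NA_integer_)
  NI <- col(NA_integer_); NS1 <- col(NA_integer_); PD2 <- col(NA_real_)
  T <- col(NA_integer_); P <- col(NA_real_); pct <- col(NA_real_)
  inest <- col(FALSE)
  k <- 0
  for (cell in names(groups$cells)) {
    members <- groups$cells[[cell]]
    for (out in outcomes) {
      is_comp <- out %in% names(comps)
      k <- k + 1
      group[k] <- cell; entity[k] <- out; composite[k] <- is_comp
      T[k] <- length(members)
      cnt_or_err <- tryCatch({
        if (length(members) == 0) stop("group is empty")
        cnt <- if (is_comp) {
          composite_counts_mats(mats, members, comps[[out]], catalog)
        } else {
          aggregate_counts_mats(mats, cohort, members, out, catalog)
        }
        list(cnt = cnt, est = estimate_prevalence(cnt))
      }, error = function(e) e)
      if (inherits(cnt_or_err, "error")) {
        if (on_inestimable == "error" && length(members) > 0) {
          stop("cell ", cell, " x ", out, ": ",
               conditionMessage(cnt_or_err), call. = FALSE)
        }
        inest[k] <- length(members) > 0
      } else {
        cnt <- cnt_or_err$cnt
        D[k] <- cnt$D; ND[k] <- cnt$ND; NI[k] <- cnt$NI
        if (!is.null(cnt$NS1)) { NS1[k] <- cnt$NS1; PD2[k] <- cnt$PD2 }
        P[k] <- cnt_or_err$est$P
        pct[k] <- cnt_or_err$est$percent_1dp
      }
    }
  }
  tibble::tibble(group = group, entity = entity, composite = composite,
                 D = D, ND = ND, NI = NI, NS1 = NS1, PD2 = PD2, T = T,
                 P = P, percent_1dp = pct, inestimable = inest)
}
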