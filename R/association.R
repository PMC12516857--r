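#' Relative risk of two prevalences
#'
#' Ratio of the minority-group prevalence to the reference-group prevalence.
#' Defined only when both prevalences are positive; otherwise `NA`
#' (rendered `"-"` in tables).
#'
#' @param p_group,p_ref Proportions (or percentages -- the ratio is
#'   scale-free) in the minority and reference group.
#' @return Numeric vector of relative risks, `NA` where undefined.
#' @export
#' @examples
#' relative_risk(0.139, 0.027)  # 5.148...
relative_risk <- function(p_group, p_ref) {
  stopifnot(length(p_group) == length(p_ref))
  bad <- !is.na(p_group) & !is.na(p_ref) & (p_group < 0 | p_ref < 0)
  if (any(bad)) stop("prevalences must be non-negative", call. = FALSE)
  out <- ifelse(!is.na(p_group) & !is.na(p_ref) & p_group > 0 & p_ref > 0,
                p_group / p_ref, NA_real_)
  out
}

#' Relative risks from displayed (rounded) percentages
#'
#' Recomputes relative risks as the ratio of two already-rounded percentage
#' displays, rounded half-up to two decimals -- the convention under which
#' a published table's RR column can be reproduced from its printed
#' prevalence columns.
#'
#' @param percent_group,percent_ref Percentages (1-decimal displays).
#' @return Relative risks at 2 decimals, `NA` where either percentage is 0.
#' @export
#' @examples
#' rr_from_rounded_percent(13.9, 2.7)   # 5.15
#' rr_from_rounded_percent(11.9, 0.7)   # 17.00
rr_from_rounded_percent <- function(percent_group, percent_ref) {
  round_half_up(relative_risk(percent_group, percent_ref), 2)
}

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector over `ns`/`*`/`**`/`***`.
#' @export
significance_stars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep("ns", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Plain Pearson chi-square without continuity correction, with the p-value
#' from the chi-square distribution on 1 degree of freedom
#' (via [stats::chisq.test()]). Degenerate tables -- a zero margin, e.g. no
#' cases in either group -- return `chi2 = 0`, `p = 1`. Tables with any
#' expected cell below 5 are flagged.
#'
#' @param cases_a,noncases_a Case/non-case counts in group A.
#' @param cases_b,noncases_b Case/non-case counts in group B.
#' @return List with `chi2`, `p` and `small_expected` (logical flag).
#' @export
#' @examples
#' chi_square_test(10, 90, 2, 98)$chi2  # 5.674 (approx.)
chi_square_test <- function(cases_a, noncases_a, cases_b, noncases_b) {
  counts <- c(cases_a, noncases_a, cases_b, noncases_b)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  if (cases_a + noncases_a <= 0 || cases_b + noncases_b <= 0) {
    stop("both group totals must be positive", call. = FALSE)
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0)) {
    return(list(chi2 = 0, p = 1, small_expected = TRUE))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value),
       small_expected = any(ht$expected < 5))
}

#' Compare minority groups with their reference group
#'
#' For each minority group x outcome, computes the relative risk against the
#' reference prevalence and a Pearson chi-square test with star coding.
#' Two schemes mirror the reporting rules of the design:
#'
#' * `vs_same_gender_heterosexual`: each orientation minority cell (asexual,
#'   homosexual, bisexual, per legal gender) against heterosexuals of the
#'   same gender;
#' * `vs_all_others`: the GD group against all non-GD participants.
#'
#' The chi-square is built from adjusted estimated case counts: `P x T`
#' rounded half-up to the nearest integer in each group, vs the remaining
#' non-cases. Relative risks use unrounded prevalences. No multiple-testing
#' correction is applied (none is part of the reported design); tables with
#' any expected cell below 5 are flagged in `small_expected`.
#'
#' @param estimates Tibble from [estimate_all()].
#' @param scheme `"vs_same_gender_heterosexual"` or `"vs_all_others"`.
#' @return Tibble: `group`, `reference`, `entity`, `RR`, `chi2`, `p`,
#'   `stars`, `small_expected`.
#' @export
compare_groups <- function(estimates,
                           scheme = c("vs_same_gender_heterosexual",
                                      "vs_all_others")) {
  scheme <- match.arg(scheme)
  pairs <- if (scheme == "vs_same_gender_heterosexual") {
    data.frame(
      group = c("female_asexual", "female_homosexual", "female_bisexual",
                "male_asexual", "male_homosexual", "male_bisexual"),
      reference = rep(c("female_heterosexual", "male_heterosexual"),
                      each = 3),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(group = "gd", reference = "non_gd", stringsAsFactors = FALSE)
  }
  pairs <- pairs[pairs$group %in% estimates$group, , drop = FALSE]
  missing_ref <- setdiff(unique(pairs$reference), estimates$group)
  if (length(missing_ref) > 0) {
    stop("missing reference group: ", paste(missing_ref, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$group[i]
    r <- pairs$reference[i]
    eg <- estimates[estimates$group == g, ]
    er <- estimates[estimates$group == r, ]
    er <- er[match(eg$entity, er$entity), ]
    for (j in seq_len(nrow(eg))) {
      if (is.na(eg$P[j]) || is.na(er$P[j])) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          group = g, reference = r, entity = eg$entity[j],
          RR = NA_real_, chi2 = NA_real_, p = NA_real_,
          stars = NA_character_, small_expected = NA)
        next
      }
      cases_g <- round_half_up(eg$P[j] * eg$T[j])
      cases_r <- round_half_up(er$P[j] * er$T[j])
      ht <- chi_square_test(cases_g, eg$T[j] - cases_g,
                            cases_r, er$T[j] - cases_r)
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, reference = r, entity = eg$entity[j],
        RR = relative_risk(eg$P[j], er$P[j]),
        chi2 = ht$chi2, p = ht$p, stars = significance_stars(ht$p),
        small_expected = ht$small_expected)
    }
  }
  do.call(rbind, rows)
}
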