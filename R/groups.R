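#' Classify sexual orientation from the two attraction items
#'
#' Orientation is derived from attraction, not self-identification: each
#' participant rates attraction to the opposite and to the same sex as
#' `not_at_all`, `somewhat` or `strongly`. Any degree of attraction
#' (`somewhat` or `strongly`) counts as attracted; the somewhat/strongly
#' distinction does not affect category membership.
#'
#' * `asexual`: not at all attracted to either sex;
#' * `homosexual`: attracted to same sex, not at all to opposite;
#' * `heterosexual`: attracted to opposite sex, not at all to same;
#' * `bisexual`: attracted to both;
#' * `unclassified`: at least one item missing.
#'
#' @param attraction_same,attraction_opposite Character vectors over
#'   `not_at_all`/`somewhat`/`strongly`, `NA` allowed.
#' @return Character vector of orientation categories.
#' @export
#' @examples
#' classify_orientation("not_at_all", "not_at_all")  # asexual
#' classify_orientation("somewhat", "strongly")      # bisexual
classify_orientation <- function(attraction_same, attraction_opposite) {
  stopifnot(length(attraction_same) == length(attraction_opposite))
  ok <- function(x) x %in% attraction_levels()
  chk <- function(x) {
    if (any(!is.na(x) & !ok(x))) {
      stop("invalid attraction level: ",
           paste(unique(x[!is.na(x) & !ok(x)]), collapse = ", "),
           call. = FALSE)
    }
  }
  chk(attraction_same); chk(attraction_opposite)
  attracted_same <- attraction_same %in% c("somewhat", "strongly")
  attracted_opp <- attraction_opposite %in% c("somewhat", "strongly")
  out <- rep("unclassified", length(attraction_same))
  known <- !is.na(attraction_same) & !is.na(attraction_opposite)
  out[known & !attracted_same & !attracted_opp] <- "asexual"
  out[known & attracted_same & !attracted_opp] <- "homosexual"
  out[known & !attracted_same & attracted_opp] <- "heterosexual"
  out[known & attracted_same & attracted_opp] <- "bisexual"
  out
}

#' Classify gender-discontent status from the contentment item
#'
#' Participants who have doubts about, or are not at all comfortable with,
#' their legal gender form the gender-discontent (GD) group.
#'
#' @param contentment Character vector over
#'   `happy`/`doubts`/`not_at_all_comfortable`, `NA` allowed.
#' @return Character vector over `content`/`discontent`/`unknown`.
#' @export
classify_gender_discontent <- function(contentment) {
  bad <- !is.na(contentment) & !(contentment %in% contentment_levels())
  if (any(bad)) {
    stop("invalid gender_contentment level: ",
         paste(unique(contentment[bad]), collapse = ", "), call. = FALSE)
  }
  out <- rep("unknown", length(contentment))
  out[contentment %in% "happy"] <- "content"
  out[contentment %in% c("doubts", "not_at_all_comfortable")] <- "discontent"
  out
}

# Canonical analysis cell order: female strata, male strata, then GD.
orientation_cells <- function() {
  c("female_asexual", "female_homosexual", "female_bisexual",
    "female_heterosexual", "male_asexual", "male_homosexual",
    "male_bisexual", "male_heterosexual")
}
analysis_cell_names <- function() c(orientation_cells(), "gd", "non_gd")

#' Assign participants to the analysis groups
#'
#' Builds the two grouping systems of the analysis: orientation cells
#' stratified by legal gender (participants with an unclassified orientation
#' are excluded from orientation analyses), and the gender-discontent split
#' (GD pooled over legal genders vs non-GD; item non-respondents are
#' `unknown` and excluded from both GD cells). Every participant falls in at
#' most one orientation cell and exactly one of GD/non-GD/unknown.
#'
#' @param cohort A validated cohort table.
#' @return An `analysis_groups` object: list with `assignments` (tibble:
#'   `participant_id`, `legal_gender`, `orientation`, `gd_status`, `cell`),
#'   `cells` (named list mapping each analysis cell to row indices into the
#'   cohort) and `sizes` (named integer vector).
#' @export
build_analysis_groups <- function(cohort) {
  orientation <- classify_orientation(cohort$attraction_same,
                                      cohort$attraction_opposite)
  gd_status <- classify_gender_discontent(cohort$gender_contentment)
  cell <- ifelse(orientation == "unclassified", NA_character_,
                 paste(cohort$legal_gender, orientation, sep = "_"))
  assignments <- tibble::tibble(
    participant_id = cohort$participant_id,
    legal_gender = cohort$legal_gender,
    orientation = orientation,
    gd_status = gd_status,
    cell = cell
  )
  cells <- lapply(setNames(nm = orientation_cells()),
                  function(cl) which(cell == cl))
  cells$gd <- which(gd_status == "discontent")
  cells$non_gd <- which(gd_status == "content")
  sizes <- vapply(cells, length, integer(1))
  structure(list(assignments = assignments, cells = cells, sizes = sizes),
            class = "analysis_groups")
}

#' @export
print.analysis_groups <- function(x, ...) {
  cat("Analysis groups (", nrow(x$assignments), " participants)\n", sep = "")
  n_unclassified <- sum(x$assignments$orientation == "unclassified")
  n_gd_unknown <- sum(x$assignments$gd_status == "unknown")
  for (nm in names(x$sizes)) {
    cat(sprintf("  %-22s %5d\n", nm, x$sizes[[nm]]))
  }
  cat("  orientation unclassified:", n_unclassified,
      "| GD item missing:", n_gd_unknown, "\n")
  invisible(x)
}
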