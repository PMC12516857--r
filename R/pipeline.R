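#' Participant-flow accounting for a cohort
#'
#' Screening/selection/interview counts mirroring the design's
#' participation accounting, plus per-item response rates for the
#' orientation and gender-contentment questions.
#'
#' @param cohort A validated cohort table.
#' @param catalog A [diagnosis_catalog()].
#' @return List with `n`, `n_selected` (screen-positive on >= 1 entity),
#'   `n_interviewed` (>= 1 instrument), `percent_interviewed_of_selected`,
#'   `n_orientation_responders`, `n_gd_responders`, `n_gd` and
#'   `gd_rate_percent` (both percentages half-up at 1 decimal).
#' @export
participation_flow <- function(cohort, catalog = diagnosis_catalog()) {
  mats <- cohort_matrices(cohort, catalog)
  selected <- rowSums(mats$screen_pos) > 0
  interviewed <- cohort$int_mini | cohort$int_addis | cohort$int_nods |
    cohort$int_igds
  gd_status <- classify_gender_discontent(cohort$gender_contentment)
  orientation <- classify_orientation(cohort$attraction_same,
                                      cohort$attraction_opposite)
  n_gd_resp <- sum(gd_status != "unknown")
  list(
    n = nrow(cohort),
    n_selected = sum(selected),
    n_interviewed = sum(interviewed),
    percent_interviewed_of_selected =
      if (sum(selected) > 0) {
        round_half_up(100 * sum(interviewed & selected) / sum(selected), 1)
      } else {
        NA_real_
      },
    n_orientation_responders = sum(orientation != "unclassified"),
    n_gd_responders = n_gd_resp,
    n_gd = sum(gd_status == "discontent"),
    gd_rate_percent = if (n_gd_resp > 0) {
      round_half_up(100 * sum(gd_status == "discontent") / n_gd_resp, 1)
    } else {
      NA_real_
    }
  )
}

#' Run the full analysis pipeline on a cohort
#'
#' Read (if given a path) -> validate -> build analysis groups -> estimate
#' adjusted prevalences for all 20 entities and the two composites in every
#' analysis cell -> compare minority groups against their references ->
#' assemble a report. Analysis cells in which every entity prevalence is
#' zero are dropped from rendered output (and logged) when
#' `drop_zero_columns` is on, mirroring the reporting convention of removing
#' all-zero columns.
#'
#' @param cohort A cohort table or a file path readable by [read_cohort()].
#' @param catalog A [diagnosis_catalog()].
#' @param drop_zero_columns Drop all-zero cells from rendering? Default
#'   `TRUE`.
#' @param quiet Suppress the participant-flow log? Default `TRUE`.
#' @param on_inestimable `"error"` (default): an inestimable cell
#'   (screen-positives but no completed interviews) aborts the pipeline;
#'   `"na"`: such cells are reported as `NA` with an `inestimable` flag --
#'   never as a silent zero.
#' @return An `analysis_report`: list with `group_sizes`, `estimates`,
#'   `comparisons`, `mean_diagnoses`, `dropped`, `flow` and `catalog`.
#' @export
run_pipeline <- function(cohort, catalog = diagnosis_catalog(),
                         drop_zero_columns = TRUE, quiet = TRUE,
                         on_inestimable = c("error", "na")) {
  on_inestimable <- match.arg(on_inestimable)
  if (is.character(cohort)) {
    cohort <- tryCatch(read_cohort(cohort, catalog),
                       error = function(e) {
                         stop("stage read_cohort: ", conditionMessage(e),
                              call. = FALSE)
                       })
  } else {
    tryCatch(validate_cohort(cohort, catalog),
             error = function(e) {
               stop("stage validate_cohort: ", conditionMessage(e),
                    call. = FALSE)
             })
  }
  flow <- participation_flow(cohort, catalog)
  if (!quiet) {
    message(sprintf(
      "cohort n=%d; screen-selected=%d; interviewed=%d (%.1f%% of selected)",
      flow$n, flow$n_selected, flow$n_interviewed,
      flow$percent_interviewed_of_selected))
    message(sprintf(
      "orientation responders=%d; GD responders=%d; GD group=%d (%.1f%%)",
      flow$n_orientation_responders, flow$n_gd_responders, flow$n_gd,
      flow$gd_rate_percent))
  }
  groups <- build_analysis_groups(cohort)
  estimates <- tryCatch(
    estimate_all(cohort, groups, catalog, on_inestimable = on_inestimable),
    error = function(e) stop("stage estimate_all: ", conditionMessage(e),
                             call. = FALSE))
  comparisons <- rbind(
    compare_groups(estimates, "vs_same_gender_heterosexual"),
    compare_groups(estimates, "vs_all_others"))
  ent_est <- estimates[!estimates$composite, ]
  mean_diagnoses <- tibble::tibble(
    group = names(groups$cells),
    mean_n = vapply(names(groups$cells), function(cl) {
      p <- ent_est$P[ent_est$group == cl]
      if (length(p) == 0 || anyNA(p)) NA_real_ else sum(p)
    }, numeric(1)))
  dropped <- character(0)
  if (drop_zero_columns) {
    dropped <- names(groups$cells)[vapply(names(groups$cells), function(cl) {
      p <- ent_est$P[ent_est$group == cl]
      length(p) > 0 && !anyNA(p) && all(p == 0) && groups$sizes[[cl]] > 0
    }, logical(1))]
    if (!quiet && length(dropped) > 0) {
      message("dropped all-zero column(s): ", paste(dropped, collapse = ", "))
    }
  }
  structure(list(group_sizes = groups$sizes, estimates = estimates,
                 comparisons = comparisons, mean_diagnoses = mean_diagnoses,
                 dropped = dropped, flow = flow, catalog = catalog),
            class = "analysis_report")
}

# Internal: display formatting helpers.
fmt_percent <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.1f", round_half_up(100 * p, 1)))
}
fmt_rr <- function(rr) {
  ifelse(is.na(rr), "-", sprintf("%.2f", round_half_up(rr, 2)))
}
fmt_stars <- function(s) ifelse(is.na(s), "",
                                ifelse(s == "ns", " n.s.",
                                       paste0("^", s, "^")))

# Internal: assemble the wide display matrix (rows x columns of strings).
report_display <- function(report) {
  cells <- setdiff(analysis_cell_names(), report$dropped)
  cells <- cells[report$group_sizes[cells] > 0]
  minority <- unique(report$comparisons$group)
  ents <- c(report$catalog$entity, "any_anxiety", "at_least_one")
  labels <- c(report$catalog$label, "Any anxiety disorder",
              "At least one of all 20 diagnoses above")
  est <- report$estimates
  cmp <- report$comparisons
  cols <- list()
  for (cl in cells) {
    e <- est[est$group == cl, ]
    e <- e[match(ents, e$entity), ]
    pct <- fmt_percent(e$P)
    if (cl %in% minority) {
      cc <- cmp[cmp$group == cl, ]
      cc <- cc[match(ents, cc$entity), ]
      pct <- paste0(pct, fmt_stars(cc$stars))
      cols[[paste0(cl, " %")]] <- pct
      cols[[paste0(cl, " RR")]] <- fmt_rr(cc$RR)
    } else {
      cols[[paste0(cl, " %")]] <- pct
    }
  }
  md <- report$mean_diagnoses
  mean_row <- vapply(names(cols), function(nm) {
    cl <- sub(" (%|RR)$", "", nm)
    if (grepl(" RR$", nm)) "" else {
      m <- md$mean_n[md$group == cl]
      if (length(m) == 0 || is.na(m)) "NA" else sprintf("%.2f",
                                                        round_half_up(m, 2))
    }
  }, character(1))
  n_row <- vapply(names(cols), function(nm) {
    cl <- sub(" (%|RR)$", "", nm)
    if (grepl(" RR$", nm)) "" else
      as.character(report$group_sizes[[cl]])
  }, character(1))
  body <- do.call(cbind, cols)
  m <- rbind(`n` = n_row, body, `No. of diagnoses (mean)` = mean_row)
  rownames(m) <- c("n", labels, "No. of diagnoses (mean)")
  m
}

#' Render an analysis report
#'
#' Deterministic, pure rendering of a report: percentages at 1 decimal with
#' significance stars, relative risks at 2 decimals with `"-"` for undefined,
#' column order female strata, male strata, GD. Formats:
#'
#' * `markdown`: a pipe table of the wide prevalence/RR display;
#' * `text`: the same display, space-aligned;
#' * `csv`: the long results table (`group`, `entity`, `D`, `ND`, `NI`,
#'   `NS1`, `PD2`, `T`, `P`, `percent_1dp`, plus comparison columns).
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param format `"markdown"`, `"csv"` or `"text"`.
#' @return A single string (the rendered document).
#' @export
render_table <- function(report, format = c("markdown", "csv", "text")) {
  format <- match.arg(format)
  if (format == "csv") {
    est <- report$estimates
    cmp <- report$comparisons
    i <- match(paste(est$group, est$entity),
               paste(cmp$group, cmp$entity))
    long <- tibble::tibble(
      group = est$group, entity = est$entity, composite = est$composite,
      D = est$D, ND = est$ND, NI = est$NI, NS1 = est$NS1, PD2 = est$PD2,
      T = est$T, P = est$P, percent_1dp = est$percent_1dp,
      reference = cmp$reference[i],
      RR = ifelse(is.na(cmp$RR[i]), "-",
                  sprintf("%.2f", round_half_up(cmp$RR[i], 2))),
      chi2 = cmp$chi2[i], p = cmp$p[i], stars = cmp$stars[i],
      small_expected = cmp$small_expected[i])
    return(readr::format_csv(long, na = "NA"))
  }
  m <- report_display(report)
  header <- c("Diagnostic entity", colnames(m))
  rows <- cbind(rownames(m), m)
  if (format == "markdown") {
    fmt_row <- function(r) paste0("| ", paste(r, collapse = " | "), " |")
    lines <- c(fmt_row(header),
               fmt_row(rep("---", length(header))),
               apply(rows, 1, fmt_row))
  } else {
    widths <- pmax(nchar(header),
                   apply(nchar(rbind(header, rows)), 2, max))
    pad <- function(r) paste(mapply(formatC, r, width = widths,
                                    flag = "-"), collapse = "  ")
    lines <- c(pad(header), apply(rows, 1, pad))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(render_table(x, "text"))
  if (length(x$dropped) > 0) {
    cat("columns removed due to zero prevalence: ",
        paste(x$dropped, collapse = ", "), "\n", sep = "")
  }
  cat("Significance of differences: *p < 0.05; **p < 0.01; ***p < 0.001;",
      "no multiple-testing correction applied\n")
  invisible(x)
}
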