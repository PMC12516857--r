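#' @importFrom stats setNames
NULL

# Enum levels for the tabular dialect. Files carry lowercase snake_case
# strings; booleans are written 0/1; missing values use the token "NA".
gender_levels      <- function() c("female", "male")
attraction_levels  <- function() c("not_at_all", "somewhat", "strongly")
contentment_levels <- function() c("happy", "doubts", "not_at_all_comfortable")
screen_levels      <- function() c("positive", "negative", "not_screened")
dx_levels          <- function() c("present", "absent", "unknown")

#' Column names of the cohort table dialect
#'
#' One row per participant. Fixed column order: `participant_id`,
#' `legal_gender`, `attraction_opposite`, `attraction_same`,
#' `gender_contentment`, `sub_cohort`, one `screen_<entity>` column per
#' catalog entity, one `int_<instrument>` flag per instrument (0/1), and one
#' `dx_<entity>` column per entity. A machine-readable description of the
#' dialect ships as `system.file("extdata", "cohort-columns.json",
#' package = "twophaseprev")`.
#'
#' @param catalog A [diagnosis_catalog()].
#' @return Character vector of column names in canonical order.
#' @export
cohort_columns <- function(catalog = diagnosis_catalog()) {
  c("participant_id", "legal_gender", "attraction_opposite",
    "attraction_same", "gender_contentment", "sub_cohort",
    paste0("screen_", catalog$entity),
    paste0("int_", instrument_codes()),
    paste0("dx_", catalog$entity))
}

#' Construct and validate a cohort table
#'
#' @param df Data frame with the columns of [cohort_columns()].
#' @param catalog A [diagnosis_catalog()].
#' @param validate Run [validate_cohort()]? Default `TRUE`.
#' @return A `twophase_cohort` tibble.
#' @export
as_cohort <- function(df, catalog = diagnosis_catalog(), validate = TRUE) {
  cols <- cohort_columns(catalog)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df)[, cols]
  out$participant_id <- as.character(out$participant_id)
  out$sub_cohort <- as.integer(out$sub_cohort)
  for (nm in grep("^int_", cols, value = TRUE)) {
    out[[nm]] <- as.logical(as.integer(out[[nm]]))
  }
  class(out) <- c("twophase_cohort", class(tibble::tibble()))
  if (validate) validate_cohort(out, catalog)
  out
}

# Internal: collect row numbers violating a predicate, as a message chunk.
bad_rows_msg <- function(bad, what) {
  if (!any(bad)) return(NULL)
  rows <- which(bad)
  shown <- if (length(rows) > 12) {
    paste0(paste(utils::head(rows, 12), collapse = ", "), ", ...")
  } else {
    paste(rows, collapse = ", ")
  }
  paste0(what, " (rows ", shown, ")")
}

#' Validate a cohort table against the record invariants
#'
#' Checks, reporting offending row numbers:
#' * all enum columns carry only documented values (or `NA` where allowed);
#' * `participant_id` values are unique and non-missing;
#' * `sub_cohort` is 1 or 2;
#' * a diagnosis is `present`/`absent` only when the owning instrument was
#'   interviewed, otherwise `unknown`;
#' * `not_screened` occurs only for the gambling/gaming entities, in
#'   sub-cohort 1 records not interviewed with the M.I.N.I. or ADDIS;
#' * interview flags are non-missing.
#'
#' @param cohort A cohort table.
#' @param catalog A [diagnosis_catalog()].
#' @return Invisibly `TRUE`; otherwise an error listing every violation.
#' @export
validate_cohort <- function(cohort, catalog = diagnosis_catalog()) {
  cols <- cohort_columns(catalog)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  msgs <- character(0)
  add <- function(m) if (!is.null(m)) msgs <<- c(msgs, m)

  enum_ok <- function(x, levels, allow_na = TRUE) {
    bad <- !(x %in% levels)
    if (allow_na) bad <- bad & !is.na(x)
    bad
  }
  add(bad_rows_msg(is.na(cohort$participant_id) | cohort$participant_id == "",
                   "missing participant_id"))
  dup <- duplicated(cohort$participant_id)
  add(bad_rows_msg(dup, "duplicated participant_id"))
  add(bad_rows_msg(enum_ok(cohort$legal_gender, gender_levels(), FALSE),
                   "invalid legal_gender"))
  add(bad_rows_msg(enum_ok(cohort$attraction_opposite, attraction_levels()),
                   "invalid attraction_opposite"))
  add(bad_rows_msg(enum_ok(cohort$attraction_same, attraction_levels()),
                   "invalid attraction_same"))
  add(bad_rows_msg(enum_ok(cohort$gender_contentment, contentment_levels()),
                   "invalid gender_contentment"))
  add(bad_rows_msg(!(cohort$sub_cohort %in% c(1L, 2L)),
                   "invalid sub_cohort (must be 1 or 2)"))
  for (instr in instrument_codes()) {
    add(bad_rows_msg(is.na(cohort[[paste0("int_", instr)]]),
                     paste0("missing int_", instr, " flag")))
  }

  int_mini_addis <- cohort$int_mini | cohort$int_addis
  for (i in seq_len(nrow(catalog))) {
    e <- catalog$entity[i]
    instr <- catalog$instrument[i]
    scr <- cohort[[paste0("screen_", e)]]
    dx <- cohort[[paste0("dx_", e)]]
    intv <- cohort[[paste0("int_", instr)]]
    add(bad_rows_msg(enum_ok(scr, screen_levels(), FALSE),
                     paste0("invalid screen_", e)))
    add(bad_rows_msg(enum_ok(dx, dx_levels(), FALSE),
                     paste0("invalid dx_", e)))
    add(bad_rows_msg(dx %in% c("present", "absent") & !(intv %in% TRUE),
                     paste0("dx_", e, " recorded without ", instr,
                            " interview")))
    if (e %in% c("gambling", "gaming")) {
      add(bad_rows_msg(scr == "not_screened" &
                         !(cohort$sub_cohort == 1L & !(int_mini_addis %in% TRUE)),
                       paste0("screen_", e, " = not_screened outside the ",
                              "sub-cohort-1 never-screened case")))
    } else {
      add(bad_rows_msg(scr == "not_screened",
                       paste0("screen_", e, " = not_screened is only allowed ",
                              "for gambling/gaming")))
    }
  }
  if (length(msgs) > 0) {
    stop("invalid cohort:\n  - ", paste(msgs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a cohort from a delimited file
#'
#' UTF-8, comma-separated, one header row, missing-value token `"NA"`,
#' booleans 0/1 (the dialect of [cohort_columns()]).
#'
#' @param path File path.
#' @param catalog A [diagnosis_catalog()].
#' @param validate Run [validate_cohort()]? Default `TRUE`.
#' @return A validated `twophase_cohort` tibble.
#' @export
read_cohort <- function(path, catalog = diagnosis_catalog(), validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- cohort_columns(catalog)
  df <- readr::read_csv(path,
                        col_types = readr::cols(
                          .default = readr::col_character()),
                        na = "NA", progress = FALSE)
  hdr <- names(df)
  if (!identical(sort(hdr), sort(cols))) {
    extra <- setdiff(hdr, cols)
    if (length(extra) > 0) {
      stop("unknown column(s) in ", path, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  as_cohort(df, catalog, validate = validate)
}

#' Write a cohort to a delimited file
#'
#' Deterministic column order and encoding; inverse of [read_cohort()] on
#' valid cohorts (byte-identical on re-write).
#'
#' @param cohort A cohort table.
#' @param path Output file path.
#' @param catalog A [diagnosis_catalog()].
#' @return Invisibly `path`.
#' @export
write_cohort <- function(cohort, path, catalog = diagnosis_catalog()) {
  cols <- cohort_columns(catalog)
  out <- tibble::as_tibble(cohort)[, cols, drop = FALSE]
  for (nm in grep("^int_", cols, value = TRUE)) {
    out[[nm]] <- as.integer(out[[nm]])
  }
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
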