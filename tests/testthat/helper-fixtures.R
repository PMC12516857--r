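# Fixtures are built in code: a blank valid cohort that tests then mutate.

catalog20 <- diagnosis_catalog()

# n participants: heterosexual content females in sub-cohort 2, all screens
# negative, nobody interviewed, all diagnoses unknown. Valid by construction.
blank_cohort <- function(n, sub_cohort = 2L) {
  df <- tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    legal_gender = "female",
    attraction_opposite = "strongly",
    attraction_same = "not_at_all",
    gender_contentment = "happy",
    sub_cohort = as.integer(sub_cohort)
  )
  for (e in catalog20$entity) df[[paste0("screen_", e)]] <- "negative"
  for (i in c("mini", "addis", "nods", "igds")) df[[paste0("int_", i)]] <- FALSE
  for (e in catalog20$entity) df[[paste0("dx_", e)]] <- "unknown"
  as_cohort(df, catalog20)
}

# Set a participant's screen/interview/diagnosis for one entity. Marks the
# owning instrument interviewed when a diagnosis outcome is recorded.
set_outcome <- function(cohort, rows, entity, screen = "positive",
                        dx = NULL, interviewed = !is.null(dx)) {
  instr <- entity_instrument(catalog20, entity)
  cohort[[paste0("screen_", entity)]][rows] <- screen
  if (interviewed) cohort[[paste0("int_", instr)]][rows] <- TRUE
  if (!is.null(dx)) cohort[[paste0("dx_", entity)]][rows] <- dx
  cohort
}

# 20 members, depression: 6 screen-positive of whom 4 interviewed
# (2 diagnosed, 2 not), 2 screen-positive not interviewed.
hand_counts_cohort <- function() {
  ch <- blank_cohort(20)
  ch <- set_outcome(ch, 1:2, "depression", dx = "present")
  ch <- set_outcome(ch, 3:4, "depression", dx = "absent")
  ch <- set_outcome(ch, 5:6, "depression", interviewed = FALSE)
  ch
}

# Mixed sub-cohorts gambling fixture, 20 members:
#   rows 1:5   sub-cohort 1, never screened for gambling/gaming (NS1 = 5)
#   rows 6:10  sub-cohort 1, in a M.I.N.I. session, gambling screen negative
#   rows 11:20 sub-cohort 2, not M.I.N.I./ADDIS-interviewed (PD2 reference):
#              rows 11:12 gambling-positive, NODS-interviewed, one diagnosed;
#              rows 13:20 gambling screen negative.
# PD2 = (1 + 1/2 * 0) / 10 = 0.1.
gambling_cohort <- function() {
  ch <- blank_cohort(20)
  ch$sub_cohort[1:10] <- 1L
  ch[["screen_gambling"]][1:5] <- "not_screened"
  ch[["screen_gaming"]][1:5] <- "not_screened"
  # rows 6:10 in-session via a depression screen + interview
  ch <- set_outcome(ch, 6:10, "depression", dx = "absent")
  ch <- set_outcome(ch, 11, "gambling", dx = "present")
  ch <- set_outcome(ch, 12, "gambling", dx = "absent")
  ch
}

no_noise_config <- function(n = 1000, seed = 1, ...) {
  cohort_config(n = n, sensitivity = 1, specificity = 1,
                interview_response_prob = 1, subcohort1_fraction = 0,
                seed = seed, ...)
}

# Independent brute-force Pearson chi-square: sum over cells of (O-E)^2/E.
chi2_oracle <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Latent-case proportion per analysis cell x entity from a generated truth
# table; rows = cells with at least one member.
latent_cell_proportions <- function(sim, groups) {
  ents <- catalog20$entity
  latent <- as.matrix(sim$truth[, paste0("latent_", ents)])
  colnames(latent) <- ents
  cells <- names(groups$cells)[vapply(groups$cells, length, 1L) > 0]
  t(vapply(cells, function(cl) {
    colMeans(latent[groups$cells[[cl]], , drop = FALSE])
  }, numeric(length(ents))))
}
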