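#' Parameter-recovery study of the two-phase estimator
#'
#' Replicates the full pipeline (generate cohort, build groups, estimate all
#' cell x entity prevalences) and measures, per cell x entity, the bias of
#' the adjusted prevalence against the realized latent-case proportion of
#' that cell. Under missing-at-random interview response given screen status
#' and sensitivity 1, the estimator is unbiased; making response depend on
#' true diagnosis status ([inject_informative_attrition()]) induces a
#' systematic bias that this study detects.
#'
#' Cells are flagged `eligible` when their expected number of observed
#' diagnoses per replicate (`E[T] * prevalence * sensitivity * response`,
#' scaled by the screened fraction for gambling/gaming) reaches
#' `min_expected_D`; very sparse cells carry too much ratio-estimator noise
#' to say anything about bias. Replicates where a cell is inestimable
#' (screen-positives but no completed interviews) are dropped for that cell.
#'
#' @param config A [cohort_config()].
#' @param reps Number of replicates.
#' @param seed Root seed; per-replicate seeds are drawn from it.
#' @param min_expected_D Eligibility threshold on the expected number of
#'   interviewed true cases per replicate.
#' @return A `recovery_study` object: list with `cells` (tibble: `group`,
#'   `entity`, `expected_D`, `eligible`, `mean_bias`, `mc_se`, `n_used`),
#'   `rep_mean_bias` (per-replicate mean bias across eligible cells) and
#'   `reps`.
#' @export
recovery_study <- function(config, reps = 500, seed = 1, min_expected_D = 5) {
  validate_config(config)
  catalog <- diagnosis_catalog()
  ents <- catalog$entity
  cells <- analysis_cell_names()
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)

  exp_d <- expected_interviewed_cases(config, catalog)
  eligible <- exp_d >= min_expected_D

  key <- function(g, e) paste(g, e, sep = ".")
  bias_sum <- bias_sq <- n_used <- matrix(
    0, length(cells), length(ents), dimnames = list(cells, ents))
  rep_mean_bias <- numeric(reps)

  for (r in seq_len(reps)) {
    sim <- generate_cohort(config, seed = rep_seeds[r])
    groups <- build_analysis_groups(sim$cohort)
    est <- estimate_all(sim$cohort, groups, catalog, on_inestimable = "na")
    est <- est[!est$composite, ]
    latent <- as.matrix(sim$truth[, paste0("latent_", ents)])
    colnames(latent) <- ents
    truth_prop <- matrix(NA_real_, length(cells), length(ents),
                         dimnames = list(cells, ents))
    for (cl in cells) {
      m <- groups$cells[[cl]]
      if (length(m) > 0) truth_prop[cl, ] <- colMeans(latent[m, , drop = FALSE])
    }
    phat <- matrix(est$P[match(key(rep(cells, each = length(ents)),
                                   rep(ents, length(cells))),
                               key(est$group, est$entity))],
                   length(cells), length(ents), byrow = TRUE,
                   dimnames = list(cells, ents))
    bias <- phat - truth_prop
    ok <- is.finite(bias)
    bias_sum[ok] <- bias_sum[ok] + bias[ok]
    bias_sq[ok] <- bias_sq[ok] + bias[ok]^2
    n_used[ok] <- n_used[ok] + 1
    eb <- bias[eligible & ok]
    rep_mean_bias[r] <- if (length(eb) > 0) mean(eb) else NA_real_
  }

  mean_bias <- bias_sum / pmax(n_used, 1)
  var_bias <- (bias_sq - n_used * mean_bias^2) / pmax(n_used - 1, 1)
  mc_se <- sqrt(pmax(var_bias, 0) / pmax(n_used, 1))
  out <- tibble::tibble(
    group = rep(cells, times = length(ents)),
    entity = rep(ents, each = length(cells)),
    expected_D = as.vector(exp_d),
    eligible = as.vector(eligible),
    mean_bias = as.vector(mean_bias),
    mc_se = as.vector(mc_se),
    n_used = as.vector(n_used)
  )
  out$mean_bias[out$n_used == 0] <- NA_real_
  out$mc_se[out$n_used < 2] <- NA_real_
  structure(list(cells = out, rep_mean_bias = rep_mean_bias, reps = reps,
                 min_expected_D = min_expected_D),
            class = "recovery_study")
}

# Internal: expected interviewed true cases per cell x entity, from the
# config alone (GD contamination of orientation cells, ~2%, is ignored --
# the quantity only gates eligibility).
expected_interviewed_cases <- function(config, catalog = diagnosis_catalog()) {
  ents <- catalog$entity
  cells <- analysis_cell_names()
  n <- config$n
  p_gender <- c(female = config$female_fraction,
                male = 1 - config$female_fraction)
  cats <- c("asexual", "homosexual", "bisexual", "heterosexual")
  exp_T <- setNames(numeric(length(cells)), cells)
  prev <- matrix(0, length(cells), length(ents),
                 dimnames = list(cells, ents))
  for (g in c("female", "male")) {
    for (o in cats) {
      cl <- paste(g, o, sep = "_")
      exp_T[cl] <- n * p_gender[[g]] * (1 - config$orientation_missing_prob) *
        config$orientation_probs[[g]][[o]]
      prev[cl, ] <- config$true_prevalence[, cl]
    }
  }
  exp_T["gd"] <- n * (1 - config$gd_missing_prob) * config$gd_prob
  exp_T["non_gd"] <- n * (1 - config$gd_missing_prob) * (1 - config$gd_prob)
  prev["gd", ] <- config$true_prevalence[, "gd"]
  pop_prev <- rep(0, length(ents))
  for (g in c("female", "male")) {
    for (o in cats) {
      pop_prev <- pop_prev + p_gender[[g]] *
        config$orientation_probs[[g]][[o]] *
        config$true_prevalence[, paste(g, o, sep = "_")]
    }
  }
  prev["non_gd", ] <- pop_prev
  sens <- config$sensitivity[catalog$instrument]
  resp <- config$interview_response_prob
  out <- prev * 0
  for (cl in cells) {
    out[cl, ] <- exp_T[cl] * prev[cl, ] * sens * resp
  }
  # gambling/gaming: only the screened fraction can yield interviews
  screened_frac <- 1 - config$subcohort1_fraction
  out[, c("gambling", "gaming")] <- out[, c("gambling", "gaming")] *
    screened_frac
  out
}

#' @export
print.recovery_study <- function(x, ...) {
  el <- x$cells[x$cells$eligible, ]
  cat("Recovery study:", x$reps, "replicates;",
      nrow(el), "eligible cell x entity combinations",
      sprintf("(expected D >= %g)\n", x$min_expected_D))
  if (nrow(el) > 0) {
    within3 <- abs(el$mean_bias) <= 3 * el$mc_se
    cat(sprintf("  mean bias across eligible cells: %+.5f\n",
                mean(el$mean_bias, na.rm = TRUE)))
    cat(sprintf("  cells with |mean bias| <= 3 MC SE: %d / %d\n",
                sum(within3, na.rm = TRUE), nrow(el)))
  }
  invisible(x)
}
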