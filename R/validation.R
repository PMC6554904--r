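#' Run the full predictive-validation analysis
#'
#' For every requested combination of population (cases and controls are
#' analysed separately), outcome (30- and 365-day mortality), model and
#' look-back window, fits the logistic model, computes the AUROC of its
#' linear predictor with a DeLong 95% confidence interval, and tests the
#' contrasts of interest for equality of correlated ROC curves: each
#' comorbidity-augmented model against the age + sex base model, and the
#' Elixhauser-alone model against the Charlson-index-alone model.
#' Deterministic given the cohort.
#'
#' @param cohort A `cohort` from [simulate_cohort()], or a list with
#'   `patients`, `events`, `codelists`.
#' @param windows Character vector of look-back window kinds.
#' @param outcomes Character vector of outcomes.
#' @param models Character vector of covariable sets (see [model_spec()]).
#' @param populations `"case"`, `"control"` or both.
#' @param weight_scheme Charlson weighting for the `cci` models.
#' @param hierarchy Passed to [comorbidity_profiles()].
#' @return Object of class `validation_results`: data frame with columns
#'   `population`, `outcome`, `model`, `window`, `auc`, `ci_low`, `ci_high`,
#'   `comparison`, `p_value`. One row per combination; `comparison` names the
#'   ROC-equality contrast whose p-value the row carries (`NA` for reference
#'   models).
#' @export
run_validation <- function(cohort,
                           windows = c("one_year", "five_year",
                                       "complete_record"),
                           outcomes = c("death_30d", "death_365d"),
                           models = c("base", "base_cci", "base_em",
                                      "cci_alone", "em_alone"),
                           populations = c("case", "control"),
                           weight_scheme = "original",
                           hierarchy = TRUE) {
  patients <- if (inherits(cohort, "cohort")) cohort$patients else
    cohort$patients
  profiles <- lapply(stats::setNames(windows, windows), function(w) {
    comorbidity_profiles(patients, cohort$events, cohort$codelists,
                         window = w, hierarchy = hierarchy)
  })
  rows <- list()
  for (popn in populations) {
    for (oc in outcomes) {
      for (w in windows) {
        fits <- list()
        ok <- TRUE
        for (mod in models) {
          spec <- model_spec(outcome = oc, covariables = mod,
                             weight_scheme = weight_scheme, window = w,
                             population = popn)
          des <- build_design(profiles[[w]], patients, spec)
          if (sum(des$y) == 0L || sum(des$y) == length(des$y)) {
            warning("skipping ", popn, "/", oc, "/", w,
                    ": single-class outcome", call. = FALSE)
            ok <- FALSE
            break
          }
          fits[[mod]] <- suppressWarnings(fit_logistic(des))
          fits[[mod]]$.y <- des$y
        }
        if (!ok) next
        y <- fits[[1]]$.y
        scores <- lapply(fits, `[[`, "linear_predictor")
        contrast_p <- function(a, b) {
          if (a %in% models && b %in% models) {
            compare_roc(list(scores[[a]], scores[[b]]), y)$p_value
          } else NA_real_
        }
        for (mod in models) {
          r <- auroc(scores[[mod]], y)
          cmp <- switch(mod,
            base_cci = c("vs_base", contrast_p("base_cci", "base")),
            base_em  = c("vs_base", contrast_p("base_em", "base")),
            base_cm  = c("vs_base", contrast_p("base_cm", "base")),
            em_alone = c("vs_cci_alone",
                         contrast_p("em_alone", "cci_alone")),
            cm_alone = c("vs_cci_alone",
                         contrast_p("cm_alone", "cci_alone")),
            c(NA_character_, NA_real_))
          rows[[length(rows) + 1L]] <- data.frame(
            population = popn, outcome = oc, model = mod, window = w,
            auc = r$auc, ci_low = r$ci95_low, ci_high = r$ci95_high,
            comparison = cmp[1], p_value = as.numeric(cmp[2]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("validation_results", "data.frame"))
}

#' @export
print.validation_results <- function(x, ...) {
  cat("<validation results>", nrow(x), "model fits\n")
  y <- x
  y$auc <- sprintf("%.3f [%.3f-%.3f]", y$auc, y$ci_low, y$ci_high)
  print(as.data.frame(y[c("population", "outcome", "model", "window",
                          "auc", "comparison", "p_value")]), digits = 3)
  invisible(x)
}
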