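#' Specify a mortality model
#'
#' The validation fits a fixed menu of logistic models -- no stepwise
#' selection. The base model carries age (continuous) and sex (1 = female);
#' comorbidity information is layered on top either as the Charlson index
#' (one integer covariable, original or Quan weights), as the 31 Elixhauser
#' category indicators entered separately, or as the 17 Charlson category
#' indicators entered separately.
#'
#' @param outcome `"death_30d"` or `"death_365d"` (day 30/365 boundaries
#'   inclusive).
#' @param covariables One of `"base"`, `"base_cci"`, `"base_em"`,
#'   `"cci_alone"`, `"em_alone"`, `"base_cm"`, `"cm_alone"` (`cm` = Charlson
#'   categories as individual covariables).
#' @param weight_scheme Charlson weighting for the `cci` variants.
#' @param window Look-back window the profiles must have been computed under.
#' @param population `"case"` or `"control"`; the populations are analysed
#'   separately, never pooled into a case-control design.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("death_30d", "death_365d"),
                       covariables = c("base", "base_cci", "base_em",
                                       "cci_alone", "em_alone", "base_cm",
                                       "cm_alone"),
                       weight_scheme = c("original", "quan"),
                       window = "complete_record",
                       population = c("case", "control")) {
  structure(list(outcome = match.arg(outcome),
                 covariables = match.arg(covariables),
                 weight_scheme = match.arg(weight_scheme),
                 window = as_lookback(window)$kind,
                 population = match.arg(population)),
            class = "model_spec")
}

#' Build a design matrix and outcome vector for a mortality model
#'
#' Filters the cohort to the spec's population, derives the binary outcome
#' (death within 30 or 365 days of index, boundary inclusive; patients dying
#' before index are excluded), and assembles the covariable columns the spec
#' requests. Profiles must have been computed under the spec's window.
#'
#' @param profiles A `comorbidity_profiles` table.
#' @param patients Patient table (or `cohort`).
#' @param spec A [model_spec()].
#' @return List with `x` (numeric design matrix, no intercept column), `y`
#'   (0/1 outcome), `patient_id`, and the `spec`.
#' @export
build_design <- function(profiles, patients, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (inherits(patients, "cohort")) patients <- patients$patients
  if (!identical(attr(profiles, "window"), spec$window)) {
    stop("profiles were computed under window '", attr(profiles, "window"),
         "' but the model spec requests '", spec$window, "'", call. = FALSE)
  }
  patients <- patients[patients$role == spec$population, , drop = FALSE]
  days <- as.numeric(patients$death_date - patients$index_date)
  pre_index_death <- !is.na(days) & days < 0
  patients <- patients[!pre_index_death, , drop = FALSE]
  days <- days[!pre_index_death]
  horizon <- if (spec$outcome == "death_30d") 30 else 365
  y <- as.integer(!is.na(days) & days <= horizon)
  prow <- match(patients$patient_id, profiles$patient_id)
  if (anyNA(prow)) stop("profiles missing for some patients", call. = FALSE)
  pr <- profiles[prow, , drop = FALSE]

  base <- cbind(age = patients$age_at_index, sex = patients$sex)
  cci <- switch(spec$weight_scheme, original = pr$cci_original,
                quan = pr$cci_quan)
  em <- profile_flags(pr, "elixhauser") * 1L
  colnames(em) <- paste0("em_", colnames(em))
  cm <- profile_flags(pr, "charlson") * 1L
  colnames(cm) <- paste0("cm_", colnames(cm))
  x <- switch(spec$covariables,
    base      = base,
    base_cci  = cbind(base, cci = cci),
    base_em   = cbind(base, em),
    cci_alone = cbind(cci = cci),
    em_alone  = em,
    base_cm   = cbind(base, cm),
    cm_alone  = cm)
  rownames(x) <- patients$patient_id
  list(x = x, y = y, patient_id = patients$patient_id, spec = spec)
}

#' Fit a logistic regression by maximum likelihood
#'
#' Deterministic iteratively reweighted least squares (no stochastic
#' optimiser), convergence tolerance 1e-8, at most 100 iterations. Constant
#' or perfectly collinear columns are dropped with a warning before fitting,
#' matching what standard statistical software does silently. Complete
#' separation (fitted probabilities pinned to 0/1 with a diverging linear
#' predictor) is flagged and the fit reported as non-converged.
#'
#' @param design List from [build_design()], or a numeric matrix.
#' @param outcome 0/1 outcome vector (only when `design` is a matrix).
#' @return Object of class `readmorbid_fit`: coefficients with standard
#'   errors, `converged`, `separation`, `log_likelihood`, `linear_predictor`
#'   per subject, `dropped` column names. Methods: `coef`, `print`,
#'   `summary`, `predict` (linear predictor or response for new design
#'   matrices), `logLik`.
#' @export
fit_logistic <- function(design, outcome = NULL) {
  if (is.list(design) && !is.data.frame(design)) {
    x <- design$x; y <- design$y; spec <- design$spec
  } else {
    x <- design; y <- outcome; spec <- NULL
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1))
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop("outcome has a single class; cannot fit", call. = FALSE)
  }
  dropped <- character()
  if (ncol(x) > 0) {
    const <- apply(x, 2, function(col) max(col) == min(col))
    dropped <- colnames(x)[const]
    x <- x[, !const, drop = FALSE]
    if (ncol(x) > 1) {
      q <- qr(cbind(1, x))
      if (q$rank < ncol(x) + 1) {
        keep <- sort(q$pivot[seq_len(q$rank)])
        keep <- setdiff(keep, 1L) - 1L
        dropped <- c(dropped, colnames(x)[-keep])
        x <- x[, keep, drop = FALSE]
      }
    }
    if (length(dropped)) {
      warning("dropped degenerate column(s): ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
  }
  dat <- data.frame(.y = y, x, check.names = FALSE)
  form <- if (ncol(x)) stats::as.formula(
    paste(".y ~", paste(sprintf("`%s`", colnames(x)), collapse = " + "))
  ) else stats::as.formula(".y ~ 1")
  fit <- stats::glm(form, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  lp <- as.vector(x %*% stats::coef(fit)[-1]) + stats::coef(fit)[1]
  if (ncol(x) == 0) lp <- rep(stats::coef(fit)[1], length(y))
  separation <- any(abs(lp) > 25)
  co <- summary(fit)$coefficients
  coefs <- data.frame(term = c("(Intercept)", colnames(x)),
                      estimate = co[, 1], std_error = co[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    coefficients = coefs,
    converged = fit$converged && !separation,
    separation = separation,
    log_likelihood = as.numeric(stats::logLik(fit)),
    linear_predictor = unname(lp),
    dropped = dropped,
    n = length(y), n_events = sum(y),
    spec = spec), class = "readmorbid_fit")
}

#' @export
coef.readmorbid_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.readmorbid_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = nrow(object$coefficients), class = "logLik")
}

#' @export
print.readmorbid_fit <- function(x, ...) {
  cat("<logistic fit>", x$n, "subjects,", x$n_events, "events;",
      if (x$converged) "converged" else "NOT converged",
      if (x$separation) "(separation detected)" else "", "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
summary.readmorbid_fit <- function(object, ...) {
  co <- object$coefficients
  co$z <- co$estimate / co$std_error
  co$p_value <- 2 * stats::pnorm(-abs(co$z))
  co
}

#' @export
predict.readmorbid_fit <- function(object, newdata = NULL,
                                   type = c("link", "response"), ...) {
  type <- match.arg(type)
  lp <- if (is.null(newdata)) {
    object$linear_predictor
  } else {
    b <- coef(object)
    x <- as.matrix(newdata)[, object$coefficients$term[-1], drop = FALSE]
    as.vector(x %*% b[-1]) + b[1]
  }
  if (type == "response") stats::plogis(lp) else lp
}
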