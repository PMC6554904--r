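#' Configuration of the synthetic hip-fracture cohort generator
#'
#' Parameterises every aspect of the synthetic case-control cohort: cohort
#' size and matching ratio, the demographic distributions, per-category
#' comorbidity prevalences, how coded events are scattered over the record,
#' and the logistic mortality model that generates deaths. Defaults emulate a
#' UK primary-care hip-fracture cohort: index events between 1999-01-01 and
#' 2013-10-09, at least three years of prior registration, 2:1 age/sex-matched
#' controls, 75.1% female, median age at index 82 (IQR 75--87).
#'
#' Age at index is drawn as `round(offset - Gamma(shape, rate))`, truncated to
#' `age_range`: a left-skewed discrete distribution appropriate for an elderly
#' fracture population. The gamma parameters are fitted at configuration time
#' so the distribution's quartiles match `age_median` and the IQR bounds.
#'
#' Per-category prevalences (cases) default to clinically plausible relative
#' magnitudes (hypertension and depression common, HIV rare) rescaled so the
#' expected fraction of cases with *no* flagged category matches
#' `target_zero_charlson` / `target_zero_elixhauser`. Controls use the same
#' prevalences scaled by `control_prevalence_scale`. Supply named probability
#' vectors to override either measure entirely.
#'
#' Mortality: 30-day death is Bernoulli with log-odds
#' `intercept_30d + case_excess_30d * case + beta_age * age + beta_sex * sex +
#' sum(beta_category * flag)`; survivors are then exposed to the analogous
#' 365-day model for death in the (30, 365] window. `beta_category` is a
#' named vector keyed `"measure:category"` (e.g. `"charlson:mets"`); the
#' default puts weight on Charlson categories in proportion to their original
#' index weights plus clinically lethal Elixhauser-only categories, so both
#' summary measures carry real signal. Sex is coded 1 = female, 0 = male
#' throughout.
#'
#' @param n_cases Number of hip-fracture cases.
#' @param control_ratio Matched controls per case (>= 1).
#' @param female_fraction Probability a case is female.
#' @param age_median,age_iqr_low,age_iqr_high Target quartiles of age at
#'   index, in years.
#' @param age_range Truncation bounds for age at index.
#' @param study_window Two dates bounding the case index dates.
#' @param prevalence_charlson,prevalence_elixhauser Optional named probability
#'   vectors over the category registries; `NULL` means calibrate defaults.
#' @param target_zero_charlson,target_zero_elixhauser Calibration targets:
#'   expected fraction of cases with zero flagged categories per measure.
#' @param control_prevalence_scale Multiplier applied to case prevalences for
#'   controls.
#' @param events_per_flag Mean number of coded events emitted per present
#'   comorbidity (>= 1; events are `1 + Poisson(events_per_flag - 1)`).
#' @param recent_fraction Optional probability that an event is placed within
#'   one year of the index date rather than uniformly over the record; `NULL`
#'   places all events uniformly over `[registration_start, index_date)`.
#' @param intercept_30d,intercept_365d Log-odds intercepts of the two
#'   mortality models.
#' @param case_excess_30d,case_excess_365d Additional log-odds of death for
#'   cases (the fracture insult itself).
#' @param beta_age,beta_sex Log-odds per year of age / for female sex.
#' @param beta_category Named log-odds vector keyed `"measure:category"`.
#' @param misspecify If `TRUE`, adds an age-by-sex interaction the validation
#'   models do not include (robustness experiments); off by default.
#' @return An object of class `generator_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
generator_config <- function(
    n_cases = 2000,
    control_ratio = 2,
    female_fraction = 0.751,
    age_median = 82, age_iqr_low = 75, age_iqr_high = 87,
    age_range = c(60, 104),
    study_window = as.Date(c("1999-01-01", "2013-10-09")),
    prevalence_charlson = NULL,
    prevalence_elixhauser = NULL,
    target_zero_charlson = 0.276,
    target_zero_elixhauser = 0.092,
    control_prevalence_scale = 0.79,
    events_per_flag = 3,
    recent_fraction = NULL,
    intercept_30d = -9.1,
    intercept_365d = -7.4,
    case_excess_30d = 1.6,
    case_excess_365d = 0.9,
    beta_age = 0.06,
    beta_sex = -0.35,
    beta_category = default_mortality_betas(),
    misspecify = FALSE) {
  stopifnot(
    n_cases >= 0, control_ratio >= 1,
    length(study_window) == 2L, study_window[1] < study_window[2],
    events_per_flag >= 1,
    age_iqr_low < age_median, age_median < age_iqr_high)
  if (female_fraction < 0 || female_fraction > 1) {
    stop("female_fraction must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.null(recent_fraction) &&
      (recent_fraction < 0 || recent_fraction > 1)) {
    stop("recent_fraction must be a probability in [0, 1]", call. = FALSE)
  }
  if (is.null(prevalence_charlson)) {
    prevalence_charlson <- calibrate_prevalence("charlson",
                                                target_zero_charlson)
  }
  if (is.null(prevalence_elixhauser)) {
    prevalence_elixhauser <- calibrate_prevalence("elixhauser",
                                                  target_zero_elixhauser)
  }
  check_prevalence(prevalence_charlson, "charlson")
  check_prevalence(prevalence_elixhauser, "elixhauser")
  if (control_prevalence_scale < 0 ||
      control_prevalence_scale * max(prevalence_charlson,
                                     prevalence_elixhauser) > 1) {
    stop("control_prevalence_scale produces probabilities outside [0, 1]",
         call. = FALSE)
  }
  age_par <- fit_age_gamma(age_median, age_iqr_low, age_iqr_high, age_range)
  structure(list(
    n_cases = as.integer(n_cases),
    control_ratio = as.integer(control_ratio),
    female_fraction = female_fraction,
    age_median = age_median, age_iqr_low = age_iqr_low,
    age_iqr_high = age_iqr_high, age_range = age_range,
    age_gamma = age_par,
    study_window = study_window,
    prevalence = list(charlson = prevalence_charlson,
                      elixhauser = prevalence_elixhauser),
    control_prevalence_scale = control_prevalence_scale,
    events_per_flag = events_per_flag,
    recent_fraction = recent_fraction,
    intercept_30d = intercept_30d, intercept_365d = intercept_365d,
    case_excess_30d = case_excess_30d, case_excess_365d = case_excess_365d,
    beta_age = beta_age, beta_sex = beta_sex,
    beta_category = beta_category,
    misspecify = isTRUE(misspecify)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>", x$n_cases, "cases,", x$control_ratio,
      ": 1 matched controls\n")
  cat("  age median", x$age_median, "(IQR", x$age_iqr_low, "-",
      x$age_iqr_high, "), female fraction", x$female_fraction, "\n")
  cat("  mortality intercepts:", x$intercept_30d, "(30d),",
      x$intercept_365d, "(365d)\n")
  invisible(x)
}

check_prevalence <- function(p, measure) {
  ids <- category_ids(measure)
  if (is.null(names(p)) || !setequal(names(p), ids)) {
    stop("prevalence_", measure, " must be named over all ", length(ids),
         " ", measure, " categories", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("prevalence_", measure, " contains values outside [0, 1]",
         call. = FALSE)
  }
  invisible(p)
}

# Relative prevalence magnitudes in an elderly UK population (common chronic
# disease high, HIV rare). Rescaled at config time so the expected
# zero-comorbidity fraction hits the configured target.
.prevalence_weights <- list(
  charlson = c(
    mi = 1.5, chf = 1.5, pvd = 1, cevd = 1.5, dementia = 1.5, copd = 2,
    rheum = 0.8, pud = 1, mild_liver = 0.4, diab = 2, diab_comp = 0.6,
    hemiplegia = 0.3, renal = 1, cancer = 1.2, severe_liver = 0.15,
    mets = 0.4, hiv = 0.05),
  elixhauser = c(
    chf = 1.5, arrhythmia = 1.5, valvular = 0.8, pulm_circ = 0.3, pvd = 1,
    htn_unc = 4, htn_comp = 0.5, paralysis = 0.3, neuro_other = 1, copd = 2,
    diab_unc = 2, diab_comp = 0.6, hypothyroid = 1.2, renal_failure = 1,
    liver = 0.4, pud_no_bleed = 1, hiv = 0.05, lymphoma = 0.3, mets = 0.4,
    solid_tumour = 1.2, rheum_arth = 0.8, coagulopathy = 0.3, obesity = 1,
    weight_loss = 0.5, fluid_electrolyte = 1.2, blood_loss_anaemia = 0.3,
    deficiency_anaemia = 1.2, alcohol = 0.7, drug_abuse = 0.3,
    psychoses = 0.5, depression = 2)
)

calibrate_prevalence <- function(measure, zero_fraction) {
  stopifnot(zero_fraction > 0, zero_fraction < 1)
  w <- .prevalence_weights[[measure]][category_ids(measure)]
  f <- function(s) sum(log1p(-pmin(s * w, 0.99))) - log(zero_fraction)
  s <- stats::uniroot(f, c(1e-9, 0.99 / max(w)))$root
  pmin(s * w, 0.99)
}

# Mortality log-odds per flagged category: Charlson categories proportional to
# their original weights; Elixhauser-only categories get clinically graded
# effects. Categories the two measures share contribute through their
# charlson flag only (the measures' latent flags are drawn independently).
default_mortality_betas <- function() {
  ch <- category_registry("charlson")
  b_ch <- stats::setNames(0.10 * ch$weight_original,
                          paste0("charlson:", ch$category))
  b_em <- c(
    arrhythmia = 0.25, valvular = 0.1, pulm_circ = 0.3, htn_unc = 0.05,
    htn_comp = 0.2, paralysis = 0.3, neuro_other = 0.2, hypothyroid = 0,
    liver = 0.2, lymphoma = 0.4, solid_tumour = 0.3, coagulopathy = 0.4,
    obesity = 0.05, weight_loss = 0.5, fluid_electrolyte = 0.4,
    blood_loss_anaemia = 0.2, deficiency_anaemia = 0.15, alcohol = 0.2,
    drug_abuse = 0.2, psychoses = 0.2, depression = 0.1)
  names(b_em) <- paste0("elixhauser:", names(b_em))
  c(b_ch, b_em)
}

# fit gamma (shape, rate) so that round(offset - G) has the target quartiles;
# offset sits a little above the upper truncation bound
fit_age_gamma <- function(med, q1, q3, range) {
  offset <- range[2] - 9
  target <- offset - c(q3, med, q1)  # gamma quantiles at .25/.5/.75
  if (any(target <= 0)) stop("age quartiles incompatible with age_range",
                             call. = FALSE)
  obj <- function(par) {
    q <- stats::qgamma(c(0.25, 0.5, 0.75), shape = exp(par[1]),
                       rate = exp(par[2]))
    sum((q - target)^2)
  }
  o <- stats::optim(c(log(2.5), log(0.16)), obj)
  list(shape = exp(o$par[1]), rate = exp(o$par[2]), offset = offset)
}
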