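#' Comorbidity category registries
#'
#' The two comorbidity summary measures supported by this package are the
#' Charlson Comorbidity Index (CCI; 17 disease categories, each carrying an
#' integer weight) and the Elixhauser Method (EM; 31 binary categories entered
#' into regression models as separate covariables). `category_registry()`
#' returns the canonical category set for a measure, in canonical order, with
#' the CCI weights under both supported schemes:
#'
#' * `weight_original`: the weights of the original index (range 1--6; e.g.
#'   peripheral vascular disease 1, metastatic solid tumour 6).
#' * `weight_quan`: the updated 12-item weights proposed by Quan and
#'   colleagues, in which five of the original categories are down-weighted to
#'   zero and the remaining twelve carry weights in \{1, 2, 4, 6\}.
#'
#' Elixhauser categories carry no weights: the method enters each category as
#' its own model covariable rather than summing a score.
#'
#' @param measure `"charlson"` or `"elixhauser"`.
#' @return A data frame with columns `category` (stable identifier),
#'   `display_name`, `measure`, and for charlson also `weight_original` and
#'   `weight_quan`.
#' @examples
#' category_registry("charlson")
#' nrow(category_registry("elixhauser"))  # 31
#' @export
category_registry <- function(measure = c("charlson", "elixhauser")) {
  measure <- match.arg(measure)
  if (measure == "charlson") .charlson_registry else .elixhauser_registry
}

# Original weights per Charlson et al. (1987); quan column per the 12-item
# re-weighting of Quan et al. (2011). Row order is the canonical order used
# for flag vectors throughout the package.
.charlson_registry <- data.frame(
  category = c(
    "mi", "chf", "pvd", "cevd", "dementia", "copd", "rheum", "pud",
    "mild_liver", "diab", "diab_comp", "hemiplegia", "renal", "cancer",
    "severe_liver", "mets", "hiv"),
  display_name = c(
    "Myocardial infarction", "Congestive heart failure",
    "Peripheral vascular disease", "Cerebrovascular disease", "Dementia",
    "Chronic pulmonary disease", "Rheumatic disease", "Peptic ulcer disease",
    "Mild liver disease", "Diabetes without complications",
    "Diabetes with complications", "Hemiplegia or paraplegia",
    "Renal disease", "Any malignancy incl. leukaemia and lymphoma",
    "Moderate or severe liver disease", "Metastatic solid tumour",
    "AIDS/HIV"),
  measure = "charlson",
  weight_original = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 3, 6, 6),
  weight_quan     = c(0, 2, 0, 0, 2, 1, 1, 0, 2, 0, 1, 2, 1, 2, 4, 6, 4),
  stringsAsFactors = FALSE
)

.elixhauser_registry <- data.frame(
  category = c(
    "chf", "arrhythmia", "valvular", "pulm_circ", "pvd", "htn_unc",
    "htn_comp", "paralysis", "neuro_other", "copd", "diab_unc", "diab_comp",
    "hypothyroid", "renal_failure", "liver", "pud_no_bleed", "hiv",
    "lymphoma", "mets", "solid_tumour", "rheum_arth", "coagulopathy",
    "obesity", "weight_loss", "fluid_electrolyte", "blood_loss_anaemia",
    "deficiency_anaemia", "alcohol", "drug_abuse", "psychoses", "depression"),
  display_name = c(
    "Congestive heart failure", "Cardiac arrhythmias", "Valvular disease",
    "Pulmonary circulation disorders", "Peripheral vascular disorders",
    "Hypertension, uncomplicated", "Hypertension, complicated", "Paralysis",
    "Other neurological disorders", "Chronic pulmonary disease",
    "Diabetes, uncomplicated", "Diabetes, complicated", "Hypothyroidism",
    "Renal failure", "Liver disease", "Peptic ulcer disease excl. bleeding",
    "AIDS/HIV", "Lymphoma", "Metastatic cancer",
    "Solid tumour without metastasis",
    "Rheumatoid arthritis/collagen vascular disease", "Coagulopathy",
    "Obesity", "Weight loss", "Fluid and electrolyte disorders",
    "Blood loss anaemia", "Deficiency anaemia", "Alcohol abuse",
    "Drug abuse", "Psychoses", "Depression"),
  measure = "elixhauser",
  stringsAsFactors = FALSE
)

#' Default severity hierarchy rules
#'
#' Severity hierarchies prevent double-counting when a patient carries codes
#' for both a mild condition and its severe counterpart: the milder category
#' is cleared when the severe one is flagged. The defaults are the rules most
#' scoring implementations apply; pass an empty data frame to
#' [comorbidity_profiles()] (or [apply_hierarchy()]) to disable hierarchies
#' entirely.
#'
#' Charlson defaults: complicated diabetes supersedes uncomplicated; moderate
#' or severe liver disease supersedes mild; metastatic solid tumour supersedes
#' any malignancy. Elixhauser defaults: complicated hypertension supersedes
#' uncomplicated; metastatic cancer supersedes solid tumour without
#' metastasis; complicated diabetes supersedes uncomplicated.
#'
#' @param measure `"charlson"` or `"elixhauser"`.
#' @return Data frame with columns `severe`, `superseded`, `measure`.
#' @export
default_hierarchy <- function(measure = c("charlson", "elixhauser")) {
  measure <- match.arg(measure)
  if (measure == "charlson") {
    data.frame(
      severe     = c("diab_comp", "severe_liver", "mets"),
      superseded = c("diab", "mild_liver", "cancer"),
      measure = "charlson", stringsAsFactors = FALSE)
  } else {
    data.frame(
      severe     = c("htn_comp", "mets", "diab_comp"),
      superseded = c("htn_unc", "solid_tumour", "diab_unc"),
      measure = "elixhauser", stringsAsFactors = FALSE)
  }
}

# internal: category id vector in canonical order
category_ids <- function(measure) category_registry(measure)$category
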