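# In-code fixtures shared across test files.

# write a small codelist CSV and return its path
write_codelist_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

tiny_charlson_rows <- function() {
  data.frame(
    code = c("H33..", "G58..", "C10E.", "C10F.", "B58..", "7K1D."),
    term = c("Asthma", "Heart failure", "Diabetes type 1",
             "Diabetes type 2", "Secondary malignant neoplasm",
             "Hip operation"),
    category = c("copd", "chf", "diab", "diab", "mets", "pvd"),
    stringsAsFactors = FALSE)
}

# named logical flag vector over a measure's categories
flag_vector <- function(measure, on = character()) {
  ids <- readmorbid::category_registry(measure)$category
  stats::setNames(ids %in% on, ids)
}

# random small codelist for property tests (assumes RNG already seeded)
random_codelist <- function(measure = "charlson", n = 8) {
  ids <- readmorbid::category_registry(measure)$category
  rows <- data.frame(
    code = paste0("Z", sample(100:999, n)),
    term = paste("term", seq_len(n)),
    category = sample(ids, n, replace = TRUE),
    stringsAsFactors = FALSE)
  readmorbid:::new_codelist(rows, measure)
}

# small deterministic cohort reused by engine/validation tests
small_cohort <- function(n_cases = 200, seed = 42, ...) {
  simulate_cohort(generator_config(n_cases = n_cases, ...), seed = seed)
}

# exhaustive Mann-Whitney pair counting: independent AUC oracle
auc_pair_count <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + (x > y) + 0.5 * (x == y)
  }
  total / (length(pos) * length(neg))
}
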