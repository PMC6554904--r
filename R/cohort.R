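#' Generate hip-fracture cases
#'
#' Draws `n_cases` synthetic patients with a first hip-fracture index date
#' uniform over the study window, sex Bernoulli(`female_fraction`), age at
#' index from the configured discretised left-skewed gamma, and a registration
#' start at least three years before the index date (the up-to-standard
#' registration rule), with additional registration history of up to 25 years.
#' Year of birth is the index year minus age at index, the convention of
#' databases that record year of birth only.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for this stage.
#' @return Data frame of patient records: `patient_id`, `sex` (1 = female,
#'   0 = male), `year_of_birth`, `registration_start`, `registration_end`,
#'   `death_date` (`NA` until [simulate_mortality()]), `role`,
#'   `matched_case_id`, `index_date`, `age_at_index`.
#' @export
generate_cases <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_cases
  if (n == 0L) return(empty_patients())
  with_seed(stage_seed(seed, "cases"), {
    sex <- stats::rbinom(n, 1L, config$female_fraction)
    g <- config$age_gamma
    age <- round(g$offset - stats::rgamma(n, shape = g$shape, rate = g$rate))
    age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
    span <- as.integer(config$study_window[2] - config$study_window[1])
    index_date <- config$study_window[1] +
      sample.int(span + 1L, n, replace = TRUE) - 1L
    extra_days <- sample.int(25L * 365L, n, replace = TRUE)
    registration_start <- index_date - (3L * 365L + extra_days)
    data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      sex = sex,
      year_of_birth = as.integer(format(index_date, "%Y")) - age,
      registration_start = registration_start,
      registration_end = index_date + 730L,
      death_date = as.Date(rep(NA, n)),
      role = "case",
      matched_case_id = NA_character_,
      index_date = index_date,
      age_at_index = as.integer(age),
      stringsAsFactors = FALSE)
  })
}

empty_patients <- function() {
  data.frame(
    patient_id = character(), sex = integer(), year_of_birth = integer(),
    registration_start = as.Date(character()),
    registration_end = as.Date(character()),
    death_date = as.Date(character()), role = character(),
    matched_case_id = character(), index_date = as.Date(character()),
    age_at_index = integer(), stringsAsFactors = FALSE)
}

#' Synthesize age- and sex-matched controls
#'
#' Emits `control_ratio` controls per case, matched exactly on sex and
#' integer age at index. Because controls are synthesized rather than sampled
#' from a finite pool, matching never fails. Each control inherits its
#' matched case's index date as the reference date for look-back windows and
#' mortality follow-up (the standard matched-design convention), and receives
#' its own registration history satisfying the three-year rule.
#'
#' @param cases Data frame from [generate_cases()].
#' @param config A [generator_config()].
#' @param seed Integer seed for this stage.
#' @return Data frame of control patient records with `matched_case_id` set.
#' @export
match_controls <- function(cases, config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  r <- config$control_ratio
  n <- nrow(cases) * r
  if (n == 0L) return(empty_patients())
  with_seed(stage_seed(seed, "controls"), {
    idx <- rep(seq_len(nrow(cases)), each = r)
    index_date <- cases$index_date[idx]
    extra_days <- sample.int(25L * 365L, n, replace = TRUE)
    registration_start <- index_date - (3L * 365L + extra_days)
    data.frame(
      patient_id = sprintf("C%06d", seq_len(n)),
      sex = cases$sex[idx],
      year_of_birth = cases$year_of_birth[idx],
      registration_start = registration_start,
      registration_end = index_date + 730L,
      death_date = as.Date(rep(NA, n)),
      role = "control",
      matched_case_id = cases$patient_id[idx],
      index_date = index_date,
      age_at_index = cases$age_at_index[idx],
      stringsAsFactors = FALSE)
  })
}

#' Scatter coded comorbidity events over patient records
#'
#' For each patient and comorbidity category a latent flag is drawn
#' Bernoulli(prevalence), with control prevalences scaled by
#' `control_prevalence_scale`. Each present flag emits at least one clinical
#' event whose code is sampled uniformly from that category's code list and
#' whose date falls in `[registration_start, index_date)`; with
#' `recent_fraction` set, that share of events is instead placed within one
#' year of the index date, to exercise look-back sensitivity. The latent flag
#' matrix is returned alongside the events as ground truth for recovery
#' tests.
#'
#' @param patients Data frame of patient records (cases plus controls).
#' @param codelists Named list with `charlson` and `elixhauser` `codelist`
#'   objects (e.g. from [synthetic_codelists()]).
#' @param config A [generator_config()].
#' @param seed Integer seed for this stage.
#' @return List with `events` (data frame `patient_id`, `event_date`, `code`)
#'   and `flags` (logical matrix, one row per patient, columns
#'   `"measure:category"`).
#' @export
generate_comorbidity_events <- function(patients, codelists, config,
                                        seed = 1L) {
  stopifnot(inherits(config, "generator_config"),
            all(c("charlson", "elixhauser") %in% names(codelists)))
  n <- nrow(patients)
  cols <- c(paste0("charlson:", category_ids("charlson")),
            paste0("elixhauser:", category_ids("elixhauser")))
  flags <- matrix(FALSE, n, length(cols),
                  dimnames = list(patients$patient_id, cols))
  empty_events <- data.frame(patient_id = character(),
                             event_date = as.Date(character()),
                             code = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(list(events = empty_events, flags = flags))

  scale <- ifelse(patients$role == "control",
                  config$control_prevalence_scale, 1)
  with_seed(stage_seed(seed, "events"), {
    ev <- vector("list", length(cols))
    for (j in seq_along(cols)) {
      parts <- strsplit(cols[j], ":", fixed = TRUE)[[1]]
      measure <- parts[1]; cat_id <- parts[2]
      p <- config$prevalence[[measure]][[cat_id]] * scale
      hit <- stats::rbinom(n, 1L, p) == 1L
      flags[, j] <- hit
      if (!any(hit)) next
      codes <- codelists[[measure]]$entries$code[
        codelists[[measure]]$entries$category == cat_id]
      if (length(codes) == 0L) {
        stop("category ", measure, ":", cat_id,
             " has nonzero prevalence but an empty code list", call. = FALSE)
      }
      who <- which(hit)
      n_ev <- 1L + stats::rpois(length(who), config$events_per_flag - 1)
      pid <- rep(who, n_ev)
      lo <- as.numeric(patients$registration_start[pid])
      hi <- as.numeric(patients$index_date[pid])  # events strictly before index
      if (!is.null(config$recent_fraction)) {
        recent <- stats::runif(length(pid)) < config$recent_fraction
        lo[recent] <- pmax(lo[recent], hi[recent] - 365)
      }
      day <- floor(stats::runif(length(pid), lo, hi))
      ev[[j]] <- data.frame(
        patient_id = patients$patient_id[pid],
        event_date = as.Date(day, origin = "1970-01-01"),
        code = sample(codes, length(pid), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    ev <- ev[!vapply(ev, is.null, TRUE)]
    events <- if (length(ev)) do.call(rbind, ev) else empty_events
    events <- events[order(events$patient_id, events$event_date), ,
                     drop = FALSE]
    rownames(events) <- NULL
    list(events = events, flags = flags)
  })
}

#' Simulate 30- and 365-day mortality
#'
#' Death within 30 days of index is Bernoulli on the logistic scale with
#' linear predictor `intercept_30d + case_excess_30d * case + beta_age * age +
#' beta_sex * sex + sum(beta_category * flag)`; patients alive at day 30 face
#' the analogous 365-day model for death in the `(30, 365]` window. The death
#' date is placed uniformly within the realized window (day 0--30 or 31--365
#' after index, boundaries inclusive), and `registration_end` is truncated at
#' death. Ground-truth linear predictors are attached as attribute
#' `"linear_predictors"` for diagnostics.
#'
#' @param patients Data frame of patient records.
#' @param flags Latent flag matrix from [generate_comorbidity_events()].
#' @param config A [generator_config()].
#' @param seed Integer seed for this stage.
#' @return `patients` with `death_date` and `registration_end` updated.
#' @export
simulate_mortality <- function(patients, flags, config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"),
            nrow(patients) == nrow(flags))
  n <- nrow(patients)
  if (n == 0L) return(patients)
  beta <- config$beta_category
  common <- intersect(colnames(flags), names(beta))
  lp_com <- as.vector(flags[, common, drop = FALSE] %*% beta[common])
  is_case <- as.numeric(patients$role == "case")
  base <- config$beta_age * patients$age_at_index +
    config$beta_sex * patients$sex + lp_com
  if (config$misspecify) {
    base <- base + 0.03 * (patients$age_at_index - 82) * patients$sex
  }
  lp30 <- config$intercept_30d + config$case_excess_30d * is_case + base
  lp365 <- config$intercept_365d + config$case_excess_365d * is_case + base
  with_seed(stage_seed(seed, "mortality"), {
    d30 <- stats::runif(n) < stats::plogis(lp30)
    d365 <- !d30 & stats::runif(n) < stats::plogis(lp365)
    offset <- rep(NA_integer_, n)
    offset[d30] <- sample(0:30, sum(d30), replace = TRUE)
    offset[d365] <- sample(31:365, sum(d365), replace = TRUE)
    dead <- d30 | d365
    patients$death_date[dead] <- patients$index_date[dead] + offset[dead]
    patients$registration_end[dead] <- pmin(patients$registration_end[dead],
                                            patients$death_date[dead])
    attr(patients, "linear_predictors") <-
      data.frame(lp_30d = lp30, lp_365d = lp365)
    patients
  })
}

#' Simulate a complete case-control cohort
#'
#' End-to-end wrapper: cases, matched controls, coded comorbidity events and
#' mortality, each stage on its own seed stream derived from `seed`.
#'
#' @param config A [generator_config()].
#' @param codelists Named list of `charlson`/`elixhauser` code lists; defaults
#'   to [synthetic_codelists()].
#' @param seed Integer root seed. Identical `config` + `seed` reproduce a
#'   bit-identical cohort.
#' @return Object of class `cohort`: list with `patients`, `events`, `flags`
#'   (latent ground truth), `codelists`, `config`, `seed`.
#' @examples
#' coh <- simulate_cohort(generator_config(n_cases = 50), seed = 1)
#' table(coh$patients$role)
#' @export
simulate_cohort <- function(config = generator_config(),
                            codelists = synthetic_codelists(),
                            seed = 1L) {
  cases <- generate_cases(config, seed)
  controls <- match_controls(cases, config, seed)
  patients <- rbind(cases, controls)
  rownames(patients) <- NULL
  gen <- generate_comorbidity_events(patients, codelists, config, seed)
  patients <- simulate_mortality(patients, gen$flags, config, seed)
  structure(list(patients = patients, events = gen$events,
                 flags = gen$flags, codelists = codelists,
                 config = config, seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  p <- x$patients
  cat("<cohort>", sum(p$role == "case"), "cases,",
      sum(p$role == "control"), "controls;", nrow(x$events),
      "coded events\n")
  if (nrow(p)) {
    dead30 <- !is.na(p$death_date) & (p$death_date - p$index_date) <= 30
    cat("  30-day deaths:", sum(dead30 & p$role == "case"), "cases /",
        sum(dead30 & p$role == "control"), "controls\n")
  }
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes `patients.csv`, `events.csv` and
#' `flags_truth.csv` into `dir` with ISO-8601 dates; a missing death date is
#' an empty field, never a sentinel date. `read_cohort()` is its inverse and
#' validates every date field, naming the offending file, column and row on
#' failure. The round trip is lossless for the three tables.
#'
#' @param cohort A `cohort` object (or a list with `patients`, `events`,
#'   `flags`).
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a list with `patients`, `events` and `flags`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$patients
  for (col in c("registration_start", "registration_end", "death_date",
                "index_date")) {
    p[[col]] <- format(p[[col]], "%Y-%m-%d")
  }
  utils::write.csv(p, file.path(dir, "patients.csv"), row.names = FALSE,
                   na = "")
  e <- cohort$events
  e$event_date <- format(e$event_date, "%Y-%m-%d")
  utils::write.csv(e, file.path(dir, "events.csv"), row.names = FALSE)
  fl <- data.frame(patient_id = rownames(cohort$flags),
                   cohort$flags * 1L, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(fl, file.path(dir, "flags_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  p <- utils::read.csv(file.path(dir, "patients.csv"),
                       colClasses = "character")
  for (col in c("registration_start", "registration_end", "death_date",
                "index_date")) {
    p[[col]] <- parse_iso_date(p[[col]], "patients.csv", col)
  }
  p$sex <- as.integer(p$sex)
  p$year_of_birth <- as.integer(p$year_of_birth)
  p$age_at_index <- as.integer(p$age_at_index)
  p$matched_case_id[p$matched_case_id == ""] <- NA_character_
  e <- utils::read.csv(file.path(dir, "events.csv"),
                       colClasses = "character")
  e$event_date <- parse_iso_date(e$event_date, "events.csv", "event_date")
  fl <- utils::read.csv(file.path(dir, "flags_truth.csv"),
                        check.names = FALSE)
  flags <- as.matrix(fl[, -1, drop = FALSE]) == 1
  rownames(flags) <- fl$patient_id
  list(patients = p, events = e, flags = flags)
}

parse_iso_date <- function(x, file, col) {
  out <- as.Date(rep(NA, length(x)))
  filled <- !is.na(x) & x != ""
  parsed <- as.Date(x[filled], format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(filled)[which(is.na(parsed))[1]]
    stop("malformed date in ", file, ", column ", col, ", row ", bad, ": '",
         x[bad], "'", call. = FALSE)
  }
  out[filled] <- parsed
  out
}
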