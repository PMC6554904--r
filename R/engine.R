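#' Look-back windows
#'
#' The period before the index date within which recorded diagnoses count
#' toward comorbidity ascertainment: one year (365 days), five years (5 x 365
#' days), or the complete record (unbounded). Windows are half-open
#' `[index - W, index)`: an event on the index date itself (the fracture
#' admission) never contributes comorbidities.
#'
#' @param kind `"one_year"`, `"five_year"` or `"complete_record"`.
#' @return Object of class `lookback_window` with elements `kind` and `days`
#'   (`Inf` for the complete record).
#' @export
lookback_window <- function(kind = c("one_year", "five_year",
                                     "complete_record")) {
  kind <- match.arg(kind)
  days <- switch(kind, one_year = 365, five_year = 5 * 365,
                 complete_record = Inf)
  structure(list(kind = kind, days = days), class = "lookback_window")
}

as_lookback <- function(window) {
  if (inherits(window, "lookback_window")) window else lookback_window(window)
}

#' Flag comorbidity categories from one patient's coded events
#'
#' A category is flagged iff at least one event carries a code mapping to it
#' (exact, case-sensitive match against the code list) with
#' `index_date - W <= event_date < index_date`. One event suffices -- no
#' "two codes on separate dates" filter is applied. Codes absent from the
#' list are ignored: real records are dominated by non-comorbidity codes.
#'
#' @param events Data frame with `event_date` and `code` for a single patient.
#' @param codelist A `codelist`.
#' @param index_date The patient's reference date.
#' @param window A [lookback_window()] or its `kind` string.
#' @return Named logical vector over the measure's categories in canonical
#'   order, with attribute `measure`.
#' @export
flag_comorbidities <- function(events, codelist, index_date,
                               window = "complete_record") {
  stopifnot(inherits(codelist, "codelist"))
  window <- as_lookback(window)
  ids <- category_ids(codelist$measure)
  flags <- stats::setNames(logical(length(ids)), ids)
  if (nrow(events)) {
    keep <- events$event_date < index_date &
      (is.infinite(window$days) |
         events$event_date >= index_date - window$days)
    codes <- trimws(events$code[keep])
    hit <- codelist$entries$category[codelist$entries$code %in% codes]
    flags[unique(hit)] <- TRUE
  }
  attr(flags, "measure") <- codelist$measure
  flags
}

#' Apply severity hierarchy rules to category flags
#'
#' For each rule whose severe category is flagged, the superseded category is
#' cleared. Idempotent; an empty rule set is the identity.
#'
#' @param flags Named logical vector (or logical matrix with named columns)
#'   of category flags.
#' @param rules Data frame with columns `severe` and `superseded`, e.g. from
#'   [default_hierarchy()].
#' @return `flags` with superseded categories cleared.
#' @export
apply_hierarchy <- function(flags, rules) {
  if (is.null(rules) || nrow(rules) == 0L) return(flags)
  if (is.matrix(flags)) {
    for (i in seq_len(nrow(rules))) {
      sev <- rules$severe[i]; sup <- rules$superseded[i]
      if (sev %in% colnames(flags) && sup %in% colnames(flags)) {
        flags[flags[, sev], sup] <- FALSE
      }
    }
  } else {
    for (i in seq_len(nrow(rules))) {
      sev <- rules$severe[i]; sup <- rules$superseded[i]
      if (!is.na(flags[sev]) && !is.na(flags[sup]) && flags[sev]) {
        flags[sup] <- FALSE
      }
    }
  }
  flags
}

#' Charlson comorbidity index from category flags
#'
#' Sum of category weights over flagged categories, under the original
#' weights (1--6) or the Quan 12-item re-weighting. No age points are added:
#' age enters the validation models as a separate continuous covariable.
#' Flags should be hierarchy-resolved first (see [apply_hierarchy()]).
#'
#' @param flags Named logical vector over the 17 charlson categories.
#' @param weight_scheme `"original"` or `"quan"`.
#' @return Integer index value.
#' @examples
#' f <- stats::setNames(logical(17), category_registry("charlson")$category)
#' f["pvd"] <- TRUE
#' charlson_index(f)                      # 1
#' f[] <- FALSE; f["mets"] <- TRUE
#' charlson_index(f)                      # 6
#' @export
charlson_index <- function(flags, weight_scheme = c("original", "quan")) {
  weight_scheme <- match.arg(weight_scheme)
  reg <- category_registry("charlson")
  w <- if (weight_scheme == "original") reg$weight_original else
    reg$weight_quan
  stopifnot(all(reg$category %in% names(flags)))
  as.integer(sum(w[flags[reg$category]]))
}

#' Elixhauser category profile
#'
#' The Elixhauser method does not weight its categories into one score; this
#' returns the 31-element binary vector in canonical registry order plus the
#' category count used for descriptive tables.
#'
#' @param flags Named logical vector over the 31 elixhauser categories.
#' @return List with `vector` (named 0/1 integer vector, canonical order) and
#'   `count`.
#' @export
elixhauser_profile <- function(flags) {
  ids <- category_ids("elixhauser")
  stopifnot(all(ids %in% names(flags)))
  v <- stats::setNames(as.integer(flags[ids]), ids)
  list(vector = v, count = sum(v))
}

#' Compute comorbidity profiles for a whole cohort
#'
#' Vectorised scoring: converts every patient's dated coded events into
#' hierarchy-resolved category flags under a look-back window, then into the
#' Charlson index (original and Quan weights) and the Elixhauser category
#' count. Deterministic: no randomness anywhere in this stage.
#'
#' @param patients Data frame of patient records (needs `patient_id`,
#'   `index_date`); a `cohort` object is also accepted.
#' @param events Data frame of coded events (`patient_id`, `event_date`,
#'   `code`); ignored when `patients` is a `cohort`.
#' @param codelists Named list with `charlson` and `elixhauser` code lists;
#'   ignored when `patients` is a `cohort`.
#' @param window A [lookback_window()] or its `kind` string.
#' @param hierarchy `TRUE` for [default_hierarchy()] rules, `FALSE`/`NULL`
#'   for none, or a named list of rule data frames per measure.
#' @return Object of class `comorbidity_profiles`: a data frame with
#'   `patient_id`, one logical column per category (named
#'   `charlson_<id>` / `elixhauser_<id>`), `cci_original`, `cci_quan`,
#'   `em_count`; the window is attached as attribute `"window"`.
#' @export
comorbidity_profiles <- function(patients, events = NULL, codelists = NULL,
                                 window = "complete_record",
                                 hierarchy = TRUE) {
  if (inherits(patients, "cohort")) {
    events <- patients$events
    codelists <- patients$codelists
    patients <- patients$patients
  }
  window <- as_lookback(window)
  rules <- hierarchy_rules(hierarchy)
  n <- nrow(patients)
  out <- data.frame(patient_id = patients$patient_id,
                    stringsAsFactors = FALSE)
  flag_blocks <- list()
  for (measure in c("charlson", "elixhauser")) {
    ids <- category_ids(measure)
    m <- matrix(FALSE, n, length(ids),
                dimnames = list(patients$patient_id, ids))
    if (nrow(events) && n > 0L) {
      entries <- codelists[[measure]]$entries
      hits <- merge(events, entries[, c("code", "category")], by = "code")
      if (nrow(hits)) {
        row <- match(hits$patient_id, patients$patient_id)
        ok <- !is.na(row)
        hits <- hits[ok, , drop = FALSE]; row <- row[ok]
        idx <- patients$index_date[row]
        keep <- hits$event_date < idx &
          (is.infinite(window$days) | hits$event_date >= idx - window$days)
        m[cbind(row[keep], match(hits$category[keep], ids))] <- TRUE
      }
    }
    m <- apply_hierarchy(m, rules[[measure]])
    flag_blocks[[measure]] <- m
  }
  ch <- flag_blocks$charlson
  reg <- category_registry("charlson")
  out$cci_original <- as.integer(ch %*% reg$weight_original)
  out$cci_quan <- as.integer(ch %*% reg$weight_quan)
  out$em_count <- as.integer(rowSums(flag_blocks$elixhauser))
  for (measure in c("charlson", "elixhauser")) {
    block <- as.data.frame(flag_blocks[[measure]])
    names(block) <- paste0(measure, "_", names(block))
    out <- cbind(out, block)
  }
  rownames(out) <- NULL
  structure(out, window = window$kind, class = c("comorbidity_profiles",
                                                 "data.frame"))
}

hierarchy_rules <- function(hierarchy) {
  if (isTRUE(hierarchy)) {
    list(charlson = default_hierarchy("charlson"),
         elixhauser = default_hierarchy("elixhauser"))
  } else if (is.list(hierarchy) && !is.data.frame(hierarchy)) {
    hierarchy
  } else {
    list(charlson = NULL, elixhauser = NULL)
  }
}

#' Extract a measure's flag matrix from a profiles table
#'
#' @param profiles A `comorbidity_profiles` data frame.
#' @param measure `"charlson"` or `"elixhauser"`.
#' @return Logical matrix, one row per patient, columns the category ids.
#' @export
profile_flags <- function(profiles, measure = c("charlson", "elixhauser")) {
  measure <- match.arg(measure)
  ids <- category_ids(measure)
  m <- as.matrix(profiles[paste0(measure, "_", ids)])
  colnames(m) <- ids
  rownames(m) <- profiles$patient_id
  m
}

#' Distribution of comorbidity counts, binned as in descriptive tables
#'
#' Tabulates the proportion of patients falling into comorbidity-count bins
#' 0, 1, 2, 3, 4, 5 and `>6`, split by cohort role (cases vs controls). The
#' published table's labels have no bin for exactly 6; by default counts of 6
#' are assigned to the `>6` bin so the partition is exhaustive. Pass
#' different `bin_edges` to change the binning.
#'
#' @param profiles A `comorbidity_profiles` data frame.
#' @param patients Patient table carrying `patient_id` and `role` (or a
#'   `cohort`).
#' @param measure `"charlson"` (counts distinct flagged CCI categories) or
#'   `"elixhauser"` (the EM count).
#' @param bin_edges Increasing integer vector of exact-count bins; everything
#'   above the last edge falls into the terminal `>` bin.
#' @return Matrix of proportions (rows = bins, columns = roles); each column
#'   sums to 1.
#' @export
count_distribution <- function(profiles, patients,
                               measure = c("charlson", "elixhauser"),
                               bin_edges = 0:5) {
  measure <- match.arg(measure)
  if (inherits(patients, "cohort")) patients <- patients$patients
  if (nrow(profiles) == 0L) stop("empty profile set", call. = FALSE)
  counts <- if (measure == "charlson") {
    rowSums(profile_flags(profiles, "charlson"))
  } else {
    profiles$em_count
  }
  role <- patients$role[match(profiles$patient_id, patients$patient_id)]
  labels <- c(as.character(bin_edges),
              paste0(">", max(bin_edges) + 1))
  binned <- ifelse(counts > max(bin_edges), labels[length(labels)],
                   as.character(counts))
  binned <- factor(binned, levels = labels)
  tab <- table(binned, role)
  prop.table(tab, margin = 2)
}
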