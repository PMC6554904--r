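#' Synthetic Read-style code lists
#'
#' Published Read-code lists for the Charlson and Elixhauser measures contain
#' 5832 and 7156 entries respectively, but real code lists derive from a
#' restricted terminology dictionary and are too large to ship as fixtures.
#' This generator deterministically fabricates *synthetic* stand-ins with the
#' same structure: one CSV-shaped table per measure with `code`, `term` and
#' `category` columns, category sizes roughly proportional to how many
#' terminology codes each disease area attracts, and opaque case-sensitive
#' five-character tokens in place of real Read codes.
#'
#' Every synthetic code is unique within its measure (no cross-category
#' codes), so an event coded from one category can be attributed back to
#' exactly that category -- the property the cohort simulator's round-trip
#' tests rely on. The output is a pure function of the arguments; no random
#' number generator is consumed.
#'
#' @param n_charlson,n_elixhauser Total number of entries per measure.
#'   Defaults are the sizes of the published lists.
#' @return Named list of two `codelist` objects (`charlson`, `elixhauser`).
#' @examples
#' cl <- synthetic_codelists()
#' nrow(cl$charlson$entries)    # 5832
#' nrow(cl$elixhauser$entries)  # 7156
#' @export
synthetic_codelists <- function(n_charlson = 5832, n_elixhauser = 7156) {
  list(
    charlson   = synthetic_codelist("charlson", n_charlson),
    elixhauser = synthetic_codelist("elixhauser", n_elixhauser)
  )
}

# Relative list sizes per category: cancer and cardiovascular chapters of a
# clinical terminology carry many more distinct codes than e.g. HIV.
.codelist_size_weights <- list(
  charlson = c(
    mi = 2, chf = 2, pvd = 3, cevd = 4, dementia = 2, copd = 5, rheum = 4,
    pud = 2, mild_liver = 3, diab = 4, diab_comp = 3, hemiplegia = 2,
    renal = 4, cancer = 18, severe_liver = 2, mets = 4, hiv = 1),
  elixhauser = c(
    chf = 2, arrhythmia = 3, valvular = 3, pulm_circ = 1, pvd = 3,
    htn_unc = 1, htn_comp = 1, paralysis = 2, neuro_other = 5, copd = 5,
    diab_unc = 3, diab_comp = 3, hypothyroid = 1, renal_failure = 3,
    liver = 4, pud_no_bleed = 2, hiv = 1, lymphoma = 4, mets = 4,
    solid_tumour = 16, rheum_arth = 4, coagulopathy = 2, obesity = 1,
    weight_loss = 1, fluid_electrolyte = 2, blood_loss_anaemia = 1,
    deficiency_anaemia = 2, alcohol = 2, drug_abuse = 2, psychoses = 3,
    depression = 3)
)

synthetic_codelist <- function(measure, n_total) {
  stopifnot(n_total >= 0)
  registry <- category_registry(measure)
  w <- .codelist_size_weights[[measure]][registry$category]
  n_per <- largest_remainder(n_total, w / sum(w))
  serial <- 0L
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    n <- n_per[i]
    if (n == 0L) return(NULL)
    idx <- serial + seq_len(n)
    serial <<- serial + n
    data.frame(
      code = paste0(substr(toupper(measure), 1, 1),
                    vapply(idx, encode_base62, "", width = 3L), "."),
      term = paste0(registry$display_name[i], ", synthetic term ",
                    seq_len(n)),
      category = registry$category[i],
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    rows <- list(data.frame(code = character(), term = character(),
                            category = character(), stringsAsFactors = FALSE))
  }
  new_codelist(do.call(rbind, rows), measure,
               source = paste0("<synthetic ", measure, ">"))
}

# apportion n among fractions summing to 1, exactly (largest remainder)
largest_remainder <- function(n, frac) {
  raw <- n * frac
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    top <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

.base62 <- c(0:9, LETTERS, letters)
encode_base62 <- function(x, width = 3L) {
  digits <- character(width)
  for (i in seq_len(width)) {
    digits[width - i + 1L] <- .base62[(x %% 62L) + 1L]
    x <- x %/% 62L
  }
  paste(digits, collapse = "")
}
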